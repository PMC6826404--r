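lncrna_id	mirna_id	mrna_id
TCONS_00026544	gga-miR-128-1-5p	RASD1
TCONS_00057272	gga-miR-146a-3p	FOXO6
TCONS_00057242	gga-miR-6615-3p	FOXO6
TCONS_00057242	gga-miR-6615-3p	ENSGALT00000043224
TCONS_00040913	gga-miR-6615-3p	ENSGALT00000043224
TCONS_00040913	gga-miR-6615-3p	ENSGALT00000050730
TCONS_00038747	gga-miR-6615-3p	ENSGALT00000050730
TCONS_00038748	gga-miR-6615-3p	ENSGALT00000050730
TCONS_00055280	gga-miR-135a-5p	JAM3
TCONS_00055280	gga-miR-135a-5p	GPR133
TCONS_00055280	gga-miR-135a-5p	CLDN1
TCONS_00055280	gga-miR-135a-5p	TMEM123
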