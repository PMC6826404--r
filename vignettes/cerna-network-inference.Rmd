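---
title: "Inferring lncRNA-associated ceRNA networks with cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-associated ceRNA networks with cernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Competing-endogenous-RNA (ceRNA) regulation is the hypothesis that two
transcripts — here a lncRNA and an mRNA — can regulate each other
indirectly by competing for a shared pool of miRNAs. A lncRNA acting as
a *sponge* sequesters a miRNA and thereby de-represses that miRNA's
mRNA targets. The observable signature in expression data from two
contrasted conditions (here: undifferentiated vs differentiated chicken
preadipocytes, three biological replicates each) is

1. all three transcripts respond to the contrast (differential
   expression),
2. the miRNA is anti-correlated with both the lncRNA and the mRNA,
3. the lncRNA and the mRNA are positively co-expressed, and
4. the lncRNA and the mRNA share *more* target miRNAs than expected by
   chance.

`cernet` operationalizes this as a filter cascade:

* **Normalization.** lncRNA/mRNA counts to FPKM,
  $10^9 C / (N L)$ with $C$ the count, $N$ the per-sample column
  total and $L$ the annotated transcript length; miRNA tag counts to
  TPM, $C/N \times 10^6$. The FPKM constant follows directly from the
  definition of "per kilobase per million": commonly-quoted renderings
  of the formula collapse the exponents typographically, but the symbol
  definitions fix it unambiguously. $N$ is taken from the supplied
  matrix because upstream alignment is out of scope; annotated (not
  effective) length is used.
* **Differential expression.** Genes with FDR < 0.05 and
  |log2FC| > 1 (strict inequalities) define the DEL/DEMi/DEM sets, with
  BH correction run separately within each biotype matrix, mirroring
  three independent experiments.
* **Correlation filters.** Spearman correlation across all six samples
  (both groups pooled — with three replicates per group, within-group
  rank correlation is meaningless at these thresholds). Predicted
  miRNA–target pairs are kept when SCC < −0.7; DEL×DEM pairs are kept
  when SCC > 0.9. All comparisons strict.
* **Shared-miRNA test.** For each co-expressed lncRNA–mRNA pair, with
  $M$ and $N$ the correlation-passed target-miRNA counts of the lncRNA
  and mRNA, $n$ their overlap, and $U$ the miRNA universe, the
  upper-tail hypergeometric probability
  $p = 1 - \sum_{i=0}^{n-1} \binom{M}{i}\binom{U-M}{N-i} / \binom{U}{N}$
  is computed by direct log-space summation of the upper tail. Pairs
  with $p < 0.05$ (raw, no multiple-testing correction by default — a
  BH option exists) yield one triple per shared miRNA.
* **Network.** Accepted triples form a tripartite graph with two edge
  classes (lncRNA–miRNA, miRNA–mRNA); no direct lncRNA–mRNA edges.
  Degree is counted on the deduplicated edge set; hubs are nodes with
  degree strictly above the network average, which is always recomputed
  from the network at hand (a published average like 4.9 is a property
  of that study's network, not a constant). Crucial interactions are
  triples whose miRNA is literature-flagged or simultaneously
  high-degree and high-expressed (mean TPM across all samples > 4.5).
* **Enrichment.** Over-representation of the network's mRNAs in
  user-supplied gene sets (GMT), using the same hypergeometric core
  with background defaulting to all genes tested for differential
  expression in that biotype. Gating is on raw p < 0.05 to match the
  original workflow; the BH FDR is reported alongside and users may
  gate on it instead.

## Choice of the differential-expression test

The package deliberately does not re-implement a count-based NB testing
framework. The test operates on log2(normalized expression + 1) behind a
pluggable interface with two backends. The default is a **moderated t**
(empirical-Bayes linear model with an intensity-trend variance prior,
via limma). The alternative `"welch"` backend is a per-gene Welch
t-test. The default matters: with three replicates per group a per-gene
test has ~4 degrees of freedom, and after BH correction its power to
call a 4-fold change at NB dispersion 0.05–0.1 is of the order of a few
percent — essentially every planted gene in our simulations is missed.
Sharing variance information across genes restores near-complete power
at the same false-positive level, which is also why moderated tests are
the field's standard at this replication level. The reported log2FC is
always `log2((mean_case + 1)/(mean_ctrl + 1))` on the normalized scale;
the pseudocount of 1 stabilizes ratios at low expression and is
configurable.

## What the simulator emulates

`generate_dataset()` produces the study design in miniature: two
conditions × 3 replicates; negative-binomial counts
(`NB(mu, size = 1/dispersion)`, default dispersion 0.1 — a typical
within-condition biological variability for this design); per-gene
baseline means log-normal around 200 (sdlog 0.5); per-sample relative
depth factors uniform in [0.85, 1.15] (three matrices share samples but
not library preparations, so depth is modelled as a relative factor and
realized library sizes are recorded in the truth sidecar); transcript
lengths uniform in 300–3000 bp for lncRNA/mRNA, none for miRNA.

Planted differential expression moves group means `de_log2fc` (default
2) log2 units apart, **split symmetrically around the baseline**
(±de/2 per group). A one-sided shift would inflate the shifted group's
library total and, under total-count normalization, systematically
deflate every planted fold change by several tenths of a log2 unit —
the familiar composition bias. The symmetric split keeps composition
balanced without changing the between-group fold change.

Planted ceRNA triples additionally share a per-sample latent state
through a Gaussian copula on the NB marginals: the lncRNA and mRNA load
positively on it, the miRNA negatively. The default coupling is 1
(comonotone). This is a deliberate idealization: with six samples,
Spearman > 0.9 tolerates at most a single adjacent rank swap, and group
shifts alone cannot get there — with independent within-group noise and
even *perfect* group separation, enumeration over rank permutations
gives P(SCC > 0.9) = 5/36 for the lncRNA–mRNA pair and
P(SCC ≤ −0.7) = 27/36 for miRNA–target pairs. A planted triple is meant
to *be* a ceRNA by the workflow's own operational definition, so its
members are coupled tightly enough to carry that signature; the
`triple_coupling` parameter lets users weaken it (at 0.99 only ~95% of
planted triples survive all three correlation filters; realistic
partial coupling is an interesting stress test, not a default).

Decoy interactions — uniformly random miRNA→(non-triple target) edges,
5 per miRNA by default — are what the correlation filters must reject.
Extra DE genes (30 per biotype by default, random direction) make the
DE sets realistic and give decoys a chance to survive the DE gate.

What the simulator does **not** emulate: read-level data, alignment
artifacts, sequence-driven MRE biology (a minimal 7-mer seed-match
predictor exists purely to exercise the pipeline on synthetic
sequences), between-sample normalization pathologies, batch effects, or
partial/weak sponge coupling. Passing tests on this generator therefore
demonstrate correctness of the inference machinery under its own model,
not performance on real tissue data.

## Numerical and degenerate-input choices

* The hypergeometric tail is summed directly over `n..min(M,N)` in log
  space (`lchoose`), which is exact to ~1e-15 against exhaustive
  enumeration for all universes up to 12 and stable for small p.
* Spearman correlation of a constant vector is an error, never a silent
  0 or NA at the API surface; inside the pair filters an undefined
  correlation marks the pair "not passed" with a warning (such pairs
  cannot demonstrate co-expression).
* All-zero sample columns make library size undefined and are rejected.
* `U` (the miRNA universe) defaults to the distinct miRNAs entering the
  correlation-filtered interaction set — the DE miRNAs that drive the
  analysis — and can be overridden with the full annotated complement.
  `M` and `N` are counted on correlation-passed interactions, not raw
  predictions, because the screening happens before the test.
* Triples are deduplicated before network construction; exports are
  lexicographically ordered so repeated runs are byte-identical.
* Empty intermediate results (no DE genes, no passed pairs) propagate
  as empty tables with warnings rather than errors, so the pipeline
  completes and writes a well-formed manifest.

## Problem sizes used in the test-suite

Structural tests run on 40/20/60-gene datasets; recovery claims use the
full generator defaults (200 lncRNAs, 100 miRNAs, 500 mRNAs, 20 planted
triples) over ten seeds, which completes in seconds. The oracle sweep
covers every hypergeometric parameter combination with U ≤ 12
(3184 cases) and one thousand random Spearman vectors.

## Known limitations

* DE calling is not count-based; exact agreement with edgeR/DESeq2
  results is neither expected nor claimed.
* The hypergeometric p is a pair-level quantity replicated onto each of
  the pair's triples, and the raw-p gate (no correction) follows the
  original workflow; both are configurable but defaults reproduce the
  published procedure.
* With three replicates per group, |log2FC| estimates have a standard
  error of roughly 0.4 log2 units at these settings, so planted genes
  with true effect 2 occasionally land under the >1 gate; end-to-end
  sensitivity for planted triples is ~95%, not 100%.
* Merging of multiple MRE prediction tools is assumed done upstream;
  the interaction file is taken as the merged set.
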