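single_triple <- data.frame(lncrna_id = "l1", mirna_id = "mi1",
                            mrna_id = "g1")

test_that("a single triple gives the closed-form network", {
  net <- build_network(single_triple)
  expect_identical(nrow(net$nodes), 3L)
  expect_identical(nrow(net$edges), 2L)
  expect_equal(net$avg_degree, 4 / 3)
  deg <- setNames(net$nodes$degree, net$nodes$id)
  expect_equal(deg[["mi1"]], 2L)
  expect_equal(deg[["l1"]], 1L)
  expect_identical(identify_hubs(net), "mi1")  # 2 > 4/3
})

test_that("duplicated triples build the identical network", {
  net1 <- build_network(single_triple)
  net2 <- build_network(rbind(single_triple, single_triple))
  expect_identical(net1$nodes, net2$nodes)
  expect_identical(net1$edges, net2$edges)
  expect_equal(net1$avg_degree, net2$avg_degree)
})

test_that("network construction is invariant under triple order", {
  tr <- chicken_crucial_triples()
  net1 <- build_network(tr)
  net2 <- build_network(tr[rev(seq_len(nrow(tr))), ])
  expect_identical(net1$nodes, net2$nodes)
  expect_identical(net1$edges, net2$edges)
  expect_identical(summarize_network(net1)[-7],
                   summarize_network(net2)[-7])
})

test_that("the crucial-interaction fixture reproduces its printed census", {
  tr <- chicken_crucial_triples()
  net <- build_network(tr)
  s <- summarize_network(net)
  expect_identical(s$n_triples, 12L)
  expect_identical(s$n_lncrna, 7L)
  expect_identical(s$n_mirna, 4L)
  # the printed table holds 8 distinct mRNAs (FOXO6 and the two ENSGALT
  # transcripts are shared across triples but distinct from each other)
  expect_identical(s$n_mrna, 8L)
  deg <- setNames(net$nodes$degree, net$nodes$id)
  # gga-miR-6615-3p: 4 lncRNA neighbours + 3 mRNA neighbours
  expect_identical(deg[["gga-miR-6615-3p"]], 7L)
  expect_identical(s$n_edges, 16L)
  expect_equal(s$avg_degree, 2 * 16 / 19)
  expect_equal(sum(net$nodes$degree), 2L * s$n_edges)
})

test_that("hub selection uses a strict cutoff at the recomputed average", {
  tr <- chicken_crucial_triples()
  net <- build_network(tr)
  manual <- sort(net$nodes$id[net$nodes$degree > 32 / 19])
  expect_identical(identify_hubs(net), manual)
  expect_true("gga-miR-6615-3p" %in% manual)
  expect_false(any(net$nodes$degree[net$nodes$id %in% manual] <= net$avg_degree))
  # a 1-regular graph (degree == avg everywhere) has no hubs
  reg <- build_network(data.frame(lncrna_id = c("l1", "l2"),
                                  mirna_id = c("mi1", "mi2"),
                                  mrna_id = c("g1", "g2")))
  expect_identical(nrow(reg$edges), 4L)
  # force the all-degrees-equal case directly: no hubs under strict ">"
  deg_eq <- data.frame(id = c("a", "b"), biotype = c("lncRNA", "miRNA"),
                       degree = c(1L, 1L))
  fake <- structure(list(nodes = deg_eq,
                         edges = data.frame(from = "a", to = "b",
                                            type = "lnc_mi"),
                         avg_degree = 1,
                         triples = single_triple[0, ]),
                    class = "cerna_network")
  expect_identical(identify_hubs(fake), character(0))
})

test_that("flagging the four study miRNAs selects all twelve crucial triples", {
  tr <- chicken_crucial_triples()
  net <- build_network(tr)
  tpm_mat <- matrix(1, nrow = 4, ncol = 6,
                    dimnames = list(chicken_flagged_mirnas(),
                                    paste0("s", 1:6)))
  sel <- select_crucial(net, tpm_mat, chicken_flagged_mirnas())
  expect_identical(nrow(sel$crucial_triples), 12L)
  expect_setequal(sel$flagged_mirnas, chicken_flagged_mirnas())
})

test_that("automatic crucial selection requires both degree and expression", {
  tr <- chicken_crucial_triples()
  net <- build_network(tr)
  mi <- net$nodes$id[net$nodes$biotype == "miRNA"]
  # all TPM below threshold: nothing auto-selected, no flags -> empty
  low <- matrix(1, nrow = length(mi), ncol = 6,
                dimnames = list(mi, paste0("s", 1:6)))
  sel <- select_crucial(net, low)
  expect_identical(nrow(sel$crucial_triples), 0L)
  expect_identical(sel$auto_mirnas, character(0))
  # one miRNA high-TPM and high-degree -> exactly its triples
  high <- low
  high["gga-miR-6615-3p", ] <- 100
  sel2 <- select_crucial(net, high)
  expect_identical(sel2$auto_mirnas, "gga-miR-6615-3p")
  expect_identical(nrow(sel2$crucial_triples),
                   sum(tr$mirna_id == "gga-miR-6615-3p"))
  # mean TPM exactly at the threshold is excluded (strict)
  edge <- low
  edge["gga-miR-6615-3p", ] <- 4.5
  sel3 <- select_crucial(net, edge)
  expect_identical(sel3$auto_mirnas, character(0))
})

test_that("unknown flagged miRNAs are ignored with a warning", {
  net <- build_network(single_triple)
  tpm_mat <- matrix(1, 1, 3, dimnames = list("mi1", paste0("s", 1:3)))
  expect_warning(sel <- select_crucial(net, tpm_mat, c("mi1", "nope")),
                 "nope")
  expect_identical(sel$flagged_mirnas, "mi1")
})

test_that("SIF export round-trips the network and is deterministic", {
  tr <- chicken_crucial_triples()
  net <- build_network(tr)
  d1 <- tempfile("net"); d2 <- tempfile("net")
  p1 <- export_network(net, d1)
  p2 <- export_network(net, d2)
  expect_identical(readLines(p1["sif"]), readLines(p2["sif"]))
  expect_identical(length(readLines(p1["sif"])), 16L)
  back <- read_sif(p1["sif"])
  expect_identical(back$edges, net$edges)
  expect_identical(back$nodes, net$nodes)
  expect_equal(back$avg_degree, net$avg_degree)
  # single triple -> 2 SIF lines
  expect_identical(length(readLines(export_network(
    build_network(single_triple), tempfile())["sif"])), 2L)
  expect_error(export_network(net, tempfile(), formats = "gml"), "gml")
})

test_that("an empty triple set warns and yields an empty network", {
  expect_warning(net <- build_network(single_triple[0, ]), "empty")
  s <- summarize_network(net)
  expect_identical(s$n_nodes, 0L)
  expect_identical(s$n_triples, 0L)
  expect_identical(identify_hubs(net), character(0))
})
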