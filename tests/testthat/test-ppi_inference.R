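set1 <- gene_set(c("S1", "S2", "S3", "SB"), "D1")
set2 <- gene_set(c("T1", "T2", "SB"), "D2")

test_that("network annotation classes nodes and drops unmapped proteins", {
  g <- toy_ppi(data.frame(a = c("C", "C", "S1"),
                          b = c("S1", "T1", "S2")))
  expect_message(net <- annotate_network(g, set1, set2), "dropped")
  cls <- setNames(igraph::V(net)$node_class, igraph::V(net)$name)
  expect_identical(unname(cls["C"]), "NEIGHBOR")
  expect_identical(unname(cls["S1"]), "SUS1")
  expect_identical(unname(cls["T1"]), "SUS2")
  # SB and T2 never map: 3 of 6 susceptibility proteins absent
  expect_equal(igraph::graph_attr(net, "n_unmapped"), 3L)

  gb <- toy_ppi(data.frame(a = "SB", b = "X"))
  netb <- suppressMessages(annotate_network(gb, set1, set2))
  clsb <- setNames(igraph::V(netb)$node_class, igraph::V(netb)$name)
  expect_identical(unname(clsb["SB"]), "SUS_BOTH")

  g0 <- toy_ppi(data.frame(a = "X", b = "Y"))
  expect_error(annotate_network(g0, set1, set2), "no susceptibility protein")
})

test_that("non-susceptibility nodes outside the first-neighbour shell are cut", {
  g <- toy_ppi(data.frame(a = c("S1", "N1", "far"),
                          b = c("N1", "far", "far2")))
  net <- suppressMessages(annotate_network(g, set1, set2))
  expect_setequal(igraph::V(net)$name, c("S1", "N1"))
})

test_that("candidate inference applies the dual-disease partner rule", {
  # N1 touches {S1, S2, T1}; N2 touches {S1} only
  g <- toy_ppi(data.frame(a = c("N1", "N1", "N1", "N2"),
                          b = c("S1", "S2", "T1", "S1")))
  net <- suppressMessages(annotate_network(g, set1, set2))
  cand <- infer_candidates(net)
  expect_identical(cand$protein, "N1")
  expect_equal(cand$deg1, 2L)
  expect_equal(cand$deg2, 1L)
  expect_false(cand$is_hub)
  # the stricter >= 2-each reading excludes N1 too
  expect_equal(nrow(infer_candidates(net, min_each = 2)), 0L)
  expect_error(infer_candidates(net, min_each = 0), "min_each")
})

test_that("shared susceptibility partners count toward both diseases", {
  g <- toy_ppi(data.frame(a = c("N1", "S1"), b = c("SB", "SB")))
  net <- suppressMessages(annotate_network(g, set1, set2))
  cand <- infer_candidates(net)
  expect_equal(cand$deg1, 1L)
  expect_equal(cand$deg2, 1L)
})

test_that("hub detection is boundary-inclusive at h partners of each disease", {
  cand <- data.frame(protein = c("H", "A", "B"),
                     deg1 = c(5L, 5L, 4L), deg2 = c(5L, 4L, 9L),
                     is_hub = FALSE)
  hubs <- detect_hubs(cand, h = 5)
  expect_identical(hubs$protein, "H")
  expect_true(all(hubs$is_hub))
  expect_equal(nrow(detect_hubs(cand, h = 6)), 0L)
  expect_error(detect_hubs(cand, h = 0), "'h'")
})

test_that("hubs are always a subset of candidates", {
  set.seed(31)
  for (i in 1:10) {
    tr <- generate_synthetic(synthetic_config(seed = 100 + i, n_decoys = 60,
                                              n_sus_edges = 40),
                             tempfile())
    g1 <- read_gene_list(tr$files$cluster1, "D1")
    g2 <- read_gene_list(tr$files$cluster2, "D2")
    net <- suppressMessages(
      annotate_network(read_ppi_table(tr$files$ppi), g1, g2))
    cand <- infer_candidates(net)
    for (h in c(1, 3, 5, 8)) {
      expect_true(all(detect_hubs(cand, h)$protein %in% cand$protein))
    }
  }
})

test_that("sub-network extraction uses induced-subgraph semantics", {
  g <- toy_ppi(data.frame(a = c("N1", "N1", "N1"),
                          b = c("S1", "S2", "T1")))
  net <- suppressMessages(annotate_network(g, set1, set2))
  sub <- extract_subnetwork(net, infer_candidates(net))
  expect_equal(igraph::vcount(sub), 4L)
  expect_equal(igraph::ecount(sub), 3L)

  # two candidates sharing a partner: partner appears once; the
  # candidate-candidate edge survives induced-subgraph semantics
  g2 <- toy_ppi(data.frame(a = c("N1", "N1", "N2", "N2", "N1", "S3"),
                           b = c("S1", "T1", "S1", "T2", "N2", "X")))
  net2 <- suppressMessages(annotate_network(g2, set1, set2))
  cand2 <- infer_candidates(net2)
  expect_setequal(cand2$protein, c("N1", "N2"))
  sub2 <- extract_subnetwork(net2, cand2)
  expect_setequal(igraph::V(sub2)$name, c("N1", "N2", "S1", "T1", "T2"))
  expect_equal(igraph::ecount(sub2), 5L)  # 4 bipartite + 1 cand-cand
  expect_gte(igraph::ecount(sub2), 4L)    # >= candidate-partner adjacencies

  expect_error(extract_subnetwork(net2, cand2[0, ]), "empty")
  expect_error(extract_subnetwork(net2,
                                  data.frame(protein = "S1", deg1 = 1,
                                             deg2 = 1, is_hub = FALSE)),
               "NEIGHBOR")
})

test_that("partner census aggregates match a brute-force recount", {
  tr <- generate_synthetic(synthetic_config(seed = 77, n_decoys = 80),
                           tempfile())
  g1 <- read_gene_list(tr$files$cluster1, "D1")
  g2 <- read_gene_list(tr$files$cluster2, "D2")
  ppi <- read_ppi_table(tr$files$ppi)
  net <- suppressMessages(annotate_network(ppi, g1, g2))
  cen <- partner_census(net)

  # independent recount straight from the adjacency structure
  cls <- setNames(igraph::V(net)$node_class, igraph::V(net)$name)
  nb <- names(cls)[cls == "NEIGHBOR"]
  d1 <- d2 <- setNames(integer(length(nb)), nb)
  for (v in nb) {
    pp <- igraph::neighbors(net, v)$name
    d1[v] <- sum(cls[pp] %in% c("SUS1", "SUS_BOTH"))
    d2[v] <- sum(cls[pp] %in% c("SUS2", "SUS_BOTH"))
  }
  want <- c(sum(d1 >= 1), sum(d1 >= 2), sum(d2 >= 1), sum(d2 >= 2),
            sum(d1 >= 1 & d2 >= 1))
  expect_equal(cen$summary$count, want)
  ord <- match(cen$neighbors$protein, nb)
  expect_equal(cen$neighbors$deg1, unname(d1[ord]))
  expect_equal(cen$neighbors$deg2, unname(d2[ord]))
})

test_that("candidate inference is invariant to edge input order", {
  tr <- generate_synthetic(synthetic_config(seed = 55, n_decoys = 50),
                           tempfile())
  lines <- readLines(tr$files$ppi)
  hdr <- lines[1]; body <- lines[-1]
  set.seed(1)
  f2 <- write_tmp(c(hdr, sample(body)), ".tsv")
  g1 <- read_gene_list(tr$files$cluster1, "D1")
  g2 <- read_gene_list(tr$files$cluster2, "D2")
  c_a <- infer_candidates(suppressMessages(
    annotate_network(read_ppi_table(tr$files$ppi), g1, g2)))
  c_b <- infer_candidates(suppressMessages(
    annotate_network(read_ppi_table(f2), g1, g2)))
  expect_identical(c_a, c_b)
})
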