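domain10 <- paste0("g", 1:10)

test_that("kappa agreement matches the 2x2 contingency computation", {
  A <- paste0("g", 1:4)
  expect_equal(kappa_score(A, A, domain10), 1)
  # a=2, b=2, c=2, d=4: Po=0.6, Pe=0.52, kappa=(0.6-0.52)/0.48 = 1/6
  expect_equal(kappa_score(A, paste0("g", 3:6), domain10), 1 / 6,
               tolerance = 1e-12)
  # complementary sets covering the domain disagree systematically
  expect_lt(kappa_score(paste0("g", 1:5), paste0("g", 6:10), domain10), 0)
  expect_error(kappa_score(c("g1", "zz"), "g2", domain10), "outside")
  expect_error(kappa_score("g1", "g2", character(0)), "empty domain")
})

test_that("kappa is symmetric and handles degenerate agreement", {
  set.seed(3)
  for (i in 1:40) {
    A <- sample(domain10, sample(0:10, 1))
    B <- sample(domain10, sample(0:10, 1))
    expect_equal(kappa_score(A, B, domain10), kappa_score(B, A, domain10))
  }
  # Pe = 1 cases: identical constant indicators score 1 by convention
  expect_equal(kappa_score(domain10, domain10, domain10), 1)
  expect_equal(kappa_score(character(0), character(0), domain10), 1)
})

# Significant-record table + collection for graph construction tests,
# bypassing the enrichment stage.
make_records <- function(ids, labels = NULL) {
  data.frame(pathway_id = ids, display_name = ids, source_db = "TOY",
             label = labels %||% rep("BOTH", length(ids)),
             p_raw = 1e-6, p_adj = 1e-5,
             total = 1L, unique1 = 1L, unique2 = 0L, common = 0L,
             stringsAsFactors = FALSE)
}

test_that("crosstalk edges appear exactly at kappa >= theta", {
  c1 <- gene_set(c("A", "B", "C"), "D1")
  c2 <- gene_set(c("D", "E"), "D2")
  coll <- toy_collection(P1 = c("A", "B", "C", "D"),
                         P2 = c("A", "B", "C", "D"),
                         P3 = c("E", "X1", "X2"))
  g <- build_crosstalk_graph(make_records(c("P1", "P2")), coll, c1, c2)
  kap <- igraph::E(g)$kappa[igraph::E(g)$etype == "crosstalk"]
  expect_equal(kap, 1)  # identical mapped membership

  # disjoint mapped genes: kappa <= 0 < theta, no crosstalk edge
  g2 <- build_crosstalk_graph(make_records(c("P1", "P3")), coll, c1, c2,
                              theta = 0.4)
  expect_equal(sum(igraph::E(g2)$etype == "crosstalk"), 0L)

  expect_error(build_crosstalk_graph(make_records("P1")[0, ], coll, c1, c2),
               "at least one")
  expect_error(build_crosstalk_graph(make_records("NOPE"), coll, c1, c2),
               "not in collection")
})

test_that("gene overlay records membership degree and cluster origin", {
  # a gene planted into 12 significant pathways gets membership degree 12
  ids <- sprintf("P%02d", 1:12)
  pws <- lapply(ids, function(i) c("HUBGENE", paste0(i, "_", 1:3)))
  names(pws) <- ids
  coll <- do.call(toy_collection, pws)
  c1 <- gene_set(c("HUBGENE", "P01_1"), "D1")
  c2 <- gene_set(c("HUBGENE", "P02_1"), "D2")
  g <- build_crosstalk_graph(make_records(ids), coll, c1, c2)
  hub <- which(igraph::V(g)$name == "HUBGENE")
  nb <- igraph::neighbors(g, hub)
  expect_equal(sum(nb$type == "pathway"), 12L)
  expect_identical(igraph::V(g)$origin[hub], "both")
  expect_identical(
    igraph::V(g)$origin[igraph::V(g)$name == "P01_1"], "1")
  expect_identical(
    igraph::V(g)$origin[igraph::V(g)$name == "P02_1"], "2")

  rep <- shared_gene_report(g)
  expect_equal(rep$n_pathways[rep$gene == "HUBGENE"], 12L)
  expect_equal(rep$n_pathways[rep$gene == "P01_1"], 1L)
  expect_identical(rep$gene[1], "HUBGENE")  # sorted by count descending
})

test_that("raising theta never adds crosstalk edges", {
  set.seed(17)
  universe <- sprintf("G%03d", 1:60)
  c1 <- gene_set(sample(universe, 25), "D1")
  c2 <- gene_set(sample(universe, 25), "D2")
  pws <- lapply(1:8, function(i) sample(universe, 15))
  names(pws) <- sprintf("P%d", 1:8)
  coll <- do.call(toy_collection, pws)
  recs <- make_records(names(pws))
  prev <- Inf
  for (theta in c(0.1, 0.3, 0.5, 0.8)) {
    g <- build_crosstalk_graph(recs, coll, c1, c2, theta = theta)
    n_edges <- sum(igraph::E(g)$etype == "crosstalk")
    expect_lte(n_edges, prev)
    prev <- n_edges
  }
})

test_that("stored kappa scores equal brute-force pairwise recomputation", {
  set.seed(23)
  universe <- sprintf("G%03d", 1:80)
  c1 <- gene_set(sample(universe, 30), "D1")
  c2 <- gene_set(sample(universe, 30), "D2")
  pws <- lapply(1:15, function(i) sample(universe, sample(8:20, 1)))
  names(pws) <- sprintf("P%02d", 1:15)
  coll <- do.call(toy_collection, pws)
  recs <- make_records(names(pws))
  theta <- 0.05
  g <- build_crosstalk_graph(recs, coll, c1, c2, theta = theta)

  query <- intersect(union(c1$members, c2$members), coll$universe)
  mapped <- lapply(pws, function(m) intersect(m, query))
  domain <- sort(unique(unlist(mapped)))
  el <- igraph::as_edgelist(g)
  ek <- igraph::E(g)$etype == "crosstalk"
  stored <- igraph::E(g)$kappa[ek]
  names(stored) <- paste(pmin(el[ek, 1], el[ek, 2]),
                         pmax(el[ek, 1], el[ek, 2]))
  cnt <- 0
  for (i in 1:14) for (j in (i + 1):15) {
    kap <- kappa_score(mapped[[i]], mapped[[j]], domain)
    key <- paste(min(names(pws)[c(i, j)]), max(names(pws)[c(i, j)]))
    if (kap >= theta) {
      cnt <- cnt + 1
      expect_equal(unname(stored[key]), kap)
    } else {
      expect_false(key %in% names(stored))
    }
  }
  expect_equal(length(stored), cnt)
})

test_that("the shared-gene report of an empty overlay is empty", {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  igraph::V(g)$type <- character(0)
  rep <- shared_gene_report(g)
  expect_equal(nrow(rep), 0L)
})
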