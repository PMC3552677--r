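# Shared fixtures built in code: tiny gene lists, GMT collections and PPI
# tables written to tempfiles.

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

toy_collection <- function(...) {
  # each ... argument: a character vector of members, named by pathway id
  pws <- list(...)
  pathway_collection(lapply(names(pws), function(id) {
    list(pathway_id = id, display_name = id, source_db = "TOY",
         members = pws[[id]])
  }))
}

toy_ppi <- function(pairs) {
  # pairs: data.frame(a, b)
  read_ppi_table(write_tmp(paste(pairs$a, pairs$b, sep = "\t"), ".tsv"))
}

# Deterministic planted-enrichment fixture: one pathway drawing 15 of its
# 20 members from cluster 1's 100 genes inside a 2,000-gene universe,
# plus null pathways filling out the BH family.
planted_enrichment_fixture <- function(seed = 11) {
  set.seed(seed)
  universe <- sprintf("G%04d", 1:2000)
  c1 <- sample(universe, 100)
  c2 <- sample(setdiff(universe, c1), 100)
  planted <- c(sample(c1, 15), sample(setdiff(universe, c1), 5))
  nulls <- lapply(1:10, function(i) sample(universe, 20))
  names(nulls) <- sprintf("NULL%02d", 1:10)
  coll <- do.call(toy_collection, c(list(PLANTED = planted), nulls))
  coll <- set_background(coll, universe)
  list(cluster1 = gene_set(c1, "D1"), cluster2 = gene_set(c2, "D2"),
       collection = coll)
}

# Independent BH step-up oracle: sort, p[i] * m / i, cumulative min from
# the largest rank down, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o] * m / seq_len(m)
  ps <- rev(cummin(rev(ps)))
  ps <- pmin(ps, 1)
  out <- numeric(m)
  out[o] <- ps
  out
}

# Exhaustive hypergeometric upper-tail oracle by enumerating all C(N, n)
# draws of the query from the universe and counting overlaps with the
# first K marked elements.
hypergeom_enum_oracle <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- combn(N, n)
  overl <- colSums(draws <= K)
  mean(overl >= k)
}
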