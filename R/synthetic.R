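#' Configuration for the synthetic comorbidity benchmark
#'
#' Defines the study conditions emulated by the generator: two partially
#' overlapping disease gene lists; a pathway collection containing
#' cluster-1-specific, cluster-2-specific, shared-enriched and null
#' pathways; and an undirected PPI network with planted non-susceptibility
#' "pleiotropic" candidate proteins wired to prescribed numbers of each
#' disease's proteins, among decoy proteins that never satisfy the dual
#' rule. Defaults mirror the dual-disease study design the package
#' implements: lists of 196 and 200 genes sharing 14, a 2,000-gene
#' universe, 10 + 11 + 7 planted enriched pathways of size 20 at
#' enrichment fraction 0.75 plus 30 null pathways, and 20 planted
#' dual-interactor candidates of which 9 are hubs (both partner degrees
#' >= 5).
#'
#' @param seed Integer seed; generation is a pure function of the config.
#' @param universe_size Number of genes in the symbol universe.
#' @param n_genes_1,n_genes_2 Disease list sizes.
#' @param n_common Genes shared by both lists.
#' @param n_pathways_cluster1,n_pathways_cluster2,n_pathways_shared,n_pathways_null
#'   Pathway plan counts.
#' @param pathway_size Members per planted pathway.
#' @param enrichment_fraction Fraction of a planted pathway drawn from its
#'   target cluster(s).
#' @param n_decoys Decoy protein count in the PPI background.
#' @param decoy_edge_prob Erdos-Renyi edge probability among decoys.
#' @param decoy_sus_max Maximum susceptibility partners (single disease)
#'   a decoy may receive.
#' @param n_sus_edges Number of random susceptibility-susceptibility
#'   edges.
#' @param candidate_plan Data frame with columns `deg1`, `deg2`: exact
#'   per-disease partner-degree targets for each planted candidate.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             universe_size = 2000L,
                             n_genes_1 = 196L,
                             n_genes_2 = 200L,
                             n_common = 14L,
                             n_pathways_cluster1 = 10L,
                             n_pathways_cluster2 = 11L,
                             n_pathways_shared = 7L,
                             n_pathways_null = 30L,
                             pathway_size = 20L,
                             enrichment_fraction = 0.75,
                             n_decoys = 200L,
                             decoy_edge_prob = 0.01,
                             decoy_sus_max = 3L,
                             n_sus_edges = 100L,
                             n_marker_pathways = 12L,
                             candidate_plan = default_candidate_plan()) {
  cfg <- list(seed = as.integer(seed), universe_size = as.integer(universe_size),
              n_genes_1 = as.integer(n_genes_1), n_genes_2 = as.integer(n_genes_2),
              n_common = as.integer(n_common),
              n_pathways_cluster1 = as.integer(n_pathways_cluster1),
              n_pathways_cluster2 = as.integer(n_pathways_cluster2),
              n_pathways_shared = as.integer(n_pathways_shared),
              n_pathways_null = as.integer(n_pathways_null),
              pathway_size = as.integer(pathway_size),
              enrichment_fraction = enrichment_fraction,
              n_decoys = as.integer(n_decoys),
              decoy_edge_prob = decoy_edge_prob,
              decoy_sus_max = as.integer(decoy_sus_max),
              n_sus_edges = as.integer(n_sus_edges),
              n_marker_pathways = as.integer(n_marker_pathways),
              candidate_plan = as.data.frame(candidate_plan))
  if (cfg$n_common > min(cfg$n_genes_1, cfg$n_genes_2)) {
    stop("synthetic_config: n_common exceeds a list size", call. = FALSE)
  }
  n_enriched <- cfg$n_pathways_cluster1 + cfg$n_pathways_cluster2 +
    cfg$n_pathways_shared
  if (cfg$n_marker_pathways > n_enriched) {
    stop("synthetic_config: n_marker_pathways exceeds the planted enriched ",
         "pathway count", call. = FALSE)
  }
  if (cfg$n_marker_pathways > 0L && cfg$n_common < 1L) {
    stop("synthetic_config: the promiscuous marker needs n_common >= 1",
         call. = FALSE)
  }
  if (cfg$pathway_size > cfg$universe_size) {
    stop("synthetic_config: pathway_size exceeds universe_size", call. = FALSE)
  }
  if (cfg$n_genes_1 + cfg$n_genes_2 - cfg$n_common > cfg$universe_size) {
    stop("synthetic_config: gene lists do not fit in the universe", call. = FALSE)
  }
  if (cfg$enrichment_fraction < 0 || cfg$enrichment_fraction > 1 ||
      cfg$decoy_edge_prob < 0 || cfg$decoy_edge_prob > 1) {
    stop("synthetic_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  cp <- cfg$candidate_plan
  if (nrow(cp) > 0L) {
    if (!all(c("deg1", "deg2") %in% names(cp))) {
      stop("synthetic_config: candidate_plan needs deg1, deg2 columns",
           call. = FALSE)
    }
    excl1 <- cfg$n_genes_1 - cfg$n_common
    excl2 <- cfg$n_genes_2 - cfg$n_common
    if (any(cp$deg1 < 1L) || any(cp$deg2 < 1L)) {
      stop("synthetic_config: planted candidates need deg1, deg2 >= 1",
           call. = FALSE)
    }
    if (any(cp$deg1 > excl1) || any(cp$deg2 > excl2)) {
      stop("synthetic_config: infeasible wiring: a degree target exceeds the ",
           "available exclusive susceptibility proteins", call. = FALSE)
    }
  }
  structure(cfg, class = "synthetic_config")
}

#' Default planted-candidate wiring plan
#'
#' Twenty planted dual-interactors: 9 hub candidates with both partner
#' degrees at least 5 (with varied connectivity up to the (7, 13) range
#' seen for highly connected kinases in real interactomes) and 11
#' non-hub candidates with at least one degree below 5.
#'
#' @return Data frame with columns `deg1`, `deg2`.
#' @export
default_candidate_plan <- function() {
  data.frame(
    deg1 = c(5L, 5L, 6L, 7L, 5L, 6L, 8L, 5L, 6L,
             1L, 2L, 1L, 3L, 2L, 4L, 1L, 2L, 3L, 4L, 1L),
    deg2 = c(5L, 6L, 5L, 13L, 7L, 6L, 5L, 5L, 7L,
             1L, 1L, 2L, 2L, 3L, 1L, 4L, 2L, 3L, 4L, 3L))
}

#' Generate a synthetic comorbidity benchmark with planted ground truth
#'
#' Deterministically (given the config seed) emits the four pipeline
#' input files — `cluster1.txt`, `cluster2.txt`, `pathways.gmt`,
#' `ppi.tsv` — plus `truth.yaml`, and returns the planted truth.
#'
#' Construction: gene symbols are neutral zero-padded tokens. The two
#' disease lists are disjoint draws plus a shared block of `n_common`
#' genes. Each cluster-specific pathway draws
#' `round(size * enrichment_fraction)` members from its target list and
#' the rest uniformly from the remaining universe; shared-enriched
#' pathways draw that planted block balanced across the two exclusive
#' lists plus one common gene; null pathways draw uniformly. The PPI
#' wires each planted candidate to exactly its target numbers of distinct
#' exclusive disease-1/disease-2 proteins, adds random
#' susceptibility-susceptibility edges, and wires decoys to at most
#' `decoy_sus_max` proteins of a single disease (never a shared protein)
#' plus Erdos-Renyi decoy-decoy edges, so no decoy can satisfy the
#' dual-interaction rule.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a `synthetic_truth` list: the config, file paths,
#'   the generated lists, a `pathway_truth` data frame (pathway id, planted
#'   type, planted target-cluster member count) and a `candidate_truth`
#'   data frame (protein, deg1, deg2, is_hub).
#' @export
generate_synthetic <- function(config = synthetic_config(), out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  width <- nchar(as.character(config$universe_size))
  universe <- sprintf(paste0("G%0", width, "d"), seq_len(config$universe_size))

  n_excl1 <- config$n_genes_1 - config$n_common
  n_excl2 <- config$n_genes_2 - config$n_common
  picked <- sample(universe, n_excl1 + n_excl2 + config$n_common)
  excl1 <- picked[seq_len(n_excl1)]
  excl2 <- picked[n_excl1 + seq_len(n_excl2)]
  common <- picked[n_excl1 + n_excl2 + seq_len(config$n_common)]
  list1 <- c(excl1, common)
  list2 <- c(excl2, common)

  # --- pathways ---------------------------------------------------------
  n_target <- round(config$pathway_size * config$enrichment_fraction)
  make_pathway <- function(id, type) {
    if (type == "cluster1") {
      planted <- sample(list1, n_target)
    } else if (type == "cluster2") {
      planted <- sample(list2, n_target)
    } else if (type == "shared") {
      h1 <- floor((n_target - 1L) / 2L)
      h2 <- n_target - 1L - h1
      planted <- c(sample(excl1, h1), sample(excl2, h2), sample(common, 1L))
    } else {
      planted <- character(0)
    }
    rest <- sample(setdiff(universe, planted),
                   config$pathway_size - length(planted))
    list(pathway_id = id, type = type, members = c(planted, rest),
         n_planted = length(planted))
  }
  plan <- c(rep("cluster1", config$n_pathways_cluster1),
            rep("cluster2", config$n_pathways_cluster2),
            rep("shared", config$n_pathways_shared),
            rep("null", config$n_pathways_null))
  tags <- c(cluster1 = "C1", cluster2 = "C2", shared = "SH", null = "NULL")
  idx <- stats::ave(seq_along(plan), plan, FUN = seq_along)
  ids <- sprintf("PW_%s_%02d", tags[plan], idx)
  pathways <- mapply(make_pathway, ids, plan, SIMPLIFY = FALSE)

  # Plant one promiscuous shared gene into the first n_marker_pathways
  # enriched pathways (a gene participating in many significant pathways,
  # as highly pleiotropic genes do in real annotations). It replaces a
  # background member so planted enrichment blocks are untouched.
  marker <- NA_character_
  if (config$n_marker_pathways > 0L) {
    marker <- common[1L]
    target_idx <- which(plan != "null")[seq_len(config$n_marker_pathways)]
    for (i in target_idx) {
      m <- pathways[[i]]$members
      if (!(marker %in% m) && length(m) > pathways[[i]]$n_planted) {
        m[length(m)] <- marker  # last slot is a background draw
        pathways[[i]]$members <- m
      }
    }
  }

  # --- PPI --------------------------------------------------------------
  cp <- config$candidate_plan
  n_cand <- nrow(cp)
  cand_names <- if (n_cand > 0L) sprintf("CAND%03d", seq_len(n_cand)) else character(0)
  decoy_names <- if (config$n_decoys > 0L)
    sprintf("DECOY%03d", seq_len(config$n_decoys)) else character(0)

  ea <- character(0); eb <- character(0)
  for (i in seq_len(n_cand)) {
    p1 <- sample(excl1, cp$deg1[i])
    p2 <- sample(excl2, cp$deg2[i])
    ea <- c(ea, rep(cand_names[i], cp$deg1[i] + cp$deg2[i]))
    eb <- c(eb, p1, p2)
  }
  sus_all <- c(excl1, excl2, common)
  if (config$n_sus_edges > 0L) {
    sa <- sample(sus_all, config$n_sus_edges, replace = TRUE)
    sb <- sample(sus_all, config$n_sus_edges, replace = TRUE)
    ok <- sa != sb
    ea <- c(ea, sa[ok]); eb <- c(eb, sb[ok])
  }
  for (d in decoy_names) {
    k <- sample(0:config$decoy_sus_max, 1L)
    if (k > 0L) {
      side <- if (runif(1) < 0.5) excl1 else excl2
      part <- sample(side, k)
      ea <- c(ea, rep(d, k)); eb <- c(eb, part)
    }
  }
  if (length(decoy_names) >= 2L && config$decoy_edge_prob > 0) {
    dp <- combn(decoy_names, 2L)
    on <- runif(ncol(dp)) < config$decoy_edge_prob
    ea <- c(ea, dp[1L, on]); eb <- c(eb, dp[2L, on])
  }

  # --- emit files -------------------------------------------------------
  paths <- list(cluster1 = file.path(out_dir, "cluster1.txt"),
                cluster2 = file.path(out_dir, "cluster2.txt"),
                gmt = file.path(out_dir, "pathways.gmt"),
                ppi = file.path(out_dir, "ppi.tsv"),
                truth = file.path(out_dir, "truth.yaml"))
  writeLines(sort(list1), paths$cluster1)
  writeLines(sort(list2), paths$cluster2)
  writeLines(vapply(pathways, function(p) {
    paste(c(p$pathway_id, paste0("synthetic_", p$type), p$members),
          collapse = "\t")
  }, character(1)), paths$gmt)
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]; hi <- hi[!dup]
  writeLines(c("#interactor_a\tinteractor_b", paste(lo, hi, sep = "\t")),
             paths$ppi)

  pathway_truth <- data.frame(
    pathway_id = ids, type = unname(plan),
    n_planted = vapply(pathways, function(p) p$n_planted, integer(1)),
    stringsAsFactors = FALSE)
  candidate_truth <- data.frame(
    protein = cand_names, deg1 = cp$deg1, deg2 = cp$deg2,
    is_hub = cp$deg1 >= 5L & cp$deg2 >= 5L, stringsAsFactors = FALSE)

  truth <- structure(list(config = config, files = paths,
                          list1 = sort(list1), list2 = sort(list2),
                          common = sort(common),
                          pathway_members = stats::setNames(
                            lapply(pathways, `[[`, "members"), ids),
                          pathway_truth = pathway_truth,
                          candidate_truth = candidate_truth,
                          marker_gene = marker,
                          marker_pathways = ids[vapply(pathways, function(p) {
                            !is.na(marker) && marker %in% p$members
                          }, logical(1))]),
                     class = "synthetic_truth")
  yaml::write_yaml(list(
    config = unclass(config)[setdiff(names(config), "candidate_plan")],
    candidate_plan = as.list(cp),
    n_list1 = length(list1), n_list2 = length(list2),
    n_common = length(common),
    pathway_truth = as.list(pathway_truth),
    candidate_truth = as.list(candidate_truth)), paths$truth)
  invisible(truth)
}

#' Verify emitted synthetic files against the stored planted truth
#'
#' Independently re-reads the generated files through the package's own
#' readers and recounts list sizes, overlap, planted pathway compositions
#' and planted candidate wiring, comparing each against the stored truth.
#'
#' @param truth A `synthetic_truth` object from [generate_synthetic()].
#' @param stop_on_mismatch If `TRUE` (default), any divergence raises an
#'   error naming the first mismatching item; otherwise all mismatches
#'   are returned.
#' @return Character vector of mismatch descriptions (empty when the
#'   files agree with the truth), invisibly when empty.
#' @export
recount_truth <- function(truth, stop_on_mismatch = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mism <- character(0)
  note <- function(...) mism <<- c(mism, paste0(...))

  g1 <- read_gene_list(truth$files$cluster1, "cluster1")
  g2 <- read_gene_list(truth$files$cluster2, "cluster2")
  if (!identical(g1$members, truth$list1)) note("cluster1 list differs from truth")
  if (!identical(g2$members, truth$list2)) note("cluster2 list differs from truth")
  if (length(intersect(g1$members, g2$members)) != length(truth$common)) {
    note("list overlap differs from truth")
  }

  coll <- read_gmt(truth$files$gmt)
  for (i in seq_len(nrow(truth$pathway_truth))) {
    id <- truth$pathway_truth$pathway_id[i]
    type <- truth$pathway_truth$type[i]
    p <- coll$pathways[[id]]
    if (is.null(p)) { note("pathway missing from GMT: ", id); next }
    if (!setequal(p$members, truth$pathway_members[[id]])) {
      note("pathway members differ from truth: ", id); next
    }
    target <- switch(type,
                     cluster1 = g1$members, cluster2 = g2$members,
                     shared = union(g1$members, g2$members), NULL)
    if (!is.null(target)) {
      got <- length(intersect(p$members, target))
      if (got < truth$pathway_truth$n_planted[i]) {
        note("pathway ", id, ": planted target-cluster members ", got,
             " < intended ", truth$pathway_truth$n_planted[i])
      }
    }
  }

  ppi <- read_ppi_table(truth$files$ppi, dialect = "edgelist")
  net <- suppressMessages(annotate_network(ppi, g1, g2))
  deg <- neighbor_degrees(net)
  for (i in seq_len(nrow(truth$candidate_truth))) {
    ct <- truth$candidate_truth[i, ]
    row <- deg[deg$protein == ct$protein, ]
    if (nrow(row) != 1L) {
      note("planted candidate absent from network: ", ct$protein)
    } else if (row$deg1 != ct$deg1 || row$deg2 != ct$deg2) {
      note("planted candidate ", ct$protein, " wiring (", row$deg1, ",",
           row$deg2, ") differs from truth (", ct$deg1, ",", ct$deg2, ")")
    }
  }

  if (length(mism) > 0L && stop_on_mismatch) {
    stop("synthetic truth mismatch: ", mism[1L],
         if (length(mism) > 1L) paste0(" (and ", length(mism) - 1L, " more)"),
         call. = FALSE)
  }
  if (length(mism) == 0L) invisible(mism) else mism
}
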