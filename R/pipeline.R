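#' Run the full comorbidity analysis pipeline
#'
#' Orchestrates the stages in flow order — gene sources (read or
#' simulate), two-cluster pathway enrichment, pathway crosstalk network
#' construction, and PPI candidate prediction — writing all artifacts to
#' an output directory and returning a summary report of counts at every
#' stage with every threshold used.
#'
#' @param config Either a path to a YAML config file or a list with the
#'   same structure:
#' \preformatted{
#' out_dir: results            # required
#' simulate:                   # either this block ...
#'   seed: 1                   # (any synthetic_config() field)
#' inputs:                     # ... or this one
#'   cluster1: scz.txt
#'   cluster2: t2d.txt
#'   gmt: [kegg.gmt, biocarta.gmt]
#'   background: bg.txt        # optional
#'   ppi: hprd.tsv
#'   ppi_dialect: hprd         # or edgelist
#'   label1: SCZ
#'   label2: T2D
#' params:
#'   alpha: 0.05               # adjusted-p significance level
#'   tau: 0.66                 # specificity fraction threshold
#'   theta: 0.4                # kappa edge threshold
#'   min_each: 1               # dual-interactor rule
#'   hub_threshold: 5          # hub rule
#' }
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `report` (named counts and thresholds),
#'   `enrichment`, `crosstalk`, `shared_genes`, `candidates`, `hubs`,
#'   `subnetwork`, `census` and `truth` (when simulated). The report is
#'   also written as `report.tsv` and `report.txt` in `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("[config] no such file: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("[config] config must be a list or YAML path", call. = FALSE)
  if (is.null(config$out_dir)) stop("[config] 'out_dir' is required", call. = FALSE)
  params <- config$params %||% list()
  alpha <- params$alpha %||% 0.05
  tau <- params$tau %||% 0.66
  theta <- params$theta %||% 0.4
  min_each <- params$min_each %||% 1L
  hub_threshold <- params$hub_threshold %||% 5L
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[comopath] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- stage 1: gene sources -------------------------------------------
  src <- stage("gene_sources", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      if (isTRUE(sim)) sim <- list()
      cfg <- do.call(synthetic_config, sim)
      say("simulating inputs (seed ", cfg$seed, ")")
      tr <- generate_synthetic(cfg, file.path(out_dir, "sim"))
      list(inp = list(cluster1 = tr$files$cluster1,
                      cluster2 = tr$files$cluster2,
                      gmt = tr$files$gmt, ppi = tr$files$ppi,
                      ppi_dialect = "edgelist",
                      label1 = "DISEASE1", label2 = "DISEASE2"),
           truth = tr)
    } else if (!is.null(config$inputs)) {
      list(inp = config$inputs, truth = NULL)
    } else {
      stop("config needs either a 'simulate' or an 'inputs' block")
    }
  })
  inp <- src$inp
  truth <- src$truth
  set1 <- stage("gene_sources",
                read_gene_list(inp$cluster1, inp$label1 %||% "CLUSTER1"))
  set2 <- stage("gene_sources",
                read_gene_list(inp$cluster2, inp$label2 %||% "CLUSTER2"))
  overlap <- length(intersect(set1$members, set2$members))
  say(length(set1$members), " + ", length(set2$members), " genes, ",
      overlap, " shared")

  # --- stage 2: pathway enrichment -------------------------------------
  coll <- stage("pathway_enrichment", {
    cl <- do.call(merge_collections, lapply(inp$gmt, read_gmt))
    if (!is.null(inp$background)) {
      cl <- set_background(cl, read_gene_list(inp$background, "background")$members)
    }
    cl
  })
  enr <- stage("pathway_enrichment",
               enrich_two_cluster(set1, set2, coll, alpha = alpha, tau = tau))
  write_enrichment_table(enr, file.path(out_dir, "enrichment.tsv"))
  say(nrow(enr), " significant pathways of ", attr(enr, "n_tested"), " tested")

  # --- stage 3: crosstalk network --------------------------------------
  crosstalk <- NULL
  shared_genes <- NULL
  if (nrow(enr) >= 1L) {
    crosstalk <- stage("crosstalk_network",
                       build_crosstalk_graph(enr, coll, set1, set2,
                                             theta = theta))
    shared_genes <- shared_gene_report(crosstalk)
    write_network(crosstalk, file.path(out_dir, "crosstalk.graphml"), "graphml")
    write_network(crosstalk, file.path(out_dir, "crosstalk.sif"), "sif")
    write.table(shared_genes, file.path(out_dir, "shared_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    say("no significant pathway; skipping crosstalk network")
  }

  # --- stage 4: candidate prediction -----------------------------------
  res4 <- stage("candidate_prediction", {
    ppi <- read_ppi_table(inp$ppi, dialect = inp$ppi_dialect %||% "edgelist")
    net <- annotate_network(ppi, set1, set2)
    cands <- infer_candidates(net, min_each = min_each,
                              hub_threshold = hub_threshold)
    hubs <- detect_hubs(cands, h = hub_threshold)
    census <- partner_census(net)
    sub <- if (nrow(cands) > 0L) extract_subnetwork(net, cands) else NULL
    list(net = net, cands = cands, hubs = hubs, census = census, sub = sub)
  })
  write.table(res4$cands, file.path(out_dir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(res4$net, file.path(out_dir, "annotated_ppi.graphml"), "graphml")
  if (!is.null(res4$sub)) {
    write_network(res4$sub, file.path(out_dir, "subnetwork.graphml"), "graphml")
    write_network(res4$sub, file.path(out_dir, "subnetwork.sif"), "sif")
  }
  say(nrow(res4$cands), " dual-disease candidates, ", nrow(res4$hubs), " hubs")

  # --- report -----------------------------------------------------------
  cls <- igraph::V(res4$net)$node_class
  etypes <- if (!is.null(crosstalk)) igraph::E(crosstalk)$etype else character(0)
  report <- list(
    label1 = set1$label, label2 = set2$label,
    n_genes_1 = length(set1$members), n_genes_2 = length(set2$members),
    n_overlap = overlap,
    n_union = length(union(set1$members, set2$members)),
    universe_size = attr(enr, "universe_size"),
    query_size = attr(enr, "query_size"),
    n_pathways_tested = attr(enr, "n_tested"),
    n_significant = nrow(enr),
    n_label_cluster1 = sum(enr$label == "CLUSTER1"),
    n_label_cluster2 = sum(enr$label == "CLUSTER2"),
    n_label_both = sum(enr$label == "BOTH"),
    n_kappa_edges = sum(etypes == "crosstalk"),
    n_overlay_genes = if (is.null(shared_genes)) 0L else nrow(shared_genes),
    ppi_nodes = igraph::vcount(res4$net),
    ppi_edges = igraph::ecount(res4$net),
    n_sus1 = sum(cls == "SUS1"), n_sus2 = sum(cls == "SUS2"),
    n_sus_both = sum(cls == "SUS_BOTH"),
    n_neighbors = sum(cls == "NEIGHBOR"),
    n_candidates = nrow(res4$cands),
    n_hubs = nrow(res4$hubs),
    subnet_nodes = if (is.null(res4$sub)) 0L else igraph::vcount(res4$sub),
    subnet_edges = if (is.null(res4$sub)) 0L else igraph::ecount(res4$sub),
    alpha = alpha, tau = tau, theta = theta,
    min_each = min_each, hub_threshold = hub_threshold)
  write.table(data.frame(key = names(report),
                         value = vapply(report, as.character, character(1))),
              file.path(out_dir, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("comopath pipeline report",
               "========================",
               sprintf("%-20s %s", names(report),
                       vapply(report, as.character, character(1)))),
             file.path(out_dir, "report.txt"))

  invisible(list(report = report, enrichment = enr, crosstalk = crosstalk,
                 shared_genes = shared_genes, candidates = res4$cands,
                 hubs = res4$hubs, subnetwork = res4$sub,
                 census = res4$census, network = res4$net, truth = truth))
}
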