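#' Map susceptibility proteins onto the interactome and extract first
#' neighbours
#'
#' Restricts a cleaned PPI network to the susceptibility proteins of both
#' diseases plus every protein directly interacting with at least one of
#' them, and classes each retained node: `SUS1`/`SUS2` for proteins
#' exclusive to one disease list, `SUS_BOTH` for proteins on both lists,
#' and `NEIGHBOR` for non-susceptibility first neighbours. Susceptibility
#' proteins absent from the interactome are dropped with a logged count.
#'
#' @param ppi An undirected simple `igraph` PPI network (see
#'   [read_ppi_table()]).
#' @param set1,set2 [gene_set()]s of the two diseases' susceptibility
#'   genes.
#' @return The induced `igraph` subgraph with a `node_class` vertex
#'   attribute partitioning nodes into `SUS1`, `SUS2`, `SUS_BOTH`,
#'   `NEIGHBOR`, and a graph attribute `n_unmapped` recording how many
#'   susceptibility proteins did not map.
#' @export
annotate_network <- function(ppi, set1, set2) {
  stopifnot(inherits(ppi, "igraph"),
            inherits(set1, "gene_set"), inherits(set2, "gene_set"))
  nodes <- igraph::V(ppi)$name
  sus_all <- union(set1$members, set2$members)
  sus_present <- intersect(sus_all, nodes)
  if (length(sus_present) == 0L) {
    stop("no susceptibility protein maps into the PPI network", call. = FALSE)
  }
  n_unmapped <- length(sus_all) - length(sus_present)
  if (n_unmapped > 0L) {
    message(n_unmapped,
            " susceptibility protein(s) absent from the PPI were dropped")
  }
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(ppi, sus_present),
                             function(v) v$name), use.names = FALSE))
  neighbors <- setdiff(nb, sus_present)
  keep <- c(sus_present, neighbors)
  sub <- igraph::induced_subgraph(ppi, keep)
  vn <- igraph::V(sub)$name
  cls <- ifelse(vn %in% set1$members & vn %in% set2$members, "SUS_BOTH",
                ifelse(vn %in% set1$members, "SUS1",
                       ifelse(vn %in% set2$members, "SUS2", "NEIGHBOR")))
  sub <- igraph::set_vertex_attr(sub, "node_class", value = cls)
  sub <- igraph::set_graph_attr(sub, "n_unmapped", n_unmapped)
  sub
}

# Distinct susceptibility partner counts per NEIGHBOR node. SUS_BOTH
# partners count toward both diseases (they sit on both lists).
neighbor_degrees <- function(net) {
  cls <- igraph::V(net)$node_class
  if (is.null(cls)) {
    stop("network lacks 'node_class'; run annotate_network() first",
         call. = FALSE)
  }
  vn <- igraph::V(net)$name
  el <- igraph::as_edgelist(net, names = TRUE)
  cls_of <- stats::setNames(cls, vn)
  nb_names <- vn[cls == "NEIGHBOR"]
  deg1 <- stats::setNames(integer(length(nb_names)), nb_names)
  deg2 <- deg1
  if (nrow(el) > 0L) {
    for (side in 1:2) {
      x <- el[, side]; y <- el[, 3L - side]
      is_nb <- cls_of[x] == "NEIGHBOR"
      part1 <- is_nb & cls_of[y] %in% c("SUS1", "SUS_BOTH")
      part2 <- is_nb & cls_of[y] %in% c("SUS2", "SUS_BOTH")
      if (any(part1)) {
        t1 <- table(x[part1])
        deg1[names(t1)] <- deg1[names(t1)] + as.integer(t1)
      }
      if (any(part2)) {
        t2 <- table(x[part2])
        deg2[names(t2)] <- deg2[names(t2)] + as.integer(t2)
      }
    }
  }
  data.frame(protein = nb_names, deg1 = unname(deg1), deg2 = unname(deg2),
             stringsAsFactors = FALSE)
}

#' Infer dual-disease candidate proteins by guilt-by-association
#'
#' Candidates are non-susceptibility first neighbours that interact with
#' at least `min_each` distinct susceptibility proteins of each disease.
#' `deg1` counts distinct partners classed `SUS1` or `SUS_BOTH`, `deg2`
#' counts `SUS2` or `SUS_BOTH`. The hub flag marks candidates with at
#' least `hub_threshold` partners from each disease.
#'
#' @param net Annotated network from [annotate_network()].
#' @param min_each Minimum distinct partners per disease; default 1
#'   ("simultaneously interacting with both"). Use 2 for the stricter
#'   "more than one of each" reading.
#' @param hub_threshold Hub rule threshold; default 5.
#' @return Data frame of candidates with columns `protein`, `deg1`,
#'   `deg2`, `is_hub`, sorted by `min(deg1, deg2)` descending, then
#'   `deg1 + deg2` descending, then symbol.
#' @export
infer_candidates <- function(net, min_each = 1L, hub_threshold = 5L) {
  if (min_each < 1L) stop("infer_candidates: 'min_each' must be >= 1",
                          call. = FALSE)
  d <- neighbor_degrees(net)
  d <- d[d$deg1 >= min_each & d$deg2 >= min_each, , drop = FALSE]
  d$is_hub <- d$deg1 >= hub_threshold & d$deg2 >= hub_threshold
  d <- d[order(-pmin(d$deg1, d$deg2), -(d$deg1 + d$deg2), d$protein), ,
         drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Filter candidates down to hub proteins
#'
#' Hubs are candidates with at least `h` distinct susceptibility partners
#' from each disease (boundary inclusive).
#'
#' @param candidates Candidate data frame from [infer_candidates()].
#' @param h Hub threshold; default 5.
#' @return The hub subset with `is_hub = TRUE`.
#' @export
detect_hubs <- function(candidates, h = 5L) {
  if (h < 1L) stop("detect_hubs: 'h' must be >= 1", call. = FALSE)
  out <- candidates[candidates$deg1 >= h & candidates$deg2 >= h, ,
                    drop = FALSE]
  if (nrow(out) > 0L) out$is_hub <- TRUE
  rownames(out) <- NULL
  out
}

#' Extract the candidate sub-network
#'
#' The induced subgraph over the candidate proteins and their
#' susceptibility partners, node classes carried over. Induced-subgraph
#' semantics: every edge of the parent network joining two retained nodes
#' is kept, including susceptibility-susceptibility and
#' candidate-candidate adjacencies.
#'
#' @param net Annotated network from [annotate_network()].
#' @param candidates Candidate data frame from [infer_candidates()]
#'   (>= 1 row); must be `NEIGHBOR` nodes of `net`.
#' @return An `igraph` subgraph with the `node_class` vertex attribute.
#' @export
extract_subnetwork <- function(net, candidates) {
  if (is.null(candidates) || nrow(candidates) < 1L) {
    stop("extract_subnetwork: empty candidate list", call. = FALSE)
  }
  vn <- igraph::V(net)$name
  cls <- stats::setNames(igraph::V(net)$node_class, vn)
  cand <- candidates$protein
  if (!all(cand %in% vn) || !all(cls[cand] == "NEIGHBOR")) {
    stop("extract_subnetwork: candidates must be NEIGHBOR nodes of the network",
         call. = FALSE)
  }
  partners <- unique(unlist(lapply(igraph::adjacent_vertices(net, cand),
                                   function(v) v$name), use.names = FALSE))
  partners <- partners[cls[partners] %in% c("SUS1", "SUS2", "SUS_BOTH")]
  igraph::induced_subgraph(net, unique(c(cand, partners)))
}

#' Census of susceptibility-partner degrees among first neighbours
#'
#' Reports each `NEIGHBOR` protein's distinct partner counts per disease
#' and aggregate counts of neighbours reaching partner-degree thresholds
#' 1 and 2 for each disease, plus the dual-interactor count (neighbours
#' with at least one partner from each disease).
#'
#' @param net Annotated network from [annotate_network()].
#' @return A list with `neighbors` (per-protein `deg1`/`deg2` table) and
#'   `summary` (data frame of `threshold_class`, `count`).
#' @export
partner_census <- function(net) {
  d <- neighbor_degrees(net)
  summary <- data.frame(
    threshold_class = c("deg1_ge_1", "deg1_ge_2", "deg2_ge_1", "deg2_ge_2",
                        "dual_interactor"),
    count = c(sum(d$deg1 >= 1L), sum(d$deg1 >= 2L),
              sum(d$deg2 >= 1L), sum(d$deg2 >= 2L),
              sum(d$deg1 >= 1L & d$deg2 >= 1L)),
    stringsAsFactors = FALSE)
  list(neighbors = d, summary = summary)
}
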