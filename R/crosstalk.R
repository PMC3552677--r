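#' Kappa-statistic agreement between two pathway membership sets
#'
#' Cohen's kappa of the two binary membership indicators over a common
#' gene domain, the agreement measure used for term-term crosstalk
#' networks. With `a = |A ∩ B|`, `b = |A \ B|`, `c = |B \ A|`,
#' `d = |domain| - a - b - c` and `T = |domain|`: observed agreement
#' `Po = (a + d) / T`, chance agreement
#' `Pe = ((a+b)(a+c) + (c+d)(b+d)) / T^2`, and
#' `kappa = (Po - Pe) / (1 - Pe)`. In the degenerate case `Pe = 1`
#' (both indicator vectors constant) the score is 1 when the two sets are
#' identical and 0 otherwise, by a continuity convention.
#'
#' @param members_a,members_b Gene sets (character vectors), subsets of
#'   `domain`.
#' @param domain Non-empty character vector: the membership domain over
#'   which agreement is scored.
#' @return Kappa score in `[-1, 1]`.
#' @export
#' @examples
#' kappa_score(paste0("g", 1:4), paste0("g", 3:6), paste0("g", 1:10))  # 1/6
kappa_score <- function(members_a, members_b, domain) {
  domain <- unique(domain)
  if (length(domain) == 0L) stop("kappa_score: empty domain", call. = FALSE)
  members_a <- unique(members_a)
  members_b <- unique(members_b)
  if (!all(members_a %in% domain)) {
    stop("kappa_score: members_a contains genes outside the domain",
         call. = FALSE)
  }
  if (!all(members_b %in% domain)) {
    stop("kappa_score: members_b contains genes outside the domain",
         call. = FALSE)
  }
  T_ <- length(domain)
  a <- length(intersect(members_a, members_b))
  b <- length(members_a) - a
  c_ <- length(members_b) - a
  d <- T_ - a - b - c_
  po <- (a + d) / T_
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / T_^2
  if (1 - pe < .Machine$double.eps^0.5) {
    return(if (b == 0L && c_ == 0L) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Build the pathway crosstalk network with overlaid gene nodes
#'
#' Connects significant pathways whose mapped-gene membership indicators
#' agree at kappa >= `theta`, and overlays the mapped query genes as a
#' bipartite layer: each gene node is linked to every significant pathway
#' containing it and tagged by its cluster of origin (`"1"`, `"2"` or
#' `"both"`). Membership vectors are each pathway's members intersected
#' with the query; the kappa domain defaults to the query genes mapped to
#' at least one of the supplied pathways.
#'
#' @param records Significant-pathway data frame from
#'   [enrich_two_cluster()] (>= 1 row).
#' @param collection The [pathway_collection()] the records were tested
#'   against.
#' @param cluster1,cluster2 The two [gene_set()]s.
#' @param theta Kappa edge threshold in `(0, 1]`; default 0.4.
#' @param domain Optional explicit kappa domain (e.g. the full universe).
#' @return An undirected `igraph` graph. Vertex attributes: `type`
#'   (`"pathway"`/`"gene"`), `display`, `specificity`, `frac1`, `frac2`
#'   for pathway nodes; `origin` for gene nodes. Edge attributes: `etype`
#'   (`"crosstalk"`/`"membership"`) and `kappa` (crosstalk edges only).
#' @export
build_crosstalk_graph <- function(records, collection, cluster1, cluster2,
                                  theta = 0.4, domain = NULL) {
  stopifnot(inherits(collection, "pathway_collection"),
            inherits(cluster1, "gene_set"), inherits(cluster2, "gene_set"))
  if (is.null(records) || nrow(records) < 1L) {
    stop("build_crosstalk_graph: need at least one significant pathway",
         call. = FALSE)
  }
  if (length(theta) != 1L || !is.finite(theta) || theta <= 0 || theta > 1) {
    stop("build_crosstalk_graph: 'theta' must lie in (0, 1]", call. = FALSE)
  }
  missing_ids <- setdiff(records$pathway_id, names(collection$pathways))
  if (length(missing_ids) > 0L) {
    stop("build_crosstalk_graph: pathway not in collection: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  universe <- collection$universe
  s1 <- intersect(cluster1$members, universe)
  s2 <- intersect(cluster2$members, universe)
  query <- union(s1, s2)
  mapped <- lapply(records$pathway_id, function(id) {
    intersect(collection$pathways[[id]]$members, query)
  })
  names(mapped) <- records$pathway_id
  genes <- sort(unique(unlist(mapped, use.names = FALSE)))
  if (is.null(domain)) domain <- genes

  ids <- records$pathway_id
  edges <- data.frame(from = character(0), to = character(0),
                      etype = character(0), kappa = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(ids) >= 2L) {
    pairs <- combn(seq_along(ids), 2L)
    kap <- apply(pairs, 2L, function(ix) {
      kappa_score(mapped[[ix[1L]]], mapped[[ix[2L]]], domain)
    })
    keep <- kap >= theta
    if (any(keep)) {
      edges <- data.frame(from = ids[pairs[1L, keep]],
                          to = ids[pairs[2L, keep]],
                          etype = "crosstalk", kappa = kap[keep],
                          stringsAsFactors = FALSE)
    }
  }
  memb <- do.call(rbind, lapply(ids, function(id) {
    g <- mapped[[id]]
    if (length(g) == 0L) return(NULL)
    data.frame(from = g, to = id, etype = "membership", kappa = NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(memb)) edges <- rbind(edges, memb)

  origin <- ifelse(genes %in% s1 & genes %in% s2, "both",
                   ifelse(genes %in% s1, "1", "2"))
  verts <- rbind(
    data.frame(name = ids, type = "pathway", display = records$display_name,
               specificity = records$label,
               frac1 = (records$unique1 + records$common) / records$total,
               frac2 = (records$unique2 + records$common) / records$total,
               origin = NA_character_, stringsAsFactors = FALSE),
    if (length(genes) > 0L)
      data.frame(name = genes, type = "gene", display = genes,
                 specificity = NA_character_, frac1 = NA_real_,
                 frac2 = NA_real_, origin = origin,
                 stringsAsFactors = FALSE)
  )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Tabulate genes shared across significant pathways
#'
#' One row per overlaid gene node of a crosstalk graph with its pathway
#' membership count and the list of pathways it maps to, sorted by count
#' descending then symbol.
#'
#' @param graph A crosstalk graph from [build_crosstalk_graph()].
#' @return Data frame with columns `gene`, `origin`, `n_pathways`,
#'   `pathways` (semicolon-separated pathway ids).
#' @export
shared_gene_report <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  types <- igraph::V(graph)$type
  gene_idx <- which(types == "gene")
  if (length(gene_idx) == 0L) {
    return(data.frame(gene = character(0), origin = character(0),
                      n_pathways = integer(0), pathways = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(gene_idx, function(i) {
    nb <- igraph::neighbors(graph, i)
    pw <- sort(nb$name[nb$type == "pathway"])
    data.frame(gene = igraph::V(graph)$name[i],
               origin = igraph::V(graph)$origin[i],
               n_pathways = length(pw),
               pathways = paste(pw, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_pathways, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
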