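#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` annotated genes in a query of
#' size `n` drawn without replacement from a universe of `N` genes of
#' which `K` are annotated to the pathway: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. The tail is inclusive of `k`.
#'
#' @param k Observed overlap count.
#' @param K Pathway size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return A probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_tail(2, 3, 3, 10)  # 11/60
hypergeom_tail <- function(k, K, n, N) {
  for (arg in c("k", "K", "n", "N")) {
    v <- get(arg)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != trunc(v)) {
      stop("hypergeom_tail: '", arg, "' must be a single non-negative integer",
           call. = FALSE)
    }
  }
  if (K > N) stop("hypergeom_tail: 'K' exceeds universe size N", call. = FALSE)
  if (n > N) stop("hypergeom_tail: 'n' exceeds universe size N", call. = FALSE)
  if (k > min(K, n)) {
    stop("hypergeom_tail: 'k' exceeds min(K, n)", call. = FALSE)
  }
  if (k == 0L) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, returned in the
#' input's original order and capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Classify the cluster specificity of an enriched pathway
#'
#' A pathway is specific to one disease cluster when more than a fraction
#' `tau` of its mapped query genes come from that cluster; genes common to
#' both lists count toward both clusters' fractions. With
#' `f_i = (unique_i + common) / total`, the label is `"CLUSTER1"` iff
#' `f_1 > tau` and `f_2 <= tau` (symmetrically for `"CLUSTER2"`), and
#' `"BOTH"` otherwise.
#'
#' @param unique1,unique2 Counts of mapped genes exclusive to each cluster.
#' @param common Count of mapped genes shared by both clusters.
#' @param tau Specificity fraction threshold in `(0.5, 1)`; default 0.66.
#' @return One of `"CLUSTER1"`, `"CLUSTER2"`, `"BOTH"`.
#' @export
#' @examples
#' classify_specificity(26, 9, 0)   # "CLUSTER1"
#' classify_specificity(4, 12, 2)   # "CLUSTER2"
classify_specificity <- function(unique1, unique2, common, tau = 0.66) {
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0.5 || tau >= 1) {
    stop("classify_specificity: 'tau' must lie in (0.5, 1)", call. = FALSE)
  }
  counts <- c(unique1, unique2, common)
  if (any(counts < 0) || any(counts != trunc(counts))) {
    stop("classify_specificity: counts must be non-negative integers",
         call. = FALSE)
  }
  total <- unique1 + unique2 + common
  if (total < 1) stop("classify_specificity: total count is zero", call. = FALSE)
  f1 <- (unique1 + common) / total
  f2 <- (unique2 + common) / total
  if (f1 > tau && f2 <= tau) return("CLUSTER1")
  if (f2 > tau && f1 <= tau) return("CLUSTER2")
  "BOTH"
}

#' Two-cluster pathway over-representation analysis
#'
#' Tests each pathway for over-representation of the combined query (the
#' union of both clusters intersected with the background universe) with
#' the hypergeometric upper tail, adjusts across all tested pathways with
#' Benjamini-Hochberg in one family, retains pathways with adjusted
#' p-value below `alpha`, and labels each significant pathway's cluster
#' specificity from its per-cluster mapped-gene counts. Pathways with no
#' mapped query gene (`k = 0`) are excluded before the testing family is
#' formed.
#'
#' @param cluster1,cluster2 [gene_set()]s for the two disease clusters.
#' @param collection A [pathway_collection()].
#' @param alpha Significance level on the adjusted p-value; default 0.05.
#' @param tau Specificity threshold passed to [classify_specificity()].
#' @return A data frame of significant pathways sorted by `p_adj`
#'   ascending (ties broken by `pathway_id`), with columns `pathway_id`,
#'   `display_name`, `source_db`, `label`, `p_raw`, `p_adj`, `total`,
#'   `unique1`, `unique2`, `common`, `k`, `K`, `n`, `N`. Attributes
#'   `n_tested`, `query_size`, `universe_size` and `clusters` record the
#'   testing family and inputs.
#' @export
enrich_two_cluster <- function(cluster1, cluster2, collection,
                               alpha = 0.05, tau = 0.66) {
  stopifnot(inherits(cluster1, "gene_set"), inherits(cluster2, "gene_set"),
            inherits(collection, "pathway_collection"))
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("enrich_two_cluster: 'alpha' must lie in (0, 1)", call. = FALSE)
  }
  universe <- collection$universe
  s1 <- intersect(cluster1$members, universe)
  s2 <- intersect(cluster2$members, universe)
  query <- union(s1, s2)
  if (length(query) == 0L) {
    stop("no query gene maps into the background universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  common_genes <- intersect(s1, s2)

  rows <- lapply(collection$pathways, function(p) {
    mem <- intersect(p$members, universe)
    mapped <- intersect(mem, query)
    k <- length(mapped)
    if (k == 0L) return(NULL)
    cmn <- length(intersect(mapped, common_genes))
    u1 <- length(intersect(mapped, s1)) - cmn
    u2 <- length(intersect(mapped, s2)) - cmn
    data.frame(pathway_id = p$pathway_id, display_name = p$display_name,
               source_db = p$source_db,
               p_raw = hypergeom_tail(k, length(mem), n, N),
               total = k, unique1 = u1, unique2 = u2, common = cmn,
               k = k, K = length(mem), n = n, N = N,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  n_tested <- length(rows)
  if (n_tested == 0L) {
    res <- data.frame(pathway_id = character(0), display_name = character(0),
                      source_db = character(0), label = character(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      total = integer(0), unique1 = integer(0),
                      unique2 = integer(0), common = integer(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0))
  } else {
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab$p_adj <- bh_adjust(tab$p_raw)
    tab <- tab[tab$p_adj < alpha, , drop = FALSE]
    if (nrow(tab) > 0L) {
      tab$label <- mapply(classify_specificity, tab$unique1, tab$unique2,
                          tab$common, MoreArgs = list(tau = tau))
      tab <- tab[order(tab$p_adj, tab$pathway_id), , drop = FALSE]
    } else {
      tab$label <- character(0)
    }
    rownames(tab) <- NULL
    res <- tab[, c("pathway_id", "display_name", "source_db", "label",
                   "p_raw", "p_adj", "total", "unique1", "unique2", "common",
                   "k", "K", "n", "N")]
  }
  attr(res, "n_tested") <- n_tested
  attr(res, "query_size") <- n
  attr(res, "universe_size") <- N
  attr(res, "clusters") <- c(cluster1$label, cluster2$label)
  res
}
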