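#' Write a network to SIF, GraphML or TSV
#'
#' Exports any of the package's networks (PPI, annotated PPI, crosstalk
#' graph) in Cytoscape-compatible formats. SIF writes one
#' `nodeA <TAB> relation <TAB> nodeB` line per edge, the relation token
#' taken from the `etype` edge attribute when present (falling back to
#' `"pp"`). GraphML (via [igraph::write_graph()]) carries all node and
#' edge attributes, e.g. node class, per-disease partner degrees,
#' specificity labels and kappa scores. TSV writes a `source`/`target`
#' table plus any edge attributes; reading it back reproduces the edge
#' set exactly.
#'
#' @param graph An `igraph` graph.
#' @param path Output path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(graph, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(graph, "igraph"))
  format <- match.arg(format)
  if (format == "graphml") {
    # igraph's GraphML writer rejects logicals; coerce to 0/1
    for (at in igraph::vertex_attr_names(graph)) {
      v <- igraph::vertex_attr(graph, at)
      if (is.logical(v)) graph <- igraph::set_vertex_attr(graph, at, value = as.integer(v))
    }
    for (at in igraph::edge_attr_names(graph)) {
      v <- igraph::edge_attr(graph, at)
      if (is.logical(v)) graph <- igraph::set_edge_attr(graph, at, value = as.integer(v))
    }
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (format == "sif") {
    if (nrow(el) == 0L) {
      writeLines(character(0), path)
    } else {
      rel <- igraph::edge_attr(graph, "etype") %||% rep("pp", nrow(el))
      rel[is.na(rel)] <- "pp"
      writeLines(paste(el[, 1L], rel, el[, 2L], sep = "\t"), path)
    }
    return(invisible(path))
  }
  d <- data.frame(source = el[, 1L], target = el[, 2L],
                  stringsAsFactors = FALSE)
  for (at in igraph::edge_attr_names(graph)) {
    d[[at]] <- igraph::edge_attr(graph, at)
  }
  if (nrow(d) == 0L) d <- d[0L, c("source", "target"), drop = FALSE]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a two-cluster enrichment table
#'
#' Writes the significant-pathway table with the columns: pathway name,
#' specificity label, adjusted p-value, total mapped gene count, unique
#' cluster-1 count, unique cluster-2 count, common count. Rows are written
#' in the order given (the enrichment result is already sorted by adjusted
#' p-value, ties preserving input order).
#'
#' @param records Enrichment result data frame from
#'   [enrich_two_cluster()].
#' @param path Output path (TSV).
#' @return Invisibly, `path`.
#' @export
write_enrichment_table <- function(records, path) {
  cols <- c("pathway", "specificity", "p_adj", "total",
            "unique1", "unique2", "common")
  if (is.null(records) || nrow(records) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- data.frame(pathway = records$display_name,
                    specificity = records$label,
                    p_adj = records$p_adj,
                    total = records$total,
                    unique1 = records$unique1,
                    unique2 = records$unique2,
                    common = records$common,
                    stringsAsFactors = FALSE)
  names(out) <- cols
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
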