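#' Read a protein-protein interaction table
#'
#' Reads a tab-delimited interaction table into an undirected
#' [igraph::igraph] network. Two column presets are supported:
#' `"edgelist"` (interactor symbols in columns 1 and 2) and `"hprd"`
#' (the HPRD binary-PPI flat-file layout, interactor gene symbols in
#' columns 1 and 4). Explicit `col_a`/`col_b` (1-based) override the
#' preset. Cleaning follows the usual interactome conventions:
#' self-interactions are removed, duplicate unordered pairs are collapsed
#' to one edge (first occurrence wins, with a warning when duplicates were
#' present), and nodes left without any edge are dropped.
#'
#' @param path Path to the TSV file. Lines starting with `#` and blank
#'   lines are skipped.
#' @param dialect Column preset, `"edgelist"` or `"hprd"`.
#' @param col_a,col_b Optional 1-based column indices overriding the
#'   preset.
#' @return An undirected simple `igraph` graph whose vertex names are
#'   normalized protein symbols.
#' @export
read_ppi_table <- function(path, dialect = c("edgelist", "hprd"),
                           col_a = NULL, col_b = NULL) {
  if (!file.exists(path)) {
    stop("cannot read PPI table: no such file: ", path, call. = FALSE)
  }
  dialect <- match.arg(dialect)
  if (is.null(col_a) || is.null(col_b)) {
    cols <- switch(dialect, edgelist = c(1L, 2L), hprd = c(1L, 4L))
    col_a <- col_a %||% cols[1L]
    col_b <- col_b %||% cols[2L]
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("PPI table contains no interaction rows: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(col_a, col_b)
  if (any(lengths(fields) < need)) {
    stop("PPI table column index out of range: need ", need,
         " columns, row ", which(lengths(fields) < need)[1L],
         " has ", min(lengths(fields)), call. = FALSE)
  }
  a <- normalize_symbols(vapply(fields, `[`, character(1), col_a))
  b <- normalize_symbols(vapply(fields, `[`, character(1), col_b))
  if (length(a) != length(fields) || length(b) != length(fields)) {
    stop("PPI table has rows with empty interactor symbols: ", path,
         call. = FALSE)
  }
  edges_from_pairs(a, b, source = path)
}

# Canonicalize symbol pairs into a clean undirected igraph: drop
# self-loops, collapse duplicate unordered pairs (first occurrence wins).
edges_from_pairs <- function(a, b, source = "input") {
  self <- a == b
  a <- a[!self]; b <- b[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate interaction pair(s) collapsed in ", source,
            call. = FALSE)
  }
  lo <- lo[!dup]; hi <- hi[!dup]
  if (length(lo) == 0L) {
    stop("no interactions survive cleaning (self-loops/duplicates): ",
         source, call. = FALSE)
  }
  igraph::graph_from_data_frame(data.frame(from = lo, to = hi,
                                           stringsAsFactors = FALSE),
                                directed = FALSE)
}

#' Validate interaction-network invariants
#'
#' Checks that a graph is undirected, simple (no self-loops, no duplicate
#' unordered pairs) and free of isolated nodes.
#'
#' @param graph An `igraph` graph.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
validate_interaction_network <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::is_directed(graph)) stop("network must be undirected", call. = FALSE)
  if (any(igraph::which_loop(graph))) stop("network contains self-loops", call. = FALSE)
  if (any(igraph::which_multiple(graph))) {
    stop("network contains duplicate edges", call. = FALSE)
  }
  if (any(igraph::degree(graph) == 0L)) {
    stop("network contains isolated nodes", call. = FALSE)
  }
  invisible(TRUE)
}
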