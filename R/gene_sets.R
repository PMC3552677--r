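#' Construct a labelled gene set
#'
#' A `gene_set` is a labelled, normalized set of gene symbols for one
#' disease cluster. Symbols are uppercased, whitespace-stripped and
#' deduplicated; empty symbols are dropped.
#'
#' @param members Character vector of gene symbols.
#' @param label Non-empty short identifier, e.g. `"SCZ"`.
#' @return An object of class `gene_set` with fields `label` and `members`
#'   (sorted, unique, normalized).
#' @export
#' @examples
#' gene_set(c("tcf7l2", "TCF7L2", " akt1 "), "T2D")
gene_set <- function(members, label) {
  if (!is.character(label) || length(label) != 1L || !nzchar(trimws(label))) {
    stop("gene set label must be a non-empty string", call. = FALSE)
  }
  members <- sort(unique(normalize_symbols(members)))
  if (length(members) == 0L) {
    stop("gene set '", label, "' has no valid symbols", call. = FALSE)
  }
  structure(list(label = label, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$label, ": ", length(x$members), " symbols\n", sep = "")
  invisible(x)
}

#' Read a disease gene list from a text file
#'
#' Accepts plain text with one symbol per line, or a tab-separated table
#' whose first column holds the symbol. Blank lines and lines starting
#' with `#` are ignored. Symbols are normalized (uppercase, trimmed) and
#' duplicates collapsed.
#'
#' @param path Path to the file.
#' @param label Label for the resulting set (e.g. the disease name).
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, label) {
  if (!file.exists(path)) {
    stop("cannot read gene list: no such file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  symbols <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1L)
  symbols <- normalize_symbols(symbols)
  if (length(symbols) == 0L) {
    stop("gene list file contains no valid symbols: ", path, call. = FALSE)
  }
  gene_set(symbols, label)
}

#' Write a gene set to a plain-text file, one symbol per line
#'
#' @param set A [gene_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_list <- function(set, path) {
  stopifnot(inherits(set, "gene_set"))
  writeLines(set$members, path)
  invisible(path)
}
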