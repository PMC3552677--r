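#' Construct a pathway collection
#'
#' A `pathway_collection` holds named pathways (each a set of normalized
#' gene symbols) together with a background universe for enrichment
#' testing. When `universe` is not supplied it is derived as the union of
#' all pathway member sets, the usual default for annotation-based
#' over-representation tools.
#'
#' @param pathways A list of pathway definitions; each element is a list
#'   with fields `pathway_id`, `display_name`, `source_db` and `members`.
#' @param universe Optional character vector overriding the background.
#' @return An object of class `pathway_collection` with fields `pathways`
#'   (named by `pathway_id`) and `universe`.
#' @export
pathway_collection <- function(pathways, universe = NULL) {
  if (length(pathways) == 0L) stop("pathway collection is empty", call. = FALSE)
  ids <- vapply(pathways, function(p) p$pathway_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate pathway_id in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  pathways <- lapply(pathways, function(p) {
    p$members <- sort(unique(normalize_symbols(p$members)))
    if (length(p$members) == 0L) {
      stop("pathway '", p$pathway_id, "' has no members", call. = FALSE)
    }
    p
  })
  names(pathways) <- ids
  derived <- sort(unique(unlist(lapply(pathways, `[[`, "members"), use.names = FALSE)))
  if (is.null(universe)) {
    universe <- derived
  } else {
    universe <- sort(unique(normalize_symbols(universe)))
    if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  }
  structure(list(pathways = pathways, universe = universe),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("<pathway_collection> ", length(x$pathways), " pathways, universe of ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Read pathway annotations in GMT format
#'
#' Standard tab-delimited GMT: each line is `name <TAB> description <TAB>
#' member1 <TAB> member2 ...` with at least three fields. The description
#' field is kept as the pathway's source tag (many GMT exports put the
#' originating database or a URL there). Member symbols are normalized and
#' deduplicated; the background universe is the union of all member sets.
#'
#' @param path Path to a GMT file.
#' @param source_db Optional source tag applied to every pathway,
#'   overriding the per-line description field.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path, source_db = NULL) {
  if (!file.exists(path)) {
    stop("cannot read GMT: no such file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("GMT file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- lineno[which(nf < 3L)[1L]]
    stop("malformed GMT line ", bad, " in ", path,
         ": expected >= 3 tab-separated fields", call. = FALSE)
  }
  pathways <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    list(pathway_id = trimws(f[1L]),
         display_name = trimws(f[1L]),
         source_db = source_db %||% trimws(f[2L]),
         members = f[-(1:2)])
  })
  pathway_collection(pathways)
}

#' Merge several pathway collections into one testing family
#'
#' Used to combine annotations from multiple databases (e.g. KEGG and
#' BioCarta GMT exports) into a single collection so that multiple-testing
#' adjustment is applied across one joint family. The universe is re-derived
#' as the union of all member sets unless overridden.
#'
#' @param ... `pathway_collection` objects.
#' @param universe Optional explicit background.
#' @return A [pathway_collection()].
#' @export
merge_collections <- function(..., universe = NULL) {
  colls <- list(...)
  stopifnot(length(colls) >= 1L,
            all(vapply(colls, inherits, logical(1), "pathway_collection")))
  pathway_collection(unlist(lapply(colls, `[[`, "pathways"), recursive = FALSE,
                            use.names = FALSE),
                     universe = universe)
}

#' Override the background universe of a collection
#'
#' @param collection A [pathway_collection()].
#' @param universe Character vector of background gene symbols (e.g. read
#'   from a file with [read_gene_list()]).
#' @return The collection with the new universe.
#' @export
set_background <- function(collection, universe) {
  stopifnot(inherits(collection, "pathway_collection"))
  pathway_collection(unname(collection$pathways), universe = universe)
}
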