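#' Gene-set collection
#'
#' A named family of gene sets standing for one of the two annotation
#' universes used throughout the package: large mosaic *pathway maps* or the
#' small functionally meaningful pathway segments called *networks*. Each
#' element (e.g. `"hsa04010"` or `"N00924"`) maps to a non-empty set of gene
#' identifiers (e.g. `"hsa:5594"`). Gene identifiers are opaque strings:
#' equality is literal string equality and no namespace normalization is
#' performed.
#'
#' @param members named list of character vectors; names are element IDs,
#'   values the gene IDs belonging to each element. Duplicate genes within an
#'   element are removed.
#' @param kind `"pathway"` or `"network"`.
#' @return An object of class `gene_set_collection`: the deduplicated member
#'   list with attributes `kind`.
#' @examples
#' gene_set_collection(list(N1 = c("g1", "g2"), N2 = "g2"), kind = "network")
#' @export
gene_set_collection <- function(members, kind = c("pathway", "network")) {
  kind <- match.arg(kind)
  if (!is.list(members)) {
    stop("`members` must be a named list of character vectors")
  }
  ids <- names(members)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("every element of `members` must be named with a non-empty element ID")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate element IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  members <- lapply(members, function(g) unique(as.character(g)))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    stop("empty gene sets are not allowed (elements: ",
         paste(ids[empty], collapse = ", "), ")")
  }
  structure(members, kind = kind, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> kind=%s, %d elements, %d distinct genes\n",
              attr(x, "kind"), length(x), length(collection_genes(x))))
  invisible(x)
}

#' Kind ("pathway" or "network") of a collection
#' @param x a [gene_set_collection()].
#' @return character scalar.
#' @export
collection_kind <- function(x) {
  stopifnot(inherits(x, "gene_set_collection"))
  attr(x, "kind")
}

#' Union of all genes contained in a collection
#'
#' For the network universe this is the pooled gene content of all network
#' elements, i.e. the set against which "drugs targeting any network" is
#' defined.
#'
#' @param x a [gene_set_collection()].
#' @return character vector of distinct gene IDs.
#' @export
collection_genes <- function(x) {
  stopifnot(inherits(x, "gene_set_collection"))
  unique(unlist(unclass(x), use.names = FALSE))
}

# gene -> element-IDs inverted index; the workhorse behind all overlap scores
invert_collection <- function(x) {
  stopifnot(inherits(x, "gene_set_collection"))
  genes <- unlist(unclass(x), use.names = FALSE)
  elems <- rep(names(x), lengths(x))
  split(elems, genes)
}

#' Read a two-column element/gene link file
#'
#' Parses the flat tab-separated dialect used by pathway-map/gene and
#' network/gene association dumps: one `element-ID<TAB>gene-ID` pair per
#' line, `#` comment lines allowed, duplicate pairs tolerated and removed.
#'
#' @param path path to the link file.
#' @param kind `"pathway"` or `"network"`; recorded on the returned
#'   collection.
#' @return A [gene_set_collection()] with one gene set per distinct
#'   element ID. The result does not depend on line order.
#' @export
read_link_file <- function(path, kind = c("pathway", "network")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("link file '", path, "' contains no data lines")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed link line (expected 2 tab-separated columns) in '",
         path, "' at line ", lineno[which(bad)[1L]])
  }
  elem <- vapply(parts, `[[`, character(1), 1L)
  gene <- vapply(parts, `[[`, character(1), 2L)
  if (any(elem == "") || any(gene == "")) {
    stop("empty element or gene ID in '", path, "' at line ",
         lineno[which(elem == "" | gene == "")[1L]])
  }
  members <- lapply(split(gene, elem), unique)
  gene_set_collection(members[order(names(members))], kind = kind)
}

#' Write a collection back to the two-column link dialect
#'
#' Inverse of [read_link_file()]: `read_link_file(write_link_file(x, f))`
#' reproduces the same element-to-gene-set mapping.
#'
#' @param x a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_link_file <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  ids <- sort(names(x))
  lines <- unlist(lapply(ids, function(id) paste0(id, "\t", sort(x[[id]]))),
                  use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
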