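#' Gene sets and gene-set collections
#'
#' A gene set is a named collection of gene identifiers (the set S tested
#' for enrichment); a collection is a named list of gene sets, typically
#' loaded from a GMT file.
#'
#' @param name set name.
#' @param members character vector of gene IDs; canonicalized to upper
#'   case, duplicates dropped.
#' @param description free-text description (GMT column 2).
#' @return `gene_set()` returns an object of class `gene_set`;
#'   `gene_set_collection()` an object of class `gene_set_collection`.
#' @export
gene_set <- function(name, members, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string")
  members <- unique(canonical_gene_ids(members))
  members <- members[nzchar(members)]
  if (!length(members)) stop("gene set '", name, "' has no members")
  structure(list(name = name, members = members,
                 description = as.character(description)),
            class = "gene_set")
}

#' @rdname gene_set
#' @param sets list of `gene_set` objects.
#' @export
gene_set_collection <- function(sets) {
  if (!all(vapply(sets, inherits, logical(1), "gene_set")))
    stop("all elements must be gene_set objects")
  nms <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate gene-set names")
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$members), integer(1))
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x), if (length(x)) min(sizes) else 0L,
              if (length(x)) max(sizes) else 0L))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(unclass(x))

#' @export
`[.gene_set_collection` <- function(x, i) {
  structure(unclass(x)[i], class = "gene_set_collection")
}

#' Read and write GMT gene-set files
#'
#' GMT is the standard tab-separated gene-set format: one set per line,
#' fields are name, description, then the member gene IDs.
#'
#' @param path file path.
#' @return `read_gmt()` returns a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d in %s (need name, description, >=1 member)",
                   i, path))
    gene_set(f[1L], f[-(1:2)], description = f[2L])
  })
  gene_set_collection(sets)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else "na",
            s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
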