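#' Ranked gene list
#'
#' The ordered list L of all N genes with a per-gene ranking metric r.
#' Genes are sorted by metric, descending; ties are broken by gene ID in
#' C-locale lexicographic order so that the ordering is total and
#' deterministic.
#'
#' @param r named numeric vector: gene ID -> ranking-metric value. All
#'   values must be finite; gene IDs are canonicalized and must be unique
#'   after canonicalization.
#' @return An object of class `ranked_list`: list with `genes` (ordered
#'   IDs), `r` (metric values in list order, named) and `n`.
#' @export
ranked_list <- function(r) {
  if (!is.numeric(r) || is.null(names(r)))
    stop("`r` must be a named numeric vector")
  if (any(!is.finite(r))) stop("ranking metric must be finite")
  names(r) <- canonical_gene_ids(names(r))
  if (anyDuplicated(names(r))) stop("duplicate gene IDs in ranked list")
  ord <- order(-r, names(r), method = "radix")
  r <- r[ord]
  structure(list(genes = names(r), r = r, n = length(r)),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("ranked_list: %d genes, metric range [%.4g, %.4g]\n",
              x$n, min(x$r), max(x$r)))
  cat("top:", paste(utils::head(x$genes, 5L), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write RNK files
#'
#' RNK is the standard pre-ranked format: two tab-separated columns,
#' gene ID and ranking metric, no header, sorted descending on write.
#'
#' @param path file path.
#' @return `read_rnk()` returns a [ranked_list()].
#' @export
read_rnk <- function(path) {
  if (!file.exists(path)) stop("RNK file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("gene", "metric"))
  v <- suppressWarnings(as.numeric(tab$metric))
  bad <- which(is.na(v))
  if (length(bad))
    stop(sprintf("non-numeric metric in %s, line %d", path, bad[1L]))
  ranked_list(stats::setNames(v, tab$gene))
}

#' @rdname read_rnk
#' @param ranked a [ranked_list()].
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(
    data.frame(gene = ranked$genes, metric = unname(ranked$r)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
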