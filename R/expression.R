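#' Expression matrix with sample-to-group map
#'
#' Light container for a genes x samples expression matrix (counts or
#' normalized expression) together with the group label of every sample.
#' Gene identifiers are canonicalized to upper case with surrounding
#' whitespace stripped; duplicated gene rows are collapsed by summation.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs). Values must be finite and
#'   non-negative.
#' @param groups named character vector mapping every sample ID to its
#'   group label.
#' @return An object of class `expr_matrix`: a list with elements
#'   `values` (the canonicalized matrix) and `groups`.
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0))
    stop("expression values must be non-negative")
  groups <- vapply(groups, as.character, character(1))
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]

  rownames(values) <- canonical_gene_ids(rownames(values))
  if (anyDuplicated(rownames(values))) {
    values <- rowsum(values, group = rownames(values), reorder = FALSE)
  }
  if (nrow(values) == 0L) stop("empty expression matrix")
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

canonical_gene_ids <- function(x) toupper(trimws(as.character(x)))

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

group_columns <- function(expr, group) {
  idx <- which(expr$groups == group)
  if (!length(idx)) stop("group not present: ", group)
  idx
}

#' Read an expression matrix and its group map from TSV files
#'
#' The counts file is tab-separated with a header row of sample IDs and a
#' first column named `gene`; the group map is a two-column TSV
#' (sample, group). Sample IDs in the two files must agree.
#'
#' @param counts_path path to the genes x samples TSV.
#' @param group_map_path path to the two-column sample/group TSV.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(counts_path, group_map_path) {
  if (!file.exists(counts_path))
    stop("counts file not found: ", counts_path)
  if (!file.exists(group_map_path))
    stop("group map file not found: ", group_map_path)
  tab <- utils::read.delim(counts_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("counts file needs a gene column plus >= 1 sample column: ",
         counts_path)
  genes <- as.character(tab[[1L]])
  num <- tab[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric cell in %s, column '%s', data line %d",
                   counts_path, colnames(num)[j], bad[1L]))
    num[[j]] <- v
  }
  values <- as.matrix(num)
  rownames(values) <- genes
  gm <- utils::read.delim(group_map_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(gm) < 2L)
    stop("group map must have two columns (sample, group): ", group_map_path)
  groups <- stats::setNames(as.character(gm[[2L]]), as.character(gm[[1L]]))
  absent <- setdiff(names(groups), colnames(values))
  if (length(absent))
    stop("group map references absent sample(s): ",
         paste(absent, collapse = ", "))
  values <- values[, names(groups), drop = FALSE]
  expr <- expression_matrix(values, groups)
  message(sprintf("read_expression: %d genes x %d samples from %s",
                  nrow(expr$values), ncol(expr$values), counts_path))
  expr
}

#' Write an expression matrix and its group map as TSV
#'
#' @param expr an [expression_matrix()] object.
#' @param counts_path,group_map_path output paths.
#' @return Invisibly, `expr`.
#' @export
write_expression <- function(expr, counts_path, group_map_path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gm <- data.frame(sample = names(expr$groups), group = unname(expr$groups),
                   stringsAsFactors = FALSE)
  utils::write.table(gm, group_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr)
}
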