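#' Degeneration-specific gene sets from a contrast
#'
#' Splits the differential calls of a contrast into an up-set, a down-set
#' and a combined signed set carrying each gene's direction. The signed
#' set feeds the direction-aware cross-contrast enrichment; the plain
#' up/down sets support the unsigned variant and set arithmetic.
#'
#' @param dge_A a `dge_result` for the defining contrast (e.g.
#'   degeneration vs control).
#' @param name_prefix prefix for the generated set names.
#' @return List with elements `up_set`, `down_set` (either may be absent
#'   from the universe of calls and is then NULL) and `signed_set`, a
#'   [gene_set()] of all differential genes whose `direction` attribute
#'   maps each member to `"up"` or `"down"`.
#' @export
build_pand_gene_set <- function(dge_A, name_prefix = "PAND") {
  stopifnot(inherits(dge_A, "dge_result"))
  up <- dge_A$gene[dge_A$call == "up"]
  down <- dge_A$gene[dge_A$call == "down"]
  if (!length(up) && !length(down))
    stop("contrast has zero differential genes; review the p/log2FC thresholds")
  signed <- gene_set(paste0(name_prefix, "_SPECIFIC"), c(up, down),
                     description = "direction-aware differential set")
  dir <- stats::setNames(rep(c("up", "down"), c(length(up), length(down))),
                         canonical_gene_ids(c(up, down)))
  attr(signed, "direction") <- dir[signed$members]
  list(up_set = if (length(up)) gene_set(paste0(name_prefix, "_UP"), up),
       down_set = if (length(down)) gene_set(paste0(name_prefix, "_DOWN"), down),
       signed_set = signed)
}

#' Pair two contrasts for cross-contrast analysis
#'
#' Binds the defining contrast's calls (A), the second contrast's calls
#' (B) and contrast B's ranked list; all counting happens on the shared
#' gene universe. Supplying `expr_B` with its group labels enables
#' phenotype permutations for the inverted-enrichment test (the ranked
#' list is derived from it when `ranked_B` is not given).
#'
#' @param dge_A,dge_B `dge_result` objects for the two contrasts.
#' @param ranked_B a [ranked_list()] for contrast B; derived from
#'   `expr_B` when NULL.
#' @param expr_B optional [expression_matrix()] for contrast B.
#' @param treated_B,reference_B group labels within `expr_B`.
#' @return An object of class `contrast_pair`.
#' @export
contrast_pair <- function(dge_A, dge_B, ranked_B = NULL, expr_B = NULL,
                          treated_B = NULL, reference_B = NULL) {
  stopifnot(inherits(dge_A, "dge_result"), inherits(dge_B, "dge_result"))
  if (is.null(ranked_B)) {
    if (is.null(expr_B))
      stop("supply ranked_B or expr_B (with treated_B/reference_B)")
    ranked_B <- rank_genes(expr_B, treated_B, reference_B)
  }
  shared <- intersect(dge_A$gene, ranked_B$genes)
  if (!length(shared)) stop("empty shared gene universe between contrasts")
  structure(list(dge_A = dge_A, dge_B = dge_B, ranked_B = ranked_B,
                 expr_B = expr_B, treated_B = treated_B,
                 reference_B = reference_B, shared_universe = shared),
            class = "contrast_pair")
}

#' @export
print.contrast_pair <- function(x, ...) {
  cat(sprintf("contrast_pair: %d shared genes; A: %d up / %d down; B: %d up / %d down\n",
              length(x$shared_universe),
              attr(x$dge_A, "n_up"), attr(x$dge_A, "n_down"),
              attr(x$dge_B, "n_up"), attr(x$dge_B, "n_down")))
  invisible(x)
}

# Direction-aware ranked list for contrast B: the metric of every A-down
# gene is negated before re-sorting, so concordant regulation pushes the
# whole signed set to the top (positive ES) and inverted regulation to the
# bottom (negative ES).
flip_ranked <- function(r, genes, down_genes) {
  flip <- genes %in% down_genes
  r[flip] <- -r[flip]
  r
}

#' Cross-contrast inverted enrichment test
#'
#' Tests whether the genes that define contrast A's differential signature
#' are concordantly or inversely regulated in contrast B. The
#' direction-aware statistic scores A-up genes by their contrast-B metric
#' and A-down genes by its negation, re-sorts the whole list and applies
#' the running-sum enrichment score to the combined signed set: a positive
#' NES means the A signature is recapitulated in B, a negative NES means
#' it is inverted. Alongside the enrichment, the report counts by exact
#' set arithmetic how many A-up genes are called down in B and how many
#' A-down genes are called up (the inverted genes), over the shared
#' universe.
#'
#' Significance comes from phenotype permutations when the pair carries
#' contrast B's expression matrix (labels reshuffled, metric recomputed
#' and re-flipped every time), otherwise from gene-set permutations on the
#' flipped ranked list. The unsigned variant (A's up-set alone against the
#' unflipped contrast-B ranking) is reported too for comparison when
#' `include_unsigned = TRUE`.
#'
#' @param pair a [contrast_pair()].
#' @param n_permutations permutations (default 1000).
#' @param seed integer seed (required).
#' @param w weight exponent for the running sum.
#' @param include_unsigned also test A's up-set against the plain
#'   contrast-B ranking.
#' @return An object of class `inversion_report`: the four counts, the
#'   direction-aware `es`/`nes`/`p_value`, the per-gene table of calls and
#'   inverted flags, and optionally `unsigned` (an `enrichment_result`).
#' @export
inverted_enrichment <- function(pair, n_permutations = 1000, seed, w = 1,
                                include_unsigned = FALSE) {
  stopifnot(inherits(pair, "contrast_pair"))
  if (missing(seed)) stop("`seed` is required")
  sets <- build_pand_gene_set(pair$dge_A)
  signed <- sets$signed_set
  cov <- mean(signed$members %in% pair$ranked_B$genes)
  if (cov < 0.9)
    warning(sprintf("only %.0f%% of the signature is covered by contrast B's universe",
                    100 * cov))
  down_genes <- names(attr(signed, "direction"))[attr(signed, "direction") == "down"]

  set.seed(as.integer(seed))
  r_obs <- flip_ranked(pair$ranked_B$r, names(pair$ranked_B$r), down_genes)
  ranked_flip <- ranked_list(r_obs)
  profile <- compute_es(ranked_flip, signed, w = w)

  mode <- if (!is.null(pair$expr_B)) "phenotype" else "gene_set"
  if (mode == "phenotype") {
    perm_ranks <- phenotype_permuted_rankings(pair$expr_B, pair$treated_B,
                                              pair$reference_B, n_permutations)
    genes_base <- rownames(pair$expr_B$values)
    flip_mask <- genes_base %in% down_genes
    mask <- genes_base %in% signed$members
    es_perm <- vapply(perm_ranks, function(pr) {
      r <- pr$r
      r[flip_mask] <- -r[flip_mask]
      ord <- order(-r, genes_base, method = "radix")
      es_core(mask[ord], abs(r[ord])^w)
    }, numeric(1))
  } else {
    n <- ranked_flip$n
    nh <- profile$n_hits
    absr_w <- abs(ranked_flip$r)^w
    es_perm <- vapply(seq_len(n_permutations), function(i) {
      h <- logical(n); h[sample.int(n, nh)] <- TRUE
      es_core(h, absr_w)
    }, numeric(1))
  }
  st <- permutation_stats(profile$es, es_perm)

  tab <- inversion_table(pair)
  counts <- attr(tab, "counts")

  unsigned <- NULL
  if (include_unsigned && !is.null(sets$up_set)) {
    unsigned <- if (mode == "phenotype")
      permutation_test(pair$expr_B, sets$up_set, pair$treated_B,
                       pair$reference_B, n_permutations = n_permutations,
                       mode = "phenotype", seed = seed, w = w)
    else
      permutation_test(pair$ranked_B, sets$up_set,
                       n_permutations = n_permutations, mode = "gene_set",
                       seed = seed, w = w)
  }

  structure(list(n_up_A = counts[["n_up_A"]],
                 n_up_A_down_B = counts[["n_up_A_down_B"]],
                 n_down_A = counts[["n_down_A"]],
                 n_down_A_up_B = counts[["n_down_A_up_B"]],
                 es = profile$es, nes = st$nes, p_value = st$p,
                 n_permutations = n_permutations, permutation_mode = mode,
                 leading_edge = leading_edge(profile, ranked_flip, signed),
                 table = tab, unsigned = unsigned),
            class = "inversion_report")
}

#' Per-gene cross-contrast call table
#'
#' One row per shared-universe gene with its call in each contrast and a
#' flag marking direction inversion (opposite non-ns calls). Column order
#' is fixed (gene, call_A, call_B, inverted) and rows are sorted by gene
#' ID, so output files are byte-stable. The four summary counts are
#' attached as the `counts` attribute.
#'
#' @param pair a [contrast_pair()].
#' @return data.frame with attribute `counts`.
#' @export
inversion_table <- function(pair) {
  stopifnot(inherits(pair, "contrast_pair"))
  shared <- sort(pair$shared_universe, method = "radix")
  call_A <- stats::setNames(pair$dge_A$call, pair$dge_A$gene)[shared]
  call_B_map <- stats::setNames(pair$dge_B$call, pair$dge_B$gene)
  call_B <- ifelse(shared %in% names(call_B_map), call_B_map[shared], "ns")
  inverted <- (call_A == "up" & call_B == "down") |
              (call_A == "down" & call_B == "up")
  tab <- data.frame(gene = shared, call_A = unname(call_A),
                    call_B = unname(call_B), inverted = inverted,
                    row.names = NULL, stringsAsFactors = FALSE)
  counts <- c(n_up_A = sum(call_A == "up"),
              n_up_A_down_B = sum(call_A == "up" & call_B == "down"),
              n_down_A = sum(call_A == "down"),
              n_down_A_up_B = sum(call_A == "down" & call_B == "up"))
  attr(tab, "counts") <- counts
  tab
}

#' @export
print.inversion_report <- function(x, ...) {
  cat("inversion_report (direction-aware cross-contrast enrichment)\n")
  cat(sprintf("  NES = %.3f, p = %.4g (%s, %d permutations)\n",
              x$nes, x$p_value, x$permutation_mode, x$n_permutations))
  cat(sprintf("  %d of %d A-up genes are down in B; %d of %d A-down genes are up in B\n",
              x$n_up_A_down_B, x$n_up_A, x$n_down_A_up_B, x$n_down_A))
  if (!is.null(x$unsigned))
    cat(sprintf("  unsigned up-set NES = %.3f, p = %.4g\n",
                x$unsigned$nes, x$unsigned$p_value))
  invisible(x)
}

#' Write the inversion table with its summary footer
#'
#' @param report an `inversion_report`.
#' @param path output TSV path.
#' @export
write_inversion <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(report$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sprintf("# n_up_A=%d n_up_A_down_B=%d n_down_A=%d n_down_A_up_B=%d nes=%.6f p=%.6g",
                     report$n_up_A, report$n_up_A_down_B, report$n_down_A,
                     report$n_down_A_up_B, report$nes, report$p_value), con)
  invisible(path)
}
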