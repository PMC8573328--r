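#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list L and accumulates two cumulative
#' distributions: the hit distribution P_hit, the running normalized sum
#' of |r_j|^w over members of S encountered so far, and the miss
#' distribution P_miss, the running count of non-members divided by
#' N - N_h. The enrichment score is the signed value of
#' P_hit - P_miss at the position where |P_hit - P_miss| is maximal, so
#' its magnitude is the maximum deviation statistic and its sign says
#' whether S concentrates at the top (positive) or bottom (negative) of
#' the list. With w = 0 the magnitude reduces to the classical two-sample
#' Kolmogorov-Smirnov statistic between hit and miss rank positions.
#'
#' Both cumulative distributions reach exactly 1 at the end of the list,
#' so the running difference terminates at 0; this is asserted on every
#' call.
#'
#' @param ranked a [ranked_list()].
#' @param gene_set a [gene_set()]; scored on its intersection with the
#'   ranked universe, which must be non-empty and a proper subset.
#' @param w weight exponent applied to |r_j| (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov form).
#' @return An object of class `enrichment_profile`: list with
#'   `running_score` (length-N numeric), `es`, `es_position`,
#'   `weight_exponent`, `hits` (logical along the ranked list), `n_hits`
#'   and `set_name`.
#' @export
compute_es <- function(ranked, gene_set, w = 1) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(gene_set, "gene_set"))
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 0)
    stop("`w` must be a single non-negative number")
  hits <- ranked$genes %in% gene_set$members
  core <- es_core(hits, abs(ranked$r)^w, full = TRUE)
  structure(list(running_score = core$running, es = core$es,
                 es_position = core$pos, weight_exponent = w,
                 hits = hits, n_hits = sum(hits),
                 set_name = gene_set$name),
            class = "enrichment_profile")
}

# Shared running-sum kernel. `hits` is a logical vector along the ranked
# list, `absr_w` the already-exponentiated |r|^w in the same order. The
# fast path (full = FALSE) returns only the signed extreme deviation.
es_core <- function(hits, absr_w, full = FALSE) {
  n <- length(hits)
  nh <- sum(hits)
  if (nh == 0L) stop("gene set has no members in the ranked universe")
  if (nh == n) stop("gene set covers the whole ranked universe (N - N_h = 0)")
  denom <- sum(absr_w[hits])
  if (denom == 0)
    stop("degenerate normalizer: all |r|^w are zero over the gene set")
  inc <- numeric(n)
  inc[hits] <- absr_w[hits] / denom
  inc[!hits] <- -1 / (n - nh)
  running <- cumsum(inc)
  if (full && abs(running[n]) > 1e-9)
    stop("internal error: running score did not terminate at 0")
  pos <- which.max(abs(running))
  if (full) list(es = running[pos], pos = pos, running = running)
  else running[pos]
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf("enrichment_profile for '%s': ES = %.4f at rank %d (N = %d, hits = %d, w = %g)\n",
              x$set_name, x$es, x$es_position, length(x$running_score),
              x$n_hits, x$weight_exponent))
  invisible(x)
}

#' Plot the running enrichment score
#'
#' Base-graphics running-score curve with hit positions marked as a rug
#' and the extreme deviation highlighted.
#'
#' @param x an `enrichment_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.enrichment_profile <- function(x, ...) {
  n <- length(x$running_score)
  graphics::plot(seq_len(n), x$running_score, type = "l",
                 xlab = "rank in ordered list",
                 ylab = "running enrichment score",
                 main = x$set_name, ...)
  graphics::abline(h = 0, lty = 3)
  graphics::rug(which(x$hits))
  graphics::points(x$es_position, x$es, pch = 19, col = "red")
  invisible(x)
}

#' Leading-edge subset of an enrichment profile
#'
#' The gene-set members driving the extreme of the running score: for a
#' positive ES, members at ranks up to and including the extreme; for a
#' negative ES, members at or after it; for ES = 0, the empty set.
#'
#' @param profile an `enrichment_profile`.
#' @param ranked the [ranked_list()] the profile was computed on.
#' @param gene_set the scored [gene_set()].
#' @return Character vector of gene IDs.
#' @export
leading_edge <- function(profile, ranked, gene_set) {
  stopifnot(inherits(profile, "enrichment_profile"),
            inherits(ranked, "ranked_list"))
  if (length(profile$running_score) != ranked$n)
    stop("profile and ranked list disagree in length")
  if (profile$es == 0) return(character(0))
  idx <- if (profile$es > 0) seq_len(profile$es_position)
         else profile$es_position:ranked$n
  intersect(ranked$genes[idx], gene_set$members)
}

#' Permutation significance for one gene set
#'
#' Estimates the significance of the observed enrichment score by
#' permutation and normalizes it into an NES. Two null models:
#'
#' * `"phenotype"` (requires an [expression_matrix()]): sample-to-group
#'   labels are shuffled within the contrast and the whole ranking is
#'   recomputed (signal-to-noise metric) for every permutation. This
#'   preserves gene-gene correlation and is the default null.
#' * `"gene_set"` (works on a bare [ranked_list()]): random member sets of
#'   the same size are drawn from the ranked universe. With
#'   `exhaustive = TRUE` every subset of size N_h is enumerated instead of
#'   sampled (only feasible for small instances).
#'
#' The p-value uses the sign-matched add-one estimator
#' `p = (1 + #\{same-sign |ES*| >= |ES|\}) / (1 + #\{same-sign permutations\})`,
#' so it can never be exactly zero; in exhaustive mode the plain
#' proportion over the enumerated subsets is used (the observed set is one
#' of them, so the p-value is still positive). The NES is the observed ES
#' divided by the mean |ES*| of same-sign permutations.
#'
#' @param x an [expression_matrix()] (phenotype mode) or [ranked_list()]
#'   (gene_set mode).
#' @param gene_set the [gene_set()] to test.
#' @param treated,reference group labels (phenotype mode only).
#' @param n_permutations number of permutations (>= 10).
#' @param mode `"phenotype"` or `"gene_set"`.
#' @param seed integer seed; required, all randomness flows through it.
#' @param w weight exponent, as in [compute_es()].
#' @param exhaustive enumerate all subsets (gene_set mode only).
#' @return An object of class `enrichment_result`.
#' @export
permutation_test <- function(x, gene_set, treated = NULL, reference = NULL,
                             n_permutations = 1000,
                             mode = c("phenotype", "gene_set"),
                             seed, w = 1, exhaustive = FALSE) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("`seed` is required for permutation tests")
  if (!exhaustive && n_permutations < 10)
    stop("n_permutations must be >= 10")
  set.seed(as.integer(seed))

  if (mode == "phenotype") {
    if (!inherits(x, "expr_matrix"))
      stop("phenotype mode needs an expression_matrix")
    if (is.null(treated) || is.null(reference))
      stop("phenotype mode needs treated and reference group labels")
    ranked <- rank_genes(x, treated, reference)
    perm_ranks <- phenotype_permuted_rankings(x, treated, reference,
                                              n_permutations)
    mask <- rownames(x$values) %in% gene_set$members
    es_perm <- vapply(perm_ranks, function(pr) {
      es_core(mask[pr$ord], abs(pr$r[pr$ord])^w)
    }, numeric(1))
  } else {
    if (!inherits(x, "ranked_list"))
      stop("gene_set mode needs a ranked_list")
    ranked <- x
  }

  profile <- compute_es(ranked, gene_set, w = w)
  nh <- profile$n_hits
  n <- ranked$n
  absr_w <- abs(ranked$r)^w

  if (mode == "gene_set") {
    if (exhaustive) {
      if (choose(n, nh) > 2e5)
        stop("exhaustive enumeration infeasible: choose(N, N_h) too large")
      subsets <- utils::combn(n, nh, simplify = FALSE)
      es_perm <- vapply(subsets, function(ix) {
        h <- logical(n); h[ix] <- TRUE
        es_core(h, absr_w)
      }, numeric(1))
      n_permutations <- length(subsets)
    } else {
      es_perm <- vapply(seq_len(n_permutations), function(i) {
        h <- logical(n); h[sample.int(n, nh)] <- TRUE
        es_core(h, absr_w)
      }, numeric(1))
    }
  }

  stats <- permutation_stats(profile$es, es_perm, exhaustive = exhaustive)
  structure(list(set_name = gene_set$name, es = profile$es,
                 nes = stats$nes, p_value = stats$p,
                 fdr_q = NA_real_,
                 leading_edge = leading_edge(profile, ranked, gene_set),
                 n_permutations = n_permutations,
                 permutation_mode = mode, n_hits = nh,
                 es_position = profile$es_position,
                 weight_exponent = w),
            class = "enrichment_result")
}

# Sign-matched add-one p-value and mean-|ES*| normalization shared by all
# permutation entry points.
permutation_stats <- function(es, es_perm, exhaustive = FALSE) {
  if (es == 0) return(list(p = 1, nes = NA_real_))
  same <- sign(es_perm) == sign(es)
  n_same <- sum(same)
  k <- sum(same & abs(es_perm) >= abs(es))
  p <- if (exhaustive) {
    if (n_same == 0) 1 else k / n_same
  } else {
    (1 + k) / (1 + n_same)
  }
  nes <- if (n_same < 2) {
    warning("fewer than 2 same-sign permutations; NES undefined")
    NA_real_
  } else {
    es / mean(abs(es_perm[same]))
  }
  list(p = p, nes = nes)
}

# Permuted signal-to-noise rankings for phenotype-label shuffles. Returns a
# list of (r, ord) pairs in matrix row order; the log transform is done once.
phenotype_permuted_rankings <- function(expr, treated, reference, n_perm) {
  it <- group_columns(expr, treated)
  ir <- group_columns(expr, reference)
  cols <- c(it, ir)
  lx <- log2(expr$values[, cols, drop = FALSE] + 1)
  genes <- rownames(expr$values)
  nt <- length(it)
  lapply(seq_len(n_perm), function(i) {
    sh <- sample(length(cols))
    r <- s2n_metric(lx, sh[seq_len(nt)], sh[-seq_len(nt)])
    list(r = r, ord = order(-r, genes, method = "radix"))
  })
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result '%s': ES = %.4f, NES = %.4f, p = %.4g (%s, %d permutations)\n",
              x$set_name, x$es, x$nes, x$p_value, x$permutation_mode,
              x$n_permutations))
  cat(sprintf("hits = %d, leading edge = %d genes\n",
              x$n_hits, length(x$leading_edge)))
  invisible(x)
}

#' Enrichment of a whole gene-set collection
#'
#' Scores every gene set in a collection against one contrast, with
#' shared permutations in phenotype mode (the same label shuffles and
#' recomputed rankings are reused for every set, the standard scheme) and
#' Benjamini-Hochberg FDR across the collection.
#'
#' @param x an [expression_matrix()] (phenotype mode) or [ranked_list()]
#'   (gene_set mode).
#' @param collection a [gene_set_collection()].
#' @param treated,reference group labels (phenotype mode).
#' @param n_permutations permutations per set.
#' @param mode `"phenotype"` or `"gene_set"`.
#' @param seed integer seed (required).
#' @param w weight exponent.
#' @param min_size,max_size size filter applied to each set's overlap with
#'   the ranked universe before testing.
#' @return A data.frame of class `gsea_result`, one row per retained set,
#'   columns `set`, `size`, `es`, `nes`, `p`, `fdr_q`, `leading_edge`
#'   (semicolon-joined), sorted by `nes` descending.
#' @export
enrich_collection <- function(x, collection, treated = NULL, reference = NULL,
                              n_permutations = 1000,
                              mode = c("phenotype", "gene_set"),
                              seed, w = 1, min_size = 5, max_size = Inf) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("`seed` is required")
  if (!inherits(collection, "gene_set_collection"))
    stop("`collection` must be a gene_set_collection")
  if (n_permutations < 10) stop("n_permutations must be >= 10")
  set.seed(as.integer(seed))

  if (mode == "phenotype") {
    if (!inherits(x, "expr_matrix"))
      stop("phenotype mode needs an expression_matrix")
    ranked <- rank_genes(x, treated, reference)
    genes_base <- rownames(x$values)
  } else {
    if (!inherits(x, "ranked_list"))
      stop("gene_set mode needs a ranked_list")
    ranked <- x
    genes_base <- ranked$genes
  }
  n <- ranked$n

  sizes <- vapply(collection, function(s) sum(s$members %in% genes_base),
                  integer(1))
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  if (!any(keep))
    stop("no gene set passes the size filter (", min_size, "..",
         if (is.finite(max_size)) max_size else "Inf", ")")
  collection <- collection[keep]
  sizes <- sizes[keep]

  if (mode == "phenotype")
    perm_ranks <- phenotype_permuted_rankings(x, treated, reference,
                                              n_permutations)
  absr_w <- abs(ranked$r)^w

  rows <- lapply(seq_along(collection), function(i) {
    gs <- collection[[i]]
    profile <- compute_es(ranked, gs, w = w)
    if (mode == "phenotype") {
      mask <- genes_base %in% gs$members
      es_perm <- vapply(perm_ranks, function(pr) {
        es_core(mask[pr$ord], abs(pr$r[pr$ord])^w)
      }, numeric(1))
    } else {
      nh <- profile$n_hits
      es_perm <- vapply(seq_len(n_permutations), function(j) {
        h <- logical(n); h[sample.int(n, nh)] <- TRUE
        es_core(h, absr_w)
      }, numeric(1))
    }
    st <- permutation_stats(profile$es, es_perm)
    data.frame(set = gs$name, size = sizes[i], es = profile$es,
               nes = st$nes, p = st$p,
               leading_edge = paste(leading_edge(profile, ranked, gs),
                                    collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr_q <- stats::p.adjust(res$p, "BH")
  res <- res[order(-res$nes, res$set, method = "radix",
                   na.last = TRUE), , drop = FALSE]
  res <- res[, c("set", "size", "es", "nes", "p", "fdr_q", "leading_edge")]
  rownames(res) <- NULL
  structure(res, class = c("gsea_result", "data.frame"),
            n_permutations = n_permutations, permutation_mode = mode,
            weight_exponent = w)
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: %d sets (%s permutations, n = %d, w = %g)\n",
              nrow(x), attr(x, "permutation_mode"),
              attr(x, "n_permutations"), attr(x, "weight_exponent")))
  print.data.frame(utils::head(x[, c("set", "size", "es", "nes", "p", "fdr_q")], 10L))
  invisible(x)
}

#' Write enrichment results as TSV and the running score as x/y pairs
#'
#' @param res a `gsea_result`.
#' @param path output TSV path.
#' @export
write_gsea <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gsea
#' @param profile an `enrichment_profile`.
#' @export
write_running_score <- function(profile, path) {
  utils::write.table(
    data.frame(rank = seq_along(profile$running_score),
               running_score = profile$running_score),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
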