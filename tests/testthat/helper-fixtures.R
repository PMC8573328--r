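# Shared fixtures and independent oracles. The oracles deliberately use
# naive loop implementations so they stay independent of the package's
# vectorized paths.

# Brute-force running-sum enrichment score: explicit P_hit/P_miss loop.
oracle_es <- function(genes_in_order, r_in_order, members, w = 1,
                      return_running = FALSE) {
  n <- length(genes_in_order)
  hits <- genes_in_order %in% members
  nh <- sum(hits)
  denom <- sum(abs(r_in_order[hits])^w)
  ph <- 0; pm <- 0
  running <- numeric(n)
  for (i in seq_len(n)) {
    if (hits[i]) ph <- ph + abs(r_in_order[i])^w / denom
    else pm <- pm + 1 / (n - nh)
    running[i] <- ph - pm
  }
  if (return_running) return(running)
  running[which.max(abs(running))]
}

# Exhaustive gene-set-permutation p-value: enumerate every subset of the
# observed size, score each with the loop oracle, and take the same-sign
# tail proportion (the observed subset is one of the enumerated ones).
oracle_subset_p <- function(ranked, members, w = 1) {
  n <- ranked$n
  hitpos <- which(ranked$genes %in% members)
  nh <- length(hitpos)
  es_obs <- oracle_es(ranked$genes, ranked$r, ranked$genes[hitpos], w)
  es_all <- apply(utils::combn(n, nh), 2, function(ix)
    oracle_es(ranked$genes, ranked$r, ranked$genes[ix], w))
  same <- sign(es_all) == sign(es_obs)
  sum(same & abs(es_all) >= abs(es_obs)) / sum(same)
}

# Tiny deterministic ranked list used across enrichment tests.
toy_ranked <- function() {
  ranked_list(stats::setNames(c(3, 2, 1, -1, -3),
                              c("GA", "GB", "GC", "GD", "GE")))
}

# Two-group expression matrix from explicit per-group value matrices.
toy_expr <- function(trt, ref, genes = sprintf("G%02d", seq_len(nrow(trt)))) {
  m <- cbind(ref, trt)
  rownames(m) <- genes
  colnames(m) <- c(sprintf("r%d", seq_len(ncol(ref))),
                   sprintf("t%d", seq_len(ncol(trt))))
  expression_matrix(m, stats::setNames(
    rep(c("control", "treated"), c(ncol(ref), ncol(trt))), colnames(m)))
}

# Named igraph builders for the hand-computed MCODE fixtures.
named_complete <- function(n, prefix = "K") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
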