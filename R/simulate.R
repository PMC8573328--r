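#' Simulation design for two-contrast count data
#'
#' Fixes every knob of the synthetic two-contrast RNA-seq experiment:
#' negative-binomial counts with log-normally drawn gene baselines, a
#' planted set of differential genes shared by both contrasts, and a
#' chosen fraction of that set whose regulation direction is flipped in
#' the second contrast (the inversion structure the cross-contrast test
#' is designed to detect).
#'
#' @param n_genes gene universe size.
#' @param n_samples_per_group samples per group in each contrast.
#' @param n_de number of truly differential genes (<= n_genes).
#' @param lfc_magnitude absolute log2 fold change planted on the treated
#'   group mean of each differential gene.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param baseline_mean scale of expression: gene baselines are drawn
#'   log-normally with median `baseline_mean` and log-sd 1.
#' @param inversion_fraction fraction in \[0, 1\] of contrast-A
#'   differential genes whose direction is flipped in contrast B.
#' @param seed RNG seed; identical designs produce identical data.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_genes = 2000, n_samples_per_group = 6,
                       n_de = 200, lfc_magnitude = 1.0, dispersion = 0.1,
                       baseline_mean = 150, inversion_fraction = 0,
                       seed = 1) {
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num_ok(n_genes) || n_genes < 1) stop("n_genes must be a positive integer")
  if (!num_ok(n_samples_per_group) || n_samples_per_group < 1)
    stop("n_samples_per_group must be a positive integer")
  if (!num_ok(n_de) || n_de < 0) stop("n_de must be a non-negative integer")
  if (n_de > n_genes) stop("n_de must not exceed n_genes")
  if (!num_ok(lfc_magnitude) || lfc_magnitude < 0)
    stop("lfc_magnitude must be non-negative")
  if (!num_ok(dispersion) || dispersion <= 0)
    stop("dispersion must be positive")
  if (!num_ok(baseline_mean) || baseline_mean <= 0)
    stop("baseline_mean must be positive")
  if (!num_ok(inversion_fraction) || inversion_fraction < 0 ||
      inversion_fraction > 1)
    stop("inversion_fraction must lie in [0, 1]")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 n_de = as.integer(n_de),
                 lfc_magnitude = lfc_magnitude, dispersion = dispersion,
                 baseline_mean = baseline_mean,
                 inversion_fraction = inversion_fraction,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate a two-contrast experiment with planted, partially inverted
#' differential expression
#'
#' Contrast A emulates degeneration vs control, contrast B a second
#' genotype contrast over the same gene universe. Both share the same
#' differential gene core; in contrast B, `round(inversion_fraction *
#' n_de)` of those genes have their direction flipped. Counts are
#' negative-binomial around log-normal gene baselines; the treated-group
#' mean of every differential gene is shifted by `±lfc_magnitude` on the
#' log2 scale, and each contrast's control group is an independent draw
#' from the shared baseline distribution.
#'
#' @param design a [sim_design()].
#' @return List with `expr_A` and `expr_B` ([expression_matrix()] objects
#'   with groups `control`/`treated`) and `truth`, a list of class
#'   `sim_truth` with `de_genes_A`, `de_genes_B` (named direction
#'   vectors), `inverted_genes` and `planted_modules`.
#' @export
simulate_two_contrast_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  ng <- design$n_genes; n <- design$n_samples_per_group
  genes <- sprintf("G%05d", seq_len(ng))
  base <- stats::rlnorm(ng, meanlog = log(design$baseline_mean), sdlog = 1)

  de_idx <- if (design$n_de > 0) sample.int(ng, design$n_de) else integer(0)
  dir_A <- if (design$n_de > 0)
    sample(c(1, -1), design$n_de, replace = TRUE) else numeric(0)
  n_inv <- round(design$inversion_fraction * design$n_de)
  inv_local <- seq_len(n_inv)          # first n_inv of the sampled DE genes
  dir_B <- dir_A
  dir_B[inv_local] <- -dir_B[inv_local]

  draw <- function(mu) {
    matrix(stats::rnbinom(ng * n, mu = rep(mu, n), size = 1 / design$dispersion),
           nrow = ng)
  }
  shifted <- function(dirs) {
    mu <- base
    mu[de_idx] <- base[de_idx] * 2^(design$lfc_magnitude * dirs)
    mu
  }
  mk_expr <- function(ctrl, trt, prefix) {
    m <- cbind(ctrl, trt)
    rownames(m) <- genes
    colnames(m) <- c(sprintf("%s_ctrl_%d", prefix, seq_len(n)),
                     sprintf("%s_trt_%d", prefix, seq_len(n)))
    expression_matrix(m, stats::setNames(rep(c("control", "treated"), each = n),
                                         colnames(m)))
  }
  expr_A <- mk_expr(draw(base), draw(shifted(dir_A)), "A")
  expr_B <- mk_expr(draw(base), draw(shifted(dir_B)), "B")

  dirchar <- function(d) ifelse(d > 0, "up", "down")
  truth <- structure(list(
    de_genes_A = stats::setNames(dirchar(dir_A), genes[de_idx]),
    de_genes_B = stats::setNames(dirchar(dir_B), genes[de_idx]),
    inverted_genes = genes[de_idx][inv_local],
    planted_modules = list()),
    class = "sim_truth")
  list(expr_A = expr_A, expr_B = expr_B, truth = truth)
}

#' Simulate a gene-set collection over a gene universe
#'
#' Random sets are sampled without replacement from the universe with
#' sizes uniform over `set_size_range`; an optional `spike_set` is
#' included verbatim under its own name, which lets tests plant a truly
#' enriched set among random ones.
#'
#' @param universe character vector of gene IDs (non-empty).
#' @param n_sets number of random sets.
#' @param set_size_range integer pair (min, max); sizes are capped at the
#'   universe size.
#' @param spike_set optional [gene_set()] included verbatim.
#' @param seed RNG seed.
#' @return A [gene_set_collection()].
#' @export
simulate_gene_sets <- function(universe, n_sets, set_size_range = c(15, 200),
                               spike_set = NULL, seed = 1) {
  universe <- unique(canonical_gene_ids(universe))
  if (!length(universe)) stop("empty gene universe")
  if (max(set_size_range) > length(universe))
    stop("set sizes must not exceed the universe size")
  set.seed(as.integer(seed))
  sets <- lapply(seq_len(n_sets), function(i) {
    k <- set_size_range[1L] +
      sample.int(set_size_range[2L] - set_size_range[1L] + 1L, 1L) - 1L
    gene_set(sprintf("RANDOM_SET_%04d", i), sample(universe, k),
             description = "simulated random set")
  })
  if (!is.null(spike_set)) {
    stopifnot(inherits(spike_set, "gene_set"))
    sets <- c(sets, list(spike_set))
  }
  gene_set_collection(sets)
}

#' Simulate an interaction network with planted dense modules
#'
#' Erdős–Rényi background over `n_nodes` nodes plus planted subgraphs on
#' disjoint node subsets whose internal edge probability is
#' `within_density`. Every retained edge gets a combined score drawn
#' uniformly in (0.4, 1], so the whole graph survives the conventional
#' score threshold and topology tests are decoupled from threshold tests.
#'
#' @param n_nodes node count.
#' @param background_edge_prob background edge probability in \[0, 1\].
#' @param modules list of `c(size, within_density)` pairs with
#'   `within_density` in (background_edge_prob, 1\].
#' @param seed RNG seed.
#' @return List with `network` (igraph, edge attribute `combined_score`)
#'   and `planted_modules` (list of character vectors).
#' @export
simulate_planted_module_graph <- function(n_nodes, background_edge_prob,
                                          modules = list(), seed = 1) {
  if (background_edge_prob < 0 || background_edge_prob > 1)
    stop("background_edge_prob must lie in [0, 1]")
  sizes <- vapply(modules, `[[`, numeric(1), 1L)
  if (length(sizes) && sum(sizes) > n_nodes)
    stop("planted modules exceed n_nodes")
  for (m in modules)
    if (m[[2L]] <= background_edge_prob || m[[2L]] > 1)
      stop("within_density must lie in (background_edge_prob, 1]")
  set.seed(as.integer(seed))
  nodes <- sprintf("N%04d", seq_len(n_nodes))

  pairs_of <- function(v) {
    if (length(v) < 2L) return(matrix(character(0), ncol = 2L))
    t(utils::combn(v, 2L))
  }
  bg <- pairs_of(nodes)
  keep <- stats::runif(nrow(bg)) < background_edge_prob
  edges <- bg[keep, , drop = FALSE]

  planted <- list()
  avail <- nodes
  for (m in modules) {
    mem <- sort(sample(avail, m[[1L]]))
    avail <- setdiff(avail, mem)
    planted[[length(planted) + 1L]] <- mem
    mp <- pairs_of(mem)
    keep <- stats::runif(nrow(mp)) < m[[2L]] | m[[2L]] >= 1
    edges <- rbind(edges, mp[keep, , drop = FALSE])
  }

  if (nrow(edges)) {
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, n_nodes, name = nodes)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(edges))
    igraph::E(g)$combined_score <- stats::runif(nrow(edges), 0.4, 1)
  }
  list(network = g, planted_modules = planted)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d DE genes (A), %d inverted in B, %d planted modules\n",
              length(x$de_genes_A), length(x$inverted_genes),
              length(x$planted_modules)))
  invisible(x)
}
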