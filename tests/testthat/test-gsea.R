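test_that("singleton sets at the extremes give ES = ±1 at the extreme rank", {
  rk <- ranked_list(stats::setNames(c(2, 1, -1, -2), c("GA", "GB", "GC", "GD")))
  top <- compute_es(rk, gene_set("TOP", "GA"), w = 0)
  expect_equal(top$es, 1)
  expect_equal(top$es_position, 1L)
  bottom <- compute_es(rk, gene_set("BOT", "GD"), w = 0)
  expect_equal(bottom$es, -1)
  expect_equal(bottom$es_position, 3L)
})

test_that("the weighted worked example reproduces the enumerated profile", {
  rk <- toy_ranked()
  gs <- gene_set("S", c("GA", "GC"))
  pr <- compute_es(rk, gs, w = 1)
  expect_equal(pr$running_score, c(0.75, 0.75 - 1/3, 0.75 - 1/3 + 0.25,
                                   0.75 - 2/3 + 0.25, 0),
               tolerance = 1e-12)
  expect_equal(pr$es, 0.75)
  expect_equal(pr$es_position, 1L)
  expect_equal(leading_edge(pr, rk, gs), "GA")
})

test_that("compute_es matches the brute-force oracle on random instances", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    r <- round(rnorm(n), 3)
    names(r) <- sprintf("G%03d", seq_len(n))
    rk <- ranked_list(r)
    gs <- gene_set("S", sample(names(r), sample(2:(n - 2), 1)))
    w <- sample(c(0, 1, 2), 1)
    pr <- compute_es(rk, gs, w = w)
    expect_equal(pr$es, oracle_es(rk$genes, rk$r, gs$members, w),
                 tolerance = 1e-12)
    expect_equal(pr$running_score[rk$n], 0, tolerance = 1e-12)
  }
})

test_that("with w = 0 the ES magnitude is the two-sample KS statistic", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    r <- rnorm(n); names(r) <- sprintf("G%03d", seq_len(n))
    rk <- ranked_list(r)
    gs <- gene_set("S", sample(names(r), sample(2:(n - 2), 1)))
    pr <- compute_es(rk, gs, w = 0)
    hitpos <- which(rk$genes %in% gs$members)
    ks <- suppressWarnings(
      stats::ks.test(hitpos, setdiff(seq_len(n), hitpos)))$statistic
    expect_equal(abs(pr$es), unname(ks), tolerance = 1e-12)
  }
})

test_that("w = 0 ES is invariant to strictly monotone metric transforms", {
  set.seed(31)
  r <- rnorm(30); names(r) <- sprintf("G%03d", 1:30)
  gs <- gene_set("S", sample(names(r), 7))
  es1 <- compute_es(ranked_list(r), gs, w = 0)$es
  es2 <- compute_es(ranked_list(exp(r)), gs, w = 0)$es
  es3 <- compute_es(ranked_list(2 * r + 5), gs, w = 0)$es
  expect_identical(es1, es2)
  expect_identical(es1, es3)
})

test_that("reversing the ranked list negates the ES", {
  set.seed(41)
  for (i in 1:20) {
    r <- rnorm(25); names(r) <- sprintf("G%03d", 1:25)
    gs <- gene_set("S", sample(names(r), 6))
    for (w in c(0, 1)) {
      es_fwd <- compute_es(ranked_list(r), gs, w = w)$es
      es_rev <- compute_es(ranked_list(-r), gs, w = w)$es
      expect_equal(es_rev, -es_fwd, tolerance = 1e-12)
    }
  }
})

test_that("compute_es agrees with fgsea's statistic at matching weights", {
  skip_if_not_installed("fgsea")
  set.seed(51)
  for (i in 1:20) {
    r <- sort(rnorm(80), decreasing = TRUE)
    names(r) <- sprintf("G%03d", 1:80)
    rk <- ranked_list(r)
    S <- sample(names(r), 12)
    for (w in c(0, 1)) {
      mine <- compute_es(rk, gene_set("S", S), w = w)$es
      theirs <- fgsea::calcGseaStat(r, which(names(r) %in% S), gseaParam = w)
      expect_equal(mine, theirs, tolerance = 1e-12)
    }
  }
})

test_that("degenerate and contract-violating inputs are rejected", {
  rk <- toy_ranked()
  expect_error(compute_es(rk, gene_set("S", "ZZZ")), "no members")
  expect_error(compute_es(rk, gene_set("S", rk$genes)), "whole ranked universe")
  rk0 <- ranked_list(stats::setNames(c(1, 0, 0, -1), c("GA", "GB", "GC", "GD")))
  expect_error(compute_es(rk0, gene_set("S", c("GB", "GC")), w = 1),
               "degenerate normalizer")
  expect_error(permutation_test(rk, gene_set("S", "GA"), mode = "gene_set",
                                n_permutations = 5, seed = 1),
               ">= 10")
})

test_that("leading edge follows the sign of the extreme and is empty at ES = 0", {
  rk <- toy_ranked()
  neg <- compute_es(rk, gene_set("S", "GE"), w = 0)
  expect_lt(neg$es, 0)
  expect_equal(leading_edge(neg, rk, gene_set("S", "GE")), "GE")
  fake <- structure(list(running_score = numeric(5), es = 0,
                         es_position = 1L), class = "enrichment_profile")
  expect_identical(leading_edge(fake, rk, gene_set("S", "GA")), character(0))
})

test_that("the permutation estimator honours its boundary identities", {
  # observed ES equal to every permuted ES -> p = 1 under the add-one form
  st <- invgsea:::permutation_stats(0.5, rep(0.5, 99))
  expect_equal(st$p, 1)
  # |ES| equal to the same-sign mean -> |NES| = 1
  expect_equal(abs(st$nes), 1)
  st2 <- invgsea:::permutation_stats(-0.4, c(-0.2, -0.6, 0.3))
  expect_equal(st2$nes, -0.4 / 0.4)
  expect_equal(st2$p, (1 + 1) / (1 + 2))
  expect_warning(invgsea:::permutation_stats(0.4, c(-0.2, -0.3)),
                 "NES undefined")
})

test_that("exhaustive gene-set permutation p matches subset enumeration", {
  set.seed(61)
  for (i in 1:8) {
    n <- sample(6:8, 1)
    r <- round(rnorm(n), 2); names(r) <- sprintf("G%02d", seq_len(n))
    rk <- ranked_list(r)
    nh <- sample(2:3, 1)
    gs <- gene_set("S", sample(names(r), nh))
    res <- permutation_test(rk, gs, mode = "gene_set", seed = 1,
                            exhaustive = TRUE, w = 1)
    expect_equal(res$p_value, oracle_subset_p(rk, gs$members, w = 1),
                 tolerance = 1e-12)
    expect_equal(res$n_permutations, choose(n, nh))
  }
})

test_that("collection enrichment ranks a planted set first with BH FDR filled", {
  d <- sim_design(n_genes = 600, n_de = 80, inversion_fraction = 0, seed = 7)
  sim <- simulate_two_contrast_counts(d)
  up <- names(sim$truth$de_genes_A)[sim$truth$de_genes_A == "up"]
  spike <- gene_set("SPIKED", up)
  coll <- simulate_gene_sets(rownames(sim$expr_A$values), 10, c(20, 60),
                             spike_set = spike, seed = 2)
  rk <- rank_genes(sim$expr_A, "treated", "control")
  res <- enrich_collection(rk, coll, n_permutations = 200,
                           mode = "gene_set", seed = 3)
  expect_s3_class(res, "gsea_result")
  expect_equal(res$set[1], "SPIKED")
  expect_equal(res$nes[1], max(res$nes))
  # no permuted ES reaches the observed one, so p sits at the add-one floor
  # 1 / (1 + #same-sign permutations), a unit fraction
  expect_lt(res$p[1], 0.05)
  expect_equal(1 / res$p[1], round(1 / res$p[1]))
  expect_true(all(res$fdr_q >= res$p - 1e-12))
  expect_equal(res$fdr_q, stats::p.adjust(res$p, "BH"))
})

test_that("a single-set collection has fdr_q equal to its p-value", {
  rk <- ranked_list(stats::setNames(rnorm(50), sprintf("G%03d", 1:50)))
  coll <- gene_set_collection(list(gene_set("ONLY", rk$genes[1:10])))
  res <- enrich_collection(rk, coll, n_permutations = 100,
                           mode = "gene_set", seed = 4)
  expect_equal(res$fdr_q, res$p)
})

test_that("size filters apply before testing and can empty the collection", {
  rk <- ranked_list(stats::setNames(rnorm(40), sprintf("G%03d", 1:40)))
  coll <- gene_set_collection(list(gene_set("SMALL", rk$genes[1:3]),
                                   gene_set("OK", rk$genes[1:12])))
  res <- enrich_collection(rk, coll, n_permutations = 50, mode = "gene_set",
                           seed = 1, min_size = 5)
  expect_equal(res$set, "OK")
  expect_error(enrich_collection(rk, coll, n_permutations = 50,
                                 mode = "gene_set", seed = 1, min_size = 20),
               "size filter")
})
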