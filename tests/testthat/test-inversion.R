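make_dge <- function(genes, calls, lfc = NULL, p = NULL) {
  # hand-built dge_result for set-arithmetic tests
  structure(data.frame(gene = genes,
                       log2fc = lfc %||% ifelse(calls == "up", 1,
                                         ifelse(calls == "down", -1, 0)),
                       p = p %||% ifelse(calls == "ns", 0.5, 0.001),
                       padj = NA_real_, call = calls,
                       stringsAsFactors = FALSE),
            class = c("dge_result", "data.frame"),
            treated = "t", reference = "r",
            p_threshold = 0.01, lfc_threshold = 0.2,
            n_up = sum(calls == "up"), n_down = sum(calls == "down"),
            n_ns = sum(calls == "ns"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("signature sets split calls by direction and reject empty signatures", {
  dge <- make_dge(c("G1", "G2", "G3"), c("up", "down", "ns"))
  sets <- build_pand_gene_set(dge)
  expect_equal(sets$up_set$members, "G1")
  expect_equal(sets$down_set$members, "G2")
  expect_setequal(sets$signed_set$members, c("G1", "G2"))
  dir <- attr(sets$signed_set, "direction")
  expect_equal(unname(dir[c("G1", "G2")]), c("up", "down"))
  expect_error(build_pand_gene_set(make_dge("G1", "ns")), "zero differential")
})

test_that("inverted counts come from exact set arithmetic on the shared universe", {
  genes <- c("G1", "G2", "G3", "G4", "G5")
  dge_A <- make_dge(genes, c("up", "up", "up", "down", "ns"))
  dge_B <- make_dge(genes, c("ns", "down", "down", "ns", "down"))
  rk <- ranked_list(stats::setNames(c(2, 1, 0.5, -1, -2), genes))
  pair <- contrast_pair(dge_A, dge_B, ranked_B = rk)
  tab <- inversion_table(pair)
  counts <- attr(tab, "counts")
  expect_equal(unname(counts["n_up_A_down_B"]), 2L)
  expect_equal(unname(counts["n_down_A_up_B"]), 0L)
  expect_equal(unname(counts["n_up_A"]), 3L)
  expect_equal(unname(counts["n_down_A"]), 1L)
  expect_equal(sum(tab$inverted), 2L)
  expect_equal(colnames(tab), c("gene", "call_A", "call_B", "inverted"))
  expect_identical(tab, inversion_table(pair))  # deterministic
})

test_that("a self-concordant pair has zero inversions and positive NES", {
  d <- sim_design(n_genes = 400, n_de = 60, seed = 17)
  sim <- simulate_two_contrast_counts(d)
  dge <- differential_expression(sim$expr_A, "treated", "control")
  rk <- rank_genes(sim$expr_A, "treated", "control")
  pair <- contrast_pair(dge, dge, ranked_B = rk)
  counts <- attr(inversion_table(pair), "counts")
  expect_equal(unname(counts["n_up_A_down_B"]), 0L)
  expect_equal(unname(counts["n_down_A_up_B"]), 0L)
  rep <- inverted_enrichment(pair, n_permutations = 100, seed = 1)
  expect_gt(rep$nes, 0)
  expect_equal(rep$permutation_mode, "gene_set")
})

test_that("planted inversion flips the sign of the cross-contrast NES", {
  run <- function(phi) {
    d <- sim_design(n_genes = 800, n_de = 100, inversion_fraction = phi,
                    seed = 13)
    sim <- simulate_two_contrast_counts(d)
    dge_A <- differential_expression(sim$expr_A, "treated", "control")
    dge_B <- differential_expression(sim$expr_B, "treated", "control")
    pair <- contrast_pair(dge_A, dge_B, expr_B = sim$expr_B,
                          treated_B = "treated", reference_B = "control")
    inverted_enrichment(pair, n_permutations = 200, seed = 13)
  }
  hi <- run(0.8); lo <- run(0)
  expect_lt(hi$nes, 0)
  expect_gt(lo$nes, 0)
  expect_lt(hi$p_value, 0.05)
  expect_equal(hi$permutation_mode, "phenotype")
  # count consistency: the four counts match the flagged table rows
  expect_equal(hi$n_up_A_down_B + hi$n_down_A_up_B, sum(hi$table$inverted))
})

test_that("the inversion table file is byte-stable and carries the footer", {
  dir <- withr::local_tempdir()
  genes <- c("G1", "G2", "G3", "G4")
  pair <- contrast_pair(make_dge(genes, c("up", "down", "ns", "up")),
                        make_dge(genes, c("down", "up", "ns", "up")),
                        ranked_B = ranked_list(
                          stats::setNames(c(1, 2, -1, -2), genes)))
  rep <- suppressWarnings(inverted_enrichment(pair, n_permutations = 50,
                                              seed = 2))
  f1 <- file.path(dir, "a.tsv"); f2 <- file.path(dir, "b.tsv")
  write_inversion(rep, f1); write_inversion(rep, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[length(readLines(f1))], "^# n_up_A=2")
})

test_that("empty shared universe and missing ranking are rejected", {
  dge_A <- make_dge(c("G1", "G2"), c("up", "down"))
  dge_B <- make_dge(c("H1", "H2"), c("up", "down"))
  rk <- ranked_list(stats::setNames(c(1, -1), c("H1", "H2")))
  expect_error(contrast_pair(dge_A, dge_B, ranked_B = rk),
               "empty shared")
  expect_error(contrast_pair(dge_A, dge_B), "supply ranked_B")
})
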