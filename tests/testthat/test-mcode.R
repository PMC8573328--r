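test_that("vertex weights reproduce hand computations on canonical graphs", {
  # K3: closed neighborhood is K3, highest core 2, density 1 -> weight 2
  expect_equal(unname(mcode_vertex_weight(named_complete(3))), rep(2, 3))
  # K4: highest core 3, density 1 -> weight 3
  expect_equal(unname(mcode_vertex_weight(named_complete(4))), rep(3, 3 + 1))
  # star S4: hub degree 4 but neighborhood is 1-core with density 2n/(n(n-1))
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("HUB", paste0("L", 1:4))
  w <- mcode_vertex_weight(star)
  expect_equal(unname(w["HUB"]), 1 * (2 * 4) / (5 * 4))
  expect_equal(unname(w[paste0("L", 1:4)]), rep(0, 4))  # degree 1 < cutoff
  # path P4: interior nodes have degree 2, neighborhood a 1-core path
  path <- igraph::make_ring(4, circular = FALSE)
  igraph::V(path)$name <- paste0("P", 1:4)
  wp <- mcode_vertex_weight(path)
  expect_equal(unname(wp), c(0, 2/3, 2/3, 0))
})

test_that("weights are invariant under node relabeling", {
  set.seed(5)
  g <- igraph::sample_gnp(40, 0.15)
  igraph::V(g)$name <- sprintf("N%02d", 1:40)
  w1 <- mcode_vertex_weight(g)
  perm <- sample(40)
  g2 <- igraph::permute(g, perm)
  w2 <- mcode_vertex_weight(g2)
  expect_equal(w2[names(w1)], w1)
})

test_that("a K5 with a path pendant yields exactly the K5 after haircut", {
  g <- named_complete(5)
  g <- igraph::add_vertices(g, 3, name = c("P1", "P2", "P3"))
  g <- igraph::add_edges(g, c("K5", "P1", "P1", "P2", "P2", "P3"))
  mods <- mcode_find_complexes(g)
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$members, paste0("K", 1:5))
  expect_equal(mods[[1]]$n_nodes, 5)
  expect_equal(mods[[1]]$n_edges, 10)
  expect_equal(mods[[1]]$score, 5.0)
  validate_modules(g, mods)
  rep <- module_report(mods)
  expect_equal(rep$rank, 1)
  expect_equal(rep$members, "K1,K2,K3,K4,K5")
})

test_that("every detected module passes the independent validity checker", {
  # uniform weights let the expansion cross a bridge: two K4s joined by one
  # edge merge into a single valid complex under the greedy rule
  g <- igraph::disjoint_union(named_complete(4, "A"), named_complete(4, "B"))
  g <- igraph::add_edges(g, c("A1", "B1"))
  mods <- mcode_find_complexes(g)
  expect_length(mods, 1)
  expect_equal(mods[[1]]$n_nodes, 8)
  validate_modules(g, mods)

  set.seed(9)
  for (i in 1:5) {
    gg <- igraph::sample_gnp(60, 0.08)
    igraph::V(gg)$name <- sprintf("N%02d", 1:60)
    mm <- mcode_find_complexes(gg)
    expect_true(validate_modules(gg, mm))
    # node-disjointness across modules
    members <- unlist(lapply(mm, `[[`, "members"))
    expect_equal(anyDuplicated(members), 0L)
  }
})

test_that("edgeless and empty graphs give empty module lists", {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  expect_length(mcode_find_complexes(g), 0)
  g10 <- igraph::add_vertices(g, 10, name = sprintf("N%02d", 1:10))
  expect_length(mcode_find_complexes(g10), 0)
  expect_equal(nrow(module_report(mcode_find_complexes(g10))), 0L)
})

test_that("planted dense modules are recovered with high overlap", {
  sim <- simulate_planted_module_graph(200, 0.01, list(c(10, 0.9)), seed = 5)
  mods <- mcode_find_complexes(sim$network)
  expect_gte(length(mods), 1)
  expect_gte(jaccard(mods[[1]]$members, sim$planted_modules[[1]]), 0.8)
  validate_modules(sim$network, mods)
})

test_that("module detection is deterministic across repeated runs", {
  sim <- simulate_planted_module_graph(150, 0.02, list(c(8, 1.0)), seed = 3)
  m1 <- mcode_find_complexes(sim$network)
  m2 <- mcode_find_complexes(sim$network)
  expect_identical(module_report(m1), module_report(m2))
})

test_that("STRING edge lists respect both score dialects and the strict threshold", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "unit.tsv"); f2 <- file.path(dir, "string.tsv")
  writeLines(c("node1\tnode2\tcombined_score",
               "A\tB\t0.39", "A\tC\t0.41", "C\tD\t0.4", "B\tD\t0.75"), f1)
  writeLines(c("node1\tnode2\tcombined_score",
               "A\tB\t390", "A\tC\t410", "C\tD\t400", "B\tD\t750"), f2)
  g1 <- load_string_edges(f1); g2 <- load_string_edges(f2)
  # only strictly > 0.4 edges survive: A-C and B-D
  el <- igraph::as_edgelist(g1)
  expect_equal(nrow(el), 2)
  expect_setequal(paste(el[, 1], el[, 2]), c("A C", "B D"))
  # both dialects give identical graphs, scores included
  expect_true(igraph::identical_graphs(g1, g2) ||
                (setequal(paste(igraph::as_edgelist(g1)[, 1],
                                igraph::as_edgelist(g1)[, 2]),
                          paste(igraph::as_edgelist(g2)[, 1],
                                igraph::as_edgelist(g2)[, 2])) &&
                   isTRUE(all.equal(sort(igraph::E(g1)$combined_score),
                                    sort(igraph::E(g2)$combined_score)))))
})

test_that("reciprocal duplicates collapse and self-loops drop", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "dup.tsv")
  writeLines(c("A\tB\t410", "B\tA\t410", "C\tC\t900", "A\tC\t500"), f)
  g <- suppressMessages(load_string_edges(f))
  expect_equal(igraph::ecount(g), 2)
  eid <- igraph::get_edge_ids(g, c("A", "B"))
  expect_equal(igraph::E(g)$combined_score[eid], 0.41)
  expect_equal(sum(igraph::which_loop(g)), 0L)
})

test_that("malformed and empty edge lists are handled per contract", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.tsv")
  writeLines(c("A\tB\t0.5", "Conly_two_fields\t0.9"), f)
  expect_error(load_string_edges(f), "line 2")
  writeLines(character(0), file.path(dir, "empty.tsv"))
  expect_warning(g <- load_string_edges(file.path(dir, "empty.tsv")), "empty")
  expect_equal(igraph::vcount(g), 0)
})

test_that("mcode parameter validation enforces the documented ranges", {
  expect_error(mcode_params(degree_cutoff = 0))
  expect_error(mcode_params(node_score_cutoff = 1.5))
  expect_error(mcode_params(fluff = TRUE), "not implemented")
  expect_error(module_report(mcode_find_complexes(named_complete(3)),
                             top_k = 0), "top_k")
})
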