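#' Write a complete synthetic fixture bundle to disk
#'
#' Runs the generator under one design and writes everything a pipeline
#' run needs: counts and group maps for both contrasts, a gene-set
#' collection (random sets plus the planted-truth up-set as a spike-in
#' when the design has differential genes), a STRING-style network with
#' planted dense modules, and the ground truth as JSON. Outputs are
#' byte-identical across reruns of the same design.
#'
#' @param design a [sim_design()].
#' @param dir output directory (created if needed).
#' @param n_sets random gene sets to simulate.
#' @param set_size_range gene-set size range.
#' @param n_network_nodes,background_edge_prob,network_modules arguments
#'   of [simulate_planted_module_graph()].
#' @return Invisibly, a named character vector of the files written.
#' @export
write_simulation <- function(design, dir, n_sets = 50,
                             set_size_range = c(15, 200),
                             n_network_nodes = 200,
                             background_edge_prob = 0.01,
                             network_modules = list(c(10, 0.9))) {
  stopifnot(inherits(design, "sim_design"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_two_contrast_counts(design)
  p <- function(f) file.path(dir, f)
  write_expression(sim$expr_A, p("counts_A.tsv"), p("groups_A.tsv"))
  write_expression(sim$expr_B, p("counts_B.tsv"), p("groups_B.tsv"))

  universe <- rownames(sim$expr_A$values)
  spike <- NULL
  up_genes <- names(sim$truth$de_genes_A)[sim$truth$de_genes_A == "up"]
  if (length(up_genes) >= 3)
    spike <- gene_set("PLANTED_UP", up_genes, "planted up-regulated core")
  sets <- simulate_gene_sets(universe, n_sets, set_size_range,
                             spike_set = spike, seed = design$seed)
  write_gmt(sets, p("gene_sets.gmt"))

  net <- simulate_planted_module_graph(n_network_nodes, background_edge_prob,
                                       network_modules, seed = design$seed)
  write_network(net$network, p("network.tsv"))

  truth <- sim$truth
  truth$planted_modules <- net$planted_modules
  jsonlite::write_json(
    list(de_genes_A = as.list(truth$de_genes_A),
         de_genes_B = as.list(truth$de_genes_B),
         inverted_genes = truth$inverted_genes,
         planted_modules = truth$planted_modules,
         design = unclass(design)),
    p("truth.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)

  files <- c(counts_A = p("counts_A.tsv"), groups_A = p("groups_A.tsv"),
             counts_B = p("counts_B.tsv"), groups_B = p("groups_B.tsv"),
             gene_sets = p("gene_sets.gmt"), network = p("network.tsv"),
             truth = p("truth.json"))
  message("write_simulation: ", length(files), " files in ", dir)
  invisible(files)
}

#' Pipeline configuration
#'
#' One object holding every input path, contrast definition, threshold
#' and algorithm parameter of an end-to-end run; can be read from and
#' written to YAML. Validation checks that every referenced file exists
#' and that a seed is present whenever permutations are requested.
#'
#' @param counts_A,groups_A,counts_B,groups_B input TSV paths.
#' @param gene_sets GMT path (optional; skips the collection-enrichment
#'   stage when NULL).
#' @param network STRING-style edge-list path (optional; skips the module
#'   stage when NULL).
#' @param treated,reference group labels used for both contrasts.
#' @param p_threshold,lfc_threshold differential-expression call
#'   thresholds.
#' @param dge_method `"exact_nb"` or `"welch"`.
#' @param score_threshold combined-score cut for network edges.
#' @param w,n_permutations,seed enrichment parameters.
#' @param min_size,max_size gene-set size filter.
#' @param mcode an [mcode_params()] list.
#' @param out_dir output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_A, groups_A, counts_B, groups_B,
                            gene_sets = NULL, network = NULL,
                            treated = "treated", reference = "control",
                            p_threshold = 0.01, lfc_threshold = 0.2,
                            dge_method = "exact_nb",
                            score_threshold = 0.4,
                            w = 1, n_permutations = 1000, seed = NULL,
                            min_size = 5, max_size = Inf,
                            mcode = mcode_params(), out_dir = ".") {
  cfg <- structure(list(counts_A = counts_A, groups_A = groups_A,
                        counts_B = counts_B, groups_B = groups_B,
                        gene_sets = gene_sets, network = network,
                        treated = treated, reference = reference,
                        p_threshold = p_threshold,
                        lfc_threshold = lfc_threshold,
                        dge_method = dge_method,
                        score_threshold = score_threshold,
                        w = w, n_permutations = n_permutations, seed = seed,
                        min_size = min_size, max_size = max_size,
                        mcode = mcode, out_dir = out_dir),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  paths <- c(cfg$counts_A, cfg$groups_A, cfg$counts_B, cfg$groups_B,
             cfg$gene_sets, cfg$network)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("config validation: missing input file(s): ",
         paste(missing, collapse = ", "))
  if (cfg$n_permutations > 0 && is.null(cfg$seed))
    stop("config validation: a seed is required when permutations are requested")
  invisible(TRUE)
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$mcode <- do.call(mcode_params, as.list(y$mcode %||% list()))
  if (!is.null(y$max_size) && identical(y$max_size, "Inf")) y$max_size <- Inf
  do.call(pipeline_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full two-contrast pipeline
#'
#' Five stages, logged with counts and written to `out_dir`:
#' differential expression of both contrasts (TSV + RNK each),
#' collection enrichment on contrast A (if a GMT is configured),
#' cross-contrast inverted enrichment (TSV report), module detection on
#' the thresholded network (if configured), and a JSON manifest with the
#' MD5 of every input, the full parameter set and per-stage output files
#' — sufficient to re-run the bundle.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, expr) {
    message("stage ", name, " ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  outputs <- list()

  dge_A <- stage("dge_A", {
    expr_A <- read_expression(cfg$counts_A, cfg$groups_A)
    d <- differential_expression(expr_A, cfg$treated, cfg$reference,
                                 cfg$p_threshold, cfg$lfc_threshold,
                                 method = cfg$dge_method)
    write_dge(d, out("dge_A.tsv"))
    write_rnk(rank_genes(expr_A, cfg$treated, cfg$reference), out("ranked_A.rnk"))
    message(sprintf("  dge_A: %d up, %d down", attr(d, "n_up"), attr(d, "n_down")))
    outputs$dge_A <- c("dge_A.tsv", "ranked_A.rnk")
    list(dge = d, expr = expr_A)
  })
  dge_B <- stage("dge_B", {
    expr_B <- read_expression(cfg$counts_B, cfg$groups_B)
    d <- differential_expression(expr_B, cfg$treated, cfg$reference,
                                 cfg$p_threshold, cfg$lfc_threshold,
                                 method = cfg$dge_method)
    write_dge(d, out("dge_B.tsv"))
    write_rnk(rank_genes(expr_B, cfg$treated, cfg$reference), out("ranked_B.rnk"))
    message(sprintf("  dge_B: %d up, %d down", attr(d, "n_up"), attr(d, "n_down")))
    outputs$dge_B <- c("dge_B.tsv", "ranked_B.rnk")
    list(dge = d, expr = expr_B)
  })

  enr <- NULL
  if (!is.null(cfg$gene_sets)) {
    enr <- stage("enrichment", {
      sets <- read_gmt(cfg$gene_sets)
      e <- enrich_collection(dge_A$expr, sets, cfg$treated, cfg$reference,
                             n_permutations = cfg$n_permutations,
                             mode = "phenotype", seed = cfg$seed, w = cfg$w,
                             min_size = cfg$min_size, max_size = cfg$max_size)
      write_gsea(e, out("enrichment_A.tsv"))
      message(sprintf("  enrichment: %d sets tested", nrow(e)))
      outputs$enrichment <- "enrichment_A.tsv"
      e
    })
  }

  inv <- stage("inversion", {
    pair <- contrast_pair(dge_A$dge, dge_B$dge, expr_B = dge_B$expr,
                          treated_B = cfg$treated, reference_B = cfg$reference)
    rep <- inverted_enrichment(pair, n_permutations = cfg$n_permutations,
                               seed = cfg$seed, w = cfg$w)
    write_inversion(rep, out("inversion.tsv"))
    message(sprintf("  inversion: NES = %.3f, p = %.4g", rep$nes, rep$p_value))
    outputs$inversion <- "inversion.tsv"
    rep
  })

  mods <- NULL
  if (!is.null(cfg$network)) {
    mods <- stage("modules", {
      net <- load_string_edges(cfg$network, cfg$score_threshold)
      m <- mcode_find_complexes(net, cfg$mcode)
      validate_modules(net, m, cfg$mcode)
      write_modules(m, out("modules.tsv"))
      message(sprintf("  modules: %d found", length(m)))
      outputs$modules <- "modules.tsv"
      m
    })
  }

  manifest <- list(
    inputs = as.list(tools::md5sum(c(cfg$counts_A, cfg$groups_A,
                                     cfg$counts_B, cfg$groups_B,
                                     cfg$gene_sets, cfg$network))),
    params = unclass(cfg)[setdiff(names(cfg), "mcode")],
    mcode = unclass(cfg$mcode),
    stages = outputs,
    package_version = as.character(utils::packageVersion("invgsea")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  message("pipeline complete: ", length(outputs), " stages")
  invisible(list(dge_A = dge_A$dge, dge_B = dge_B$dge, enrichment = enr,
                 inversion = inv, modules = mods, manifest = manifest))
}
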