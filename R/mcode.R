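#' Load a STRING-style edge list into an interaction network
#'
#' Reads a three-column tab-separated edge list (node1, node2,
#' combined_score) and builds a simple undirected graph. Both STRING score
#' dialects are accepted: confidences already in \[0, 1\], or STRING's
#' integer 0-1000 export (auto-detected: if any score exceeds 1 the whole
#' column is divided by 1000). Self-loops are dropped (with a logged
#' count), reciprocal/duplicate rows are collapsed keeping the maximum
#' score, and only edges with combined score strictly greater than
#' `score_threshold` are retained.
#'
#' @param path edge-list path. A header line is detected and skipped when
#'   the third field is non-numeric.
#' @param score_threshold strict lower bound on the combined score
#'   (default 0.4, i.e. the conventional medium-confidence cut).
#' @return An `igraph` undirected graph with edge attribute
#'   `combined_score`; node names upper-cased.
#' @export
load_string_edges <- function(path, score_threshold = 0.4) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty edge list: ", path)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  first <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L]))))
    lines <- lines[-1L]
  if (!length(lines)) {
    warning("edge list has a header but no rows: ", path)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("malformed edge row at line %d of %s (need node1, node2, combined_score)",
                 bad[1L], path))
  a <- canonical_gene_ids(vapply(parts, `[[`, character(1), 1L))
  b <- canonical_gene_ids(vapply(parts, `[[`, character(1), 2L))
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(s))
    stop(sprintf("non-numeric combined score at line %d of %s",
                 which(is.na(s))[1L], path))
  if (any(s > 1)) s <- s / 1000   # STRING 0-1000 integer dialect
  interaction_network(a, b, s, score_threshold = score_threshold)
}

#' Build an interaction network from edge vectors
#'
#' @param node1,node2 character vectors of endpoints.
#' @param score numeric combined scores in \[0, 1\] (after any dialect
#'   rescaling).
#' @param score_threshold strict retention threshold.
#' @return igraph object as in [load_string_edges()].
#' @export
interaction_network <- function(node1, node2, score, score_threshold = 0.4) {
  n_loops <- sum(node1 == node2)
  if (n_loops)
    message(sprintf("dropping %d self-loop(s)", n_loops))
  keep <- node1 != node2
  node1 <- node1[keep]; node2 <- node2[keep]; score <- score[keep]
  # canonical unordered pair, then collapse duplicates keeping max score
  lo <- pmin(node1, node2); hi <- pmax(node1, node2)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    score <- tapply(score, key, max)
    pairs <- strsplit(names(score), "\r", fixed = TRUE)
    lo <- vapply(pairs, `[[`, character(1), 1L)
    hi <- vapply(pairs, `[[`, character(1), 2L)
    score <- unname(score)
  }
  keep <- score > score_threshold
  lo <- lo[keep]; hi <- hi[keep]; score <- score[keep]
  if (!length(lo)) return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, combined_score = score,
               stringsAsFactors = FALSE),
    directed = FALSE)
  g
}

#' MCODE parameter set
#'
#' The standard parameter panel of the molecular-complex-detection
#' algorithm: degree cutoff 2, node score cutoff 0.2, haircut on, fluff
#' off, K-core 2, maximum depth from seed 100.
#'
#' @param degree_cutoff minimum degree for a node to receive a non-zero
#'   weight (>= 1).
#' @param node_score_cutoff admissible fractional deviation of a
#'   candidate's weight from the seed's weight, in \[0, 1\].
#' @param haircut iteratively strip complex members of induced degree < 2.
#' @param fluff reserved; only the default FALSE is implemented.
#' @param k_core a complex is kept only if it contains a k-core of this
#'   order.
#' @param max_depth breadth-first expansion limit from the seed.
#' @return A list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         haircut = TRUE, fluff = FALSE, k_core = 2,
                         max_depth = 100) {
  stopifnot(degree_cutoff >= 1, node_score_cutoff >= 0,
            node_score_cutoff <= 1, k_core >= 1, max_depth >= 1)
  if (isTRUE(fluff)) stop("fluff post-processing is not implemented")
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 haircut = isTRUE(haircut), fluff = FALSE,
                 k_core = as.integer(k_core),
                 max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

graph_density_simple <- function(n, e) if (n < 2) 0 else 2 * e / (n * (n - 1))

#' MCODE vertex weighting
#'
#' Weights every node by the density of the densest region of its closed
#' neighborhood: nodes with degree below `degree_cutoff` get weight 0;
#' otherwise the induced subgraph on the node and its neighbors is taken,
#' its highest-order k-core extracted, and the weight is that core order
#' times the core's edge density 2E/(n(n-1)).
#'
#' @param net igraph network (simple, undirected).
#' @param params an [mcode_params()] object.
#' @return Named numeric vector of node weights.
#' @export
mcode_vertex_weight <- function(net, params = mcode_params()) {
  stopifnot(inherits(net, "igraph"), inherits(params, "mcode_params"))
  nms <- igraph::V(net)$name
  if (is.null(nms)) nms <- as.character(seq_len(igraph::vcount(net)))
  deg <- igraph::degree(net)
  w <- stats::setNames(numeric(igraph::vcount(net)), nms)
  for (v in which(deg >= params$degree_cutoff)) {
    nb <- c(v, as.integer(igraph::neighbors(net, v)))
    sub <- igraph::induced_subgraph(net, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    inside <- which(core == kmax)
    if (length(inside) < 2L) next
    csub <- igraph::induced_subgraph(sub, inside)
    w[v] <- kmax * graph_density_simple(igraph::vcount(csub),
                                        igraph::ecount(csub))
  }
  w
}

#' Detect core modules (MCODE)
#'
#' Greedy seeded growth on the vertex-weighted graph: nodes are visited as
#' seeds in decreasing weight order (ties broken by node ID); from each
#' unassigned seed a breadth-first expansion admits unassigned neighbors
#' whose weight exceeds `seed_weight * (1 - node_score_cutoff)`, up to
#' `max_depth` levels. Each node belongs to at most one complex.
#' Post-processing discards complexes that contain no `k_core`-core, then
#' (haircut) iteratively removes members of induced degree < 2; if the
#' haircut disconnects a complex the component containing the seed is
#' kept (largest component, ties by smallest member ID, when the seed
#' itself was stripped). Module score is induced edge density times node
#' count, and the output is sorted by score, then size, then seed ID, so
#' results are deterministic.
#'
#' @param net igraph network.
#' @param params an [mcode_params()].
#' @return List of class `mcode_result`; each element is a `module` list
#'   with `rank`, `members`, `n_nodes`, `n_edges`, `score`, `seed_node`.
#' @export
mcode_find_complexes <- function(net, params = mcode_params()) {
  stopifnot(inherits(net, "igraph"))
  if (igraph::vcount(net) == 0L)
    return(structure(list(), class = "mcode_result", params = params))
  if (is.null(igraph::V(net)$name))
    net <- igraph::set_vertex_attr(net, "name",
                                   value = as.character(seq_len(igraph::vcount(net))))
  w <- mcode_vertex_weight(net, params)
  nms <- names(w)
  ord <- order(-w, nms, method = "radix")
  assigned <- stats::setNames(logical(length(w)), nms)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  adj <- lapply(adj, function(v) nms[as.integer(v)])
  names(adj) <- nms

  raw <- list()
  for (v in nms[ord]) {
    if (assigned[[v]] || w[[v]] <= 0) next
    thr <- w[[v]] * (1 - params$node_score_cutoff)
    members <- v
    assigned[[v]] <- TRUE
    frontier <- v
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      cand <- unique(unlist(adj[frontier], use.names = FALSE))
      cand <- cand[!assigned[cand] & w[cand] > thr]
      if (!length(cand)) break
      cand <- sort(cand, method = "radix")
      assigned[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
      depth <- depth + 1L
    }
    raw[[length(raw) + 1L]] <- list(seed = v, members = members)
  }

  modules <- list()
  for (cx in raw) {
    sub <- igraph::induced_subgraph(net, cx$members)
    if (max(igraph::coreness(sub)) < params$k_core) next
    if (params$haircut) {
      repeat {
        low <- which(igraph::degree(sub) < 2)
        if (!length(low)) break
        sub <- igraph::delete_vertices(sub, low)
      }
      if (igraph::vcount(sub) == 0L) next
      comp <- igraph::components(sub)
      if (comp$no > 1L) {
        mem_names <- igraph::V(sub)$name
        if (cx$seed %in% mem_names) {
          keep_comp <- comp$membership[[cx$seed]]
        } else {
          sz <- comp$csize
          cands <- which(sz == max(sz))
          first_member <- vapply(cands, function(ci)
            min(mem_names[comp$membership == ci]), character(1))
          keep_comp <- cands[order(first_member)][1L]
        }
        sub <- igraph::induced_subgraph(sub, comp$membership == keep_comp)
      }
    }
    n <- igraph::vcount(sub); e <- igraph::ecount(sub)
    if (n < 2L) next
    modules[[length(modules) + 1L]] <- structure(
      list(rank = NA_integer_,
           members = sort(igraph::V(sub)$name, method = "radix"),
           n_nodes = n, n_edges = e,
           score = graph_density_simple(n, e) * n,
           seed_node = cx$seed),
      class = "mcode_module")
  }

  if (length(modules)) {
    scores <- vapply(modules, `[[`, numeric(1), "score")
    sizes <- vapply(modules, `[[`, numeric(1), "n_nodes")
    seeds <- vapply(modules, `[[`, character(1), "seed_node")
    ord <- order(-scores, -sizes, seeds, method = "radix")
    modules <- modules[ord]
    for (i in seq_along(modules)) modules[[i]]$rank <- i
  }
  structure(modules, class = "mcode_result", params = params)
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("mcode_result: %d module(s)\n", length(x)))
  for (m in x)
    cat(sprintf("  #%d score %.2f: %d nodes, %d edges (seed %s)\n",
                m$rank, m$score, m$n_nodes, m$n_edges, m$seed_node))
  invisible(x)
}

#' Independent post-hoc validity check of detected modules
#'
#' Re-derives every claimed property of a module list directly from the
#' input graph, without reusing the detection code: member connectivity,
#' edge counts and scores of the induced subgraphs, existence of the
#' required k-core, the haircut degree bound, and pairwise node
#' disjointness.
#'
#' @param net the igraph network the modules were detected on.
#' @param modules an `mcode_result`.
#' @param params the [mcode_params()] used.
#' @return TRUE invisibly; stops with a message on the first violation.
#' @export
validate_modules <- function(net, modules, params = attr(modules, "params")) {
  seen <- character(0)
  for (m in modules) {
    sub <- igraph::induced_subgraph(net, m$members)
    if (igraph::components(sub)$no != 1L)
      stop("module ", m$rank, " is not connected")
    if (igraph::ecount(sub) != m$n_edges)
      stop("module ", m$rank, " edge count mismatch")
    if (igraph::vcount(sub) != m$n_nodes)
      stop("module ", m$rank, " node count mismatch")
    d <- graph_density_simple(m$n_nodes, m$n_edges)
    if (abs(d * m$n_nodes - m$score) > 1e-9)
      stop("module ", m$rank, " score mismatch")
    if (max(igraph::coreness(sub)) < params$k_core)
      stop("module ", m$rank, " lacks the required k-core")
    if (params$haircut && any(igraph::degree(sub) < 2))
      stop("module ", m$rank, " violates the haircut degree bound")
    if (length(intersect(seen, m$members)))
      stop("modules are not node-disjoint")
    seen <- c(seen, m$members)
  }
  invisible(TRUE)
}

#' Tabular module report
#'
#' One row per module with the columns of a core-module table: rank,
#' score, node count, edge count and the comma-joined upper-case member
#' genes.
#'
#' @param modules an `mcode_result`.
#' @param top_k number of top modules to keep (>= 1).
#' @return data.frame.
#' @export
module_report <- function(modules, top_k = length(modules)) {
  if (!missing(top_k) && top_k < 1) stop("top_k must be >= 1")
  modules <- utils::head(modules, max(top_k, 0L))
  if (!length(modules))
    return(data.frame(rank = integer(0), score = numeric(0),
                      n_nodes = integer(0), n_edges = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  data.frame(
    rank = vapply(modules, `[[`, numeric(1), "rank"),
    score = vapply(modules, `[[`, numeric(1), "score"),
    n_nodes = vapply(modules, `[[`, numeric(1), "n_nodes"),
    n_edges = vapply(modules, `[[`, numeric(1), "n_edges"),
    members = vapply(modules, function(m)
      paste(toupper(m$members), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

#' Write edge list / module report files
#'
#' @param net igraph network with `combined_score` edge attribute.
#' @param path output TSV path.
#' @export
write_network <- function(net, path) {
  if (igraph::ecount(net) == 0) {
    writeLines("node1\tnode2\tcombined_score", path)
    return(invisible(path))
  }
  el <- igraph::as_edgelist(net)
  df <- data.frame(node1 = el[, 1L], node2 = el[, 2L],
                   combined_score = igraph::E(net)$combined_score,
                   stringsAsFactors = FALSE)
  df <- df[order(df$node1, df$node2, method = "radix"), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @param modules an `mcode_result`.
#' @param top_k rows to keep.
#' @export
write_modules <- function(modules, path, top_k = length(modules)) {
  utils::write.table(module_report(modules, top_k), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
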