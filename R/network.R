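#' Build a feature-based molecular network
#'
#' Scores every pair of spectra with the modified cosine (neutral-loss shift
#' enabled) and keeps an edge when the score and the number of matched peaks
#' both reach their thresholds. Optional topology filters mirror the hosted
#' networking tools: `top_k` keeps an edge only if each endpoint ranks the
#' other within its `top_k` best-scoring neighbours, and `max_component`
#' repeatedly removes the globally lowest-scoring edge from oversized
#' connected components until no component exceeds the bound.
#'
#' @param spectra List of preprocessed [msms_spectrum()] objects. Spectra
#'   flagged empty by [preprocess_spectrum()] are skipped.
#' @param min_cosine Minimum modified-cosine score in (0, 1\] (default 0.7).
#' @param min_matched Minimum number of matched peaks (default 6).
#' @param frag_tol Fragment m/z tolerance in Da (default 0.01).
#' @param top_k Mutual-rank topology filter; `NULL` (default) disables.
#' @param max_component Maximum connected-component size; `NULL` (default)
#'   disables.
#' @return An object of class `molecular_network`: a list with `graph` (an
#'   \pkg{igraph} graph whose vertices carry `name` = feature id,
#'   `precursor_mz`, `rt`) and `edges` (data frame with `id_a`, `id_b`,
#'   `score`, `matched_peaks`, `precursor_delta`).
#' @export
build_network <- function(spectra, min_cosine = 0.7, min_matched = 6,
                          frag_tol = 0.01, top_k = NULL,
                          max_component = NULL) {
  if (min_cosine <= 0 || min_cosine > 1) stop("min_cosine must be in (0, 1]")
  if (min_matched < 1) stop("min_matched must be >= 1")
  spectra <- Filter(Negate(is_empty_spectrum), spectra)
  ids <- vapply(spectra, function(s) s$feature_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate feature ids among spectra")
  verts <- data.frame(
    name = ids,
    precursor_mz = vapply(spectra, function(s) s$precursor_mz, numeric(1)),
    rt = vapply(spectra, function(s) s$rt, numeric(1)),
    stringsAsFactors = FALSE
  )
  empty_edges <- data.frame(id_a = character(0), id_b = character(0),
                            score = numeric(0), matched_peaks = integer(0),
                            precursor_delta = numeric(0),
                            stringsAsFactors = FALSE)
  if (length(spectra) < 2L) {
    warning("fewer than 2 usable spectra; returning an empty network")
    g <- igraph::graph_from_data_frame(empty_edges[, 1:2], directed = FALSE,
                                       vertices = verts)
    return(molecular_network(g, empty_edges))
  }
  n <- length(spectra)
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      r <- modified_cosine(spectra[[i]], spectra[[j]], frag_tol = frag_tol,
                           allow_shift = TRUE)
      if (r$score >= min_cosine && r$matched_peaks >= min_matched) {
        k <- k + 1L
        rows[[k]] <- data.frame(id_a = ids[i], id_b = ids[j],
                                score = r$score,
                                matched_peaks = r$matched_peaks,
                                precursor_delta = r$precursor_delta,
                                stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (k > 0L) do.call(rbind, rows[seq_len(k)]) else empty_edges

  if (!is.null(top_k) && nrow(edges) > 0L) {
    edges <- filter_top_k(edges, top_k)
  }
  g <- igraph::graph_from_data_frame(edges[, c("id_a", "id_b")],
                                     directed = FALSE, vertices = verts)
  if (nrow(edges) > 0L) {
    igraph::E(g)$score <- edges$score
    igraph::E(g)$matched_peaks <- edges$matched_peaks
    igraph::E(g)$precursor_delta <- edges$precursor_delta
  }
  net <- molecular_network(g, edges)
  if (!is.null(max_component)) {
    net <- trim_components(net, max_component)
  }
  net
}

molecular_network <- function(graph, edges) {
  structure(list(graph = graph, edges = edges), class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  comp <- igraph::components(x$graph)
  fam <- sum(table(comp$membership) >= 2L)
  cat(sprintf("<molecular_network> %d nodes, %d edges, %d molecular families\n",
              igraph::vcount(x$graph), nrow(x$edges), fam))
  invisible(x)
}

# mutual top-k rank filter: an edge survives only if each endpoint ranks the
# other within its top_k neighbours by score
filter_top_k <- function(edges, top_k) {
  rank_ok <- function(node, other, score) {
    nb <- edges[edges$id_a == node | edges$id_b == node, ]
    sum(nb$score > score) < top_k
  }
  keep <- vapply(seq_len(nrow(edges)), function(e) {
    rank_ok(edges$id_a[e], edges$id_b[e], edges$score[e]) &&
      rank_ok(edges$id_b[e], edges$id_a[e], edges$score[e])
  }, logical(1))
  edges[keep, , drop = FALSE]
}

# remove globally lowest-score edges (ties by node-id order) from oversized
# components until every component size <= max_component
trim_components <- function(net, max_component) {
  edges <- net$edges
  verts <- data.frame(
    name = igraph::V(net$graph)$name,
    precursor_mz = igraph::V(net$graph)$precursor_mz,
    rt = igraph::V(net$graph)$rt, stringsAsFactors = FALSE
  )
  repeat {
    g <- igraph::graph_from_data_frame(edges[, c("id_a", "id_b")],
                                       directed = FALSE, vertices = verts)
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership]
    names(sizes) <- igraph::V(g)$name
    oversized <- sizes[edges$id_a] > max_component
    if (!any(oversized)) break
    cand <- which(oversized)
    ord <- cand[order(edges$score[cand], edges$id_a[cand],
                      edges$id_b[cand])]
    edges <- edges[-ord[1L], , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges[, c("id_a", "id_b")],
                                     directed = FALSE, vertices = verts)
  if (nrow(edges) > 0L) {
    igraph::E(g)$score <- edges$score
    igraph::E(g)$matched_peaks <- edges$matched_peaks
    igraph::E(g)$precursor_delta <- edges$precursor_delta
  }
  molecular_network(g, edges)
}

#' Extract molecular families from a network
#'
#' Molecular families (the "MN1, MN2, ..." of networking figures) are the
#' connected components with at least `min_size` nodes; smaller components are
#' reported separately as singletons.
#'
#' @param net A [build_network()] result.
#' @param min_size Minimum component size to count as a family (default 2).
#' @return A list with `families` (list of character vectors of feature ids,
#'   sorted by size descending then by smallest feature id) and `singletons`
#'   (character vector).
#' @export
molecular_families <- function(net, min_size = 2) {
  stopifnot(inherits(net, "molecular_network"))
  if (min_size < 1) stop("min_size must be >= 1")
  comp <- igraph::components(net$graph)
  ids <- igraph::V(net$graph)$name
  groups <- split(ids, comp$membership)
  groups <- lapply(groups, function(g) sort(g))
  big <- groups[vapply(groups, length, integer(1)) >= min_size]
  ord <- order(-vapply(big, length, integer(1)),
               vapply(big, function(g) g[1L], character(1)))
  small <- groups[vapply(groups, length, integer(1)) < min_size]
  list(families = unname(big[ord]),
       singletons = sort(unlist(small, use.names = FALSE)))
}

#' Export a molecular network to GraphML
#'
#' Node attributes (precursor m/z, rt, plus any supplied annotation columns)
#' and edge attributes (score, matched peaks, precursor delta) are written so
#' the file loads in standard graph viewers.
#'
#' @param net A [build_network()] result.
#' @param path Output `.graphml` path.
#' @param node_data Optional data frame with a `feature_id` column and extra
#'   node attributes (annotations, class labels, per-organ abundances).
#' @return Invisibly, `path`.
#' @export
export_graphml <- function(net, path, node_data = NULL) {
  g <- net$graph
  if (!is.null(node_data)) {
    stopifnot("feature_id" %in% names(node_data))
    m <- match(igraph::V(g)$name, node_data$feature_id)
    for (col in setdiff(names(node_data), "feature_id")) {
      g <- igraph::set_vertex_attr(g, col, value = node_data[[col]][m])
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export the network edge list as CSV
#' @param net A [build_network()] result.
#' @param path Output `.csv` path.
#' @return Invisibly, `path`.
#' @export
export_edgelist <- function(net, path) {
  utils::write.csv(net$edges, path, row.names = FALSE)
  invisible(path)
}
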