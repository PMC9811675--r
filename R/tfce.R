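#' Spatiotemporal connectivity graph
#'
#' The domain of cluster enhancement: one node per (vertex, latency) cell,
#' with mesh adjacency at equal latency plus same-vertex links between
#' consecutive latencies (no diagonal space-time links). Node index for
#' vertex v at latency slot l is (l-1) * n_vertices + v, matching the
#' column-major layout of a vertices x latencies map matrix.
#'
#' @param mesh A `cortical_mesh` (see [make_mesh]).
#' @param n_latencies Number of latency slots.
#' @return An object of class `st_graph` with fields `edges`, `n_vertices`,
#'   `n_latencies`, `vertex`, `latency_index`, `hemisphere`.
#' @export
spatiotemporal_graph <- function(mesh, n_latencies) {
  stopifnot(inherits(mesh, "cortical_mesh"), n_latencies >= 1L)
  nv <- nrow(mesh$coords)
  nl <- as.integer(n_latencies)
  spatial <- do.call(rbind, lapply(seq_len(nl) - 1L, function(l) {
    mesh$edges + l * nv
  }))
  temporal <- if (nl > 1L) {
    base <- rep(seq_len(nv), nl - 1L) + nv * rep(seq_len(nl - 1L) - 1L,
                                                 each = nv)
    cbind(base, base + nv)
  } else {
    matrix(integer(0), 0L, 2L)
  }
  structure(list(edges = unname(rbind(spatial, temporal)),
                 n_vertices = nv, n_latencies = nl,
                 vertex = rep(seq_len(nv), nl),
                 latency_index = rep(seq_len(nl), each = nv),
                 hemisphere = rep(mesh$hemisphere, nl)),
            class = "st_graph")
}

#' @export
print.st_graph <- function(x, ...) {
  cat("<st_graph> ", x$n_vertices, " vertices x ", x$n_latencies,
      " latencies, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

graph_values <- function(map, graph) {
  v <- if (is.matrix(map)) as.vector(map) else
    if (is.list(map) && !is.null(map$values)) as.vector(map$values) else
      as.numeric(map)
  if (length(v) != x_nodes(graph)) {
    stop("map size does not match the spatiotemporal graph")
  }
  v
}

x_nodes <- function(graph) graph$n_vertices * graph$n_latencies

# igraph over the cells passing `keep` (logical over nodes)
subgraph_components <- function(graph, keep) {
  e <- graph$edges
  e <- e[keep[e[, 1L]] & keep[e[, 2L]], , drop = FALSE]
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, x_nodes(graph) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  memb[!keep] <- NA_integer_
  memb
}

#' Cluster extent of a cell at a threshold
#'
#' The size (cell count) of the connected component containing `cell` in the
#' subgraph of cells whose statistic is at least `h`; 0 if the cell itself is
#' below threshold.
#'
#' @param map A `t_map`, matrix, or numeric vector of cell values.
#' @param h Positive threshold.
#' @param graph An [spatiotemporal_graph] result.
#' @param cell Node index (see [spatiotemporal_graph] for the layout).
#' @return Integer extent.
#' @export
cluster_extent <- function(map, h, graph, cell) {
  stopifnot(h > 0)
  v <- graph_values(map, graph)
  if (v[cell] < h) return(0L)
  memb <- subgraph_components(graph, v >= h)
  sum(memb == memb[cell], na.rm = TRUE)
}

#' Threshold-free cluster enhancement
#'
#' Replaces each cell's statistic t by the discrete threshold integral
#' sum over i >= 1 with i*delta_h <= t of (i*delta_h)^2 * e(i*delta_h),
#' where e(h) is the cell's cluster extent at threshold h. The sum is
#' evaluated literally as printed (no extra delta_h factor; the missing
#' constant is a uniform monotone scale that leaves maxima and permutation
#' p-values unchanged). Enhancement is one-sided: cells with t < delta_h
#' (including all negative t) get 0.
#'
#' @param map A `t_map`, matrix, or numeric vector of cell values.
#' @param graph An [spatiotemporal_graph] result.
#' @param delta_h Threshold step (default 0.1).
#' @return A `tfce_map` with the same vertices x latencies layout.
#' @export
tfce_transform <- function(map, graph, delta_h = 0.1) {
  stopifnot(delta_h > 0)
  v <- graph_values(map, graph)
  enh <- tfce_cpp(v, graph$edges, delta_h)
  structure(list(values = matrix(enh, graph$n_vertices, graph$n_latencies),
                 delta_h = delta_h),
            class = "tfce_map")
}

#' @export
print.tfce_map <- function(x, ...) {
  cat("<tfce_map> ", nrow(x$values), " vertices x ", ncol(x$values),
      " latencies, delta_h = ", x$delta_h, "\n", sep = "")
  invisible(x)
}

#' Check that enhancement preserves isocontour order
#'
#' TFCE must not relocate local maxima: for any two adjacent cells the
#' original and enhanced values may never be ordered in opposite directions,
#' and adjacent ties must stay tied. This edgewise order preservation holds
#' exactly for [tfce_transform] (adjacent suprathreshold cells share a
#' component at every common threshold) and implies that every local maximum
#' of the statistic map remains a local maximum of the enhanced map.
#'
#' @param map Original statistic map (`t_map`, matrix or vector).
#' @param enhanced Enhanced map (`tfce_map`, matrix or vector).
#' @param graph An [spatiotemporal_graph] result.
#' @return `TRUE` if order is preserved along every edge, else `FALSE`.
#' @export
isocontour_check <- function(map, enhanced, graph) {
  v <- graph_values(map, graph)
  e <- graph_values(enhanced, graph)
  a <- graph$edges[, 1L]
  b <- graph$edges[, 2L]
  dv <- v[a] - v[b]
  de <- e[a] - e[b]
  !any((dv > 0 & de < 0) | (dv < 0 & de > 0) | (dv == 0 & de != 0))
}

# t statistics for one sign-flip assignment, vectorized over cells;
# flat: subjects x cells matrix of rho values, flips: +/-1 per subject
flip_tstats <- function(flat, flips, ss) {
  n <- nrow(flat)
  mu <- as.vector(flips %*% flat) / n
  va <- pmax((ss - n * mu^2) / (n - 1), 0)
  tt <- ifelse(va > 0, mu / sqrt(va / n), sign(mu) * 100)
  tt
}

#' Map-maximum sign-flip null distributions
#'
#' Simulates the null hypothesis that subjects' rho values are symmetric
#' about zero: each permutation draws one independent +/-1 per subject
#' (shared across all cells and both hemispheres, preserving within-subject
#' spatial covariance), recomputes the group t-map, applies TFCE, and
#' records the per-hemisphere map maximum. Separate null distributions are
#' collected for each hemisphere.
#'
#' @param rho_maps List of per-subject `rho_map`s.
#' @param graph An [spatiotemporal_graph] result.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param delta_h TFCE threshold step.
#' @return A `null_distribution`: list with per-hemisphere maxima
#'   (`maxima$L`, `maxima$R`), `n_perm`, `seed`, `delta_h`.
#' @export
signflip_null <- function(rho_maps, graph, n_perm = 1000, seed = 1L,
                          delta_h = 0.1) {
  if (length(rho_maps) < 2L) stop("sign-flip null needs at least 2 subjects")
  flat <- t(vapply(rho_maps, function(m) as.vector(m$values),
                   numeric(length(rho_maps[[1L]]$values))))
  if (ncol(flat) != x_nodes(graph)) {
    stop("rho maps do not match the spatiotemporal graph")
  }
  ss <- colSums(flat^2)
  flips <- withr::with_seed(seed, {
    matrix(sample(c(-1, 1), n_perm * nrow(flat), replace = TRUE),
           n_perm, nrow(flat))
  })
  hemis <- sort(unique(graph$hemisphere))
  maxima <- matrix(NA_real_, n_perm, length(hemis),
                   dimnames = list(NULL, hemis))
  for (p in seq_len(n_perm)) {
    tt <- flip_tstats(flat, flips[p, , drop = FALSE], ss)
    enh <- tfce_cpp(tt, graph$edges, delta_h)
    for (h in hemis) maxima[p, h] <- max(enh[graph$hemisphere == h])
  }
  structure(list(maxima = lapply(stats::setNames(hemis, hemis),
                                 function(h) maxima[, h]),
                 n_perm = n_perm, seed = seed, delta_h = delta_h),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$n_perm, " permutations, hemispheres: ",
      paste(names(x$maxima), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Corrected p-values from a map-maximum null
#'
#' Each cell's enhanced statistic is referred to the null distribution of
#' map maxima of its own hemisphere: p = (1 + #\{null maxima > observed\}) /
#' n_perm, clamped to at most 1 (strictly-greater counting). This controls
#' the family-wise error rate over all cells of a hemisphere.
#'
#' @param observed_tfce A `tfce_map`.
#' @param null A `null_distribution` from [signflip_null].
#' @param graph An [spatiotemporal_graph] result.
#' @return A `p_map` (vertices x latencies matrix of corrected p-values).
#' @export
corrected_pmap <- function(observed_tfce, null, graph) {
  stopifnot(inherits(null, "null_distribution"))
  v <- graph_values(observed_tfce, graph)
  p <- rep(NA_real_, length(v))
  for (h in names(null$maxima)) {
    idx <- which(graph$hemisphere == h)
    nm <- null$maxima[[h]]
    counts <- vapply(v[idx], function(val) sum(nm > val), numeric(1))
    p[idx] <- pmin((1 + counts) / null$n_perm, 1)
  }
  structure(list(values = matrix(p, graph$n_vertices, graph$n_latencies),
                 alpha_resolution = 1 / null$n_perm),
            class = "p_map")
}

#' @export
print.p_map <- function(x, ...) {
  cat("<p_map> ", nrow(x$values), " vertices x ", ncol(x$values),
      " latencies, min p = ", min(x$values), "\n", sep = "")
  invisible(x)
}

#' Threshold a corrected p-map and report clusters
#'
#' Groups the cells passing `p < alpha` into connected components of the
#' spatiotemporal graph and reports, per cluster, its extent, peak enhanced
#' value and peak latency. The summary statistic `max_summed_extent` is the
#' maximum over latencies of the total suprathreshold extent at that
#' latency, summing spatiotemporally discontinuous clusters.
#'
#' @param pmap A `p_map`.
#' @param alpha Corrected significance level (default 0.01).
#' @param tfce_map The observed `tfce_map` (for peak values).
#' @param graph An [spatiotemporal_graph] result.
#' @param latencies_ms Optional latency grid for labeling peak latencies.
#' @return A `cluster_report`: list with `clusters` (data frame), `members`
#'   (list of cell indices), `extent_by_latency`, `max_summed_extent`.
#' @export
threshold_and_report <- function(pmap, alpha = 0.01, tfce_map, graph,
                                 latencies_ms = NULL) {
  p <- graph_values(pmap, graph)
  enh <- graph_values(tfce_map, graph)
  keep <- p < alpha
  lat_of <- function(idx) {
    li <- graph$latency_index[idx]
    if (is.null(latencies_ms)) li else latencies_ms[li]
  }
  if (!any(keep)) {
    return(structure(list(
      clusters = data.frame(cluster = integer(0), hemisphere = character(0),
                            n_cells = integer(0), peak_value = numeric(0),
                            peak_latency = numeric(0)),
      members = list(),
      extent_by_latency = rep(0L, graph$n_latencies),
      max_summed_extent = 0L), class = "cluster_report"))
  }
  memb <- subgraph_components(graph, keep)
  ids <- sort(unique(memb[!is.na(memb)]))
  members <- lapply(ids, function(k) which(!is.na(memb) & memb == k))
  clusters <- do.call(rbind, lapply(seq_along(members), function(i) {
    cells <- members[[i]]
    peak <- cells[which.max(enh[cells])]
    data.frame(cluster = i, hemisphere = graph$hemisphere[peak],
               n_cells = length(cells), peak_value = enh[peak],
               peak_latency = lat_of(peak))
  }))
  ext <- tabulate(graph$latency_index[keep], nbins = graph$n_latencies)
  structure(list(clusters = clusters, members = members,
                 extent_by_latency = ext,
                 max_summed_extent = max(ext)),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report> ", nrow(x$clusters), " cluster(s), max summed extent ",
      x$max_summed_extent, "\n", sep = "")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
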