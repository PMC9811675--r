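# Independent reference implementations used as oracles, plus tiny fixtures.
# These deliberately avoid the package's own computational paths.

# Spearman rho by explicit mid-rank construction and the product-moment
# formula on ranks (no call to stats::cor's "spearman" path).
spearman_naive <- function(x, y) {
  rk <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }, numeric(1))
  }
  a <- rk(x)
  b <- rk(y)
  da <- a - mean(a)
  db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Davies-Bouldin by a naive double loop over clusters.
db_naive <- function(points, labels) {
  points <- as.matrix(points)
  labs <- unique(labels)
  k <- length(labs)
  cent <- lapply(labs, function(l) colMeans(points[labels == l, , drop = FALSE]))
  scat <- vapply(seq_len(k), function(i) {
    m <- points[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums((m - matrix(cent[[i]], nrow(m), ncol(m),
                                  byrow = TRUE))^2)))
  }, numeric(1))
  r <- numeric(k)
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      d <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (scat[i] + scat[j]) / d)
    }
    r[i] <- best
  }
  mean(r)
}

# TFCE by per-threshold component enumeration with igraph flood fill.
tfce_oracle <- function(values, edges, delta_h) {
  n <- length(values)
  out <- numeric(n)
  if (max(values) < delta_h) return(out)
  i <- 1
  while (i * delta_h <= max(values)) {
    h <- i * delta_h
    keep <- values >= h
    e <- edges[keep[edges[, 1]] & keep[edges[, 2]], , drop = FALSE]
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
    sizes <- tabulate(memb)
    out[keep] <- out[keep] + h^2 * sizes[memb[keep]]
    i <- i + 1
  }
  out
}

# a hand-built spatiotemporal graph over an arbitrary edge list
mini_graph <- function(edges, n_vertices, n_latencies,
                       hemisphere = rep("L", n_vertices)) {
  structure(list(edges = edges, n_vertices = n_vertices,
                 n_latencies = n_latencies,
                 vertex = rep(seq_len(n_vertices), n_latencies),
                 latency_index = rep(seq_len(n_latencies),
                                     each = n_vertices),
                 hemisphere = rep(hemisphere, n_latencies)),
            class = "st_graph")
}

random_rdm <- function(n, seed, features = n + 3) {
  withr::with_seed(seed, {
    correlation_distance_rdm(matrix(rnorm(n * features), n))
  })
}

# small synthetic world shared by searchlight/latency tests
tiny_world <- function(seed = 3, n_subjects = 2, effect_size = 1,
                       noise_sd = 1, n_vertices = 24, latency = 0) {
  cfg <- synth_config(n_conditions = 12, n_subjects = n_subjects,
                      n_vertices_per_hemisphere = n_vertices,
                      effect_size = effect_size, noise_sd = noise_sd,
                      planted_latency_ms = latency,
                      layer_dims = c(L2 = 15L, L7 = 8L), seed = seed)
  segs <- make_segment_table(cfg)
  tls <- make_layer_activations(cfg, segs)
  ms <- build_model_stream(tls$L7)
  mesh <- make_mesh(cfg$n_vertices_per_hemisphere, cfg$mesh_radius_mm,
                    cfg$seed)
  list(cfg = cfg, segs = segs, tls = tls, ms = ms, mesh = mesh)
}

# truncate an RDM stream to its first k frames
short_stream <- function(stream, k) {
  rdm_stream(stream$times_ms[seq_len(k)], stream$rdms[seq_len(k)])
}
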