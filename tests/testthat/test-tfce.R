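test_that("cluster extent flood-fills the suprathreshold component", {
  mesh <- make_mesh(4, 30, 1)          # two K4 hemispheres
  g <- spatiotemporal_graph(mesh, 2)   # 16 cells
  vals <- rep(0, 16)
  expect_equal(cluster_extent(vals, 0.5, g, 1), 0L)          # below h
  vals[3] <- 1
  expect_equal(cluster_extent(vals, 0.5, g, 3), 1L)          # isolated cell
  # 2x2 block: two adjacent vertices at two consecutive latencies
  vals <- rep(0, 16)
  vals[c(1, 2, 9, 10)] <- 1
  expect_equal(cluster_extent(vals, 0.5, g, 1), 4L)
})

test_that("TFCE matches the literal discrete sum on a hand example", {
  mesh <- make_mesh(4, 30, 1)
  g <- spatiotemporal_graph(mesh, 1)
  vals <- rep(0, 8)
  vals[c(1, 2)] <- 1.0                 # adjacent pair, e(h) = 2 for all h
  enh <- tfce_transform(vals, g, 0.1)
  expect_equal(enh$values[1, 1], 2 * sum((0.1 * (1:10))^2))  # = 7.7
  expect_equal(enh$values[2, 1], enh$values[1, 1])
  expect_equal(sum(enh$values != 0), 2)
  # all-zero map stays zero; 0 <= t < delta_h gets 0
  expect_true(all(tfce_transform(rep(0, 8), g)$values == 0))
  v2 <- rep(0, 8); v2[5] <- 0.09
  expect_true(all(tfce_transform(v2, g)$values == 0))
})

test_that("TFCE equals the brute-force threshold-enumeration oracle on random maps", {
  mesh <- make_mesh(5, 30, 2)          # 10 vertices
  g <- spatiotemporal_graph(mesh, 5)   # 50 cells
  for (s in 1:50) {
    vals <- withr::with_seed(600 + s, rnorm(50, mean = 0.5, sd = 1.5))
    enh <- tfce_transform(vals, g, 0.1)
    expect_equal(as.vector(enh$values), tfce_oracle(vals, g$edges, 0.1),
                 tolerance = 1e-12)
    expect_true(isocontour_check(vals, enh, g))
  }
})

test_that("raising one cell's statistic never decreases any TFCE value", {
  mesh <- make_mesh(5, 30, 3)
  g <- spatiotemporal_graph(mesh, 3)
  vals <- withr::with_seed(77, rnorm(30, 0.5, 1))
  base <- as.vector(tfce_transform(vals, g)$values)
  for (cell in c(4, 17, 29)) {
    up <- vals
    up[cell] <- up[cell] + 0.7
    expect_true(all(as.vector(tfce_transform(up, g)$values) >= base - 1e-12))
  }
})

test_that("isocontour order preservation rejects corrupted maps", {
  mesh <- make_mesh(5, 30, 4)
  g <- spatiotemporal_graph(mesh, 2)
  vals <- withr::with_seed(9, runif(20, 0, 2))
  enh <- tfce_transform(vals, g)
  expect_true(isocontour_check(vals, vals, g))   # identity map
  expect_true(isocontour_check(vals, enh, g))
  bad <- as.vector(enh$values)
  # corrupt along an edge: force the enhanced order to oppose the map order
  e <- g$edges[which.max(abs(vals[g$edges[, 1]] - vals[g$edges[, 2]])), ]
  hi <- e[which.max(vals[e])]
  lo <- e[which.min(vals[e])]
  bad[hi] <- bad[lo] - 1
  expect_false(isocontour_check(vals, bad, g))
})

test_that("sign-flip nulls are seed-reproducible and respect hemispheres", {
  w <- tiny_world(seed = 31, n_subjects = 4, effect_size = 0)
  slc <- searchlight_config(epoch_ms = c(0, 120))
  target <- short_stream(w$ms, 4)
  ep <- make_source_epochs(w$cfg, w$mesh, target, epoch_end_ms = 120)
  lat <- seq(0, 30, 10)
  maps <- searchlight_rho_maps(target, ep, w$mesh, slc, lat)
  g <- spatiotemporal_graph(w$mesh, length(lat))
  n1 <- signflip_null(maps, g, n_perm = 40, seed = 5)
  n2 <- signflip_null(maps, g, n_perm = 40, seed = 5)
  expect_identical(n1$maxima, n2$maxima)
  expect_named(n1$maxima, c("L", "R"))
  expect_length(n1$maxima$L, 40)
  # all-zero rho maps give an all-zero null
  zmaps <- lapply(maps, function(m) { m$values[] <- 0; m })
  nz <- signflip_null(zmaps, g, n_perm = 10, seed = 1)
  expect_true(all(unlist(nz$maxima) == 0))
})

test_that("map-maximum p-values use strictly-greater counting with the +1 rule", {
  null <- structure(list(maxima = list(L = as.numeric(1:1000),
                                       R = as.numeric(1:1000)),
                         n_perm = 1000, seed = 1, delta_h = 0.1),
                    class = "null_distribution")
  mesh <- make_mesh(4, 30, 1)
  g <- spatiotemporal_graph(mesh, 1)
  vals <- c(2000, 0, 500.5, rep(0, 5))        # L vertices 1..4, R 5..8
  tf <- structure(list(values = matrix(vals, 8, 1), delta_h = 0.1),
                  class = "tfce_map")
  p <- corrected_pmap(tf, null, g)
  expect_equal(p$values[1, 1], 0.001)          # above all 1000 maxima
  expect_equal(p$values[2, 1], 1)              # below all (clamped)
  expect_equal(p$values[3, 1], (1 + 500) / 1000)  # empirical median
})

test_that("cluster reports group suprathreshold cells and sum discontinuous extents", {
  mesh <- make_mesh(6, 30, 6)
  g <- spatiotemporal_graph(mesh, 2)           # 24 cells
  enh <- rep(0, 24)
  p <- rep(1, 24)
  report0 <- threshold_and_report(p, 0.01, enh, g)
  expect_equal(nrow(report0$clusters), 0)
  expect_equal(report0$max_summed_extent, 0L)
  # one left-hemisphere cluster of 5 cells and one right singleton at the
  # same latency: summed extent 6 at that latency
  cells_l <- c(1, 2, 3, 13, 14)                # spatially/temporally linked
  cell_r <- 8
  p[c(cells_l, cell_r)] <- 0.001
  enh[c(cells_l, cell_r)] <- c(5, 4, 3, 2, 1, 9)
  rep1 <- threshold_and_report(p, 0.01, enh, g, latencies_ms = c(0, 10))
  expect_equal(sort(rep1$clusters$n_cells), c(1, 5))
  expect_equal(rep1$extent_by_latency, c(4L, 2L))
  expect_equal(rep1$max_summed_extent, 4L)
  peak <- rep1$clusters[rep1$clusters$n_cells == 1, ]
  expect_equal(peak$peak_value, 9)
})
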