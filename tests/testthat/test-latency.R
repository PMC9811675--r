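stream_of <- function(rdms, step = 10, t0 = 0) {
  rdm_stream(t0 + step * (seq_along(rdms) - 1), rdms)
}

test_that("latency_rho averages Spearman over alignable pairs", {
  rdms <- lapply(1:6, function(s) random_rdm(5, 100 + s))
  model <- stream_of(rdms[1:3])
  brain <- stream_of(rdms, t0 = 0)
  # brain stream equal to model at latency 0 gives rho 1
  expect_equal(latency_rho(model, stream_of(rdms[1:3]), 0), 1)
  # single alignable pair equals spearman_rdm of that pair
  m1 <- stream_of(rdms[1])
  expect_equal(latency_rho(m1, brain, 20),
               spearman_rdm(rdms[[1]], rdms[[3]]))
  # three alignable pairs: mean of the three pairwise values (brute force)
  expected <- mean(c(spearman_naive(vectorize_upper(rdms[[1]]),
                                    vectorize_upper(rdms[[2]])),
                     spearman_naive(vectorize_upper(rdms[[2]]),
                                    vectorize_upper(rdms[[3]])),
                     spearman_naive(vectorize_upper(rdms[[3]]),
                                    vectorize_upper(rdms[[4]]))))
  expect_equal(latency_rho(model, brain, 10), expected)
  expect_error(latency_rho(model, brain, 500), "alignable")
})

test_that("latency pairing is consistent under stream shifts", {
  rdms <- lapply(1:8, function(s) random_rdm(4, 200 + s))
  model <- stream_of(rdms[1:4])
  brain <- stream_of(rdms)
  shifted <- stream_of(rdms, t0 = 30)   # same frames, timeline moved by +30
  for (k in c(0, 10, 20)) {
    expect_equal(latency_rho(model, shifted, k + 30),
                 latency_rho(model, brain, k))
  }
})

test_that("rho_map grids and group t-maps follow the t-statistic definition", {
  rdms <- lapply(1:6, function(s) random_rdm(4, 300 + s))
  model <- stream_of(rdms[1:2])
  brains <- list(stream_of(rdms), stream_of(rev(rdms)))
  rm <- rho_map(model, brains, latencies_ms = seq(0, 30, 10))
  expect_equal(dim(rm$values), c(2, 4))
  expect_true(all(rm$values >= -1 & rm$values <= 1))
  # group t: hand arithmetic for rho 0.2 / 0.4 across two subjects
  mk <- function(vals) {
    structure(list(values = matrix(vals, 1, 2),
                   latencies_ms = c(0, 10),
                   subject = "s", layer = NA_character_),
              class = "rho_map")
  }
  tm <- group_tmap(list(mk(c(0.2, 0.3)), mk(c(0.4, -0.3))))
  expect_equal(tm$values[1, 1], 0.3 / (sd(c(0.2, 0.4)) / sqrt(2)))
  expect_equal(tm$values[1, 2], 0)      # symmetric +a/-a cell
  # zero-variance cell gets the documented sentinel and flag
  tms <- group_tmap(list(mk(c(0.5, 0.1)), mk(c(0.5, 0.2))))
  expect_equal(tms$values[1, 1], 100)
  expect_true(attr(tms, "zero_variance")[1, 1])
  expect_error(group_tmap(list(mk(c(1, 2)))), "2 subjects")
  # antisymmetric under negating all subjects
  neg <- group_tmap(list(mk(-c(0.2, 0.3)), mk(-c(0.4, -0.3))))
  expect_equal(neg$values, -tm$values)
})

test_that("vectorized searchlight maps equal the compositional stream + rho_map path", {
  w <- tiny_world(seed = 11, n_subjects = 2, effect_size = 0.6)
  slc <- searchlight_config(epoch_ms = c(0, 120))
  target <- short_stream(w$ms, 4)
  ep <- make_source_epochs(w$cfg, w$mesh, target, epoch_end_ms = 120)
  lat <- seq(0, 40, 10)
  fast <- searchlight_rho_maps(target, ep, w$mesh, slc, lat)
  nv <- nrow(w$mesh$coords)
  for (subj in names(ep$data)) {
    streams <- lapply(seq_len(nv), function(v) {
      brain_rdm_stream(ep, w$mesh, slc, v, subj)
    })
    slow <- rho_map(target, streams, lat)
    expect_equal(fast[[subj]]$values, slow$values, tolerance = 1e-8)
  }
})

test_that("the averaged-RDM fixed-effects mode matches per-subject maps when they coincide", {
  w <- tiny_world(seed = 61, n_subjects = 2, effect_size = 0.5)
  slc <- searchlight_config(epoch_ms = c(0, 100))
  target <- short_stream(w$ms, 3)
  ep <- make_source_epochs(w$cfg, w$mesh, target, epoch_end_ms = 100)
  lat <- c(0, 10)
  # with a single subject, averaging RDMs is a no-op: the fixed-effects map
  # must equal that subject's searchlight map
  ep1 <- source_epochs(ep$data["s01"], ep$conditions, ep$times_ms)
  avg <- averaged_rho_map(target, ep1, w$mesh, slc, lat)
  per <- searchlight_rho_maps(target, ep1, w$mesh, slc, lat)
  expect_equal(avg$values, per$s01$values, tolerance = 1e-8)
  expect_equal(avg$subject, "group-average")
})

test_that("noise-free planted effects are recovered at the planted cell", {
  w <- tiny_world(seed = 21, n_subjects = 2, effect_size = 1,
                  n_vertices = 80, latency = 20)
  slc <- searchlight_config(epoch_ms = c(0, 200))
  target <- short_stream(w$ms, 10)
  ep <- make_source_epochs(w$cfg, w$mesh, target, epoch_end_ms = 200)
  eff <- attr(ep, "effect_vertices")
  lat <- seq(0, 60, 10)
  maps <- searchlight_rho_maps(target, ep, w$mesh, slc, lat)
  gm <- (maps[[1]]$values + maps[[2]]$values) / 2
  pk <- arrayInd(which.max(gm), dim(gm))
  expect_true(pk[1] %in% eff)
  expect_equal(lat[pk[2]], 20)
  # the realized window RDMs match the planted stream near-perfectly in
  # rank order (slice construction is exact up to rank truncation)
  expect_gt(gm[attr(ep, "effect_center"), which(lat == 20)], 0.9)
})
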