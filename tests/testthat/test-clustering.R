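test_that("segment averaging assigns frames by window midpoint and splits repeats", {
  conds <- condition_set("bulb", 200)
  frames <- matrix(rep(1:18, each = 3) + 0, 18, 3)   # frame t has value t
  frames[] <- rep(1:18, 3)
  tl <- feature_timeline(conds, list(bulb = frames), "L7")
  segs <- segment_table(data.frame(
    condition = "bulb",
    start_ms = c(0, 60, 120, 170),
    end_ms = c(60, 120, 170, 200),
    phone = c("b", "ah", "l", "b")))
  sv <- segment_average(tl, segs)
  # midpoints 12.5, 22.5, ... frame t covers [10(t-1), 10(t-1)+25)
  # segment [0,60): frames with midpoint < 60 -> frames 1..5
  expect_equal(unname(sv$vectors[1, 1]), mean(1:5))
  # repeated phone yields two distinct vectors
  expect_equal(sum(sv$info$phone == "b"), 2)
  expect_false(isTRUE(all.equal(sv$vectors[1, ], sv$vectors[4, ])))
  # hand-checked: frame t covers [10(t-1), 10(t-1)+25), midpoint
  # 10(t-1)+12.5, so [120,170) holds the midpoints of frames 12..16
  expect_equal(unname(sv$vectors[3, 1]), mean(12:16))
  # a segment with no midpoint errors with its description
  bad <- segment_table(data.frame(condition = "bulb", start_ms = 3,
                                  end_ms = 11, phone = "s"))
  expect_error(segment_average(tl, bad), "no frame midpoint")
})

test_that("Davies-Bouldin agrees with hand arithmetic and a naive reference", {
  # clusters {0,1} and {4,5}: scatter 0.5 each, centroid distance 4 -> 0.25
  pts <- matrix(c(0, 1, 4, 5), 4, 1)
  labs <- c("a", "a", "b", "b")
  expect_equal(davies_bouldin(pts, labs), 0.25)
  # duplicated identical points per label -> exactly 0
  dup <- rbind(matrix(1:3, 4, 3, byrow = TRUE),
               matrix(7:9, 4, 3, byrow = TRUE))
  expect_equal(davies_bouldin(dup, rep(c("x", "y"), each = 4)), 0)
  # invariant under point order permutation
  perm <- withr::with_seed(1, sample(4))
  expect_equal(davies_bouldin(pts[perm, , drop = FALSE], labs[perm]), 0.25)
  expect_error(davies_bouldin(pts, rep("a", 4)), "2 distinct labels")
  expect_error(davies_bouldin(rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1)),
                              c("a", "a", "b", "b")), "coincident")
  # exact agreement with the naive double-loop reference
  for (s in 1:100) {
    withr::with_seed(900 + s, {
      k <- sample(2:5, 1)
      pts <- matrix(rnorm(20 * 3), 20, 3)
      labs <- sample(letters[1:k], 20, replace = TRUE)
      while (length(unique(labs)) < 2) labs <- sample(letters[1:k], 20, TRUE)
      expect_equal(davies_bouldin(pts, labs), db_naive(pts, labs))
    })
  }
})

test_that("Davies-Bouldin is invariant to rigid motions and isotropic scaling", {
  withr::with_seed(12, {
    pts <- matrix(rnorm(30), 10, 3)
    labs <- rep(c("a", "b"), 5)
    base <- davies_bouldin(pts, labs)
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    expect_equal(davies_bouldin(pts %*% rot, labs), base)
    expect_equal(davies_bouldin(pts + 5, labs), base)
    expect_equal(davies_bouldin(pts * 3.7, labs), base)
  })
})

test_that("label-permutation p-values use the (1 + stricter)/n convention", {
  pts <- matrix(withr::with_seed(8, runif(6, 0, 10)), 6, 1)
  labs <- rep(c("a", "b", "c"), each = 2)
  res <- db_permutation_p(pts, labs, n_perm = 200, seed = 2)
  expect_equal(res$index, davies_bouldin(pts, labs))
  # observed no better than any null is clamped to 1
  worst <- db_permutation_p(pts, c("a", "b", "a", "c", "b", "c"),
                            n_perm = 50, seed = 3)
  expect_lte(worst$p, 1)
  expect_gte(worst$p, 1 / 50)
})

test_that("permutation p-values are near-uniform without label structure", {
  ps <- vapply(1:50, function(s) {
    withr::with_seed(1500 + s, {
      pts <- matrix(rnorm(24), 12, 2)
      labs <- rep(c("a", "b", "c"), each = 4)
      db_permutation_p(pts, labs, n_perm = 99, seed = 1500 + s)$p
    })
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("scheme evaluation filters phones by applicability and flags degenerate schemes", {
  w <- tiny_world(seed = 41)
  res <- evaluate_all_schemes(w$tls["L7"], w$segs, n_perm = 50, seed = 1)
  expect_equal(nrow(res), 5)
  expect_setequal(res$scheme,
                  c("phone", "place", "manner", "frontness", "closeness"))
  schemes <- default_label_schemes()
  phones_in <- unique(w$segs$phone)
  for (i in seq_len(nrow(res))) {
    sc <- schemes[[res$scheme[i]]]
    sv <- segment_average(w$tls$L7, w$segs)
    expect_equal(res$n_points[i], sum(sv$info$phone %in% names(sc$map)))
  }
  # planted clusters (separation driven by phone labels) score better than
  # label-free noise on the phone scheme
  noise_cfg <- synth_config(n_conditions = 12, n_subjects = 2,
                            cluster_separation = 0,
                            layer_dims = c(L7 = 8L), seed = 41,
                            planted_latency_ms = 0)
  noise_tl <- make_layer_activations(noise_cfg, w$segs)
  res_noise <- evaluate_all_schemes(noise_tl, w$segs, n_perm = 50, seed = 1)
  expect_lt(res$index[res$scheme == "phone"],
            res_noise$index[res_noise$scheme == "phone"])
  # scheme with < 2 labels after filtering is flagged
  two <- label_scheme("degenerate",
                      stats::setNames(rep("only", length(phones_in)),
                                      phones_in))
  resd <- evaluate_all_schemes(w$tls["L7"], w$segs, schemes = list(two),
                               n_perm = 10, seed = 1)
  expect_true(is.na(resd$index))
  expect_match(resd$note, "fewer than 2")
})

test_that("Sammon embedding reproduces planar configurations and is seeded", {
  withr::with_seed(3, {
    pts <- matrix(rnorm(16), 8, 2)
    d <- as.matrix(dist(pts))
  })
  fit <- sammon_embed(d, seed = 4)
  expect_lt(fit$stress, 1e-4)          # exactly embeddable in the plane
  fit2 <- sammon_embed(d, seed = 4)
  expect_identical(fit$points, fit2$points)
  # any metric triangle embeds exactly
  tri <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3)
  expect_lt(sammon_embed(tri, seed = 1)$stress, 1e-6)
  # a regular tetrahedron cannot: strictly positive stress
  tet <- matrix(1, 4, 4) - diag(4)
  expect_gt(sammon_embed(tet, seed = 1)$stress, 1e-4)
  bad <- tet
  bad[1, 2] <- bad[2, 1] <- 0
  expect_error(sammon_embed(bad), "zero")
})
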