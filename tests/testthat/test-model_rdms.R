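make_timeline <- function(frames_per_cond, dim = 4, seed = 1,
                          durations = NULL) {
  ids <- sprintf("c%d", seq_along(frames_per_cond))
  if (is.null(durations)) durations <- 10 * (frames_per_cond - 1) + 25
  conds <- condition_set(ids, durations)
  frames <- withr::with_seed(seed, {
    lapply(stats::setNames(seq_along(ids), ids), function(i) {
      matrix(rnorm(frames_per_cond[i] * dim), frames_per_cond[i], dim)
    })
  })
  feature_timeline(conds, frames, "L1")
}

test_that("delta features use the central difference with duplicated boundaries", {
  tl <- make_timeline(c(4, 4), dim = 3)
  # constant timeline: all deltas 0
  const <- tl
  const$frames <- lapply(const$frames, function(m) {
    matrix(1, nrow(m), ncol(m))
  })
  d0 <- append_deltas(feature_timeline(tl$conditions, const$frames, "L1"))
  expect_true(all(vapply(d0$frames, function(m) all(m[, 4:6] == 0),
                         logical(1))))
  # dimension doubles: 40 -> 80
  tl40 <- make_timeline(c(3, 3), dim = 40)
  expect_equal(ncol(append_deltas(tl40)$frames[[1]]), 80)
  # ramp o_t = t * v has interior deltas v
  v <- c(1, -2, 0.5)
  ramp <- feature_timeline(condition_set("c1", 65),
                           list(c1 = outer(1:5, v)), "L1")
  dr <- append_deltas(ramp)$frames$c1
  expect_equal(dr[2:4, 4:6], outer(rep(1, 3), v))
  expect_equal(dr[1, 4:6], v / 2)     # duplicated first neighbour
  expect_equal(dr[5, 4:6], v / 2)
  single <- feature_timeline(condition_set("c1", 25),
                             list(c1 = matrix(1, 1, 3)), "L1")
  expect_error(append_deltas(single), "single frame")
})

test_that("context stacking clamps boundary frames and multiplies dimension by 9", {
  tl80 <- make_timeline(c(5, 5), dim = 80)
  st <- stack_context(tl80)
  expect_equal(ncol(st$frames[[1]]), 720)
  # single-frame condition: 9 copies of that frame
  single <- feature_timeline(condition_set("c1", 25),
                             list(c1 = matrix(1:4, 1, 4)), "L1")
  expect_equal(as.vector(stack_context(single)$frames$c1), rep(1:4, 9))
  # first frame of a 3-frame condition concatenates frames (1,1,1,1,1,2,3,3,3)
  tl3 <- make_timeline(3, dim = 2)
  st3 <- stack_context(tl3)
  base <- tl3$frames$c1
  expect_equal(st3$frames$c1[1, ],
               as.vector(t(base[c(1, 1, 1, 1, 1, 2, 3, 3, 3), ])))
})

test_that("frame reservation follows the shift*t + frame <= duration rule", {
  expect_identical(reserved_frame_count(285, 25, 10), 27L)
  expect_identical(reserved_frame_count(25, 25, 10), 1L)
  expect_identical(reserved_frame_count(284, 25, 10), 26L)
  expect_error(reserved_frame_count(20, 25, 10), "shorter")
  # matches exhaustive enumeration of valid 0-based indices
  for (dur in seq(25, 600, by = 7)) {
    enumerated <- sum(10 * (0:100) + 25 <= dur)
    expect_identical(reserved_frame_count(dur, 25, 10), as.integer(enumerated))
  }
})

test_that("model streams hold one RDM per reserved frame at 10 ms spacing", {
  tl <- make_timeline(c(27, 30, 35), dim = 6, durations = c(285, 320, 370))
  st <- build_model_stream(tl)
  expect_length(st$rdms, 27)
  expect_equal(st$times_ms, seq(0, 260, 10))
  expect_equal(dim(st$rdms[[1]]$values), c(3, 3))
  # identical activations for two conditions at a frame give distance 0 there
  tl$frames$c2[5, ] <- tl$frames$c1[5, ]
  st2 <- build_model_stream(tl)
  expect_equal(st2$rdms[[5]]$values["c1", "c2"], 0)
  # commutes with condition reordering
  perm <- c(3, 1, 2)
  tlp <- feature_timeline(condition_set(tl$conditions$ids[perm],
                                        tl$conditions$durations_ms[perm]),
                          tl$frames[perm], "L1")
  stp <- build_model_stream(tlp)
  expect_equal(stp$rdms[[4]]$values,
               st$rdms[[4]]$values[perm, perm], ignore_attr = TRUE)
  # missing frames error names the condition
  short <- tl
  short$frames$c3 <- short$frames$c3[1:10, ]
  expect_error(build_model_stream(
    feature_timeline(tl$conditions, short$frames, "L1")), "c3")
})

test_that("input-layer selection recovers bare central features from stacked input", {
  tl <- make_timeline(c(6, 8), dim = 40, seed = 9)
  stacked <- stack_context(append_deltas(tl))
  expect_equal(ncol(stacked$frames[[1]]), 720)
  back <- fbk_stream_select(stacked)
  expect_equal(back$frames, tl$frames)
  # identity on a bare timeline
  expect_equal(fbk_stream_select(tl)$frames, tl$frames)
})
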