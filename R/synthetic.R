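#' Synthetic-world configuration
#'
#' The stated world for the synthetic generator: a desk-scale stand-in for a
#' 400-word, 16-subject source-space experiment. Defaults: 40 conditions with
#' the shortest pinned at 285 ms (so 27 frames are reserved on the
#' 25 ms / 10 ms grid), 6 subjects, 160 vertices per hemisphere on a 50 mm
#' sphere, a planted effect of size 0.8 at latency 70 ms, unit noise, and a
#' small layer inventory ending in a 26-node bottleneck.
#'
#' @param n_conditions Number of conditions (>= 3).
#' @param condition_durations_ms Durations (ms); `NULL` draws them on a 5 ms
#'   grid in \[285, 540\] with the first pinned at 285.
#' @param n_subjects Number of subjects (>= 2).
#' @param n_vertices_per_hemisphere Mesh vertices per hemisphere.
#' @param mesh_radius_mm Hemisphere sphere radius (mm).
#' @param effect_vertices Vertex ids carrying the planted effect; `NULL`
#'   selects a 20 mm patch around a seeded random left-hemisphere vertex
#'   when the epochs are generated.
#' @param planted_latency_ms Planted processing latency (ms, multiple of the
#'   10 ms step).
#' @param effect_size Signal mixing weight in \[0, 1\].
#' @param noise_sd Noise standard deviation.
#' @param layer_dims Named integer vector of layer sizes.
#' @param cluster_separation Between-centroid distance scale for planted
#'   phone clusters in the activations.
#' @param seed Integer master seed; all generator sub-streams derive from it.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_conditions = 40L,
                         condition_durations_ms = NULL,
                         n_subjects = 6L,
                         n_vertices_per_hemisphere = 160L,
                         mesh_radius_mm = 50,
                         effect_vertices = NULL,
                         planted_latency_ms = 70,
                         effect_size = 0.8,
                         noise_sd = 1,
                         layer_dims = c(L2 = 40L, L4 = 40L, L7 = 26L),
                         cluster_separation = 2,
                         seed = 1L) {
  if (n_conditions < 3L) stop("need at least 3 conditions")
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (effect_size < 0 || effect_size > 1) stop("effect_size must be in [0,1]")
  if (any(layer_dims < 1L)) stop("all layer dimensions must be >= 1")
  if (planted_latency_ms < 0) stop("planted latency must be non-negative")
  if (is.null(condition_durations_ms)) {
    condition_durations_ms <- withr::with_seed(
      derive_seed(seed, "durations"),
      c(285, sample(seq(285, 540, by = 5), n_conditions - 1L,
                    replace = TRUE)))
  }
  if (length(condition_durations_ms) != n_conditions) {
    stop("need one duration per condition")
  }
  structure(list(n_conditions = as.integer(n_conditions),
                 condition_durations_ms = condition_durations_ms,
                 n_subjects = as.integer(n_subjects),
                 n_vertices_per_hemisphere =
                   as.integer(n_vertices_per_hemisphere),
                 mesh_radius_mm = mesh_radius_mm,
                 effect_vertices = effect_vertices,
                 planted_latency_ms = planted_latency_ms,
                 effect_size = effect_size, noise_sd = noise_sd,
                 layer_dims = layer_dims,
                 cluster_separation = cluster_separation,
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_conditions <- function(config) {
  condition_set(sprintf("w%03d", seq_len(config$n_conditions)),
                config$condition_durations_ms)
}

#' Generate a phonetic segmentation for synthetic conditions
#'
#' Tiles each condition's duration with phone segments of seeded random
#' length (40-120 ms on a 5 ms grid, last segment truncated to the
#' condition's end), drawing phones from the built-in inventory.
#'
#' @param config A [synth_config].
#' @return A [segment_table].
#' @export
make_segment_table <- function(config) {
  inventory <- phone_feature_table()$phone
  withr::with_seed(derive_seed(config$seed, "segments"), {
    conds <- synth_conditions(config)
    rows <- lapply(seq_along(conds$ids), function(i) {
      dur <- conds$durations_ms[i]
      starts <- c()
      t0 <- 0
      while (t0 < dur) {
        starts <- c(starts, t0)
        t0 <- t0 + sample(seq(40, 120, by = 5), 1L)
      }
      # a truncated tail past the last frame midpoint would average over no
      # frames; merge it into the preceding segment
      n_frames <- reserved_frame_count(dur, 25, 10)
      last_mid <- 10 * (n_frames - 1L) + 12.5
      if (length(starts) > 1L && starts[length(starts)] > last_mid) {
        starts <- starts[-length(starts)]
      }
      ends <- c(starts[-1L], dur)
      data.frame(condition = conds$ids[i], start_ms = starts, end_ms = ends,
                 phone = sample(inventory, length(starts), replace = TRUE))
    })
    segment_table(do.call(rbind, rows))
  })
}

#' Generate layer activation timelines with planted phone clusters
#'
#' For each layer, every 25 ms / 10 ms frame of every condition receives an
#' activation vector drawn around a label-specific centroid: the label is the
#' scheme's label for the phone whose segment contains the frame's midpoint.
#' Centroids are unit random directions scaled by `cluster_separation`;
#' isotropic Gaussian noise with `noise_sd` is added. Draws are arranged so
#' that, at a fixed seed, changing `cluster_separation` or `noise_sd` only
#' rescales the same underlying deviates (making cluster quality monotone in
#' the separation).
#'
#' @param config A [synth_config].
#' @param segments A [segment_table] covering each condition's duration.
#' @param scheme A [label_scheme] assigning a label to every phone present
#'   (default: phone identity).
#' @return Named list of [feature_timeline]s, one per configured layer.
#' @export
make_layer_activations <- function(config, segments,
                                   scheme = default_label_schemes()$phone) {
  stopifnot(inherits(config, "synth_config"),
            inherits(segments, "segment_table"),
            inherits(scheme, "label_scheme"))
  conds <- synth_conditions(config)
  missing <- setdiff(unique(segments$phone), names(scheme$map))
  if (length(missing)) {
    stop("scheme '", scheme$name, "' has no label for phone(s): ",
         paste(missing, collapse = ", "))
  }
  # frame labels per condition (frame midpoint 10t + 12.5 within [start,end))
  frame_labels <- lapply(seq_along(conds$ids), function(i) {
    cid <- conds$ids[i]
    # all frames of the condition, not just the globally reserved ones
    n <- reserved_frame_count(conds$durations_ms[i], 25, 10)
    mids <- 10 * (seq_len(n) - 1L) + 12.5
    seg <- segments[segments$condition == cid, ]
    si <- findInterval(mids, seg$start_ms)
    if (any(si == 0L) || any(mids >= seg$end_ms[si])) {
      stop("segments do not cover condition ", cid)
    }
    unname(scheme$map[seg$phone[si]])
  })
  names(frame_labels) <- conds$ids
  labels <- sort(unique(unlist(frame_labels)))
  lapply(stats::setNames(names(config$layer_dims), names(config$layer_dims)),
         function(layer) {
    d <- config$layer_dims[[layer]]
    withr::with_seed(derive_seed(config$seed, paste0("activations-", layer)), {
      dirs <- vapply(labels, function(l) {
        u <- stats::rnorm(d)
        u / sqrt(sum(u^2))
      }, numeric(d))
      frames <- lapply(conds$ids, function(cid) {
        lab <- frame_labels[[cid]]
        noise <- matrix(stats::rnorm(length(lab) * d), length(lab), d)
        config$cluster_separation * t(dirs[, lab, drop = FALSE]) +
          config$noise_sd * noise
      })
      names(frames) <- conds$ids
      feature_timeline(conds, frames, layer)
    })
  })
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Construct per-condition signal time-courses whose overlapping window
# slices realize a sequence of target correlation matrices.
#
# The signal is partitioned into time blocks of gcd(window, step) ms; every
# window is a disjoint union of blocks, and because each block's rows are
# built with zero mean, the Gram matrix of a window is the *sum* of its
# blocks' Gram matrices. Realizing target correlations therefore reduces to
# a convex feasibility problem: find one PSD Gram per block such that each
# window's banded sum equals (window/block) times its target correlation
# matrix, up to a free multiple of the identity per window (shrinkage
# toward the identity rescales all off-diagonal correlations by one
# positive constant, so the realized dissimilarities match the target in
# rank order exactly, which is all the Spearman-based matching sees). The
# relaxed problem is solved by alternating projections between the affine
# constraint set and the PSD cone (both convex, so the iteration
# converges); each block is then realized exactly from its Gram via an
# orthonormal zero-mean row basis. The `residual` attribute reports one
# minus the worst Spearman correlation between a realized slice's
# dissimilarities and its target (rank truncation contributes when a block
# Gram has rank exceeding n_effect * block - 1).
construct_planted_signal <- function(c_list, n_effect, sig_len,
                                     starts_smp, window_smp,
                                     n_iter = 150L, seed = 1L) {
  n <- nrow(c_list[[1L]])
  n_frames <- length(c_list)
  step_smp <- if (n_frames > 1L) starts_smp[2L] - starts_smp[1L] else window_smp
  blk <- gcd2(window_smp, step_smp)
  stopifnot(sig_len %% blk == 0, all(starts_smp %% blk == 0))
  n_blocks <- sig_len %/% blk
  wb <- window_smp %/% blk              # blocks per window
  sb <- step_smp %/% blk                # block shift between windows
  d_b <- n_effect * blk                 # columns per block
  if (d_b < 2L) stop("too few effect vertices to carry a planted signal")

  a_mat <- matrix(0, n_frames, n_blocks)
  for (j in seq_len(n_frames)) a_mat[j, sb * (j - 1L) + seq_len(wb)] <- 1
  aa_inv <- solve(tcrossprod(a_mat))
  b_mat <- t(vapply(c_list, function(cc) as.vector(wb * cc), numeric(n * n)))
  diag_idx <- which(as.vector(diag(n) == 1))

  # init each block at the target of the nearest window
  nearest <- pmin(pmax(round((seq_len(n_blocks) - (wb + 1) / 2) / sb) + 1L,
                       1L), n_frames)
  x <- t(vapply(nearest, function(j) as.vector(c_list[[j]]), numeric(n * n)))
  psd_project <- function(x) {
    t(apply(x, 1L, function(row) {
      eg <- eigen(matrix(row, n, n), symmetric = TRUE)
      as.vector(eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors)))
    }))
  }
  affine_project <- function(x) {
    y <- a_mat %*% x - b_mat
    axd <- a_mat %*% x[, diag_idx, drop = FALSE]
    y[, diag_idx] <- axd - rowMeans(axd)   # diagonal: equal, level free
    x - crossprod(a_mat, aa_inv %*% y)
  }
  for (it in seq_len(n_iter)) {
    x <- affine_project(x)
    x <- psd_project(x)
  }

  # realize each block: rows = A_h %*% Q with Q orthonormal zero-mean rows
  basis <- qr.Q(qr(stats::contr.helmert(d_b)))    # d_b x (d_b - 1), span of 1-perp
  max_rank <- d_b - 1L
  m <- withr::with_seed(seed, {
    m <- matrix(0, n, n_effect * sig_len)
    for (h in seq_len(n_blocks)) {
      eg <- eigen(matrix(x[h, ], n, n), symmetric = TRUE)
      keep <- which(eg$values > 1e-12)
      keep <- keep[seq_len(min(length(keep), max_rank))]
      r <- length(keep)
      if (r == 0L) next
      a_h <- eg$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(eg$values[keep]), r)
      rot <- qr.Q(qr(matrix(stats::rnorm((d_b - 1L) * r), d_b - 1L, r)))
      q <- t(basis %*% rot)                       # r x d_b
      cols <- as.vector(outer(blk * (h - 1L) + seq_len(blk),
                              (seq_len(n_effect) - 1L) * sig_len, "+"))
      m[, cols] <- a_h %*% q
    }
    m
  })
  slice_idx <- lapply(starts_smp, function(t0) {
    as.vector(outer(t0 + seq_len(window_smp),
                    (seq_len(n_effect) - 1L) * sig_len, "+"))
  })
  ut <- upper.tri(c_list[[1L]])
  resid <- 1 - min(vapply(seq_along(slice_idx), function(j) {
    cr <- stats::cor(t(m[, slice_idx[[j]]]))
    stats::cor(rank(cr[ut]), rank(c_list[[j]][ut]))
  }, numeric(1)))
  structure(m / stats::sd(m), residual = resid)
}

#' Generate multi-subject source-space epochs with a planted effect
#'
#' Fills every (subject, condition, vertex) cell with 1 ms Gaussian noise
#' over the epoch, then injects, at the effect vertices and starting at the
#' planted latency, a shared condition-wise signal whose 25 ms window slices
#' realize the target RDM stream: the response patterns inside window
#' \[tau + latency, tau + latency + 25) match the target RDM for model time
#' tau (up to the slice-overlap residual), mixed as
#' `effect_size * signal + (1 - effect_size) * noise`. With `effect_size`
#' 0 the epochs are pure noise.
#'
#' @param config A [synth_config].
#' @param mesh A `cortical_mesh` (see [make_mesh]) (its vertex count must match the config).
#' @param target_rdm_stream Target [rdm_stream] (e.g. a model layer stream).
#' @param epoch_end_ms Epoch end (default 540 ms; epoch starts at 0).
#' @param window_ms Searchlight window the effect is built for (25 ms).
#' @param n_iter Projection iterations for the signal construction.
#' @return A [source_epochs] with attributes `effect_vertices`,
#'   `effect_center`, `planted_latency_ms`, and `signal_residual` (one
#'   minus the worst Spearman correlation between a realized slice's
#'   dissimilarities and its target; `NA` when no effect is planted).
#' @export
make_source_epochs <- function(config, mesh, target_rdm_stream,
                               epoch_end_ms = 540, window_ms = 25,
                               n_iter = 150L) {
  stopifnot(inherits(config, "synth_config"),
            inherits(mesh, "cortical_mesh"),
            inherits(target_rdm_stream, "rdm_stream"))
  step <- stream_step(target_rdm_stream)
  if (is.na(step)) step <- 10
  if (config$planted_latency_ms %% step != 0) {
    stop("planted latency (", config$planted_latency_ms,
         " ms) must be a multiple of the ", step, " ms step")
  }
  last_t <- max(target_rdm_stream$times_ms)
  if (config$planted_latency_ms + last_t + window_ms > epoch_end_ms) {
    stop("planted latency pushes the signal past the epoch end")
  }
  nv <- nrow(mesh$coords)
  n <- length(target_rdm_stream$conditions)
  stopifnot(n == config$n_conditions)

  effect <- config$effect_vertices
  center <- NA_integer_
  if (is.null(effect)) {
    center <- withr::with_seed(derive_seed(config$seed, "effect-center"), {
      sample(which(mesh$hemisphere == "L"), 1L)
    })
    effect <- patch_vertices(mesh, center, 20)
  }
  effect <- sort(as.integer(effect))
  if (any(effect < 1L | effect > nv)) {
    stop("effect vertices must be valid mesh vertex ids")
  }

  sig_len <- as.integer(last_t + window_ms)  # signal spans [0, sig_len) ms
  n_time <- as.integer(epoch_end_ms) + 1L
  t_idx <- as.integer(config$planted_latency_ms) + seq_len(sig_len)
  residual <- NA_real_
  if (config$effect_size > 0) {
    c_list <- lapply(target_rdm_stream$rdms, function(r) 1 - r$values)
    signal <- construct_planted_signal(
      c_list, length(effect), sig_len,
      starts_smp = as.integer(target_rdm_stream$times_ms),
      window_smp = as.integer(window_ms), n_iter = n_iter,
      seed = derive_seed(config$seed, "signal"))
    residual <- attr(signal, "residual")
    sig_arr <- array(signal, dim = c(n, sig_len, length(effect)))
    sig_arr <- aperm(sig_arr, c(1L, 3L, 2L))   # condition x vertex x time
  }

  subjects <- sprintf("s%02d", seq_len(config$n_subjects))
  data <- lapply(stats::setNames(subjects, subjects), function(subj) {
    withr::with_seed(derive_seed(config$seed, paste0("epochs-", subj)), {
      arr <- array(config$noise_sd * stats::rnorm(n * nv * n_time),
                   dim = c(n, nv, n_time))
      if (config$effect_size > 0) {
        arr[, effect, t_idx] <- config$effect_size * sig_arr +
          (1 - config$effect_size) * arr[, effect, t_idx, drop = FALSE]
      }
      arr
    })
  })
  ep <- source_epochs(data, synth_conditions(config),
                      times_ms = 0:as.integer(epoch_end_ms))
  attr(ep, "effect_vertices") <- effect
  attr(ep, "effect_center") <- center
  attr(ep, "planted_latency_ms") <- config$planted_latency_ms
  attr(ep, "signal_residual") <- residual
  ep
}

#' Write / read a segment table as TSV
#'
#' @param segments A [segment_table].
#' @param path File path.
#' @return `write_segments_tsv` returns `path` invisibly;
#'   `read_segments_tsv` a [segment_table].
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(as.data.frame(segments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
read_segments_tsv <- function(path) {
  segment_table(utils::read.delim(path, stringsAsFactors = FALSE))
}
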