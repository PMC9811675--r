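#' Model-brain fit at a fixed processing latency
#'
#' Cortical responses lag the stimulus, so the model RDM for stimulus time
#' tau is matched against the brain RDM at epoch time tau + k for a
#' hypothesized processing latency k. The fit at latency k is the mean over
#' all alignable model times of the Spearman rank correlation between the
#' model and brain RDMs; pairing truncates at stream ends (only fully valid
#' (tau, tau+k) pairs contribute).
#'
#' @param model,brain [rdm_stream] objects sharing a condition set and step.
#' @param latency_ms Latency k (ms) on the shared step grid.
#' @return Mean Spearman rho.
#' @export
latency_rho <- function(model, brain, latency_ms) {
  stopifnot(inherits(model, "rdm_stream"), inherits(brain, "rdm_stream"))
  want <- model$times_ms + latency_ms
  hit <- match(want, brain$times_ms)
  ok <- which(!is.na(hit))
  if (length(ok) == 0L) {
    stop("no alignable window pairs at latency ", latency_ms, " ms")
  }
  mean(vapply(ok, function(i) {
    spearman_rdm(model$rdms[[i]], brain$rdms[[hit[i]]])
  }, numeric(1)))
}

new_rho_map <- function(values, latencies, subject = NA_character_,
                        layer = NA_character_) {
  structure(list(values = values, latencies_ms = latencies,
                 subject = subject, layer = layer),
            class = "rho_map")
}

#' @export
print.rho_map <- function(x, ...) {
  cat("<rho_map> ", nrow(x$values), " vertices x ", ncol(x$values),
      " latencies", if (!is.na(x$subject)) paste0(", subject ", x$subject),
      "\n", sep = "")
  invisible(x)
}

#' Latency map of model fit across vertices
#'
#' One Spearman rho per (vertex, latency): each vertex's searchlight RDM
#' stream is matched to the model stream at every latency of the grid
#' (default 0-250 ms in 10 ms steps).
#'
#' @param model Model [rdm_stream].
#' @param brain_streams List of per-vertex [rdm_stream]s (one subject).
#' @param latencies_ms Latency grid (ms).
#' @param subject,layer Optional labels carried into the result.
#' @return A `rho_map`: vertices x latencies matrix plus grid metadata.
#' @export
rho_map <- function(model, brain_streams, latencies_ms = seq(0, 250, 10),
                    subject = NA_character_, layer = NA_character_) {
  values <- t(vapply(brain_streams, function(b) {
    vapply(latencies_ms, function(k) latency_rho(model, b, k), numeric(1))
  }, numeric(length(latencies_ms))))
  if (length(latencies_ms) == 1L) values <- matrix(values, ncol = 1L)
  new_rho_map(values, latencies_ms, subject, layer)
}

# rank-transform columns (average ties) and scale each to zero mean / unit
# norm, so that crossprod of two such matrices is the Spearman correlation
# of the columns
rank_standardize <- function(m, what = "RDM") {
  r <- col_rank_standardize_cpp(as.matrix(m))
  if (anyNA(r)) {
    stop("constant ", what, " vector: Spearman correlation undefined")
  }
  r
}

#' Per-subject latency maps for a whole mesh
#'
#' Computes, for every subject and every mesh vertex, the searchlight RDM
#' stream and its latency-wise Spearman match to the model stream. This is
#' the vectorized equivalent of [brain_rdm_stream] + [rho_map] over all
#' vertices and subjects: per vertex it rank-transforms the model and brain
#' RDM vectors once and obtains all (model frame, window) Spearman
#' correlations in a single cross-product.
#'
#' @param model Model [rdm_stream].
#' @param epochs A [source_epochs].
#' @param mesh A `cortical_mesh` (see [make_mesh]).
#' @param config A [searchlight_config].
#' @param latencies_ms Latency grid (ms).
#' @param layer Optional layer label.
#' @return Named list (per subject) of `rho_map` objects.
#' @export
searchlight_rho_maps <- function(model, epochs, mesh,
                                 config = searchlight_config(),
                                 latencies_ms = seq(0, 250, 10),
                                 layer = NA_character_) {
  stopifnot(inherits(model, "rdm_stream"), inherits(epochs, "source_epochs"))
  if (!identical(model$conditions, epochs$conditions$ids)) {
    stop("model stream and epochs must share the condition set")
  }
  starts <- window_starts(config$epoch_ms, config$window_ms, config$step_ms)
  step <- config$step_ms
  if (any(latencies_ms %% step != 0)) {
    stop("latencies must lie on the ", step, " ms window grid")
  }
  mt <- model$times_ms
  # model ranks: p x n_frames, standardized columns
  mv <- vapply(model$rdms, vectorize_upper,
               numeric(length(vectorize_upper(model$rdms[[1L]]))))
  mr <- rank_standardize(mv, "model RDM")
  n_frames <- ncol(mr)
  nv <- nrow(mesh$coords)
  patches <- lapply(seq_len(nv), function(v) {
    patch_vertices(mesh, v, config$radius_mm)
  })
  sample_idx <- lapply(starts, function(t0) {
    window_sample_idx(epochs, t0, config$window_ms)
  })
  # latency k pairs model frame tau with the window starting at tau + k
  pair_cols <- lapply(latencies_ms, function(k) match(mt + k, starts))
  starts0 <- vapply(sample_idx, function(si) si[1L] - 1L, integer(1))
  d <- dim(epochs$data[[1L]])
  lapply(names(epochs$data), function(subj) {
    arr <- epochs$data[[subj]]
    values <- matrix(NA_real_, nv, length(latencies_ms))
    for (v in seq_len(nv)) {
      bv <- window_rdm_cpp(arr, d[1L], d[2L], d[3L], patches[[v]],
                           starts0, as.integer(config$window_ms))
      if (anyNA(bv)) {
        stop("zero-variance response (subject ", subj, ", vertex ", v, ")")
      }
      br <- rank_standardize(bv, "brain RDM")
      s <- crossprod(mr, br)          # n_frames x n_windows Spearman matrix
      values[v, ] <- vapply(seq_along(pair_cols), function(ki) {
        cols <- pair_cols[[ki]]
        ok <- which(!is.na(cols))
        if (length(ok) == 0L) {
          stop("no alignable window pairs at latency ",
               latencies_ms[ki], " ms")
        }
        mean(s[cbind(ok, cols[ok])])
      }, numeric(1))
    }
    new_rho_map(values, latencies_ms, subject = subj, layer = layer)
  }) |> stats::setNames(names(epochs$data))
}

#' Group t-map across subjects
#'
#' One-sample t statistic of the per-subject rho values at every
#' (vertex, latency) cell: mean / (sd / sqrt(n)), sd with the n-1
#' denominator. Cells where all subjects agree exactly (zero variance) get a
#' sentinel t of +/-100 with the sign of the mean (0 if the mean is 0 too)
#' and are flagged in the `zero_variance` attribute; the sentinel keeps the
#' TFCE threshold loop bounded and never occurs with continuous noise.
#'
#' @param rho_maps List of per-subject `rho_map`s on identical grids.
#' @return A `t_map`: vertices x latencies matrix with `n_subjects` field.
#' @export
group_tmap <- function(rho_maps) {
  if (length(rho_maps) < 2L) stop("group t-map needs at least 2 subjects")
  lat <- rho_maps[[1L]]$latencies_ms
  for (m in rho_maps) {
    if (!identical(m$latencies_ms, lat) ||
        !identical(dim(m$values), dim(rho_maps[[1L]]$values))) {
      stop("rho maps must share an identical (vertex, latency) grid")
    }
  }
  flat <- vapply(rho_maps, function(m) as.vector(m$values),
                 numeric(length(rho_maps[[1L]]$values)))
  n <- length(rho_maps)
  mu <- rowMeans(flat)
  va <- rowSums((flat - mu)^2) / (n - 1)
  tt <- mu / sqrt(va / n)
  zv <- va == 0
  tt[zv] <- sign(mu[zv]) * 100
  values <- matrix(tt, nrow(rho_maps[[1L]]$values))
  structure(list(values = values, latencies_ms = lat, n_subjects = n,
                 layer = rho_maps[[1L]]$layer),
            class = "t_map",
            zero_variance = matrix(zv, nrow(values)))
}

#' @export
print.t_map <- function(x, ...) {
  cat("<t_map> ", nrow(x$values), " vertices x ", ncol(x$values),
      " latencies, n = ", x$n_subjects, " subjects\n", sep = "")
  invisible(x)
}

#' Fixed-effects latency map from subject-averaged RDMs
#'
#' Alternative mode: average the per-subject searchlight RDMs entrywise
#' before comparing to the model, yielding a single map with no group
#' inference. Provided for comparability; the per-subject maps of
#' [searchlight_rho_maps] feed the randomization inference and are the
#' default pathway.
#'
#' @inheritParams searchlight_rho_maps
#' @return A single `rho_map` (subject `"group-average"`).
#' @export
averaged_rho_map <- function(model, epochs, mesh,
                             config = searchlight_config(),
                             latencies_ms = seq(0, 250, 10),
                             layer = NA_character_) {
  nv <- nrow(mesh$coords)
  starts <- window_starts(config$epoch_ms, config$window_ms, config$step_ms)
  streams <- lapply(seq_len(nv), function(v) {
    per_subj <- lapply(names(epochs$data), function(s) {
      brain_rdm_stream(epochs, mesh, config, v, s)
    })
    rdm_stream(starts, lapply(seq_along(starts), function(w) {
      average_rdms(lapply(per_subj, function(st) st$rdms[[w]]))
    }))
  })
  rho_map(model, streams, latencies_ms, subject = "group-average",
          layer = layer)
}
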