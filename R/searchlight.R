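#' Searchlight configuration
#'
#' The spatiotemporal searchlight geometry: a spatial patch of fixed radius
#' moved to center on every mesh vertex, and a fixed-width temporal window
#' slid through the epoch in fixed steps. Defaults follow the standard
#' source-space analysis: 20 mm patch, 25 ms window (matching the acoustic
#' frame duration), 10 ms step, epoch \[0, 540\] ms at 1 ms resolution.
#'
#' @param radius_mm Patch radius (mm).
#' @param window_ms Sliding window duration (ms).
#' @param step_ms Window step (ms).
#' @param epoch_ms Length-2 numeric, epoch start and end (ms).
#' @return An object of class `searchlight_config`.
#' @export
searchlight_config <- function(radius_mm = 20, window_ms = 25, step_ms = 10,
                               epoch_ms = c(0, 540)) {
  stopifnot(radius_mm >= 0, window_ms > 0, step_ms > 0,
            length(epoch_ms) == 2L, diff(epoch_ms) >= window_ms)
  structure(list(radius_mm = radius_mm, window_ms = window_ms,
                 step_ms = step_ms, epoch_ms = epoch_ms),
            class = "searchlight_config")
}

#' Sliding-window start times
#'
#' Start times t = 0, step, 2*step, ... such that the whole window
#' \[t, t+window) fits inside the epoch. The default epoch \[0, 540\] ms with
#' a 25 ms window and 10 ms step yields the 52 starts 0, 10, ..., 510.
#'
#' @param epoch_ms Length-2 numeric, epoch start and end (ms).
#' @param window_ms,step_ms Window duration and step (ms).
#' @return Numeric vector of start times.
#' @export
window_starts <- function(epoch_ms, window_ms = 25, step_ms = 10) {
  stopifnot(length(epoch_ms) == 2L)
  if (diff(epoch_ms) < window_ms) stop("epoch shorter than one window")
  seq(epoch_ms[1L], epoch_ms[2L] - window_ms, by = step_ms)
}

#' Source-space epoch container
#'
#' Rectangular source estimates: for every subject, condition and mesh
#' vertex, a 1 ms-resolution time series over the epoch. Stored as one
#' conditions x vertices x samples array per subject.
#'
#' @param data Named list (one per subject) of 3-d arrays
#'   \[condition, vertex, sample\].
#' @param conditions A [condition_set].
#' @param times_ms Sample times (ms), 1 ms apart, starting at the epoch start.
#' @return An object of class `source_epochs`.
#' @export
source_epochs <- function(data, conditions, times_ms) {
  stopifnot(is.list(data), length(data) >= 1L, !is.null(names(data)),
            inherits(conditions, "condition_set"))
  dims <- dim(data[[1L]])
  for (a in data) {
    if (!identical(dim(a), dims)) stop("epochs must be rectangular")
    if (anyNA(a)) stop("epochs must be finite")
  }
  if (dims[1L] != length(conditions$ids)) {
    stop("first array dimension must index conditions")
  }
  if (dims[3L] != length(times_ms)) {
    stop("third array dimension must index samples")
  }
  structure(list(data = data, conditions = conditions,
                 times_ms = as.numeric(times_ms)),
            class = "source_epochs")
}

#' @export
print.source_epochs <- function(x, ...) {
  d <- dim(x$data[[1L]])
  cat("<source_epochs> ", length(x$data), " subjects x ", d[1L],
      " conditions x ", d[2L], " vertices x ", d[3L], " samples\n", sep = "")
  invisible(x)
}

# sample indices (into the epoch array) for a window starting at t
window_sample_idx <- function(epochs, start_ms, window_ms) {
  idx <- which(epochs$times_ms >= start_ms &
                 epochs$times_ms < start_ms + window_ms)
  if (length(idx) != window_ms) {
    stop("window [", start_ms, ", ", start_ms + window_ms,
         ") not fully covered by 1 ms samples")
  }
  idx
}

# condition x (vertex, sample) response matrix for one subject/patch/window;
# samples are nested within vertices, vertices in ascending id order
patch_response <- function(arr, patch, sample_idx) {
  sub <- arr[, patch, sample_idx, drop = FALSE]
  sub <- aperm(sub, c(1L, 3L, 2L))
  dim(sub) <- c(dim(sub)[1L], length(sample_idx) * length(patch))
  sub
}

#' Searchlight RDM stream at one vertex
#'
#' For every window start, concatenates the source values of all patch
#' vertices over the window's 1 ms samples into one response vector per
#' condition, and computes a correlation-distance RDM. The stream is indexed
#' by window start times.
#'
#' @param epochs A [source_epochs].
#' @param mesh A `cortical_mesh` (see [make_mesh]).
#' @param config A [searchlight_config].
#' @param center Center vertex id.
#' @param subject Subject name (must match `names(epochs$data)`).
#' @return An [rdm_stream], one frame per window start.
#' @export
brain_rdm_stream <- function(epochs, mesh, config, center, subject) {
  stopifnot(inherits(epochs, "source_epochs"),
            inherits(config, "searchlight_config"))
  if (!subject %in% names(epochs$data)) stop("unknown subject: ", subject)
  patch <- patch_vertices(mesh, center, config$radius_mm)
  starts <- window_starts(config$epoch_ms, config$window_ms, config$step_ms)
  arr <- epochs$data[[subject]]
  rdms <- lapply(starts, function(t0) {
    resp <- patch_response(arr, patch,
                           window_sample_idx(epochs, t0, config$window_ms))
    rownames(resp) <- epochs$conditions$ids
    tryCatch(correlation_distance_rdm(resp), error = function(e) {
      stop("subject ", subject, ", vertex ", center, ", window [", t0, ", ",
           t0 + config$window_ms, ") ms: ", conditionMessage(e))
    })
  })
  rdm_stream(starts, rdms)
}
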