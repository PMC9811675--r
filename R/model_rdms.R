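#' Per-layer activation timelines
#'
#' A feature timeline holds, for one named layer, each condition's ordered
#' sequence of per-frame activation vectors. Frames follow the standard
#' speech-analysis grid: 25 ms windows advanced in 10 ms steps, so frame t
#' (0-based) covers \[10t, 10t+25) ms of the condition.
#'
#' @param conditions A [condition_set].
#' @param frames Named list (one entry per condition id) of numeric matrices,
#'   frames x nodes; all matrices must share the node dimension.
#' @param layer_name Layer label, e.g. `"L7"` or `"FBK"`.
#' @param frame_ms,shift_ms Frame duration and shift in ms.
#' @param base_dim Dimension of the underlying base features (defaults to the
#'   node dimension); tracked so delta-augmented and context-stacked
#'   timelines can recover the bare central features.
#' @param has_deltas,context Bookkeeping set by [append_deltas] and
#'   [stack_context].
#' @return An object of class `feature_timeline`.
#' @export
feature_timeline <- function(conditions, frames, layer_name,
                             frame_ms = 25, shift_ms = 10,
                             base_dim = NULL, has_deltas = FALSE,
                             context = 0L) {
  stopifnot(inherits(conditions, "condition_set"))
  if (!setequal(names(frames), conditions$ids)) {
    stop("frames must be named by the condition ids")
  }
  frames <- frames[conditions$ids]
  dims <- vapply(frames, ncol, integer(1))
  if (length(unique(dims)) != 1L) {
    stop("all conditions must share one activation dimension")
  }
  if (is.null(base_dim)) base_dim <- dims[[1L]]
  structure(list(conditions = conditions, frames = frames,
                 layer_name = layer_name, frame_ms = frame_ms,
                 shift_ms = shift_ms, base_dim = as.integer(base_dim),
                 has_deltas = has_deltas, context = as.integer(context)),
            class = "feature_timeline")
}

#' @export
print.feature_timeline <- function(x, ...) {
  cat("<feature_timeline> layer ", x$layer_name, ": ",
      length(x$frames), " conditions, dim ", ncol(x$frames[[1L]]),
      if (x$has_deltas) " (+deltas)" else "",
      if (x$context > 0L) sprintf(" (context %d)", x$context) else "",
      "\n", sep = "")
  invisible(x)
}

#' Append first-order delta features
#'
#' Augments every frame vector with its first-order time derivative,
#' estimated by the central difference (o\[t+1\] - o\[t-1\]) / 2 with boundary
#' neighbours duplicated, doubling the dimension (40 -> 80 for filterbank
#' features). The +/-1-frame support is what extends a 9-frame stacked input
#' from 105 ms to the 125 ms receptive field.
#'
#' @param timeline A [feature_timeline] without deltas.
#' @return A [feature_timeline] of doubled dimension.
#' @export
append_deltas <- function(timeline) {
  stopifnot(inherits(timeline, "feature_timeline"))
  if (timeline$has_deltas) stop("timeline already carries delta features")
  frames <- lapply(names(timeline$frames), function(cid) {
    x <- timeline$frames[[cid]]
    n <- nrow(x)
    if (n < 2L) stop("condition ", cid, " has a single frame; ",
                     "delta features need at least 2")
    nxt <- x[c(2:n, n), , drop = FALSE]      # duplicate last frame
    prv <- x[c(1L, 1:(n - 1L)), , drop = FALSE]  # duplicate first frame
    cbind(x, (nxt - prv) / 2)
  })
  names(frames) <- names(timeline$frames)
  feature_timeline(timeline$conditions, frames, timeline$layer_name,
                   timeline$frame_ms, timeline$shift_ms,
                   base_dim = timeline$base_dim, has_deltas = TRUE,
                   context = timeline$context)
}

#' Stack a symmetric context window of frames
#'
#' Builds the network input representation: frame t's vector becomes the
#' concatenation of frames t-c ... t+c (default c = 4, nine frames), with
#' out-of-range indices clamped to the nearest valid frame (boundary
#' duplication). 80-dim delta-augmented frames yield 720-dim stacked inputs.
#'
#' @param timeline A [feature_timeline].
#' @param context Frames of context on each side (default 4).
#' @return A [feature_timeline] whose dimension is (2*context+1) times the
#'   input dimension.
#' @export
stack_context <- function(timeline, context = 4L) {
  stopifnot(inherits(timeline, "feature_timeline"), context >= 0L)
  if (timeline$context > 0L) stop("timeline is already context-stacked")
  span <- seq.int(-context, context)
  frames <- lapply(timeline$frames, function(x) {
    n <- nrow(x)
    do.call(cbind, lapply(span, function(off) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      x[idx, , drop = FALSE]
    }))
  })
  feature_timeline(timeline$conditions, frames, timeline$layer_name,
                   timeline$frame_ms, timeline$shift_ms,
                   base_dim = timeline$base_dim,
                   has_deltas = timeline$has_deltas,
                   context = as.integer(context))
}

#' Number of frames usable for every condition
#'
#' Model RDM frames exist only where every condition still has activations,
#' so frames are reserved up to the shortest condition: the 0-based frame
#' indices t satisfying shift*t + frame <= shortest duration. With the
#' standard 25 ms / 10 ms grid and a 285 ms shortest word this yields 27.
#'
#' @param shortest_duration_ms Duration of the shortest condition (ms).
#' @param frame_ms,shift_ms Frame duration and shift (ms).
#' @return Integer frame count.
#' @export
reserved_frame_count <- function(shortest_duration_ms, frame_ms = 25,
                                 shift_ms = 10) {
  if (shortest_duration_ms < frame_ms) {
    stop("shortest condition (", shortest_duration_ms,
         " ms) is shorter than one frame (", frame_ms, " ms)")
  }
  as.integer(floor((shortest_duration_ms - frame_ms) / shift_ms)) + 1L
}

#' Build a dynamic model RDM stream from a layer timeline
#'
#' For each reserved frame index t, gathers every condition's frame-t
#' activation vector and computes a correlation-distance RDM; the stream is
#' indexed by window start times 10*t ms.
#'
#' @param timeline A [feature_timeline].
#' @return An [rdm_stream] with one frame per reserved index.
#' @export
build_model_stream <- function(timeline) {
  stopifnot(inherits(timeline, "feature_timeline"))
  conds <- timeline$conditions
  n_frames <- reserved_frame_count(min(conds$durations_ms),
                                   timeline$frame_ms, timeline$shift_ms)
  short <- vapply(timeline$frames, nrow, integer(1)) < n_frames
  if (any(short)) {
    stop("condition(s) missing reserved frames: ",
         paste(names(timeline$frames)[short], collapse = ", "))
  }
  rdms <- lapply(seq_len(n_frames), function(t1) {
    m <- do.call(rbind, lapply(timeline$frames, function(x) x[t1, ]))
    rownames(m) <- conds$ids
    correlation_distance_rdm(m)
  })
  rdm_stream(timeline$shift_ms * (seq_len(n_frames) - 1L), rdms)
}

#' Temporal span of the stacked network input
#'
#' A stacked input frame concatenates 2*context+1 consecutive frames, and
#' delta features extend the support by `delta_support` frames on each side;
#' the audio span covered is therefore
#' (2*(context+delta_support))*shift + frame ms — 125 ms for the standard
#' 9-frame stack of delta-augmented 25 ms / 10 ms features.
#'
#' @param context Context frames per side (default 4).
#' @param delta_support Extra frames per side used by the delta features.
#' @param frame_ms,shift_ms Frame duration and shift (ms).
#' @return Receptive field in ms.
#' @export
input_receptive_field_ms <- function(context = 4, delta_support = 1,
                                     frame_ms = 25, shift_ms = 10) {
  2 * (context + delta_support) * shift_ms + frame_ms
}

#' Recover the bare central filterbank features
#'
#' Input-layer ("FBK") RDMs are built from the 40 base filterbank values of
#' the central 25 ms window only — no delta features, no overlapping context
#' windows. Given a delta-augmented and/or context-stacked timeline this
#' extracts the central frame's base block; a bare timeline passes through
#' unchanged.
#'
#' @param timeline A [feature_timeline].
#' @return A [feature_timeline] of the base dimension.
#' @export
fbk_stream_select <- function(timeline) {
  stopifnot(inherits(timeline, "feature_timeline"))
  bd <- timeline$base_dim
  block <- bd * (1L + timeline$has_deltas)           # per-frame dim pre-stack
  offset <- timeline$context * block                 # central frame's block
  cols <- seq.int(offset + 1L, offset + bd)
  frames <- lapply(timeline$frames, function(x) x[, cols, drop = FALSE])
  feature_timeline(timeline$conditions, frames, timeline$layer_name,
                   timeline$frame_ms, timeline$shift_ms,
                   base_dim = bd, has_deltas = FALSE, context = 0L)
}
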