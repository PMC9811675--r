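#' Condition sets
#'
#' A condition set names the experimental conditions (e.g. the spoken words
#' of a stimulus list) shared by every RDM in an analysis, together with each
#' condition's duration in milliseconds. Durations drive the frame-reservation
#' rule for dynamic model RDM streams: only frames present for *every*
#' condition can enter a stream, so the shortest duration is the binding one.
#'
#' @param ids Character vector of unique condition identifiers.
#' @param durations_ms Positive numeric vector of durations (ms), one per
#'   condition.
#' @return An object of class `condition_set`.
#' @export
condition_set <- function(ids, durations_ms) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("condition ids must be unique")
  if (length(durations_ms) != length(ids)) {
    stop("durations_ms must have one entry per condition")
  }
  if (any(!is.finite(durations_ms)) || any(durations_ms <= 0)) {
    stop("durations_ms must be positive and finite")
  }
  structure(list(ids = ids, durations_ms = as.numeric(durations_ms)),
            class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat("<condition_set> ", length(x$ids), " conditions, durations ",
      min(x$durations_ms), "-", max(x$durations_ms), " ms\n", sep = "")
  invisible(x)
}

new_rdm <- function(values, conditions) {
  structure(list(values = values, conditions = as.character(conditions)),
            class = "rdm")
}

#' Representational dissimilarity matrices
#'
#' An RDM is a square symmetric matrix of pairwise dissimilarities between
#' conditions; here the dissimilarity is always Pearson's correlation
#' distance, 1 - r, so entries lie in \[0, 2\] with an exactly zero diagonal.
#'
#' @param values Square numeric matrix of dissimilarities.
#' @param conditions Character vector of condition ids (row/column order).
#' @return An object of class `rdm`.
#' @export
rdm <- function(values, conditions = rownames(values)) {
  if (is.null(conditions)) conditions <- as.character(seq_len(nrow(values)))
  validate_rdm(new_rdm(as.matrix(values), conditions))
}

validate_rdm <- function(x, tol = 1e-8) {
  v <- x$values
  if (nrow(v) != ncol(v)) stop("RDM must be square")
  if (length(x$conditions) != nrow(v)) stop("condition ids must match RDM size")
  if (any(!is.finite(v))) stop("RDM entries must be finite")
  if (max(abs(v - t(v))) > tol) stop("RDM must be symmetric")
  if (any(abs(diag(v)) > tol)) stop("RDM diagonal must be zero")
  if (min(v) < -tol || max(v) > 2 + tol) stop("RDM entries must lie in [0, 2]")
  # snap to exact invariants so downstream code can rely on them
  v <- (v + t(v)) / 2
  diag(v) <- 0
  x$values <- pmin(pmax(v, 0), 2)
  x
}

#' @export
print.rdm <- function(x, ...) {
  cat("<rdm> ", nrow(x$values), "x", ncol(x$values),
      " correlation-distance matrix\n", sep = "")
  invisible(x)
}

#' @export
dim.rdm <- function(x) dim(x$values)

#' Compute a correlation-distance RDM from a response matrix
#'
#' Each row of `responses` is one condition's response pattern (activation
#' vector, searchlight pattern, ...). The RDM entry for conditions i and j is
#' 1 minus the Pearson correlation of rows i and j.
#'
#' @param responses Numeric matrix, conditions x features. Row names (if any)
#'   become condition ids.
#' @return An [rdm].
#' @export
correlation_distance_rdm <- function(responses) {
  responses <- as.matrix(responses)
  if (nrow(responses) < 2L) stop("need at least 2 conditions")
  if (ncol(responses) < 2L) stop("need at least 2 features")
  if (any(!is.finite(responses))) stop("responses must be finite")
  sds <- apply(responses, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(responses)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance response for condition(s): ",
         paste(bad, collapse = ", "),
         " (correlation distance undefined)")
  }
  v <- 1 - stats::cor(t(responses))
  ids <- rownames(responses)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(responses)))
  rdm(v, ids)
}

# row-major upper triangle of a plain square matrix (internal fast path)
ut_rowmajor <- function(m) t(m)[lower.tri(m)]

#' Vectorize the upper triangle of an RDM
#'
#' Returns the above-diagonal entries in a fixed, documented order: row-major
#' over the upper triangle, i.e. (1,2), (1,3), ..., (1,n), (2,3), ...,
#' (n-1,n). [rdm_from_vector] inverts it.
#'
#' @param x An [rdm].
#' @return Numeric vector of length n(n-1)/2.
#' @export
vectorize_upper <- function(x) {
  stopifnot(inherits(x, "rdm"))
  t(x$values)[lower.tri(x$values)]
}

#' Rebuild an RDM from its vectorized upper triangle
#'
#' @param v Numeric vector as produced by [vectorize_upper].
#' @param conditions Condition ids; its length determines the matrix size.
#' @return An [rdm].
#' @export
rdm_from_vector <- function(v, conditions) {
  n <- length(conditions)
  if (length(v) != n * (n - 1) / 2) stop("vector length must be n(n-1)/2")
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v       # row-major upper triangle = column-major lower
  m <- t(m)
  m <- m + t(m)
  rdm(m, conditions)
}

#' Spearman rank correlation between two RDMs
#'
#' The standard RSA model-fit statistic: Spearman's rho between the two
#' vectorized upper triangles, with average-rank (mid-rank) tie handling.
#' Being rank-based it is invariant under any strictly increasing transform
#' of either RDM's entries.
#'
#' @param a,b [rdm] objects over the same condition set.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rdm <- function(a, b) {
  stopifnot(inherits(a, "rdm"), inherits(b, "rdm"))
  if (!identical(a$conditions, b$conditions)) {
    stop("RDMs must share the same condition set")
  }
  va <- vectorize_upper(a)
  vb <- vectorize_upper(b)
  if (length(unique(va)) < 2L || length(unique(vb)) < 2L) {
    stop("Spearman correlation undefined for a constant RDM")
  }
  stats::cor(rank(va), rank(vb))
}

#' Average a list of RDMs entrywise
#'
#' Used e.g. to average per-subject searchlight RDMs into a group RDM.
#'
#' @param rdms Non-empty list of [rdm] objects over one condition set.
#' @return The entrywise mean [rdm].
#' @export
average_rdms <- function(rdms) {
  if (length(rdms) == 0L) stop("cannot average an empty list of RDMs")
  stopifnot(all(vapply(rdms, inherits, logical(1), "rdm")))
  conds <- rdms[[1L]]$conditions
  for (r in rdms) {
    if (!identical(r$conditions, conds)) stop("RDMs must share conditions")
  }
  m <- Reduce(`+`, lapply(rdms, `[[`, "values")) / length(rdms)
  rdm(m, conds)
}

#' Time-indexed RDM streams
#'
#' A dynamic RDM timeline: one RDM per time point on a uniform grid, all
#' sharing one condition set. Model streams index stimulus time; searchlight
#' data streams index epoch time (window starts).
#'
#' @param times_ms Strictly increasing numeric vector on a uniform step.
#' @param rdms List of [rdm] objects, one per time.
#' @return An object of class `rdm_stream`.
#' @export
rdm_stream <- function(times_ms, rdms) {
  if (length(times_ms) != length(rdms)) stop("one RDM per time point required")
  if (length(times_ms) > 1L) {
    steps <- diff(times_ms)
    if (any(steps <= 0)) stop("times must be strictly increasing")
    if (max(abs(steps - steps[1L])) > 1e-9) stop("time step must be uniform")
  }
  stopifnot(all(vapply(rdms, inherits, logical(1), "rdm")))
  conds <- rdms[[1L]]$conditions
  for (r in rdms) {
    if (!identical(r$conditions, conds)) {
      stop("all frames of a stream must share one condition set")
    }
  }
  structure(list(times_ms = as.numeric(times_ms), rdms = rdms,
                 conditions = conds),
            class = "rdm_stream")
}

#' @export
print.rdm_stream <- function(x, ...) {
  cat("<rdm_stream> ", length(x$times_ms), " frames, ",
      length(x$conditions), " conditions, t = ",
      min(x$times_ms), "..", max(x$times_ms), " ms\n", sep = "")
  invisible(x)
}

stream_step <- function(x) {
  if (length(x$times_ms) < 2L) return(NA_real_)
  x$times_ms[2L] - x$times_ms[1L]
}

#' Write / read an RDM as TSV
#'
#' Plain-text serialization for small RDMs: a condition-by-condition matrix
#' with ids as row and column names.
#'
#' @param x An [rdm].
#' @param path File path.
#' @return `write_rdm_tsv` returns `path` invisibly; `read_rdm_tsv` an [rdm].
#' @export
write_rdm_tsv <- function(x, path) {
  stopifnot(inherits(x, "rdm"))
  m <- x$values
  dimnames(m) <- list(x$conditions, x$conditions)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_rdm_tsv
#' @export
read_rdm_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
  rdm(m, rownames(m))
}
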