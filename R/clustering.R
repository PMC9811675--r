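#' Phonetic segment tables
#'
#' A segmentation of each condition into labelled phone segments: rows of
#' (condition id, start_ms, end_ms, phone). Within a condition segments must
#' be ordered and non-overlapping.
#'
#' @param df Data frame with columns `condition`, `start_ms`, `end_ms`,
#'   `phone`.
#' @return A `segment_table` (validated data frame).
#' @export
segment_table <- function(df) {
  need <- c("condition", "start_ms", "end_ms", "phone")
  if (!all(need %in% names(df))) {
    stop("segment table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$end_ms <= df$start_ms)) stop("segment end must exceed start")
  for (cid in unique(df$condition)) {
    seg <- df[df$condition == cid, ]
    if (is.unsorted(seg$start_ms, strictly = TRUE) ||
        any(seg$start_ms[-1L] < seg$end_ms[-nrow(seg)])) {
      stop("segments overlap or are unordered in condition ", cid)
    }
  }
  structure(as.data.frame(df), class = c("segment_table", "data.frame"))
}

#' Phone labelling schemes
#'
#' A labelling scheme maps phones to cluster labels. Five schemes are used:
#' the phone identity itself, articulatory place and manner (defined for
#' obstruents only), and vowel frontness and closeness (defined for syllabic
#' vowels only). Phones outside a scheme's domain are simply absent from its
#' map and are filtered out before clustering.
#'
#' @param name Scheme name.
#' @param map Named character vector: phone -> label.
#' @return A `label_scheme`.
#' @export
label_scheme <- function(name, map) {
  stopifnot(is.character(map), !is.null(names(map)), !anyNA(map))
  if (anyDuplicated(names(map))) stop("each phone must have exactly one label")
  structure(list(name = name, map = map), class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme> ", x$name, ": ", length(x$map), " phones -> ",
      length(unique(x$map)), " labels\n", sep = "")
  invisible(x)
}

#' Built-in phone inventory and labelling schemes
#'
#' A compact synthetic stand-in for a phone-to-feature assignment table
#' (the full table used with real stimuli depends on the lexicon): 29
#' ARPAbet-style phones with place and manner features for obstruents and
#' frontness and closeness features for vowels. Also shipped as
#' `inst/extdata/phone_features_synthetic.tsv`.
#'
#' @return Named list of five [label_scheme]s: `phone`, `place`, `manner`,
#'   `frontness`, `closeness`.
#' @export
default_label_schemes <- function() {
  tab <- phone_feature_table()
  keep <- function(col) {
    ok <- !is.na(tab[[col]])
    stats::setNames(tab[[col]][ok], tab$phone[ok])
  }
  list(phone = label_scheme("phone", stats::setNames(tab$phone, tab$phone)),
       place = label_scheme("place", keep("place")),
       manner = label_scheme("manner", keep("manner")),
       frontness = label_scheme("frontness", keep("frontness")),
       closeness = label_scheme("closeness", keep("closeness")))
}

phone_feature_table <- function() {
  # phone, class, place, manner, frontness, closeness (NA = not applicable)
  p <- function(phone, place = NA, manner = NA, front = NA, close = NA) {
    data.frame(phone = phone, place = place, manner = manner,
               frontness = front, closeness = close)
  }
  rbind(
    p("p", "bilabial", "stop"),        p("b", "bilabial", "stop"),
    p("t", "alveolar", "stop"),        p("d", "alveolar", "stop"),
    p("k", "velar", "stop"),           p("g", "velar", "stop"),
    p("f", "labiodental", "fricative"), p("v", "labiodental", "fricative"),
    p("th", "dental", "fricative"),    p("dh", "dental", "fricative"),
    p("s", "alveolar", "fricative"),   p("z", "alveolar", "fricative"),
    p("sh", "postalveolar", "fricative"),
    p("zh", "postalveolar", "fricative"),
    p("ch", "postalveolar", "affricate"),
    p("jh", "postalveolar", "affricate"),
    p("m"), p("n"), p("ng"), p("l"), p("r"), p("w"), p("y"),
    p("iy", front = "front", close = "close"),
    p("ih", front = "front", close = "close"),
    p("eh", front = "front", close = "mid"),
    p("ae", front = "front", close = "open"),
    p("aa", front = "back", close = "open"),
    p("ao", front = "back", close = "mid"),
    p("uw", front = "back", close = "close"),
    p("uh", front = "back", close = "close"),
    p("ah", front = "central", close = "mid"),
    p("er", front = "central", close = "mid"))
}

# midpoints (ms) of the frames of a condition on the timeline's frame grid
frame_midpoints <- function(timeline, cid) {
  n <- nrow(timeline$frames[[cid]])
  timeline$shift_ms * (seq_len(n) - 1L) + timeline$frame_ms / 2
}

#' Average layer activations over phonetic segments
#'
#' Adjacent frames overlap acoustically and are highly correlated, so
#' clustering is evaluated on the mean activation vector over each
#' contiguous phone segment: a frame belongs to a segment iff its window
#' midpoint falls in \[start, end). Repeated phones within one condition
#' yield separate vectors.
#'
#' @param timeline A [feature_timeline].
#' @param segments A [segment_table] over the same conditions.
#' @return A `segment_vectors`: list with `vectors` (segments x nodes
#'   matrix) and `info` (condition, segment index, phone, frame count).
#' @export
segment_average <- function(timeline, segments) {
  stopifnot(inherits(timeline, "feature_timeline"),
            inherits(segments, "segment_table"))
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    cid <- as.character(seg$condition)
    if (!cid %in% names(timeline$frames)) {
      stop("segment condition not in timeline: ", cid)
    }
    mid <- frame_midpoints(timeline, cid)
    hit <- which(mid >= seg$start_ms & mid < seg$end_ms)
    if (length(hit) == 0L) {
      stop("segment contains no frame midpoint: condition ", cid,
           ", [", seg$start_ms, ", ", seg$end_ms, ") ms, phone ", seg$phone)
    }
    list(v = colMeans(timeline$frames[[cid]][hit, , drop = FALSE]),
         n = length(hit))
  })
  structure(list(
    vectors = do.call(rbind, lapply(rows, `[[`, "v")),
    info = data.frame(condition = as.character(segments$condition),
                      segment = seq_len(nrow(segments)),
                      phone = as.character(segments$phone),
                      n_frames = vapply(rows, `[[`, integer(1), "n"))),
    class = "segment_vectors")
}

#' Davies-Bouldin clustering index
#'
#' For each cluster k with centroid c_k and scatter s_k (mean Euclidean
#' distance of members to the centroid), the index is the average over
#' clusters of the worst-case ratio max_\{j != k\} (s_k + s_j) / d(c_k, c_j).
#' Lower is better; 0 is attained only when labels are shared only between
#' identical points.
#'
#' @param points Numeric matrix, points x dimensions.
#' @param labels Cluster label per point (>= 2 distinct labels).
#' @return The index (non-negative scalar).
#' @export
davies_bouldin <- function(points, labels) {
  db_index(points, labels, strict = TRUE)
}

# strict = FALSE returns +Inf for coincident centroids (the divergent limit
# of the within/between ratio) instead of erroring; used for permutation
# nulls, where a degenerate relabelling is a legitimate draw, not bad input
db_index <- function(points, labels, strict) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  stopifnot(nrow(points) == length(labels))
  labs <- unique(labels)
  k <- length(labs)
  if (k < 2L) stop("Davies-Bouldin index needs at least 2 distinct labels")
  cent <- do.call(rbind, lapply(labs, function(l) {
    colMeans(points[labels == l, , drop = FALSE])
  }))
  scat <- vapply(seq_along(labs), function(i) {
    m <- points[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(m, 2L, cent[i, ])^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(cent))
  if (any(cd[upper.tri(cd)] == 0)) {
    if (strict) stop("coincident cluster centroids: index undefined")
    return(Inf)
  }
  ratios <- outer(scat, scat, "+") / cd
  diag(ratios) <- -Inf
  mean(apply(ratios, 1L, max))
}

#' Permutation p-value for a Davies-Bouldin index
#'
#' The null randomizes the assignment of labels to points (shuffling the
#' label multiset) and recomputes the index. Lower indices indicate better
#' clustering, so "more extreme" means strictly lower:
#' p = (1 + #\{null < observed\}) / n_perm, clamped to at most 1; ties do
#' not count as more extreme. An observed index below every null value with
#' 5,000 permutations therefore gives p = 0.0002 exactly. A permuted
#' labelling with coincident centroids scores the divergent limit +Inf
#' (worst possible clustering) rather than aborting the null.
#'
#' @inheritParams davies_bouldin
#' @param n_perm Number of label permutations (default 5000).
#' @param seed Integer seed.
#' @return List with `index` (observed) and `p`.
#' @export
db_permutation_p <- function(points, labels, n_perm = 5000, seed = 1L) {
  observed <- davies_bouldin(points, labels)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      db_index(points, sample(labels), strict = FALSE)
    }, numeric(1))
  })
  list(index = observed,
       p = min((1 + sum(null < observed)) / n_perm, 1))
}

#' Clustering evaluation across layers and labelling schemes
#'
#' Segment-averages each layer's activations, restricts to the phones a
#' scheme labels (place/manner: obstruents; frontness/closeness: vowels),
#' and computes the Davies-Bouldin index with a label-permutation p-value.
#' Schemes left with fewer than 2 distinct labels after filtering are
#' flagged and get no index.
#'
#' @param timelines Named list of [feature_timeline]s (one per layer).
#' @param segments A [segment_table].
#' @param schemes List of [label_scheme]s (default [default_label_schemes]).
#' @param n_perm Permutations per index (default 5000).
#' @param seed Integer seed.
#' @return Data frame with one row per (layer, scheme): `layer`, `scheme`,
#'   `n_points`, `n_labels`, `index`, `p`, `note`.
#' @export
evaluate_all_schemes <- function(timelines, segments,
                                 schemes = default_label_schemes(),
                                 n_perm = 5000, seed = 1L) {
  stopifnot(is.list(timelines), !is.null(names(timelines)))
  out <- list()
  for (layer in names(timelines)) {
    sv <- segment_average(timelines[[layer]], segments)
    for (sc in schemes) {
      ok <- sv$info$phone %in% names(sc$map)
      labs <- unname(sc$map[sv$info$phone[ok]])
      row <- data.frame(layer = layer, scheme = sc$name,
                        n_points = sum(ok),
                        n_labels = length(unique(labs)),
                        index = NA_real_, p = NA_real_, note = "")
      if (length(unique(labs)) < 2L) {
        row$note <- "fewer than 2 labels after applicability filtering"
      } else {
        res <- db_permutation_p(sv$vectors[ok, , drop = FALSE], labs,
                                n_perm = n_perm,
                                seed = derive_seed(seed, paste(layer, sc$name)))
        row$index <- res$index
        row$p <- res$p
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Sammon non-linear multidimensional scaling
#'
#' Embeds points in (by default) two dimensions so as to minimize Sammon
#' stress, which weights each pairwise distance error by the inverse of the
#' original distance, preserving local structure. Optimization is the
#' classical step-halving gradient descent (via `MASS::sammon`) from a
#' seeded random initial configuration, so results are deterministic given
#' the seed.
#'
#' @param distances Square symmetric distance matrix (positive
#'   off-diagonal; zero distances between distinct points are an error
#'   since their stress weight is undefined).
#' @param dims Embedding dimension (default 2).
#' @param max_iter Maximum iterations.
#' @param seed Integer seed for the random initialization.
#' @return List with `points` (n x dims coordinates) and `stress`.
#' @export
sammon_embed <- function(distances, dims = 2L, max_iter = 200L, seed = 1L) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("distances must be a square symmetric matrix")
  }
  if (any(d[upper.tri(d)] <= 0)) {
    stop("zero or negative off-diagonal distance: Sammon stress undefined")
  }
  n <- nrow(d)
  init <- withr::with_seed(derive_seed(seed, "sammon-init"), {
    matrix(stats::rnorm(n * dims, sd = mean(d[upper.tri(d)])), n, dims)
  })
  fit <- MASS::sammon(stats::as.dist(d), y = init, k = dims,
                      niter = max_iter, trace = FALSE)
  list(points = fit$points, stress = fit$stress)
}
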