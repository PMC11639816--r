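# Supervised dataset construction: shift-lag labels, sliding windows,
# fixed-length padded segments, patient-wise splits, inverse-frequency
# class weights.

#' Shift labels so each row predicts the future
#'
#' Row `t` is re-paired with the label originally observed at `t + lag`
#' minutes, and the final `lag` rows (whose future label does not exist) are
#' dropped. Applied per admission. With the default 5-minute lag, a model
#' trained on the result predicts hypoxemia severity 5 minutes ahead.
#'
#' @param series table with a `label` column, ordered by time; if an
#'   `admission_id` column is present the shift is applied per admission.
#' @param lag_minutes non-negative integer lag (default 5).
#' @return the table with `label` replaced by the future label and the last
#'   `lag` rows of each admission removed. Empty (with a warning) when the
#'   series is not longer than the lag.
#' @export
shift_labels <- function(series, lag_minutes = 5L) {
  dt <- as.data.table(series)
  stopifnot("label" %in% names(dt))
  lag_minutes <- as.integer(lag_minutes)
  if (lag_minutes < 0L) stop("lag must be non-negative")
  if (lag_minutes == 0L) return(dt)
  one <- function(d) {
    if (nrow(d) <= lag_minutes) return(d[0])
    d <- copy(d)
    d[, label := shift(label, n = lag_minutes, type = "lead")]
    d[seq_len(nrow(d) - lag_minutes)]
  }
  out <- if ("admission_id" %in% names(dt)) {
    dt[, .ai := admission_id]
    res <- dt[, one(.SD), by = .ai][, .ai := NULL][]
    res
  } else one(dt)
  if (nrow(out) == 0L) warning("series not longer than lag; empty output")
  out
}

#' Sliding windows for sequence models
#'
#' Consecutive `width`-minute windows with the given stride (stride 1 gives
#' a `width - 1`-minute overlap between successive windows). Each window's
#' target is the (already shift-lagged) label of its last row, i.e. the
#' severity `width`-th minute + lag ahead. Windows touching padded rows are
#' flagged invalid and excluded from training.
#'
#' @param series a shift-lagged table (one admission) with feature columns,
#'   `label`, and optionally `pad` (1 = real row, 0 = padding).
#' @param width window width in minutes (default 5).
#' @param stride step between window starts (default 1).
#' @param feature_cols feature columns (default [feature_schema()] when
#'   present, otherwise all numeric non-label columns).
#' @return list of window samples, each `list(features = width x F matrix,
#'   target = label, valid = logical)`; empty list when the series is
#'   shorter than `width`.
#' @export
make_windows <- function(series, width = 5L, stride = 1L,
                         feature_cols = NULL) {
  dt <- as.data.table(series)
  n <- nrow(dt)
  width <- as.integer(width); stride <- as.integer(stride)
  if (n < width) return(list())
  if (is.null(feature_cols)) {
    feature_cols <- if (all(feature_schema() %in% names(dt))) feature_schema()
      else setdiff(names(dt)[vapply(dt, is.numeric, logical(1))],
                   c("label", "pad", "charttime", "row_interpolated",
                     "patient_id", "admission_id"))
  }
  x <- as.matrix(dt[, feature_cols, with = FALSE])
  pad_ok <- if ("pad" %in% names(dt)) dt$pad == 1L else rep(TRUE, n)
  starts <- seq.int(1L, n - width + 1L, by = stride)
  lapply(starts, function(s) {
    idx <- s:(s + width - 1L)
    list(features = x[idx, , drop = FALSE],
         target = dt$label[idx[width]],
         valid = all(pad_ok[idx]))
  })
}

#' Split a series into fixed-length padded segments
#'
#' Sequences longer than `seg_len` rows are cut into `seg_len`-row segments;
#' the final partial segment is padded with a constant sentinel that cannot
#' collide with real feature values (all clamped vitals are <= 300). The pad
#' mask marks real rows with 1.
#'
#' @param series table of one admission's rows.
#' @param seg_len segment length in rows (default 1024, about 18 h).
#' @param pad_value padding sentinel (default 1000).
#' @return list of segments, each `list(data = seg_len-row data.table,
#'   pad_mask = integer vector, n_real = count)`.
#' @export
segment_and_pad <- function(series, seg_len = 1024L, pad_value = 1000) {
  dt <- as.data.table(series)
  n <- nrow(dt)
  stopifnot(n >= 1L)
  seg_len <- as.integer(seg_len)
  n_seg <- ceiling(n / seg_len)
  out <- vector("list", n_seg)
  numcols <- names(dt)[vapply(dt, is.numeric, logical(1))]
  for (i in seq_len(n_seg)) {
    lo <- (i - 1L) * seg_len + 1L
    hi <- min(i * seg_len, n)
    seg <- dt[lo:hi]
    n_real <- nrow(seg)
    if (n_real < seg_len) {
      fill <- dt[rep(1L, seg_len - n_real)]
      for (j in numcols) set(fill, j = j, value = pad_value)
      seg <- rbind(seg, fill)
    }
    seg[, pad := c(rep(1L, n_real), rep(0L, seg_len - n_real))]
    out[[i]] <- list(data = seg, pad_mask = seg$pad, n_real = n_real)
  }
  out
}

#' Patient-wise train/validation/test split
#'
#' Partitions patients (never admissions) into the three sets with
#' largest-remainder rounding of the requested fractions, then a
#' seed-shuffled assignment. Every admission of a patient inherits the
#' patient's split, so no patient leaks across sets.
#'
#' @param patient_ids vector of unique patient identifiers (>= 8).
#' @param fractions train/val/test fractions summing to 1
#'   (default 0.75/0.125/0.125).
#' @param seed RNG seed.
#' @return named character vector `patient_id -> "train"|"val"|"test"`, with
#'   the fractions and seed attached as attributes.
#' @export
split_patients <- function(patient_ids, fractions = c(0.75, 0.125, 0.125),
                           seed = 42L) {
  ids <- unique(patient_ids)
  if (length(ids) < 8L) stop("need at least 8 patients to split")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(ids)
  base <- floor(fractions * n)
  rem <- fractions * n - base
  extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
  sizes <- base
  sizes[extra] <- sizes[extra] + 1L
  set.seed(seed)
  shuffled <- sample(ids)
  assignment <- rep(c("train", "val", "test"), times = sizes)
  out <- setNames(assignment, shuffled)[as.character(ids)]
  names(out) <- as.character(ids)
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- seed
  out
}

#' Inverse-frequency class weights
#'
#' `w_c = N_total / (K * n_c)` with `K` the number of classes, so equal
#' counts give unit weights and rare classes are up-weighted in proportion
#' to their rarity.
#'
#' @param label_counts named vector/table of per-class counts; all classes
#'   must be present (a zero-count class cannot be weighted).
#' @return named numeric vector of weights in class order.
#' @export
class_weights <- function(label_counts) {
  counts <- as.numeric(label_counts)
  if (any(counts <= 0) || anyNA(counts))
    stop("all classes must have positive counts")
  k <- length(counts)
  w <- sum(counts) / (k * counts)
  names(w) <- names(label_counts) %||% as.character(seq_len(k) - 1L)
  w
}
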