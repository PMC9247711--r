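# Internal helpers shared across modules.
#
# Conventions: time is seconds from session start; every analysis window is
# half-open [t0, t1) unless a function documents otherwise; events map to
# frames by "last frame_time <= event time".

#' @keywords internal
#' @noRd
.count_in <- function(sorted_times, a, b) {
  # number of elements with a <= x < b, vectorised over a/b
  findInterval(b, sorted_times, left.open = TRUE) -
    findInterval(a, sorted_times, left.open = TRUE)
}

#' @keywords internal
#' @noRd
.frames_in <- function(frame_times, t0, t1) {
  # index range of frames with t0 <= frame_time < t1 (possibly empty)
  i0 <- findInterval(t0, frame_times, left.open = TRUE) + 1L
  i1 <- findInterval(t1, frame_times, left.open = TRUE)
  if (i1 < i0) integer(0) else i0:i1
}

#' Mean of each ROI trace over a half-open time window
#'
#' Returns a vector (one value per ROI row of `values`) of the mean over
#' frames falling in [t0, t1), or NA if no frame falls inside.
#' @keywords internal
#' @noRd
.window_mean <- function(values, frame_times, t0, t1) {
  idx <- .frames_in(frame_times, t0, t1)
  if (length(idx) == 0L) {
    return(rep(NA_real_, nrow(values)))
  }
  if (length(idx) == 1L) values[, idx] else rowMeans(values[, idx, drop = FALSE])
}

#' Per-trial windowed ROI means
#'
#' @return ROI x trial matrix of window means (NA where a window has no
#'   frame coverage).
#' @keywords internal
#' @noRd
.window_mean_mat <- function(values, frame_times, t0, t1) {
  stopifnot(length(t0) == length(t1))
  out <- matrix(NA_real_, nrow(values), length(t0))
  for (k in seq_along(t0)) {
    out[, k] <- .window_mean(values, frame_times, t0[k], t1[k])
  }
  out
}

#' Running boxcar mean with truncation at the edges
#'
#' Centered window of `halfwin` samples each side; shorter near the edges.
#' Exact (cumsum-based), no padding.
#' @keywords internal
#' @noRd
.running_mean <- function(x, halfwin) {
  if (halfwin <= 0L) {
    return(x)
  }
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - halfwin, 1L)
  hi <- pmin(seq_len(n) + halfwin, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Type-7 sample quantile of a numeric vector (matches stats::quantile)
#' @keywords internal
#' @noRd
.quantile7 <- function(x, p) {
  n <- length(x)
  if (n == 1L) {
    return(x)
  }
  h <- (n - 1) * p
  lo <- floor(h)
  s <- sort.int(x, method = "quick")
  s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
}

#' One-sample / paired t-test p-value without the htest overhead
#'
#' @return list(stat, p, df) with p NA when the variance is zero.
#' @keywords internal
#' @noRd
.t_one <- function(d, alternative = "two.sided") {
  n <- length(d)
  if (n < 2L) {
    return(list(stat = NA_real_, p = NA_real_, df = n - 1))
  }
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) {
    return(list(stat = NA_real_, p = NA_real_, df = n - 1))
  }
  t <- mean(d) / (s / sqrt(n))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(t), n - 1),
    greater   = stats::pt(t, n - 1, lower.tail = FALSE),
    less      = stats::pt(t, n - 1)
  )
  list(stat = t, p = p, df = n - 1)
}

#' Seed helper: derive a stream-specific 32-bit seed from a master seed
#' @keywords internal
#' @noRd
.sub_seed <- function(seed, stream) {
  (as.integer(seed) + 1000003L * as.integer(stream)) %% .Machine$integer.max
}
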