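# Raw-fluorescence processing: sliding-percentile delta-F/F conversion,
# correlation-based bouton merging, and cross-channel bleed-through QC.

#' Convert raw fluorescence to delta-F/F
#'
#' The baseline F0 for each sample is the `percentile`-th percentile of the
#' boxcar-smoothed trace within a `window_s`-second window centered on the
#' sample (truncated at the session edges), and
#' \eqn{\Delta F/F = (F - F0)/F0}. F0 is floored at `1e-3` times the trace
#' median to keep the division stable; ROIs where the floor engages are
#' flagged in the `floored` attribute.
#'
#' @param f a `fluorescence_set` of kind `"raw_F"`.
#' @param window_s baseline window length (s), default 20.
#' @param percentile baseline percentile (0-100), default 5.
#' @param smooth_s boxcar smoothing window applied before the percentile
#'   (s), default 1.
#' @return a `fluorescence_set` of kind `"dff"` with the same shape and
#'   timestamps; attribute `floored` is a logical vector per ROI.
#' @export
compute_dff <- function(f, window_s = 20, percentile = 5, smooth_s = 1) {
  stopifnot(inherits(f, "fluorescence_set"))
  if (f$kind != "raw_F") stop("compute_dff expects raw_F input")
  if (!all(is.finite(f$values))) {
    bad <- which(apply(f$values, 1, function(x) all(is.na(x))))
    if (length(bad)) stop("all-NaN ROI(s): ", paste(bad, collapse = ", "))
    stop("non-finite fluorescence values")
  }
  ft <- f$frame_times
  if (diff(range(ft)) <= window_s / 2) {
    stop("frame_times must span more than half the baseline window")
  }
  dt <- stats::median(diff(ft))
  halfwin <- max(1L, round((window_s / 2) / dt))
  smooth_half <- max(0L, round((smooth_s / 2) / dt))
  n <- ncol(f$values)
  out <- f$values
  floored <- logical(nrow(f$values))
  lo <- pmax(seq_len(n) - halfwin, 1L)
  hi <- pmin(seq_len(n) + halfwin, n)
  p <- percentile / 100
  for (r in seq_len(nrow(f$values))) {
    x <- f$values[r, ]
    xs <- .running_mean(x, smooth_half)
    f0 <- vapply(
      seq_len(n),
      function(i) .quantile7(xs[lo[i]:hi[i]], p),
      numeric(1)
    )
    floor_val <- 1e-3 * stats::median(x)
    if (any(f0 < floor_val)) {
      f0 <- pmax(f0, floor_val)
      floored[r] <- TRUE
    }
    out[r, ] <- (x - f0) / f0
  }
  res <- fluorescence_set(out, ft,
    channel = f$channel,
    roi_pixels = f$roi_pixels, kind = "dff"
  )
  attr(res, "floored") <- floored
  res
}

# union-find over ROI indices
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Merge correlated boutons into putative axons
#'
#' Boutons whose pairwise trace correlation exceeds `threshold` (strictly)
#' are taken to belong to the same axon. Grouping is by connected components
#' of the correlation graph (transitive closure), and each group is replaced
#' by the pixel-count-weighted average of its members. Zero-variance ROIs
#' have undefined correlations; they are kept as singletons and flagged.
#'
#' @param dff a `fluorescence_set` (delta-F/F).
#' @param threshold correlation threshold, default 0.7 (strict `>`).
#' @return `list(merged = fluorescence_set, map = merge_map)` where the map
#'   holds `groups` (list of member ROI indices per output trace),
#'   `weights` (member pixel counts) and `flagged_zero_variance`.
#' @export
merge_boutons <- function(dff, threshold = 0.7) {
  stopifnot(inherits(dff, "fluorescence_set"))
  v <- dff$values
  n <- nrow(v)
  if (n < 1L) stop("need at least one ROI")
  if (!all(is.finite(v))) stop("non-finite trace values")
  sds <- apply(v, 1, stats::sd)
  zero_var <- sds == 0

  parent <- seq_len(n)
  ok <- which(!zero_var)
  if (length(ok) > 1L) {
    cm <- stats::cor(t(v[ok, , drop = FALSE]))
    for (a in seq_along(ok)) {
      for (b in seq_len(a - 1L)) {
        if (cm[a, b] > threshold) {
          ra <- .uf_find(parent, ok[a])
          rb <- .uf_find(parent, ok[b])
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  root <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  groups <- split(seq_len(n), match(root, unique(root)))
  names(groups) <- NULL

  merged_vals <- matrix(0, length(groups), ncol(v))
  merged_px <- integer(length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    w <- dff$roi_pixels[idx]
    merged_vals[g, ] <- if (length(idx) == 1L) {
      v[idx, ]
    } else {
      colSums(v[idx, , drop = FALSE] * w) / sum(w)
    }
    merged_px[g] <- sum(w)
  }
  merged <- fluorescence_set(merged_vals, dff$frame_times,
    channel = dff$channel, roi_pixels = merged_px, kind = dff$kind
  )
  map <- structure(
    list(
      groups = groups,
      weights = lapply(groups, function(idx) dff$roi_pixels[idx]),
      flagged_zero_variance = which(zero_var)
    ),
    class = "merge_map"
  )
  list(merged = merged, map = map)
}

#' Cross-channel bleed-through quality control
#'
#' Regresses each ROI's green-channel fluorescence on its red-channel
#' fluorescence (ordinary least squares) and summarises the slopes and R^2
#' values. A red trace with zero variance makes the regression undefined;
#' that ROI is flagged and excluded from the summary.
#'
#' @param green,red `fluorescence_set` objects with matched ROI sets and
#'   frame counts.
#' @return a `bleedthrough_report` list with per-ROI `slope` and
#'   `r_squared`, the summary `frac_positive_slope` and `mean_r_squared`,
#'   and `excluded` ROI indices.
#' @export
bleedthrough_qc <- function(green, red) {
  stopifnot(
    inherits(green, "fluorescence_set"), inherits(red, "fluorescence_set")
  )
  if (nrow(green$values) != nrow(red$values) ||
    ncol(green$values) != ncol(red$values)) {
    stop("green and red sets must have matched ROI and frame counts")
  }
  n <- nrow(green$values)
  slope <- r2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    x <- red$values[i, ]
    y <- green$values[i, ]
    vx <- stats::var(x)
    if (vx == 0) next
    slope[i] <- stats::cov(x, y) / vx
    vy <- stats::var(y)
    r2[i] <- if (vy == 0) 0 else stats::cov(x, y)^2 / (vx * vy)
  }
  excluded <- which(is.na(slope))
  keep <- !is.na(slope)
  structure(
    list(
      slope = slope, r_squared = r2,
      frac_positive_slope = mean(slope[keep] > 0),
      mean_r_squared = mean(r2[keep]),
      excluded = excluded
    ),
    class = "bleedthrough_report"
  )
}
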