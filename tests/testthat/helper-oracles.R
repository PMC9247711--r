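# Independent brute-force oracles and fixture builders. Each oracle is a
# direct, quadratic-time transcription of the definition it checks, kept
# deliberately separate from the package's implementation path.

# O(n*w) sliding-percentile delta-F/F: naive smoothing, naive windowed
# percentile via stats::quantile, explicit loops.
oracle_dff <- function(x, frame_times, window_s = 20, percentile = 5,
                       smooth_s = 1) {
  n <- length(x)
  dt <- median(diff(frame_times))
  sh <- max(0L, round((smooth_s / 2) / dt))
  xs <- numeric(n)
  for (i in seq_len(n)) {
    xs[i] <- mean(x[max(1, i - sh):min(n, i + sh)])
  }
  hw <- max(1L, round((window_s / 2) / dt))
  out <- numeric(n)
  med <- median(x)
  for (i in seq_len(n)) {
    f0 <- unname(quantile(xs[max(1, i - hw):min(n, i + hw)], percentile / 100))
    f0 <- max(f0, 1e-3 * med)
    out[i] <- (x[i] - f0) / f0
  }
  out
}

# O(n*m) interval count for the lick rate
oracle_lick_rate <- function(licks, frame_times, window_s = 1) {
  sapply(frame_times, function(t) {
    sum(licks >= t - window_s / 2 & licks < t + window_s / 2)
  })
}

# exhaustive lick-bout scanner: checks every lick index against the raw
# definition (>= silence_s without licking before, 3rd lick within span_s)
oracle_bouts <- function(licks, span_s = 0.5, silence_s = 1) {
  starts <- c()
  for (i in seq_along(licks)) {
    prior <- licks[licks < licks[i]]
    if (length(prior) && max(prior) > licks[i] - silence_s) next
    later <- licks[licks >= licks[i]]
    if (length(later) < 3) next
    if (later[3] - later[1] < span_s) starts <- c(starts, licks[i])
  }
  starts
}

# point-in-polygon (even-odd ray casting) against a densely sampled
# eyelid-contour polygon
oracle_inside <- function(points, medial, lateral, superior, inferior,
                          n_samp = 2000) {
  axis <- lateral - medial
  len <- sqrt(sum(axis^2))
  ex <- axis / len
  ey <- c(-ex[2], ex[1])
  tf <- function(p) c(sum((p - medial) * ex), sum((p - medial) * ey))
  sup <- tf(superior)
  inf <- tf(inferior)
  cu <- sup[2] / (sup[1] * (sup[1] - len))
  cl <- inf[2] / (inf[1] * (inf[1] - len))
  xs <- seq(0, len, length.out = n_samp)
  poly_u <- cbind(xs, cu * xs * (xs - len))
  poly_l <- cbind(rev(xs), cl * rev(xs) * (rev(xs) - len))
  poly <- rbind(poly_u, poly_l)
  n <- nrow(poly)
  xi <- poly[, 1]
  yi <- poly[, 2]
  xj <- poly[c(n, seq_len(n - 1)), 1]
  yj <- poly[c(n, seq_len(n - 1)), 2]
  in_poly <- function(px, py) {
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    sum(cross, na.rm = TRUE) %% 2 == 1
  }
  apply(points, 1, function(p) {
    u <- tf(p)
    in_poly(u[1], u[2])
  })
}

# minimal hand-built trial table (regular clock, no timeouts)
make_trials <- function(n, types = rep(c("go", "nogo"), length.out = n),
                        responses = NULL, sides = rep("monocular", n),
                        period = 12) {
  tone <- 5 + period * (seq_len(n) - 1)
  stim_on <- tone + 1
  stim_off <- stim_on + 4
  go <- types == "go"
  if (is.null(responses)) responses <- ifelse(go, "lick", "no_lick")
  licked <- responses == "lick"
  correct <- ifelse(go, licked, !licked)
  data.frame(
    trial_id = seq_len(n), trial_type = types, side = sides, contrast = 1,
    tone_time = tone, stim_on = stim_on, stim_off = stim_off,
    response = responses, correct = correct,
    reward_time = ifelse(go & licked, stim_on + 2.2, NA_real_),
    airpuff_time = ifelse(!go & licked, stim_on + 2.2, NA_real_)
  )
}

# fluorescence set on a uniform clock from a ROI x frame matrix
make_fset <- function(values, frame_rate = 10, kind = "dff", pixels = 10L) {
  values <- matrix(values, nrow = if (is.matrix(values)) nrow(values) else 1)
  n <- ncol(values)
  fluorescence_set(values, (seq_len(n) - 0.5) / frame_rate,
    channel = "green", roi_pixels = pixels, kind = kind
  )
}

# traces with an exact target correlation structure: rows = L %*% z where
# the rows of z are zero-mean orthonormal basis vectors, so for unit-norm
# rows of L, cor(t(L %*% z)) == L %*% t(L) exactly
make_correlated_traces <- function(L, n_frames = 400, seed = 1) {
  set.seed(seed)
  k <- ncol(L)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n_frames * k), n_frames, k))))
  z <- t(q[, -1, drop = FALSE]) * sqrt(n_frames - 1)
  L %*% z
}
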