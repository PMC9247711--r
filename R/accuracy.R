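# Behavioral accuracy (d-prime, sliding d-prime) and the per-bouton linear
# model linking trial activity to correctness and trial type.

#' Signal-detection d-prime
#'
#' `qnorm(hit_rate) - qnorm(fa_rate)`. Rates of exactly 0 or 1 make the
#' quantile infinite; the default policy replaces them by `1/(2n)` and
#' `1 - 1/(2n)` using the relevant trial counts. The `"loglinear"` policy
#' applies the Hautus adjustment (add 0.5 to counts, 1 to totals) to both
#' rates; `"none"` returns the infinite value with a warning.
#'
#' @param hit_rate,fa_rate fractions in [0, 1].
#' @param correction `"half_n"`, `"loglinear"`, or `"none"`.
#' @param n_go,n_nogo trial counts behind each rate (required by the
#'   correcting policies when a rate sits on the boundary).
#' @return d-prime (unitless scalar).
#' @export
compute_dprime <- function(hit_rate, fa_rate,
                           correction = c("half_n", "loglinear", "none"),
                           n_go = NULL, n_nogo = NULL) {
  correction <- match.arg(correction)
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  if (correction == "half_n") {
    clamp <- function(r, n) {
      if (r %in% c(0, 1)) {
        if (is.null(n)) stop("boundary rate needs a trial count")
        r <- min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
      }
      r
    }
    hit_rate <- clamp(hit_rate, n_go)
    fa_rate <- clamp(fa_rate, n_nogo)
  } else if (correction == "loglinear") {
    if (is.null(n_go) || is.null(n_nogo)) {
      stop("loglinear correction needs trial counts")
    }
    hit_rate <- (hit_rate * n_go + 0.5) / (n_go + 1)
    fa_rate <- (fa_rate * n_nogo + 0.5) / (n_nogo + 1)
  } else if (hit_rate %in% c(0, 1) || fa_rate %in% c(0, 1)) {
    warning("boundary rate with correction = 'none'; d-prime is infinite")
  }
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' Sliding-window d-prime over a session
#'
#' Hit rate, false-alarm rate and d-prime over a window of `window` trials
#' slid one trial at a time. Windows lacking either a go or a no-go trial
#' are dropped.
#'
#' @param trials trial table.
#' @param window window length in trials, default 20.
#' @param correction boundary-rate policy passed to [compute_dprime()].
#' @return a `dprime_series` data.frame with columns `center` (center trial
#'   index), `hit_rate`, `fa_rate`, `dprime`.
#' @export
sliding_dprime <- function(trials, window = 20, correction = "half_n") {
  n <- nrow(trials)
  if (window < 2) stop("window must be >= 2")
  if (n < window) stop("fewer trials than the window length")
  is_go <- trials$trial_type == "go"
  licked <- trials$response == "lick"
  rows <- list()
  for (s in seq_len(n - window + 1L)) {
    idx <- s:(s + window - 1L)
    g <- is_go[idx]
    if (!any(g) || all(g)) next
    hr <- mean(licked[idx][g])
    fr <- mean(licked[idx][!g])
    rows[[length(rows) + 1L]] <- data.frame(
      center = s + (window - 1L) / 2, hit_rate = hr, fa_rate = fr,
      dprime = compute_dprime(hr, fr,
        correction = correction,
        n_go = sum(g), n_nogo = sum(!g)
      )
    )
  }
  if (!length(rows)) {
    warning("no window contained both trial types; empty d-prime series")
    return(structure(
      data.frame(
        center = numeric(0), hit_rate = numeric(0),
        fa_rate = numeric(0), dprime = numeric(0)
      ),
      class = c("dprime_series", "data.frame"), window = window
    ))
  }
  structure(do.call(rbind, rows),
    class = c("dprime_series", "data.frame"), window = window
  )
}

#' Per-trial bouton activity in a selectable task window
#'
#' @param dff a `fluorescence_set` (delta-F/F).
#' @param trials trial table.
#' @param window `"full"` (tone onset to stimulus offset), `"tone1s"` (1 s
#'   after tone onset), `"stim2s"` (initial 2 s of stimulus), `"pretrial1s"`
#'   (1 s before tone onset), or `"response"` (reward-eligible 2-4 s after
#'   stimulus onset).
#' @return bouton x trial matrix of window means.
#' @export
trial_activity_matrix <- function(dff, trials,
                                  window = c(
                                    "full", "tone1s", "stim2s",
                                    "pretrial1s", "response"
                                  )) {
  window <- match.arg(window)
  w <- switch(window,
    full = cbind(trials$tone_time, trials$stim_off),
    tone1s = cbind(trials$tone_time, trials$tone_time + 1),
    stim2s = cbind(trials$stim_on, trials$stim_on + 2),
    pretrial1s = cbind(trials$tone_time - 1, trials$tone_time),
    response = cbind(trials$stim_on + 2, trials$stim_on + 4)
  )
  .window_mean_mat(dff$values, dff$frame_times, w[, 1], w[, 2])
}

#' Linear model of trial activity on correctness and trial type
#'
#' Per bouton, fits ordinary least squares of per-trial activity on trial
#' correctness, trial type, and their interaction (treatment coding:
#' correct 1/0, go 1 / no-go 0), with t-tests on the coefficients and
#' Benjamini-Hochberg adjustment across boutons per coefficient. With
#' `predictor = "previous_correct"` the correctness of the preceding trial
#' is used instead (the first trial is dropped). The correct modulation
#' index is `(R_correct - R_incorrect)/(R_correct + R_incorrect)` on
#' condition-mean activity.
#'
#' @param activity bouton x trial matrix (see [trial_activity_matrix()]).
#' @param trials trial table aligned with the columns of `activity`.
#' @param predictor `"correct"` or `"previous_correct"`.
#' @return a `correctness_fit` list: `coefficients`, `p_raw`, `p_adj`
#'   (bouton x term matrices), `cmi`, and `skipped` (boutons with a
#'   rank-deficient design, e.g. all trials correct).
#' @export
correctness_model <- function(activity, trials,
                              predictor = c("correct", "previous_correct")) {
  predictor <- match.arg(predictor)
  stopifnot(ncol(activity) == nrow(trials))
  correct <- as.numeric(trials$correct)
  if (predictor == "previous_correct") {
    keep <- 2:nrow(trials)
    correct <- correct[keep - 1L]
    activity <- activity[, keep, drop = FALSE]
    trials <- trials[keep, ]
  }
  go <- as.numeric(trials$trial_type == "go")
  if (length(unique(correct)) < 2L) {
    stop("both correctness levels must be present")
  }
  if (nrow(trials) < 4L) stop("need at least 4 trials")
  has_both_types <- length(unique(go)) == 2L
  X <- if (has_both_types) {
    cbind(intercept = 1, correct = correct, trial_type = go, interaction = correct * go)
  } else {
    cbind(intercept = 1, correct = correct)
  }
  rank_ok <- qr(X)$rank == ncol(X)

  nb <- nrow(activity)
  terms <- colnames(X)
  coefs <- p_raw <- matrix(NA_real_, nb, length(terms),
    dimnames = list(NULL, terms)
  )
  cmi <- rep(NA_real_, nb)
  skipped <- integer(0)
  for (b in seq_len(nb)) {
    y <- activity[b, ]
    ok <- !is.na(y)
    if (!rank_ok || sum(ok) < ncol(X) + 1L ||
      length(unique(correct[ok])) < 2L) {
      skipped <- c(skipped, b)
      next
    }
    fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
    res <- fit$residuals
    df <- sum(ok) - ncol(X)
    sigma2 <- sum(res^2) / df
    xtx_inv <- chol2inv(chol(crossprod(X[ok, , drop = FALSE])))
    se <- sqrt(sigma2 * diag(xtx_inv))
    tval <- fit$coefficients / se
    coefs[b, ] <- fit$coefficients
    p_raw[b, ] <- 2 * stats::pt(-abs(tval), df)
    rc <- mean(y[ok & correct == 1])
    ri <- mean(y[ok & correct == 0])
    cmi[b] <- if (rc + ri == 0) 0 else (rc - ri) / (rc + ri)
  }
  p_adj <- apply(p_raw, 2, stats::p.adjust, method = "BH")
  structure(
    list(
      coefficients = coefs, p_raw = p_raw, p_adj = p_adj,
      cmi = cmi, skipped = skipped, predictor = predictor
    ),
    class = "correctness_fit"
  )
}

#' Regression of population activity on sliding d-prime
#'
#' For each session, pairs the sliding d-prime series with the mean bouton
#' population delta-F/F over the same trial windows and fits a straight
#' line (least squares) of population activity on d-prime. Across sessions,
#' tests whether the mean slope differs from zero (two-sided one-sample
#' t-test). Sessions with constant population activity or constant d-prime
#' have an undefined slope and are excluded.
#'
#' @param sessions list of `list(dprime = dprime_series, pop = per-trial
#'   population mean delta-F/F vector)`, one per session. The `pop` vector
#'   must align with the session's trials; it is averaged over each sliding
#'   window to pair with the d-prime points.
#' @return list with per-session `slopes`, the excluded session indices,
#'   and `t_stat` / `p_value` of the group test (needs >= 2 usable
#'   sessions).
#' @export
dprime_activity_regression <- function(sessions) {
  slopes <- rep(NA_real_, length(sessions))
  for (s in seq_along(sessions)) {
    dp <- sessions[[s]]$dprime
    pop <- sessions[[s]]$pop
    w <- attr(dp, "window")
    if (!nrow(dp)) next
    pop_win <- vapply(dp$center, function(ctr) {
      idx <- (ctr - (w - 1) / 2):(ctr + (w - 1) / 2)
      mean(pop[idx], na.rm = TRUE)
    }, numeric(1))
    if (stats::var(dp$dprime) == 0 || stats::var(pop_win) == 0) next
    slopes[s] <- stats::cov(dp$dprime, pop_win) / stats::var(dp$dprime)
  }
  usable <- which(!is.na(slopes))
  if (length(usable) < 2L) {
    return(list(
      slopes = slopes, excluded = which(is.na(slopes)),
      t_stat = NA_real_, p_value = NA_real_
    ))
  }
  tt <- .t_one(slopes[usable], "two.sided")
  list(
    slopes = slopes, excluded = which(is.na(slopes)),
    t_stat = tt$stat, p_value = tt$p
  )
}
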