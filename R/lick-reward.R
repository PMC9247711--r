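# Lick-rate construction, circular-shift permutation test for
# lick-correlated boutons, rewarded vs unrewarded comparisons (raw and
# bout-matched), and the reward-targeting index.

#' Lick rate on the frame grid
#'
#' Counts the licks in a centered 1 s window `[t - 0.5, t + 0.5)` around
#' each frame time (a sliding sum over the binary lick event trace).
#'
#' @param licks lick raster (sorted numeric, s).
#' @param frame_times frame timestamps (s).
#' @param window_s window length (s), default 1.
#' @return integer-valued numeric vector, one count per frame.
#' @export
lick_rate <- function(licks, frame_times, window_s = 1) {
  .count_in(licks, frame_times - window_s / 2, frame_times + window_s / 2)
}

#' Circular-shift permutation test for lick-correlated boutons
#'
#' Computes each bouton's Pearson correlation with the lick-rate trace and
#' builds a null distribution by circularly shifting the lick rate
#' `n_perm` times with a minimum shift of `min_shift_s` seconds in either
#' direction (shifts are uniform over the allowed circular offsets, in
#' whole frames). A bouton is significant when its observed correlation
#' exceeds the 95th percentile of its null; boutons with observed
#' correlation above 0.2 are additionally labelled highly lick-correlated.
#' Deterministic given `seed`.
#'
#' @param dff a `fluorescence_set` (delta-F/F) aligned with `rate`.
#' @param rate lick-rate vector (one value per frame).
#' @param n_perm number of circular shifts, default 1000.
#' @param min_shift_s minimum shift magnitude (s), default 10.
#' @param seed integer RNG seed.
#' @param high_r threshold for the highly-correlated label, default 0.2.
#' @return data.frame with one row per bouton: `r_obs`,
#'   `null_quantile_95`, `p_perm`, `significant`, `highly_correlated`,
#'   `excluded` (zero-variance traces). Attribute `shifts` holds the frame
#'   offsets used.
#' @export
lick_correlation_perm <- function(dff, rate, n_perm = 1000, min_shift_s = 10,
                                  seed = 1, high_r = 0.2) {
  stopifnot(inherits(dff, "fluorescence_set"))
  v <- dff$values
  nf <- ncol(v)
  stopifnot(length(rate) == nf)
  dt <- stats::median(diff(dff$frame_times))
  min_shift <- ceiling(min_shift_s / dt)
  if (nf <= 2 * min_shift) stop("session shorter than twice the minimum shift")

  set.seed(as.integer(seed))
  shifts <- sample(seq.int(min_shift, nf - min_shift), n_perm, replace = TRUE)

  sds <- apply(v, 1, stats::sd)
  excluded <- sds == 0
  r_obs <- rep(NA_real_, nrow(v))
  if (stats::sd(rate) == 0) stop("lick rate has zero variance")
  r_obs[!excluded] <- as.vector(stats::cor(t(v[!excluded, , drop = FALSE]), rate))

  # null correlations via one centered matrix product per shift block
  vc <- v[!excluded, , drop = FALSE]
  vc <- vc - rowMeans(vc)
  vnorm <- sqrt(rowSums(vc^2))
  rc <- rate - mean(rate)
  rnorm_ <- sqrt(sum(rc^2))
  null_r <- matrix(NA_real_, sum(!excluded), n_perm)
  block <- 200L
  for (s0 in seq(1L, n_perm, by = block)) {
    s1 <- min(s0 + block - 1L, n_perm)
    S <- vapply(
      shifts[s0:s1],
      function(k) rc[((seq_len(nf) - 1L + k) %% nf) + 1L],
      numeric(nf)
    )
    null_r[, s0:s1] <- (vc %*% S) / (vnorm * rnorm_)
  }

  q95 <- p_perm <- rep(NA_real_, nrow(v))
  keep_idx <- which(!excluded)
  for (j in seq_along(keep_idx)) {
    b <- keep_idx[j]
    q95[b] <- .quantile7(null_r[j, ], 0.95)
    p_perm[b] <- (1 + sum(null_r[j, ] >= r_obs[b])) / (n_perm + 1)
  }
  out <- data.frame(
    r_obs = r_obs, null_quantile_95 = q95, p_perm = p_perm,
    significant = !excluded & r_obs > q95,
    highly_correlated = !excluded & r_obs > high_r,
    excluded = excluded
  )
  attr(out, "shifts") <- shifts
  out
}

# lick-containing half-open periods of a given type within go trials
.reward_periods <- function(trials) {
  go <- trials[trials$trial_type == "go" & !is.na(trials$reward_time), ]
  cbind(go$reward_time, go$stim_off, go$side == "contra" | go$side == "monocular")
}

.unrewarded_periods <- function(trials) {
  go <- trials[trials$trial_type == "go", ]
  cbind(go$stim_on, go$stim_on + 2, go$side == "contra" | go$side == "monocular")
}

# per-bouton mean dff pooled over the lick-containing periods in `per`
.period_mean <- function(dff, licks, per) {
  has_lick <- .count_in(licks, per[, 1], per[, 2]) > 0L
  per <- per[has_lick, , drop = FALSE]
  if (!nrow(per)) {
    return(NULL)
  }
  idx <- unlist(lapply(
    seq_len(nrow(per)),
    function(k) .frames_in(dff$frame_times, per[k, 1], per[k, 2])
  ))
  if (!length(idx)) {
    return(NULL)
  }
  rowMeans(dff$values[, idx, drop = FALSE])
}

#' Rewarded versus unrewarded licking comparison
#'
#' Compares each bouton's mean delta-F/F during rewarded licking (the
#' reward period of correct go trials, reward delivery to stimulus offset)
#' against unrewarded licking (the initial 2 s of the stimulus on go
#' trials). Only periods that contain at least one lick contribute. A
#' paired t-test across boutons tests the population difference. With
#' `scope = "per_side"` the rewarded means are additionally split into
#' contralateral (`C_reward`) and ipsilateral (`I_reward`) trials, the
#' reward targeting index `rti = (C - I)/(C + I)` is computed per bouton,
#' and a two-tailed one-sample t-test compares the population RTI to zero.
#'
#' @param dff a `fluorescence_set` (delta-F/F).
#' @param trials trial table.
#' @param licks lick raster.
#' @param scope `"all"` or `"per_side"`.
#' @return a `reward_comparison` list: `dff_unrewarded`, `dff_rewarded`
#'   (per bouton), `paired_p`; and for `per_side` also `C_reward`,
#'   `I_reward`, `rti`, `rti_t_p`.
#' @export
rewarded_vs_unrewarded <- function(dff, trials, licks,
                                   scope = c("all", "per_side")) {
  scope <- match.arg(scope)
  rp <- .reward_periods(trials)
  up <- .unrewarded_periods(trials)
  rew <- .period_mean(dff, licks, rp)
  unrew <- .period_mean(dff, licks, up)
  if (is.null(rew)) stop("no rewarded licking period in session")
  if (is.null(unrew)) stop("no unrewarded licking period in go trials")
  res <- list(
    dff_unrewarded = unrew, dff_rewarded = rew,
    paired_p = .t_one(rew - unrew, "two.sided")$p
  )
  if (scope == "per_side") {
    if (!(any(rp[, 3] == 1) && any(rp[, 3] == 0))) {
      stop("per_side comparison needs both contra and ipsi rewarded trials")
    }
    C <- .period_mean(dff, licks, rp[rp[, 3] == 1, , drop = FALSE])
    I <- .period_mean(dff, licks, rp[rp[, 3] == 0, , drop = FALSE])
    rti <- ifelse(C + I == 0, 0, (C - I) / (C + I))
    res$C_reward <- C
    res$I_reward <- I
    res$rti <- rti
    res$rti_t_p <- .t_one(rti, "two.sided")$p
  }
  structure(res, class = "reward_comparison")
}

#' Detect lick bouts
#'
#' A bout starts at a lick that is preceded by at least 1 s without
#' licking and is followed by two further licks such that all three fall
#' within 0.5 s. Each bout is labelled rewarded if its first lick falls in
#' the reward period of a correct go trial (reward delivery to stimulus
#' offset). Downstream activity analyses use only the first three licks of
#' each bout.
#'
#' @param licks lick raster (sorted numeric).
#' @param trials trial table (for the rewarded label).
#' @param span_s bout span (s) containing the first three licks, 0.5.
#' @param silence_s required pre-bout silence (s), 1.
#' @return data.frame with one row per bout: `start`, `lick2`, `lick3`,
#'   `rewarded`.
#' @export
detect_bouts <- function(licks, trials, span_s = 0.5, silence_s = 1) {
  n <- length(licks)
  rows <- list()
  rp <- .reward_periods(trials)
  for (i in seq_len(max(0L, n - 2L))) {
    if (i > 1L && licks[i] - licks[i - 1L] < silence_s) next
    if (licks[i + 2L] - licks[i] >= span_s) next
    rewarded <- nrow(rp) > 0 &&
      any(licks[i] >= rp[, 1] & licks[i] < rp[, 2])
    rows[[length(rows) + 1L]] <- data.frame(
      start = licks[i], lick2 = licks[i + 1L], lick3 = licks[i + 2L],
      rewarded = rewarded
    )
  }
  if (!length(rows)) {
    return(data.frame(
      start = numeric(0), lick2 = numeric(0), lick3 = numeric(0),
      rewarded = logical(0)
    ))
  }
  do.call(rbind, rows)
}

#' Bout-matched rewarded versus unrewarded comparison
#'
#' Compares per-bouton mean delta-F/F over the first three licks of each
#' bout (window from the first to the third lick, inclusive of the third
#' lick's frame), split by bout reward status, with a paired t-test across
#' boutons. Frequency and count are matched by construction of the bout
#' definition. With a single bout in a class the means rest on one sample
#' and the result is flagged degenerate.
#'
#' @param dff a `fluorescence_set` (delta-F/F).
#' @param bouts output of [detect_bouts()].
#' @return a `reward_comparison` list with `dff_rewarded`,
#'   `dff_unrewarded`, `paired_p`, `n_rewarded`, `n_unrewarded`,
#'   `degenerate`.
#' @export
bout_matched_comparison <- function(dff, bouts) {
  for (cls in c(TRUE, FALSE)) {
    if (!any(bouts$rewarded == cls)) {
      stop(
        "no ", if (cls) "rewarded" else "unrewarded",
        " bouts in session"
      )
    }
  }
  ft <- dff$frame_times
  bout_mean <- function(sub) {
    idx <- unlist(lapply(
      seq_len(nrow(sub)),
      function(k) {
        ii <- .frames_in(ft, sub$start[k], sub$lick3[k])
        # include the frame holding the third lick (closed right endpoint)
        last <- findInterval(sub$lick3[k], ft)
        union(ii, if (last >= 1L) last else integer(0))
      }
    ))
    rowMeans(dff$values[, idx, drop = FALSE])
  }
  rew <- bout_mean(bouts[bouts$rewarded, , drop = FALSE])
  unrew <- bout_mean(bouts[!bouts$rewarded, , drop = FALSE])
  structure(
    list(
      dff_rewarded = rew, dff_unrewarded = unrew,
      paired_p = .t_one(rew - unrew, "two.sided")$p,
      n_rewarded = sum(bouts$rewarded),
      n_unrewarded = sum(!bouts$rewarded),
      degenerate = sum(bouts$rewarded) < 2L || sum(!bouts$rewarded) < 2L
    ),
    class = "reward_comparison"
  )
}
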