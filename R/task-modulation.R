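# Trial-modulation classification and event-triggered response testing.

#' Per-trial within/between period activity
#'
#' For each bouton and trial, computes the mean delta-F/F over the
#' within-trial period (trial-onset tone to stimulus offset) and over the
#' final 2 s of the properly executed quiescent period immediately before
#' trial onset. A quiescent period counts as properly executed only if it
#' contains no lick in that final 2 s window; trials failing this (or with
#' incomplete frame coverage of either window) are excluded from the paired
#' set.
#'
#' @param dff a `fluorescence_set` (delta-F/F).
#' @param trials trial table (see [session_record()]).
#' @param licks lick raster (numeric, sorted).
#' @param between_s length of the pre-trial quiescent window (s), default 2.
#' @return a `trial_activity` object: matrices `within` and `between`
#'   (bouton x retained trial), the retained `trial_id`s, and the ids
#'   excluded for licking or coverage.
#' @export
trial_period_activity <- function(dff, trials, licks, between_s = 2) {
  stopifnot(inherits(dff, "fluorescence_set"))
  ft <- dff$frame_times
  t0w <- trials$tone_time
  t1w <- trials$stim_off
  t0b <- trials$tone_time - between_s
  t1b <- trials$tone_time

  quiet <- .count_in(licks, t0b, t1b) == 0L
  within <- .window_mean_mat(dff$values, ft, t0w, t1w)
  between <- .window_mean_mat(dff$values, ft, t0b, t1b)
  covered <- !is.na(within[1L, ]) & !is.na(between[1L, ])
  keep <- quiet & covered
  if (!any(keep)) stop("no valid trials for within/between pairing")
  structure(
    list(
      within = within[, keep, drop = FALSE],
      between = between[, keep, drop = FALSE],
      trial_id = trials$trial_id[keep],
      excluded_licking = trials$trial_id[!quiet],
      excluded_coverage = trials$trial_id[quiet & !covered]
    ),
    class = "trial_activity"
  )
}

#' Classify trial modulation of each bouton
#'
#' Two-sided paired t-test of within-trial versus inter-trial activity per
#' bouton; boutons with p < `alpha` are labelled `increased` or `decreased`
#' by the sign of the mean difference, otherwise `ns`. The task modulation
#' index is `(within - between) / (within + between)` on trial-mean
#' activities: +1 means active only inside trials, -1 only during the
#' intertrial quiescent period. With nonnegative activity the index lies in
#' [-1, 1]; negative delta-F/F can push it outside, in which case the value
#' is reported as-is and flagged.
#'
#' @param activity a `trial_activity` object.
#' @param alpha significance level, default 0.01.
#' @return data.frame with one row per bouton: `class_label`, `p_value`,
#'   `tmi`, `tmi_out_of_range`, `degenerate`.
#' @export
classify_trial_modulation <- function(activity, alpha = 0.01) {
  stopifnot(inherits(activity, "trial_activity"))
  if (ncol(activity$within) < 2L) stop("need at least 2 paired trials")
  nb <- nrow(activity$within)
  p <- tmi <- rep(NA_real_, nb)
  lab <- rep("ns", nb)
  degen <- logical(nb)
  for (b in seq_len(nb)) {
    d <- activity$within[b, ] - activity$between[b, ]
    tt <- .t_one(d, "two.sided")
    if (is.na(tt$p)) {
      degen[b] <- TRUE
    } else {
      p[b] <- tt$p
      if (tt$p < alpha) lab[b] <- if (mean(d) > 0) "increased" else "decreased"
    }
    mw <- mean(activity$within[b, ])
    mb <- mean(activity$between[b, ])
    tmi[b] <- if (mw + mb == 0) 0 else (mw - mb) / (mw + mb)
  }
  data.frame(
    class_label = lab, p_value = p, tmi = tmi,
    tmi_out_of_range = !is.na(tmi) & abs(tmi) > 1,
    degenerate = degen
  )
}

#' Event-triggered response test with FDR control
#'
#' For each event type, compares each bouton's mean delta-F/F in the 0.5 s
#' before event onset against the 1 s after, with a one-sided (increase)
#' paired t-test across events, then applies Benjamini-Hochberg correction
#' across boutons within the event type. Boutons with adjusted p < `level`
#' are flagged responsive. Event types with fewer than two usable events are
#' omitted (recorded in the `omitted` attribute).
#'
#' @param dff a `fluorescence_set` (delta-F/F).
#' @param events named list of event-time vectors (e.g. `tone`, `go_stim`,
#'   `nogo_stim`, `reward`, `airpuff`).
#' @param pre_window,post_window comparison windows (s), defaults 0.5 / 1.
#' @param level adjusted-p threshold, default 0.05.
#' @return data.frame with one row per bouton x event type: `event`,
#'   `bouton`, `p_raw`, `p_adj`, `responsive`.
#' @export
event_response_test <- function(dff, events, pre_window = 0.5,
                                post_window = 1, level = 0.05) {
  stopifnot(inherits(dff, "fluorescence_set"))
  ft <- dff$frame_times
  nb <- nrow(dff$values)
  out <- NULL
  omitted <- character(0)
  for (ev in names(events)) {
    times <- events[[ev]]
    times <- times[!is.na(times)]
    if (length(times) < 2L) {
      omitted <- c(omitted, ev)
      next
    }
    pre <- .window_mean_mat(dff$values, ft, times - pre_window, times)
    post <- .window_mean_mat(dff$values, ft, times, times + post_window)
    ok <- !is.na(pre[1L, ]) & !is.na(post[1L, ])
    if (sum(ok) < 2L) {
      omitted <- c(omitted, ev)
      next
    }
    p <- vapply(
      seq_len(nb),
      function(b) .t_one(post[b, ok] - pre[b, ok], "greater")$p,
      numeric(1)
    )
    p_adj <- stats::p.adjust(p, method = "BH")
    out <- rbind(out, data.frame(
      event = ev, bouton = seq_len(nb), p_raw = p, p_adj = p_adj,
      responsive = !is.na(p_adj) & p_adj < level
    ))
  }
  attr(out, "omitted") <- omitted
  out
}
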