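# Passive-stimulation analysis: responsiveness, constrained double-Gaussian
# direction tuning, OSI/DSI, and trial splits by concurrent axon-population
# activity.

#' Build the per-condition response table
#'
#' For each soma and stimulus presentation, the response is the mean
#' delta-F/F over the 1 s after stimulus onset. Presentations without frame
#' coverage are dropped; conditions left with zero repeats are omitted.
#'
#' @param dff_somas a `fluorescence_set` with the soma traces.
#' @param stimuli stimulus log (`onset`, `direction`, `position_index`).
#' @param window_s response window (s), default 1.
#' @return a long data.frame: `neuron`, `direction`, `position_index`,
#'   `stim_index`, `response`.
#' @export
build_response_table <- function(dff_somas, stimuli, window_s = 1) {
  stopifnot(inherits(dff_somas, "fluorescence_set"))
  resp <- .window_mean_mat(
    dff_somas$values, dff_somas$frame_times,
    stimuli$onset, stimuli$onset + window_s
  )
  covered <- !is.na(resp[1L, ])
  nb <- nrow(resp)
  out <- data.frame(
    neuron = rep(seq_len(nb), each = sum(covered)),
    direction = rep(stimuli$direction[covered], nb),
    position_index = rep(stimuli$position_index[covered], nb),
    stim_index = rep(which(covered), nb),
    response = as.vector(t(resp[, covered, drop = FALSE]))
  )
  out
}

#' Visual responsiveness test
#'
#' One-way ANOVA of responses across all stimulus conditions (direction x
#' position) per neuron; responsive when p < `level`. Zero-variance data
#' make the F statistic degenerate; such neurons are flagged and labelled
#' not responsive.
#'
#' @param table response table from [build_response_table()].
#' @param level significance level, default 0.05.
#' @return data.frame per neuron: `neuron`, `p_value`, `responsive`,
#'   `degenerate`.
#' @export
test_responsive <- function(table, level = 0.05) {
  neurons <- sort(unique(table$neuron))
  cond <- interaction(table$direction, table$position_index, drop = TRUE)
  if (nlevels(cond) < 2L) stop("need at least 2 stimulus conditions")
  res <- lapply(neurons, function(nn) {
    sub <- table$neuron == nn
    y <- table$response[sub]
    g <- droplevels(cond[sub])
    if (stats::var(y) == 0 || nlevels(g) < 2L) {
      return(data.frame(
        neuron = nn, p_value = NA_real_, responsive = FALSE,
        degenerate = TRUE
      ))
    }
    p <- stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1]
    data.frame(
      neuron = nn, p_value = p, responsive = !is.na(p) && p < level,
      degenerate = is.na(p)
    )
  })
  do.call(rbind, res)
}

# wrapped angular distance in degrees
.ang_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Fit a constrained double-Gaussian direction tuning curve
#'
#' Model: `R(theta) = offset + A1 * G(theta - theta_p) +
#' A2 * G(theta - theta_p - 180)`, where G is a Gaussian in wrapped angular
#' distance with shared width, the preferred direction `theta_p` is fixed
#' at the direction eliciting the largest mean response, one peak is
#' constrained to `theta_p` and the second to 180 degrees away, and both
#' amplitudes are nonnegative. Fitted by bounded Levenberg-Marquardt
#' nonlinear least squares on the per-direction mean responses (at the
#' neuron's best position, i.e. the position with the largest mean
#' response). OSI and DSI are evaluated from the fitted curve:
#' `OSI = (R_pref - R_ortho)/(R_pref + R_ortho)` with `R_ortho` at
#' `theta_p + 90`, and `DSI = (R_pref_dir - R_pref_dir+180)/(R_pref_dir +
#' R_pref_dir+180)`.
#'
#' @param table response table from [build_response_table()].
#' @param neuron neuron index to fit.
#' @return a `tuning_fit` list: `pref_direction`, `A1`, `A2`, `sigma`,
#'   `offset`, `r_squared`, `osi`, `dsi`, the fitted responses at the
#'   evaluation angles, `best_position`, and `converged`.
#' @export
fit_tuning <- function(table, neuron) {
  sub <- table[table$neuron == neuron, ]
  # collapse the position grid to the best position
  pos_mean <- tapply(sub$response, sub$position_index, mean)
  best_pos <- as.numeric(names(pos_mean)[which.max(pos_mean)])
  sub <- sub[sub$position_index == best_pos, ]
  dir_mean <- tapply(sub$response, sub$direction, mean)
  dirs <- as.numeric(names(dir_mean))
  y <- as.numeric(dir_mean)
  if (length(dirs) < 5L) stop("need at least 5 direction conditions")

  theta_p <- dirs[which.max(y)]
  d1 <- .ang_dist(dirs, theta_p)
  d2 <- .ang_dist(dirs, theta_p + 180)
  ymin <- min(y)
  ymax <- max(y)
  start <- list(
    A1 = max(ymax - ymin, 1e-6),
    A2 = max(y[which.max(d1)] - ymin, 1e-6),
    sigma = 30,
    offset = ymin
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ offset + A1 * exp(-d1^2 / (2 * sigma^2)) +
        A2 * exp(-d2^2 / (2 * sigma^2)),
      start = start,
      lower = c(A1 = 0, A2 = 0, sigma = 3, offset = -Inf),
      upper = c(A1 = Inf, A2 = Inf, sigma = 180, offset = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  cf <- if (!is.null(fit)) stats::coef(fit) else NULL
  if (is.null(cf)) {
    # bounded quasi-Newton fallback on the same least-squares objective
    # (Levenberg-Marquardt can fail on degenerate geometry, e.g. an exactly
    # vanishing second peak)
    obj <- function(p) {
      sum((y - (p[4] + p[1] * exp(-d1^2 / (2 * p[3]^2)) +
        p[2] * exp(-d2^2 / (2 * p[3]^2))))^2)
    }
    op <- tryCatch(
      stats::optim(unlist(start), obj,
        method = "L-BFGS-B",
        lower = c(0, 0, 3, -Inf), upper = c(Inf, Inf, 180, Inf)
      ),
      error = function(e) NULL
    )
    if (!is.null(op) && op$convergence == 0) {
      cf <- c(A1 = op$par[[1]], A2 = op$par[[2]],
              sigma = op$par[[3]], offset = op$par[[4]])
    }
  }
  if (is.null(cf)) {
    return(structure(
      list(
        pref_direction = theta_p, A1 = NA_real_, A2 = NA_real_,
        sigma = NA_real_, offset = NA_real_, r_squared = NA_real_,
        osi = NA_real_, dsi = NA_real_, best_position = best_pos,
        converged = FALSE
      ),
      class = "tuning_fit"
    ))
  }
  curve_at <- function(theta) {
    cf[["offset"]] +
      cf[["A1"]] * exp(-.ang_dist(theta, theta_p)^2 / (2 * cf[["sigma"]]^2)) +
      cf[["A2"]] * exp(-.ang_dist(theta, theta_p + 180)^2 / (2 * cf[["sigma"]]^2))
  }
  pred <- curve_at(dirs)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum((y - pred)^2) / sst
  r_pref <- curve_at(theta_p)
  r_ortho <- curve_at(theta_p + 90)
  r_null <- curve_at(theta_p + 180)
  structure(
    list(
      pref_direction = theta_p,
      A1 = unname(cf["A1"]), A2 = unname(cf["A2"]),
      sigma = unname(cf["sigma"]), offset = unname(cf["offset"]),
      r_squared = r2,
      R_pref = r_pref, R_ortho = r_ortho,
      R_pref_dir = r_pref, R_pref_dir_plus180 = r_null,
      osi = (r_pref - r_ortho) / (r_pref + r_ortho),
      dsi = (r_pref - r_null) / (r_pref + r_null),
      best_position = best_pos,
      converged = TRUE
    ),
    class = "tuning_fit"
  )
}

#' Split trials by axon-population activity and compare tuning
#'
#' Splits stimulus presentations at the median of the concurrent
#' axon-population activity into high and low halves, fits the tuning
#' model per neuron in each half, retains neurons that are visually
#' responsive and have fit `r_squared > r2_gate` in both halves, and
#' compares the OSI (and DSI) distributions of the retained neurons
#' between halves with a Kruskal-Wallis test. The change in preferred
#' direction between halves is reported per neuron.
#'
#' @param table response table from [build_response_table()].
#' @param axon_pop per-presentation axon-population mean delta-F/F,
#'   indexed like `stim_index` in the table.
#' @param r2_gate fit-quality gate, default 0.3.
#' @param level responsiveness level passed to [test_responsive()].
#' @return an `activity_split` list: per-neuron `osi_high`, `osi_low`,
#'   `dsi_high`, `dsi_low`, `delta_pref`, the retained neuron ids, the
#'   split labels, and `osi_kw_p` / `dsi_kw_p`.
#' @export
split_and_compare <- function(table, axon_pop, r2_gate = 0.3, level = 0.05) {
  stim_ids <- sort(unique(table$stim_index))
  stopifnot(length(axon_pop) >= max(stim_ids))
  pop <- axon_pop[stim_ids]
  ord <- order(pop)
  half <- length(ord) %/% 2
  low_ids <- stim_ids[ord[seq_len(half)]]
  high_ids <- setdiff(stim_ids, low_ids)

  responsive <- test_responsive(table, level = level)
  neurons <- responsive$neuron[responsive$responsive]

  fit_half <- function(nn, ids) {
    sub <- table[table$stim_index %in% ids, ]
    tryCatch(fit_tuning(sub, nn), error = function(e) NULL)
  }
  keep <- integer(0)
  osi_h <- osi_l <- dsi_h <- dsi_l <- dpref <- numeric(0)
  for (nn in neurons) {
    fh <- fit_half(nn, high_ids)
    fl <- fit_half(nn, low_ids)
    if (is.null(fh) || is.null(fl) || !fh$converged || !fl$converged) next
    if (is.na(fh$r_squared) || is.na(fl$r_squared)) next
    if (fh$r_squared <= r2_gate || fl$r_squared <= r2_gate) next
    keep <- c(keep, nn)
    osi_h <- c(osi_h, fh$osi)
    osi_l <- c(osi_l, fl$osi)
    dsi_h <- c(dsi_h, fh$dsi)
    dsi_l <- c(dsi_l, fl$dsi)
    dpref <- c(dpref, .ang_dist(fh$pref_direction, fl$pref_direction))
  }
  kw <- function(a, b) {
    if (length(a) < 2L) {
      return(NA_real_)
    }
    stats::kruskal.test(list(a, b))$p.value
  }
  structure(
    list(
      neurons = keep, osi_high = osi_h, osi_low = osi_l,
      dsi_high = dsi_h, dsi_low = dsi_l, delta_pref = dpref,
      high_ids = high_ids, low_ids = low_ids,
      osi_kw_p = kw(osi_h, osi_l), dsi_kw_p = kw(dsi_h, dsi_l)
    ),
    class = "activity_split"
  )
}

#' Per-presentation axon-population activity
#'
#' Mean of all axon ROIs over the same window used for the soma responses.
#'
#' @param dff_axons a `fluorescence_set` with the axon traces.
#' @param stimuli stimulus log.
#' @param window_s response window (s), default 1.
#' @return numeric vector, one value per stimulus presentation.
#' @export
axon_population_activity <- function(dff_axons, stimuli, window_s = 1) {
  m <- .window_mean_mat(
    dff_axons$values, dff_axons$frame_times,
    stimuli$onset, stimuli$onset + window_s
  )
  colMeans(m)
}
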