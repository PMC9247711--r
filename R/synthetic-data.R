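# Synthetic session generator.
#
# Emulates the statistical structure the analysis stages assume: the
# go/no-go trial clock (0.1 s tone, stimulus 1 s after tone for 4 s, reward
# window 2-4 s after go-stimulus onset, 0.5 s airpuff plus 10 s timeout on
# false alarms, 2-10 s quiescent periods), an agent that licks rhythmically
# (~7 Hz) when rewarded and sparsely otherwise, slow-indicator bouton traces
# built from known couplings convolved with a GCaMP6s-like kernel, tuned
# soma responses for the passive protocol, and pupil landmark tables.
# Every simulation returns the ground truth needed for recovery tests.

#' Go/no-go task configuration
#'
#' Defaults are the task timings used throughout: 0.1 s / 5 kHz tone, visual
#' stimulus from 1 s after tone onset lasting 4 s, reward window 2-4 s after
#' go-stimulus onset, quiescent periods drawn from 2-10 s, 0.5 s airpuff and
#' a 10 s timeout after false alarms, 10 Hz imaging.
#'
#' @param n_trials number of trials.
#' @param frac_go fraction of go trials.
#' @param sides stimulus sides to sample from (`"monocular"` or
#'   `c("contra","ipsi")` for the bilateral task variant).
#' @param contrasts stimulus contrasts to sample from, each in (0,1].
#' @param frame_rate imaging frame rate (Hz).
#' @param tone_duration,tone_to_stim,stim_duration,airpuff_duration s.
#' @param response_window reward-eligible window relative to stimulus onset.
#' @param quiescent_range range (s) of the uniform quiescent-period draw.
#' @param timeout_after_fa timeout (s) appended after a false alarm.
#' @return a `task_config` list.
#' @export
task_config <- function(n_trials = 200, frac_go = 0.5,
                        sides = "monocular", contrasts = 1,
                        frame_rate = 10,
                        tone_duration = 0.1, tone_to_stim = 1,
                        stim_duration = 4, response_window = c(2, 4),
                        quiescent_range = c(2, 10),
                        timeout_after_fa = 10, airpuff_duration = 0.5) {
  cfg <- list(
    n_trials = as.integer(n_trials), frac_go = frac_go, sides = sides,
    contrasts = contrasts, frame_rate = frame_rate,
    tone_duration = tone_duration, tone_to_stim = tone_to_stim,
    stim_duration = stim_duration, response_window = response_window,
    quiescent_range = quiescent_range, timeout_after_fa = timeout_after_fa,
    airpuff_duration = airpuff_duration
  )
  if (n_trials < 1 || frac_go < 0 || frac_go > 1 ||
    any(c(
      tone_duration, tone_to_stim, stim_duration, frame_rate,
      airpuff_duration, timeout_after_fa
    ) <= 0) ||
    response_window[1] < 0 || response_window[2] > stim_duration ||
    response_window[1] >= response_window[2] ||
    quiescent_range[1] <= 0 || quiescent_range[1] > quiescent_range[2] ||
    any(contrasts <= 0 | contrasts > 1)) {
    stop("invalid task configuration", call. = FALSE)
  }
  structure(cfg, class = "task_config")
}

#' Licking-agent parameters
#'
#' @param hit_rate probability of licking on a go trial.
#' @param fa_rate probability of licking on a no-go trial.
#' @param reward_lick_freq lick frequency (Hz) of rewarded bouts; rewarded
#'   licking is rhythmic at > 6 Hz, default 7.
#' @param unrewarded_lick_freq lick frequency (Hz) of unrewarded bursts.
#' @param impulsive_lick_prob probability of an impulsive burst in the first
#'   2 s of the stimulus (unrelated to trial type).
#' @param spontaneous_lick_rate Poisson rate (Hz) of stray intertrial licks.
#' @param accuracy_drift_sd per-trial sd of a bounded logit-scale random
#'   walk on hit/fa rates (0 disables drift); used to exercise the sliding
#'   d-prime analyses.
#' @return an `agent_params` list.
#' @export
agent_params <- function(hit_rate = 0.8, fa_rate = 0.2,
                         reward_lick_freq = 7, unrewarded_lick_freq = 7,
                         impulsive_lick_prob = 0.25,
                         spontaneous_lick_rate = 0.05,
                         accuracy_drift_sd = 0) {
  p <- list(
    hit_rate = hit_rate, fa_rate = fa_rate,
    reward_lick_freq = reward_lick_freq,
    unrewarded_lick_freq = unrewarded_lick_freq,
    impulsive_lick_prob = impulsive_lick_prob,
    spontaneous_lick_rate = spontaneous_lick_rate,
    accuracy_drift_sd = accuracy_drift_sd
  )
  probs <- c(hit_rate, fa_rate, impulsive_lick_prob)
  if (any(probs < 0 | probs > 1) ||
    any(c(reward_lick_freq, unrewarded_lick_freq, spontaneous_lick_rate) < 0) ||
    accuracy_drift_sd < 0) {
    stop("invalid agent parameters", call. = FALSE)
  }
  structure(p, class = "agent_params")
}

#' Bouton coupling specification
#'
#' Coupling weights (delta-F/F units at regressor peak) linking a simulated
#' bouton to task variables. The trace is the weighted sum of each regressor
#' convolved with a difference-of-exponentials indicator kernel, plus
#' kernel-filtered background transients and Gaussian noise.
#'
#' @param lick_rate,reward,tone,go_stim,nogo_stim,in_trial,correctness
#'   coupling weights. `lick_rate` couples to the instantaneous lick rate,
#'   `reward`/`tone`/`go_stim`/`nogo_stim` to event impulses, `in_trial` to
#'   a boxcar spanning tone onset to stimulus offset, and `correctness` to
#'   that boxcar on correct trials only.
#' @param hemispheric_gain multiplicative gain applied to the
#'   reward-coupled component on contralateral versus ipsilateral trials.
#' @param baseline_rate rate (events/s) of background calcium transients.
#' @param noise_sd additive Gaussian noise sd (delta-F/F units).
#' @param response_jitter sd of the multiplicative per-event amplitude
#'   variability of the impulse-coupled responses (reward, tone, go/no-go
#'   stimulus), independent across boutons and events; emulates the
#'   trial-to-trial response variability of real boutons.
#' @param kernel_tau_rise,kernel_tau_decay indicator kernel time constants
#'   (s); defaults are GCaMP6s-like (0.2 / 1.5).
#' @return a `bouton_spec` list.
#' @export
bouton_spec <- function(lick_rate = 0, reward = 0, tone = 0, go_stim = 0,
                        nogo_stim = 0, in_trial = 0, correctness = 0,
                        hemispheric_gain = 1, baseline_rate = 0.1,
                        noise_sd = 0.05, response_jitter = 0.25,
                        kernel_tau_rise = 0.2, kernel_tau_decay = 1.5) {
  s <- list(
    lick_rate = lick_rate, reward = reward, tone = tone, go_stim = go_stim,
    nogo_stim = nogo_stim, in_trial = in_trial, correctness = correctness,
    hemispheric_gain = hemispheric_gain, baseline_rate = baseline_rate,
    noise_sd = noise_sd, response_jitter = response_jitter,
    kernel_tau_rise = kernel_tau_rise,
    kernel_tau_decay = kernel_tau_decay
  )
  if (kernel_tau_rise <= 0 || kernel_tau_decay <= kernel_tau_rise ||
    baseline_rate < 0 || noise_sd < 0 || response_jitter < 0 ||
    hemispheric_gain < 0 ||
    !all(vapply(s, function(x) is.finite(x), logical(1)))) {
    stop("invalid bouton specification", call. = FALSE)
  }
  structure(s, class = "bouton_spec")
}

#' Soma tuning specification
#'
#' Ground-truth direction tuning for a simulated visually responsive soma:
#' a sum of two Gaussians 180 degrees apart with shared width.
#'
#' @param pref_direction preferred direction (deg).
#' @param amp_pref,amp_null amplitudes at the preferred direction and the
#'   opposite direction (response units, >= 0).
#' @param width_sigma shared Gaussian width (deg).
#' @param offset baseline response.
#' @param modulator_interaction response gain applied on trials where the
#'   concurrent axon-population activity is high (1 = no interaction).
#' @param modulator_target `"both"` scales both amplitudes on high trials,
#'   `"pref_only"` scales only the preferred-direction amplitude.
#' @param noise_sd per-repeat response noise sd.
#' @return a `soma_spec` list.
#' @export
soma_spec <- function(pref_direction = 0, amp_pref = 1, amp_null = 0.4,
                      width_sigma = 25, offset = 0.1,
                      modulator_interaction = 1,
                      modulator_target = c("both", "pref_only"),
                      noise_sd = 0.05) {
  modulator_target <- match.arg(modulator_target)
  s <- list(
    pref_direction = pref_direction %% 360, amp_pref = amp_pref,
    amp_null = amp_null, width_sigma = width_sigma, offset = offset,
    modulator_interaction = modulator_interaction,
    modulator_target = modulator_target, noise_sd = noise_sd
  )
  if (amp_pref < 0 || amp_null < 0 || width_sigma <= 0 || noise_sd < 0 ||
    modulator_interaction < 0) {
    stop("invalid soma specification", call. = FALSE)
  }
  structure(s, class = "soma_spec")
}

# difference-of-exponentials kernel on the frame grid, peak-normalised
.indicator_kernel <- function(tau_rise, tau_decay, dt) {
  tt <- seq(0, 6 * tau_decay, by = dt)
  h <- exp(-tt / tau_decay) - exp(-tt / tau_rise)
  h / max(h)
}

# causal convolution of x with kernel h, truncated to length(x)
.conv_causal <- function(x, h) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(h))), rev(h), type = "open")
  out[seq_len(n)]
}

# rhythmic lick burst: n licks at freq Hz with small timing jitter
.lick_burst <- function(start, n, freq, jitter = 0.12) {
  if (n < 1) {
    return(numeric(0))
  }
  ili <- (1 / freq) * (1 + stats::runif(n - 1, -jitter, jitter))
  start + c(0, cumsum(ili))
}

#' Simulate a go/no-go behavioral imaging session
#'
#' Builds a full session: trial clock per the task configuration, Bernoulli
#' trial outcomes (hit probability on go, false-alarm probability on no-go),
#' licking placed per the agent parameters (rhythmic rewarded bouts, short
#' unrewarded and impulsive bursts, sparse spontaneous licks), and bouton
#' traces formed as coupling-weighted regressors convolved with the
#' indicator kernel plus background transients and noise. Deterministic
#' given `seed`.
#'
#' @param config a [task_config()].
#' @param agent an [agent_params()].
#' @param boutons list of [bouton_spec()] objects (>= 1).
#' @param seed integer RNG seed.
#' @param emit `"raw_F"` writes traces as `F = f_base * (1 + signal)` so the
#'   delta-F/F stage can be exercised; `"dff"` writes the signal directly.
#' @param f_base mean raw-fluorescence offset (a.u.) used when
#'   `emit = "raw_F"`; each ROI gets a jittered copy.
#' @param dual_channel if `TRUE`, also generate an independent red-channel
#'   set (for bleed-through QC).
#' @return `list(session = session_record, truth = ground truth list)`. The
#'   truth records the bouton specs, agent and task parameters, the
#'   per-trial latent hit/false-alarm probabilities, and the seed.
#' @export
simulate_session <- function(config = task_config(), agent = agent_params(),
                             boutons = list(bouton_spec()), seed = 1,
                             emit = c("raw_F", "dff"), f_base = 100,
                             dual_channel = FALSE) {
  emit <- match.arg(emit)
  if (!inherits(config, "task_config")) stop("config must be a task_config")
  if (length(boutons) < 1) stop("need at least one bouton spec")
  set.seed(as.integer(seed))

  n <- config$n_trials
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  hit_l <- logit(min(max(agent$hit_rate, 1e-4), 1 - 1e-4))
  fa_l <- logit(min(max(agent$fa_rate, 1e-4), 1 - 1e-4))

  trials <- data.frame(
    trial_id = seq_len(n), trial_type = NA_character_, side = NA_character_,
    contrast = NA_real_, tone_time = NA_real_, stim_on = NA_real_,
    stim_off = NA_real_, response = NA_character_, correct = NA,
    reward_time = NA_real_, airpuff_time = NA_real_
  )
  hit_p <- fa_p <- numeric(n)
  licks <- numeric(0)
  t_cursor <- 2
  rw <- config$response_window

  for (i in seq_len(n)) {
    if (agent$accuracy_drift_sd > 0 && i > 1) {
      hit_l <- min(max(hit_l + stats::rnorm(1, 0, agent$accuracy_drift_sd), -3), 3)
      fa_l <- min(max(fa_l + stats::rnorm(1, 0, agent$accuracy_drift_sd), -3), 3)
    }
    hit_p[i] <- inv_logit(hit_l)
    fa_p[i] <- inv_logit(fa_l)

    quiescent <- stats::runif(1, config$quiescent_range[1], config$quiescent_range[2])
    tone <- t_cursor + quiescent
    stim_on <- tone + config$tone_to_stim
    stim_off <- stim_on + config$stim_duration
    go <- stats::runif(1) < config$frac_go
    side <- if (length(config$sides) == 1L) {
      config$sides
    } else {
      sample(config$sides, 1)
    }
    contrast <- if (length(config$contrasts) == 1L) {
      config$contrasts
    } else {
      sample(config$contrasts, 1)
    }

    trial_licks <- numeric(0)
    if (stats::runif(1) < agent$impulsive_lick_prob) {
      burst <- .lick_burst(
        stats::runif(1, stim_on, stim_on + rw[1] - 0.5),
        sample(2:4, 1), agent$unrewarded_lick_freq
      )
      trial_licks <- c(trial_licks, burst[burst < stim_on + rw[1]])
    }

    reward_time <- airpuff_time <- NA_real_
    if (go) {
      respond <- stats::runif(1) < hit_p[i]
      correct <- respond
      if (respond) {
        rt <- stim_on + rw[1] + min(stats::rexp(1, 1 / 0.4), rw[2] - rw[1] - 0.3)
        reward_time <- rt
        bout_dur <- stats::runif(1, 1, 2)
        n_licks <- max(3L, round(bout_dur * agent$reward_lick_freq))
        trial_licks <- c(
          trial_licks,
          .lick_burst(rt, n_licks, agent$reward_lick_freq)
        )
      }
    } else {
      respond <- stats::runif(1) < fa_p[i]
      correct <- !respond
      if (respond) {
        ft <- stats::runif(1, stim_on + rw[1], stim_on + rw[2] - 0.5)
        airpuff_time <- ft
        trial_licks <- c(
          trial_licks,
          .lick_burst(ft, 3L, agent$unrewarded_lick_freq)
        )
      }
    }

    trials$trial_type[i] <- if (go) "go" else "nogo"
    trials$side[i] <- side
    trials$contrast[i] <- contrast
    trials$tone_time[i] <- tone
    trials$stim_on[i] <- stim_on
    trials$stim_off[i] <- stim_off
    trials$response[i] <- if (respond) "lick" else "no_lick"
    trials$correct[i] <- correct
    trials$reward_time[i] <- reward_time
    trials$airpuff_time[i] <- airpuff_time

    licks <- c(licks, trial_licks)
    t_cursor <- stim_off + if (!go && respond) config$timeout_after_fa else 0
    # allow rewarded bouts to finish before the next quiescent period
    t_cursor <- max(t_cursor, if (length(trial_licks)) max(trial_licks) else 0)
  }

  duration <- t_cursor + 5

  # sparse spontaneous licks in the intertrial gaps
  if (agent$spontaneous_lick_rate > 0) {
    n_sp <- stats::rpois(1, agent$spontaneous_lick_rate * duration)
    sp <- stats::runif(n_sp, 0, duration)
    in_trial <- vapply(
      sp,
      function(t) any(t >= trials$tone_time & t < trials$stim_off),
      logical(1)
    )
    licks <- c(licks, sp[!in_trial])
  }
  licks <- sort(licks)
  if (length(licks) > 1L) {
    licks <- licks[c(TRUE, diff(licks) > 1e-3)]
  }
  licks <- licks[licks >= 0 & licks <= duration]

  dt <- 1 / config$frame_rate
  frame_times <- seq(dt / 2, duration, by = dt)
  nf <- length(frame_times)

  # regressors on the frame grid
  boxcar <- function(t0, t1, value = 1) {
    r <- numeric(nf)
    for (k in seq_along(t0)) {
      ii <- .frames_in(frame_times, t0[k], t1[k])
      r[ii] <- r[ii] + value[min(k, length(value))]
    }
    r
  }
  go_tr <- trials$trial_type == "go"
  contra_tr <- trials$side %in% c("contra", "monocular")
  reg <- list(
    lick_rate = .count_in(licks, frame_times - dt / 2, frame_times + dt / 2) / dt,
    in_trial = boxcar(trials$tone_time, trials$stim_off),
    correctness = boxcar(
      trials$tone_time[trials$correct], trials$stim_off[trials$correct]
    )
  )
  event_times <- list(
    reward_contra = trials$reward_time[contra_tr],
    reward_ipsi = trials$reward_time[!contra_tr],
    tone = trials$tone_time,
    go_stim = trials$stim_on[go_tr],
    nogo_stim = trials$stim_on[!go_tr]
  )
  event_times <- lapply(event_times, function(t) t[!is.na(t)])

  # sustained regressors are convolved once per distinct kernel and
  # normalised by the kernel mass, so a coupling weight reads as delta-F/F
  # per unit of sustained regressor; impulse-coupled responses are added
  # sparsely per bouton with the peak-normalised kernel (weight = transient
  # peak) and per-event amplitude jitter
  kernel_key <- vapply(
    boutons,
    function(b) paste(b$kernel_tau_rise, b$kernel_tau_decay),
    character(1)
  )
  conv_cache <- kernels <- list()
  values <- matrix(0, length(boutons), nf)
  for (key in unique(kernel_key)) {
    b0 <- boutons[[match(key, kernel_key)]]
    h <- .indicator_kernel(b0$kernel_tau_rise, b0$kernel_tau_decay, dt)
    kernels[[key]] <- h
    cv <- lapply(reg, .conv_causal, h = h)
    conv_cache[[key]] <- lapply(cv, function(x) x / sum(h))
  }
  for (j in seq_along(boutons)) {
    b <- boutons[[j]]
    cv <- conv_cache[[kernel_key[j]]]
    h <- kernels[[kernel_key[j]]]
    sig <- b$lick_rate * cv$lick_rate + b$in_trial * cv$in_trial +
      b$correctness * cv$correctness
    add_events <- function(times, w) {
      if (w == 0 || !length(times)) {
        return()
      }
      amps <- w * (1 + b$response_jitter * stats::rnorm(length(times)))
      ks <- findInterval(times, frame_times)
      for (e in seq_along(ks)) {
        if (ks[e] < 1L) next
        jj <- ks[e]:min(nf, ks[e] + length(h) - 1L)
        sig[jj] <<- sig[jj] + amps[e] * h[seq_along(jj)]
      }
    }
    add_events(event_times$reward_contra, b$reward * b$hemispheric_gain)
    add_events(event_times$reward_ipsi, b$reward)
    add_events(event_times$tone, b$tone)
    add_events(event_times$go_stim, b$go_stim)
    add_events(event_times$nogo_stim, b$nogo_stim)
    if (b$baseline_rate > 0) {
      ev_t <- stats::runif(
        stats::rpois(1, b$baseline_rate * duration), 0, duration
      )
      for (k in findInterval(ev_t, frame_times)) {
        if (k < 1L) next
        jj <- k:min(nf, k + length(h) - 1L)
        sig[jj] <- sig[jj] + 0.5 * h[seq_along(jj)]
      }
    }
    if (b$noise_sd > 0) sig <- sig + stats::rnorm(nf, 0, b$noise_sd)
    values[j, ] <- sig
  }

  roi_pixels <- sample(4:40, length(boutons), replace = TRUE)
  if (emit == "raw_F") {
    f0 <- f_base * stats::runif(length(boutons), 0.8, 1.2)
    green <- fluorescence_set(
      f0 * (1 + values), frame_times,
      channel = "green", roi_pixels = roi_pixels, kind = "raw_F"
    )
  } else {
    green <- fluorescence_set(
      values, frame_times,
      channel = "green", roi_pixels = roi_pixels, kind = "dff"
    )
  }
  fl <- list(green = green)
  if (dual_channel) {
    red_vals <- f_base * (1 + matrix(
      stats::rnorm(length(boutons) * nf, 0, 0.03), length(boutons), nf
    ))
    fl$red <- fluorescence_set(
      red_vals, frame_times,
      channel = "red", roi_pixels = roi_pixels, kind = "raw_F"
    )
  }

  session <- session_record(
    trials = trials, licks = licks, fluorescence = fl, duration = duration
  )
  truth <- list(
    boutons = boutons, config = config, agent = agent,
    hit_p = hit_p, fa_p = fa_p, seed = as.integer(seed)
  )
  list(session = session, truth = truth)
}

# evaluate the double-Gaussian tuning curve of a soma_spec
.tuning_curve <- function(spec, directions, gain_pref = 1, gain_null = 1) {
  dd <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  g <- function(d) exp(-d^2 / (2 * spec$width_sigma^2))
  spec$offset +
    gain_pref * spec$amp_pref * g(dd(directions, spec$pref_direction)) +
    gain_null * spec$amp_null * g(dd(directions, spec$pref_direction + 180))
}

#' Simulate a passive-stimulation tuning experiment
#'
#' Generates a drifting-grating stimulus log (8 directions x positions, 1 s
#' per stimulus, no gaps), soma responses drawn from each soma's
#' double-Gaussian ground truth — optionally scaled on trials where the
#' concurrent axon population is active (`modulator_interaction`) — and
#' concurrent axon traces with slow multiplicative fluctuations so that
#' population activity spans a wide range.
#'
#' @param somas list of [soma_spec()] objects (>= 1).
#' @param n_axons number of concurrent axon ROIs.
#' @param n_repeats repeats per stimulus condition (>= 2).
#' @param n_positions stimulus positions per direction.
#' @param frame_rate imaging frame rate (Hz).
#' @param seed integer RNG seed.
#' @return `list(session, truth)`; in the session, the green channel holds
#'   the axon population and the red channel the somas (both delta-F/F).
#'   The truth records soma specs, the per-stimulus axon state and high/low
#'   labels actually applied.
#' @export
simulate_tuning_experiment <- function(somas, n_axons = 20, n_repeats = 10,
                                       n_positions = 2, frame_rate = 10,
                                       seed = 1) {
  if (length(somas) < 1) stop("need at least one soma spec")
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  set.seed(as.integer(seed))

  directions <- seq(0, 315, by = 45)
  grid <- expand.grid(direction = directions, position_index = seq_len(n_positions))
  onsets <- numeric(0)
  stim <- NULL
  t0 <- 1
  for (r in seq_len(n_repeats)) {
    ord <- sample(nrow(grid))
    block <- grid[ord, ]
    block$onset <- t0 + seq_len(nrow(block)) - 1
    stim <- rbind(stim, block)
    t0 <- t0 + nrow(block)
  }
  stim <- stim[c("onset", "direction", "position_index")]
  duration <- t0 + 2
  dt <- 1 / frame_rate
  frame_times <- seq(dt / 2, duration, by = dt)
  nf <- length(frame_times)
  ns <- nrow(stim)

  # slow multiplicative axon-population state: smoothed log-normal walk
  z <- .running_mean(stats::rnorm(nf), as.integer(10 * frame_rate))
  state <- exp(4 * z)
  axons <- matrix(0, n_axons, nf)
  for (a in seq_len(n_axons)) {
    gain <- stats::runif(1, 0.5, 1.5)
    axons[a, ] <- gain * state + stats::rnorm(nf, 0, 0.05)
  }
  pop_per_stim <- vapply(
    seq_len(ns),
    function(k) {
      mean(.window_mean(axons, frame_times, stim$onset[k], stim$onset[k] + 1))
    },
    numeric(1)
  )
  high <- pop_per_stim > stats::median(pop_per_stim)

  soma_vals <- matrix(0, length(somas), nf)
  resp_truth <- matrix(0, length(somas), ns)
  for (j in seq_along(somas)) {
    sp <- somas[[j]]
    m <- sp$modulator_interaction
    gp <- ifelse(high, m, 1)
    gn <- if (sp$modulator_target == "pref_only") rep(1, ns) else gp
    for (k in seq_len(ns)) {
      r <- .tuning_curve(sp, stim$direction[k], gp[k], gn[k])
      resp_truth[j, k] <- r
      ii <- .frames_in(frame_times, stim$onset[k], stim$onset[k] + 1)
      soma_vals[j, ii] <- r
    }
    if (sp$noise_sd > 0) {
      soma_vals[j, ] <- soma_vals[j, ] + stats::rnorm(nf, 0, sp$noise_sd)
    }
  }

  fl <- list(
    green = fluorescence_set(axons, frame_times,
      channel = "green",
      roi_pixels = sample(4:40, n_axons, replace = TRUE), kind = "dff"
    ),
    red = fluorescence_set(soma_vals, frame_times,
      channel = "red",
      roi_pixels = sample(40:200, length(somas), replace = TRUE), kind = "dff"
    )
  )
  empty_trials <- data.frame(
    trial_id = integer(0), trial_type = character(0), side = character(0),
    contrast = numeric(0), tone_time = numeric(0), stim_on = numeric(0),
    stim_off = numeric(0), response = character(0), correct = logical(0),
    reward_time = numeric(0), airpuff_time = numeric(0)
  )
  session <- session_record(
    trials = empty_trials, licks = numeric(0), fluorescence = fl,
    stimuli = stim, duration = duration
  )
  truth <- list(
    somas = somas, high = high, pop_per_stim = pop_per_stim,
    responses = resp_truth, seed = as.integer(seed)
  )
  list(session = session, truth = truth)
}

#' Simulate pupil landmark frames
#'
#' Places eight pupil markers on a known per-frame ellipse at octagon
#' angles (plus Gaussian jitter), four eyelid markers at fixed positions,
#' and optionally displaces markers outside the eye contour (outliers) or
#' pushes all pupil markers above the upper eyelid parabola (blinks).
#'
#' @param ellipse_truth data.frame with columns `frame_time, cx, cy, a, b`
#'   and optional `theta` (deg, default 0) and `blink` (logical).
#' @param eye_geometry named list of eyelid marker coordinates `medial`,
#'   `lateral`, `superior`, `inferior`, each `c(x, y)`.
#' @param jitter_sd marker jitter sd (px).
#' @param outlier_rate per-marker probability of being displaced outside
#'   the eye contour.
#' @param seed integer RNG seed.
#' @return pupil landmark table (one row per frame) in the on-disk layout:
#'   `frame_time`, then `<marker>_x`, `<marker>_y`, `<marker>_valid` for the
#'   four eyelid markers and `pupil_1` .. `pupil_8`.
#' @export
simulate_pupil_frames <- function(ellipse_truth, eye_geometry,
                                  jitter_sd = 0, outlier_rate = 0, seed = 1) {
  set.seed(as.integer(seed))
  contour <- eye_contour(
    medial = eye_geometry$medial, lateral = eye_geometry$lateral,
    superior = eye_geometry$superior, inferior = eye_geometry$inferior
  )
  if (!contour$valid) stop("degenerate eye geometry", call. = FALSE)
  if (is.null(ellipse_truth$theta)) ellipse_truth$theta <- 0
  if (is.null(ellipse_truth$blink)) ellipse_truth$blink <- FALSE

  # outliers/blinks go well above the upper eyelid
  out_base <- eye_geometry$superior +
    2 * (eye_geometry$superior - (eye_geometry$medial + eye_geometry$lateral) / 2)

  angles <- (0:7) * 45 * pi / 180
  nfr <- nrow(ellipse_truth)
  cols <- list(frame_time = ellipse_truth$frame_time)
  eye_pts <- list(
    eye_medial = eye_geometry$medial, eye_lateral = eye_geometry$lateral,
    eye_superior = eye_geometry$superior, eye_inferior = eye_geometry$inferior
  )
  for (nm in names(eye_pts)) {
    cols[[paste0(nm, "_x")]] <- rep(eye_pts[[nm]][1], nfr) +
      stats::rnorm(nfr, 0, jitter_sd / 4)
    cols[[paste0(nm, "_y")]] <- rep(eye_pts[[nm]][2], nfr) +
      stats::rnorm(nfr, 0, jitter_sd / 4)
    cols[[paste0(nm, "_valid")]] <- rep(TRUE, nfr)
  }
  px <- py <- matrix(0, nfr, 8)
  for (i in seq_len(nfr)) {
    th <- ellipse_truth$theta[i] * pi / 180
    ex <- ellipse_truth$a[i] * cos(angles)
    ey <- ellipse_truth$b[i] * sin(angles)
    x <- ellipse_truth$cx[i] + ex * cos(th) - ey * sin(th)
    y <- ellipse_truth$cy[i] + ex * sin(th) + ey * cos(th)
    if (isTRUE(ellipse_truth$blink[i])) {
      x <- out_base[1] + stats::rnorm(8, 0, 1)
      y <- out_base[2] + stats::rnorm(8, 0, 1)
    } else {
      if (!all(in_eye_contour(cbind(x, y), contour))) {
        stop("true ellipse not inside the eye contour", call. = FALSE)
      }
      x <- x + stats::rnorm(8, 0, jitter_sd)
      y <- y + stats::rnorm(8, 0, jitter_sd)
      is_out <- stats::runif(8) < outlier_rate
      x[is_out] <- out_base[1] + stats::rnorm(sum(is_out), 0, 1)
      y[is_out] <- out_base[2] + stats::rnorm(sum(is_out), 0, 1)
    }
    px[i, ] <- x
    py[i, ] <- y
  }
  for (k in 1:8) {
    cols[[paste0("pupil_", k, "_x")]] <- px[, k]
    cols[[paste0("pupil_", k, "_y")]] <- py[, k]
    cols[[paste0("pupil_", k, "_valid")]] <- rep(TRUE, nfr)
  }
  as.data.frame(cols)
}
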