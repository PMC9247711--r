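test_that("identical seeds reproduce sessions bit for bit", {
  b <- replicate(3, bouton_spec(lick_rate = 0.05, reward = 0.2), simplify = FALSE)
  a <- simulate_session(task_config(n_trials = 15), agent_params(), b, seed = 42)
  c <- simulate_session(task_config(n_trials = 15), agent_params(), b, seed = 42)
  d <- simulate_session(task_config(n_trials = 15), agent_params(), b, seed = 43)
  expect_identical(a$session$trials, c$session$trials)
  expect_identical(a$session$licks, c$session$licks)
  expect_identical(
    a$session$fluorescence$green$values,
    c$session$fluorescence$green$values
  )
  expect_false(identical(a$session$licks, d$session$licks))
})

test_that("generated sessions always pass validation", {
  configs <- list(
    task_config(n_trials = 10),
    task_config(n_trials = 10, sides = c("contra", "ipsi"), contrasts = c(0.1, 0.5)),
    task_config(n_trials = 10, frame_rate = 5)
  )
  agents <- list(
    agent_params(),
    agent_params(hit_rate = 1, fa_rate = 0),
    agent_params(accuracy_drift_sd = 0.2)
  )
  for (cfg in configs) {
    for (ag in agents) {
      sim <- simulate_session(cfg, ag, list(bouton_spec()), seed = 3)
      expect_length(validate_session(sim$session), 0)
    }
  }
})

test_that("trial timing honours the task clock", {
  cfg <- task_config(n_trials = 25)
  sim <- simulate_session(cfg, boutons = list(bouton_spec()), seed = 9)
  tr <- sim$session$trials
  expect_equal(tr$stim_on - tr$tone_time, rep(1, 25))
  expect_equal(tr$stim_off - tr$stim_on, rep(4, 25))
  gaps <- tr$tone_time[-1] - tr$stim_off[-25]
  expect_true(all(gaps >= cfg$quiescent_range[1] - 1e-9))
  # rewards land in the response window
  rw <- tr$reward_time[!is.na(tr$reward_time)]
  so <- tr$stim_on[!is.na(tr$reward_time)]
  expect_true(all(rw >= so + 2 & rw < so + 4))
})

test_that("a degenerate perfect agent yields all-correct trials", {
  sim <- simulate_session(
    task_config(n_trials = 30),
    agent_params(hit_rate = 1, fa_rate = 0),
    list(bouton_spec()),
    seed = 4
  )
  expect_true(all(sim$session$trials$correct))
})

test_that("zero couplings and zero noise give constant baseline traces", {
  b <- list(bouton_spec(baseline_rate = 0, noise_sd = 0))
  sim <- simulate_session(task_config(n_trials = 5), agent_params(), b,
    seed = 8, emit = "dff"
  )
  expect_equal(max(abs(sim$session$fluorescence$green$values)), 0)
})

test_that("empirical hit fraction matches the binomial oracle at n = 200", {
  sim <- simulate_session(
    task_config(n_trials = 200),
    agent_params(hit_rate = 0.8, fa_rate = 0.2),
    list(bouton_spec()),
    seed = 123
  )
  tr <- sim$session$trials
  go <- tr$trial_type == "go"
  hit_frac <- mean(tr$response[go] == "lick")
  n_go <- sum(go)
  ci <- qnorm(0.995) * sqrt(0.8 * 0.2 / n_go)
  expect_lt(abs(hit_frac - 0.8), ci)
  fa_frac <- mean(tr$response[!go] == "lick")
  expect_lt(abs(fa_frac - 0.2), qnorm(0.995) * sqrt(0.2 * 0.8 / sum(!go)))
})

test_that("rewarded licking is rhythmic above 6 Hz within bouts", {
  sim <- simulate_session(
    task_config(n_trials = 40),
    agent_params(reward_lick_freq = 7, spontaneous_lick_rate = 0),
    list(bouton_spec()),
    seed = 21
  )
  tr <- sim$session$trials
  lk <- sim$session$licks
  rates <- c()
  for (i in which(!is.na(tr$reward_time))) {
    in_bout <- lk[lk >= tr$reward_time[i] & lk < tr$reward_time[i] + 1]
    if (length(in_bout) > 2) {
      rates <- c(rates, 1 / mean(diff(in_bout)))
    }
  }
  expect_gt(length(rates), 5)
  expect_true(all(rates > 6))
})

test_that("noiseless soma responses reproduce the ground-truth curve", {
  somas <- list(
    soma_spec(pref_direction = 90, amp_pref = 1, amp_null = 0, noise_sd = 0),
    soma_spec(pref_direction = 45, amp_pref = 0.8, amp_null = 0.3, noise_sd = 0)
  )
  sim <- simulate_tuning_experiment(somas, n_repeats = 3, seed = 5)
  tab <- build_response_table(sim$session$fluorescence$red, sim$session$stimuli)
  s1 <- tab[tab$neuron == 1, ]
  m <- tapply(s1$response, s1$direction, mean)
  expect_equal(unname(m["90"]), 0.1 + 1, tolerance = 1e-9)
  expect_equal(unname(m["270"]), 0.1, tolerance = 1e-6)
})

test_that("per-condition soma means converge to truth at the CLT rate", {
  spec <- soma_spec(pref_direction = 0, noise_sd = 0.05)
  sim <- simulate_tuning_experiment(list(spec), n_repeats = 10, seed = 6)
  tab <- build_response_table(sim$session$fluorescence$red, sim$session$stimuli)
  truth_mean <- tapply(sim$truth$responses[1, ], sim$session$stimuli$direction, mean)
  obs_mean <- tapply(tab$response, tab$direction, mean)
  n_per_dir <- nrow(sim$session$stimuli) / 8
  expect_true(all(abs(obs_mean - truth_mean) < 4 * 0.05 / sqrt(10 * n_per_dir / 10)))
})

test_that("axon population activity fluctuates over a wide range", {
  sim <- simulate_tuning_experiment(list(soma_spec()), n_repeats = 10, seed = 7)
  pop <- sim$truth$pop_per_stim
  q <- quantile(pop, c(0.2, 0.8))
  expect_gt((q[2] - q[1]) / mean(pop), 0.3)
})

test_that("pupil frames place clean octagon markers on the true ellipse", {
  eye <- list(
    medial = c(0, 0), lateral = c(40, 0),
    superior = c(20, 14), inferior = c(20, -14)
  )
  truth <- data.frame(frame_time = 0:4 / 30, cx = 20, cy = 0, a = 10, b = 10)
  pf <- simulate_pupil_frames(truth, eye, jitter_sd = 0, outlier_rate = 0, seed = 1)
  ts <- pupil_timeseries(pf)
  expect_true(all(ts$valid))
  expect_equal(ts$diameter, rep(20, 5), tolerance = 1e-9)
})

test_that("blink frames push every pupil marker outside the contour", {
  eye <- list(
    medial = c(0, 0), lateral = c(40, 0),
    superior = c(20, 14), inferior = c(20, -14)
  )
  truth <- data.frame(
    frame_time = 0:3 / 30, cx = 20, cy = 0, a = 6, b = 5,
    blink = c(FALSE, TRUE, TRUE, FALSE)
  )
  pf <- simulate_pupil_frames(truth, eye, seed = 2)
  ts <- pupil_timeseries(pf)
  expect_identical(ts$valid, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(ts$n_valid_markers[2:3], c(0L, 0L))
})

test_that("an ellipse poking outside the eye contour is rejected", {
  eye <- list(
    medial = c(0, 0), lateral = c(40, 0),
    superior = c(20, 8), inferior = c(20, -8)
  )
  truth <- data.frame(frame_time = 0, cx = 20, cy = 0, a = 25, b = 6)
  expect_error(simulate_pupil_frames(truth, eye), "contour")
})

test_that("degenerate eye geometry is a parameter error", {
  eye <- list(
    medial = c(40, 0), lateral = c(0, 0),
    superior = c(20, 8), inferior = c(20, -8)
  )
  truth <- data.frame(frame_time = 0, cx = 20, cy = 0, a = 2, b = 2)
  expect_error(simulate_pupil_frames(truth, eye), "eye geometry")
})
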