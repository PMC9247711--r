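test_that("lick rate equals the brute-force interval count", {
  ft <- seq(0.05, 60, by = 0.1)
  expect_equal(lick_rate(numeric(0), ft), rep(0L, length(ft)))
  licks <- c(10.0, 10.05, 10.1, 10.15, 10.2, 10.28)
  expect_identical(max(lick_rate(licks, ft)), 6L)
  for (seed in 1:10) {
    set.seed(seed)
    r <- sort(runif(sample(5:80, 1), 0, 60))
    expect_identical(
      as.integer(lick_rate(r, ft)),
      as.integer(oracle_lick_rate(r, ft))
    )
  }
})

test_that("a kernel-coupled bouton is declared lick correlated", {
  sim <- simulate_session(
    task_config(n_trials = 30), agent_params(),
    boutons = list(
      bouton_spec(lick_rate = 0.1, baseline_rate = 0, noise_sd = 0.02),
      bouton_spec(baseline_rate = 0.2, noise_sd = 0.05)
    ),
    seed = 61, emit = "dff"
  )
  s <- sim$session
  rate <- lick_rate(s$licks, s$fluorescence$green$frame_times)
  res <- lick_correlation_perm(s$fluorescence$green, rate,
    n_perm = 500, seed = 3
  )
  expect_true(res$significant[1])
  expect_true(res$highly_correlated[1])
  expect_gt(res$r_obs[1], 0.2)
})

test_that("every circular shift honours the minimum-shift constraint", {
  set.seed(62)
  nf <- 3000
  f <- make_fset(matrix(rnorm(2 * nf), 2), frame_rate = 10)
  rate <- rpois(nf, 0.3)
  res <- lick_correlation_perm(f, rate, n_perm = 1000, min_shift_s = 10, seed = 9)
  shifts <- attr(res, "shifts")
  expect_length(shifts, 1000)
  expect_true(all(shifts >= 100 & shifts <= nf - 100))
  res2 <- lick_correlation_perm(f, rate, n_perm = 1000, min_shift_s = 10, seed = 9)
  expect_identical(res$p_perm, res2$p_perm)
})

test_that("zero-variance traces are excluded from the permutation test", {
  nf <- 2500
  set.seed(63)
  v <- rbind(rnorm(nf), rep(1, nf))
  res <- lick_correlation_perm(make_fset(v), rpois(nf, 0.3),
    n_perm = 100, seed = 1
  )
  expect_identical(res$excluded, c(FALSE, TRUE))
  expect_true(is.na(res$r_obs[2]))
  expect_false(res$significant[2])
})

test_that("permutation p-values are within their defined range", {
  set.seed(64)
  nf <- 2500
  v <- matrix(rnorm(5 * nf), 5)
  res <- lick_correlation_perm(make_fset(v), rpois(nf, 0.3),
    n_perm = 200, seed = 2
  )
  expect_true(all(res$p_perm >= 1 / 201 & res$p_perm <= 1))
  expect_identical(res$significant, res$r_obs > res$null_quantile_95)
})

test_that("bout detection matches the textbook cases", {
  tr <- make_trials(2)
  b <- detect_bouts(c(5.0, 5.2, 5.4), tr)
  expect_identical(nrow(b), 1L)
  expect_equal(b$start, 5.0)
  # a lick 0.5 s before the triple breaks the pre-silence requirement
  expect_identical(nrow(detect_bouts(c(4.5, 5.0, 5.2, 5.4), tr)), 0L)
  # exactly 0.5 s span fails the strict within-0.5 s definition
  expect_identical(nrow(detect_bouts(c(5.0, 5.2, 5.5), tr)), 0L)
})

test_that("bout detection equals the exhaustive oracle on fuzzed rasters", {
  tr <- make_trials(2)
  for (seed in 1:300) {
    set.seed(seed)
    n <- sample(0:25, 1)
    licks <- sort(round(runif(n, 0, 20), 2))
    licks <- licks[!duplicated(licks)]
    got <- detect_bouts(licks, tr)$start
    want <- oracle_bouts(licks)
    expect_identical(got, if (is.null(want)) numeric(0) else as.numeric(want))
  }
})

test_that("bouts are labelled rewarded inside go reward periods", {
  tr <- make_trials(2) # go trial 1 rewarded at stim_on + 2.2 = 8.2
  licks <- c(8.3, 8.45, 8.58, 30.0, 30.1, 30.2)
  b <- detect_bouts(licks, tr)
  expect_identical(b$rewarded, c(TRUE, FALSE))
})

# constant-activity session with controllable per-side reward-period levels
toy_reward_session <- function(c_level, i_level, u_level = 0.1) {
  tr <- make_trials(8,
    types = rep("go", 8),
    sides = rep(c("contra", "ipsi"), 4)
  )
  dur <- max(tr$stim_off) + 5
  ft <- seq(0.05, dur, by = 0.1)
  x <- rep(0, length(ft))
  for (i in seq_len(8)) {
    lvl <- if (tr$side[i] == "contra") c_level else i_level
    x[ft >= tr$reward_time[i] & ft < tr$stim_off[i]] <- lvl
    x[ft >= tr$stim_on[i] & ft < tr$stim_on[i] + 2] <- u_level
  }
  licks <- sort(c(tr$reward_time + 0.3, tr$stim_on + 0.5))
  list(
    trials = tr, licks = licks,
    fset = fluorescence_set(matrix(x, 1), ft, roi_pixels = 4L, kind = "dff")
  )
}

test_that("identical activity in both period types gives zero difference", {
  s <- toy_reward_session(0.5, 0.5, u_level = 0.5)
  rv <- rewarded_vs_unrewarded(s$fset, s$trials, s$licks)
  expect_equal(rv$dff_rewarded, rv$dff_unrewarded, tolerance = 1e-12)
})

test_that("the reward targeting index follows its defining arithmetic", {
  s <- toy_reward_session(0.48, 0.39)
  rv <- rewarded_vs_unrewarded(s$fset, s$trials, s$licks, scope = "per_side")
  expect_equal(rv$C_reward, 0.48, tolerance = 1e-9)
  expect_equal(rv$I_reward, 0.39, tolerance = 1e-9)
  expect_equal(rv$rti, (0.48 - 0.39) / (0.48 + 0.39), tolerance = 1e-9)

  s2 <- toy_reward_session(0.4, 0)
  rv2 <- rewarded_vs_unrewarded(s2$fset, s2$trials, s2$licks, scope = "per_side")
  expect_equal(rv2$rti, 1)
})

test_that("per-side comparison on a monocular session is an error", {
  s <- make_trials(6, types = rep("go", 6))
  ft <- seq(0.05, max(s$stim_off) + 5, by = 0.1)
  fset <- fluorescence_set(matrix(0.2, 1, length(ft)), ft, kind = "dff")
  licks <- c(s$reward_time + 0.2, s$stim_on + 0.5)
  expect_error(
    rewarded_vs_unrewarded(fset, s, sort(licks), scope = "per_side"),
    "contra and ipsi"
  )
})

test_that("periods without licking contribute no sample", {
  tr <- make_trials(4, types = rep("go", 4))
  ft <- seq(0.05, max(tr$stim_off) + 5, by = 0.1)
  x <- rep(0, length(ft))
  # activity 1.0 only in trial 1 reward period, 5.0 in trial 2 reward period
  x[ft >= tr$reward_time[1] & ft < tr$stim_off[1]] <- 1
  x[ft >= tr$reward_time[2] & ft < tr$stim_off[2]] <- 5
  fset <- fluorescence_set(matrix(x, 1), ft, kind = "dff")
  # licks only in trial 1 reward period and in an early stimulus window
  licks <- c(tr$stim_on[1] + 0.5, tr$reward_time[1] + 0.3)
  rv <- rewarded_vs_unrewarded(fset, tr, licks)
  expect_equal(rv$dff_rewarded, 1, tolerance = 1e-9) # trial 2 excluded
})

test_that("bout-matched comparison reflects a reward gain", {
  tr <- make_trials(12, types = rep(c("go", "nogo"), 6))
  dur <- max(tr$stim_off) + 10
  ft <- seq(0.05, dur, by = 0.1)
  g <- 2.0
  base <- 0.4
  x <- rep(0, length(ft))
  licks <- c()
  for (i in which(!is.na(tr$reward_time))) {
    t0 <- tr$reward_time[i]
    licks <- c(licks, t0, t0 + 0.15, t0 + 0.3)
    x[ft >= t0 & ft < t0 + 0.5] <- g * base
  }
  for (i in which(tr$trial_type == "nogo")) {
    t0 <- tr$stim_off[i] + 2
    licks <- c(licks, t0, t0 + 0.15, t0 + 0.3)
    x[ft >= t0 & ft < t0 + 0.5] <- base
  }
  fset <- fluorescence_set(matrix(x, 1), ft, kind = "dff")
  bouts <- detect_bouts(sort(licks), tr)
  expect_true(any(bouts$rewarded) && any(!bouts$rewarded))
  bm <- bout_matched_comparison(fset, bouts)
  expect_equal(bm$dff_rewarded / bm$dff_unrewarded, g, tolerance = 1e-9)
  expect_false(bm$degenerate)
})

test_that("bout-matched comparison flags single-bout classes and errors on empty", {
  tr <- make_trials(2)
  ft <- seq(0.05, 40, by = 0.1)
  fset <- fluorescence_set(matrix(rnorm(length(ft)), 1), ft, kind = "dff")
  one_each <- data.frame(
    start = c(8.3, 20.0), lick2 = c(8.45, 20.15), lick3 = c(8.6, 20.3),
    rewarded = c(TRUE, FALSE)
  )
  bm <- bout_matched_comparison(fset, one_each)
  expect_true(bm$degenerate)
  no_unrew <- one_each[1, ]
  expect_error(bout_matched_comparison(fset, no_unrew), "unrewarded")
})
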