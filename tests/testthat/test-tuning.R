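# noiseless response table straight from a ground-truth tuning curve
truth_table <- function(spec, n_repeats = 4, noise_sd = 0) {
  dirs <- seq(0, 315, by = 45)
  grid <- expand.grid(direction = dirs, rep = seq_len(n_repeats))
  curve <- axontools:::.tuning_curve(spec, grid$direction)
  data.frame(
    neuron = 1L, direction = grid$direction, position_index = 1L,
    stim_index = seq_len(nrow(grid)),
    response = curve + rnorm(nrow(grid), 0, noise_sd)
  )
}

test_that("response windows equal their brute-force recomputation", {
  set.seed(71)
  ft <- seq(0.05, 100, by = 0.1)
  v <- matrix(rnorm(2 * length(ft)), 2)
  f <- fluorescence_set(v, ft, channel = "red", kind = "dff")
  stim <- data.frame(
    onset = seq(2, 90, by = 1),
    direction = rep(seq(0, 315, 45), length.out = 89), position_index = 1L
  )
  tab <- build_response_table(f, stim)
  for (k in sample(nrow(stim), 6)) {
    idx <- which(ft >= stim$onset[k] & ft < stim$onset[k] + 1)
    want <- mean(v[2, idx])
    got <- tab$response[tab$neuron == 2 & tab$stim_index == k]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("a constant trace yields equal condition means everywhere", {
  ft <- seq(0.05, 50, by = 0.1)
  f <- fluorescence_set(matrix(0.3, 1, length(ft)), ft, kind = "dff")
  stim <- data.frame(
    onset = 1:40, direction = rep(seq(0, 315, 45), 5), position_index = 1L
  )
  tab <- build_response_table(f, stim)
  expect_equal(var(tab$response), 0)
})

test_that("responsiveness testing is calibrated and powered", {
  # strong tuning, low noise: detected
  set.seed(72)
  spec <- soma_spec(amp_pref = 1, noise_sd = 0.05)
  tab <- truth_table(spec, n_repeats = 5, noise_sd = 0.05)
  expect_true(test_responsive(tab)$responsive)

  # null: rejection fraction near the nominal level
  n_neurons <- 400
  tabs <- lapply(seq_len(n_neurons), function(nn) {
    t1 <- truth_table(soma_spec(amp_pref = 0, amp_null = 0, offset = 0.2),
      n_repeats = 4, noise_sd = 0.1
    )
    t1$neuron <- nn
    t1$stim_index <- t1$stim_index + (nn - 1) * max(t1$stim_index)
    t1
  })
  res <- test_responsive(do.call(rbind, tabs))
  frac <- mean(res$responsive)
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / n_neurons)
  expect_lt(abs(frac - 0.05), ci + 0.01)

  # zero-variance data are degenerate, not responsive
  flat <- truth_table(soma_spec(amp_pref = 0, amp_null = 0), noise_sd = 0)
  resf <- test_responsive(flat)
  expect_true(resf$degenerate)
  expect_false(resf$responsive)
})

test_that("noiseless double-Gaussian parameters are recovered", {
  spec <- soma_spec(
    pref_direction = 90, amp_pref = 1, amp_null = 0.4,
    width_sigma = 25, offset = 0.1, noise_sd = 0
  )
  fit <- fit_tuning(truth_table(spec), 1)
  expect_true(fit$converged)
  expect_equal(fit$pref_direction, 90)
  expect_lt(abs(fit$A1 - 1), 1e-3)
  expect_lt(abs(fit$A2 - 0.4), 1e-3)
  expect_lt(abs(fit$sigma - 25), 1e-2)
  expect_lt(abs(fit$offset - 0.1), 1e-3)
  expect_gt(fit$r_squared, 0.999)
  expect_equal(fit$dsi, (1.1 - 0.5) / (1.1 + 0.5), tolerance = 1e-3)
})

test_that("a sharply tuned cell without offset has an OSI near one", {
  spec <- soma_spec(
    pref_direction = 0, amp_pref = 1, amp_null = 0,
    width_sigma = 20, offset = 0, noise_sd = 0
  )
  fit <- fit_tuning(truth_table(spec), 1)
  expect_gt(fit$osi, 0.99)
})

test_that("flat responses fit poorly and fail the r-squared gate", {
  spec <- soma_spec(amp_pref = 0, amp_null = 0, offset = 0.2, noise_sd = 0)
  fit <- fit_tuning(truth_table(spec, noise_sd = 0), 1)
  expect_lt(fit$A1, 1e-3)
  expect_lt(fit$A2, 1e-3)
  expect_identical(fit$r_squared, 0)
  expect_lt(fit$r_squared, 0.3) # excluded by the fit-quality gate
})

test_that("OSI and DSI stay in [0,1] for nonnegative fitted responses", {
  set.seed(74)
  for (k in 1:12) {
    spec <- soma_spec(
      pref_direction = sample(seq(0, 315, 45), 1),
      amp_pref = runif(1, 0.2, 2), amp_null = runif(1, 0, 1.5),
      width_sigma = runif(1, 15, 60), offset = runif(1, 0, 0.5),
      noise_sd = 0
    )
    fit <- fit_tuning(truth_table(spec), 1)
    if (!fit$converged) next
    if (min(fit$R_pref, fit$R_ortho, fit$R_pref_dir_plus180) >= 0) {
      expect_true(fit$osi >= 0 && fit$osi <= 1)
      expect_true(fit$dsi >= 0 && fit$dsi <= 1)
    }
  }
})

test_that("the best stimulus position is selected before direction fitting", {
  spec <- soma_spec(pref_direction = 45, noise_sd = 0)
  tab1 <- truth_table(spec)
  tab2 <- tab1
  tab2$position_index <- 2L
  tab2$response <- 0.1 * tab2$response
  tab2$stim_index <- tab2$stim_index + max(tab1$stim_index)
  fit <- fit_tuning(rbind(tab1, tab2), 1)
  expect_identical(fit$best_position, 1)
  expect_lt(abs(fit$A1 - spec$amp_pref), 1e-3)
})

test_that("a null modulator leaves the high/low OSI comparison flat", {
  sim <- simulate_tuning_experiment(
    replicate(12, soma_spec(modulator_interaction = 1, noise_sd = 0.03),
      simplify = FALSE
    ),
    n_repeats = 12, seed = 75
  )
  tab <- build_response_table(sim$session$fluorescence$red, sim$session$stimuli)
  pop <- axon_population_activity(sim$session$fluorescence$green, sim$session$stimuli)
  sp <- split_and_compare(tab, pop)
  expect_gt(length(sp$neurons), 5)
  expect_gt(sp$osi_kw_p, 0.01)
  expect_lt(mean(abs(sp$osi_high - sp$osi_low)), 0.2)
})

test_that("a preferred-amplitude modulator raises OSI on high trials", {
  sim <- simulate_tuning_experiment(
    replicate(
      14,
      soma_spec(
        modulator_interaction = 2, modulator_target = "pref_only",
        amp_pref = 1, amp_null = 0.2, offset = 0.3, noise_sd = 0.03
      ),
      simplify = FALSE
    ),
    n_repeats = 12, seed = 76
  )
  tab <- build_response_table(sim$session$fluorescence$red, sim$session$stimuli)
  pop <- axon_population_activity(sim$session$fluorescence$green, sim$session$stimuli)
  sp <- split_and_compare(tab, pop)
  expect_gt(length(sp$neurons), 7)
  expect_gt(mean(sp$osi_high - sp$osi_low), 0)
  expect_lt(sp$osi_kw_p, 0.05)
})

test_that("identical halves by construction give zero preferred-direction shift", {
  specs <- replicate(
    6, soma_spec(pref_direction = sample(seq(0, 315, 45), 1), noise_sd = 0),
    simplify = FALSE
  )
  sim <- simulate_tuning_experiment(specs, n_repeats = 8, seed = 77)
  tab <- build_response_table(sim$session$fluorescence$red, sim$session$stimuli)
  pop <- axon_population_activity(sim$session$fluorescence$green, sim$session$stimuli)
  # noiseless responses make the responsiveness ANOVA complain about an
  # essentially perfect fit; that is the point of this construction
  sp <- suppressWarnings(split_and_compare(tab, pop))
  expect_gt(length(sp$neurons), 0)
  expect_true(all(sp$delta_pref == 0))
})

test_that("the median split is balanced and deterministic", {
  set.seed(78)
  tab <- truth_table(soma_spec(noise_sd = 0.02), n_repeats = 6, noise_sd = 0.02)
  pop <- runif(max(tab$stim_index))
  sp1 <- split_and_compare(tab, pop)
  sp2 <- split_and_compare(tab, pop)
  expect_identical(sp1$high_ids, sp2$high_ids)
  expect_lte(abs(length(sp1$high_ids) - length(sp1$low_ids)), 1)
  expect_identical(sort(c(sp1$high_ids, sp1$low_ids)), sort(unique(tab$stim_index)))
})
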