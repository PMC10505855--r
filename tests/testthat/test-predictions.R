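test_that("HPD intervals are shortest windows with the right mass", {
  expect_equal(hpd_interval(rep(3.2, 25)), c(3.2, 3.2))

  x <- 1:100
  h <- hpd_interval(x, 0.89)
  # enumeration oracle: every 89-point window has width 88
  expect_equal(h[2] - h[1], 88)
  m <- ceiling(0.89 * 100)
  widths <- sapply(1:(100 - m + 1), function(i) x[i + m - 1] - x[i])
  expect_equal(h[2] - h[1], min(widths))

  # skewed samples: HPD hugs the mode and beats the equal-tailed interval
  set.seed(7)
  e <- rexp(5000)
  h2 <- hpd_interval(e, 0.89)
  et <- unname(quantile(e, c(0.055, 0.945)))
  expect_lt(h2[1], et[1])
  expect_lt(h2[2] - h2[1], et[2] - et[1])
  expect_lt(h2[1], 0.01)  # lower bound at the minimum

  # monotone in mass: the 50% interval nests inside the 89% interval
  z <- rnorm(4000)
  h50 <- hpd_interval(z, 0.5)
  h89 <- hpd_interval(z, 0.89)
  expect_gte(h50[1], h89[1])
  expect_lte(h50[2], h89[2])

  expect_error(hpd_interval(1:10), "at least 20")
})

test_that("profile predictions equal the deterministic push-through for delta draws", {
  pr <- random_params(50)
  sc <- covariate_scaling(get_std_trips())
  fit <- make_fake_fit(rep(list(pr), 25), scaling = sc)
  profile <- profile_preset("reference_adult")
  pred <- profile_prediction(fit, profile)

  row <- tibble::tibble(
    gender = "man", age_class = "40to50", season = "ice",
    patch = NA_character_,
    income_std = 0,
    in_degree_std = (4 - sc$center[sc$covariate == "in_degree"]) /
      sc$scale[sc$covariate == "in_degree"],
    out_degree_std = (4 - sc$center[sc$covariate == "out_degree"]) /
      sc$scale[sc$covariate == "out_degree"],
    group_size_std = 0
  )
  p_choice <- softmax_probs(drop(linear_predictor_choice(row, pr)))
  expect_equal(unname(pred$summary$choice_mean), unname(p_choice),
               tolerance = 1e-12)
  expect_equal(pred$summary$choice_lo, pred$summary$choice_hi,
               tolerance = 1e-12)
  per_patch <- row[rep(1, 7), ]
  per_patch$patch <- patch_levels()
  expect_equal(unname(pred$summary$success_mean),
               unname(success_prob(per_patch, pr)), tolerance = 1e-12)
})

test_that("per-draw choice probabilities form a simplex", {
  fit <- get_full_fit()
  pred <- profile_prediction(fit, profile_preset("young_high_income"))
  expect_lt(max(abs(rowSums(pred$choice_draws) - 1)), 1e-12)
  expect_true(all(pred$summary$choice_lo <= pred$summary$choice_mean + 1e-12))
  expect_true(all(pred$summary$choice_hi >= pred$summary$choice_mean - 1e-12))
  expect_true(all(pred$summary$success_lo >= 0 &
                    pred$summary$success_hi <= 1))
})

test_that("income sweeps follow the generative income effect and respect range", {
  sc <- covariate_scaling(get_std_trips())
  # fabricated posterior: a single parameter set with a positive income
  # effect on winter inland choice
  pr <- model_params()
  pr$beta_choice["winter_inland", "income_std"] <- 1
  fit <- make_fake_fit(rep(list(pr), 25), scaling = sc)

  rng <- sc[sc$covariate == "income", ]
  grid <- seq(rng$min, rng$max, length.out = 5)
  sw <- income_sweep(fit, profile_preset("reference_adult"), grid)
  wi <- sw[sw$patch == "winter_inland", ]
  expect_equal(nrow(wi), 5)
  expect_true(all(diff(wi$choice_mean) > 0))

  one <- income_sweep(fit, profile_preset("reference_adult"), grid[2])
  direct <- profile_prediction(fit, {
    p <- profile_preset("reference_adult"); p$raw$income <- grid[2]; p
  })
  expect_equal(one$choice_mean, direct$summary$choice_mean,
               tolerance = 1e-12)

  expect_error(
    income_sweep(fit, profile_preset("reference_adult"), rng$max + 1),
    "outside the observed range")
})

test_that("patch removal renormalizes the remaining choice mass", {
  sc <- covariate_scaling(get_std_trips())
  pr <- random_params(60)
  fit <- make_fake_fit(rep(list(pr), 25), scaling = sc)
  profile <- profile_preset("adult_low_income")

  base <- profile_prediction(fit, profile)
  none <- scenario_patch_removal(fit, profile, character(0))
  expect_equal(none$summary, base$summary, tolerance = 1e-12)

  rm1 <- scenario_patch_removal(fit, profile, "winter_marine")
  expect_true(all(rm1$choice_draws[, "winter_marine"] == 0))
  # renormalization algebra: p_j / (1 - p_removed), an independent route
  keep <- setdiff(patch_levels(), "winter_marine")
  manual <- base$choice_draws[, keep] /
    (1 - base$choice_draws[, "winter_marine"])
  expect_equal(rm1$choice_draws[, keep], manual, tolerance = 1e-12)
  # success probabilities unchanged for remaining patches
  expect_equal(rm1$success_draws, base$success_draws, tolerance = 1e-12)

  # uniform draws: removing one of seven leaves 1/6 each
  fit_u <- make_fake_fit(rep(list(model_params()), 25), scaling = sc)
  rm_u <- scenario_patch_removal(fit_u, profile, "winter_marine")
  expect_equal(unname(rm_u$summary$choice_mean[rm_u$summary$patch != "winter_marine"]),
               rep(1 / 6, 6), tolerance = 1e-12)

  expect_error(scenario_patch_removal(fit, profile, patch_levels()),
               "every patch")
  expect_error(scenario_patch_removal(fit, profile, "lunar"), "unknown")
})

test_that("recovery report is exact for delta-mass posteriors", {
  tp <- random_params(70)
  fits <- list(make_fake_fit(rep(list(tp), 25)),
               make_fake_fit(rep(list(tp), 25)))
  rep_ <- parameter_recovery_report(tp, fits)
  expect_true(all(abs(rep_$bias) < 1e-12))
  expect_true(all(rep_$rmse < 1e-12))
  expect_true(all(rep_$coverage == 1))
  expect_true(all(rep_$n_fits == 2))
})

test_that("HPD coverage is calibrated on synthetic Gaussian posteriors", {
  # classic conjugate setup: truth fixed, replicate posterior N(mu_r, 1)
  # with mu_r ~ N(truth, 1); the 89% HPD then covers the truth with
  # probability 0.89 by construction
  set.seed(123)
  truth <- model_params()
  fits <- lapply(1:40, function(r) {
    mu <- rnorm(1)
    draws <- tibble::tibble(
      .chain = 1L, .draw = 1:800,
      `alpha_choice[winter_inland,ice]` = rnorm(800, mu, 1)
    )
    structure(list(draws = draws, warn = FALSE,
                   model = model_options(), scaling = NULL, n_trips = 0L),
              class = "patch_fit")
  })
  rep_ <- parameter_recovery_report(truth, fits)
  expect_equal(rep_$param, "alpha_choice[winter_inland,ice]")
  expect_gte(rep_$coverage, 0.75)
  expect_lte(rep_$coverage, 0.97)

  # a single replicate reports 0/1 coverage without crashing
  one <- parameter_recovery_report(truth, fits[1])
  expect_true(one$coverage %in% c(0, 1))

  mismatched <- list(fits[[1]], make_fake_fit(list(model_params())))
  expect_error(parameter_recovery_report(truth, mismatched), "mismatched")
})

test_that("plot builders return ggplot objects", {
  sc <- covariate_scaling(get_std_trips())
  fit <- make_fake_fit(rep(list(random_params(4)), 25), scaling = sc)
  pred <- profile_prediction(fit, profile_preset("reference_adult"))
  expect_s3_class(ggplot2::autoplot(pred), "ggplot")
  rng <- sc[sc$covariate == "income", ]
  sw <- income_sweep(fit, profile_preset("reference_adult"),
                     seq(rng$min, rng$max, length.out = 3))
  expect_s3_class(plot_income_sweep(sw), "ggplot")
  expect_s3_class(plot_income_sweep(sw, "success"), "ggplot")
})
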