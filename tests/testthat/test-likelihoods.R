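one_row <- function(patch = "winter_marine", season = "ice",
                    gender = "man", age_class = "under30") {
  tibble::tibble(
    gender = gender, age_class = age_class, season = season, patch = patch,
    success = 1L, income_std = 0.5, in_degree_std = -0.3,
    out_degree_std = 1.1, group_size_std = 0.2
  )
}

test_that("choice linear predictor assembles its terms correctly", {
  row <- one_row()
  expect_equal(drop(linear_predictor_choice(row, model_params())),
               setNames(rep(0, 7), patch_levels()))

  p1 <- model_params()
  p1$alpha_choice["winter_marine", "ice"] <- 1.5
  eta <- drop(linear_predictor_choice(row, p1))
  expect_equal(unname(eta["winter_marine"]), 1.5)
  expect_equal(sum(abs(eta)), 1.5)

  # random parameters against an independent hand-built dot product
  pr <- random_params(11)
  eta2 <- drop(linear_predictor_choice(row, pr))
  x <- c(0.5, -0.3, 1.1, 0.2)
  for (k in 1:7) {
    expect_equal(
      unname(eta2[k]),
      pr$alpha_choice[k, "ice"] + pr$gamma_choice[k, "man"] +
        pr$age_choice[k, "under30"] + sum(pr$beta_choice[k, ] * x),
      tolerance = 1e-12
    )
  }
})

test_that("softmax is a stable simplex map with shift invariance and masking", {
  expect_equal(softmax_probs(rep(0, 7)), rep(1 / 7, 7))
  expect_equal(softmax_probs(c(log(2), rep(0, 6))),
               c(2 / 8, rep(1 / 8, 6)))
  eta <- c(2.2, -1, 0.4, 0, 7, -3, 1)
  expect_equal(softmax_probs(eta), softmax_probs(eta + 123.4),
               tolerance = 1e-12)
  # no overflow at |eta| = 700
  expect_true(all(is.finite(softmax_probs(c(700, -700, rep(0, 5))))))

  p <- softmax_probs(setNames(rep(0, 7), patch_levels()),
                     mask = c("tidal", "incidental"))
  expect_equal(unname(p[c("tidal", "incidental")]), c(0.5, 0.5))
  expect_true(all(p[setdiff(patch_levels(), c("tidal", "incidental"))] == 0))
  expect_error(softmax_probs(rep(0, 7), mask = rep(FALSE, 7)),
               "mask excludes all")

  # simplex property over many random vectors
  set.seed(99)
  etas <- matrix(rnorm(1e4 * 7, sd = 5), ncol = 7)
  ps <- softmax_probs(etas)
  expect_lt(max(abs(rowSums(ps) - 1)), 1e-12)
  expect_true(all(ps >= 0))
})

test_that("choice log-likelihood matches the brute-force oracle", {
  row <- one_row()
  expect_equal(choice_loglik(row, model_params()), log(1 / 7))
  many <- row[rep(1, 13), ]
  many$trip_id <- as.character(1:13)
  expect_equal(choice_loglik(many, model_params()), 13 * log(1 / 7))

  std <- get_std_trips()[1:50, ]
  pr <- random_params(21)
  expect_equal(choice_loglik(std, pr), brute_choice_loglik(std, pr),
               tolerance = 1e-10)

  expect_error(choice_loglik(row, model_params(), mask = c("tidal")),
               "probability 0 under the mask")
})

test_that("the age covariance has the squared-exponential form and is PD", {
  K <- gp_age_cov(2, 0.5, 0.1)
  expect_equal(K[1, 2], 2 * exp(-0.5), tolerance = 1e-12)
  expect_equal(diag(K), rep(2.1, 4))
  expect_equal(K, t(K))
  # limits: strong decay -> diagonal; no decay -> constant off-diagonal
  Kfar <- gp_age_cov(1, 1e6, 0.2)
  expect_equal(Kfar, diag(1.2, 4), tolerance = 1e-8)
  Kflat <- gp_age_cov(1, 1e-12, 0.2)
  expect_equal(Kflat[1, 4], 1, tolerance = 1e-9)
  expect_error(gp_age_cov(-1, 1, 1), "positive")
  expect_error(gp_age_cov(1, 0, 1), "positive")

  set.seed(12)
  for (i in 1:1000) {
    h <- rexp(3) + 1e-6
    expect_silent(chol(gp_age_cov(h[1], h[2], h[3])))
  }
})

test_that("success probability behaves like a logistic regression", {
  row <- one_row()
  expect_equal(success_prob(row, model_params()), 0.5)

  p <- model_params()
  p$alpha_succ["winter_marine", "ice"] <- qlogis(0.225)
  expect_equal(success_prob(row, p), 0.225, tolerance = 1e-12)

  # negating every parameter maps p to 1 - p
  pr <- random_params(5)
  neg <- pr
  for (b in c("alpha_succ", "gamma_succ", "beta_succ", "age_succ")) {
    neg[[b]] <- -pr[[b]]
  }
  neg$income_miss <- -pr$income_miss
  row0 <- row
  row0$income_std <- 0; row0$in_degree_std <- 0
  row0$out_degree_std <- 0; row0$group_size_std <- 0
  expect_equal(success_prob(row0, neg), 1 - success_prob(row0, pr),
               tolerance = 1e-12)
})

test_that("success log-likelihood matches the brute-force oracle and stays finite", {
  row <- one_row()
  expect_equal(success_loglik(row, model_params()), log(0.5))

  std <- get_std_trips()[31:80, ]
  pr <- random_params(8)
  expect_equal(success_loglik(std, pr), brute_success_loglik(std, pr),
               tolerance = 1e-10)

  extreme <- model_params()
  extreme$alpha_succ[, ] <- 35
  fail_row <- row; fail_row$success <- 0L
  expect_true(is.finite(success_loglik(fail_row, extreme)))
  extreme$alpha_succ[, ] <- -35
  expect_true(is.finite(success_loglik(row, extreme)))
})

test_that("log prior has its closed forms and the joint density is additive", {
  # all-zero parameter blocks: each m-parameter standard-normal block
  # contributes -(m/2) log(2 pi)
  p0 <- model_params(gp_choice = c(eta_sq = 1, rho_sq = 0.5, sigma_sq = 0.1),
                     gp_succ = c(eta_sq = 1, rho_sq = 0.5, sigma_sq = 0.1),
                     income_mu = 0.5, income_sigma = 1, income_miss = 0.5)
  pr <- default_prior_config()
  # independent recomputation: normal blocks + MVN age blocks + half-Cauchy
  # scales + imputation block
  K1 <- gp_age_cov(1, 0.5, 0.1)
  mvn0 <- -0.5 * 4 * log(2 * pi) -
    0.5 * determinant(K1, logarithm = TRUE)$modulus[1]
  expected <-
    -(14 + 14 + 28 + 14 + 14 + 4) / 2 * log(2 * pi) +  # normal blocks at 0
    8 * mvn0 +                                         # 7 choice + 1 success
    sum(dcauchy(c(1, 0.5, 0.1), 0, 1, log = TRUE) + log(2)) * 2 +
    dnorm(0.5, 0.5, 1, log = TRUE) +                   # income_mu at mode
    dcauchy(1, 0, 1, log = TRUE) + log(2) +            # income_sigma
    dnorm(0.5, 0.5, 1, log = TRUE)                     # income_miss latent
  expect_equal(log_prior(p0, pr), expected, tolerance = 1e-10)

  bad <- p0; bad$income_sigma <- -1
  expect_equal(log_prior(bad, pr), -Inf)

  std <- get_std_trips()[1:40, ]
  prm <- random_params(2)
  expect_equal(joint_log_density(std, prm),
               log_prior(prm) + choice_loglik(std, prm) +
                 success_loglik(std, prm),
               tolerance = 1e-10)
})

test_that("prior predictive is symmetric: mean choice 1/7, mean success 1/2", {
  pp <- sample_prior_predictive(n_draws = 3000, seed = 42)
  se_c <- apply(pp$choice, 2, sd) / sqrt(3000)
  expect_true(all(abs(colMeans(pp$choice) - 1 / 7) < 3 * se_c))
  se_s <- sd(rowMeans(pp$success)) / sqrt(3000)
  expect_lt(abs(mean(pp$success) - 0.5), 3 * se_s)
  # degenerate priors with all mass at zero give exactly 1/7 and 1/2
  tiny <- default_prior_config()
  for (b in c("alpha_choice", "gamma_choice", "beta_choice", "alpha_succ",
              "gamma_succ", "beta_succ")) {
    tiny[[b]]$scale <- 1e-12
  }
  tiny$gp_eta$scale <- 1e-12
  tiny$gp_sigma$scale <- 1e-12
  pp0 <- sample_prior_predictive(tiny, n_draws = 50, seed = 1)
  expect_equal(unname(colMeans(pp0$choice)), rep(1 / 7, 7),
               tolerance = 1e-6)
  expect_equal(mean(pp0$success), 0.5, tolerance = 1e-6)
})

test_that("missing income requires a bound imputation latent", {
  row <- one_row()
  row$income_std <- NA_real_
  p <- model_params(income_miss = 0.7)
  eta <- drop(linear_predictor_choice(row, p))
  p$income_miss <- NA_real_
  expect_error(linear_predictor_choice(row, p), "imputation latent")
})
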