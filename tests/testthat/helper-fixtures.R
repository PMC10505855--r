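# shared fixtures, built once per test run

.cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.cache$fx)) .cache$fx <- default_fixture()
  .cache$fx
}

get_std_trips <- function() {
  if (is.null(.cache$std)) {
    .cache$std <- standardize_covariates(get_fixture()$trips)
  }
  .cache$std
}

# one moderately sized full-model fit shared across integration tests;
# chain lengths are kept short, so convergence warnings are expected
get_full_fit <- function() {
  if (is.null(.cache$fit)) {
    .cache$fit <- suppressWarnings(fit_posterior(
      get_std_trips(),
      config = fit_config(n_chains = 2, n_warmup = 400, n_draws = 400,
                          seed = 11)
    ))
  }
  .cache$fit
}

# a patch_fit whose "draws" are the flattened parameter sets supplied —
# lets prediction algebra be checked against deterministic push-throughs
make_fake_fit <- function(params_list, scaling = NULL,
                          model = model_options()) {
  draws <- purrr::map_dfr(seq_along(params_list), function(i) {
    v <- param_vector(params_list[[i]])
    out <- tibble::as_tibble(as.list(v))
    out$.chain <- 1L
    out$.draw <- i
    out
  })
  draws <- dplyr::relocate(draws, ".chain", ".draw")
  structure(
    list(draws = draws, diagnostics = NULL, warn = FALSE,
         config = fit_config(n_chains = 1, n_draws = nrow(draws)),
         model = model, priors = default_prior_config(),
         scaling = scaling, n_trips = 0L),
    class = "patch_fit"
  )
}

# independent brute-force oracles: plain per-row loops, no shared code path
brute_choice_loglik <- function(trips, params) {
  total <- 0
  for (i in seq_len(nrow(trips))) {
    row <- trips[i, ]
    eta <- numeric(length(params$patches))
    for (k in seq_along(params$patches)) {
      eta[k] <- params$alpha_choice[k, row$season] +
        params$gamma_choice[k, row$gender] +
        params$age_choice[k, row$age_class]
      for (cv in params$covariates) {
        x <- row[[cv]]
        if (cv == "income_std" && is.na(x)) x <- params$income_miss
        eta[k] <- eta[k] + params$beta_choice[k, cv] * x
      }
    }
    p <- exp(eta) / sum(exp(eta))
    total <- total + log(p[match(row$patch, params$patches)])
  }
  total
}

brute_success_loglik <- function(trips, params) {
  total <- 0
  for (i in seq_len(nrow(trips))) {
    row <- trips[i, ]
    k <- match(row$patch, params$patches)
    theta <- params$alpha_succ[k, row$season] +
      params$gamma_succ[k, row$gender] +
      params$age_succ[row$age_class]
    for (cv in params$covariates) {
      x <- row[[cv]]
      if (cv == "income_std" && is.na(x)) x <- params$income_miss
      theta <- theta + params$beta_succ[cv] * x
    }
    p <- 1 / (1 + exp(-unname(theta)))
    total <- total + if (row$success == 1) log(p) else log(1 - p)
  }
  total
}

# random parameter set with every block populated (for oracle comparisons)
random_params <- function(seed) {
  set.seed(seed)
  model_params(
    alpha_choice = matrix(rnorm(14, 0, 0.8), 7),
    gamma_choice = matrix(rnorm(14, 0, 0.8), 7),
    beta_choice = matrix(rnorm(28, 0, 0.5), 7),
    age_choice = matrix(rnorm(28, 0, 0.5), 7),
    alpha_succ = matrix(rnorm(14, 0, 0.8), 7),
    gamma_succ = matrix(rnorm(14, 0, 0.8), 7),
    beta_succ = rnorm(4, 0, 0.5),
    age_succ = rnorm(4, 0, 0.5),
    gp_choice = c(eta_sq = 0.7, rho_sq = 0.4, sigma_sq = 0.2),
    gp_succ = c(eta_sq = 0.5, rho_sq = 0.6, sigma_sq = 0.1),
    income_mu = 0.3, income_sigma = 0.9, income_miss = -0.4
  )
}
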