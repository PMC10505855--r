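#' Highest-posterior-density interval
#'
#' The shortest contiguous interval of the sorted sample containing
#' `ceiling(mass * n)` points (shortest-sorted-window construction) —
#' deterministic and, unlike equal-tailed intervals, hugging the mode of
#' skewed distributions.
#'
#' @param samples Numeric vector (at least 20 values).
#' @param mass Probability mass, default 0.89.
#' @return `c(lo, hi)`.
#' @export
#' @examples
#' hpd_interval(rexp(1000), 0.89)  # lower bound near 0
hpd_interval <- function(samples, mass = 0.89) {
  stopifnot(mass > 0, mass < 1)
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 20) {
    stop("hpd_interval needs at least 20 samples, got ", n, call. = FALSE)
  }
  s <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1], s[n]))
  starts <- seq_len(n - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  i <- which.min(widths)
  c(s[i], s[i + m - 1])
}

#' Counterfactual harvester profile
#'
#' A single covariate profile for prediction: gender, age class, season,
#' and the model covariates either on the raw scale (converted with the
#' fit's stored scaling) or directly on the standardized scale via `std`.
#' Raw values left `NULL` sit at the sample mean (standardized 0).
#'
#' @param gender,age_class,season Categorical fields.
#' @param income,in_degree,out_degree,group_size Raw-scale covariate values
#'   (`NULL` = sample mean).
#' @param std Named list of standardized overrides, e.g.
#'   `list(income_std = 1)`; these win over raw values.
#' @return An object of class `"harvester_profile"`.
#' @export
harvester_profile <- function(gender = "man", age_class = "40to50",
                              season = "ice", income = NULL,
                              in_degree = NULL, out_degree = NULL,
                              group_size = NULL, std = list()) {
  stopifnot(gender %in% gender_levels(),
            age_class %in% age_class_levels(),
            season %in% season_levels())
  for (v in c(in_degree, out_degree)) stopifnot(v >= 0)
  structure(
    list(gender = gender, age_class = age_class, season = season,
         raw = list(income = income, in_degree = in_degree,
                    out_degree = out_degree, group_size = group_size),
         std = std),
    class = "harvester_profile"
  )
}

#' Named harvester profile presets
#'
#' * `reference_adult` — a 40-50-year-old with an average number of giving
#'   and receiving ties (in-degree 4, out-degree 4), the reference profile
#'   for income sweeps.
#' * `young_high_income` — a young adult (under 30) with
#'   higher-than-average household income (+1 sd) and good embedding in the
#'   sharing network (in-degree 8, out-degree 8).
#' * `young_high_income_30s` — the same profile in the 30-40 age class
#'   (the "young adult" label is ambiguous between the two classes; both
#'   are provided).
#' * `adult_low_income` — a 40-50-year-old with low income (-1 sd) who
#'   receives more than they give (in-degree 4, out-degree 1).
#'
#' @param name Preset name.
#' @param gender,season Passed through to [harvester_profile()].
#' @return A `"harvester_profile"`.
#' @export
profile_preset <- function(name = c("reference_adult", "young_high_income",
                                    "young_high_income_30s",
                                    "adult_low_income"),
                           gender = "man", season = "ice") {
  name <- match.arg(name)
  switch(name,
    reference_adult = harvester_profile(
      gender = gender, age_class = "40to50", season = season,
      in_degree = 4, out_degree = 4),
    young_high_income = harvester_profile(
      gender = gender, age_class = "under30", season = season,
      in_degree = 8, out_degree = 8, std = list(income_std = 1)),
    young_high_income_30s = harvester_profile(
      gender = gender, age_class = "30to40", season = season,
      in_degree = 8, out_degree = 8, std = list(income_std = 1)),
    adult_low_income = harvester_profile(
      gender = gender, age_class = "40to50", season = season,
      in_degree = 4, out_degree = 1, std = list(income_std = -1))
  )
}

# one-row standardized tibble for a profile; raw values need `scaling`
profile_row <- function(profile, scaling = NULL) {
  covs <- c("income", "in_degree", "out_degree", "group_size")
  row <- tibble::tibble(
    gender = profile$gender, age_class = profile$age_class,
    season = profile$season, patch = NA_character_
  )
  for (cv in covs) {
    std_name <- paste0(cv, "_std")
    if (!is.null(profile$std[[std_name]])) {
      row[[std_name]] <- profile$std[[std_name]]
    } else if (!is.null(profile$raw[[cv]])) {
      if (is.null(scaling)) {
        # no fitted scale available: raw values fall back to the mean
        row[[std_name]] <- 0
      } else {
        row[[std_name]] <- raw_to_std(scaling, cv, profile$raw[[cv]])
      }
    } else {
      row[[std_name]] <- 0
    }
  }
  row
}

# per-draw linear predictors at a profile: list(choice = DxK, success = DxK)
draw_predictors <- function(fit, profile) {
  draws <- fit$draws
  model <- fit$model
  patches <- model$patches
  K <- length(patches)
  D <- nrow(draws)
  row <- profile_row(profile, scaling = fit$scaling)

  col_or_zero <- function(nm) {
    if (nm %in% names(draws)) draws[[nm]] else rep(0, D)
  }
  block <- function(block_name, col_key) {
    m <- sapply(patches, function(p) {
      col_or_zero(paste0(block_name, "[", p, ",", col_key, "]"))
    })
    matrix(m, nrow = D, dimnames = list(NULL, patches))
  }

  x <- vapply(model$covariates, function(cv) row[[cv]], numeric(1))
  eta <- block("alpha_choice", row$season) +
    block("gamma_choice", row$gender) +
    block("age_choice", row$age_class)
  theta <- block("alpha_succ", row$season) +
    block("gamma_succ", row$gender)
  theta <- theta + col_or_zero(paste0("age_succ[", row$age_class, "]"))
  for (cv in model$covariates) {
    eta <- eta + block("beta_choice", cv) * x[[cv]]
    theta <- theta + col_or_zero(paste0("beta_succ[", cv, "]")) * x[[cv]]
  }
  list(choice = eta, success = theta)
}

summarize_prediction <- function(choice, success, profile, mass = 0.89) {
  patches <- colnames(choice)
  summary <- purrr::map_dfr(seq_along(patches), function(k) {
    hc <- hpd_interval(choice[, k], mass)
    hs <- hpd_interval(success[, k], mass)
    tibble::tibble(
      patch = patches[k],
      choice_mean = mean(choice[, k]), choice_lo = hc[1], choice_hi = hc[2],
      success_mean = mean(success[, k]), success_lo = hs[1],
      success_hi = hs[2]
    )
  })
  structure(
    list(choice_draws = choice, success_draws = success,
         summary = summary, profile = profile, mass = mass),
    class = "profile_prediction"
  )
}

#' @export
print.profile_prediction <- function(x, ...) {
  cat("<profile_prediction>", nrow(x$choice_draws), "draws;",
      sprintf("%.0f%% HPD\n", 100 * x$mass))
  print(x$summary)
  invisible(x)
}

#' Posterior prediction for a counterfactual profile
#'
#' For every posterior draw, computes the softmax choice probabilities over
#' the patch set and the per-patch success probability at the profile's
#' covariates, then summarizes each patch with the posterior mean and the
#' 89% HPD interval. Raw-valued profile covariates are converted with the
#' scaling stored in the fit.
#'
#' @param fit A `"patch_fit"`.
#' @param profile A [harvester_profile()].
#' @param mass HPD probability mass (default 0.89).
#' @return A `"profile_prediction"`: per-draw choice (simplex) and success
#'   matrices plus a per-patch summary tibble.
#' @export
profile_prediction <- function(fit, profile, mass = 0.89) {
  lp <- draw_predictors(fit, profile)
  choice <- softmax_probs(lp$choice)
  success <- stats::plogis(lp$success)
  summarize_prediction(choice, success, profile, mass)
}

#' Choice and success curves along an income grid
#'
#' One [profile_prediction()] per raw income value. The grid must lie
#' within the income range observed at fit time — predictions never
#' extrapolate beyond observed incomes; an out-of-range point is an error,
#' not a silent clamp.
#'
#' @param fit A `"patch_fit"` with covariate scaling attached.
#' @param profile A [harvester_profile()]; its income field is overridden
#'   by the grid.
#' @param income_grid Raw income values.
#' @param mass HPD probability mass.
#' @return A tibble: one row per (grid point, patch) with means and HPD
#'   bounds.
#' @export
income_sweep <- function(fit, profile, income_grid, mass = 0.89) {
  if (is.null(fit$scaling)) {
    stop("fit carries no covariate scaling; cannot place raw incomes",
         call. = FALSE)
  }
  rng <- fit$scaling[fit$scaling$covariate == "income", c("min", "max")]
  bad <- income_grid < rng$min | income_grid > rng$max
  if (any(bad)) {
    stop(sprintf(
      "income grid point %g outside the observed range [%g, %g]",
      income_grid[which(bad)[1]], rng$min, rng$max), call. = FALSE)
  }
  purrr::map_dfr(income_grid, function(v) {
    p <- profile
    p$raw$income <- v
    p$std$income_std <- NULL
    pred <- profile_prediction(fit, p, mass)
    dplyr::mutate(pred$summary, income = v, .before = 1)
  })
}

#' Patch-removal scenario
#'
#' Restricts the choice set (e.g. a winter with no safe floe edge removes
#' the winter marine patch) by renormalizing each posterior draw's softmax
#' probabilities over the remaining patches — equivalent to masking inside
#' the softmax. Removed patches get probability 0; each remaining patch
#' inherits the removed mass in proportion to its own probability.
#' Within-patch success probabilities are unchanged.
#'
#' @param fit A `"patch_fit"`.
#' @param profile A [harvester_profile()].
#' @param removed_patches Character vector of patches to remove.
#' @param mass HPD probability mass.
#' @return A `"profile_prediction"` over the full patch set with removed
#'   patches at exactly 0.
#' @export
scenario_patch_removal <- function(fit, profile, removed_patches,
                                   mass = 0.89) {
  patches <- fit$model$patches
  unknown <- setdiff(removed_patches, patches)
  if (length(unknown) > 0) {
    stop("unknown patch(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- !patches %in% removed_patches
  if (!any(keep)) stop("cannot remove every patch", call. = FALSE)
  lp <- draw_predictors(fit, profile)
  choice <- softmax_probs(lp$choice, mask = keep)
  success <- stats::plogis(lp$success)
  summarize_prediction(choice, success, profile, mass)
}

#' Parameter-recovery report across replicate fits
#'
#' Given the generative truth and a list of fits to data simulated from it,
#' reports per parameter the bias of the posterior mean, the RMSE, and the
#' empirical coverage of the 89% HPD intervals — the calibration check that
#' a well-implemented Bayesian pipeline should pass at roughly the nominal
#' rate.
#'
#' @param true_params A [model_params()] object (the generative truth).
#' @param fits A list of `"patch_fit"` objects.
#' @param mass HPD mass for the coverage check.
#' @return A tibble `param, truth, bias, rmse, coverage, n_fits`, restricted
#'   to parameters present in the fits' draws.
#' @export
parameter_recovery_report <- function(true_params, fits, mass = 0.89) {
  stopifnot(length(fits) >= 1)
  truth <- param_vector(true_params)
  pars <- setdiff(names(fits[[1]]$draws), c(".chain", ".draw"))
  for (f in fits) {
    if (!identical(setdiff(names(f$draws), c(".chain", ".draw")), pars)) {
      stop("fits have mismatched parameter layouts", call. = FALSE)
    }
  }
  pars <- intersect(pars, names(truth))
  purrr::map_dfr(pars, function(p) {
    post_means <- vapply(fits, function(f) mean(f$draws[[p]]), numeric(1))
    covered <- vapply(fits, function(f) {
      x <- f$draws[[p]]
      if (stats::var(x) == 0) return(x[1] == truth[[p]])
      h <- hpd_interval(x, mass)
      truth[[p]] >= h[1] && truth[[p]] <= h[2]
    }, logical(1))
    tv <- truth[[p]]
    tibble::tibble(
      param = p, truth = tv,
      bias = mean(post_means) - tv,
      rmse = sqrt(mean((post_means - tv)^2)),
      coverage = mean(covered),
      n_fits = length(fits)
    )
  })
}
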