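#' MCMC fit configuration
#'
#' @param n_chains Number of chains (default 4).
#' @param n_warmup Adaptation + burn-in iterations per chain (default 1000).
#' @param n_draws Retained draws per chain (default 1000).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param target_accept Acceptance target for step-size-adapting backends;
#'   the conditional (Gibbs/slice) backend has no such knob and ignores it.
#' @param rhat_threshold,ess_threshold Convergence thresholds applied by
#'   [diagnostics()] (defaults 1.01 and 400).
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(n_chains = 4L, n_warmup = 1000L, n_draws = 1000L,
                       seed = 1L, target_accept = 0.9,
                       rhat_threshold = 1.01, ess_threshold = 400) {
  stopifnot(n_chains >= 1, n_warmup >= 0, n_draws >= 1,
            target_accept > 0, target_accept < 1)
  structure(
    list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
         n_draws = as.integer(n_draws), seed = as.integer(seed),
         target_accept = target_accept, rhat_threshold = rhat_threshold,
         ess_threshold = ess_threshold),
    class = "fit_config"
  )
}

#' Model structure options
#'
#' Controls which terms enter the linear predictors. The default is the
#' full joint model: 7-way softmax over all patches with season-by-patch
#' and gender-by-patch varying intercepts, latent GP age effects, all four
#' covariates in both sub-models, and income imputation. Reductions (fewer
#' patches, no intercepts, a single sub-model) are used for validation
#' against low-dimensional oracles and for scenario experiments.
#'
#' @param patches Patch identifiers of the choice set.
#' @param covariates Standardized covariate columns entering the linear
#'   predictors (possibly empty).
#' @param use_intercepts Include season-by-patch varying intercepts.
#' @param use_gender Include gender-by-patch varying intercepts.
#' @param use_age Include the latent GP age effects.
#' @param submodel `"joint"`, `"choice"`, or `"success"`.
#' @param impute_income Sample a latent standardized income for trips with
#'   missing income (ignored when no income is missing).
#' @return A list of class `"model_options"`.
#' @export
model_options <- function(patches = patch_levels(),
                          covariates = c("income_std", "in_degree_std",
                                         "out_degree_std", "group_size_std"),
                          use_intercepts = TRUE, use_gender = TRUE,
                          use_age = TRUE,
                          submodel = c("joint", "choice", "success"),
                          impute_income = TRUE) {
  structure(
    list(patches = patches, covariates = covariates,
         use_intercepts = use_intercepts, use_gender = use_gender,
         use_age = use_age, submodel = match.arg(submodel),
         impute_income = impute_income),
    class = "model_options"
  )
}

# assemble the BUGS-language model source for the configured structure
build_model_string <- function(model, priors, C, any_missing) {
  choice_on <- model$submodel %in% c("joint", "choice")
  succ_on <- model$submodel %in% c("joint", "success")
  imp_on <- any_missing && model$impute_income &&
    "income_std" %in% model$covariates
  ic <- match("income_std", model$covariates)

  term <- function(prefix) {
    idx <- if (prefix %in% c("a_s", "g_s")) "patch[i]" else "k"
    switch(prefix,
      a_c = "a_c[k, season[i]]", g_c = "g_c[k, gender[i]]",
      f_c = "f_c[k, age[i]]",
      a_s = "a_s[patch[i], season[i]]", g_s = "g_s[patch[i], gender[i]]",
      f_s = "f_s[age[i]]")
  }
  lines <- c("model {")

  if (C > 0) {
    xi <- vapply(seq_len(C), function(cc) {
      if (imp_on && cc == ic) {
        sprintf("    xi[i,%d] <- X[i,%d] + miss[i] * (inc_miss - X[i,%d])",
                cc, cc, cc)
      } else {
        sprintf("    xi[i,%d] <- X[i,%d]", cc, cc)
      }
    }, character(1))
  } else xi <- character(0)

  eta_terms <- c(
    if (model$use_intercepts) term("a_c"),
    if (model$use_gender) term("g_c"),
    if (model$use_age) term("f_c"),
    if (C > 0) "inprod(b_c[k, 1:C], xi[i, 1:C])"
  )
  th_terms <- c(
    if (model$use_intercepts) term("a_s"),
    if (model$use_gender) term("g_s"),
    if (model$use_age) term("f_s"),
    if (C > 0) "inprod(b_s[1:C], xi[i, 1:C])"
  )
  if (length(eta_terms) == 0) eta_terms <- "0"
  if (length(th_terms) == 0) th_terms <- "0"

  lines <- c(lines, "  for (i in 1:N) {", xi)
  if (choice_on) {
    lines <- c(lines,
      "    for (k in 1:K) {",
      sprintf("      eta[i,k] <- %s", paste(eta_terms, collapse = " + ")),
      "      w[i,k] <- exp(eta[i,k] - emax[i])",
      "    }",
      "    emax[i] <- max(eta[i, 1:K])",
      "    patch[i] ~ dcat(w[i, 1:K])")
  }
  if (succ_on) {
    lines <- c(lines,
      sprintf("    logit(ps[i]) <- %s", paste(th_terms, collapse = " + ")),
      "    succ[i] ~ dbern(ps[i])")
  }
  lines <- c(lines, "  }")

  # priors ------------------------------------------------------------------
  pb <- c("  for (k in 1:K) {")
  if (model$use_intercepts) {
    if (choice_on) pb <- c(pb,
      "    for (s in 1:2) { a_c[k,s] ~ dnorm(loc_a, prec_ac) }")
    if (succ_on) pb <- c(pb,
      "    for (s in 1:2) { a_s[k,s] ~ dnorm(loc_as, prec_as) }")
  }
  if (model$use_gender) {
    if (choice_on) pb <- c(pb,
      "    for (g in 1:2) { g_c[k,g] ~ dnorm(loc_g, prec_gc) }")
    if (succ_on) pb <- c(pb,
      "    for (g in 1:2) { g_s[k,g] ~ dnorm(loc_gs, prec_gs) }")
  }
  if (C > 0 && choice_on) pb <- c(pb,
    "    for (c in 1:C) { b_c[k,c] ~ dnorm(loc_b, prec_bc) }")
  if (model$use_age && choice_on) pb <- c(pb,
    "    f_c[k, 1:A] ~ dmnorm(zeroA[1:A], Omc[1:A, 1:A])")
  pb <- c(pb, "  }")
  lines <- c(lines, pb)

  if (C > 0 && succ_on) lines <- c(lines,
    "  for (c in 1:C) { b_s[c] ~ dnorm(loc_bs, prec_bs) }")

  if (model$use_age) {
    lines <- c(lines,
      "  for (r in 1:A) { for (cc in 1:A) {")
    if (choice_on) lines <- c(lines,
      paste0("    Kc[r,cc] <- gp_eta_c * exp(-gp_rho_c * ",
             "pow(agepos[r] - agepos[cc], 2)) + equals(r,cc) * ",
             "(gp_sig_c + 1.0E-6 * gp_eta_c + 1.0E-8)"))
    if (succ_on) lines <- c(lines,
      paste0("    Ks[r,cc] <- gp_eta_s * exp(-gp_rho_s * ",
             "pow(agepos[r] - agepos[cc], 2)) + equals(r,cc) * ",
             "(gp_sig_s + 1.0E-6 * gp_eta_s + 1.0E-8)"))
    lines <- c(lines, "  } }")
    if (choice_on) lines <- c(lines,
      "  Omc[1:A, 1:A] <- inverse(Kc[1:A, 1:A])",
      "  gp_eta_c ~ dt(0, prec_hc, 1) T(0,)",
      "  gp_rho_c ~ dt(0, prec_hc, 1) T(0,)",
      "  gp_sig_c ~ dt(0, prec_hc, 1) T(0,)")
    if (succ_on) lines <- c(lines,
      "  Oms[1:A, 1:A] <- inverse(Ks[1:A, 1:A])",
      "  f_s[1:A] ~ dmnorm(zeroA[1:A], Oms[1:A, 1:A])",
      "  gp_eta_s ~ dt(0, prec_hc, 1) T(0,)",
      "  gp_rho_s ~ dt(0, prec_hc, 1) T(0,)",
      "  gp_sig_s ~ dt(0, prec_hc, 1) T(0,)")
  }

  if (imp_on) {
    lines <- c(lines,
      "  inc_miss ~ dnorm(mu_inc, pow(sigma_inc, -2))",
      "  mu_inc ~ dnorm(loc_mu_inc, prec_mu_inc)",
      "  sigma_inc ~ dt(0, prec_sig_inc, 1) T(0,)")
  }
  lines <- c(lines, "}")
  structure(paste(lines, collapse = "\n"), imputing = imp_on)
}

# map JAGS monitor names to package parameter names
rename_jags <- function(nms, model) {
  K <- length(model$patches); C <- length(model$covariates)
  seasons <- season_levels(); genders <- gender_levels()
  ages <- age_class_levels()
  lab <- function(block, r, cc, rn, cn) {
    paste0(block, "[", rn[r], ",", cn[cc], "]")
  }
  out <- nms
  pat <- "^([a-z_]+)\\[(\\d+)(?:,(\\d+))?\\]$"
  m <- regmatches(nms, regexec(pat, nms))
  for (i in seq_along(nms)) {
    if (length(m[[i]]) == 0) {
      out[i] <- switch(nms[i],
        gp_eta_c = "gp_choice[eta_sq]", gp_rho_c = "gp_choice[rho_sq]",
        gp_sig_c = "gp_choice[sigma_sq]",
        gp_eta_s = "gp_succ[eta_sq]", gp_rho_s = "gp_succ[rho_sq]",
        gp_sig_s = "gp_succ[sigma_sq]",
        inc_miss = "income_miss", mu_inc = "income_mu",
        sigma_inc = "income_sigma", nms[i])
      next
    }
    block <- m[[i]][2]
    r <- as.integer(m[[i]][3])
    cc <- if (m[[i]][4] == "") NA_integer_ else as.integer(m[[i]][4])
    out[i] <- switch(block,
      a_c = lab("alpha_choice", r, cc, model$patches, seasons),
      g_c = lab("gamma_choice", r, cc, model$patches, genders),
      b_c = lab("beta_choice", r, cc, model$patches, model$covariates),
      f_c = lab("age_choice", r, cc, model$patches, ages),
      a_s = lab("alpha_succ", r, cc, model$patches, seasons),
      g_s = lab("gamma_succ", r, cc, model$patches, genders),
      f_s = paste0("age_succ[", ages[r], "]"),
      b_s = paste0("beta_succ[", model$covariates[r], "]"),
      nms[i])
  }
  out
}

#' Sample the joint posterior
#'
#' Fits the configured model by MCMC through the JAGS backend (conditional
#' slice/Gibbs sampling). The target density is exactly the package's
#' [joint_log_density()] contract: categorical softmax choice likelihood,
#' Bernoulli success likelihood, normal priors on intercepts and
#' coefficients, the GP prior on age effects with half-Cauchy scale
#' hyperpriors, and — when any trip's income is missing — a shared latent
#' standardized income for the missing household with
#' Normal(0.5, 1)/half-Cauchy(0, 1) hyperpriors. Convergence diagnostics
#' (split R-hat, effective sample size) are computed for every scalar
#' parameter; the fit carries a prominent `warn` state when any parameter
#' misses its threshold.
#'
#' @param trips A standardized trip tibble (see [standardize_covariates()]).
#' @param priors A `"prior_config"` list.
#' @param config A [fit_config()].
#' @param model A [model_options()].
#' @return An object of class `"patch_fit"`: list with `draws` (tibble with
#'   `.chain`, `.draw` and one column per scalar parameter), `diagnostics`
#'   (tibble), `warn` (logical), plus the configs and the covariate scaling
#'   used at fit time.
#' @export
fit_posterior <- function(trips, priors = default_prior_config(),
                          config = fit_config(), model = model_options()) {
  stopifnot(nrow(trips) > 0)
  scaling <- attr(trips, "scaling", exact = TRUE)
  C <- length(model$covariates)
  for (cv in model$covariates) {
    if (!cv %in% names(trips)) {
      stop("trips lack covariate '", cv, "'; run standardize_covariates()",
           call. = FALSE)
    }
  }
  k <- match(trips$patch, model$patches)
  if (anyNA(k)) stop("trip patch outside the model's patch set",
                     call. = FALSE)

  X <- if (C > 0) {
    as.matrix(trips[, model$covariates, drop = FALSE])
  } else matrix(0, nrow(trips), 0)
  miss <- if ("income_std" %in% model$covariates) {
    as.integer(is.na(X[, "income_std"]))
  } else integer(nrow(trips))
  if (any(miss == 1)) X[miss == 1, "income_std"] <- 0
  if (anyNA(X)) stop("missing covariate values (other than income)",
                     call. = FALSE)

  prec <- function(pr) 1 / pr$scale^2
  data <- list(
    N = nrow(trips), K = length(model$patches),
    patch = k, succ = trips$success,
    season = match(trips$season, season_levels()),
    gender = match(trips$gender, gender_levels()),
    age = match(trips$age_class, age_class_levels()),
    A = 4L, agepos = 1:4, zeroA = rep(0, 4),
    loc_a = priors$alpha_choice$loc, prec_ac = prec(priors$alpha_choice),
    loc_g = priors$gamma_choice$loc, prec_gc = prec(priors$gamma_choice),
    loc_b = priors$beta_choice$loc, prec_bc = prec(priors$beta_choice),
    loc_as = priors$alpha_succ$loc, prec_as = prec(priors$alpha_succ),
    loc_gs = priors$gamma_succ$loc, prec_gs = prec(priors$gamma_succ),
    loc_bs = priors$beta_succ$loc, prec_bs = prec(priors$beta_succ),
    prec_hc = prec(priors$gp_eta),
    loc_mu_inc = priors$income_mu$loc,
    prec_mu_inc = prec(priors$income_mu),
    prec_sig_inc = prec(priors$income_sigma)
  )
  if (C > 0) {
    data$X <- X
    data$C <- C
    data$miss <- miss
  }

  src <- build_model_string(model, priors, C, any_missing = any(miss == 1))
  imputing <- attr(src, "imputing")

  choice_on <- model$submodel %in% c("joint", "choice")
  succ_on <- model$submodel %in% c("joint", "success")
  monitors <- c(
    if (model$use_intercepts && choice_on) "a_c",
    if (model$use_gender && choice_on) "g_c",
    if (C > 0 && choice_on) "b_c",
    if (model$use_age && choice_on)
      c("f_c", "gp_eta_c", "gp_rho_c", "gp_sig_c"),
    if (model$use_intercepts && succ_on) "a_s",
    if (model$use_gender && succ_on) "g_s",
    if (C > 0 && succ_on) "b_s",
    if (model$use_age && succ_on)
      c("f_s", "gp_eta_s", "gp_rho_s", "gp_sig_s"),
    if (imputing) c("inc_miss", "mu_inc", "sigma_inc")
  )

  # drop unused data entries to keep JAGS quiet about them
  used <- vapply(names(data), function(nm) grepl(nm, src, fixed = TRUE),
                 logical(1))
  data <- data[used | names(data) %in% c("N", "K")]

  inits <- lapply(seq_len(config$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed + ch)
  })
  jm <- rjags::jags.model(textConnection(src), data = data, inits = inits,
                          n.chains = config$n_chains,
                          n.adapt = max(100L, config$n_warmup %/% 2L),
                          quiet = TRUE)
  extra_burn <- config$n_warmup - max(100L, config$n_warmup %/% 2L)
  if (extra_burn > 0) stats::update(jm, extra_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = config$n_draws,
                              progress.bar = "none")

  nms <- rename_jags(coda::varnames(samp), model)
  draws <- purrr::map_dfr(seq_along(samp), function(ch) {
    m <- as.matrix(samp[[ch]])
    colnames(m) <- nms
    out <- tibble::as_tibble(m)
    out$.chain <- ch
    out$.draw <- seq_len(nrow(m))
    out
  })
  draws <- dplyr::relocate(draws, ".chain", ".draw")

  diag <- diagnostics_table(draws, config)
  fit <- structure(
    list(draws = draws, diagnostics = diag,
         warn = any(!diag$pass, na.rm = TRUE),
         config = config, model = model, priors = priors,
         scaling = scaling, n_trips = nrow(trips)),
    class = "patch_fit"
  )
  if (fit$warn) {
    warning("convergence diagnostics failed for ",
            sum(!diag$pass, na.rm = TRUE),
            " parameter(s); inspect diagnostics(fit)", call. = FALSE)
  }
  fit
}

#' @export
print.patch_fit <- function(x, ...) {
  cat("<patch_fit> ", x$config$n_chains, "chains x", x$config$n_draws,
      "draws;", ncol(x$draws) - 2, "parameters;",
      x$n_trips, "trips\n")
  cat(if (x$warn) "WARN: convergence diagnostics failed\n"
      else "diagnostics: all parameters pass\n")
  invisible(x)
}

# split-R-hat for one parameter: matrix iterations x chains
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- n %/% 2
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  if (stats::var(as.vector(splits)) == 0) return(NA_real_)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  B <- half * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

diagnostics_table <- function(draws, config) {
  pars <- setdiff(names(draws), c(".chain", ".draw"))
  chains <- sort(unique(draws$.chain))
  purrr::map_dfr(pars, function(p) {
    x <- sapply(chains, function(ch) draws[[p]][draws$.chain == ch])
    x <- matrix(x, ncol = length(chains))
    rhat <- if (length(chains) >= 2) split_rhat(x) else NA_real_
    ess <- sum(vapply(seq_len(ncol(x)), function(j) {
      v <- x[, j]
      if (stats::var(v) == 0) return(0)
      unname(coda::effectiveSize(v))
    }, numeric(1)))
    degenerate <- stats::var(as.vector(x)) == 0
    tibble::tibble(
      param = p, rhat = rhat, ess = ess, degenerate = degenerate,
      pass = if (degenerate) NA else {
        (is.na(rhat) || rhat <= config$rhat_threshold) &&
          ess >= config$ess_threshold
      }
    )
  })
}

#' Convergence report
#'
#' Split R-hat (chains halved, so within-chain drift is visible) and
#' effective sample size per scalar parameter, with pass/fail against the
#' fit's thresholds. With a single chain R-hat is undefined and reported as
#' `NA`; constant parameters are flagged `degenerate` rather than failed.
#'
#' @param fit A `"patch_fit"` object, or a draws tibble with `.chain` /
#'   `.draw` columns.
#' @param config A [fit_config()] supplying thresholds (taken from the fit
#'   when omitted).
#' @return A tibble `param, rhat, ess, degenerate, pass`.
#' @export
diagnostics <- function(fit, config = NULL) {
  if (inherits(fit, "patch_fit")) {
    if (is.null(config)) return(fit$diagnostics)
    return(diagnostics_table(fit$draws, config))
  }
  if (is.null(config)) config <- fit_config()
  diagnostics_table(fit, config)
}

#' Prior-predictive simulation at a covariate profile
#'
#' Draws parameter sets from the prior ([sample_prior_params()]) and pushes
#' a single harvester profile through the softmax choice model and the
#' logistic success model. Under the default symmetric priors the
#' Monte-Carlo mean of each patch's choice probability is 1/K (0.14 for
#' K = 7) and the mean success probability is 1/2 — the structural
#' symmetry this model family exhibits before seeing data.
#'
#' @param priors A `"prior_config"` list.
#' @param profile A [harvester_profile()].
#' @param n_draws Number of prior draws.
#' @param seed Integer seed.
#' @param patches Patch identifiers.
#' @return A list: `choice` (draws x patch matrix of choice probabilities),
#'   `success` (draws x patch matrix of success probabilities), and
#'   `summary` — a tibble per patch with mean and 89% HPD of both.
#' @export
sample_prior_predictive <- function(priors = default_prior_config(),
                                    profile = profile_preset("reference_adult"),
                                    n_draws = 10000L, seed = 1L,
                                    patches = patch_levels()) {
  set.seed(seed)
  row <- profile_row(profile, scaling = NULL)
  K <- length(patches)
  choice <- matrix(NA_real_, n_draws, K, dimnames = list(NULL, patches))
  succ <- matrix(NA_real_, n_draws, K, dimnames = list(NULL, patches))
  for (d in seq_len(n_draws)) {
    par <- sample_prior_params(priors, patches = patches)
    eta <- linear_predictor_choice(row, par)
    choice[d, ] <- softmax_probs(drop(eta))
    per_patch <- row[rep(1, K), ]
    per_patch$patch <- patches
    succ[d, ] <- success_prob(per_patch, par)
  }
  summary <- purrr::map_dfr(seq_len(K), function(kk) {
    hc <- hpd_interval(choice[, kk], 0.89)
    hs <- hpd_interval(succ[, kk], 0.89)
    tibble::tibble(
      patch = patches[kk],
      choice_mean = mean(choice[, kk]),
      choice_lo = hc[1], choice_hi = hc[2],
      success_mean = mean(succ[, kk]),
      success_lo = hs[1], success_hi = hs[2]
    )
  })
  list(choice = choice, success = succ, summary = summary)
}
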