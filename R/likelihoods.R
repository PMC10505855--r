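#' Covariate matrix for the linear predictors
#'
#' Assembles the standardized covariate matrix used by both sub-models,
#' substituting the imputation latent `income_miss` for trips whose
#' household income is missing.
#'
#' @param trips A standardized trip tibble (see [standardize_covariates()]).
#' @param params A [model_params()] object (supplies `income_miss` and the
#'   covariate ordering).
#' @return An N x C numeric matrix.
#' @keywords internal
covariate_matrix <- function(trips, params) {
  X <- sapply(params$covariates, function(cv) {
    x <- trips[[cv]]
    if (is.null(x)) {
      stop("trips lack standardized covariate column '", cv,
           "'; run standardize_covariates()", call. = FALSE)
    }
    x
  })
  X <- matrix(X, nrow = nrow(trips),
              dimnames = list(NULL, params$covariates))
  if ("income_std" %in% params$covariates) {
    miss <- is.na(X[, "income_std"])
    if (any(miss)) {
      if (is.null(params$income_miss) || is.na(params$income_miss)) {
        stop("missing income with no imputation latent bound", call. = FALSE)
      }
      X[miss, "income_std"] <- params$income_miss
    }
  }
  if (anyNA(X)) stop("missing covariate values", call. = FALSE)
  X
}

#' Linear predictor of the patch-choice model
#'
#' For trip i and patch k the predictor is
#' `alpha_choice[k, season_i] + gamma_choice[k, gender_i] +
#'  age_choice[k, age_i] + sum_c beta_choice[k, c] * x_ic`.
#'
#' @inheritParams covariate_matrix
#' @return An N x K matrix of linear predictors (columns in patch order).
#' @export
linear_predictor_choice <- function(trips, params) {
  s <- match(trips$season, season_levels())
  g <- match(trips$gender, gender_levels())
  a <- match(trips$age_class, age_class_levels())
  if (anyNA(s) || anyNA(g) || anyNA(a)) {
    stop("unknown season/gender/age_class level", call. = FALSE)
  }
  X <- covariate_matrix(trips, params)
  eta <- t(params$alpha_choice[, s, drop = FALSE]) +
    t(params$gamma_choice[, g, drop = FALSE]) +
    t(params$age_choice[, a, drop = FALSE]) +
    X %*% t(params$beta_choice)
  colnames(eta) <- params$patches
  eta
}

#' Numerically stable softmax
#'
#' Maps a vector of linear predictors to the probability simplex,
#' `p_k = exp(eta_k) / sum_j exp(eta_j)`, with max-subtraction so there is
#' no overflow for |eta| up to about 700. An optional mask restricts the
#' support: masked patches get probability exactly 0 and the rest
#' renormalize.
#'
#' @param eta Numeric vector (one trip) or matrix (trips x patches).
#' @param mask Optional: a logical keep-vector the length of `eta`'s
#'   patch dimension, or a character vector of patch names to keep
#'   (requires named/column-named `eta`).
#' @return Probabilities with the same shape as `eta`; each row sums to 1.
#' @export
#' @examples
#' softmax_probs(c(log(2), 0, 0, 0, 0, 0, 0))
softmax_probs <- function(eta, mask = NULL) {
  vec <- is.null(dim(eta))
  if (vec) eta <- matrix(eta, nrow = 1, dimnames = list(NULL, names(eta)))
  if (!all(is.finite(eta))) stop("non-finite linear predictor", call. = FALSE)
  keep <- rep(TRUE, ncol(eta))
  if (!is.null(mask)) {
    if (is.character(mask)) {
      if (is.null(colnames(eta))) {
        stop("character mask requires named patches", call. = FALSE)
      }
      keep <- colnames(eta) %in% mask
    } else {
      stopifnot(length(mask) == ncol(eta))
      keep <- as.logical(mask)
    }
    if (!any(keep)) stop("mask excludes all patches", call. = FALSE)
  }
  work <- eta[, keep, drop = FALSE]
  mx <- apply(work, 1, max)
  ew <- exp(work - mx)
  pw <- ew / rowSums(ew)
  p <- matrix(0, nrow(eta), ncol(eta), dimnames = dimnames(eta))
  p[, keep] <- pw
  if (vec) p[1, ] else p
}

#' Log-likelihood of the categorical patch-choice model
#'
#' Sum over trips of the log softmax probability of the observed patch.
#'
#' @inheritParams covariate_matrix
#' @param mask Optional patch mask as in [softmax_probs()]; an observed
#'   patch that is masked is an impossible observation and errors.
#' @return A single finite number for finite parameters.
#' @export
choice_loglik <- function(trips, params, mask = NULL) {
  eta <- linear_predictor_choice(trips, params)
  p <- softmax_probs(eta, mask = mask)
  k <- match(trips$patch, params$patches)
  if (anyNA(k)) stop("trip patch not in model patch set", call. = FALSE)
  pk <- p[cbind(seq_len(nrow(p)), k)]
  if (any(pk == 0)) {
    stop("observed patch has probability 0 under the mask", call. = FALSE)
  }
  sum(log(pk))
}

#' Squared-exponential covariance over ordinal age classes
#'
#' `K[a, b] = eta_sq * exp(-rho_sq * d(a, b)^2) + 1{a = b} * sigma_sq` with
#' `d` the distance between integer age-class positions. The jitter term
#' `sigma_sq` keeps the matrix positive-definite for all hyperparameter
#' values.
#'
#' @param eta_sq Marginal variance (> 0).
#' @param rho_sq Inverse squared length-scale (> 0).
#' @param sigma_sq Independent (jitter) variance (> 0).
#' @param positions Numeric positions of the age classes; default `1:4`.
#' @return A symmetric positive-definite matrix.
#' @export
#' @examples
#' gp_age_cov(2, 0.5, 0.1)[1, 2]  # 2 * exp(-0.5)
gp_age_cov <- function(eta_sq, rho_sq, sigma_sq, positions = 1:4) {
  if (eta_sq <= 0 || rho_sq <= 0 || sigma_sq <= 0) {
    stop("GP hyperparameters must be positive", call. = FALSE)
  }
  d2 <- outer(positions, positions, function(a, b) (a - b)^2)
  eta_sq * exp(-rho_sq * d2) + diag(sigma_sq, length(positions))
}

#' Linear predictor (logit) of the harvest-success model
#'
#' `theta_i = alpha_succ[X_i, season_i] + gamma_succ[X_i, gender_i] +
#'  age_succ[age_i] + sum_c beta_succ[c] * x_ic`, where `X_i` is the trip's
#' observed (or assigned) patch.
#'
#' @inheritParams covariate_matrix
#' @return Numeric vector of logits, one per trip.
#' @export
success_logit <- function(trips, params) {
  k <- match(trips$patch, params$patches)
  if (anyNA(k)) stop("trip patch not in model patch set", call. = FALSE)
  s <- match(trips$season, season_levels())
  g <- match(trips$gender, gender_levels())
  a <- match(trips$age_class, age_class_levels())
  X <- covariate_matrix(trips, params)
  unname(params$alpha_succ[cbind(k, s)] + params$gamma_succ[cbind(k, g)] +
           params$age_succ[a] + drop(X %*% params$beta_succ))
}

#' Within-patch success probability
#'
#' Inverse-logit of [success_logit()]; always strictly inside (0, 1).
#'
#' @inheritParams covariate_matrix
#' @return Numeric vector of probabilities.
#' @export
success_prob <- function(trips, params) {
  stats::plogis(success_logit(trips, params))
}

#' Bernoulli log-likelihood of the harvest-success model
#'
#' Probabilities are kept away from exactly 0 and 1, so the log-likelihood
#' stays finite for logits up to at least +/- 35.
#'
#' @inheritParams covariate_matrix
#' @return A single finite number for finite parameters.
#' @export
success_loglik <- function(trips, params) {
  p <- success_prob(trips, params)
  eps <- 1e-15
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(stats::dbinom(trips$success, 1, p, log = TRUE))
}

mvn_logpdf <- function(x, K) {
  L <- chol(K)
  z <- backsolve(L, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

half_cauchy_logpdf <- function(x, scale) {
  if (x <= 0) return(-Inf)
  stats::dcauchy(x, 0, scale, log = TRUE) + log(2)
}

#' Joint log prior density
#'
#' Sums the log prior over all parameter blocks: normal priors on the
#' varying intercepts and coefficients, the multivariate-normal GP prior on
#' each age-effect vector given [gp_age_cov()] of the block's
#' hyperparameters, half-Cauchy priors on the GP scales, and the
#' hierarchical imputation block
#' `income_miss ~ Normal(income_mu, income_sigma)`,
#' `income_mu ~ Normal(0.5, 1)`, `income_sigma ~ half-Cauchy(0, 1)`.
#' Out-of-support values (non-positive scales) give `-Inf`.
#'
#' @param params A [model_params()] object.
#' @param priors A `"prior_config"` list ([default_prior_config()]).
#' @return The log prior density (possibly `-Inf`).
#' @export
log_prior <- function(params, priors = default_prior_config()) {
  if (params$gp_choice["eta_sq"] <= 0 || params$gp_choice["rho_sq"] <= 0 ||
      params$gp_choice["sigma_sq"] <= 0 || params$gp_succ["eta_sq"] <= 0 ||
      params$gp_succ["rho_sq"] <= 0 || params$gp_succ["sigma_sq"] <= 0 ||
      params$income_sigma <= 0) {
    return(-Inf)
  }
  norm_block <- function(x, pr) {
    stopifnot(pr$family == "normal")
    sum(stats::dnorm(as.vector(x), pr$loc, pr$scale, log = TRUE))
  }
  lp <- norm_block(params$alpha_choice, priors$alpha_choice) +
    norm_block(params$gamma_choice, priors$gamma_choice) +
    norm_block(params$beta_choice, priors$beta_choice) +
    norm_block(params$alpha_succ, priors$alpha_succ) +
    norm_block(params$gamma_succ, priors$gamma_succ) +
    norm_block(params$beta_succ, priors$beta_succ)

  Kc <- gp_age_cov(params$gp_choice["eta_sq"], params$gp_choice["rho_sq"],
                   params$gp_choice["sigma_sq"])
  for (k in seq_along(params$patches)) {
    lp <- lp + mvn_logpdf(params$age_choice[k, ], Kc)
  }
  Ks <- gp_age_cov(params$gp_succ["eta_sq"], params$gp_succ["rho_sq"],
                   params$gp_succ["sigma_sq"])
  lp <- lp + mvn_logpdf(params$age_succ, Ks)

  for (h in c("eta_sq", "rho_sq", "sigma_sq")) {
    pr <- priors[[paste0("gp_", sub("_sq", "", h))]]
    lp <- lp + half_cauchy_logpdf(params$gp_choice[[h]], pr$scale) +
      half_cauchy_logpdf(params$gp_succ[[h]], pr$scale)
  }

  lp <- lp +
    stats::dnorm(params$income_mu, priors$income_mu$loc,
                 priors$income_mu$scale, log = TRUE) +
    half_cauchy_logpdf(params$income_sigma, priors$income_sigma$scale) +
    stats::dnorm(params$income_miss, params$income_mu, params$income_sigma,
                 log = TRUE)
  lp
}

#' Joint log density (prior + both likelihoods)
#'
#' `log_prior(params, priors) + choice_loglik(trips, params) +
#'  success_loglik(trips, params)` — the (unnormalized) log posterior
#' density targeted by [fit_posterior()].
#'
#' @inheritParams covariate_matrix
#' @param priors A `"prior_config"` list.
#' @return The joint log density.
#' @export
joint_log_density <- function(trips, params, priors = default_prior_config()) {
  lp <- log_prior(params, priors)
  if (!is.finite(lp)) return(lp)
  lp + choice_loglik(trips, params) + success_loglik(trips, params)
}

#' Draw one parameter set from the prior
#'
#' Used by prior-predictive simulation and as generative ground truth in
#' recovery experiments. Age effects are drawn from their GP prior given
#' freshly drawn hyperparameters; the imputation block is drawn
#' hierarchically.
#'
#' @param priors A `"prior_config"` list.
#' @param patches Patch identifiers.
#' @param covariates Covariate names.
#' @return A [model_params()] object.
#' @export
sample_prior_params <- function(priors = default_prior_config(),
                                patches = patch_levels(),
                                covariates = c("income_std", "in_degree_std",
                                               "out_degree_std",
                                               "group_size_std")) {
  K <- length(patches); C <- length(covariates)
  rn <- function(n, pr) stats::rnorm(n, pr$loc, pr$scale)
  rhc <- function(pr) abs(stats::rcauchy(1, 0, pr$scale))
  gp_c <- c(eta_sq = rhc(priors$gp_eta), rho_sq = rhc(priors$gp_rho),
            sigma_sq = rhc(priors$gp_sigma))
  gp_s <- c(eta_sq = rhc(priors$gp_eta), rho_sq = rhc(priors$gp_rho),
            sigma_sq = rhc(priors$gp_sigma))
  rmvn <- function(n, K) {
    L <- chol(K)
    matrix(stats::rnorm(n * nrow(K)), n) %*% L
  }
  income_mu <- rn(1, priors$income_mu)
  income_sigma <- rhc(priors$income_sigma)
  model_params(
    patches = patches, covariates = covariates,
    alpha_choice = matrix(rn(K * 2, priors$alpha_choice), K),
    gamma_choice = matrix(rn(K * 2, priors$gamma_choice), K),
    beta_choice = matrix(rn(K * C, priors$beta_choice), K),
    age_choice = rmvn(K, gp_age_cov(gp_c["eta_sq"], gp_c["rho_sq"],
                                    gp_c["sigma_sq"])),
    alpha_succ = matrix(rn(K * 2, priors$alpha_succ), K),
    gamma_succ = matrix(rn(K * 2, priors$gamma_succ), K),
    beta_succ = rn(C, priors$beta_succ),
    age_succ = drop(rmvn(1, gp_age_cov(gp_s["eta_sq"], gp_s["rho_sq"],
                                       gp_s["sigma_sq"]))),
    gp_choice = gp_c, gp_succ = gp_s,
    income_mu = income_mu, income_sigma = income_sigma,
    income_miss = stats::rnorm(1, income_mu, income_sigma)
  )
}
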