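#' Model parameter container
#'
#' Holds every parameter of the joint model: the choice block (per-patch
#' season and gender varying intercepts, covariate coefficients, and latent
#' Gaussian-process age effects), the success block (season/gender varying
#' intercepts by patch, one shared coefficient vector and one shared age
#' effect), the GP hyperparameters of both blocks, and the income-imputation
#' latents. All arrays are initialised to zero unless supplied.
#'
#' @param patches Character vector of patch identifiers (model order).
#' @param covariates Names of the standardized covariate columns entering
#'   the linear predictors.
#' @param alpha_choice,gamma_choice Patch x season / patch x gender matrices
#'   of varying intercepts for the choice model.
#' @param beta_choice Patch x covariate coefficient matrix (choice model).
#' @param age_choice Patch x age-class matrix of latent GP age effects.
#' @param alpha_succ,gamma_succ Patch x season / patch x gender varying
#'   intercepts for the success model.
#' @param beta_succ Covariate coefficient vector (success model).
#' @param age_succ Age-class vector of latent GP age effects (success).
#' @param gp_choice,gp_succ Named vectors `c(eta_sq, rho_sq, sigma_sq)`:
#'   marginal variance, inverse squared length-scale, and independent jitter
#'   variance of the squared-exponential age kernel.
#' @param income_mu,income_sigma,income_miss Imputation block: hyper-mean and
#'   hyper-sd of the latent standardized income, and the latent value shared
#'   by all trips of the income-missing household.
#' @return An object of class `"model_params"`.
#' @export
model_params <- function(patches = patch_levels(),
                         covariates = c("income_std", "in_degree_std",
                                        "out_degree_std", "group_size_std"),
                         alpha_choice = NULL, gamma_choice = NULL,
                         beta_choice = NULL, age_choice = NULL,
                         alpha_succ = NULL, gamma_succ = NULL,
                         beta_succ = NULL, age_succ = NULL,
                         gp_choice = c(eta_sq = 1, rho_sq = 0.5, sigma_sq = 0.1),
                         gp_succ = c(eta_sq = 1, rho_sq = 0.5, sigma_sq = 0.1),
                         income_mu = 0.5, income_sigma = 1, income_miss = 0) {
  K <- length(patches)
  C <- length(covariates)
  seasons <- season_levels()
  genders <- gender_levels()
  ages <- age_class_levels()
  m <- function(x, nr, nc, rn, cn) {
    if (is.null(x)) x <- matrix(0, nr, nc)
    x <- as.matrix(x)
    stopifnot(nrow(x) == nr, ncol(x) == nc)
    dimnames(x) <- list(rn, cn)
    x
  }
  v <- function(x, n, nm) {
    if (is.null(x)) x <- numeric(n)
    stopifnot(length(x) == n)
    stats::setNames(as.numeric(x), nm)
  }
  structure(
    list(
      patches = patches,
      covariates = covariates,
      alpha_choice = m(alpha_choice, K, 2, patches, seasons),
      gamma_choice = m(gamma_choice, K, 2, patches, genders),
      beta_choice = m(beta_choice, K, C, patches, covariates),
      age_choice = m(age_choice, K, 4, patches, ages),
      alpha_succ = m(alpha_succ, K, 2, patches, seasons),
      gamma_succ = m(gamma_succ, K, 2, patches, genders),
      beta_succ = v(beta_succ, C, covariates),
      age_succ = v(age_succ, 4, ages),
      gp_choice = v(gp_choice, 3, c("eta_sq", "rho_sq", "sigma_sq")),
      gp_succ = v(gp_succ, 3, c("eta_sq", "rho_sq", "sigma_sq")),
      income_mu = income_mu,
      income_sigma = income_sigma,
      income_miss = income_miss
    ),
    class = "model_params"
  )
}

#' Flatten model parameters to a named vector
#'
#' Scalar names follow the `block[row,col]` convention, e.g.
#' `alpha_choice[winter_marine,ice]`, matching the columns of posterior
#' draw tables.
#'
#' @param params A [model_params()] object.
#' @return A named numeric vector.
#' @export
param_vector <- function(params) {
  flat <- function(x, block) {
    if (is.matrix(x)) {
      nm <- as.vector(outer(rownames(x), colnames(x),
                            function(r, c) paste0(block, "[", r, ",", c, "]")))
      stats::setNames(as.vector(x), nm)
    } else if (length(x) > 1 || !is.null(names(x))) {
      stats::setNames(as.numeric(x), paste0(block, "[", names(x), "]"))
    } else {
      stats::setNames(as.numeric(x), block)
    }
  }
  c(
    flat(params$alpha_choice, "alpha_choice"),
    flat(params$gamma_choice, "gamma_choice"),
    flat(params$beta_choice, "beta_choice"),
    flat(params$age_choice, "age_choice"),
    flat(params$alpha_succ, "alpha_succ"),
    flat(params$gamma_succ, "gamma_succ"),
    flat(params$beta_succ, "beta_succ"),
    flat(params$age_succ, "age_succ"),
    flat(params$gp_choice, "gp_choice"),
    flat(params$gp_succ, "gp_succ"),
    income_mu = params$income_mu,
    income_sigma = params$income_sigma,
    income_miss = params$income_miss
  )
}

#' Default prior configuration
#'
#' Weakly-informative defaults: zero-centered unit-scale normal priors on
#' all varying intercepts and coefficients (symmetric, which makes the
#' prior-predictive mean choice probability exactly 1/K and the mean success
#' probability exactly 1/2), half-Cauchy(0, 1) priors on the GP scale
#' hyperparameters, and the imputation hyper-priors Normal(0.5, 1) for the
#' latent-income mean and half-Cauchy(0, 1) for its standard deviation.
#'
#' @return A named list of blocks, each `list(family, loc, scale)`, of class
#'   `"prior_config"`. Families: `"normal"` and `"half_cauchy"`.
#' @export
default_prior_config <- function() {
  n <- function(loc, scale) list(family = "normal", loc = loc, scale = scale)
  hc <- function(scale) list(family = "half_cauchy", loc = 0, scale = scale)
  structure(
    list(
      alpha_choice = n(0, 1), gamma_choice = n(0, 1), beta_choice = n(0, 1),
      alpha_succ = n(0, 1), gamma_succ = n(0, 1), beta_succ = n(0, 1),
      gp_eta = hc(1), gp_rho = hc(1), gp_sigma = hc(1),
      income_mu = n(0.5, 1), income_sigma = hc(1)
    ),
    class = "prior_config"
  )
}

#' Read a prior configuration from YAML or JSON
#'
#' One entry per block with fields `family`, `loc`, `scale`; unlisted blocks
#' keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"prior_config"` list.
#' @export
read_prior_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_prior_config()
  for (block in names(raw)) {
    if (!block %in% names(cfg)) {
      stop("unknown prior block '", block, "'; known blocks: ",
           paste(names(cfg), collapse = ", "), call. = FALSE)
    }
    entry <- raw[[block]]
    for (f in c("family", "loc", "scale")) {
      if (is.null(entry[[f]])) {
        stop("prior block '", block, "' is missing field '", f, "'",
             call. = FALSE)
      }
    }
    if (!entry$family %in% c("normal", "half_cauchy")) {
      stop("prior block '", block, "': unsupported family '", entry$family,
           "'", call. = FALSE)
    }
    if (entry$scale <= 0) {
      stop("prior block '", block, "': scale must be positive", call. = FALSE)
    }
    cfg[[block]] <- list(family = entry$family, loc = entry$loc,
                         scale = entry$scale)
  }
  cfg
}
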