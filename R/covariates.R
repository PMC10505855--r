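#' Standardize model covariates
#'
#' Centers and scales the covariates that enter the regression models —
#' household income, in-degree, out-degree, and group size — to sample mean
#' 0 and sample standard deviation 1 (n − 1 denominator), computed over
#' non-missing entries. Missing incomes stay missing; they are handled by
#' Bayesian imputation at fit time. The scaling (center, scale, and the
#' observed range of each covariate) is recorded so that raw-valued
#' counterfactual profiles ("in-degree: 8") can be mapped onto the fitted
#' scale, and so predictions never silently extrapolate beyond observed
#' income.
#'
#' @param trips A validated trip tibble.
#' @param covariates Character vector of raw columns to standardize.
#' @return The trip tibble with added `<col>_std` columns and a
#'   `"scaling"` attribute: a tibble with columns `covariate`, `center`,
#'   `scale`, `min`, `max` (raw-scale range over non-missing values).
#'   Retrieve it with [covariate_scaling()].
#' @export
#' @examples
#' fx <- default_fixture()
#' trips <- standardize_covariates(fx$trips)
#' covariate_scaling(trips)
standardize_covariates <- function(trips,
                                   covariates = c("income", "in_degree",
                                                  "out_degree", "group_size")) {
  scaling <- purrr::map_dfr(covariates, function(cv) {
    x <- trips[[cv]]
    obs <- x[!is.na(x)]
    if (length(unique(obs)) < 2) {
      stop("covariate '", cv, "' is constant or has < 2 observed values; ",
           "cannot standardize (sd = 0)", call. = FALSE)
    }
    tibble::tibble(
      covariate = cv,
      center = mean(obs),
      scale = stats::sd(obs),   # sample sd, n - 1 denominator
      min = min(obs),
      max = max(obs)
    )
  })
  for (i in seq_len(nrow(scaling))) {
    cv <- scaling$covariate[i]
    trips[[paste0(cv, "_std")]] <-
      (trips[[cv]] - scaling$center[i]) / scaling$scale[i]
  }
  attr(trips, "scaling") <- scaling
  trips
}

#' Retrieve the covariate scaling attached to a standardized trip table
#'
#' @param trips A tibble returned by [standardize_covariates()].
#' @return The scaling tibble.
#' @export
covariate_scaling <- function(trips) {
  sc <- attr(trips, "scaling", exact = TRUE)
  if (is.null(sc)) {
    stop("no covariate scaling attached; run standardize_covariates() first",
         call. = FALSE)
  }
  sc
}

#' Map raw covariate values onto the standardized model scale
#'
#' @param scaling A scaling tibble from [standardize_covariates()].
#' @param covariate Covariate name (raw-scale column name).
#' @param x Raw values.
#' @return Standardized values `(x - center) / scale`.
#' @export
raw_to_std <- function(scaling, covariate, x) {
  i <- match(covariate, scaling$covariate)
  if (is.na(i)) stop("unknown covariate: ", covariate, call. = FALSE)
  (x - scaling$center[i]) / scaling$scale[i]
}

#' Invert the covariate standardization
#'
#' @inheritParams raw_to_std
#' @param z Standardized values.
#' @return Raw values `z * scale + center`.
#' @export
std_to_raw <- function(scaling, covariate, z) {
  i <- match(covariate, scaling$covariate)
  if (is.na(i)) stop("unknown covariate: ", covariate, call. = FALSE)
  z * scaling$scale[i] + scaling$center[i]
}
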