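#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted model
#'
#' One row per scalar parameter: posterior mean, sd, 89% HPD bounds, and
#' the convergence diagnostics.
#'
#' @param x A `"patch_fit"`.
#' @param mass HPD probability mass.
#' @param ... Unused.
#' @return A tibble `param, mean, sd, lo, hi, rhat, ess`.
#' @method tidy patch_fit
#' @export
tidy.patch_fit <- function(x, mass = 0.89, ...) {
  pars <- setdiff(names(x$draws), c(".chain", ".draw"))
  out <- purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    h <- if (stats::var(v) == 0) c(v[1], v[1]) else hpd_interval(v, mass)
    tibble::tibble(param = p, mean = mean(v), sd = stats::sd(v),
                   lo = h[1], hi = h[2])
  })
  dplyr::left_join(out, x$diagnostics[, c("param", "rhat", "ess")],
                   by = "param")
}

#' One-row fit overview
#'
#' @param x A `"patch_fit"`.
#' @param ... Unused.
#' @return A tibble with chain/draw counts, parameter count, worst R-hat,
#'   smallest ESS, and the warn state.
#' @method glance patch_fit
#' @export
glance.patch_fit <- function(x, ...) {
  tibble::tibble(
    n_trips = x$n_trips,
    n_chains = x$config$n_chains,
    n_draws = x$config$n_draws,
    n_params = ncol(x$draws) - 2L,
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_ess = min(x$diagnostics$ess[!x$diagnostics$degenerate]),
    warn = x$warn
  )
}

#' Tidy a profile prediction
#'
#' @param x A `"profile_prediction"`.
#' @param ... Unused.
#' @return The per-patch summary tibble.
#' @method tidy profile_prediction
#' @export
tidy.profile_prediction <- function(x, ...) x$summary
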