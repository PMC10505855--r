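#' Descriptive summary of a trip sample
#'
#' Reproduces the descriptive statistics reported for foraging-trip samples:
#' total trips, trips per patch and per gender, trips-per-harvester and
#' group-size quantiles (25/50/75%, linear interpolation between order
#' statistics, i.e. `stats::quantile(type = 7)`), and Pearson correlations
#' among household income, in-degree, and out-degree. Income correlations
#' use only households with non-missing income; the degree-degree
#' correlation uses all households.
#'
#' @param trips A validated trip tibble.
#' @param households A household tibble (`household_id, income, in_degree,
#'   out_degree, n_hunters`). If `NULL`, household rows are reconstructed
#'   from the trip table (one row per distinct household).
#' @return A list of class `"sample_summary"`: `n_trips`, `trips_per_patch`
#'   (tibble), `trips_per_gender` (tibble), `trips_per_harvester_quantiles`,
#'   `group_size_quantiles`, `correlations` (tibble with `pair`, `r`, `n`).
#' @export
summarize_sample <- function(trips, households = NULL) {
  stopifnot(nrow(trips) > 0)
  if (is.null(households)) {
    households <- trips |>
      dplyr::distinct(.data$household_id, .data$income, .data$in_degree,
                      .data$out_degree) |>
      dplyr::arrange(.data$household_id)
  }
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = TRUE)

  per_harvester <- trips |>
    dplyr::count(.data$harvester_id, name = "n_trips")

  known <- households[!is.na(households$income), ]
  correlations <- tibble::tibble(
    pair = c("income~in_degree", "income~out_degree", "in_degree~out_degree"),
    r = c(
      stats::cor(known$income, known$in_degree),
      stats::cor(known$income, known$out_degree),
      stats::cor(households$in_degree, households$out_degree)
    ),
    n = c(nrow(known), nrow(known), nrow(households))
  )

  structure(
    list(
      n_trips = nrow(trips),
      n_harvesters = dplyr::n_distinct(trips$harvester_id),
      n_households = dplyr::n_distinct(trips$household_id),
      trips_per_patch = dplyr::count(trips, .data$patch, name = "n"),
      trips_per_gender = dplyr::count(trips, .data$gender, name = "n"),
      trips_per_harvester_quantiles = q(per_harvester$n_trips),
      group_size_quantiles = q(trips$group_size),
      correlations = correlations
    ),
    class = "sample_summary"
  )
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("Foraging-trip sample:", x$n_trips, "trips,",
      x$n_harvesters, "harvesters,", x$n_households, "households\n")
  cat("\nTrips per patch:\n")
  print(x$trips_per_patch)
  cat("\nTrips per gender:\n")
  print(x$trips_per_gender)
  cat("\nGroup-size quantiles (25/50/75%):",
      paste(x$group_size_quantiles, collapse = " / "), "\n")
  cat("Trips per harvester (25/50/75%):",
      paste(x$trips_per_harvester_quantiles, collapse = " / "), "\n")
  cat("\nHousehold-level Pearson correlations:\n")
  print(x$correlations)
  invisible(x)
}
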