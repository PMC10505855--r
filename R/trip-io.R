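#' Read and validate a foraging-trip table
#'
#' Reads a CSV of foraging episodes (one row per trip) and validates it
#' against the patch taxonomy. Expected columns:
#' `trip_id, harvester_id, household_id, gender, age_class, season, patch,
#' success, group_size, income, in_degree, out_degree`. A missing household
#' income is an empty field in the CSV and becomes `NA` — never a sentinel
#' number.
#'
#' @param path Path to the CSV file (UTF-8, header required).
#' @param catalog Patch catalog used to resolve patch labels
#'   (case-insensitive, with aliasing; see [normalize_patch_label()]).
#' @param strict_season If `TRUE` (the default, intended for real data),
#'   reject trips whose season contradicts the patch's season tag; patches
#'   tagged `"both"` are compatible with either season.
#' @return A validated trip tibble with typed columns; `gender`, `age_class`,
#'   `season` and `patch` are plain character vectors restricted to their
#'   canonical levels.
#' @export
read_trip_table <- function(path, catalog = patch_catalog(),
                            strict_season = TRUE) {
  if (!file.exists(path)) {
    stop("trip file does not exist: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      trip_id = readr::col_character(),
      harvester_id = readr::col_character(),
      household_id = readr::col_character(),
      gender = readr::col_character(),
      age_class = readr::col_character(),
      season = readr::col_character(),
      patch = readr::col_character(),
      success = readr::col_integer(),
      group_size = readr::col_integer(),
      income = readr::col_double(),
      in_degree = readr::col_integer(),
      out_degree = readr::col_integer()
    ),
    progress = FALSE
  )
  validate_trip_table(raw, catalog = catalog, strict_season = strict_season)
}

#' Validate a trip tibble
#'
#' Applies the same checks as [read_trip_table()] to an in-memory table:
#' resolvable patch labels, known gender/age/season levels, positive group
#' sizes, non-negative degrees, unique trip ids, binary success, and
#' (optionally) season-patch consistency.
#'
#' @inheritParams read_trip_table
#' @param trips A data frame of trips.
#' @return The validated tibble, with patch labels normalized.
#' @export
validate_trip_table <- function(trips, catalog = patch_catalog(),
                                strict_season = TRUE) {
  trips <- tibble::as_tibble(trips)
  required <- c(
    "trip_id", "harvester_id", "household_id", "gender", "age_class",
    "season", "patch", "success", "group_size", "income",
    "in_degree", "out_degree"
  )
  missing_cols <- setdiff(required, names(trips))
  if (length(missing_cols) > 0) {
    stop("trip table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  bad_row <- function(flag, what) {
    if (any(flag)) {
      stop(what, " in row(s) ", paste(which(flag), collapse = ", "),
           call. = FALSE)
    }
  }

  norm <- normalize_patch_label(trips$patch, catalog)
  bad_row(is.na(norm), "unknown patch label")
  trips$patch <- norm

  bad_row(!trips$gender %in% gender_levels(), "unknown gender")
  bad_row(!trips$age_class %in% age_class_levels(), "unknown age_class")
  bad_row(!trips$season %in% season_levels(), "unknown season")
  bad_row(is.na(trips$group_size) | trips$group_size < 1,
          "group_size must be >= 1")
  bad_row(is.na(trips$in_degree) | trips$in_degree < 0, "negative in_degree")
  bad_row(is.na(trips$out_degree) | trips$out_degree < 0,
          "negative out_degree")
  bad_row(!trips$success %in% c(0L, 1L), "success must be 0 or 1")

  dup <- duplicated(trips$trip_id)
  if (any(dup)) {
    stop("duplicate trip_id in row(s) ", paste(which(dup), collapse = ", "),
         call. = FALSE)
  }

  if (strict_season) {
    tag <- catalog$season_tag[match(trips$patch, catalog$patch)]
    clash <- tag != "both" & tag != trips$season
    bad_row(clash, "season inconsistent with patch season tag")
  }

  trips$success <- as.integer(trips$success)
  trips$group_size <- as.integer(trips$group_size)
  trips$in_degree <- as.integer(trips$in_degree)
  trips$out_degree <- as.integer(trips$out_degree)
  trips
}

#' Write a trip table to CSV
#'
#' Round-trips with [read_trip_table()]: integer and categorical fields are
#' preserved exactly and missing income is written as an empty field.
#'
#' @param trips A trip tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trip_table <- function(trips, path) {
  readr::write_csv(trips, path, na = "")
  invisible(path)
}

#' Read a household table
#'
#' Columns: `household_id, income, in_degree, out_degree, n_hunters`;
#' missing income is an empty field.
#'
#' @param path Path to the CSV file.
#' @return A household tibble.
#' @export
read_household_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      household_id = readr::col_character(),
      income = readr::col_double(),
      in_degree = readr::col_integer(),
      out_degree = readr::col_integer(),
      n_hunters = readr::col_integer()
    ),
    progress = FALSE
  )
}

#' Write a household table to CSV
#' @param households A household tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_household_table <- function(households, path) {
  readr::write_csv(households, path, na = "")
  invisible(path)
}
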