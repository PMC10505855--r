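#' Configuration of the synthetic trip generator
#'
#' Defaults encode the study sample that the generator emulates: 281 trips
#' by 23 harvesters in 13 households; per-patch trip counts 47 (winter
#' inland), 38 (winter marine), 72 (spring inland), 21 (summer/autumn
#' inland), 75 (summer/autumn marine), 20 (tidal) and 8 (incidental); 228
#' trips by men; one household with missing income whose 3 hunters account
#' for 35 trips; household-level Pearson correlations of income with
#' in-degree (-0.22) and out-degree (0.39) over the 12 income-known
#' households and of in- with out-degree (-0.07) over all 13; and
#' group-size quartiles (2, 3, 4).
#'
#' @param n_trips,n_harvesters,n_households Sample sizes.
#' @param patch_margins Named integer vector of trips per patch; must sum to
#'   `n_trips`.
#' @param men_trips Number of trips by men (the rest are by women).
#' @param men_harvesters,women_harvesters Harvester gender composition
#'   (only the trip-level gender split is reported for the study sample;
#'   the 18/5 split is a documented assumption).
#' @param missing_income_household Household id whose income is missing.
#' @param missing_n_hunters,missing_n_trips Hunters and trips of the
#'   income-missing household.
#' @param target_correlations Named vector `r_income_in`, `r_income_out`
#'   (over income-known households), `r_in_out` (over all households).
#' @param group_size_quartiles Targets for the 25/50/75% group-size
#'   quantiles.
#' @param degree_mean Target mean of in- and out-degrees (held exactly by
#'   the solver).
#' @param seed Integer seed driving every random choice in the generator.
#' @param max_iter Iteration budget of the correlation solver.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_trips = 281L,
                             n_harvesters = 23L,
                             n_households = 13L,
                             patch_margins = c(
                               winter_inland = 47L, winter_marine = 38L,
                               spring_inland = 72L,
                               summerautumn_inland = 21L,
                               summerautumn_marine = 75L,
                               tidal = 20L, incidental = 8L
                             ),
                             men_trips = 228L,
                             men_harvesters = 18L,
                             women_harvesters = 5L,
                             missing_income_household = "h07",
                             missing_n_hunters = 3L,
                             missing_n_trips = 35L,
                             target_correlations = c(
                               r_income_in = -0.22, r_income_out = 0.39,
                               r_in_out = -0.07
                             ),
                             group_size_quartiles = c(2L, 3L, 4L),
                             degree_mean = 4,
                             seed = 20131L,
                             max_iter = 50000L) {
  if (sum(patch_margins) != n_trips) {
    stop("patch_margins must sum to n_trips (", n_trips, "), got ",
         sum(patch_margins), call. = FALSE)
  }
  if (men_trips > n_trips) stop("men_trips exceeds n_trips", call. = FALSE)
  if (men_harvesters + women_harvesters != n_harvesters) {
    stop("harvester gender composition must sum to n_harvesters",
         call. = FALSE)
  }
  structure(
    list(
      n_trips = as.integer(n_trips),
      n_harvesters = as.integer(n_harvesters),
      n_households = as.integer(n_households),
      patch_margins = patch_margins,
      men_trips = as.integer(men_trips),
      men_harvesters = as.integer(men_harvesters),
      women_harvesters = as.integer(women_harvesters),
      missing_income_household = missing_income_household,
      missing_n_hunters = as.integer(missing_n_hunters),
      missing_n_trips = as.integer(missing_n_trips),
      target_correlations = target_correlations,
      group_size_quartiles = group_size_quartiles,
      degree_mean = degree_mean,
      seed = as.integer(seed),
      max_iter = as.integer(max_iter)
    ),
    class = "generator_config"
  )
}

#' Generative ground-truth parameters for the default fixture
#'
#' Choice intercepts follow the log of the fixture patch margins (so
#' model-based simulations resemble the sample composition); per-patch
#' baseline success probabilities reflect the ethnographic description of
#' patch reliability — tidal gathering highly reliable, winter marine
#' floe-edge hunting succeeding on 22.5% of trips (within the reported
#' 20-25% range) — and modest covariate effects: income favouring inland
#' patches and disfavouring winter marine, group size favouring spring
#' inland.
#'
#' @param config A [generator_config()].
#' @return A [model_params()] object usable as `TrueParams`.
#' @export
default_true_params <- function(config = generator_config()) {
  patches <- names(config$patch_margins)
  K <- length(patches)
  base_choice <- log(config$patch_margins / sum(config$patch_margins))
  base_choice <- base_choice - mean(base_choice)
  succ_p <- c(
    winter_inland = 0.60, winter_marine = 0.225, spring_inland = 0.70,
    summerautumn_inland = 0.50, summerautumn_marine = 0.45,
    tidal = 0.90, incidental = 0.50
  )[patches]
  beta_choice <- matrix(0, K, 4,
                        dimnames = list(patches,
                                        c("income_std", "in_degree_std",
                                          "out_degree_std",
                                          "group_size_std")))
  beta_choice["winter_inland", "income_std"] <- 0.3
  beta_choice["summerautumn_inland", "income_std"] <- 0.3
  beta_choice["winter_marine", "income_std"] <- -0.4
  beta_choice["spring_inland", "group_size_std"] <- 0.3
  model_params(
    patches = patches,
    alpha_choice = cbind(base_choice, base_choice),
    beta_choice = beta_choice,
    alpha_succ = cbind(stats::qlogis(succ_p), stats::qlogis(succ_p)),
    gamma_succ = cbind(rep(0, K), rep(0.1, K)),
    gp_choice = c(eta_sq = 0.25, rho_sq = 0.5, sigma_sq = 0.05),
    gp_succ = c(eta_sq = 0.25, rho_sq = 0.5, sigma_sq = 0.05)
  )
}

# split `total` into n decreasing positive integer parts (deterministic)
split_total <- function(total, n) {
  stopifnot(total >= n)
  w <- 0.7^(0:(n - 1))
  raw <- total * w / sum(w)
  parts <- floor(raw)
  parts[parts < 1] <- 1L
  rem <- total - sum(parts)
  i <- 1
  while (rem != 0) {
    idx <- ((i - 1) %% n) + 1
    step <- sign(rem)
    if (parts[idx] + step >= 1) {
      parts[idx] <- parts[idx] + step
      rem <- rem - step
    }
    i <- i + 1
  }
  as.integer(parts)
}

#' Deterministic household table matching the target correlations
#'
#' Constructs the synthetic household table: integer in- and out-degrees
#' with mean held exactly at `degree_mean`, brought to the target
#' degree-degree correlation by a seeded hill-climbing search over
#' sum-preserving unit moves, and incomes solved in closed form so that the
#' Pearson correlations of income with each degree over the income-known
#' households hit their targets essentially exactly (a linear combination
#' of the standardized degree vectors plus an orthogonalized residual).
#' One household's income is left missing.
#'
#' @param config A [generator_config()].
#' @return A tibble `household_id, income, in_degree, out_degree, n_hunters`
#'   with `nrow == config$n_households`; deterministic given `config$seed`.
#' @export
solve_household_table <- function(config = generator_config()) {
  H <- config$n_households
  if (H < 3) {
    stop("correlation targets are underdetermined with fewer than 3 ",
         "households", call. = FALSE)
  }
  tc <- config$target_correlations
  if (any(abs(tc) >= 1)) stop("target correlations must satisfy |r| < 1",
                              call. = FALSE)
  ids <- sprintf("h%02d", seq_len(H))
  if (!config$missing_income_household %in% ids) {
    stop("missing_income_household not among generated ids", call. = FALSE)
  }
  rng <- local({
    set.seed(config$seed)
    NULL
  })

  # --- degrees: seeded start with exact mean, then sum-preserving moves ----
  start_vec <- function() {
    v <- rep(round(config$degree_mean), H)
    for (j in seq_len(3 * H)) {
      i1 <- sample.int(H, 1); i2 <- sample.int(H, 1)
      if (i1 != i2 && v[i1] < 9 && v[i2] > 0) {
        v[i1] <- v[i1] + 1L; v[i2] <- v[i2] - 1L
      }
    }
    v
  }
  in_deg <- start_vec()
  out_deg <- start_vec()
  obj <- function(a, b) abs(stats::cor(a, b) - tc["r_in_out"])
  cur <- obj(in_deg, out_deg)
  it <- 0L
  while (cur > 0.004 && it < config$max_iter) {
    it <- it + 1L
    which_vec <- sample(c("in", "out"), 1)
    v <- if (which_vec == "in") in_deg else out_deg
    i1 <- sample.int(H, 1); i2 <- sample.int(H, 1)
    if (i1 == i2 || v[i1] >= 9 || v[i2] <= 0) next
    v2 <- v
    v2[i1] <- v2[i1] + 1L; v2[i2] <- v2[i2] - 1L
    new <- if (which_vec == "in") obj(v2, out_deg) else obj(in_deg, v2)
    if (new <= cur) {
      cur <- new
      if (which_vec == "in") in_deg <- v2 else out_deg <- v2
    }
  }
  if (cur > 0.005) {
    stop(sprintf(
      "degree solver failed: best |r(in,out) - target| = %.4f after %d moves",
      cur, it), call. = FALSE)
  }

  # --- incomes: exact linear-algebra construction over known households ---
  miss_idx <- match(config$missing_income_household, ids)
  known <- setdiff(seq_len(H), miss_idx)
  u1 <- in_deg[known]; u2 <- out_deg[known]
  std <- function(x) (x - mean(x)) / stats::sd(x)
  u1s <- std(u1); u2s <- std(u2)
  S <- stats::cor(cbind(u1, u2))
  r <- c(tc["r_income_in"], tc["r_income_out"])
  a <- solve(S, r)
  b2 <- 1 - sum(a * r)
  if (b2 < 0) {
    stop("income correlation targets are jointly infeasible given the ",
         "degree correlation", call. = FALSE)
  }
  eps <- stats::rnorm(length(known))
  eps <- stats::residuals(stats::lm(eps ~ u1s + u2s))
  eps <- eps / stats::sd(eps)
  x <- a[1] * u1s + a[2] * u2s + sqrt(b2) * eps
  income <- rep(NA_real_, H)
  income[known] <- 65 + 20 * std(x)   # arbitrary currency units (thousands)

  achieved <- c(stats::cor(income[known], in_deg[known]),
                stats::cor(income[known], out_deg[known]),
                stats::cor(in_deg, out_deg))
  if (any(abs(achieved - tc) > 0.005)) {
    stop(sprintf(
      "household solver missed tolerance; achieved r = (%.4f, %.4f, %.4f)",
      achieved[1], achieved[2], achieved[3]), call. = FALSE)
  }

  # hunters per household: missing household fixed, remainder in 2s and 1s
  n_hunters <- integer(H)
  n_hunters[miss_idx] <- config$missing_n_hunters
  rest <- config$n_harvesters - config$missing_n_hunters
  other <- setdiff(seq_len(H), miss_idx)
  base <- rest %/% length(other)
  n_hunters[other] <- base
  extra <- rest - base * length(other)
  if (extra > 0) n_hunters[other[seq_len(extra)]] <-
      n_hunters[other[seq_len(extra)]] + 1L

  tibble::tibble(
    household_id = ids,
    income = income,
    in_degree = as.integer(in_deg),
    out_degree = as.integer(out_deg),
    n_hunters = n_hunters
  )
}

# integer group sizes with the configured quartiles, built by construction
group_size_counts <- function(n) {
  props <- c(`1` = 30, `2` = 60, `3` = 90, `4` = 60, `5` = 20, `6` = 15,
             `8` = 6) / 281
  counts <- floor(props * n)
  rem <- n - sum(counts)
  ord <- order(props * n - counts, decreasing = TRUE)
  i <- 1
  while (rem > 0) {
    counts[ord[i]] <- counts[ord[i]] + 1
    rem <- rem - 1
    i <- i %% length(counts) + 1
  }
  rep(as.integer(names(props)), counts)
}

#' The margin-matched synthetic fixture
#'
#' Builds a deterministic trip table and household table replicating the
#' study's sample composition exactly: all marginal counts (trips, per-patch
#' margins, men's trips, the missing-income household's 35 trips by 3
#' hunters) hold by construction for every seed; the seed only shuffles
#' assignments and draws success flags from the generative success model.
#' Women are never assigned to the winter marine patch, matching the
#' ethnographic record.
#'
#' @param config A [generator_config()].
#' @param true_params Ground-truth parameters driving the success flags;
#'   defaults to [default_true_params()].
#' @return A list with elements `trips` (tibble, one row per foraging
#'   episode), `households`, and `true_params`.
#' @export
#' @examples
#' fx <- default_fixture()
#' nrow(fx$trips)  # 281
default_fixture <- function(config = generator_config(),
                            true_params = default_true_params(config)) {
  set.seed(config$seed)
  households <- solve_household_table(config)
  catalog <- patch_catalog()

  # harvesters -------------------------------------------------------------
  women_trips_total <- config$n_trips - config$men_trips
  miss_hh <- config$missing_income_household
  n_men <- config$men_harvesters
  n_women <- config$women_harvesters

  men_ids <- sprintf("x%02d", seq_len(n_men))
  women_ids <- sprintf("x%02d", n_men + seq_len(n_women))
  # the missing-income household's hunters are the first men
  miss_men <- men_ids[seq_len(config$missing_n_hunters)]
  other_men <- setdiff(men_ids, miss_men)

  trips_miss <- split_total(config$missing_n_trips,
                            config$missing_n_hunters)
  trips_other_men <- split_total(config$men_trips - config$missing_n_trips,
                                 length(other_men))
  trips_women <- split_total(women_trips_total, n_women)

  harvesters <- tibble::tibble(
    harvester_id = c(miss_men, other_men, women_ids),
    gender = c(rep("man", n_men), rep("woman", n_women)),
    n_trips = c(trips_miss, trips_other_men, trips_women)
  )
  harvesters$age_class <-
    rep(age_class_levels(), length.out = nrow(harvesters))

  # household assignment: missing household first, others filled by slots
  slots <- households[households$household_id != miss_hh, ]
  slot_ids <- rep(slots$household_id, slots$n_hunters)
  harvesters$household_id <- NA_character_
  harvesters$household_id[harvesters$harvester_id %in% miss_men] <- miss_hh
  rest <- which(is.na(harvesters$household_id))
  harvesters$household_id[rest] <- slot_ids[seq_along(rest)]

  # trips ------------------------------------------------------------------
  trips <- tibble::tibble(
    harvester_id = rep(harvesters$harvester_id, harvesters$n_trips)
  )
  trips <- dplyr::left_join(
    trips,
    harvesters[, c("harvester_id", "gender", "age_class", "household_id")],
    by = "harvester_id"
  )

  patch_vec <- sample(rep(names(config$patch_margins), config$patch_margins))
  trips$patch <- patch_vec
  # keep women out of winter marine by swapping with men's other patches
  w_wm <- which(trips$gender == "woman" & trips$patch == "winter_marine")
  m_ok <- which(trips$gender == "man" & trips$patch != "winter_marine")
  if (length(w_wm) > 0) {
    swap <- m_ok[seq_along(w_wm)]
    tmp <- trips$patch[swap]
    trips$patch[swap] <- trips$patch[w_wm]
    trips$patch[w_wm] <- tmp
  }

  tag <- catalog$season_tag[match(trips$patch, catalog$patch)]
  trips$season <- ifelse(tag == "both", NA_character_, tag)
  for (p in catalog$patch[catalog$season_tag == "both"]) {
    idx <- which(trips$patch == p)
    half <- length(idx) %/% 2
    trips$season[idx] <- rep(c("ice", "ice_free"),
                             c(half, length(idx) - half))
  }

  trips$group_size <- sample(group_size_counts(config$n_trips))

  trips <- dplyr::left_join(
    trips, households[, c("household_id", "income", "in_degree",
                          "out_degree")],
    by = "household_id"
  )

  trips <- trips[sample.int(nrow(trips)), ]
  trips$trip_id <- sprintf("t%03d", seq_len(nrow(trips)))
  trips$success <- 0L
  trips <- trips[, c("trip_id", "harvester_id", "household_id", "gender",
                     "age_class", "season", "patch", "success", "group_size",
                     "income", "in_degree", "out_degree")]

  std <- standardize_covariates(trips)
  p_succ <- success_prob(std, true_params)
  trips$success <- as.integer(stats::rbinom(nrow(trips), 1, p_succ))

  list(trips = tibble::as_tibble(trips), households = households,
       true_params = true_params)
}

#' Simulate trips from the generative model
#'
#' Draws each trip's patch from the categorical softmax choice model at the
#' trip's covariates, then its success from the logistic success model
#' given the drawn patch. Covariate handling: rows of `design` that already
#' carry `*_std` columns are used as-is; raw covariate columns are
#' converted with `scaling` if supplied; covariates absent from `design`
#' sit at their mean (standardized 0).
#'
#' @param true_params A [model_params()] object (generative truth).
#' @param design A tibble of trip-level covariates (`gender`, `age_class`,
#'   `season`, and optionally covariate columns); rows are recycled to `n`.
#' @param n Number of trips to simulate.
#' @param seed Integer seed.
#' @param scaling Optional scaling tibble for raw-to-standardized
#'   conversion of `design` covariates.
#' @return A trip tibble of `n` rows with drawn `patch` and `success`.
#' @export
simulate_trips <- function(true_params, design, n, seed,
                           scaling = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  design <- tibble::as_tibble(design)
  idx <- rep_len(seq_len(nrow(design)), n)
  sim <- design[idx, , drop = FALSE]

  raw_of <- function(std_name) sub("_std$", "", std_name)
  for (cv in true_params$covariates) {
    if (!cv %in% names(sim)) {
      raw <- raw_of(cv)
      if (raw %in% names(sim) && !is.null(scaling)) {
        sim[[cv]] <- raw_to_std(scaling, raw, sim[[raw]])
      } else {
        sim[[cv]] <- 0
      }
    }
  }
  for (col in c("gender", "age_class", "season")) {
    if (!col %in% names(sim)) {
      stop("design must supply column '", col, "'", call. = FALSE)
    }
  }

  eta <- linear_predictor_choice(sim, true_params)
  # Gumbel-max trick: exact categorical draw per row
  g <- -log(-log(stats::runif(length(eta))))
  sim$patch <- true_params$patches[max.col(eta + g, ties.method = "first")]

  p <- success_prob(sim, true_params)
  sim$success <- as.integer(stats::rbinom(n, 1, p))
  sim$trip_id <- sprintf("s%05d", seq_len(n))
  if (!"harvester_id" %in% names(sim)) sim$harvester_id <- "sim"
  if (!"household_id" %in% names(sim)) sim$household_id <- "sim"
  if (!"group_size" %in% names(sim)) sim$group_size <- 1L
  if (!"income" %in% names(sim)) sim$income <- NA_real_
  if (!"in_degree" %in% names(sim)) sim$in_degree <- 0L
  if (!"out_degree" %in% names(sim)) sim$out_degree <- 0L
  tibble::as_tibble(sim)
}

#' Blank out one household's income
#'
#' Sets `income` (and `income_std`, when present) to missing for every trip
#' of the given household; idempotent and otherwise a no-op.
#'
#' @param trips A trip tibble.
#' @param household_id Household whose income to remove.
#' @param households Optional household table defining the known household
#'   ids; a household with no trips then leaves the table unchanged rather
#'   than erroring.
#' @return The modified tibble.
#' @export
inject_missing_income <- function(trips, household_id, households = NULL) {
  known <- if (is.null(households)) trips$household_id else
    households$household_id
  if (!household_id %in% known) {
    stop("unknown household: ", household_id, call. = FALSE)
  }
  hit <- trips$household_id == household_id
  trips$income[hit] <- NA_real_
  if ("income_std" %in% names(trips)) trips$income_std[hit] <- NA_real_
  trips
}
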