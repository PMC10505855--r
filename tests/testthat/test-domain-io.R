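test_that("patch catalog has the seven patches with their season tags", {
  cat <- patch_catalog()
  expect_equal(nrow(cat), 7)
  expect_false(any(duplicated(cat$patch)))
  tags <- setNames(cat$season_tag, cat$patch)
  expect_equal(unname(tags[c("winter_inland", "winter_marine",
                             "spring_inland")]), rep("ice", 3))
  expect_equal(unname(tags[c("summerautumn_inland", "summerautumn_marine")]),
               rep("ice_free", 2))
  expect_equal(unname(tags[c("tidal", "incidental")]), rep("both", 2))
})

test_that("trip CSV round-trips exactly and aliases resolve", {
  trips <- tibble::tibble(
    trip_id = c("t1", "t2", "t3"),
    harvester_id = "x1", household_id = "h1",
    gender = "man", age_class = "30to40",
    season = c("ice", "ice", "ice_free"),
    patch = c("Winter Marine", "spring-inland", "summer/autumn marine"),
    success = c(1L, 0L, 1L), group_size = c(2L, 3L, 1L),
    income = c(50, 50, 50), in_degree = 4L, out_degree = 2L
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(trips, path)
  got <- read_trip_table(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$patch,
               c("winter_marine", "spring_inland", "summerautumn_marine"))
  # round trip preserves every field
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trip_table(got, path2)
  again <- read_trip_table(path2)
  expect_equal(as.data.frame(again), as.data.frame(got))
})

test_that("missing income round-trips as NA, never a sentinel", {
  trips <- get_fixture()$trips
  path <- withr::local_tempfile(fileext = ".csv")
  write_trip_table(trips, path)
  expect_false(grepl("NA", readLines(path)[1]))
  got <- read_trip_table(path)
  expect_equal(sum(is.na(got$income)), sum(is.na(trips$income)))
  expect_equal(sort(got$income[!is.na(got$income)]),
               sort(trips$income[!is.na(trips$income)]),
               tolerance = 1e-12)
})

test_that("invalid trip rows are rejected with their row number", {
  base <- tibble::tibble(
    trip_id = c("t1", "t2"), harvester_id = "x1", household_id = "h1",
    gender = "man", age_class = "30to40", season = "ice",
    patch = "winter_inland", success = 0L, group_size = 2L,
    income = 10, in_degree = 1L, out_degree = 1L
  )
  bad <- base; bad$patch[2] <- "lunar_marine"
  expect_error(validate_trip_table(bad), "unknown patch.*2")
  bad <- base; bad$group_size[2] <- 0L
  expect_error(validate_trip_table(bad), "group_size.*2")
  bad <- base; bad$trip_id[2] <- "t1"
  expect_error(validate_trip_table(bad), "duplicate trip_id.*2")
  bad <- base; bad$in_degree[1] <- -1L
  expect_error(validate_trip_table(bad), "in_degree")
})

test_that("strict-season mode rejects patch/season contradictions", {
  base <- tibble::tibble(
    trip_id = "t1", harvester_id = "x1", household_id = "h1",
    gender = "man", age_class = "30to40", season = "ice_free",
    patch = "winter_inland", success = 0L, group_size = 2L,
    income = 10, in_degree = 1L, out_degree = 1L
  )
  expect_error(validate_trip_table(base, strict_season = TRUE),
               "season inconsistent")
  expect_silent(validate_trip_table(base, strict_season = FALSE))
  # year-round patches are compatible with either season
  both <- base; both$patch <- "tidal"
  expect_silent(validate_trip_table(both, strict_season = TRUE))
})

test_that("standardization uses the n-1 sd convention and inverts exactly", {
  trips <- tibble::tibble(
    trip_id = c("a", "b", "c"), harvester_id = "x", household_id = "h",
    gender = "man", age_class = "under30", season = "ice",
    patch = "winter_inland", success = 0L,
    group_size = c(1L, 2L, 3L), income = c(10, 20, 30),
    in_degree = c(0L, 1L, 2L), out_degree = c(2L, 1L, 0L)
  )
  std <- standardize_covariates(trips)
  # sample sd of (10, 20, 30) is 10, so values map to (-1, 0, 1)
  expect_equal(std$income_std, c(-1, 0, 1), tolerance = 1e-12)
  sc <- covariate_scaling(std)
  expect_equal(sc$center[sc$covariate == "income"], 20)
  expect_equal(sc$scale[sc$covariate == "income"], 10)
  # inverse transform is the identity
  for (cv in sc$covariate) {
    back <- std_to_raw(sc, cv, std[[paste0(cv, "_std")]])
    expect_equal(back, as.numeric(trips[[cv]]), tolerance = 1e-10)
  }
})

test_that("standardization errors on constants and preserves missingness", {
  trips <- get_fixture()$trips
  std <- standardize_covariates(trips)
  expect_identical(is.na(std$income_std), is.na(std$income))
  obs <- std$income_std[!is.na(std$income_std)]
  expect_equal(mean(obs), 0, tolerance = 1e-12)
  expect_equal(sd(obs), 1, tolerance = 1e-12)

  const <- trips
  const$group_size <- 2L
  expect_error(standardize_covariates(const), "constant")
})

test_that("network degrees count distinct non-self-reported ties", {
  hh <- c("A", "B", "C")
  edges <- tibble::tibble(
    giver = c("A", "A"), receiver = c("B", "C"), reporter = c("B", "C")
  )
  deg <- compute_network_degrees(edges, hh)
  expect_equal(deg$out_degree[deg$household_id == "A"], 2)
  # B's in-degree rests on B's own report only, so it does not count
  expect_equal(deg$in_degree[deg$household_id == "B"], 0)
  # once a third party attests the same tie, it does
  deg_att <- compute_network_degrees(
    dplyr::add_row(edges, giver = "A", receiver = "B", reporter = "C"), hh)
  expect_equal(deg_att$in_degree[deg_att$household_id == "B"], 1)

  # a tie attested only by the focal household itself does not count
  own <- tibble::tibble(giver = "A", receiver = "B", reporter = "A")
  deg2 <- compute_network_degrees(own, hh)
  expect_equal(deg2$out_degree[deg2$household_id == "A"], 0)
  # ... but it still counts for the other endpoint
  expect_equal(deg2$in_degree[deg2$household_id == "B"], 1)

  # duplicate reports collapse; self-loops are dropped; empty list is zeros
  dup <- tibble::tibble(
    giver = c("A", "A", "C"), receiver = c("B", "B", "C"),
    reporter = c("B", "C", "A")
  )
  deg3 <- compute_network_degrees(dup, hh)
  expect_equal(deg3$out_degree[deg3$household_id == "A"], 1)
  empty <- compute_network_degrees(tibble::tibble(
    giver = character(), receiver = character(), reporter = character()
  ), hh)
  expect_true(all(empty$in_degree == 0) && all(empty$out_degree == 0))

  # permutation invariance in edge order
  set.seed(4)
  perm <- dup[sample(nrow(dup)), ]
  expect_equal(compute_network_degrees(perm, hh), deg3)
})

test_that("sample summary reports counts, quantiles, and correlations", {
  fx <- get_fixture()
  s <- summarize_sample(fx$trips, fx$households)
  expect_equal(s$n_trips, 281)
  per_patch <- setNames(s$trips_per_patch$n, s$trips_per_patch$patch)
  expect_equal(unname(per_patch["winter_inland"]), 47)
  expect_equal(unname(per_patch["summerautumn_marine"]), 75)
  expect_equal(unname(s$trips_per_gender$n[s$trips_per_gender$gender ==
                                             "man"]), 228)
  expect_equal(unname(s$group_size_quantiles["50%"]), 3)

  single <- fx$trips[1, ]
  s1 <- summarize_sample(single)
  expect_equal(s1$n_trips, 1)
  expect_equal(s1$trips_per_patch$n, 1)
  expect_equal(s1$trips_per_patch$patch, single$patch)
})
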