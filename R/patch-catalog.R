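#' The seven-patch foraging taxonomy
#'
#' Contemporary Inuit harvesting activities fall into seven patch categories
#' defined by season, habitat, target species, and harvest method. Three
#' patches are tied to the snow-and-ice season (winter inland char netting,
#' winter marine floe-edge hunting, spring inland jigging and bird hunting),
#' two to the ice-free season (summer/autumn inland and marine), and two —
#' tidal gathering and incidental harvests embedded in other travel — can be
#' pursued year-round.
#'
#' @return A tibble with one row per patch and columns `patch`, `season_tag`
#'   (`"ice"`, `"ice_free"`, or `"both"`), `major_resources`, `major_methods`.
#'   Row order defines the canonical patch ordering used throughout the
#'   package (patch index k = 1..7).
#' @export
#' @examples
#' patch_catalog()
patch_catalog <- function() {
  tibble::tibble(
    patch = c(
      "winter_inland", "winter_marine", "spring_inland",
      "summerautumn_inland", "summerautumn_marine", "tidal", "incidental"
    ),
    season_tag = c("ice", "ice", "ice", "ice_free", "ice_free", "both", "both"),
    major_resources = c(
      "char",
      "seal, polar bear",
      "char, goose, ptarmigan",
      "caribou, char",
      "beluga, seal, char",
      "mussels",
      "char, birds"
    ),
    major_methods = c(
      "ice netting, rifle snowmobile hunting",
      "rifle hunting at ice floe edge",
      "ice jigging, rifle snowmobile hunting",
      "rifle ATV hunting, lake rod and net fishing",
      "canoe hunting, netting, rod fishing",
      "gathering at low tide",
      "embedded in other activities on the land"
    )
  )
}

#' Canonical patch identifiers, in model order
#'
#' @param catalog A patch catalog, as returned by [patch_catalog()].
#' @return Character vector of patch identifiers.
#' @export
patch_levels <- function(catalog = patch_catalog()) {
  catalog$patch
}

#' Season levels
#' @return `c("ice", "ice_free")` — the two-level season variable
#'   (winter + spring vs. summer + autumn).
#' @export
season_levels <- function() c("ice", "ice_free")

#' Gender levels
#' @return `c("man", "woman")`.
#' @export
gender_levels <- function() c("man", "woman")

#' Ordinal age-class levels
#' @return `c("under30", "30to40", "40to50", "over50")`, the four ordered
#'   harvester age classes used by the latent Gaussian-process age effect.
#' @export
age_class_levels <- function() c("under30", "30to40", "40to50", "over50")

#' Normalize free-form patch labels to canonical identifiers
#'
#' Case-insensitive; spaces, hyphens and slashes collapse to underscores, so
#' `"Winter Marine"`, `"winter-marine"` and `"WINTER_MARINE"` all resolve to
#' `"winter_marine"`, and `"summer/autumn marine"` resolves to
#' `"summerautumn_marine"`.
#'
#' @param x Character vector of patch labels.
#' @param catalog Patch catalog to resolve against.
#' @return Character vector of canonical identifiers; `NA` where a label does
#'   not resolve.
#' @export
normalize_patch_label <- function(x, catalog = patch_catalog()) {
  key <- function(s) {
    s <- tolower(trimws(s))
    s <- gsub("[/ -]+", "_", s)
    s <- gsub("_+", "_", s)
    s
  }
  canon <- patch_levels(catalog)
  lookup <- stats::setNames(canon, key(canon))
  # aliases beyond mechanical normalization
  extra <- c(
    "summer_autumn_inland" = "summerautumn_inland",
    "summer_autumn_marine" = "summerautumn_marine",
    "summerautumn_inland"  = "summerautumn_inland",
    "summerautumn_marine"  = "summerautumn_marine",
    "tidal_zone"           = "tidal"
  )
  lookup <- c(lookup, extra[setdiff(names(extra), names(lookup))])
  unname(lookup[key(x)])
}
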