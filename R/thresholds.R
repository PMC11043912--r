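#' Multiple-traffic-light threshold configuration
#'
#' The UK front-of-package multiple-traffic-light (MTL) scheme colours each of
#' fat, saturated fat, total sugar and salt green ("low"), amber ("medium") or
#' red ("high") against per-100 g cut-offs for foods and stricter per-100 ml
#' cut-offs for drinks. A threshold configuration holds, for every
#' (nutrient, basis) pair, the two bounds that delimit the bands:
#' a value is green iff `value <= low_max`, red iff `value > high_min`,
#' and amber otherwise. Both conventions are inclusive on the green side and
#' exclusive on the red side, so an item sitting exactly on a printed bound
#' gets the milder colour.
#'
#' `mtl_thresholds()` returns the default configuration: the Food Standards
#' Agency / Department of Health 2016 front-of-pack guidance values.
#' `read_thresholds()` loads an alternative cut-off set from a CSV file with
#' columns `nutrient`, `basis`, `low_max`, `high_min`, so altered cut-off
#' points can be explored without code change.
#'
#' @param path Path to a CSV threshold file.
#' @return A tibble with columns `nutrient` (one of `"fat"`, `"satfat"`,
#'   `"sugar"`, `"salt"`), `basis` (`"food"` or `"drink"`), `low_max` and
#'   `high_min` (grams per 100 g / 100 ml), of class `mtl_thresholds`.
#' @examples
#' cfg <- mtl_thresholds()
#' cfg[cfg$nutrient == "fat", ]
#' @export
mtl_thresholds <- function() {
  path <- system.file("extdata", "fsa_mtl_cutoffs.csv", package = "novafopl")
  read_thresholds(path)
}

#' @rdname mtl_thresholds
#' @export
read_thresholds <- function(path) {
  cfg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_thresholds(cfg)
  class(cfg) <- c("mtl_thresholds", class(cfg))
  cfg
}

#' Validate a threshold configuration
#'
#' Checks structural completeness (all four nutrients on both bases) and the
#' ordering invariants: `low_max < high_min` within each (nutrient, basis),
#' and drink `high_min` never above the food `high_min` for the same nutrient
#' (drink cut-offs are lower or equal by construction of the scheme).
#'
#' @param cfg A threshold tibble as returned by [read_thresholds()].
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_thresholds <- function(cfg) {
  req <- c("nutrient", "basis", "low_max", "high_min")
  missing_cols <- setdiff(req, names(cfg))
  if (length(missing_cols) > 0) {
    stop("threshold config lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  want <- expand.grid(nutrient = fopl_nutrients(), basis = c("food", "drink"),
                      stringsAsFactors = FALSE)
  have <- paste(cfg$nutrient, cfg$basis)
  lack <- setdiff(paste(want$nutrient, want$basis), have)
  if (length(lack) > 0) {
    stop("threshold config missing (nutrient, basis) pair(s): ",
         paste(lack, collapse = "; "), call. = FALSE)
  }
  if (anyDuplicated(have)) {
    stop("duplicated (nutrient, basis) rows in threshold config", call. = FALSE)
  }
  bad <- cfg$low_max >= cfg$high_min
  if (any(bad)) {
    stop("low_max must be < high_min; violated for: ",
         paste(cfg$nutrient[bad], cfg$basis[bad], collapse = "; "), call. = FALSE)
  }
  for (nut in fopl_nutrients()) {
    hf <- cfg$high_min[cfg$nutrient == nut & cfg$basis == "food"]
    hd <- cfg$high_min[cfg$nutrient == nut & cfg$basis == "drink"]
    if (hd > hf) {
      stop("drink high_min exceeds food high_min for ", nut, call. = FALSE)
    }
  }
  invisible(cfg)
}

#' The four FOPL nutrients
#'
#' @return Character vector `c("fat", "satfat", "sugar", "salt")`, the nutrients
#'   carried on the UK front-of-package label, in canonical order.
#' @export
fopl_nutrients <- function() c("fat", "satfat", "sugar", "salt")
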