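#' Traffic-light levels
#'
#' The three front-of-package colours as an ordered factor,
#' GREEN < AMBER < RED, so "at least amber" style comparisons and monotonicity
#' checks can use the natural order.
#'
#' @param x Character vector of light names.
#' @return Ordered factor with levels GREEN, AMBER, RED.
#' @export
traffic_light <- function(x) {
  factor(x, levels = c("GREEN", "AMBER", "RED"), ordered = TRUE)
}

#' Assign a traffic light to one nutrient value
#'
#' Green iff `value <= low_max`, red iff `value > high_min`, amber otherwise,
#' using the food or drink cut-offs as selected by `is_drink` (drink values are
#' taken per 100 ml, assumed equivalent to 100 g). Vectorised over `value` and
#' `is_drink`.
#'
#' @param nutrient One of `"fat"`, `"satfat"`, `"sugar"`, `"salt"`.
#' @param value Nutrient content in g per 100 g (or 100 ml), `>= 0`.
#' @param is_drink Logical; selects the drink cut-off basis.
#' @param cfg Threshold configuration, see [mtl_thresholds()].
#' @return Ordered factor of lights, same length as `value`.
#' @export
assign_light <- function(nutrient, value, is_drink, cfg = mtl_thresholds()) {
  if (length(nutrient) != 1 || !nutrient %in% cfg$nutrient) {
    stop("config error: unknown nutrient '", paste(nutrient, collapse = ","),
         "'", call. = FALSE)
  }
  if (any(value < 0, na.rm = TRUE)) {
    stop("validation error: negative nutrient value", call. = FALSE)
  }
  n <- max(length(value), length(is_drink))
  value <- rep_len(value, n)
  basis <- ifelse(rep_len(is_drink, n), "drink", "food")
  low <- high <- numeric(n)
  for (b in c("food", "drink")) {
    row <- cfg[cfg$nutrient == nutrient & cfg$basis == b, ]
    low[basis == b] <- row$low_max
    high[basis == b] <- row$high_min
  }
  out <- rep("AMBER", n)
  out[value <= low] <- "GREEN"
  out[value > high] <- "RED"
  out[is.na(value)] <- NA
  traffic_light(out)
}

light_score <- function(light) {
  # green = 1, amber = 2, red = 3
  as.integer(light)
}

#' Score a databank against the MTL criteria
#'
#' Assigns the four traffic lights to every item and derives the composite
#' front-of-package measures used throughout the analysis:
#' \describe{
#'   \item{n_red, n_green}{counts of red / green lights, 0--4}
#'   \item{any_red, any_green}{presence of at least one red / green light}
#'   \item{mtl_continuous}{sum of per-light scores (green 1, amber 2, red 3),
#'     ranging 4 (four greens) to 12 (four reds)}
#'   \item{mtl_ordinal8}{the continuous score as an 8-level ordinal measure:
#'     scores 11 and 12 (three reds + one amber, four reds) are merged into the
#'     top level because such items are rare, so level = min(score, 11) - 3}
#' }
#'
#' @param d A classifiable databank (all scoring nutrients present).
#' @param cfg Threshold configuration.
#' @return Tibble with one row per item: `item_id`, `light_fat`,
#'   `light_satfat`, `light_sugar`, `light_salt`, and the derived fields above.
#' @export
profile_databank <- function(d, cfg = mtl_thresholds()) {
  values <- list(fat = d$fat_g, satfat = d$satfat_g, sugar = d$sugar_g,
                 salt = d$salt_g)
  for (nut in fopl_nutrients()) {
    if (any(is.na(values[[nut]]))) {
      bad <- d$item_id[which(is.na(values[[nut]]))[1]]
      stop("validation error: missing ", nut, " for item '", bad, "'",
           call. = FALSE)
    }
  }
  lights <- lapply(fopl_nutrients(), function(nut) {
    assign_light(nut, values[[nut]], d$is_drink, cfg)
  })
  names(lights) <- fopl_nutrients()
  score <- Reduce(`+`, lapply(lights, light_score))
  n_red <- Reduce(`+`, lapply(lights, function(l) as.integer(l == "RED")))
  n_green <- Reduce(`+`, lapply(lights, function(l) as.integer(l == "GREEN")))
  tibble::tibble(
    item_id = d$item_id,
    light_fat = lights$fat,
    light_satfat = lights$satfat,
    light_sugar = lights$sugar,
    light_salt = lights$salt,
    n_red = n_red,
    n_green = n_green,
    any_red = n_red >= 1L,
    any_green = n_green >= 1L,
    mtl_continuous = as.integer(score),
    mtl_ordinal8 = as.integer(pmin(score, 11L) - 3L)
  )
}

#' Score a single item
#'
#' Convenience wrapper over [profile_databank()] for a one-row databank.
#'
#' @param item A one-row databank (or data frame with the databank columns).
#' @param cfg Threshold configuration.
#' @return One-row profile tibble; see [profile_databank()].
#' @export
profile_item <- function(item, cfg = mtl_thresholds()) {
  if (nrow(item) != 1) {
    stop("profile_item expects exactly one row", call. = FALSE)
  }
  profile_databank(item, cfg)
}

#' Per-nutrient light counts
#'
#' Summarises a profile table into counts (and shares) of green, amber and red
#' lights for each of the four nutrients.
#'
#' @param profiles Output of [profile_databank()].
#' @return Tibble with columns `nutrient`, `light`, `n`, `pct`.
#' @export
light_summary <- function(profiles) {
  out <- lapply(fopl_nutrients(), function(nut) {
    l <- profiles[[paste0("light_", nut)]]
    tab <- table(factor(l, levels = c("GREEN", "AMBER", "RED")))
    tibble::tibble(nutrient = nut,
                   light = names(tab),
                   n = as.integer(tab),
                   pct = if (nrow(profiles) > 0)
                     100 * as.integer(tab) / nrow(profiles) else NA_real_)
  })
  dplyr::bind_rows(out)
}
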