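#' Macronutrient energy fractions and sodium mass fraction
#'
#' Computes, per item, the quantities the hyper-palatability thresholds apply
#' to: the fraction of energy from fat (`9 * fat_g / energy_kcal`), from total
#' sugar (`4 * sugar_g / energy_kcal`) and from carbohydrate
#' (`factor_carb * carb_g / energy_kcal`), and sodium as percent by weight
#' (g sodium per 100 g, numerically `sodium_g`, derived from salt / 2.5 when
#' the sodium column is absent). Fractions of zero-energy items (e.g. water,
#' black tea) are defined as 0, never a division error.
#'
#' Energy conversion factors default to 9 kcal/g for fat and 4 kcal/g for
#' sugar and carbohydrate; UK composition tables sometimes use 3.75 kcal/g for
#' carbohydrate, hence `factor_carb` is exposed.
#'
#' @param d A databank.
#' @param factor_fat,factor_sugar,factor_carb kcal per gram conversion factors.
#' @return Tibble with `item_id`, `frac_kcal_fat`, `frac_kcal_sugar`,
#'   `frac_kcal_carb` (NA when carbohydrate is absent) and `na_pct_weight`.
#' @export
energy_fractions <- function(d, factor_fat = 9, factor_sugar = 4,
                             factor_carb = 4) {
  e <- d$energy_kcal
  safe_frac <- function(kcal) ifelse(e > 0, kcal / e, 0)
  tibble::tibble(
    item_id = d$item_id,
    frac_kcal_fat = safe_frac(factor_fat * d$fat_g),
    frac_kcal_sugar = safe_frac(factor_sugar * d$sugar_g),
    frac_kcal_carb = ifelse(is.na(d$carb_g), NA_real_,
                            safe_frac(factor_carb * d$carb_g)),
    na_pct_weight = sodium_g(d)
  )
}

#' Hyper-palatable food classification
#'
#' Flags each food item against the three hyper-palatability clusters defined
#' from quantitative descriptive work on palatability:
#' \describe{
#'   \item{cluster_fat_na}{> 25 \% of kcal from fat AND >= 0.30 \% sodium by
#'     weight}
#'   \item{cluster_fat_sugar}{> 20 \% of kcal from fat AND > 20 \% of kcal from
#'     sugars}
#'   \item{cluster_carb_na}{> 40 \% of kcal from carbohydrate AND >= 0.20 \%
#'     sodium by weight}
#' }
#' The strict (>) and non-strict (>=) inequalities are applied exactly as
#' stated; `any_hpf` is the OR of the three flags. The definition exists for
#' foods only: drinks get `applicable = FALSE` and all flags `FALSE`.
#' Zero-energy items have all fractions 0 and are therefore never
#' hyper-palatable. Items without a carbohydrate value cannot be evaluated for
#' the carbohydrate/sodium cluster; that flag is `FALSE` with a warning.
#'
#' @inheritParams energy_fractions
#' @return Tibble: `item_id`, the three fractions, `na_pct_weight`, the three
#'   cluster flags, `any_hpf`, `applicable`.
#' @export
classify_hpf <- function(d, factor_fat = 9, factor_sugar = 4, factor_carb = 4) {
  fr <- energy_fractions(d, factor_fat, factor_sugar, factor_carb)
  applicable <- !d$is_drink
  c1 <- fr$frac_kcal_fat > 0.25 & fr$na_pct_weight >= 0.30
  c2 <- fr$frac_kcal_fat > 0.20 & fr$frac_kcal_sugar > 0.20
  carb_missing <- is.na(fr$frac_kcal_carb)
  if (any(carb_missing & applicable)) {
    warning(sum(carb_missing & applicable),
            " food item(s) lack carbohydrate; carbohydrate/sodium cluster",
            " evaluated as FALSE for them", call. = FALSE)
  }
  c3 <- !carb_missing & fr$frac_kcal_carb > 0.40 & fr$na_pct_weight >= 0.20
  c1 <- c1 & applicable
  c2 <- c2 & applicable
  c3 <- c3 & applicable
  tibble::tibble(
    fr,
    cluster_fat_na = c1,
    cluster_fat_sugar = c2,
    cluster_carb_na = c3,
    any_hpf = c1 | c2 | c3,
    applicable = applicable
  )
}
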