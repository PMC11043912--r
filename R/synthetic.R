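#' Default synthetic databank scenario
#'
#' Describes a synthetic UK-style food and drink databank with the structure
#' the analysis assumes: ~3000 items split across NOVA groups in the observed
#' shares (55.4 % UPF, 33.1 % MPF, 9.5 % PF, 2.0 % PCI), right-skewed
#' log-normal nutrient distributions with the ultra-processed group shifted
#' above the minimally processed group in fat, saturated fat, sugar, salt and
#' energy density, a drinks subset, and water content derived as the
#' complement of solids (hence inversely related to energy density).
#'
#' Per group the scenario holds the item count, the drink fraction, a
#' log-normal `(meanlog, sdlog)` pair per nutrient (fat, sugar, starch,
#' protein, fibre, salt; grams per 100 g), and a logit-normal saturated-fat
#' share of total fat (so saturated fat can never exceed fat). Carbohydrate is
#' sugar + starch; energy is derived at 9/4/4/2 kcal per g of
#' fat/carbohydrate/protein/fibre; drinks are the same draws diluted by a
#' fixed factor.
#'
#' @return A `scenario_config`: named list of per-group parameter lists.
#' @export
scenario_default <- function() {
  ln <- function(med, sd) c(meanlog = log(med), sdlog = sd)
  cfg <- list(
    MPF = list(
      n = 986, drink_frac = 0.10,
      nutrients = list(fat = ln(2.0, 1.1), sugar = ln(3.0, 1.2),
                       starch = ln(2.0, 1.2), protein = ln(3.0, 0.9),
                       fibre = ln(1.5, 0.9), salt = ln(0.1, 1.2)),
      satfat_share = c(mu = stats::qlogis(0.35), sigma = 0.5)
    ),
    PCI = list(
      n = 61, drink_frac = 0,
      nutrients = list(fat = ln(25, 1.2), sugar = ln(2.0, 1.8),
                       starch = ln(1.0, 1.2), protein = ln(0.5, 1.0),
                       fibre = ln(0.2, 1.0), salt = ln(0.3, 1.8)),
      satfat_share = c(mu = stats::qlogis(0.40), sigma = 0.8)
    ),
    PF = list(
      n = 283, drink_frac = 0.05,
      nutrients = list(fat = ln(8.0, 0.9), sugar = ln(3.0, 1.2),
                       starch = ln(8.0, 1.0), protein = ln(6.0, 0.7),
                       fibre = ln(1.5, 0.8), salt = ln(0.9, 0.8)),
      satfat_share = c(mu = stats::qlogis(0.40), sigma = 0.6)
    ),
    UPF = list(
      n = 1650, drink_frac = 0.10,
      nutrients = list(fat = ln(9.0, 0.9), sugar = ln(6.5, 1.0),
                       starch = ln(14.0, 0.8), protein = ln(5.0, 0.7),
                       fibre = ln(1.5, 0.8), salt = ln(0.6, 0.9)),
      satfat_share = c(mu = stats::qlogis(0.40), sigma = 0.6)
    )
  )
  structure(cfg, class = "scenario_config", drink_dilution = 0.25)
}

validate_scenario <- function(scenario) {
  for (g in names(scenario)) {
    grp <- scenario[[g]]
    if (grp$n < 0) stop("n must be >= 0 for group ", g, call. = FALSE)
    if (grp$drink_frac < 0 || grp$drink_frac > 1) {
      stop("drink_frac must be in [0, 1] for group ", g, call. = FALSE)
    }
    for (nut in names(grp$nutrients)) {
      if (grp$nutrients[[nut]][["sdlog"]] < 0) {
        stop("sdlog must be >= 0 for ", nut, " in group ", g, call. = FALSE)
      }
    }
  }
  invisible(scenario)
}

#' Generate a synthetic databank
#'
#' Draws a reproducible databank from a scenario (see [scenario_default()]).
#' NOVA shares are exactly as configured; per-group food-item nutrient medians
#' converge to the configured log-normal medians. Items whose solids would
#' exceed 100 g/100 g are resampled (count recorded in the `resampled`
#' attribute); water is the complement of solids, floored at 0.
#'
#' @param scenario A `scenario_config`.
#' @param seed Integer seed; same seed, same databank.
#' @return A `databank` with an extra `resampled` attribute.
#' @export
generate_databank <- function(scenario = scenario_default(), seed = 1L) {
  validate_scenario(scenario)
  set.seed(seed)
  dilution <- attr(scenario, "drink_dilution")
  if (is.null(dilution)) dilution <- 0.25
  resampled <- 0L
  rows <- lapply(names(scenario), function(g) {
    grp <- scenario[[g]]
    n <- grp$n
    if (n == 0) return(NULL)
    n_drink <- round(n * grp$drink_frac)
    draw <- function(m) {
      out <- sapply(grp$nutrients, function(p) {
        stats::rlnorm(m, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]])
      })
      if (m == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(grp$nutrients)))
      share <- stats::plogis(stats::rnorm(m, grp$satfat_share[["mu"]],
                                          grp$satfat_share[["sigma"]]))
      cbind(out, satfat = out[, "fat"] * share)
    }
    mat <- draw(n)
    # resample items with infeasible composition (solids > 100 g)
    for (iter in 1:100) {
      solids <- mat[, "fat"] + mat[, "sugar"] + mat[, "starch"] +
        mat[, "protein"] + mat[, "fibre"] + mat[, "salt"]
      bad <- which(solids > 100)
      if (length(bad) == 0) break
      resampled <<- resampled + length(bad)
      mat[bad, ] <- draw(length(bad))
    }
    is_drink <- seq_len(n) <= n_drink
    scale <- ifelse(is_drink, dilution, 1)
    fat <- mat[, "fat"] * scale
    satfat <- mat[, "satfat"] * scale
    sugar <- mat[, "sugar"] * scale
    carb <- (mat[, "sugar"] + mat[, "starch"]) * scale
    protein <- mat[, "protein"] * scale
    fibre <- mat[, "fibre"] * scale
    salt <- mat[, "salt"] * scale
    energy <- 9 * fat + 4 * carb + 4 * protein + 2 * fibre
    solids <- fat + carb + protein + fibre + salt
    tibble::tibble(
      item_id = sprintf("%s_%05d", g, seq_len(n)),
      name = sprintf("synthetic %s item %d", g, seq_len(n)),
      subgroup_code = "SYN",
      nova_group = g,
      is_drink = is_drink,
      energy_kcal = energy,
      fat_g = fat, satfat_g = satfat, sugar_g = sugar, salt_g = salt,
      sodium_g = NA_real_,
      protein_g = protein, fibre_g = fibre, carb_g = carb,
      water_g = pmax(0, 100 - solids)
    )
  })
  d <- as_databank(dplyr::bind_rows(rows),
                   provenance = sprintf("synthetic scenario, seed %d", seed))
  attr(d, "resampled") <- resampled
  d
}

# ---------------------------------------------------------------------------
# Printed-counts fixture: a deterministic databank built from nutrient
# archetypes so that profiling and HPF classification hit exact target cell
# counts per NOVA group.

#' Fixture specification realising the published contingency counts
#'
#' A cell-level specification: one row per (NOVA group, light pattern, HPF
#' cluster combination, drink flag) with the number of identical archetype
#' items to emit. `pattern` is four characters over G/A/R in nutrient order
#' fat, saturated fat, sugar, salt; `clusters` is a string over "1", "2", "3"
#' naming the hyper-palatability clusters the archetype must satisfy (and no
#' others).
#'
#' The default realises every published marginal simultaneously: per-group
#' any-red counts (MPF 166/986, PCI 52/61, PF 121/283, UPF 795/1650), the
#' no-green counts behind the any-green analysis (8, 20, 11, 231), the no-red
#' subgroup (1846 with composition 820/9/162/855), the no-red + >= 2-green
#' subgroup (1403 = 738/9/102/554), and the hyper-palatable counts (1246 of
#' 2665 foods, 994 UPF; clusters 642/421/365 with UPF 504/318/342). Drink
#' counts per group (150/0/15/150) and the non-UPF HPF split are not published
#' and are fixed synthetic choices.
#'
#' @return Tibble with columns `nova_group`, `pattern`, `clusters`,
#'   `is_drink`, `n`.
#' @export
fixture_spec_printed <- function() {
  row <- function(g, pattern, clusters, drink, n) {
    tibble::tibble(nova_group = g, pattern = pattern, clusters = clusters,
                   is_drink = drink, n = n)
  }
  dplyr::bind_rows(
    # MPF: 986 = 150 drinks + 588 + 82 + (26+23+11+98 red&green) + 8 red-only
    row("MPF", "GGGG", "", TRUE, 150),
    row("MPF", "GGAA", "", FALSE, 588),
    row("MPF", "AGAA", "", FALSE, 82),
    row("MPF", "RGGA", "1", FALSE, 26),
    row("MPF", "RARG", "2", FALSE, 23),
    row("MPF", "GGRA", "3", FALSE, 11),
    row("MPF", "RGGA", "", FALSE, 98),
    row("MPF", "RAAA", "", FALSE, 8),
    # PCI: 61
    row("PCI", "GGAA", "", FALSE, 9),
    row("PCI", "RGGA", "1", FALSE, 12),
    row("PCI", "RGGA", "", FALSE, 20),
    row("PCI", "RAAA", "", FALSE, 20),
    # PF: 283
    row("PF", "GGGG", "", TRUE, 15),
    row("PF", "GGAA", "", FALSE, 87),
    row("PF", "AGAA", "1", FALSE, 59),
    row("PF", "AGAA", "", FALSE, 1),
    row("PF", "RAAA", "1", FALSE, 11),
    row("PF", "RGGA", "1", FALSE, 18),
    row("PF", "RARG", "2", FALSE, 68),
    row("PF", "RGRA", "12", FALSE, 12),
    row("PF", "GGRA", "3", FALSE, 12),
    # UPF: 1650
    row("UPF", "GGGG", "", TRUE, 150),
    row("UPF", "GGAA", "", FALSE, 404),
    row("UPF", "AGAA", "3", FALSE, 199),
    row("UPF", "AGAA", "", FALSE, 102),
    row("UPF", "RAAA", "1", FALSE, 231),
    row("UPF", "RGGA", "1", FALSE, 103),
    row("UPF", "RARG", "2", FALSE, 148),
    row("UPF", "RGRA", "12", FALSE, 170),
    row("UPF", "GGRA", "3", FALSE, 143)
  )
}

# Solve a nutrient vector realising a light pattern and an exact set of HPF
# clusters. Gram values sit mid-band so the pattern is stable under modest
# perturbation of the cut-offs; energy and carbohydrate are found by grid
# search against the six cluster inequalities.
solve_archetype <- function(pattern, clusters) {
  lights <- strsplit(pattern, "")[[1]]
  if (length(lights) != 4 || !all(lights %in% c("G", "A", "R"))) {
    stop("infeasible fixture spec: bad light pattern '", pattern, "'",
         call. = FALSE)
  }
  names(lights) <- fopl_nutrients()
  cl <- as.integer(strsplit(clusters, "")[[1]])
  need_na30 <- 1 %in% cl
  need_na20 <- 3 %in% cl
  if ((need_na30 || need_na20) && lights[["salt"]] == "G") {
    stop("infeasible fixture spec: clusters ", clusters,
         " need sodium >= 0.2 % wt but salt light is GREEN", call. = FALSE)
  }
  salt <- switch(lights[["salt"]],
                 G = 0.1,
                 A = if (need_na30) 0.8 else 0.6,
                 R = 2.0)
  if (lights[["fat"]] == "G" && lights[["satfat"]] == "R") {
    stop("infeasible fixture spec: satfat RED requires fat > 5 g (pattern ",
         pattern, ")", call. = FALSE)
  }
  fat <- switch(lights[["fat"]],
                G = if (lights[["satfat"]] == "A") 2.7 else 1.0,
                A = if (lights[["satfat"]] == "R") 17.0 else 10.0,
                R = 30.0)
  satfat <- switch(lights[["satfat"]],
                   G = 0.4,
                   A = if (lights[["fat"]] == "G") 2.0 else 3.0,
                   R = 10.0)
  sugar <- switch(lights[["sugar"]], G = 2.0, A = 10.0, R = 30.0)
  na_pct <- salt / 2.5
  want <- c(`1` = 1 %in% cl, `2` = 2 %in% cl, `3` = 3 %in% cl)
  for (carb in seq(max(sugar, 2), 80, by = 1)) {
    for (energy in seq(60, 900, by = 5)) {
      ff <- 9 * fat / energy
      fs <- 4 * sugar / energy
      fc <- 4 * carb / energy
      if (ff > 1.5 || fs > 1.5 || fc > 1.5) next
      got <- c(`1` = ff > 0.25 && na_pct >= 0.30,
               `2` = ff > 0.20 && fs > 0.20,
               `3` = fc > 0.40 && na_pct >= 0.20)
      solids <- fat + carb + 2 + 1 + salt
      if (all(got == want) && solids <= 100) {
        return(list(fat_g = fat, satfat_g = satfat, sugar_g = sugar,
                    salt_g = salt, carb_g = carb, energy_kcal = energy,
                    protein_g = 2, fibre_g = 1,
                    water_g = max(0, 100 - solids)))
      }
    }
  }
  stop("infeasible fixture spec: no nutrient vector realises pattern ",
       pattern, " with clusters {", clusters, "}", call. = FALSE)
}

#' Build the deterministic printed-counts fixture databank
#'
#' Expands a fixture specification (see [fixture_spec_printed()]) into a
#' databank of archetype items whose traffic-light profiles and
#' hyper-palatability flags hit every target cell exactly. Drinks are all-zero
#' water-like items (four green lights, zero energy). Running the full study
#' pipeline on the default fixture reproduces the contingency-derivable odds
#' ratios and percentages.
#'
#' @param spec Fixture specification tibble.
#' @return A `databank`.
#' @export
fixture_printed_counts <- function(spec = fixture_spec_printed()) {
  req <- c("nova_group", "pattern", "clusters", "is_drink", "n")
  if (!all(req %in% names(spec))) {
    stop("fixture spec needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(spec$n < 0)) stop("infeasible fixture spec: negative cell count",
                            call. = FALSE)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    if (s$n == 0) return(NULL)
    if (s$is_drink) {
      nut <- list(fat_g = 0, satfat_g = 0, sugar_g = 0, salt_g = 0,
                  carb_g = 0, energy_kcal = 0, protein_g = 0, fibre_g = 0,
                  water_g = 100)
      if (nzchar(s$clusters)) {
        stop("infeasible fixture spec: drinks cannot be hyper-palatable",
             call. = FALSE)
      }
    } else {
      nut <- solve_archetype(s$pattern, s$clusters)
    }
    tibble::tibble(
      item_id = sprintf("%s_%s_%s%s_%04d", s$nova_group, s$pattern,
                        ifelse(nzchar(s$clusters), s$clusters, "0"),
                        ifelse(s$is_drink, "d", "f"), seq_len(s$n)),
      name = sprintf("archetype %s %s", s$pattern, s$clusters),
      subgroup_code = "FIX",
      nova_group = s$nova_group,
      is_drink = s$is_drink,
      energy_kcal = nut$energy_kcal,
      fat_g = nut$fat_g, satfat_g = nut$satfat_g, sugar_g = nut$sugar_g,
      salt_g = nut$salt_g, sodium_g = NA_real_,
      protein_g = nut$protein_g, fibre_g = nut$fibre_g, carb_g = nut$carb_g,
      water_g = nut$water_g
    )
  })
  as_databank(dplyr::bind_rows(rows),
              provenance = "deterministic printed-counts fixture")
}
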