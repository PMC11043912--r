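#' Analysis configuration
#'
#' Collects the knobs of the full study pipeline: the traffic-light threshold
#' set, the reference NOVA group for all regressions, whether processed foods
#' and processed culinary ingredients are pooled where category counts are
#' small (the ordinal models, the any-green binary model and the above-median
#' MTL-score model), an output directory for the report tables, and a seed
#' recorded in the provenance block.
#'
#' @param thresholds Threshold configuration, see [mtl_thresholds()].
#' @param reference Reference group, one of `"MPF"`, `"PCI"`, `"PF"`, `"UPF"`.
#' @param pool_pci_pf Pool PCI and PF into one `"PF_PCI"` level for the
#'   analyses named above.
#' @param seed Integer recorded in the provenance block.
#' @param out_dir Directory to write report tables into, or `NULL`.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(thresholds = mtl_thresholds(), reference = "MPF",
                            pool_pci_pf = TRUE, seed = 1L, out_dir = NULL) {
  if (!reference %in% c("MPF", "PCI", "PF", "UPF")) {
    stop("reference must be one of MPF, PCI, PF, UPF", call. = FALSE)
  }
  validate_thresholds(thresholds)
  structure(list(thresholds = thresholds, reference = reference,
                 pool_pci_pf = pool_pci_pf, seed = seed, out_dir = out_dir),
            class = "analysis_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

pool_groups <- function(group, pool) {
  g <- as.character(group)
  if (pool) g[g %in% c("PCI", "PF")] <- "PF_PCI"
  g
}

study_nutrients <- function() {
  c(fat = "fat_g", satfat = "satfat_g", sugar = "sugar_g", salt = "salt_g",
    energy = "energy_kcal", energy_density = "energy_density",
    protein = "protein_g", fibre = "fibre_g", water = "water_g")
}

summarise_by_group <- function(d, value_cols = study_nutrients()) {
  d$energy_density <- d$energy_kcal / 100
  groups <- levels(droplevels(d$nova_group))
  rows <- list()
  for (nm in names(value_cols)) {
    col <- value_cols[[nm]]
    vals <- d[[col]]
    if (all(is.na(vals))) next
    samples <- lapply(groups, function(g) {
      v <- vals[d$nova_group == g]
      v[!is.na(v)]
    })
    names(samples) <- groups
    test <- if (sum(lengths(samples) > 0) >= 2) {
      kruskal_wallis(samples[lengths(samples) > 0])
    } else NULL
    for (g in c("ALL", groups)) {
      v <- if (g == "ALL") vals[!is.na(vals)] else samples[[g]]
      if (length(v) == 0) next
      q <- median_iqr(v)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = nm, group = g, n = length(v),
        median = q[["median"]], q1 = q[["q1"]], q3 = q[["q3"]],
        kw_p = if (is.null(test)) NA_real_ else test$p_value)
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full NOVA vs front-of-package study
#'
#' Executes the whole comparison on a databank: exclusion filtering,
#' traffic-light profiling, hyper-palatability classification, per-group
#' nutrient summaries (median/IQR with Kruskal--Wallis and Dunn pairwise
#' tests), per-nutrient light distributions with chi-square tests, any-red and
#' any-green binary logistic models, ordinal (proportional-odds) models of the
#' red-count, green-count and 8-level MTL score with the configured pooling,
#' the sensitivity battery (above-median splits, linear score models,
#' above-median MTL), the healthy-subset stratifications, and
#' hyper-palatability proportions among foods. Deterministic given inputs and
#' configuration.
#'
#' @param databank A `databank`, or a path to a databank CSV.
#' @param cfg An [analysis_config()].
#' @return List of class `study_report` whose elements are tidy tables; see
#'   the package vignette for a walk-through.
#' @export
run_study <- function(databank, cfg = analysis_config()) {
  d0 <- with_stage("read", {
    if (is.character(databank)) read_databank(databank) else databank
  })
  if (nrow(d0) == 0) stop("stage 'read': empty databank", call. = FALSE)
  d <- with_stage("filter", filter_classifiable(d0))
  if (nrow(d) == 0) stop("stage 'filter': no classifiable items", call. = FALSE)
  removal <- removal_report(d)
  profiles <- with_stage("profile", profile_databank(d, cfg$thresholds))
  hpf <- with_stage("hpf", suppressWarnings(classify_hpf(d)))
  group <- as.character(d$nova_group)
  pooled <- pool_groups(group, cfg$pool_pci_pf)
  ref <- cfg$reference

  group_counts <- with_stage("describe", {
    tab <- table(factor(group, levels = intersect(nova_levels(), unique(group))))
    tibble::tibble(group = names(tab), n = as.integer(tab),
                   pct = 100 * as.integer(tab) / nrow(d))
  })
  nutrient_summary <- with_stage("describe", summarise_by_group(d))
  nutrient_pairwise <- with_stage("describe", {
    d2 <- d; d2$energy_density <- d2$energy_kcal / 100
    rows <- lapply(names(study_nutrients()), function(nm) {
      col <- study_nutrients()[[nm]]
      vals <- d2[[col]]
      if (all(is.na(vals))) return(NULL)
      samples <- split(vals[!is.na(vals)], group[!is.na(vals)])
      samples <- samples[lengths(samples) > 0]
      if (length(samples) < 2) return(NULL)
      kw <- kruskal_wallis(samples)
      dplyr::mutate(kw$pairwise, variable = nm, .before = 1)
    })
    dplyr::bind_rows(rows)
  })

  light_distribution <- with_stage("lights", {
    ls <- light_summary(profiles)
    per_group <- lapply(fopl_nutrients(), function(nut) {
      tab <- table(factor(group), profiles[[paste0("light_", nut)]])
      test <- chi_square_independence(tab[, colSums(tab) > 0, drop = FALSE])
      df <- as.data.frame(tab, stringsAsFactors = FALSE)
      names(df) <- c("group", "light", "n")
      dplyr::mutate(tibble::as_tibble(df), nutrient = nut,
                    chisq_p = test$p_value, .before = 1)
    })
    list(overall = ls, by_group = dplyr::bind_rows(per_group))
  })

  redgreen_counts <- with_stage("lights", {
    count_tab <- function(x) {
      tab <- table(factor(group), factor(x, levels = 0:4))
      test <- chi_square_independence(tab[, colSums(tab) > 0, drop = FALSE])
      df <- as.data.frame(tab, stringsAsFactors = FALSE)
      names(df) <- c("group", "count", "n")
      dplyr::mutate(tibble::as_tibble(df), chisq_p = test$p_value)
    }
    list(red = count_tab(profiles$n_red), green = count_tab(profiles$n_green))
  })

  binary_or <- with_stage("binary_regression", {
    red <- binary_logistic(group, profiles$any_red, ref)
    green <- binary_logistic(pooled, profiles$any_green, ref)
    dplyr::bind_rows(
      dplyr::mutate(red, outcome = "any_red", .before = 1),
      dplyr::mutate(green, outcome = "any_green", .before = 1))
  })

  ordinal_or <- with_stage("ordinal_regression", {
    fits <- list(
      n_red = proportional_odds(pooled, profiles$n_red, ref),
      n_green = proportional_odds(pooled, profiles$n_green, ref),
      mtl_ordinal8 = proportional_odds(pooled, profiles$mtl_ordinal8, ref))
    dplyr::bind_rows(lapply(names(fits), function(nm) {
      dplyr::mutate(fits[[nm]], outcome = nm, .before = 1)
    }))
  })

  sensitivity <- with_stage("sensitivity", {
    d2 <- d; d2$energy_density <- d2$energy_kcal / 100
    med_split <- dplyr::bind_rows(lapply(names(study_nutrients()), function(nm) {
      col <- study_nutrients()[[nm]]
      vals <- d2[[col]]
      if (all(is.na(vals))) return(NULL)
      keep <- !is.na(vals)
      res <- median_split_logistic(group[keep], vals[keep], ref)
      dplyr::mutate(res, variable = nm, .before = 1)
    }))
    linear <- dplyr::bind_rows(
      dplyr::mutate(linear_score_model(group, profiles$n_red, ref),
                    outcome = "n_red", .before = 1),
      dplyr::mutate(linear_score_model(group, profiles$n_green, ref),
                    outcome = "n_green", .before = 1),
      dplyr::mutate(linear_score_model(group, profiles$mtl_continuous, ref),
                    outcome = "mtl_continuous", .before = 1))
    mtl_above_median <- dplyr::mutate(
      median_split_logistic(pooled, profiles$mtl_continuous, ref),
      outcome = "mtl_above_median", .before = 1)
    list(median_split = med_split, linear = linear,
         mtl_above_median = mtl_above_median)
  })

  subgroups <- with_stage("subgroups", {
    list(
      no_red = subgroup_analysis(d, profiles, profiles$n_red == 0,
                                 "no_red"),
      no_red_two_green = subgroup_analysis(
        d, profiles, profiles$n_red == 0 & profiles$n_green >= 2,
        "no_red_two_green"))
  })

  hpf_tables <- with_stage("hpf_proportions", {
    list(all_foods = hpf_proportions(d, profiles, hpf, subset = "all_foods"),
         healthy_foods = hpf_proportions(d, profiles, hpf,
                                         subset = "healthy_foods"))
  })

  report <- structure(list(
    group_counts = group_counts,
    removal = removal,
    nutrient_summary = nutrient_summary,
    nutrient_pairwise = nutrient_pairwise,
    light_distribution = light_distribution,
    redgreen_counts = redgreen_counts,
    binary_or = binary_or,
    ordinal_or = ordinal_or,
    sensitivity = sensitivity,
    subgroups = subgroups,
    hpf = hpf_tables,
    profiles = profiles,
    provenance = list(
      provenance = attr(d, "provenance"),
      n_input = nrow(d0), n_classifiable = nrow(d),
      reference = ref, pool_pci_pf = cfg$pool_pci_pf,
      seed = cfg$seed,
      config_hash = rlang::hash(cfg$thresholds),
      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "study_report")

  if (!is.null(cfg$out_dir)) {
    with_stage("write", write_study_report(report, cfg$out_dir))
  }
  report
}

#' Subset of items with no red traffic light
#'
#' The "healthy" stratum: items whose four lights contain no red. Returned as
#' the item subset; `subgroup_analysis()` (used by [run_study()]) adds the
#' within-UPF Mann--Whitney comparisons and the across-group tests among
#' healthy items.
#'
#' @param d A classifiable databank.
#' @param profiles Matching [profile_databank()] output.
#' @return The databank rows with `n_red == 0`.
#' @export
subgroup_no_red <- function(d, profiles) {
  stopifnot(nrow(d) == nrow(profiles))
  d[profiles$n_red == 0, , drop = FALSE]
}

#' Subset with no red and at least two green traffic lights
#'
#' @inheritParams subgroup_no_red
#' @return The databank rows with `n_red == 0` and `n_green >= 2`.
#' @export
subgroup_no_red_two_green <- function(d, profiles) {
  stopifnot(nrow(d) == nrow(profiles))
  d[profiles$n_red == 0 & profiles$n_green >= 2, , drop = FALSE]
}

subgroup_analysis <- function(d, profiles, keep, label) {
  sub <- d[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("subgroup '", label, "' is empty; analyses skipped",
            call. = FALSE)
    return(list(n = 0L, composition = tibble::tibble(), upf_within = NULL,
                across_groups = NULL))
  }
  g <- as.character(sub$nova_group)
  tab <- table(factor(g, levels = intersect(nova_levels(), unique(g))))
  composition <- tibble::tibble(group = names(tab), n = as.integer(tab),
                                pct = 100 * as.integer(tab) / nrow(sub))
  # within UPF: healthy vs unhealthy items, Mann-Whitney per variable
  d2 <- d; d2$energy_density <- d2$energy_kcal / 100
  upf <- d2$nova_group == "UPF"
  upf_within <- NULL
  if (any(upf & keep) && any(upf & !keep)) {
    upf_within <- dplyr::bind_rows(lapply(names(study_nutrients()), function(nm) {
      col <- study_nutrients()[[nm]]
      x <- d2[[col]][upf & keep]; y <- d2[[col]][upf & !keep]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) == 0 || length(y) == 0) return(NULL)
      mw <- mann_whitney(x, y)
      tibble::tibble(variable = nm,
                     median_in = median_iqr(x)[["median"]],
                     median_out = median_iqr(y)[["median"]],
                     U = mw$U, p_value = mw$p_value)
    }))
  }
  across_groups <- summarise_by_group(sub)
  list(n = nrow(sub), composition = composition, upf_within = upf_within,
       across_groups = across_groups)
}

#' Hyper-palatability proportions across NOVA groups
#'
#' Per NOVA group, the count and share of food items meeting each
#' hyper-palatability cluster and any cluster, over all foods or over the
#' "healthy" (no red light) foods; with a chi-square comparison of UPF vs MPF
#' per cluster. Drinks are excluded from the denominator (the definition
#' applies to foods only).
#'
#' @param d A classifiable databank.
#' @param profiles Matching profiles.
#' @param hpf Matching [classify_hpf()] output.
#' @param subset `"all_foods"` or `"healthy_foods"` (no red light).
#' @return Tibble with columns `cluster`, `group`, `n_group`, `n_hpf`, `pct`,
#'   `chisq_p_upf_vs_mpf`.
#' @export
hpf_proportions <- function(d, profiles, hpf,
                            subset = c("all_foods", "healthy_foods")) {
  subset <- match.arg(subset)
  keep <- !d$is_drink
  if (subset == "healthy_foods") keep <- keep & profiles$n_red == 0
  if (!any(keep)) stop("no food items in subset", call. = FALSE)
  g <- as.character(d$nova_group)[keep]
  flags <- hpf[keep, c("cluster_fat_na", "cluster_fat_sugar",
                       "cluster_carb_na", "any_hpf")]
  groups <- intersect(nova_levels(), unique(g))
  rows <- lapply(names(flags), function(cl) {
    f <- flags[[cl]]
    chisq_p <- NA_real_
    if (all(c("UPF", "MPF") %in% groups)) {
      sel <- g %in% c("UPF", "MPF")
      tab <- table(g[sel], factor(f[sel], levels = c(FALSE, TRUE)))
      chisq_p <- tryCatch(chi_square_independence(tab)$p_value,
                          error = function(e) NA_real_)
    }
    dplyr::bind_rows(lapply(c("ALL", groups), function(grp) {
      sel <- if (grp == "ALL") rep(TRUE, length(g)) else g == grp
      tibble::tibble(cluster = cl, group = grp, n_group = sum(sel),
                     n_hpf = sum(f[sel]),
                     pct = 100 * sum(f[sel]) / sum(sel),
                     chisq_p_upf_vs_mpf = chisq_p)
    }))
  })
  dplyr::bind_rows(rows)
}

round_numeric <- function(df, digits) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- round(df[[col]], digits)
  }
  df
}

#' Write the study report tables
#'
#' Emits each report table as CSV under `out_dir` (odds ratios and scores to
#' 2 decimals, percentages to 1, matching the reporting precision of the
#' printed tables) plus a `provenance.json`. On failure, partially written
#' outputs are removed.
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name, digits = 2) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    df <- round_numeric(as.data.frame(df), digits)
    readr::write_csv(df, path, progress = FALSE)
    written <<- c(written, path)
  }
  tryCatch({
    emit(dplyr::mutate(report$group_counts, pct = round(pct, 1)),
         "group_counts", 1)
    emit(report$nutrient_summary, "nutrient_summary", 2)
    emit(report$nutrient_pairwise, "nutrient_pairwise", 4)
    emit(report$light_distribution$overall, "light_summary", 1)
    emit(report$light_distribution$by_group, "light_by_group", 4)
    emit(report$redgreen_counts$red, "red_counts", 4)
    emit(report$redgreen_counts$green, "green_counts", 4)
    emit(report$binary_or, "binary_or", 2)
    emit(report$ordinal_or, "ordinal_or", 2)
    emit(report$sensitivity$median_split, "sensitivity_median_split", 2)
    emit(report$sensitivity$linear, "sensitivity_linear", 2)
    emit(report$sensitivity$mtl_above_median, "sensitivity_mtl_above_median", 2)
    emit(report$subgroups$no_red$composition, "no_red_composition", 1)
    emit(report$subgroups$no_red_two_green$composition,
         "no_red_two_green_composition", 1)
    emit(report$hpf$all_foods, "hpf_all_foods", 1)
    emit(report$hpf$healthy_foods, "hpf_healthy_foods", 1)
    jsonlite::write_json(report$provenance,
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }, error = function(e) {
    unlink(written)
    stop("stage 'write': ", conditionMessage(e), call. = FALSE)
  })
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", x$provenance$n_classifiable, "classifiable items\n")
  cat("Groups:\n")
  print(as.data.frame(x$group_counts), row.names = FALSE)
  cat("\nBinary odds ratios (reference", x$provenance$reference, "):\n")
  print(as.data.frame(dplyr::select(x$binary_or, "outcome", "group",
                                    "estimate", "ci_low", "ci_high")),
        row.names = FALSE)
  invisible(x)
}
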