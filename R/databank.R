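#' @importFrom rlang .data
NULL

# Canonical databank columns. Identity + classification fields first, then the
# per-100 g nutrient vector. Optional columns may be entirely NA.
databank_columns <- function() {
  c("item_id", "name", "subgroup_code", "nova_group", "is_drink",
    "energy_kcal", "fat_g", "satfat_g", "sugar_g", "salt_g", "sodium_g",
    "protein_g", "fibre_g", "carb_g", "water_g")
}

databank_mandatory <- function() {
  c("item_id", "nova_group", "is_drink",
    "energy_kcal", "fat_g", "satfat_g", "sugar_g", "salt_g")
}

nova_levels <- function() c("MPF", "PCI", "PF", "UPF", "EXCLUDED")

#' Default databank column schema
#'
#' Maps canonical field names to the column names expected in an input CSV.
#' Override entries to read files with different headers, e.g.
#' `databank_schema(fat_g = "FAT_100G")`.
#'
#' @param ... Named overrides, `canonical_name = "column in file"`.
#' @return Named character vector mapping canonical names to file columns.
#' @export
databank_schema <- function(...) {
  schema <- stats::setNames(databank_columns(), databank_columns())
  overrides <- c(...)
  if (length(overrides) > 0) {
    unknown <- setdiff(names(overrides), names(schema))
    if (length(unknown) > 0) {
      stop("unknown schema field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    schema[names(overrides)] <- overrides
  }
  schema
}

#' Read a food-composition databank from CSV
#'
#' One row per item: identity, NOVA processing group (MPF, PCI, PF, UPF or
#' EXCLUDED for items outside the classification such as supplements), a drink
#' flag, and per-100 g nutrients. Energy and the four front-of-package
#' nutrients (fat, saturated fat, total sugar, salt) are mandatory columns;
#' their values may still be missing for individual items, which
#' [filter_classifiable()] later removes. Optional nutrients (sodium, protein,
#' fibre, carbohydrate, water) are recorded as `NA` when absent, never as zero.
#'
#' @param path CSV file with a header row; comma-separated, UTF-8, `.` decimal.
#' @param schema Column-name mapping from [databank_schema()].
#' @param provenance Free-text metadata stored on the result.
#' @return A `databank`: a tibble with the canonical columns, row order as in
#'   the file, NOVA group as a factor.
#' @export
read_databank <- function(path, schema = databank_schema(), provenance = path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  mand_cols <- unname(schema[databank_mandatory()])
  absent <- setdiff(mand_cols, names(raw))
  if (length(absent) > 0) {
    stop("databank schema error: missing mandatory column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  out <- tibble::tibble(.rows = n)
  numeric_fields <- setdiff(databank_columns(),
                            c("item_id", "name", "subgroup_code", "nova_group",
                              "is_drink"))
  for (field in databank_columns()) {
    col <- schema[[field]]
    if (!col %in% names(raw)) {
      out[[field]] <- if (field %in% numeric_fields) NA_real_ else NA_character_
      next
    }
    x <- raw[[col]]
    if (field %in% numeric_fields) {
      out[[field]] <- parse_nutrient_column(x, col)
    } else {
      out[[field]] <- x
    }
  }
  out$nova_group <- parse_nova(out$nova_group)
  out$is_drink <- parse_flag(out$is_drink, schema[["is_drink"]])
  out <- as_databank(out, provenance = provenance)
  out
}

parse_nutrient_column <- function(x, col) {
  val <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(val))
  if (length(bad) > 0) {
    stop("parse error: non-numeric value '", x[bad[1]], "' in column '", col,
         "' at row ", bad[1], call. = FALSE)
  }
  neg <- which(!is.na(val) & val < 0)
  if (length(neg) > 0) {
    stop("validation error: negative value in column '", col, "' at row ",
         neg[1], call. = FALSE)
  }
  val
}

parse_nova <- function(x) {
  up <- toupper(trimws(as.character(x)))
  map <- c("1" = "MPF", "2" = "PCI", "3" = "PF", "4" = "UPF")
  up[up %in% names(map)] <- map[up[up %in% names(map)]]
  bad <- which(!is.na(up) & !up %in% nova_levels())
  if (length(bad) > 0) {
    stop("validation error: unknown NOVA group '", up[bad[1]], "' at row ",
         bad[1], call. = FALSE)
  }
  factor(up, levels = nova_levels())
}

parse_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  lo <- tolower(trimws(as.character(x)))
  val <- rep(NA, length(lo))
  val[lo %in% c("true", "t", "1", "yes", "y")] <- TRUE
  val[lo %in% c("false", "f", "0", "no", "n")] <- FALSE
  bad <- which(!is.na(lo) & is.na(val))
  if (length(bad) > 0) {
    stop("parse error: non-boolean value '", x[bad[1]], "' in column '", col,
         "' at row ", bad[1], call. = FALSE)
  }
  val
}

#' Construct a databank from a data frame
#'
#' Fills in any missing optional columns as `NA`, coerces types and runs
#' [validate_databank()].
#'
#' @param df Data frame with at least the mandatory databank columns.
#' @param provenance Free-text metadata.
#' @return A validated `databank` tibble.
#' @export
as_databank <- function(df, provenance = "constructed in R") {
  d <- tibble::as_tibble(df)
  for (field in databank_columns()) {
    if (!field %in% names(d)) {
      d[[field]] <- if (field %in% c("item_id", "name", "subgroup_code")) {
        NA_character_
      } else if (field == "is_drink") NA else NA_real_
    }
  }
  d <- d[, databank_columns()]
  if (!is.factor(d$nova_group)) d$nova_group <- parse_nova(d$nova_group)
  d$item_id <- as.character(d$item_id)
  validate_databank(d)
  attr(d, "provenance") <- provenance
  class(d) <- unique(c("databank", class(d)))
  d
}

#' Validate databank invariants
#'
#' Item ids unique and present; nutrients non-negative; saturated fat never
#' exceeds total fat; sugar never exceeds carbohydrate where both are present;
#' the mass balance fat + carbohydrate + protein + fibre + water + salt stays
#' below 105 g/100 g (5 % slack for rounding and ash) where all are present.
#'
#' @param d A databank tibble.
#' @return `d`, invisibly; errors on the first violated invariant.
#' @export
validate_databank <- function(d) {
  if (any(is.na(d$item_id))) {
    stop("validation error: missing item_id", call. = FALSE)
  }
  if (anyDuplicated(d$item_id)) {
    dup <- d$item_id[duplicated(d$item_id)][1]
    stop("validation error: duplicated item_id '", dup, "'", call. = FALSE)
  }
  num <- c("energy_kcal", "fat_g", "satfat_g", "sugar_g", "salt_g", "sodium_g",
           "protein_g", "fibre_g", "carb_g", "water_g")
  for (col in num) {
    if (any(d[[col]] < 0, na.rm = TRUE)) {
      stop("validation error: negative ", col, call. = FALSE)
    }
  }
  bad <- which(!is.na(d$satfat_g) & !is.na(d$fat_g) &
                 d$satfat_g > d$fat_g + 1e-9)
  if (length(bad) > 0) {
    stop("validation error: satfat_g > fat_g for item '", d$item_id[bad[1]],
         "'", call. = FALSE)
  }
  bad <- which(!is.na(d$sugar_g) & !is.na(d$carb_g) &
                 d$sugar_g > d$carb_g + 1e-9)
  if (length(bad) > 0) {
    stop("validation error: sugar_g > carb_g for item '", d$item_id[bad[1]],
         "'", call. = FALSE)
  }
  comp <- d$fat_g + d$carb_g + d$protein_g + d$fibre_g + d$water_g + d$salt_g
  bad <- which(!is.na(comp) & comp > 105)
  if (length(bad) > 0) {
    stop("validation error: composition exceeds 105 g/100 g for item '",
         d$item_id[bad[1]], "'", call. = FALSE)
  }
  invisible(d)
}

#' Write a databank to CSV
#'
#' Canonical column order, `NA` written as empty fields; a subsequent
#' [read_databank()] round-trips to a value-identical databank.
#'
#' @param d A databank.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_databank <- function(d, path) {
  out <- as.data.frame(d)[, databank_columns()]
  out$nova_group <- as.character(out$nova_group)
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Keep only items the analysis can classify
#'
#' Removes items outside the NOVA classification (group `EXCLUDED`, e.g. fish
#' oil supplements and multivitamins) and items missing any of the five
#' scoring-mandatory values (energy, fat, saturated fat, total sugar, salt),
#' for which traffic-light scoring is undefined. The counts removed per reason
#' are attached as the `removal` attribute (see [removal_report()]).
#' Idempotent: filtering a filtered databank removes nothing further.
#'
#' @param d A databank.
#' @return The filtered databank with a `removal` attribute
#'   `c(outside_nova = ..., incomplete = ...)`.
#' @export
filter_classifiable <- function(d) {
  outside <- !is.na(d$nova_group) & d$nova_group == "EXCLUDED"
  outside[is.na(d$nova_group)] <- TRUE
  need <- c("energy_kcal", "fat_g", "satfat_g", "sugar_g", "salt_g")
  incomplete <- !outside & Reduce(`|`, lapply(need, function(col) is.na(d[[col]])))
  incomplete <- incomplete | (!outside & is.na(d$is_drink))
  keep <- !outside & !incomplete
  out <- d[keep, , drop = FALSE]
  out$nova_group <- factor(as.character(out$nova_group),
                           levels = setdiff(nova_levels(), "EXCLUDED"))
  attr(out, "provenance") <- attr(d, "provenance")
  attr(out, "removal") <- c(outside_nova = sum(outside),
                            incomplete = sum(incomplete))
  class(out) <- unique(c("databank", class(out)))
  out
}

#' Removal report of a filtered databank
#'
#' @param d A databank returned by [filter_classifiable()].
#' @param path Optional path; when given, the report is also written as JSON.
#' @return Named integer vector of items removed per reason.
#' @export
removal_report <- function(d, path = NULL) {
  rep <- attr(d, "removal")
  if (is.null(rep)) rep <- c(outside_nova = 0L, incomplete = 0L)
  if (!is.null(path)) {
    jsonlite::write_json(as.list(rep), path, auto_unbox = TRUE)
  }
  rep
}

#' Sodium content, deriving from salt where absent
#'
#' Sodium in g/100 g is taken from the sodium column when present, otherwise
#' derived as `salt_g / 2.5` (the standard UK salt-to-sodium conversion).
#'
#' @param d A databank.
#' @return Numeric vector of sodium g/100 g.
#' @export
sodium_g <- function(d) {
  ifelse(!is.na(d$sodium_g), d$sodium_g, d$salt_g / 2.5)
}
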