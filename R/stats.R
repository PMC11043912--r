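or_result <- function(group, estimate, log_se, method, corrected,
                      p_value = NA_real_) {
  tibble::tibble(
    group = group,
    estimate = estimate,
    log_se = log_se,
    ci_low = exp(log(estimate) - 1.96 * log_se),
    ci_high = exp(log(estimate) + 1.96 * log_se),
    p_value = p_value,
    method = method,
    corrected = corrected
  )
}

#' Odds ratio of a 2x2 table with Woolf interval
#'
#' For counts `a` (exposed, event), `b` (exposed, non-event), `c` (reference,
#' event), `d` (reference, non-event): estimate `(a*d)/(b*c)`, standard error
#' of the log odds ratio `sqrt(1/a + 1/b + 1/c + 1/d)` and the Woolf 95 \%
#' interval `exp(log(OR) -/+ 1.96 * SE)`. When any cell is zero the
#' Haldane--Anscombe correction adds 0.5 to every cell first and the result is
#' flagged `corrected`.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return One-row tibble: `estimate`, `log_se`, `ci_low`, `ci_high`,
#'   `p_value` (two-sided Wald), `method`, `corrected`.
#' @examples
#' odds_ratio_2x2(795, 855, 166, 820)  # OR ~ 4.59 (3.79, 5.57)
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("counts must be non-negative", call. = FALSE)
  if (a + b == 0 || c + d == 0) {
    stop("undefined-margin error: a row of the 2x2 table is empty",
         call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  est <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- log(est) / se
  or_result(group = NA_character_, estimate = est, log_se = se,
            method = "woolf_2x2", corrected = corrected,
            p_value = 2 * stats::pnorm(-abs(z)))
}

group_2x2 <- function(group, outcome, g, reference) {
  a <- sum(group == g & outcome)
  b <- sum(group == g & !outcome)
  cc <- sum(group == reference & outcome)
  dd <- sum(group == reference & !outcome)
  c(a, b, cc, dd)
}

#' Binary logistic regression of a group factor
#'
#' Maximum-likelihood logistic fit of a boolean outcome on a categorical
#' predictor, dummy-coded against `reference`; per-group Wald odds ratios with
#' 95 \% intervals. Being a saturated one-factor model, each OR equals the
#' corresponding collapsed 2x2 odds ratio. Groups whose 2x2 table against the
#' reference contains a zero cell (separation: constant outcome in a group)
#' are reported via the Haldane--Anscombe-corrected [odds_ratio_2x2()] instead
#' and flagged `corrected`.
#'
#' @param group Factor or character vector of group labels per item.
#' @param outcome Logical vector per item.
#' @param reference Reference group label.
#' @return Tibble with one row per non-reference group: `group`, `estimate`,
#'   `log_se`, `ci_low`, `ci_high`, `p_value`, `method`, `corrected`.
#' @export
binary_logistic <- function(group, outcome, reference) {
  group <- as.character(group)
  stopifnot(length(group) == length(outcome))
  if (!reference %in% group) {
    stop("reference group '", reference, "' absent", call. = FALSE)
  }
  levels_other <- setdiff(unique(group), reference)
  if (length(levels_other) < 1) stop("need >= 2 groups", call. = FALSE)
  tabs <- lapply(levels_other, function(g) group_2x2(group, outcome, g, reference))
  names(tabs) <- levels_other
  separated <- vapply(tabs, function(t) any(t == 0), logical(1))
  constant_overall <- length(unique(outcome)) < 2

  fit <- NULL
  if (!constant_overall && !all(separated)) {
    gf <- stats::relevel(factor(group), ref = reference)
    agg <- stats::aggregate(cbind(ev = outcome, nev = !outcome) ~ gf,
                            FUN = sum)
    fit <- suppressWarnings(
      stats::glm(cbind(ev, nev) ~ gf, family = stats::binomial(),
                 data = agg,
                 control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
    cf <- summary(fit)$coefficients
  }

  rows <- lapply(levels_other, function(g) {
    if (separated[[g]] || is.null(fit)) {
      t <- tabs[[g]]
      res <- odds_ratio_2x2(t[1], t[2], t[3], t[4])
      res$group <- g
      res$corrected <- TRUE
      res
    } else {
      nm <- paste0("gf", g)
      est <- exp(cf[nm, "Estimate"])
      se <- cf[nm, "Std. Error"]
      or_result(group = g, estimate = est, log_se = se,
                method = "wald_logistic", corrected = FALSE,
                p_value = cf[nm, "Pr(>|z|)"])
    }
  })
  dplyr::bind_rows(rows)
}

#' Proportional-odds (cumulative-logit) ordinal regression
#'
#' Fits the proportional-odds model of an ordinal outcome on a categorical
#' predictor dummy-coded against `reference`. An odds ratio above 1 means
#' higher odds of more-extreme (higher) outcome levels. Wald 95 \% intervals.
#' Outcome levels that are empty after any pooling are dropped with a warning.
#'
#' @param group Factor or character vector per item.
#' @param outcome Ordinal outcome per item (integer or ordered factor).
#' @param reference Reference group label.
#' @param direction Only `"higher_is_event"` is defined: OR > 1 means greater
#'   odds of higher outcome levels.
#' @return Tibble as in [binary_logistic()], `method = "wald_logistic"`.
#' @export
proportional_odds <- function(group, outcome, reference,
                              direction = "higher_is_event") {
  direction <- match.arg(direction)
  group <- as.character(group)
  if (!reference %in% group) {
    stop("reference group '", reference, "' absent", call. = FALSE)
  }
  y <- if (is.factor(outcome)) outcome else factor(outcome)
  empty <- setdiff(levels(y), unique(as.character(y)))
  if (length(empty) > 0) {
    warning("dropping empty outcome level(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
    y <- droplevels(y)
  }
  if (nlevels(y) < 2) {
    stop("need >= 2 outcome levels with nonzero counts", call. = FALSE)
  }
  if (nlevels(y) == 2) {
    # with two levels the cumulative-logit model IS binary logistic
    return(binary_logistic(group, y == levels(y)[2], reference))
  }
  y <- factor(y, ordered = TRUE)
  gf <- stats::relevel(factor(group), ref = reference)
  dat <- stats::aggregate(w ~ y + gf,
                          data = data.frame(y = y, gf = gf, w = 1), FUN = sum)
  # explicit starting values (zero slopes, logit cumulative-share intercepts):
  # polr's internal start heuristic fails on sparse/degenerate tables
  prop <- tapply(dat$w, dat$y, sum)
  prop[is.na(prop)] <- 0
  cum <- cumsum(prop / sum(prop))
  zeta0 <- stats::qlogis(pmin(pmax(cum[-length(cum)], 1e-6), 1 - 1e-6))
  start <- c(rep(0, nlevels(gf) - 1), zeta0)
  fit <- tryCatch(
    MASS::polr(y ~ gf, data = dat, weights = w, Hess = TRUE, start = start,
               control = list(maxit = 200, reltol = 1e-12)),
    error = function(e) {
      stop("proportional-odds fit failed to converge: ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- summary(fit)$coefficients
  levels_other <- setdiff(levels(gf), reference)
  rows <- lapply(levels_other, function(g) {
    nm <- paste0("gf", g)
    est <- exp(cf[nm, "Value"])
    se <- cf[nm, "Std. Error"]
    z <- cf[nm, "Value"] / se
    or_result(group = g, estimate = est, log_se = se,
              method = "wald_logistic", corrected = FALSE,
              p_value = 2 * stats::pnorm(-abs(z)))
  })
  dplyr::bind_rows(rows)
}

#' Kruskal--Wallis test with Dunn pairwise comparisons
#'
#' Tie-corrected Kruskal--Wallis H with a chi-square p-value on k - 1 degrees
#' of freedom, followed by Dunn's pairwise z-tests on the pooled ranks with
#' Bonferroni adjustment over all k(k-1)/2 pairs. When every observation is
#' identical the statistic is defined as 0 with p = 1 (the tie-correction
#' denominator would otherwise vanish).
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return List of class `group_test`: `statistic`, `df`, `p_value`,
#'   `pairwise` (tibble: `group_a`, `group_b`, `z`, `p_raw`, `p_adj`),
#'   `adjustment = "bonferroni"`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  k <- length(groups)
  if (length(unique(x)) == 1) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(x, g)
    H <- unname(kt$statistic)
    p <- kt$p.value
  }
  # Dunn post hoc on pooled ranks
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  pw <- lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    denom <- sqrt(sigma2 * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (denom > 0) (rbar[[a]] - rbar[[b]]) / denom else 0
    p_raw <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(group_a = a, group_b = b, z = z, p_raw = p_raw,
                   p_adj = min(1, p_raw * m))
  })
  structure(list(statistic = H, df = k - 1, p_value = p,
                 pairwise = dplyr::bind_rows(pw),
                 adjustment = "bonferroni"),
            class = "group_test")
}

#' Mann--Whitney U test
#'
#' Two-sided rank-sum comparison via the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` (number of (x, y) pairs where x wins, ties half) and
#'   `p_value`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Pearson chi-square test of independence
#'
#' No continuity correction; degrees of freedom (r - 1)(c - 1). Errors when a
#' row or column margin is zero, naming it.
#'
#' @param table Matrix of counts.
#' @return List of class `group_test`: `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0)) {
    stop("zero margin in row ", which(rs == 0)[1], call. = FALSE)
  }
  if (any(cs == 0)) {
    stop("zero margin in column ", which(cs == 0)[1], call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value),
            class = "group_test")
}

#' Median and interquartile range
#'
#' Quantiles by the SPSS weighted-average convention (type 6: linear
#' interpolation of order statistics at positions `(n + 1) * p`), fixed so
#' that all reported medians/IQRs share one documented definition.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  if (length(values) == 0) stop("non-empty sample required", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), type = 6,
                       names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Binary regression on an above-median split
#'
#' Dichotomises `values` at the whole-sample median (event = strictly above)
#' and runs [binary_logistic()]. When a group -- or the whole sample -- has a
#' constant outcome, its OR comes from the corrected 2x2 fallback and is
#' flagged.
#'
#' @param group Group labels per item.
#' @param values Numeric per item.
#' @param reference Reference group label.
#' @return Tibble as [binary_logistic()].
#' @export
median_split_logistic <- function(group, values, reference) {
  med <- median_iqr(values)[["median"]]
  binary_logistic(group, values > med, reference)
}

#' Linear model of a score on group membership
#'
#' Ordinary least squares with dummy coding against `reference`; each
#' coefficient is the group-vs-reference mean difference, with a t-based
#' 95 \% interval. Groups with fewer than 2 items are dropped with a warning.
#'
#' @param group Group labels per item.
#' @param score Numeric score per item.
#' @param reference Reference group label.
#' @return Tibble: `group`, `estimate` (mean difference), `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
linear_score_model <- function(group, score, reference) {
  group <- as.character(group)
  n_by <- table(group)
  small <- names(n_by)[n_by < 2]
  if (length(small) > 0) {
    warning("dropping group(s) with < 2 items: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !group %in% small
    group <- group[keep]; score <- score[keep]
  }
  if (length(unique(group)) < 2) {
    stop("need >= 2 groups with >= 2 items each", call. = FALSE)
  }
  if (!reference %in% group) {
    stop("reference group '", reference, "' absent after dropping",
         call. = FALSE)
  }
  gf <- stats::relevel(factor(group), ref = reference)
  fit <- stats::lm(score ~ gf)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  levels_other <- setdiff(levels(gf), reference)
  rows <- lapply(levels_other, function(g) {
    nm <- paste0("gf", g)
    tibble::tibble(group = g, estimate = cf[nm, "Estimate"],
                   ci_low = ci[nm, 1], ci_high = ci[nm, 2],
                   p_value = cf[nm, "Pr(>|t|)"])
  })
  dplyr::bind_rows(rows)
}
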