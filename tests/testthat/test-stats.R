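# --- independent oracles -----------------------------------------------------

# Woolf arithmetic written out by hand, kept separate from the implementation.
woolf_by_hand <- function(a, b, c, d) {
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(est = est, lo = exp(log(est) - 1.96 * se), hi = exp(log(est) + 1.96 * se))
}

# Cumulative-logit likelihood maximised with a generic optimiser; independent
# of the fitting route used by the package.
polr_bruteforce_or <- function(group, y, reference) {
  gf <- stats::relevel(factor(group), ref = reference)
  X <- stats::model.matrix(~gf)[, -1, drop = FALSE]
  yf <- as.integer(factor(y))
  J <- max(yf)
  nll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    zeta <- cumsum(c(par[ncol(X) + 1], exp(par[-(1:(ncol(X) + 1))])))
    eta <- drop(X %*% beta)
    p <- vapply(seq_along(yf), function(i) {
      hi <- if (yf[i] == J) 1 else stats::plogis(zeta[yf[i]] - eta[i])
      lo <- if (yf[i] == 1) 0 else stats::plogis(zeta[yf[i] - 1] - eta[i])
      hi - lo
    }, numeric(1))
    -sum(log(pmax(p, 1e-300)))
  }
  par0 <- c(rep(0, ncol(X)), stats::qlogis((1:(J - 1)) / J)[1],
            rep(0, J - 2))
  fit <- stats::optim(par0, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  exp(fit$par[seq_len(ncol(X))])
}

# --- 2x2 odds ratios ---------------------------------------------------------

test_that("Woolf odds ratio reproduces the published any-red contrast", {
  res <- odds_ratio_2x2(795, 855, 166, 820)
  expect_equal(round(res$estimate, 2), 4.59)
  expect_equal(round(res$ci_low, 2), 3.79)
  expect_equal(round(res$ci_high, 2), 5.57)
  expect_false(res$corrected)
})

test_that("the unit table gives OR 1 with a log-symmetric interval", {
  res <- odds_ratio_2x2(1, 1, 1, 1)
  expect_equal(res$estimate, 1)
  expect_equal(res$ci_low * res$ci_high, 1, tolerance = 1e-12)
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  res <- odds_ratio_2x2(0, 10, 5, 5)
  expect_true(res$corrected)
  oracle <- woolf_by_hand(0.5, 10.5, 5.5, 5.5)
  expect_equal(res$estimate, oracle$est)
  expect_equal(res$ci_low, oracle$lo)
  expect_equal(res$ci_high, oracle$hi)
})

test_that("empty table margins are rejected", {
  expect_error(odds_ratio_2x2(0, 0, 5, 5), "margin")
})

test_that("the Woolf interval widens as any cell count decreases", {
  base <- odds_ratio_2x2(40, 40, 40, 40)
  for (cell in 1:4) {
    counts <- c(40, 40, 40, 40)
    counts[cell] <- 10
    shrunk <- do.call(odds_ratio_2x2, as.list(counts))
    expect_gt(shrunk$log_se, base$log_se)
  }
})

# --- binary logistic ---------------------------------------------------------

test_that("logistic ORs equal collapsed 2x2 Woolf ORs on saturated designs", {
  set.seed(7)
  for (rep in 1:5) {
    counts <- matrix(sample(5:80, 8), nrow = 4)  # events / non-events x 4 groups
    groups <- paste0("G", 1:4)
    group <- rep(rep(groups, 2), times = as.vector(counts))
    outcome <- rep(rep(c(TRUE, FALSE), each = 4), times = as.vector(counts))
    fit <- binary_logistic(group, outcome, "G1")
    for (g in groups[-1]) {
      oracle <- woolf_by_hand(counts[match(g, groups), 1],
                              counts[match(g, groups), 2],
                              counts[1, 1], counts[1, 2])
      got <- fit$estimate[fit$group == g]
      expect_equal(got, oracle$est, tolerance = 1e-7)
      expect_equal(fit$log_se[fit$group == g],
                   sqrt(sum(1 / counts[c(match(g, groups), 1), ])),
                   tolerance = 1e-6)
    }
  }
})

test_that("identical event rates across groups give OR 1", {
  group <- rep(c("A", "B"), each = 30)
  outcome <- rep(c(rep(TRUE, 10), rep(FALSE, 20)), 2)
  fit <- binary_logistic(group, outcome, "A")
  expect_equal(fit$estimate, 1, tolerance = 1e-6)
})

test_that("the published four-group any-red table is reproduced", {
  counts <- list(MPF = c(166, 820), UPF = c(795, 855), PF = c(121, 162),
                 PCI = c(52, 9))
  group <- unlist(lapply(names(counts), function(g) rep(g, sum(counts[[g]]))))
  outcome <- unlist(lapply(counts, function(x) rep(c(TRUE, FALSE), x)))
  fit <- binary_logistic(group, outcome, "MPF")
  expect_equal(round(fit$estimate[fit$group == "UPF"], 2), 4.59)
  expect_equal(round(fit$estimate[fit$group == "PF"], 2), 3.69)
  expect_equal(round(fit$estimate[fit$group == "PCI"], 2), 28.54)
})

test_that("separated groups fall back to the corrected 2x2 estimate", {
  group <- rep(c("A", "B", "C"), each = 20)
  outcome <- c(rep(c(TRUE, FALSE), 10), rep(TRUE, 20), rep(c(TRUE, FALSE), 10))
  fit <- binary_logistic(group, outcome, "A")
  expect_true(fit$corrected[fit$group == "B"])
  expect_false(fit$corrected[fit$group == "C"])
  oracle <- woolf_by_hand(20.5, 0.5, 10.5, 10.5)
  expect_equal(fit$estimate[fit$group == "B"], oracle$est)
})

# --- proportional odds -------------------------------------------------------

test_that("identical ordinal distributions give OR 1", {
  group <- rep(c("A", "B"), each = 30)
  y <- rep(rep(1:3, each = 10), 2)
  fit <- proportional_odds(group, y, "A")
  expect_equal(fit$estimate, 1, tolerance = 1e-5)
})

test_that("the cumulative-logit fit matches brute-force likelihood maximisation", {
  set.seed(11)
  group <- rep(c("A", "B"), each = 15)
  y <- c(sample(1:3, 15, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
         sample(1:3, 15, replace = TRUE, prob = c(0.2, 0.3, 0.5)))
  fit <- proportional_odds(group, y, "A")
  oracle <- polr_bruteforce_or(group, y, "A")
  expect_equal(fit$estimate, unname(oracle), tolerance = 1e-4)
})

test_that("two outcome levels reduce to binary logistic", {
  set.seed(12)
  group <- rep(c("A", "B"), each = 40)
  y <- ifelse(runif(80) < ifelse(group == "A", 0.3, 0.6), 2L, 1L)
  po <- proportional_odds(group, y, "A")
  bl <- binary_logistic(group, y == 2L, "A")
  expect_equal(po$estimate, bl$estimate, tolerance = 1e-10)
  expect_equal(po$log_se, bl$log_se, tolerance = 1e-10)
})

test_that("empty ordinal levels are dropped with a warning", {
  group <- rep(c("A", "B"), each = 20)
  y <- factor(rep(c(1, 3), 20), levels = 1:3)
  expect_warning(fit <- proportional_odds(group, y, "A"), "empty")
  expect_equal(nrow(fit), 1)
})

# --- rank tests --------------------------------------------------------------

test_that("Kruskal-Wallis H equals the hand rank formula on a toy triple", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- kruskal_wallis(groups)
  # H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1), no ties
  rbars <- c(2, 5, 8)
  H <- 12 / (9 * 10) * sum(3 * rbars^2) - 3 * 10
  expect_equal(res$statistic, H)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, stats::pchisq(H, 2, lower.tail = FALSE))
  # Bonferroni never reduces a p-value
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw - 1e-15))
  expect_true(all(res$pairwise$p_adj <= 1))
})

test_that("with two groups and no ties H equals the squared Dunn z", {
  set.seed(3)
  groups <- list(a = rnorm(12), b = rnorm(15) + 0.5)
  res <- kruskal_wallis(groups)
  expect_equal(res$statistic, res$pairwise$z[1]^2, tolerance = 1e-10)
})

test_that("degenerate all-equal samples give H = 0 and p = 1", {
  res <- kruskal_wallis(list(a = c(2, 2, 2), b = c(2, 2)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(kruskal_wallis(list(a = 1:3)), "2 non-empty")
})

test_that("Mann-Whitney normal approximation tracks exact enumeration at small n", {
  # in the inferentially relevant region (shifted samples, exact p well below
  # 0.5) the approximation agrees with exhaustive enumeration to 0.01
  set.seed(5)
  for (rep in 1:6) {
    x <- runif(sample(5:8, 1), 0, 10)
    y <- runif(sample(5:8, 1), 0, 10) + 6
    got <- mann_whitney(x, y)
    exact <- mw_exact_p(x, y)
    expect_lt(exact, 0.35)
    expect_lt(abs(got$p_value - exact), 0.01)
  }
  # across the full exact distribution the discrepancy is bounded by the
  # discreteness of the enumerated p (largest null atom ~ 0.05 at these n)
  set.seed(6)
  for (rep in 1:6) {
    x <- runif(sample(5:8, 1), 0, 10)
    y <- runif(sample(5:8, 1), 0, 10)
    got <- mann_whitney(x, y)
    expect_lt(abs(got$p_value - mw_exact_p(x, y)), 0.035)
  }
})

test_that("Mann-Whitney degenerate and separated samples behave", {
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.95)
  apart <- mann_whitney(1:20, 101:120)
  expect_lt(apart$p_value, 0.001)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

# --- chi-square --------------------------------------------------------------

test_that("chi-square matches the direct sum over (O-E)^2/E", {
  tab <- matrix(c(10, 20, 20, 10), nrow = 2)
  res <- chi_square_independence(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E))
  expect_equal(res$df, 1)
  # proportional rows: independence exactly
  prop <- matrix(c(10, 20, 30, 60), nrow = 2)
  res2 <- chi_square_independence(prop)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), nrow = 2)),
               "column 1")
  expect_error(chi_square_independence(matrix(c(0, 5, 0, 5), nrow = 2)),
               "row 1")
})

# --- descriptive + sensitivity models ---------------------------------------

test_that("median and IQR follow the weighted-average quantile convention", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)),
               c(median = 3, q1 = 1.5, q3 = 4.5))
  expect_equal(median_iqr(7), c(median = 7, q1 = 7, q3 = 7))
  expect_equal(unname(median_iqr(rep(2.5, 9))), rep(2.5, 3))
})

test_that("median-split regression dichotomises strictly above the pooled median", {
  group <- rep(c("A", "B"), each = 10)
  values <- c(1:10, 11:20)  # pooled median 10.5; B entirely above
  fit <- median_split_logistic(group, values, "A")
  expect_true(fit$corrected)  # separation: all of B above, none of A
  # constant values: no events anywhere, flagged on all groups
  fit2 <- median_split_logistic(group, rep(5, 20), "A")
  expect_true(all(fit2$corrected))
})

test_that("median-split OR direction follows a known lognormal shift", {
  set.seed(21)
  hits <- 0L
  for (rep in 1:500) {
    a <- rlnorm(40, 0, 0.5)
    b <- rlnorm(40, 0.7, 0.5)
    fit <- median_split_logistic(rep(c("A", "B"), each = 40), c(a, b), "A")
    if (fit$estimate > 1) hits <- hits + 1L
  }
  expect_gte(hits, 475L)  # >= 95 % of replicates
})

test_that("linear score coefficients equal direct group mean differences", {
  set.seed(9)
  group <- rep(c("A", "B", "C"), each = 12)
  score <- rnorm(36) + rep(c(0, 1.2, -0.4), each = 12)
  fit <- linear_score_model(group, score, "A")
  mA <- mean(score[group == "A"])
  expect_equal(fit$estimate[fit$group == "B"],
               mean(score[group == "B"]) - mA)
  expect_equal(fit$estimate[fit$group == "C"],
               mean(score[group == "C"]) - mA)
  expect_true(all(fit$ci_low < fit$estimate & fit$estimate < fit$ci_high))
  # equal means -> coefficient ~ 0
  fit2 <- linear_score_model(rep(c("A", "B"), each = 20),
                             rep(c(1, 2), 20), "A")
  expect_equal(fit2$estimate, 0)
  expect_warning(
    linear_score_model(rep(c("A", "B", "C"), c(5, 5, 1)), rnorm(11), "A"),
    "dropping")
})
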