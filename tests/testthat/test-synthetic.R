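test_that("the same seed reproduces the databank byte for byte", {
  d1 <- generate_databank(scenario_default(), seed = 99)
  d2 <- generate_databank(scenario_default(), seed = 99)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_databank(d1, p1); write_databank(d2, p2)
  expect_identical(readLines(p1), readLines(p2))
  d3 <- generate_databank(scenario_default(), seed = 100)
  expect_false(identical(d1$fat_g, d3$fat_g))
})

test_that("NOVA shares are exact and invariants hold on generated data", {
  d <- generate_databank(scenario_default(), seed = 2)
  expect_equal(as.integer(table(d$nova_group)[c("MPF", "PCI", "PF", "UPF")]),
               c(986L, 61L, 283L, 1650L))
  expect_silent(validate_databank(d))
  expect_true(all(d$water_g >= 0))
  # water complements solids: high energy density goes with low water
  expect_lt(stats::cor(d$energy_kcal, d$water_g), -0.5)
})

test_that("per-group food medians recover the configured log-normal medians", {
  sc <- scenario_default()
  sc$MPF$n <- 2000; sc$UPF$n <- 2000
  sc$MPF$drink_frac <- 0; sc$UPF$drink_frac <- 0
  sc$PCI$n <- 0; sc$PF$n <- 0
  d <- generate_databank(sc, seed = 3)
  for (g in c("MPF", "UPF")) {
    foods <- d[d$nova_group == g & !d$is_drink, ]
    for (nut in c("fat", "sugar", "salt")) {
      target <- exp(sc[[g]]$nutrients[[nut]][["meanlog"]])
      got <- stats::median(foods[[paste0(nut, "_g")]])
      expect_lt(abs(got - target) / target, 0.10)
    }
  }
})

test_that("zero-scale distributions collapse to the configured location", {
  sc <- scenario_default()
  sc$MPF$n <- 50
  sc$PCI$n <- 0; sc$PF$n <- 0; sc$UPF$n <- 0
  for (nut in names(sc$MPF$nutrients)) sc$MPF$nutrients[[nut]][["sdlog"]] <- 0
  sc$MPF$satfat_share[["sigma"]] <- 0
  sc$MPF$drink_frac <- 0
  d <- generate_databank(sc, seed = 4)
  expect_equal(nrow(d), 50)
  expect_equal(unique(d$fat_g), exp(sc$MPF$nutrients$fat[["meanlog"]]))
  expect_equal(length(unique(d$energy_kcal)), 1L)
})

test_that("scenario validation rejects malformed configs", {
  sc <- scenario_default()
  sc$MPF$drink_frac <- 1.4
  expect_error(generate_databank(sc, seed = 1), "drink_frac")
  sc2 <- scenario_default()
  sc2$PF$n <- -3
  expect_error(generate_databank(sc2, seed = 1), "n must be")
})

test_that("the printed-counts fixture realises every target cell exactly", {
  fx <- filter_classifiable(fixture_printed_counts())
  expect_equal(nrow(fx), 2980)
  prof <- profile_databank(fx)
  hpf <- classify_hpf(fx)
  g <- as.character(fx$nova_group)

  red <- table(g, prof$any_red)[, "TRUE"]
  expect_equal(as.integer(red[c("MPF", "PCI", "PF", "UPF")]),
               c(166L, 52L, 121L, 795L))
  nogreen <- table(g, prof$n_green == 0)[, "TRUE"]
  expect_equal(as.integer(nogreen[c("MPF", "PCI", "PF", "UPF")]),
               c(8L, 20L, 11L, 231L))
  expect_equal(sum(prof$n_red == 0), 1846)
  expect_equal(sum(prof$n_red == 0 & prof$n_green >= 2), 1403)
  expect_equal(sum(!fx$is_drink), 2665)
  expect_equal(sum(hpf$any_hpf), 1246)
  expect_equal(sum(hpf$any_hpf & g == "UPF"), 994)
  expect_equal(c(sum(hpf$cluster_fat_na), sum(hpf$cluster_fat_sugar),
                 sum(hpf$cluster_carb_na)), c(642, 421, 365))
  expect_equal(c(sum(hpf$cluster_fat_na & g == "UPF"),
                 sum(hpf$cluster_fat_sugar & g == "UPF"),
                 sum(hpf$cluster_carb_na & g == "UPF")), c(504, 318, 342))
})

test_that("fixture outcomes are stable under perturbed cut-off sets", {
  fx <- filter_classifiable(fixture_printed_counts())
  cfg <- mtl_thresholds()
  shrunk <- cfg; shrunk$low_max <- cfg$low_max * 0.95
  shrunk$high_min <- cfg$high_min * 1.05
  grown <- cfg; grown$low_max <- cfg$low_max * 1.05
  grown$high_min <- cfg$high_min * 0.95
  p0 <- profile_databank(fx, cfg)
  for (alt in list(shrunk, grown)) {
    p1 <- profile_databank(fx, alt)
    expect_equal(p1$mtl_continuous, p0$mtl_continuous)
    expect_equal(p1$n_red, p0$n_red)
    expect_equal(p1$n_green, p0$n_green)
  }
})

test_that("a fixture spec with identical cells across groups gives null odds ratios", {
  spec <- dplyr::bind_rows(lapply(c("MPF", "UPF"), function(g) {
    tibble::tibble(nova_group = g,
                   pattern = c("GGAA", "RAAA"),
                   clusters = "", is_drink = FALSE, n = c(30L, 30L))
  }))
  fx <- filter_classifiable(fixture_printed_counts(spec))
  prof <- profile_databank(fx)
  fit <- binary_logistic(as.character(fx$nova_group), prof$any_red, "MPF")
  expect_equal(fit$estimate, 1, tolerance = 1e-6)
})

test_that("infeasible fixture cells are rejected with the violated constraint", {
  bad <- tibble::tibble(nova_group = "MPF", pattern = "GGGG",
                        clusters = "1", is_drink = FALSE, n = 1L)
  expect_error(fixture_printed_counts(bad), "sodium")
  bad2 <- tibble::tibble(nova_group = "MPF", pattern = "GRAA",
                         clusters = "", is_drink = FALSE, n = 1L)
  expect_error(fixture_printed_counts(bad2), "satfat RED")
})
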