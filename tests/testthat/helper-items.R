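# Build a small databank in code. Defaults give a bland all-green food item;
# override any column. n rows share the overrides unless a vector is given.
make_bank <- function(n = 1, ...) {
  defaults <- list(
    item_id = sprintf("item_%03d", seq_len(n)),
    name = "test item",
    subgroup_code = "TST",
    nova_group = "MPF",
    is_drink = FALSE,
    energy_kcal = 100,
    fat_g = 1, satfat_g = 0.4, sugar_g = 2, salt_g = 0.1,
    sodium_g = NA_real_, protein_g = NA_real_, fibre_g = NA_real_,
    carb_g = NA_real_, water_g = NA_real_
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  as_databank(tibble::as_tibble(defaults), provenance = "test")
}

# Nutrient values realising a given light under the default (food) cut-offs,
# chosen mid-band; used to enumerate light combinations.
light_value <- function(nutrient, light) {
  vals <- list(
    fat = c(G = 1, A = 10, R = 30),
    satfat = c(G = 0.5, A = 3, R = 10),
    sugar = c(G = 2, A = 10, R = 30),
    salt = c(G = 0.1, A = 1, R = 2)
  )
  unname(vals[[nutrient]][light])
}

# A plain tibble (no databank validation) realising one light pattern; the
# satfat <= fat physical constraint is deliberately ignored so that all 81
# combinations can be enumerated.
pattern_row <- function(pattern, id = pattern) {
  l <- strsplit(pattern, "")[[1]]
  tibble::tibble(
    item_id = id, is_drink = FALSE,
    fat_g = light_value("fat", l[1]),
    satfat_g = light_value("satfat", l[2]),
    sugar_g = light_value("sugar", l[3]),
    salt_g = light_value("salt", l[4])
  )
}

# Exact two-sided Mann-Whitney p by enumerating all assignments of the pooled
# values to the two samples; independent of the normal-approximation route.
mw_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y),
                      numeric(1)))
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(vapply(xs, function(xi) sum(xi > ys) + 0.5 * sum(xi == ys),
               numeric(1)))
  })
  mean(abs(us - n * m / 2) >= abs(u_obs - n * m / 2) - 1e-12)
}

# A scaled-down synthetic scenario for pipeline tests.
small_scenario <- function() {
  sc <- scenario_default()
  sc$MPF$n <- 200; sc$PCI$n <- 20; sc$PF$n <- 60; sc$UPF$n <- 320
  sc
}

all_patterns <- function() {
  g <- expand.grid(f = c("G", "A", "R"), s = c("G", "A", "R"),
                   u = c("G", "A", "R"), l = c("G", "A", "R"),
                   stringsAsFactors = FALSE)
  paste0(g$f, g$s, g$u, g$l)
}
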