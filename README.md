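# novafopl

Scores food-composition databanks against the UK front-of-package
multiple-traffic-light (MTL) nutrient criteria and compares the outcomes
across NOVA food-processing groups — minimally processed foods (MPF),
processed culinary ingredients (PCI), processed foods (PF) and
ultra-processed foods (UPF). It is written for nutrition and public-health
researchers who want to quantify how far "high in fat, salt and sugar"
labelling and "ultra-processed" classification identify the same items.

## What it computes

Each item's fat, saturated fat, total sugar and salt per 100 g (per 100 ml
for drinks) are coloured against the FSA cut-offs: green iff
*value ≤ low_max*, red iff *value > high_min*, amber otherwise. From the
four lights come the presence flags (any red / any green), the red and green
counts, the continuous MTL score

```
score = Σ nutrient light,  green = 1, amber = 2, red = 3   (range 4–12)
```

and an 8-level ordinal version with the rare top scores {11, 12} merged.
Items are also flagged as hyper-palatable (HPF) when they meet any of three
cluster definitions on energy fractions and sodium: fat + sodium
(> 25 % kcal fat, ≥ 0.30 % Na by weight), fat + sugar (> 20 % kcal each), or
carbohydrate + sodium (> 40 % kcal carbohydrate, ≥ 0.20 % Na).

Group contrasts use Woolf 2×2 odds ratios

```
OR = ad/bc,   SE(log OR) = √(1/a + 1/b + 1/c + 1/d),   CI = exp(log OR ∓ 1.96·SE)
```

binary and proportional-odds logistic regression against a reference group
(MPF by default), Kruskal–Wallis with Dunn/Bonferroni pairwise tests,
Mann–Whitney comparisons, chi-square tests, and a sensitivity battery
(above-median splits, linear score models). `run_study()` orchestrates the
whole analysis, including the "healthy" stratifications (no red lights;
no red + ≥ 2 greens) and HPF proportions among foods.

The package also ships a synthetic databank generator (log-normal nutrient
model with UPF shifted above MPF) and a deterministic fixture whose
profiles hit the published contingency counts exactly, so the pipeline's
arithmetic can be validated end to end without the licensed survey databank.

## Worked example

```r
library(novafopl)

d    <- filter_classifiable(fixture_printed_counts())  # 2980 items
prof <- profile_databank(d)
fit  <- binary_logistic(as.character(d$nova_group), prof$any_red, "MPF")
fit[, c("group", "estimate", "ci_low", "ci_high", "p_value")]
#>   group estimate ci_low ci_high  p_value
#> 1   PCI    28.54  13.80   59.05 1.64e-19
#> 2    PF     3.69   2.76    4.92 7.56e-19
#> 3   UPF     4.59   3.79    5.57 3.33e-54
```

Ultra-processed items have 4.59 times the odds of carrying at least one red
traffic light compared with minimally processed items; processed culinary
ingredients (fats, oils, salt, sugar) are almost always red somewhere, hence
the extreme OR. The saturated one-factor model makes each row identical to
the collapsed 2×2 Woolf odds ratio:

```r
odds_ratio_2x2(795, 855, 166, 820)[, c("estimate", "ci_low", "ci_high")]
#>   estimate ci_low ci_high
#> 1     4.59   3.79    5.57
```

A full study on a synthetic databank:

```r
report <- run_study(generate_databank(scenario_default(), seed = 1),
                    analysis_config(out_dir = "novafopl_out"))
```

writes the descriptive, regression, subgroup and HPF tables as CSVs. A thin
command-line wrapper with `profile` / `run` / `fixture` / `simulate`
subcommands is installed at `inst/cli/novafopl.R`.

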