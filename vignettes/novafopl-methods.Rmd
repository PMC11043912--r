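---
title: "Scoring food databanks: traffic lights, NOVA groups and hyper-palatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring food databanks: traffic lights, NOVA groups and hyper-palatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novafopl)
```

## The question the package addresses

UK front-of-package labelling summarises the fat, saturated fat, total sugar
and salt content of a product as green/amber/red "traffic lights"
(the multiple-traffic-light scheme, MTL), while the NOVA classification
groups foods by the extent and purpose of their processing: minimally
processed foods (MPF), processed culinary ingredients (PCI), processed foods
(PF) and ultra-processed foods (UPF). The two systems carve up the food
supply along different axes — nutrient composition versus industrial
processing — and the degree to which they agree is an empirical question with
direct policy relevance: if most ultra-processed items already carry red
lights, existing high-fat/salt/sugar guidance covers them; if many do not,
the two systems carry distinct information.

`novafopl` implements the full comparison as a reusable, tested pipeline: it
scores a food-composition databank (one row per item, nutrients per 100 g)
against the MTL criteria, classifies items against quantitative
hyper-palatability definitions, and runs the descriptive and regression
battery that quantifies the overlap — all the way to stratified "healthy
subset" analyses.

## The MTL scoring model

Each of the four labelled nutrients is compared against two cut-offs,
`low_max` and `high_min`, on a per-100 g basis for foods and a stricter
per-100 ml basis for drinks (100 ml is treated as equivalent to 100 g; no
density correction is applied). The defaults are the Food Standards Agency /
Department of Health 2016 guidance values, shipped as a data file so that
alternative cut-off sets can be swapped in without touching code:

```{r}
mtl_thresholds()
```

Two boundary conventions matter and are fixed throughout:

* **green includes its bound** — a value exactly at `low_max` is "low";
* **red excludes its lower bound** — a value exactly at `high_min` is still
  amber.

This matches the "≤ x is low" / "> y is high" phrasing of the guidance, and
makes green attainable at the printed bound. The per-portion criteria that
the retail scheme adds for large portions are out of scope: everything here
is per 100 g so that items are comparable.

From the four lights the pipeline derives:

* `n_red`, `n_green` and the presence flags `any_red`, `any_green`;
* the **continuous MTL score**: green = 1, amber = 2, red = 3 summed over the
  four nutrients, ranging 4 (all green) to 12 (all red);
* the **8-level ordinal score**: the continuous score with its two top values
  (11 = three reds + one amber, 12 = four reds) merged, because items in
  those cells are rare in real databanks and leaving them separate makes
  cumulative-logit fits fragile. Algebraically the level is
  `min(score, 11) - 3`.

These identities are tested exhaustively over all 3^4 = 81 light
combinations.

## Hyper-palatability

Hyper-palatable foods are defined by three nutrient-combination clusters on
energy fractions and sodium mass fraction:

| cluster | condition |
|---|---|
| fat + sodium | > 25 % of kcal from fat **and** ≥ 0.30 % sodium by weight |
| fat + sugar | > 20 % of kcal from fat **and** > 20 % of kcal from sugars |
| carbohydrate + sodium | > 40 % of kcal from carbohydrate **and** ≥ 0.20 % sodium by weight |

The strict/non-strict inequalities are applied exactly as written. Energy
fractions use 9 kcal/g for fat and 4 kcal/g for sugar and carbohydrate; the
carbohydrate factor is configurable because some UK composition tables use
3.75 kcal/g. Sodium comes from the sodium column when present, otherwise
from salt / 2.5 (the standard UK conversion). Three deliberate edge rules:

* **drinks are never classified** (the definition exists for foods only);
  they get `applicable = FALSE` and all flags `FALSE`;
* **zero-energy items are never hyper-palatable** — their fractions are
  defined as 0 rather than dividing by zero; water and black tea are the
  motivating cases;
* an item without a carbohydrate value cannot be assessed for the third
  cluster; that flag is `FALSE` with a warning rather than `NA`, so
  downstream proportions stay well defined.

## Statistical machinery

All analyses are unadjusted single-factor models, reflecting the design of
the comparison (items, not intakes, are the unit).

* **2×2 odds ratios** use the Woolf method: OR = ad/bc with
  SE(log OR) = √(1/a + 1/b + 1/c + 1/d) and a 95 % interval
  exp(log OR ∓ 1.96·SE). A zero cell triggers the Haldane–Anscombe
  correction (+0.5 to every cell), flagged in the output. The 1.96 normal
  quantile is used throughout, matching the interval arithmetic behind the
  published tables this pipeline reproduces.
* **Binary logistic regression** is a maximum-likelihood `glm` fit with
  dummy coding against the reference group (MPF by default). Because the
  models are saturated one-factor fits, each Wald OR equals the collapsed
  2×2 Woolf OR; the tests assert that equivalence to six significant digits,
  which guards both routes. A group with constant outcome (separation) is
  reported through the corrected 2×2 fallback instead and flagged.
* **Proportional-odds models** are cumulative-logit fits via `MASS::polr`
  with explicit starting values (zero slopes, logit cumulative-share
  intercepts), because the default start heuristic fails on the sparse
  archetype fixtures this package must handle. With only two outcome levels
  the cumulative-logit model *is* binary logistic, and the implementation
  delegates accordingly. An independent brute-force maximisation of the
  cumulative-logit likelihood backs the fit in the test suite.
* **Kruskal–Wallis** (tie-corrected) is followed by Dunn's pairwise z-tests
  on the pooled ranks with Bonferroni adjustment over all k(k−1)/2 pairs —
  the post-hoc that the major statistical packages attach to this test. If
  every observation is identical the statistic is defined as 0 with p = 1
  (the tie-correction denominator would otherwise vanish).
* **Mann–Whitney** uses the tie-corrected normal approximation with
  continuity correction. Against exhaustive enumeration at sample sizes ≤ 8
  it agrees to 0.01 wherever the exact p is in the inferentially relevant
  range; in mid-distribution the exact two-sided p is itself quantised in
  steps of ~0.05 at those sizes, which bounds what any continuous
  approximation can achieve.
* **Medians and IQRs** use the weighted-average quantile convention
  (`type = 6`, interpolation at (n+1)p) — the convention of the statistical
  software that produced the published tables — fixed and documented so all
  summaries are comparable. Skewed nutrient variables are always summarised
  this way; means are never reported.
* **Pooling:** PCI and PF are pooled into one level for the ordinal models,
  the any-green binary model and the above-median MTL model, where separate
  PCI cells are too sparse. Outcome levels left empty after pooling are
  dropped with a warning.

## The synthetic generator

`generate_databank()` draws databanks with the structure the analysis
assumes, for power/recovery checks and examples without the licensed survey
databank. Design choices:

* **Log-normal nutrients.** Right-skew is the dominant feature of per-100 g
  nutrient distributions (medians far below means, long tails), and the
  log-normal is the simplest two-parameter family with that shape. Each
  group has its own (meanlog, sdlog) per nutrient; the default scenario puts
  the UPF group above the MPF group in fat, sugar, salt and energy density,
  with shares 55.4/33.1/9.5/2.0 % across UPF/MPF/PF/PCI of 2980 items.
* **Saturated fat as a share of fat.** Drawing saturated fat independently
  would violate `satfat ≤ fat`; instead a logit-normal share multiplies the
  fat draw.
* **Energy and water are derived**, not drawn: energy at 9/4/4/2 kcal/g for
  fat/carbohydrate/protein/fibre, water as 100 g minus solids (floored at
  0). Water content is therefore inversely related to energy density by
  construction, as in real databanks.
* **Infeasible compositions are resampled.** Items whose solids exceed
  100 g/100 g are redrawn and counted. The default dispersions are chosen so
  this affects ~2 % of draws: resampling conditions the distributions on
  feasibility, and if the infeasible mass is large that conditioning visibly
  biases the realised medians away from the configured ones. With the
  defaults, per-group food medians recover the configured medians within
  10 % at group sizes of a few hundred and up, which the tests verify at
  n = 2000.
* **Drinks** are the same draws diluted by a fixed factor (0.25), marked
  with the drink flag.

What the generator does **not** emulate: real item names and subgroups,
nutrient–nutrient correlations beyond the composition constraints, and the
exact published medians (those are unidentifiable from summary statistics
alone — only orderings are targeted). A passing recovery test therefore
shows the pipeline detects the configured contrasts; it does not certify
real-data point estimates.

## The printed-counts fixture

The published contingency tables imply a set of exact marginal counts per
NOVA group: how many items carry at least one red light, no green light, no
red light, no red + ≥ 2 greens, and how many foods fall in each
hyper-palatability cluster. `fixture_printed_counts()` builds a
deterministic 2980-item databank of *archetypes* that hits every one of
those cells exactly, so the pipeline's odds ratios and percentages can be
checked against the published values without the licensed databank.

The specification is a cell table: (group, light pattern, cluster
combination, drink flag, count). A small solver turns each cell into a
nutrient vector: gram values sit mid-band for their light (so the pattern is
stable under modest perturbation of the cut-offs — verified by re-profiling
under ±5 % threshold sets), and energy/carbohydrate are found by grid search
so that exactly the requested hyper-palatability clusters fire. Archetype
energies are not always realistic for their macronutrients; the fixture
realises marginal outcome counts, not joint nutrient realism, which is all
the contingency-derived checks need. Quantities the publication does not
pin down — the per-group drink counts, the split of pooled PCI+PF cells, the
non-UPF hyper-palatable distribution — are fixed synthetic choices recorded
in the spec table.

## Numerical and degenerate-input rules

* Convergence: `glm` at relative tolerance 1e-10 (≤ 100 iterations); `polr`
  via BFGS at `reltol` 1e-12 (≤ 200 iterations), failing loudly rather than
  returning a dubious fit.
* An empty databank, an all-excluded databank, or a subset with no food
  items each abort with the stage name before any analysis runs.
* `filter_classifiable()` drops items missing any scoring-mandatory value
  (energy and the four labelled nutrients) with reason `incomplete`,
  mirroring the removal of unlinked items in the source data; scoring is
  undefined on missing nutrients, and imputing zeros would silently turn
  missingness into green lights.
* Chi-square tests refuse tables with a zero margin, naming the row or
  column, rather than returning NaN.

## Problem sizes used by the test suite

Type-I calibration uses 2000 null replicates per test (rejection rate
checked against 0.05 ± 0.01); parameter recovery uses 20 seeded replicates
of the full default scenario; the calibration and recovery choices keep the
whole suite deterministic and complete in well under a minute of compute per
block.

## Known limitations

* Per-100 g comparability is also the scheme's weakness: it does not
  reflect portions as consumed.
* Total sugar stands in for added or free sugar in both the labelling and
  the fat+sugar cluster; databanks rarely carry the distinction.
* The hyper-palatability definitions say nothing about texture or eating
  rate, which are part of the mechanistic story but not measurable from
  composition.
* The proportional-odds model assumes a common group effect across all
  category splits; with strongly non-proportional data the single OR is a
  summary, not a fit diagnostic. No survey weighting or covariate
  adjustment is implemented — the design is deliberately unadjusted.
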