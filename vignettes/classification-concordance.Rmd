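---
title: "Comparing Nutri-Score, NOVA and Chilean warning labels: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing Nutri-Score, NOVA and Chilean warning labels: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriconcord)
```

## The problem

Front-of-package guidance systems disagree. The Nutri-Score grades the
nutrient balance of a product; NOVA grades its degree of industrial
processing; the Chilean warning-label scheme (Law 20.606) stamps products
whose critical-nutrient content exceeds legal limits. A product list can be
mostly "recommended" under one system and mostly "not recommended" under
another, which matters to any health authority choosing a labelling policy.
`nutriconcord` implements the three classifiers over one shared food-record
model and the concordance layer — distributions by food group, pairwise
cross-tabulations with row percentages, recommendation agreement and PCA
ordination — used to quantify their disagreement on a Chilean
basic-basket product list of 736 supermarket foods.

## The food-record model

Every food is a row of a per-100 g (solids) or per-100 mL (liquids)
declaration: energy (kcal and kJ, either derivable from the other at
4.184 kJ/kcal), sugars, saturated and total fat, sodium (mg; a `salt_g`
column is converted at 400 mg sodium per g salt), fibre, protein, and the
fruit/vegetable/nut/legume (FVNL) fraction, plus a food group (cereals,
dairy, protein foods, oils/fats, sugars/others), physical state,
added-ingredient flags, ingredient-marker tags and a special category
(beverage, added fat, cheese). Validation returns issues as data: a fatal
issue (missing nutrient, negative value, saturated > total fat, kcal/kJ
disagreement beyond 2%, unknown group/state/tag) excludes only that record,
mirroring the exclusion of catalogue products with incomplete declarations.
A missing FVNL fraction defaults to 0 with a warning — conservative, since
FVNL only ever improves a Nutri-Score.

## Nutri-Score

We implement the 2017 general-food algorithm behind the official calculator:
negative points (0–10 each) for energy (kJ), sugars, saturated fat and
sodium; positive points for FVNL (0/1/2/5 at >40/>60/>80%), fibre and
protein (0–5). A value earns a point only when it *strictly* exceeds a
threshold, which keeps the printed closed bands ("B between 0 and 2")
consistent at their edges. The balance rule: with N = negative total and
P = positive total, the score is N − P unless N ≥ 11 and FVNL points are
below the maximum, in which case protein is excluded (score =
N − fibre − FVNL). Cheeses always count protein; added fats score saturated
fat from the saturated:total ratio (bands 10, 16, …, 64%); beverages use
compressed energy/sugar tables and a doubled FVNL scale, and plain water is
A by fiat. Scores are integers in −15…40 and band as A (≤ −1), B (0–2),
C (3–10), D (11–18), E (19–40); we apply this single banding to all
variants, since it is the only one the study conditions state. Two
interactions worth noting: the protein-exclusion condition is implemented
as "FVNL points ≥ 5" so that the beverage scale (maximum 10) also
satisfies it, and `variant = "general"` lets users score everything with
the general tables, because whether the beverage variant was applied to the
surveyed liquids is not recorded — the default (`"auto"`) honours each
record's special category.

## Warning labels

A label is due when the declared amount strictly exceeds the limit for the
product's state — solids: 275 kcal, 400 mg sodium, 10 g sugars, 4 g
saturated fat per 100 g; liquids: 70 kcal, 100 mg, 5 g, 3 g per 100 mL —
giving 0–4 labels per food. Equality earns no label; the opposite
convention would be a one-line change and is deliberately not exposed as an
option. The law scopes labelling to foods with *added* sugars, saturated
fat or sodium; the `gate = "on"` mode reproduces that scope from the
added-ingredient flags (the calorie label then requires at least one added
flag). The default is `gate = "off"` — composition alone decides — because
the surveyed classification worked from the declared composition per
100 g/mL, and how foods exceeding limits without added critical ingredients
were handled is not recorded.

## NOVA as a rule ladder

The published NOVA classes are defined qualitatively and were historically
assigned by expert raters. To make verdicts reproducible we replace the
rater with a deterministic ladder over a closed tag vocabulary:
any ultra-processing marker (colourings, flavourings, emulsifiers,
thickeners, non-caloric sweeteners, hydrogenated oils, protein isolates,
maltodextrin, HFCS) → NOVA 4; otherwise a record whose markers are all
culinary substances (oil, butter, lard, sugar, salt, starch, honey) →
NOVA 2; otherwise any processing marker (salting, sugaring, canning,
fermenting, smoking, oiling) → NOVA 3; otherwise NOVA 1. The
culinary-substance tag itself is the "this food *is* a culinary substance"
flag — the input CSV carries no separate ingredient list — so a tagged
substance with an extra processing marker (salted butter) correctly falls
through to NOVA 3, and rule-1 precedence makes a sweetener-blended sugar
NOVA 4. Every result reports the fired rule, its marker evidence and the
vocabulary version hash; the vocabulary ships as YAML configuration, not
code, and is an editorial default that users can re-align with any NOVA
guidance revision.

## Concordance layer

Distributions and cross-tabs are plain counts; percentages are rounded
half-up (integers for headline distributions, one decimal for row
percentages), with unrounded values always written alongside so rounding
never feeds back into computation. The published tables themselves round
inconsistently (some cells are truncated: 37/197 printed as 18.7%), so
tests pin only cells where half-up matches print. Recommendation agreement
maps categories to recommended / neutral / not-recommended (defaults: A–B /
C / D–E; NOVA 1–3 / 4; 0 labels / ≥1), then reports directional
recommended-overlap shares, percent agreement and unweighted Cohen's kappa
on the foods non-neutral under both systems.

The ordination encodes the three verdicts ordinally — A–E → 1–5, NOVA → 1–4,
labels 0–4 → 1–5, higher always less favourable — standardises the columns
and eigen-decomposes the 3×3 correlation matrix. The encoding is a declared
reconstruction: the original analysis does not state its own. Treating
ordinal codes as numeric is the usual pragmatic choice at three variables;
a polychoric alternative is out of scope. Each component's sign is fixed so
its largest-magnitude loading is positive, making results unique and
order-invariant. The biplot geometry is summarised as the pairwise angles
between the systems' correlation-circle arrows (eigenvectors scaled by
√eigenvalue, restricted to the first two components): small angles mean two
systems rank foods along the same dimension. Degenerate strata — a
constant column, fewer than 3 foods — are errors at the API and are
recorded, not fatal, in the pipeline output.

## The synthetic basket

The surveyed 736-product table is not publicly deposited, so the pipeline
runs on synthetic baskets. The generator's fixed conditions are the
surveyed group sizes (198 cereals, 109 dairy, 139 protein foods, 100
oils/fats, 190 sugars/others) and a library of ~29 archetypes — plausible
label declarations for common product types (plain oats, white bread,
sweetened breakfast cereal, cheese, canned tuna, sunflower oil, cola, …),
explicitly synthetic and not any real brand's values. Each archetype's
intended profile (Nutri-Score band, NOVA class, label count at zero noise)
was computed with an independent brute-force threshold scan and frozen into
the library; a test verifies the package classifiers reproduce all of them.

Default mixture weights per group are calibrated so the zero-noise NOVA
distribution matches the reported per-group NOVA distributions. Because
each archetype hits exactly one category, the L1-optimal calibration is
closed-form: split each category's target mass evenly over the archetypes
reaching it. Unreachable target categories are an error by default; the
shipped default uses `strict = FALSE` for the protein group, whose 2%
NOVA-2 share has no culinary-substance archetype and is renormalised away.
Archetype counts are apportioned deterministically (largest remainder), so
a calibrated zero-noise basket reproduces its target exactly whenever the
target is attainable in whole records.

Noise is multiplicative lognormal per nutrient, `sigma = 0.1` by default —
about a 10% coefficient of variation, the order of declaration spread among
brands of one product type — truncated so saturated ≤ total fat and
FVNL ≤ 100, with kJ rederived from kcal. A single seeded stream is consumed
in a fixed order (per-group shuffles, then one draw per record × nutrient),
so baskets are bit-reproducible. NOVA verdicts depend only on markers and
are therefore noise-invariant: the calibrated NOVA frequencies stay within
apportionment error of target at any sigma. Nutri-Score and label
frequencies do move under noise — archetypes near a band edge flip in a
large fraction of draws — which is intended heterogeneity, not error, and
is why recovery guarantees are stated for the calibrated system only.

What passing tests show, and what they do not: the generator reproduces the
*structure* of the surveyed basket (sizes, per-group NOVA mix,
heterogeneous Nutri-Score/label profiles, and the qualitative ordination
geometry — Nutri-Score and warning labels loading together, NOVA apart),
but its nutrient values are synthetic, so per-group Nutri-Score and label
distributions are not calibrated to the published ones and should not be
read as replications of them.

## Numerical choices

* Threshold ties: strict exceedance everywhere (points and labels); a value
  on a threshold takes the lower verdict.
* Percentages: half-up rounding (`round_half_up()`), never R's banker's
  rounding; displayed and unrounded values kept separate.
* PCA: eigen-decomposition of the correlation matrix; explained variances
  are eigenvalues over 3; negative eigenvalue round-off is clamped at 0;
  arrow angles use √eigenvalue scaling so a zero-variance second component
  cannot inject arbitrary directions.
* Kappa: defined as 1 when both raters agree perfectly with a single
  category (expected agreement 1); undefined chance-corrected cases return
  `NA`.
* Apportionment ties (equal fractional remainders) break by archetype
  order, which is fixed by the shipped library.

## Problem sizes

The test suite classifies the full 736-record basket throughout; the
noisy-recovery property uses 200 seeds × 736 records, and oracle-equivalence
checks use 1,000 random panels against a brute-force scan. Everything runs
in well under a minute on one core.

## Known limitations

Marker tags are input data: the package does not parse ingredient
statements, so NOVA verdicts are only as good as the tagging. The default
vocabulary is an editorial choice. The 2023 Nutri-Score revision is not
implemented. Cross-tab inference (tests, weighted kappa, correspondence
analysis) is out of scope, as the comparison layer is deliberately
descriptive.
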