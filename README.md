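# nutriconcord

Three front-of-package food classification systems, one shared data model,
and the statistics to compare them.

Health authorities disagree about how to label food. The **Nutri-Score**
profiles nutrient balance into letters A–E; **NOVA** grades the degree of
industrial processing 1–4; Chile's **warning labels** (Law 20.606) stamp
products whose critical nutrients exceed legal per-100 g/mL limits, 0–4
stamps per product. Applied to the same shelf, the three systems can point
in opposite directions — a basket can be mostly "A", mostly "ultra-processed"
and mostly "no stamps" at the same time. `nutriconcord` implements all three
classifiers deterministically over a common food-record model and provides
the concordance layer used to quantify their disagreement on a 736-item
Chilean basic-basket product list: frequency distributions by food group,
pairwise cross-tabulations with row percentages, recommendation agreement
(Cohen's kappa), and PCA ordination of the three verdicts.

## The classifiers in brief

* **Nutri-Score** (2017 general-food algorithm): negative points for energy
  (kJ), sugars, saturated fat, sodium (0–10 each); positive points for
  fruit/vegetable/nut/legume content, fibre, protein (0–5). Score
  `S = N − P`, except protein is dropped when `N ≥ 11` without maximal FVNL
  points. Bands: A `[−15,−1]`, B `[0,2]`, C `[3,10]`, D `[11,18]`,
  E `[19,40]`. Cheese, added-fat and beverage variants included.
* **NOVA** as an auditable rule ladder over ingredient-marker tags: any
  ultra-processing marker → 4; a pure culinary substance → 2; any
  processing marker → 3; else 1. Every verdict reports its fired rule,
  evidence and vocabulary version.
* **Warning labels**: strict exceedance of the solid limits
  (275 kcal / 400 mg Na / 10 g sugar / 4 g sat fat per 100 g) or liquid
  limits (70 / 100 / 5 / 3 per 100 mL); an optional gate restricts labels
  to foods with the corresponding added ingredient.

Because the surveyed 736-food table is not publicly deposited, the package
ships a synthetic basket generator: ~29 documented food archetypes with
frozen zero-noise classification profiles, mixture weights calibrated to
the reported per-group NOVA distributions, lognormal nutrient noise, and
bit-reproducible output from a seed.

## Worked example

```r
library(nutriconcord)

rec <- food_record("yog1", "sweetened yogurt drink", group = "dairy",
                   state = "liquid", energy_kcal = 80, sugars_g = 11,
                   saturated_fat_g = 1.5, total_fat_g = 2, sodium_mg = 60,
                   protein_g = 3, added_sugar = 1,
                   markers = c("colouring", "flavouring", "added_sugar"))

compute_nutriscore(rec)
#> Nutri-Score: 2 (B)  [N = 3, P = 1, protein counted, variant none]
classify_nova(rec)
#> NOVA 4 (rule: ultra_processing_marker; evidence: colouring, flavouring)
count_warnings(rec)
#> FoP warning labels (liquid limits): 2 [high_calories, high_sugars]
```

One product, three verdicts: "recommended" by Nutri-Score (B), worst class
by NOVA (4), two warning stamps. That tension, at basket scale:

```r
basket <- generate_basket(default_basket_config(seed = 7))
cl <- classify_basket(basket)
run_pca(ordinal_encode(cl))
#> PCA ordination, stratum 'all': PC1 78.3%, PC2 15.3% of variance
#> Loading angles (degrees):
#>            nutriscore nova  fop
#> nutriscore        0.0 44.2 10.8
#> nova             44.2  0.0 55.1
#> fop              10.8 55.1  0.0
```

Nutri-Score and the warning labels rank the basket along nearly the same
dimension (arrows 10.8° apart); NOVA points somewhere else entirely
(44–55° away). `run_full_analysis()` writes the whole set of outputs —
classified table, distributions, cross-tabs, agreement, ordinations and a
run manifest — in one call, and
`inst/scripts/run_basket_analysis.R` wraps it for the shell.

## Package layout

| Surface | Functions |
| --- | --- |
| Food model | `food_record()`, `read_food_table()`, `write_food_table()`, `validate_record()` |
| Nutri-Score | `compute_nutriscore()`, `component_points()`, `score_to_category()`, `nutriscore_classify()` |
| Warning labels | `fop_thresholds()`, `count_warnings()`, `fop_classify()` |
| NOVA | `classify_nova()`, `nova_classify()`, `marker_vocabulary()`, `read_marker_vocabulary()` |
| Concordance | `tabulate_distribution()`, `cross_tabulate()`, `recommendation_agreement()`, `cohen_kappa()`, `ordinal_encode()`, `run_pca()`, `plot_ordination()` |
| Synthetic basket | `archetype_library()`, `basket_config()`, `calibrate_mixture()`, `generate_basket()` |
| Pipeline | `classify_basket()`, `run_full_analysis()` |

See `vignettes/classification-concordance.Rmd` for the full methods
account: algorithms, tie-breaking, the noise model, calibration, and what
the synthetic basket does and does not emulate.
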