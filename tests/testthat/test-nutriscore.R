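test_that("component points match the adopted tables at spot values", {
  expect_equal(component_points("energy", 0), 0L)
  expect_equal(component_points("energy", 1500), 4L) # 1340 < 1500 <= 1675
  expect_equal(component_points("protein", 9), 5L) # > 8.0
  expect_equal(component_points("sugars", 4.5), 0L) # ties stay below
  expect_equal(component_points("sugars", 4.5 + 1e-9), 1L)
  expect_equal(component_points("satfat", 14, variant = "added_fat"), 1L)
  expect_equal(component_points("fvnl", 85, variant = "beverage"), 10L)
  expect_error(component_points("energy", -1), "non-negative")
  expect_error(component_points("protein", 5, variant = "beverage"), "beverage")
  expect_error(component_points("tannins", 5))
})

test_that("the worked panel scores 13/D generally and 10/C as cheese", {
  panel <- list(
    energy_kj = 1500, sugars_g = 20, saturated_fat_g = 3, total_fat_g = 3,
    sodium_mg = 500, fibre_g = 2, protein_g = 5, fvnl_pct = 0
  )
  res <- compute_nutriscore(panel)
  expect_equal(res$n_total, 15L) # 4 + 4 + 2 + 5
  expect_equal(res$fibre_pts, 2L)
  expect_false(res$protein_counted) # N >= 11 and fvnl points < 5
  expect_equal(res$final_score, 13L)
  expect_equal(res$category, "D")

  cheese <- compute_nutriscore(panel, special_category = "cheese")
  expect_true(cheese$protein_counted)
  expect_equal(cheese$final_score, 10L)
  expect_equal(cheese$category, "C")
})

test_that("an all-zero panel scores 0 and bands B; water is A by fiat", {
  zero <- list(
    energy_kj = 0, sugars_g = 0, saturated_fat_g = 0, total_fat_g = 0,
    sodium_mg = 0, fibre_g = 0, protein_g = 0, fvnl_pct = 0
  )
  res <- compute_nutriscore(zero)
  expect_equal(res$final_score, 0L)
  expect_equal(res$category, "B")
  expect_equal(
    compute_nutriscore(zero, "beverage", water = TRUE)$category, "A"
  )
})

test_that("score bands partition [-15, 40] exactly as printed", {
  scores <- -15:40
  bands <- score_to_category(scores)
  expect_equal(bands[scores <= -1], rep("A", 15))
  expect_equal(bands[scores >= 0 & scores <= 2], rep("B", 3))
  expect_equal(bands[scores >= 3 & scores <= 10], rep("C", 8))
  expect_equal(bands[scores >= 11 & scores <= 18], rep("D", 8))
  expect_equal(bands[scores >= 19], rep("E", 22))
  expect_false(anyNA(bands)) # exhaustive
  expect_error(score_to_category(-16), "-15")
  expect_error(score_to_category(41), "40")
})

test_that("score is monotone in each component's health direction", {
  set.seed(11)
  rank_of <- function(cat) match(cat, c("A", "B", "C", "D", "E"))
  for (i in 1:50) {
    p <- random_panel()
    base <- rank_of(compute_nutriscore(p)$category)
    worse <- p
    worse$sugars_g <- worse$sugars_g + runif(1, 0, 30)
    expect_gte(rank_of(compute_nutriscore(worse)$category), base)
    better <- p
    better$fibre_g <- better$fibre_g + runif(1, 0, 5)
    expect_lte(rank_of(compute_nutriscore(better)$category), base)
  }
})

test_that("the score bounds -15 and +40 are attained exactly", {
  legume <- list(
    energy_kj = 0, sugars_g = 0, saturated_fat_g = 0, total_fat_g = 0,
    sodium_mg = 0, fibre_g = 10, protein_g = 10, fvnl_pct = 100
  )
  expect_equal(compute_nutriscore(legume)$final_score, -15L)
  worst <- list(
    energy_kj = 4000, sugars_g = 50, saturated_fat_g = 11, total_fat_g = 11,
    sodium_mg = 1000, fibre_g = 0, protein_g = 0, fvnl_pct = 0
  )
  res <- compute_nutriscore(worst)
  expect_equal(res$final_score, 40L)
  expect_equal(res$category, "E")
})

test_that("an invalid panel is rejected with an informative error", {
  expect_error(
    compute_nutriscore(list(
      energy_kj = 100, sugars_g = 1, saturated_fat_g = 5, total_fat_g = 3,
      sodium_mg = 0, fibre_g = 0, protein_g = 0, fvnl_pct = 0
    )),
    "saturated"
  )
  expect_error(
    compute_nutriscore(list(
      energy_kj = 100, sugars_g = -1, saturated_fat_g = 0, total_fat_g = 0,
      sodium_mg = 0, fibre_g = 0, protein_g = 0, fvnl_pct = 0
    )),
    "panel"
  )
})

test_that("variant = general overrides special categories in bulk scoring", {
  rec <- food_record("oil1", group = "oils_fats", state = "liquid",
                     energy_kcal = 884, saturated_fat_g = 10,
                     total_fat_g = 100, markers = "vegetable_oil",
                     special_category = "added_fat")
  auto <- nutriscore_classify(rec, variant = "auto")
  gen <- nutriscore_classify(rec, variant = "general")
  expect_equal(auto$satfat_pts, 0L) # ratio 10% not above first band
  expect_equal(gen$satfat_pts, 9L) # 10 g on the general gram table
})
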