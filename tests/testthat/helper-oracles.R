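# Fixtures and independent brute-force oracles used across the suite.

# Random nutrient panel spanning all point bands.
random_panel <- function() {
  list(
    energy_kj = runif(1, 0, 4000),
    sugars_g = runif(1, 0, 60),
    total_fat_g = tf <- runif(1, 0, 40),
    saturated_fat_g = runif(1, 0, tf),
    sodium_mg = runif(1, 0, 1200),
    fibre_g = runif(1, 0, 8),
    protein_g = runif(1, 0, 15),
    fvnl_pct = runif(1, 0, 100)
  )
}

# Brute-force Nutri-Score: linear scans of every threshold table, written
# independently of the package's findInterval-based implementation.
oracle_scan <- function(x, thr) {
  p <- 0L
  for (t in thr) if (x > t) p <- p + 1L
  p
}

oracle_nutriscore <- function(panel, special = "none") {
  bev <- special == "beverage"
  e_thr <- if (bev) c(0, 30, 60, 90, 120, 150, 180, 210, 240, 270) else
    c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350)
  s_thr <- if (bev) c(0, 1.5, 3, 4.5, 6, 7.5, 9, 10.5, 12, 13.5) else
    c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45)
  ep <- oracle_scan(panel$energy_kj, e_thr)
  sp <- oracle_scan(panel$sugars_g, s_thr)
  if (special == "added_fat") {
    ratio <- if (panel$total_fat_g > 0) {
      100 * panel$saturated_fat_g / panel$total_fat_g
    } else 0
    fp <- oracle_scan(ratio, c(10, 16, 22, 28, 34, 40, 46, 52, 58, 64))
  } else {
    fp <- oracle_scan(panel$saturated_fat_g, 1:10)
  }
  np <- oracle_scan(panel$sodium_mg, seq(90, 900, 90))
  fv <- panel$fvnl_pct
  fvp <- if (bev) {
    if (fv > 80) 10L else if (fv > 60) 4L else if (fv > 40) 2L else 0L
  } else {
    if (fv > 80) 5L else if (fv > 60) 2L else if (fv > 40) 1L else 0L
  }
  fip <- oracle_scan(panel$fibre_g, c(0.9, 1.9, 2.8, 3.7, 4.7))
  pp <- oracle_scan(panel$protein_g, c(1.6, 3.2, 4.8, 6.4, 8.0))
  N <- ep + sp + fp + np
  score <- if (special == "cheese" || N < 11 || fvp >= 5) {
    N - (fvp + fip + pp)
  } else {
    N - (fvp + fip)
  }
  band <- if (score <= -1) "A" else if (score <= 2) "B" else
    if (score <= 10) "C" else if (score <= 18) "D" else "E"
  list(score = score, category = band)
}

# A tiny valid food table as CSV text.
fixture_csv <- function(rows) {
  header <- paste(
    "food_id,name,group,state,energy_kcal,sugars_g,saturated_fat_g",
    "total_fat_g,sodium_mg,fibre_g,protein_g,fvnl_pct,added_sugar",
    "added_sat_fat,added_sodium,markers,special_category",
    sep = ","
  )
  I(paste(c(header, rows), collapse = "\n"))
}

good_rows <- c(
  "f1,oats,cereals,solid,375,1,1.2,7,5,10,13,0,0,0,0,,none",
  "f2,milk,dairy,liquid,61,4.7,2,3.3,44,0,3.2,0,0,0,0,,none",
  "f3,cola,sugars_others,liquid,42,10.6,0,0,10,0,0,0,1,0,0,colouring;added_sugar,beverage"
)
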