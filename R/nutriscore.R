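# Nutri-Score: the 2017 general-food nutrient-profiling algorithm.
#
# Negative (N) points from energy, sugars, saturated fat and sodium (0-10
# each); positive (P) points from fruit/vegetable/nut/legume content, fibre
# and protein (0-5 each; FVNL up to 10 for beverages). A value earns point
# k+1 only when it STRICTLY exceeds threshold k, so a value sitting exactly
# on a threshold keeps the lower score. The continuous score runs from -15
# (healthiest) to +40 (least healthy) and is banded A-E.

NS_TABLES <- list(
  energy_kj = c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350),
  energy_kj_beverage = c(0, 30, 60, 90, 120, 150, 180, 210, 240, 270),
  sugars_g = c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45),
  sugars_g_beverage = c(0, 1.5, 3, 4.5, 6, 7.5, 9, 10.5, 12, 13.5),
  satfat_g = 1:10,
  satfat_ratio_pct = c(10, 16, 22, 28, 34, 40, 46, 52, 58, 64),
  sodium_mg = seq(90, 900, by = 90),
  fibre_g = c(0.9, 1.9, 2.8, 3.7, 4.7),
  protein_g = c(1.6, 3.2, 4.8, 6.4, 8.0)
)

# points = number of thresholds strictly exceeded
threshold_points <- function(value, thresholds) {
  findInterval(value, thresholds, left.open = TRUE)
}

fvnl_points <- function(pct, beverage = FALSE) {
  ifelse(beverage,
    2L * (pct > 40) + 2L * (pct > 60) + 6L * (pct > 80),
    1L * (pct > 40) + 1L * (pct > 60) + 3L * (pct > 80)
  )
}

#' Nutri-Score points for a single component
#'
#' Looks up the point contribution of one scoring component. Negative
#' components (energy in kJ, sugars, saturated fat, sodium in mg) score 0-10;
#' positive components (fvnl %, fibre, protein, in g) score 0-5 (fvnl 0-10 for
#' beverages). Points increment only when the value strictly exceeds a
#' threshold. For the `added_fat` variant of `satfat`, `value` is the
#' saturated-to-total-fat ratio expressed as a percentage.
#'
#' @param component One of `"energy"`, `"sugars"`, `"satfat"`, `"sodium"`,
#'   `"fvnl"`, `"fibre"`, `"protein"`.
#' @param value Amount in component units (kJ, g, mg or %); non-negative.
#' @param variant `"general"`, `"beverage"` (energy, sugars, fvnl only) or
#'   `"added_fat"` (satfat only).
#' @return Integer vector of points, monotone non-decreasing in `value`.
#' @export
#' @examples
#' component_points("energy", 1500) # 4
#' component_points("protein", 9) # 5
component_points <- function(component, value,
                             variant = c("general", "beverage", "added_fat")) {
  component <- match.arg(component, c(
    "energy", "sugars", "satfat", "sodium", "fvnl", "fibre", "protein"
  ))
  variant <- match.arg(variant)
  if (any(is.na(value)) || any(value < 0)) {
    stop_nc("component value must be non-negative and non-missing")
  }
  if (variant == "beverage" && !component %in% c("energy", "sugars", "fvnl")) {
    stop_nc("beverage variant applies only to energy, sugars and fvnl")
  }
  if (variant == "added_fat" && component != "satfat") {
    stop_nc("added_fat variant applies only to satfat")
  }
  as.integer(switch(component,
    energy = threshold_points(value, if (variant == "beverage") {
      NS_TABLES$energy_kj_beverage
    } else {
      NS_TABLES$energy_kj
    }),
    sugars = threshold_points(value, if (variant == "beverage") {
      NS_TABLES$sugars_g_beverage
    } else {
      NS_TABLES$sugars_g
    }),
    satfat = threshold_points(value, if (variant == "added_fat") {
      NS_TABLES$satfat_ratio_pct
    } else {
      NS_TABLES$satfat_g
    }),
    sodium = threshold_points(value, NS_TABLES$sodium_mg),
    fvnl = fvnl_points(value, beverage = variant == "beverage"),
    fibre = threshold_points(value, NS_TABLES$fibre_g),
    protein = threshold_points(value, NS_TABLES$protein_g)
  ))
}

#' Map a Nutri-Score to its letter band
#'
#' A for scores -15 to -1, B for 0 to 2, C for 3 to 10, D for 11 to 18 and E
#' for 19 to 40. Bands are contiguous and exhaustive on the integer range
#' -15..40; anything outside is an error.
#'
#' @param score Integer score(s) in -15..40.
#' @return Character vector of letters A-E.
#' @export
#' @examples
#' score_to_category(c(-1, 0, 10, 11, 40))
score_to_category <- function(score) {
  if (any(is.na(score)) || any(score < -15 | score > 40)) {
    stop_nc("score must lie in [-15, 40]")
  }
  as.character(cut(score,
    breaks = c(-15.5, -0.5, 2.5, 10.5, 18.5, 40.5),
    labels = c("A", "B", "C", "D", "E")
  ))
}

# Vectorised core over parallel nutrient vectors. `special` selects the
# variant per element: beverages use the beverage energy/sugar/fvnl tables,
# added fats score saturated fat from the saturated:total ratio, and cheeses
# always count protein.
ns_points_vec <- function(energy_kj, sugars_g, saturated_fat_g, total_fat_g,
                          sodium_mg, fvnl_pct, fibre_g, protein_g, special) {
  n <- length(energy_kj)
  is_bev <- special == "beverage"
  is_fat <- special == "added_fat"
  is_cheese <- special == "cheese"

  energy_pts <- ifelse(is_bev,
    threshold_points(energy_kj, NS_TABLES$energy_kj_beverage),
    threshold_points(energy_kj, NS_TABLES$energy_kj)
  )
  sugars_pts <- ifelse(is_bev,
    threshold_points(sugars_g, NS_TABLES$sugars_g_beverage),
    threshold_points(sugars_g, NS_TABLES$sugars_g)
  )
  satfat_ratio <- ifelse(total_fat_g > 0,
                         100 * saturated_fat_g / total_fat_g, 0)
  satfat_pts <- ifelse(is_fat,
    threshold_points(satfat_ratio, NS_TABLES$satfat_ratio_pct),
    threshold_points(saturated_fat_g, NS_TABLES$satfat_g)
  )
  sodium_pts <- threshold_points(sodium_mg, NS_TABLES$sodium_mg)
  fvnl_pts <- fvnl_points(fvnl_pct, beverage = is_bev)
  fibre_pts <- threshold_points(fibre_g, NS_TABLES$fibre_g)
  protein_pts <- threshold_points(protein_g, NS_TABLES$protein_g)

  n_total <- energy_pts + sugars_pts + satfat_pts + sodium_pts
  p_total <- fvnl_pts + fibre_pts + protein_pts

  # N/P balance: protein only counts when N < 11, or FVNL points are maximal
  # (>= 5; 10 for beverages), or the food is a cheese.
  protein_counted <- is_cheese | n_total < 11 | fvnl_pts >= 5
  final_score <- ifelse(protein_counted,
    n_total - p_total,
    n_total - (fibre_pts + fvnl_pts)
  )

  tibble::tibble(
    energy_pts = as.integer(energy_pts),
    sugars_pts = as.integer(sugars_pts),
    satfat_pts = as.integer(satfat_pts),
    sodium_pts = as.integer(sodium_pts),
    fvnl_pts = as.integer(fvnl_pts),
    fibre_pts = as.integer(fibre_pts),
    protein_pts = as.integer(protein_pts),
    n_total = as.integer(n_total),
    p_total = as.integer(p_total),
    protein_counted = protein_counted,
    final_score = as.integer(final_score),
    category = score_to_category(final_score)
  )
}

check_panel <- function(panel) {
  vals <- unlist(panel[c(
    "energy_kj", "sugars_g", "saturated_fat_g", "total_fat_g", "sodium_mg",
    "fibre_g", "protein_g", "fvnl_pct"
  )])
  if (any(is.na(vals)) || any(vals < 0)) {
    stop_nc("invalid nutrient panel: all values must be present and >= 0")
  }
  if (panel$fvnl_pct > 100) stop_nc("invalid nutrient panel: fvnl_pct > 100")
  if (panel$saturated_fat_g > panel$total_fat_g + 1e-9) {
    stop_nc("invalid nutrient panel: saturated fat exceeds total fat")
  }
  invisible(panel)
}

#' Compute the full Nutri-Score breakdown for one nutrient panel
#'
#' Applies the point tables and the N/P balance rule and bands the final
#' score. `special_category = "cheese"` always counts protein;
#' `"added_fat"` scores saturated fat from the saturated:total fat ratio;
#' `"beverage"` uses the beverage energy/sugar/FVNL scales. Plain water is
#' category A by convention (`water = TRUE`).
#'
#' @param panel Named list or one-row data frame with `energy_kj` (or
#'   `energy_kcal`, converted at 4.184 kJ/kcal), `sugars_g`,
#'   `saturated_fat_g`, `total_fat_g`, `sodium_mg`, `fibre_g`, `protein_g`,
#'   `fvnl_pct`.
#' @param special_category One of `"none"`, `"beverage"`, `"added_fat"`,
#'   `"cheese"`.
#' @param water If `TRUE` the food is plain water and is banded A by fiat.
#' @return A `nutriscore_points` list: per-component points, `n_total`,
#'   `p_total`, `protein_counted`, `final_score` and `category`.
#' @export
#' @examples
#' compute_nutriscore(list(
#'   energy_kj = 1500, sugars_g = 20, saturated_fat_g = 3, total_fat_g = 3,
#'   sodium_mg = 500, fibre_g = 2, protein_g = 5, fvnl_pct = 0
#' )) # score 13, category D
compute_nutriscore <- function(panel, special_category = "none",
                               water = FALSE) {
  special_category <- match.arg(special_category, SPECIAL_CATEGORIES)
  panel <- as.list(panel)
  if (is.null(panel$energy_kj)) {
    if (is.null(panel$energy_kcal)) stop_nc("panel must give energy_kj or energy_kcal")
    panel$energy_kj <- panel$energy_kcal * KJ_PER_KCAL
  }
  check_panel(panel)
  res <- as.list(ns_points_vec(
    panel$energy_kj, panel$sugars_g, panel$saturated_fat_g,
    panel$total_fat_g, panel$sodium_mg, panel$fvnl_pct, panel$fibre_g,
    panel$protein_g, special_category
  ))
  res$special_category <- special_category
  if (water) res$category <- "A"
  structure(res, class = "nutriscore_points")
}

#' @export
print.nutriscore_points <- function(x, ...) {
  cat(sprintf(
    "Nutri-Score: %d (%s)  [N = %d, P = %d, protein %scounted, variant %s]\n",
    x$final_score, x$category, x$n_total, x$p_total,
    if (x$protein_counted) "" else "not ", x$special_category
  ))
  invisible(x)
}

#' Nutri-Score classification of a whole food table
#'
#' Vectorised wrapper over [compute_nutriscore()]. With `variant = "auto"`
#' each record's `special_category` selects its algorithm variant; with
#' `variant = "general"` every record is scored with the general-food tables.
#'
#' @param records A `food_table` tibble.
#' @param variant `"auto"` or `"general"`.
#' @return Tibble with one row per record: the point breakdown, `final_score`
#'   and `category`.
#' @export
nutriscore_classify <- function(records, variant = c("auto", "general")) {
  variant <- match.arg(variant)
  special <- if (variant == "general") {
    rep("none", nrow(records))
  } else {
    records$special_category
  }
  res <- ns_points_vec(
    records$energy_kj, records$sugars_g, records$saturated_fat_g,
    records$total_fat_g, records$sodium_mg, records$fvnl_pct,
    records$fibre_g, records$protein_g, special
  )
  dplyr::bind_cols(tibble::tibble(food_id = records$food_id), res)
}
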