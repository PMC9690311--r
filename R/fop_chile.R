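# Chilean front-of-package "high in" warning labels (Law 20.606).
#
# A label is due when the declared per-100 g (solid) or per-100 mL (liquid)
# amount STRICTLY exceeds the legal limit for that state; a value exactly at
# the limit earns no label. The law scopes labelling to foods with added
# sugars, saturated fat or sodium; that gate is reproduced with the added_*
# flags but is off by default, classifying on declared composition alone.

FOP_LIMITS <- list(
  solid = c(energy_kcal = 275, sodium_mg = 400, sugars_g = 10,
            saturated_fat_g = 4),
  liquid = c(energy_kcal = 70, sodium_mg = 100, sugars_g = 5,
             saturated_fat_g = 3)
)

FOP_LABELS <- c("high_calories", "high_sodium", "high_sugars", "high_sat_fat")

#' Warning-label limits for a physical state
#'
#' Solids: energy 275 kcal, sodium 400 mg, sugars 10 g, saturated fat 4 g per
#' 100 g. Liquids: energy 70 kcal, sodium 100 mg, sugars 5 g, saturated fat
#' 3 g per 100 mL.
#'
#' @param state `"solid"` or `"liquid"`.
#' @return Named numeric vector of the four limits.
#' @export
#' @examples
#' fop_thresholds("solid")
fop_thresholds <- function(state) {
  if (length(state) != 1 || !state %in% FOOD_STATES) {
    stop_nc("unknown state: ", paste(state, collapse = ", "),
            " (expected solid or liquid)")
  }
  FOP_LIMITS[[state]]
}

# Vectorised core. gate = "on" requires the matching added-ingredient flag
# (any flag, for the calorie label); gate = "off" classifies on composition.
fop_labels_vec <- function(energy_kcal, sodium_mg, sugars_g, saturated_fat_g,
                           state, added_sugar, added_sat_fat, added_sodium,
                           gate = c("off", "on")) {
  gate <- match.arg(gate)
  lim <- do.call(rbind, FOP_LIMITS)[state, , drop = FALSE]
  over <- cbind(
    high_calories = energy_kcal > lim[, "energy_kcal"],
    high_sodium = sodium_mg > lim[, "sodium_mg"],
    high_sugars = sugars_g > lim[, "sugars_g"],
    high_sat_fat = saturated_fat_g > lim[, "saturated_fat_g"]
  )
  if (gate == "on") {
    any_added <- (added_sugar | added_sat_fat | added_sodium)
    over[, "high_calories"] <- over[, "high_calories"] & any_added
    over[, "high_sodium"] <- over[, "high_sodium"] & as.logical(added_sodium)
    over[, "high_sugars"] <- over[, "high_sugars"] & as.logical(added_sugar)
    over[, "high_sat_fat"] <- over[, "high_sat_fat"] & as.logical(added_sat_fat)
  }
  margins <- cbind(
    high_calories = energy_kcal - lim[, "energy_kcal"],
    high_sodium = sodium_mg - lim[, "sodium_mg"],
    high_sugars = sugars_g - lim[, "sugars_g"],
    high_sat_fat = saturated_fat_g - lim[, "saturated_fat_g"]
  )
  list(over = over, margins = margins)
}

#' Count warning labels for one food record
#'
#' @param record A one-row `food_table` tibble (see [food_record()]).
#' @param gate `"off"` (default; composition alone decides, the mode used to
#'   reproduce declared-composition classification) or `"on"` (a nutrient
#'   label additionally requires its added-ingredient flag; the calorie label
#'   requires at least one added flag).
#' @return A `fop_result` list: `labels` (subset of `high_calories`,
#'   `high_sodium`, `high_sugars`, `high_sat_fat`), `n_labels`,
#'   `thresholds_used` and `per_nutrient_margin` (signed distance to each
#'   limit, positive = above).
#' @export
#' @examples
#' count_warnings(food_record("f1",
#'   group = "sugars_others", state = "liquid",
#'   sugars_g = 8, added_sugar = 1
#' )) # one label: high_sugars
count_warnings <- function(record, gate = c("off", "on")) {
  gate <- match.arg(gate)
  stopifnot(nrow(record) == 1)
  iss <- validate_record(record)
  if (any(iss$severity == "fatal")) {
    stop_nc("invalid record: ", paste(iss$message[iss$severity == "fatal"],
                                      collapse = "; "))
  }
  res <- fop_labels_vec(
    record$energy_kcal, record$sodium_mg, record$sugars_g,
    record$saturated_fat_g, record$state, record$added_sugar,
    record$added_sat_fat, record$added_sodium, gate
  )
  structure(list(
    labels = FOP_LABELS[res$over[1, ]],
    n_labels = sum(res$over[1, ]),
    thresholds_used = record$state,
    per_nutrient_margin = res$margins[1, ]
  ), class = "fop_result")
}

#' @export
print.fop_result <- function(x, ...) {
  cat(sprintf(
    "FoP warning labels (%s limits): %d%s\n", x$thresholds_used, x$n_labels,
    if (x$n_labels > 0) paste0(" [", paste(x$labels, collapse = ", "), "]") else ""
  ))
  invisible(x)
}

#' Warning-label classification of a whole food table
#'
#' Vectorised wrapper over the limit comparisons of [count_warnings()].
#'
#' @inheritParams count_warnings
#' @param records A `food_table` tibble.
#' @return Tibble with `food_id`, one logical column per label and `n_labels`.
#' @export
fop_classify <- function(records, gate = c("off", "on")) {
  gate <- match.arg(gate)
  res <- fop_labels_vec(
    records$energy_kcal, records$sodium_mg, records$sugars_g,
    records$saturated_fat_g, records$state, records$added_sugar,
    records$added_sat_fat, records$added_sodium, gate
  )
  out <- tibble::as_tibble(res$over)
  dplyr::bind_cols(
    tibble::tibble(food_id = records$food_id),
    out,
    tibble::tibble(n_labels = as.integer(rowSums(res$over)))
  )
}
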