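# Food-record data model: the CSV food table every classifier consumes.
#
# All composition is interpreted per 100 g (solids) or 100 mL (liquids) of
# product as sold. Energy is carried in both kcal (warning-label thresholds)
# and kJ (Nutri-Score tables); whichever is absent is derived from the other.

NUTRIENT_COLUMNS <- c(
  "energy_kcal", "sugars_g", "saturated_fat_g", "total_fat_g",
  "sodium_mg", "fibre_g", "protein_g", "fvnl_pct"
)

REQUIRED_COLUMNS <- c(
  "food_id", "name", "group", "state", NUTRIENT_COLUMNS,
  "added_sugar", "added_sat_fat", "added_sodium", "markers", "special_category"
)

FLAG_COLUMNS <- c("added_sugar", "added_sat_fat", "added_sodium")

new_issue <- function(food_id, field, severity, message) {
  tibble::tibble(
    food_id = as.character(food_id), field = field,
    severity = severity, message = message
  )
}

empty_issues <- function() {
  tibble::tibble(
    food_id = character(), field = character(),
    severity = character(), message = character()
  )
}

as_food_table <- function(x) {
  class(x) <- unique(c("food_table", class(x)))
  x
}

#' Construct a single food record
#'
#' Convenience constructor used throughout the examples and tests. Nutrient
#' values default to zero; `energy_kj` is derived from `energy_kcal` when not
#' given (1 kcal = 4.184 kJ).
#'
#' @param food_id,name Identifiers.
#' @param group One of [food_groups()].
#' @param state `"solid"` or `"liquid"` (selects the warning-label limit set).
#' @param energy_kcal,energy_kj,sugars_g,saturated_fat_g,total_fat_g,sodium_mg,fibre_g,protein_g,fvnl_pct
#'   Declared composition per 100 g / 100 mL. `fvnl_pct` is the percentage of
#'   fruits, vegetables, nuts and legumes (0-100).
#' @param added_sugar,added_sat_fat,added_sodium 0/1 added-ingredient flags.
#' @param markers Character vector of ingredient-marker tags (see
#'   [default_marker_vocabulary()]).
#' @param special_category `"none"`, `"beverage"`, `"added_fat"` or `"cheese"`;
#'   selects the Nutri-Score variant under `variant = "auto"`.
#' @return A one-row `food_table` tibble.
#' @export
#' @examples
#' food_record("f1", "porridge oats", "cereals",
#'   energy_kcal = 375, fibre_g = 10, protein_g = 13
#' )
food_record <- function(food_id, name = food_id, group, state = "solid",
                        energy_kcal = 0, energy_kj = NULL, sugars_g = 0,
                        saturated_fat_g = 0, total_fat_g = saturated_fat_g,
                        sodium_mg = 0, fibre_g = 0, protein_g = 0,
                        fvnl_pct = 0, added_sugar = 0, added_sat_fat = 0,
                        added_sodium = 0, markers = character(0),
                        special_category = "none") {
  as_food_table(tibble::tibble(
    food_id = as.character(food_id), name = as.character(name),
    group = group, state = state,
    energy_kcal = energy_kcal,
    energy_kj = energy_kj %||% (energy_kcal * KJ_PER_KCAL),
    sugars_g = sugars_g, saturated_fat_g = saturated_fat_g,
    total_fat_g = total_fat_g, sodium_mg = sodium_mg, fibre_g = fibre_g,
    protein_g = protein_g, fvnl_pct = fvnl_pct,
    added_sugar = as.integer(added_sugar),
    added_sat_fat = as.integer(added_sat_fat),
    added_sodium = as.integer(added_sodium),
    markers = list(as.character(markers)),
    special_category = special_category
  ))
}

parse_numeric_column <- function(raw, col, issues) {
  txt <- raw[[col]]
  val <- suppressWarnings(as.numeric(txt))
  bad <- !is.na(txt) & trimws(txt) != "" & is.na(val)
  if (any(bad)) {
    issues <- dplyr::bind_rows(issues, new_issue(
      raw$food_id[bad], col, "fatal",
      sprintf("non-numeric value '%s'", txt[bad])
    ))
  }
  blank <- !is.na(txt) & trimws(txt) == ""
  val[blank] <- NA_real_
  list(value = val, issues = issues)
}

#' Read and validate a food-composition table
#'
#' Parses the CSV food table (comma-separated, UTF-8, mandatory header) into a
#' `food_table` tibble, validating every row. Rows with fatal issues are
#' excluded from the returned records but reported, mirroring the exclusion of
#' products with incomplete nutrition declarations from the surveyed basket;
#' record order is otherwise preserved.
#'
#' Required columns: `food_id, name, group, state, energy_kcal, sugars_g,
#' saturated_fat_g, total_fat_g, sodium_mg, fibre_g, protein_g, fvnl_pct,
#' added_sugar, added_sat_fat, added_sodium, markers, special_category`.
#' `markers` is a semicolon-joined tag list; flags are 0/1. Optional columns:
#' `energy_kj` (otherwise derived as 4.184 x kcal) and `salt_g` (converted to
#' `sodium_mg = salt_g * 400` when `sodium_mg` is missing). A missing
#' `fvnl_pct` defaults to 0 with a warning issue; missing fibre, protein or
#' sodium is fatal.
#'
#' @param source Path or connection readable by [readr::read_csv()].
#' @param strict If `TRUE`, any fatal issue aborts with an error instead of
#'   excluding the offending rows.
#' @param vocabulary Marker vocabulary used to check that marker tags are known.
#' @return A list with elements `records` (a `food_table` tibble) and `issues`
#'   (a tibble with columns `food_id`, `field`, `severity`, `message`).
#' @seealso [write_food_table()], [validate_record()]
#' @export
read_food_table <- function(source, strict = FALSE,
                            vocabulary = default_marker_vocabulary()) {
  raw <- readr::read_csv(source,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop_nc(
      "food table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }
  if (!"food_id" %in% names(raw) || nrow(raw) == 0) {
    return(list(records = food_record("x", group = "cereals")[0, ],
                issues = empty_issues()))
  }

  issues <- empty_issues()
  num <- list()
  numeric_cols <- c(NUTRIENT_COLUMNS,
                    intersect(c("energy_kj", "salt_g"), names(raw)))
  for (col in numeric_cols) {
    parsed <- parse_numeric_column(raw, col, issues)
    num[[col]] <- parsed$value
    issues <- parsed$issues
  }
  for (col in FLAG_COLUMNS) {
    parsed <- parse_numeric_column(raw, col, issues)
    bad <- !is.na(parsed$value) & !parsed$value %in% c(0, 1)
    if (any(bad)) {
      issues <- dplyr::bind_rows(issues, new_issue(
        raw$food_id[bad], col, "fatal", "flag must be 0 or 1"
      ))
    }
    num[[col]] <- parsed$value
    issues <- parsed$issues
  }

  # Unit harmonisation: salt -> sodium, kcal <-> kJ.
  sodium <- num$sodium_mg
  if (!is.null(num$salt_g)) {
    use_salt <- is.na(sodium) & !is.na(num$salt_g)
    sodium[use_salt] <- num$salt_g[use_salt] * 400
  }
  kcal <- num$energy_kcal
  kj <- num$energy_kj %||% rep(NA_real_, nrow(raw))
  kcal[is.na(kcal) & !is.na(kj)] <- kj[is.na(kcal) & !is.na(kj)] / KJ_PER_KCAL
  kj[is.na(kj) & !is.na(kcal)] <- kcal[is.na(kj) & !is.na(kcal)] * KJ_PER_KCAL

  fvnl <- num$fvnl_pct
  fvnl_missing <- is.na(fvnl)
  if (any(fvnl_missing)) {
    issues <- dplyr::bind_rows(issues, new_issue(
      raw$food_id[fvnl_missing], "fvnl_pct", "warning",
      "missing fvnl_pct defaulted to 0"
    ))
    fvnl[fvnl_missing] <- 0
  }

  records <- as_food_table(tibble::tibble(
    food_id = as.character(raw$food_id),
    name = as.character(raw$name),
    group = as.character(raw$group),
    state = as.character(raw$state),
    energy_kcal = kcal, energy_kj = kj,
    sugars_g = num$sugars_g, saturated_fat_g = num$saturated_fat_g,
    total_fat_g = num$total_fat_g, sodium_mg = sodium,
    fibre_g = num$fibre_g, protein_g = num$protein_g, fvnl_pct = fvnl,
    added_sugar = as.integer(num$added_sugar),
    added_sat_fat = as.integer(num$added_sat_fat),
    added_sodium = as.integer(num$added_sodium),
    markers = lapply(
      as.character(raw$markers),
      function(m) {
        if (is.na(m) || trimws(m) == "") return(character(0))
        tags <- trimws(strsplit(m, ";", fixed = TRUE)[[1]])
        tags[tags != ""]
      }
    ),
    special_category = as.character(raw$special_category)
  ))

  issues <- dplyr::bind_rows(issues, validate_record(records, vocabulary))
  fatal_ids <- unique(issues$food_id[issues$severity == "fatal"])
  if (strict && length(fatal_ids) > 0) {
    stop_nc(
      "fatal validation issues in ", length(fatal_ids), " record(s): ",
      paste(utils::head(fatal_ids, 5), collapse = ", ")
    )
  }
  list(
    records = records[!records$food_id %in% fatal_ids, ],
    issues = issues
  )
}

#' Write a food table to CSV
#'
#' Inverse of [read_food_table()]: marker lists are re-joined with semicolons.
#' Reading the written file back reproduces all fields.
#'
#' @param records A `food_table` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_food_table <- function(records, path) {
  out <- records
  out$markers <- vapply(out$markers, paste, character(1), collapse = ";")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate food records against the model invariants
#'
#' Checks every invariant required for a record to be classifiable by all
#' three systems: known group/state/special category, non-negative nutrients,
#' `fvnl_pct <= 100`, saturated fat not exceeding total fat, kcal/kJ agreement
#' within 2%, 0/1 flags, unique ids, and marker tags drawn from the closed
#' vocabulary. Issues are returned as data, never raised; a record with no
#' fatal issue is classifiable by all three systems.
#'
#' @param record A `food_table` tibble (one or more rows).
#' @param vocabulary Marker vocabulary (see [marker_vocabulary()]).
#' @return Tibble of issues (`food_id`, `field`, `severity`, `message`);
#'   zero rows when the records are fully valid.
#' @export
#' @examples
#' rec <- food_record("f1", group = "cereals", saturated_fat_g = 5, total_fat_g = 3)
#' validate_record(rec)
validate_record <- function(record, vocabulary = default_marker_vocabulary()) {
  issues <- empty_issues()
  add <- function(idx, field, severity, message) {
    if (any(idx)) {
      issues <<- dplyr::bind_rows(
        issues, new_issue(record$food_id[idx], field, severity, message)
      )
    }
  }

  add(duplicated(record$food_id), "food_id", "fatal", "duplicated food_id")
  add(!record$group %in% FOOD_GROUPS, "group", "fatal",
      paste0("unknown group (expected one of: ",
             paste(FOOD_GROUPS, collapse = ", "), ")"))
  add(!record$state %in% FOOD_STATES, "state", "fatal",
      "unknown state (expected solid or liquid)")
  add(!record$special_category %in% SPECIAL_CATEGORIES, "special_category",
      "fatal", "unknown special_category")

  for (col in c(NUTRIENT_COLUMNS, "energy_kj")) {
    v <- record[[col]]
    add(is.na(v), col, "fatal", "missing value")
    add(!is.na(v) & v < 0, col, "fatal", "negative value")
  }
  add(!is.na(record$fvnl_pct) & record$fvnl_pct > 100, "fvnl_pct", "fatal",
      "fvnl_pct above 100")
  sf <- record$saturated_fat_g
  tf <- record$total_fat_g
  add(!is.na(sf) & !is.na(tf) & sf > tf + 1e-9, "saturated_fat_g", "fatal",
      "saturated fat exceeds total fat")

  kcal <- record$energy_kcal
  kj <- record$energy_kj
  both <- !is.na(kcal) & !is.na(kj) & kcal > 0
  rel <- abs(kj - KJ_PER_KCAL * kcal) / (KJ_PER_KCAL * pmax(kcal, 1e-12))
  add(both & rel > 0.02, "energy_kj", "fatal",
      "energy_kj and energy_kcal disagree by more than 2%")

  for (col in FLAG_COLUMNS) {
    add(!is_flag01(record[[col]]), col, "fatal", "flag must be 0 or 1")
  }

  known <- unlist(vocabulary[c("up_markers", "processing_markers",
                               "culinary_substances")], use.names = FALSE)
  unknown <- vapply(
    record$markers,
    function(m) paste(setdiff(m, known), collapse = ", "),
    character(1)
  )
  add(unknown != "", "markers", "fatal",
      paste0("unknown marker tag(s): ", unknown)[unknown != ""])

  issues
}
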