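# Synthetic basket generator.
#
# Real per-product declarations for the 736-item Chilean basic-basket product
# list are not publicly deposited, so the pipeline is exercised on synthetic
# baskets: each record is an archetype (a plausible label declaration for a
# common product type, stored as data in inst/extdata/archetypes.csv together
# with the classification profile it is constructed to hit at zero noise)
# perturbed by multiplicative lognormal noise per nutrient. Group sizes
# default to the surveyed basket's: 198 cereals, 109 dairy, 139 protein
# foods, 100 oils/fats, 190 sugars/others (n = 736).

DEFAULT_GROUP_SIZES <- c(
  cereals = 198L, dairy = 109L, protein_foods = 139L,
  oils_fats = 100L, sugars_others = 190L
)

NOISED_NUTRIENTS <- c(
  "energy_kcal", "sugars_g", "saturated_fat_g", "total_fat_g",
  "sodium_mg", "fibre_g", "protein_g", "fvnl_pct"
)

#' The shipped archetype library
#'
#' ~29 product templates (plain cereals, breads, sweetened breakfast cereals,
#' dairy, fresh and processed protein foods, culinary fats, confectionery,
#' beverages, ...) spread over the five food groups. Each carries a baseline
#' nutrient panel, marker tags, added-ingredient flags, a special category
#' and its `intended_*` profile: the (Nutri-Score band, NOVA class, warning
#' label count) the baseline panel classifies to at zero noise, frozen from
#' an independent threshold-scan computation. Baselines are plausible label
#' values and synthetic: they do not reproduce any real brand.
#'
#' @return A `food_table`-compatible tibble with one row per archetype plus
#'   the `intended_nutriscore`, `intended_nova`, `intended_fop` columns.
#' @export
archetype_library <- function() {
  path <- system.file("extdata", "archetypes.csv", package = "nutriconcord")
  raw <- readr::read_csv(path, col_types = readr::cols(
    name = "c", group = "c", state = "c", markers = "c",
    special_category = "c", intended_nutriscore = "c",
    intended_nova = "i", intended_fop = "i", .default = "d"
  ), progress = FALSE)
  raw$markers <- lapply(raw$markers, function(m) {
    if (is.na(m) || m == "") character(0) else strsplit(m, ";", fixed = TRUE)[[1]]
  })
  raw$energy_kj <- raw$energy_kcal * KJ_PER_KCAL
  raw
}

#' Basket generation configuration
#'
#' @param n_total Total basket size; must equal `sum(group_sizes)`.
#' @param group_sizes Named integer vector of records per food group;
#'   defaults to the surveyed basket's sizes (198/109/139/100/190).
#' @param weights Named list: for each group, a named numeric vector of
#'   archetype mixture weights summing to 1 over that group's archetypes.
#'   `NULL` selects the calibrated default of [default_basket_config()].
#' @param sigma Lognormal noise scale applied multiplicatively to every
#'   nutrient (0 = archetype baselines verbatim). Default 0.1, i.e. roughly
#'   a 10% coefficient of variation, the order of label-declaration spread
#'   between brands of one product type.
#' @param seed Integer seed; the basket is fully reproducible from it.
#' @return A `basket_config` list.
#' @export
basket_config <- function(n_total = 736L, group_sizes = DEFAULT_GROUP_SIZES,
                          weights = NULL, sigma = 0.1, seed = 1L) {
  if (is.null(names(group_sizes)) ||
      !setequal(names(group_sizes), FOOD_GROUPS)) {
    stop_nc("group_sizes must be named by the five food groups")
  }
  group_sizes <- group_sizes[FOOD_GROUPS]
  if (sum(group_sizes) != n_total) {
    stop_nc("group_sizes must sum to n_total (",
            sum(group_sizes), " != ", n_total, ")")
  }
  if (any(group_sizes < 0)) stop_nc("group sizes must be non-negative")
  if (length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    stop_nc("sigma must be a single non-negative number")
  }
  if (!is.null(weights)) {
    lib <- archetype_library()
    for (g in names(weights)) {
      w <- weights[[g]]
      if (abs(sum(w) - 1) > 1e-8 || any(w < 0)) {
        stop_nc("weights for group '", g, "' must be non-negative and sum to 1")
      }
      if (!all(names(w) %in% lib$name[lib$group == g])) {
        stop_nc("weights for group '", g, "' name unknown archetypes")
      }
    }
  }
  structure(list(
    n_total = as.integer(n_total),
    group_sizes = setNames(as.integer(group_sizes), FOOD_GROUPS),
    weights = weights, sigma = sigma, seed = as.integer(seed)
  ), class = "basket_config")
}

#' Calibrate archetype mixture weights to a target distribution
#'
#' Finds, within one food group, mixture weights over the archetype library
#' minimising the L1 distance between the zero-noise classification
#' distribution and a target distribution for one system. Because every
#' archetype hits exactly one category at zero noise, the optimum is closed
#' form: each category's target mass is split evenly among the archetypes
#' that reach it, and mass on unreachable categories is either an error
#' (`strict = TRUE`, the default) or renormalised over the reachable ones
#' (`strict = FALSE`), with the residual L1 distance reported.
#'
#' @param target Named numeric vector over the system's categories
#'   (percentages or proportions; normalised internally).
#' @param group Food group to calibrate.
#' @param system `"nutriscore"`, `"nova"` or `"fop"`.
#' @param library Archetype library (defaults to the shipped one).
#' @param strict Error on unreachable target categories?
#' @return List: `weights` (named by archetype, summing to 1), `achieved`
#'   (the zero-noise distribution), `distance` (L1).
#' @export
#' @examples
#' calibrate_mixture(c(`1` = 19, `2` = 12, `3` = 15, `4` = 54),
#'   group = "cereals", system = "nova", strict = FALSE
#' )
calibrate_mixture <- function(target, group, system = "nova",
                              library = archetype_library(), strict = TRUE) {
  system <- match.arg(system, c("nutriscore", "nova", "fop"))
  lv <- system_levels(system)
  if (is.null(names(target)) || !all(names(target) %in% lv)) {
    stop_nc("target must be named by ", system, " categories")
  }
  if (any(target < 0) || sum(target) <= 0) stop_nc("invalid target distribution")
  t <- setNames(numeric(length(lv)), lv)
  t[names(target)] <- target
  t <- t / sum(t)

  lib <- library[library$group == group, ]
  if (nrow(lib) == 0) stop_nc("no archetypes for group '", group, "'")
  cat_of <- as.character(lib[[paste0("intended_", system)]])

  unreachable <- names(t)[t > 0 & !names(t) %in% cat_of]
  if (length(unreachable) > 0) {
    if (strict) {
      stop_nc("target categories unreachable by any '", group,
              "' archetype: ", paste(unreachable, collapse = ", "))
    }
    t[unreachable] <- 0
    t <- t / sum(t)
  }

  w <- setNames(numeric(nrow(lib)), lib$name)
  for (cat in names(t)[t > 0]) {
    hit <- cat_of == cat
    w[hit] <- t[cat] / sum(hit)
  }
  achieved <- vapply(lv, function(cat) sum(w[cat_of == cat]), numeric(1))
  list(
    weights = w,
    achieved = achieved,
    distance = sum(abs(achieved - {
      t0 <- setNames(numeric(length(lv)), lv)
      t0[names(target)] <- target / sum(target)
      t0
    }))
  )
}

#' Default study-conditions basket configuration
#'
#' Group sizes of the surveyed 736-item basket, mixture weights calibrated
#' per group so the zero-noise NOVA distribution matches the reported
#' per-group NOVA distributions (see [reference_distributions()]), and noise
#' `sigma = 0.1`. The protein-foods group's 2% NOVA-2 target has no
#' culinary-substance archetype and is renormalised away (`strict = FALSE`).
#'
#' @param seed Integer seed.
#' @param sigma Noise scale (default 0.1).
#' @return A `basket_config`.
#' @export
default_basket_config <- function(seed = 1L, sigma = 0.1) {
  ref <- reference_distributions()
  lib <- archetype_library()
  weights <- lapply(setNames(FOOD_GROUPS, FOOD_GROUPS), function(g) {
    tgt <- ref[ref$system == "nova" & ref$group == g, ]
    calibrate_mixture(setNames(tgt$pct, tgt$category),
      group = g, system = "nova", library = lib, strict = FALSE
    )$weights
  })
  basket_config(weights = weights, sigma = sigma, seed = seed)
}

# Deterministic largest-remainder apportionment of n among weights.
apportion <- function(weights, n) {
  quota <- weights * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    # ties broken by archetype order (stable)
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic food basket
#'
#' For each group, archetype counts are apportioned deterministically from
#' the mixture weights (largest-remainder method, so a zero-noise calibrated
#' basket reproduces its target distribution exactly whenever the target is
#' attainable in whole records); the records are then shuffled within the
#' group and every nutrient is multiplied by independent lognormal noise
#' `exp(rnorm(0, sigma))`. Saturated fat is truncated at total fat and the
#' FVNL fraction at 100 after noising; kJ energy is rederived from kcal.
#' Randomness comes from a single seeded stream consumed in a fixed order
#' (per-group shuffles in group order, then one noise draw per record x
#' nutrient), so baskets are bit-reproducible from the seed.
#'
#' @param config A [basket_config()].
#' @return A `food_table` tibble of `config$n_total` records (plus an
#'   `archetype` column), every one passing [validate_record()] with no
#'   fatal issues.
#' @export
#' @examples
#' basket <- generate_basket(basket_config(
#'   n_total = 10,
#'   group_sizes = c(cereals = 4, dairy = 2, protein_foods = 2,
#'                   oils_fats = 1, sugars_others = 1),
#'   sigma = 0, seed = 42
#' ))
#' table(basket$group)
generate_basket <- function(config) {
  if (!inherits(config, "basket_config")) {
    stop_nc("config must be a basket_config")
  }
  lib <- archetype_library()
  weights <- config$weights
  if (is.null(weights)) {
    weights <- default_basket_config(seed = config$seed,
                                     sigma = config$sigma)$weights
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  pieces <- list()
  for (g in FOOD_GROUPS) {
    n_g <- config$group_sizes[[g]]
    if (n_g == 0) next
    w <- weights[[g]]
    if (is.null(w)) stop_nc("no mixture weights for group '", g, "'")
    counts <- apportion(w / sum(w), n_g)
    idx <- rep(match(names(w), lib$name), counts)
    idx <- idx[sample.int(length(idx))]
    pieces[[g]] <- lib[idx, ]
  }
  basket <- dplyr::bind_rows(pieces)

  n <- nrow(basket)
  if (config$sigma > 0) {
    noise <- matrix(
      exp(rnorm(n * length(NOISED_NUTRIENTS), mean = 0, sd = config$sigma)),
      nrow = n
    )
    for (j in seq_along(NOISED_NUTRIENTS)) {
      col <- NOISED_NUTRIENTS[j]
      basket[[col]] <- basket[[col]] * noise[, j]
    }
    basket$saturated_fat_g <- pmin(basket$saturated_fat_g, basket$total_fat_g)
    basket$fvnl_pct <- pmin(basket$fvnl_pct, 100)
    basket$energy_kj <- basket$energy_kcal * KJ_PER_KCAL
  }

  out <- tibble::tibble(
    food_id = sprintf("syn_%04d", seq_len(n)),
    name = basket$name, group = basket$group, state = basket$state,
    energy_kcal = basket$energy_kcal, energy_kj = basket$energy_kj,
    sugars_g = basket$sugars_g, saturated_fat_g = basket$saturated_fat_g,
    total_fat_g = basket$total_fat_g, sodium_mg = basket$sodium_mg,
    fibre_g = basket$fibre_g, protein_g = basket$protein_g,
    fvnl_pct = basket$fvnl_pct,
    added_sugar = as.integer(basket$added_sugar),
    added_sat_fat = as.integer(basket$added_sat_fat),
    added_sodium = as.integer(basket$added_sodium),
    markers = basket$markers,
    special_category = basket$special_category,
    archetype = basket$name
  )
  as_food_table(out)
}

#' Reference category distributions of the surveyed basket
#'
#' The per-system, per-group category percentages reported for the 736-item
#' Chilean basic-basket product survey (overall and for each of the five
#' groups), shipped as plain text. Used to calibrate the default synthetic
#' basket and by the acceptance checks.
#'
#' @return Tibble with columns `system`, `group`, `category`, `pct`.
#' @export
reference_distributions <- function() {
  readr::read_csv(
    system.file("extdata", "reference_distributions.csv",
                package = "nutriconcord"),
    col_types = "cccd", progress = FALSE
  )
}

#' Reference cross-tabulations of the surveyed basket
#'
#' The three pairwise cross-classification count matrices reported for the
#' 736-item basket: Nutri-Score x NOVA, Nutri-Score x FoP and NOVA x FoP.
#'
#' @return Named list of integer count matrices (`nutriscore_nova`,
#'   `nutriscore_fop`, `nova_fop`) with category dimnames.
#' @export
reference_crosstabs <- function() {
  read_one <- function(file, row_system, col_system) {
    d <- readr::read_csv(
      system.file("extdata", file, package = "nutriconcord"),
      col_types = readr::cols(row_category = "c", .default = "i"),
      progress = FALSE
    )
    m <- as.matrix(d[, -1])
    dimnames(m) <- list(system_levels(row_system), system_levels(col_system))
    m
  }
  list(
    nutriscore_nova = read_one("reference_crosstab_nutriscore_nova.csv",
                               "nutriscore", "nova"),
    nutriscore_fop = read_one("reference_crosstab_nutriscore_fop.csv",
                              "nutriscore", "fop"),
    nova_fop = read_one("reference_crosstab_nova_fop.csv", "nova", "fop")
  )
}
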