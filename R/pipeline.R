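# One-call orchestration: classify a basket with all three systems and emit
# every concordance output, with a run manifest for reproducibility.

#' Classify every record with the three systems
#'
#' One row per food with the Nutri-Score breakdown (score and band), the NOVA
#' class with its fired rule and evidence, and the warning-label count with
#' the individual labels — the per-food rationale log.
#'
#' @param records A `food_table` tibble.
#' @param fop_gate `"off"` or `"on"` (see [count_warnings()]).
#' @param nutriscore_variant `"auto"` or `"general"` (see
#'   [nutriscore_classify()]).
#' @param vocabulary Marker vocabulary for the NOVA ladder.
#' @return Tibble with identity columns, `nutriscore_score`, `nutriscore`
#'   (A-E), the N/P point totals, `nova`, `nova_rule`, `nova_evidence`,
#'   `fop` (label count as category "0".."4"), and one logical column per
#'   warning label.
#' @export
classify_basket <- function(records, fop_gate = "off",
                            nutriscore_variant = "auto",
                            vocabulary = default_marker_vocabulary()) {
  ns <- nutriscore_classify(records, variant = nutriscore_variant)
  nv <- nova_classify(records, vocab = vocabulary)
  fp <- fop_classify(records, gate = fop_gate)
  tibble::tibble(
    food_id = records$food_id,
    name = records$name,
    group = records$group,
    state = records$state,
    nutriscore_score = ns$final_score,
    nutriscore = ns$category,
    n_total = ns$n_total,
    p_total = ns$p_total,
    protein_counted = ns$protein_counted,
    nova = as.character(nv$nova),
    nova_rule = nv$fired_rule,
    nova_evidence = nv$evidence,
    fop = as.character(fp$n_labels),
    high_calories = fp$high_calories,
    high_sodium = fp$high_sodium,
    high_sugars = fp$high_sugars,
    high_sat_fat = fp$high_sat_fat
  )
}

strata_of <- function(classified) {
  c("all", intersect(FOOD_GROUPS, unique(classified$group)))
}

stratum_rows <- function(classified, stratum) {
  if (stratum == "all") classified else classified[classified$group == stratum, ]
}

all_distributions <- function(classified, digits = 0) {
  out <- list()
  for (system in c("nutriscore", "nova", "fop")) {
    for (stratum in strata_of(classified)) {
      rows <- stratum_rows(classified, stratum)
      out[[paste(system, stratum)]] <-
        tabulate_distribution(rows[[system]], system, group = stratum,
                              digits = digits)
    }
  }
  dplyr::bind_rows(out)
}

crosstab_pairs <- list(
  c("nutriscore", "nova"),
  c("nutriscore", "fop"),
  c("nova", "fop")
)

crosstab_csv <- function(ct, what = c("counts", "row_pct")) {
  what <- match.arg(what)
  m <- if (what == "counts") ct$counts else ct$row_pct
  df <- tibble::as_tibble(as.data.frame.matrix(m), rownames = "row_category")
  names(df)[-1] <- paste(ct$col_system, colnames(m), sep = "_")
  df
}

ordination_json <- function(ord) {
  list(
    stratum = ord$stratum,
    eigenvalues = unname(ord$eigenvalues),
    explained_variance = unname(ord$explained_variance),
    rotation = apply(ord$rotation, 1, identity, simplify = FALSE),
    loadings = apply(ord$loadings, 1, identity, simplify = FALSE),
    angles_deg = list(
      nutriscore_nova = ord$angles["nutriscore", "nova"],
      nutriscore_fop = ord$angles["nutriscore", "fop"],
      nova_fop = ord$angles["nova", "fop"]
    )
  )
}

#' Run the full concordance analysis
#'
#' Reads (or generates) a basket, classifies it with the three systems and
#' writes to `out_dir`: the classified table (`classified.csv`), stacked
#' distribution tables for every system and stratum (`distributions.csv`),
#' the three pairwise cross-tabulations (`crosstab_*_counts.csv` and
#' `crosstab_*_rowpct.csv`, unrounded), the recommendation-agreement report
#' (`agreement.json`), PCA ordinations per stratum (`ordination.json`), any
#' validation issues (`issues.csv`) and a run manifest (`manifest.json`).
#' With `round = "paper"`, additional `display_*` files carry the
#' conventional rounding (integer percentages for distributions, one decimal
#' for cross-tab row percentages); the main outputs stay unrounded so
#' rounding never contaminates downstream computation. Re-running with
#' identical inputs reproduces byte-identical outputs.
#'
#' @param input A CSV path, a `food_table` tibble, or a [basket_config()]
#'   (a synthetic basket is then generated).
#' @param out_dir Output directory (created if needed).
#' @inheritParams classify_basket
#' @param round `"none"` or `"paper"`.
#' @param strict Passed to [read_food_table()] when `input` is a path.
#' @return The run manifest, invisibly: input/config/vocabulary hashes, seed,
#'   per-stage record counts and the output file list.
#' @export
run_full_analysis <- function(input, out_dir, fop_gate = "off",
                              nutriscore_variant = "auto",
                              round = c("none", "paper"),
                              vocabulary = default_marker_vocabulary(),
                              strict = FALSE) {
  round <- match.arg(round)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  issues <- empty_issues()
  seed <- NULL
  n_input <- NA_integer_
  if (inherits(input, "basket_config")) {
    records <- generate_basket(input)
    seed <- input$seed
    n_input <- nrow(records)
  } else if (is.character(input)) {
    parsed <- read_food_table(input, strict = strict)
    records <- parsed$records
    issues <- parsed$issues
    n_input <- nrow(records) +
      length(unique(issues$food_id[issues$severity == "fatal"]))
  } else {
    records <- input
    n_input <- nrow(records)
  }
  if (nrow(records) == 0) stop_nc("no classifiable records in input")

  classified <- classify_basket(records,
    fop_gate = fop_gate, nutriscore_variant = nutriscore_variant,
    vocabulary = vocabulary
  )

  files <- character(0)
  emit_csv <- function(df, file) {
    path <- file.path(out_dir, file)
    readr::write_csv(df, path, progress = FALSE)
    files <<- c(files, file)
  }
  emit_json <- function(x, file) {
    path <- file.path(out_dir, file)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, file)
  }

  emit_csv(classified, "classified.csv")
  if (nrow(issues) > 0) emit_csv(issues, "issues.csv")

  dist <- all_distributions(classified)
  emit_csv(dist[, c("system", "group", "category", "count", "pct")],
           "distributions.csv")
  if (round == "paper") {
    disp <- dist
    disp$pct <- disp$pct_display
    emit_csv(disp[, c("system", "group", "category", "count", "pct")],
             "display_distributions.csv")
  }

  crosstabs <- list()
  for (pair in crosstab_pairs) {
    ct <- cross_tabulate(
      setNames(classified[[pair[1]]], classified$food_id),
      setNames(classified[[pair[2]]], classified$food_id),
      pair[1], pair[2]
    )
    key <- paste(pair, collapse = "_")
    crosstabs[[key]] <- ct
    emit_csv(crosstab_csv(ct, "counts"),
             sprintf("crosstab_%s_counts.csv", key))
    emit_csv(crosstab_csv(ct, "row_pct"),
             sprintf("crosstab_%s_rowpct.csv", key))
    if (round == "paper") {
      disp <- crosstab_csv(ct, "row_pct")
      disp[-1] <- lapply(disp[-1], round_half_up, digits = 1)
      emit_csv(disp, sprintf("display_crosstab_%s_rowpct.csv", key))
    }
  }

  agreement <- lapply(crosstabs, function(ct) {
    recommendation_agreement(
      rep(rownames(ct$counts), times = ct$row_totals),
      unlist(lapply(seq_len(nrow(ct$counts)), function(i) {
        rep(colnames(ct$counts), times = ct$counts[i, ])
      })),
      default_recommendation_map(ct$row_system),
      default_recommendation_map(ct$col_system)
    )
  })
  emit_json(agreement, "agreement.json")

  ordinations <- list()
  for (stratum in strata_of(classified)) {
    rows <- stratum_rows(classified, stratum)
    ordinations[[stratum]] <- tryCatch(
      ordination_json(run_pca(ordinal_encode(rows, stratum))),
      error = function(e) list(stratum = stratum,
                               error = conditionMessage(e))
    )
  }
  emit_json(ordinations, "ordination.json")

  manifest <- list(
    input_hash = rlang::hash(records),
    config = list(
      fop_gate = fop_gate, nutriscore_variant = nutriscore_variant,
      round = round
    ),
    config_hash = rlang::hash(list(fop_gate, nutriscore_variant, round)),
    vocabulary_version = vocabulary$version,
    seed = seed,
    counts = list(
      n_input = n_input,
      n_excluded = n_input - nrow(records),
      n_classified = nrow(classified)
    ),
    files = c(files, "manifest.json")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(structure(manifest, class = "run_manifest"))
}
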