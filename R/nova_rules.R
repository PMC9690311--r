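# NOVA processing classification as an auditable rule ladder.
#
# The published NOVA definitions are qualitative (expert judgement on the
# degree of processing). Here the judgement is replaced by a deterministic
# ladder over a closed vocabulary of ingredient-marker tags, so every verdict
# is reproducible and carries the rule and evidence that produced it:
#   1. any ultra-processing marker            -> NOVA 4
#   2. markers are all culinary substances    -> NOVA 2 (>= 1 tag present)
#   3. any processing marker                  -> NOVA 3
#   4. otherwise                              -> NOVA 1
# The shipped vocabulary is configuration (YAML), not code, and is versioned
# by hash in every result.

#' Construct a marker vocabulary
#'
#' Three pairwise-disjoint tag sets: `up_markers` (ultra-processing markers:
#' cosmetic additives and industrial refined ingredients), `processing_markers`
#' (ordinary preservation/processing operations) and `culinary_substances`
#' (substances that are themselves processed culinary ingredients). The
#' vocabulary is closed: a record carrying any tag outside it is an error.
#'
#' @param up_markers,processing_markers,culinary_substances Character vectors.
#' @return A `marker_vocabulary` list with a `version` hash.
#' @export
marker_vocabulary <- function(up_markers, processing_markers,
                              culinary_substances) {
  sets <- list(
    up_markers = sort(unique(as.character(up_markers))),
    processing_markers = sort(unique(as.character(processing_markers))),
    culinary_substances = sort(unique(as.character(culinary_substances)))
  )
  overlap <- c(
    intersect(sets$up_markers, sets$processing_markers),
    intersect(sets$up_markers, sets$culinary_substances),
    intersect(sets$processing_markers, sets$culinary_substances)
  )
  if (length(overlap) > 0) {
    stop_nc("marker sets must be pairwise disjoint; shared tag(s): ",
            paste(unique(overlap), collapse = ", "))
  }
  sets$version <- rlang::hash(sets)
  structure(sets, class = "marker_vocabulary")
}

#' Read a marker vocabulary from YAML or JSON
#'
#' The file must contain the keys `up_markers`, `processing_markers` and
#' `culinary_substances`, each a list of tags.
#'
#' @param path File path.
#' @return A `marker_vocabulary`.
#' @export
read_marker_vocabulary <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  needed <- c("up_markers", "processing_markers", "culinary_substances")
  if (!all(needed %in% names(spec))) {
    stop_nc("vocabulary file must define: ", paste(needed, collapse = ", "))
  }
  marker_vocabulary(spec$up_markers, spec$processing_markers,
                    spec$culinary_substances)
}

#' The vocabulary shipped with the package
#'
#' An editorial default covering the markers named in the NOVA literature
#' (colourings, flavourings, emulsifiers, thickeners, non-caloric sweeteners,
#' hydrogenated oils, protein isolates, maltodextrin, HFCS as ultra-processing
#' markers; salting, sugaring, oiling, canning, fermenting and smoking as
#' processing markers; oils, butter, lard, table sugar, salt, starch and
#' honey as culinary substances). Stored at
#' `system.file("extdata", "nova_vocabulary.yml", package = "nutriconcord")`;
#' users aligning with a different NOVA guidance revision can supply their
#' own file via [read_marker_vocabulary()].
#'
#' @return A `marker_vocabulary`.
#' @export
default_marker_vocabulary <- function() {
  if (is.null(.vocab_cache$default)) {
    .vocab_cache$default <- read_marker_vocabulary(
      system.file("extdata", "nova_vocabulary.yml", package = "nutriconcord")
    )
  }
  .vocab_cache$default
}

.vocab_cache <- new.env(parent = emptyenv())

classify_nova_markers <- function(markers, vocab) {
  unknown <- setdiff(markers, c(vocab$up_markers, vocab$processing_markers,
                                vocab$culinary_substances))
  if (length(unknown) > 0) {
    stop_nc("unknown marker tag(s): ", paste(unknown, collapse = ", "))
  }
  up <- intersect(markers, vocab$up_markers)
  if (length(up) > 0) {
    return(list(nova = 4L, fired_rule = "ultra_processing_marker",
                evidence = up))
  }
  if (length(markers) > 0 && all(markers %in% vocab$culinary_substances)) {
    return(list(nova = 2L, fired_rule = "culinary_substance",
                evidence = markers))
  }
  proc <- intersect(markers, vocab$processing_markers)
  if (length(proc) > 0) {
    return(list(nova = 3L, fired_rule = "processing_marker", evidence = proc))
  }
  list(nova = 1L, fired_rule = "no_processing_markers", evidence = character(0))
}

#' NOVA class of a single food record
#'
#' Evaluates the marker ladder in fixed order. Rule 1 (ultra-processing
#' markers) takes precedence, so a culinary substance blended with, say, a
#' non-caloric sweetener is NOVA 4, not 2.
#'
#' @param record A one-row `food_table` tibble.
#' @param vocab A [marker_vocabulary()].
#' @return A `nova_result` list: `nova` (1-4), `fired_rule`, `evidence`
#'   (the markers that triggered the rule) and `vocab_version`.
#' @export
#' @examples
#' classify_nova(food_record("oil", group = "oils_fats", markers = "vegetable_oil"))
classify_nova <- function(record, vocab = default_marker_vocabulary()) {
  stopifnot(nrow(record) == 1)
  res <- classify_nova_markers(record$markers[[1]], vocab)
  res$vocab_version <- vocab$version
  structure(res, class = "nova_result")
}

#' @export
print.nova_result <- function(x, ...) {
  cat(sprintf(
    "NOVA %d (rule: %s%s)\n", x$nova, x$fired_rule,
    if (length(x$evidence) > 0) {
      paste0("; evidence: ", paste(x$evidence, collapse = ", "))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' NOVA classification of a whole food table
#'
#' @inheritParams classify_nova
#' @param records A `food_table` tibble.
#' @return Tibble with `food_id`, `nova`, `fired_rule`, `evidence`
#'   (semicolon-joined) and `vocab_version`.
#' @export
nova_classify <- function(records, vocab = default_marker_vocabulary()) {
  res <- lapply(records$markers, classify_nova_markers, vocab = vocab)
  tibble::tibble(
    food_id = records$food_id,
    nova = vapply(res, `[[`, integer(1), "nova"),
    fired_rule = vapply(res, `[[`, character(1), "fired_rule"),
    evidence = vapply(res, function(r) paste(r$evidence, collapse = ";"),
                      character(1)),
    vocab_version = vocab$version
  )
}
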