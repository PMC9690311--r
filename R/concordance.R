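# Concordance layer: frequency distributions, pairwise cross-tabulations with
# row percentages, recommended/not-recommended agreement, and PCA ordination
# of the three systems' ordinally encoded verdicts.

as_system_factor <- function(labels, system) {
  lv <- system_levels(system)
  f <- factor(as.character(labels), levels = lv)
  if (anyNA(f) && !anyNA(labels)) {
    bad <- unique(setdiff(as.character(labels), lv))
    stop_nc("labels outside the ", system, " category set: ",
            paste(bad, collapse = ", "))
  }
  f
}

#' Frequency distribution of one system's categories
#'
#' Counts and percentages of each category over a stratum (a food group or
#' the whole list). Percentages are `100 * count / n`, rounded half-up to
#' `digits` decimals (integers by default, matching headline figures).
#'
#' @param labels Category labels for the foods in the stratum.
#' @param system `"nutriscore"`, `"nova"` or `"fop"`.
#' @param group Stratum name (a food group or `"all"`); metadata only.
#' @param digits Decimal places for the rounded percentage.
#' @return A `distribution_table` tibble: `system`, `group`, `category`,
#'   `count`, `pct` (unrounded) and `pct_display` (half-up rounded).
#' @export
#' @examples
#' tabulate_distribution(c("A", "A", "B", "E"), "nutriscore")
tabulate_distribution <- function(labels, system, group = "all", digits = 0) {
  if (length(labels) == 0) stop_nc("empty stratum: ", group)
  counts <- table(as_system_factor(labels, system))
  distribution_from_counts(as.integer(counts), system,
    group = group, digits = digits
  )
}

#' Distribution table from pre-tabulated counts
#'
#' Same output as [tabulate_distribution()] but starting from category counts
#' (e.g. counts printed in a report), in the order of [system_levels()].
#'
#' @param counts Integer vector, one count per category of the system.
#' @inheritParams tabulate_distribution
#' @export
distribution_from_counts <- function(counts, system, group = "all",
                                     digits = 0) {
  lv <- system_levels(system)
  counts <- unname(counts)
  stopifnot(length(counts) == length(lv), all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop_nc("empty stratum: ", group)
  pct <- 100 * counts / n
  out <- tibble::tibble(
    system = system, group = group, category = lv,
    count = as.integer(counts), pct = pct,
    pct_display = round_half_up(pct, digits)
  )
  class(out) <- c("distribution_table", class(out))
  out
}

#' Cross-tabulate two systems' labels
#'
#' Counts of foods by (row category, column category), with row percentages
#' (each cell over its row marginal, half-up to one decimal), marginals and
#' grand total. Label vectors must describe the same foods: if both are named
#' by `food_id` they are aligned by name; otherwise they are taken as
#' positionally aligned and must have equal length.
#'
#' @param row_labels,col_labels Category label vectors (optionally named by
#'   food id).
#' @param row_system,col_system The system of each vector.
#' @return A `crosstab` list: `counts`, `row_pct` (unrounded),
#'   `row_pct_display`, `row_totals`, `col_totals`, `total`.
#' @export
cross_tabulate <- function(row_labels, col_labels, row_system, col_system) {
  rn <- names(row_labels)
  cn <- names(col_labels)
  if (!is.null(rn) && !is.null(cn)) {
    if (!setequal(rn, cn) || anyDuplicated(rn) || anyDuplicated(cn)) {
      stop_nc("row and column labels must cover the same food_id set")
    }
    col_labels <- col_labels[rn]
  } else if (length(row_labels) != length(col_labels)) {
    stop_nc("label vectors must be aligned and of equal length")
  }
  counts <- table(
    as_system_factor(row_labels, row_system),
    as_system_factor(col_labels, col_system)
  )
  crosstab_from_counts(unclass(counts), row_system, col_system)
}

#' Cross-tabulation from a pre-tabulated count matrix
#'
#' @param counts Matrix of cell counts (rows = `row_system` categories in
#'   [system_levels()] order, columns = `col_system` categories).
#' @inheritParams cross_tabulate
#' @export
crosstab_from_counts <- function(counts, row_system, col_system) {
  counts <- as.matrix(counts)
  dimnames(counts) <- list(system_levels(row_system),
                           system_levels(col_system))
  storage.mode(counts) <- "integer"
  row_totals <- rowSums(counts)
  pct <- 100 * sweep(counts, 1, pmax(row_totals, 1), "/")
  structure(list(
    row_system = row_system, col_system = col_system,
    counts = counts,
    row_pct = pct,
    row_pct_display = round_half_up(pct, 1),
    row_totals = row_totals,
    col_totals = colSums(counts),
    total = sum(counts)
  ), class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat(sprintf("Cross-tabulation: %s (rows) x %s (columns), n = %d\n\n",
              x$row_system, x$col_system, x$total))
  disp <- matrix(
    sprintf("%d (%.1f%%)", x$counts, x$row_pct_display),
    nrow = nrow(x$counts), dimnames = dimnames(x$counts)
  )
  print(cbind(disp, total = as.character(x$row_totals)), quote = FALSE)
  invisible(x)
}

#' Default recommendation mapping for a system
#'
#' Nutri-Score: A/B recommended, C neutral, D/E not recommended. NOVA: 1-3
#' recommended, 4 not. FoP: 0 labels recommended, 1-4 not.
#'
#' @param system `"nutriscore"`, `"nova"` or `"fop"`.
#' @return Named character vector mapping each category to `"recommended"`,
#'   `"neutral"` or `"not_recommended"`.
#' @export
default_recommendation_map <- function(system) {
  switch(match.arg(system, c("nutriscore", "nova", "fop")),
    nutriscore = c(A = "recommended", B = "recommended", C = "neutral",
                   D = "not_recommended", E = "not_recommended"),
    nova = c(`1` = "recommended", `2` = "recommended", `3` = "recommended",
             `4` = "not_recommended"),
    fop = c(`0` = "recommended", `1` = "not_recommended",
            `2` = "not_recommended", `3` = "not_recommended",
            `4` = "not_recommended")
  )
}

#' Unweighted Cohen's kappa between two label vectors
#'
#' Chance-corrected agreement on the shared level set. Defined as 1 when
#' observed agreement is perfect even if expected agreement is 1 (a single
#' shared category).
#'
#' @param a,b Vectors of equal length.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  lv <- union(unique(as.character(a)), unique(as.character(b)))
  a <- factor(as.character(a), levels = lv)
  b <- factor(as.character(b), levels = lv)
  po <- mean(a == b)
  pe <- sum((table(a) / length(a)) * (table(b) / length(b)))
  if (abs(1 - pe) < 1e-12) {
    return(if (po >= 1 - 1e-12) 1 else NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Agreement between two systems' consumption recommendations
#'
#' Maps each system's categories to recommended / neutral / not_recommended
#' and summarises the congruence of the two verdicts: the directional share
#' of foods recommended under A that are also recommended under B (and vice
#' versa), the overall percent agreement restricted to foods non-neutral
#' under both systems, and unweighted Cohen's kappa on the same restriction.
#'
#' @param labelsA,labelsB Aligned category label vectors.
#' @param mappingA,mappingB Named character vectors mapping every category to
#'   `"recommended"`, `"neutral"` or `"not_recommended"` (see
#'   [default_recommendation_map()]).
#' @return List: `n`, `n_non_neutral`, `recommended_a_to_b_pct`,
#'   `recommended_b_to_a_pct`, `percent_agreement`, `kappa`.
#' @export
recommendation_agreement <- function(labelsA, labelsB, mappingA, mappingB) {
  stopifnot(length(labelsA) == length(labelsB))
  map_one <- function(labels, mapping, which) {
    labels <- as.character(labels)
    missing_cat <- setdiff(unique(labels), names(mapping))
    if (length(missing_cat) > 0) {
      stop_nc("category absent from mapping ", which, ": ",
              paste(missing_cat, collapse = ", "))
    }
    ok <- mapping %in% c("recommended", "neutral", "not_recommended")
    if (!all(ok)) stop_nc("mapping ", which, " has invalid verdict(s)")
    unname(mapping[labels])
  }
  ra <- map_one(labelsA, mappingA, "A")
  rb <- map_one(labelsB, mappingB, "B")

  dir_pct <- function(from, to) {
    n_from <- sum(from == "recommended")
    if (n_from == 0) return(NA_real_)
    100 * sum(from == "recommended" & to == "recommended") / n_from
  }
  keep <- ra != "neutral" & rb != "neutral"
  list(
    n = length(ra),
    n_non_neutral = sum(keep),
    recommended_a_to_b_pct = dir_pct(ra, rb),
    recommended_b_to_a_pct = dir_pct(rb, ra),
    percent_agreement = if (any(keep)) 100 * mean(ra[keep] == rb[keep]) else NA_real_,
    kappa = if (any(keep)) cohen_kappa(ra[keep], rb[keep]) else NA_real_
  )
}

#' Ordinal encoding of the three systems' verdicts
#'
#' Nutri-Score A..E map to 1..5, NOVA 1..4 to 1..4 and FoP 0..4 labels to
#' 1..5, so that a higher code is always less favourable. Columns are also
#' returned standardised (zero mean, unit variance) ready for the
#' correlation-matrix PCA; a zero-variance column in the stratum is an error
#' because its correlation with the others is undefined.
#'
#' @param labels_df Data frame with columns `nutriscore`, `nova`, `fop`
#'   holding each food's category under the three systems.
#' @param stratum Stratum name used in error messages and carried to
#'   [run_pca()].
#' @return List: `codes` (n x 3 integer matrix), `standardized`, `stratum`.
#' @export
ordinal_encode <- function(labels_df, stratum = "all") {
  needed <- c("nutriscore", "nova", "fop")
  stopifnot(all(needed %in% names(labels_df)))
  codes <- cbind(
    nutriscore = as.integer(as_system_factor(labels_df$nutriscore, "nutriscore")),
    nova = as.integer(as_system_factor(labels_df$nova, "nova")),
    fop = as.integer(as_system_factor(labels_df$fop, "fop"))
  )
  sds <- apply(codes, 2, stats::sd)
  if (any(sds == 0)) {
    stop_nc("zero-variance column(s) in stratum '", stratum, "': ",
            paste(colnames(codes)[sds == 0], collapse = ", "))
  }
  list(codes = codes, standardized = scale(codes), stratum = stratum)
}

#' PCA ordination of the encoded verdicts
#'
#' Eigen-decomposition of the 3 x 3 correlation matrix of the ordinal codes.
#' The first two components are returned; each component's sign is fixed so
#' its largest-magnitude loading is positive, making the output unique and
#' order-invariant. `loadings` are the correlation-circle coordinates
#' (eigenvectors scaled by the square root of their eigenvalues), i.e. the
#' arrows of a biplot; `angles` are the pairwise angles in degrees between
#' the three systems' arrows in the plane of the first two components — the
#' quantitative analogue of "closeness and remoteness" between the systems'
#' classification dimensions.
#'
#' @param encoded Output of [ordinal_encode()], or a numeric matrix of codes
#'   with three columns.
#' @param stratum Stratum name (defaults to the one carried by `encoded`).
#' @return An `ordination` list: `stratum`, `explained_variance` (fractions,
#'   non-increasing, summing to 1 over all three components of which two are
#'   reported), `rotation` (eigenvectors), `loadings`, `scores`, `angles`
#'   (3 x 3 symmetric matrix, degrees) and `eigenvalues`.
#' @export
run_pca <- function(encoded, stratum = NULL) {
  if (is.list(encoded) && !is.data.frame(encoded)) {
    stratum <- stratum %||% encoded$stratum
    codes <- encoded$codes
  } else {
    codes <- as.matrix(encoded)
  }
  stratum <- stratum %||% "all"
  if (ncol(codes) != 3) stop_nc("encoded matrix must have 3 columns")
  if (nrow(codes) < 3) stop_nc("need at least 3 foods for a 3-column PCA")
  if (any(apply(codes, 2, stats::sd) == 0)) {
    stop_nc("zero-variance column(s) in stratum '", stratum, "'")
  }

  R <- stats::cor(codes)
  ev <- eigen(R, symmetric = TRUE)
  values <- pmax(ev$values, 0)
  vectors <- ev$vectors[, 1:2, drop = FALSE]
  # sign convention: largest-magnitude loading of each component positive
  for (j in 1:2) {
    k <- which.max(abs(vectors[, j]))
    if (vectors[k, j] < 0) vectors[, j] <- -vectors[, j]
  }
  rownames(vectors) <- colnames(codes)
  colnames(vectors) <- c("PC1", "PC2")
  loadings <- sweep(vectors, 2, sqrt(values[1:2]), "*")
  scores <- scale(codes) %*% vectors

  norms <- sqrt(rowSums(loadings^2))
  cosang <- (loadings %*% t(loadings)) / pmax(outer(norms, norms), 1e-300)
  angles <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  angles[norms == 0, ] <- NA_real_
  angles[, norms == 0] <- NA_real_
  diag(angles) <- 0

  structure(list(
    stratum = stratum,
    eigenvalues = values,
    explained_variance = values[1:2] / sum(values),
    rotation = vectors,
    loadings = loadings,
    scores = scores,
    angles = angles
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf(
    "PCA ordination, stratum '%s': PC1 %.1f%%, PC2 %.1f%% of variance\n",
    x$stratum, 100 * x$explained_variance[1], 100 * x$explained_variance[2]
  ))
  cat("Loading angles (degrees):\n")
  print(round(x$angles, 1))
  invisible(x)
}
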