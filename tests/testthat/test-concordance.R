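test_that("distribution tables count, percentage and round as specified", {
  d <- tabulate_distribution(c("A", "A", "A", "A"), "nutriscore")
  expect_equal(d$pct_display[d$category == "A"], 100)
  expect_equal(sum(d$count), 4)

  # headline distribution from the surveyed basket's printed counts
  ns <- distribution_from_counts(c(197, 118, 129, 165, 127), "nutriscore")
  expect_equal(ns$pct_display, c(27, 16, 18, 22, 17))
  nova <- distribution_from_counts(c(143, 89, 109, 395), "nova")
  expect_equal(nova$pct_display[nova$category == "4"], 54)
  fop <- distribution_from_counts(c(421, 73, 67, 171, 4), "fop")
  expect_equal(fop$pct_display, c(57, 10, 9, 23, 1))

  expect_error(tabulate_distribution(character(0), "nova"), "empty stratum")
  expect_error(tabulate_distribution(c("A", "F"), "nutriscore"), "outside")
})

test_that("cross-tabulation computes row percentages over row marginals", {
  # a system crossed with itself is diagonal with 100% rows
  lab <- c("1", "2", "2", "4")
  self <- cross_tabulate(lab, lab, "nova", "nova")
  expect_true(all(self$counts[row(self$counts) != col(self$counts)] == 0))
  expect_equal(unname(diag(self$row_pct_display)[c(1, 2, 4)]),
               c(100, 100, 100))

  ref <- reference_crosstabs()$nutriscore_nova
  ct <- crosstab_from_counts(ref, "nutriscore", "nova")
  expect_equal(unname(ct$row_totals["A"]), 197)
  expect_equal(unname(ct$row_pct_display["A", ]), c(54.3, 1.5, 25.4, 18.8))
  nf <- crosstab_from_counts(reference_crosstabs()$nova_fop, "nova", "fop")
  expect_equal(unname(nf$row_pct_display["1", ]), c(100, 0, 0, 0, 0))
  expect_equal(nf$total, 736)
  # rounded row sums stay within half a point of 100
  sums <- rowSums(ct$row_pct_display)
  expect_true(all(abs(sums - 100) <= 0.5))
})

test_that("cross-tab marginals conserve the distribution counts and transpose", {
  set.seed(41)
  a <- sample(system_levels("nutriscore"), 120, replace = TRUE)
  b <- sample(system_levels("fop"), 120, replace = TRUE)
  ids <- sprintf("f%03d", 1:120)
  ct <- cross_tabulate(setNames(a, ids), setNames(b, ids),
                       "nutriscore", "fop")
  expect_equal(unname(ct$row_totals),
               tabulate_distribution(a, "nutriscore")$count)
  expect_equal(unname(ct$col_totals), tabulate_distribution(b, "fop")$count)
  tct <- cross_tabulate(setNames(b, ids), setNames(a, ids),
                        "fop", "nutriscore")
  expect_equal(tct$counts, t(ct$counts))
  # misaligned id sets are refused
  expect_error(
    cross_tabulate(setNames(a, ids), setNames(b, rev(paste0(ids, "x"))),
                   "nutriscore", "fop"),
    "same food_id"
  )
})

test_that("recommendation agreement handles identity, independence and direction", {
  mapns <- default_recommendation_map("nutriscore")
  same <- recommendation_agreement(c("A", "A", "E"), c("A", "A", "E"),
                                   mapns, mapns)
  expect_equal(same$percent_agreement, 100)
  expect_equal(same$kappa, 1)

  # independence: equal cell counts in the 2x2 gives kappa 0
  mapnova <- default_recommendation_map("nova")
  la <- rep(c("1", "1", "4", "4"), 5)
  lb <- rep(c("1", "4", "1", "4"), 5)
  indep <- recommendation_agreement(la, lb, mapnova, mapnova)
  expect_equal(indep$kappa, 0)
  expect_equal(indep$percent_agreement, 50)

  # all 143 NOVA-1 foods of the surveyed basket carry zero labels
  nf <- reference_crosstabs()$nova_fop
  nova_lab <- rep(rownames(nf), times = rowSums(nf))
  fop_lab <- unlist(lapply(seq_len(nrow(nf)), function(i) {
    rep(colnames(nf), times = nf[i, ])
  }))
  share_nova1_fop0 <- 100 * mean(fop_lab[nova_lab == "1"] == "0")
  expect_equal(share_nova1_fop0, 100)

  expect_error(
    recommendation_agreement(c("A", "Z"), c("A", "A"), mapns, mapns),
    "absent from mapping"
  )
})

test_that("kappa matches an independent implementation on random tables", {
  skip_if_not_installed("caret")
  set.seed(42)
  for (i in 1:10) {
    a <- sample(c("recommended", "not_recommended"), 60, replace = TRUE)
    b <- sample(c("recommended", "not_recommended"), 60, replace = TRUE)
    lv <- c("not_recommended", "recommended")
    cm <- caret::confusionMatrix(table(factor(a, lv), factor(b, lv)))
    expect_equal(cohen_kappa(a, b), unname(cm$overall["Kappa"]),
                 tolerance = 1e-10)
  }
})

test_that("ordinal encoding maps verdicts to health-ordered codes", {
  df <- tibble::tibble(
    nutriscore = c("A", "E"), nova = c("1", "4"), fop = c("0", "4")
  )
  enc <- ordinal_encode(df)
  expect_equal(enc$codes[1, ], c(nutriscore = 1L, nova = 1L, fop = 1L))
  expect_equal(enc$codes[2, ], c(nutriscore = 5L, nova = 4L, fop = 5L))
  expect_equal(unname(colMeans(enc$standardized)), c(0, 0, 0))

  const <- tibble::tibble(
    nutriscore = c("A", "B"), nova = c("2", "2"), fop = c("0", "1")
  )
  expect_error(ordinal_encode(const, stratum = "oils_fats"), "oils_fats")
})

test_that("PCA of the correlation matrix has the closed-form degenerate cases", {
  x <- cbind(a = 1:12, b = 2 * (1:12) + 3, c = 0.5 * (1:12) + 1)
  colnames(x) <- c("nutriscore", "nova", "fop")
  ord <- run_pca(x)
  expect_equal(unname(ord$explained_variance), c(1, 0), tolerance = 1e-12)
  expect_lt(max(abs(ord$angles)), 1e-3)

  # two identical columns plus one exactly orthogonal: PC1 explains 2/3
  set.seed(43)
  base <- 1:40
  ind <- rnorm(40)
  ind <- ind - mean(ind)
  ind <- ind - sum(ind * scale(base)) * scale(base)[, 1] / sum(scale(base)^2)
  x2 <- cbind(nutriscore = base, nova = base * 3 - 7, fop = ind)
  ord2 <- run_pca(x2)
  expect_equal(unname(ord2$explained_variance[1]), 2 / 3, tolerance = 1e-10)
})

test_that("PCA is order-invariant and sign-fixed", {
  set.seed(44)
  x <- matrix(rnorm(300), ncol = 3,
              dimnames = list(NULL, c("nutriscore", "nova", "fop")))
  x[, 2] <- x[, 1] * 0.7 + x[, 2]
  a <- run_pca(x)
  b <- run_pca(x[sample(nrow(x)), ])
  expect_equal(a$rotation, b$rotation, tolerance = 1e-10)
  expect_equal(a$angles, b$angles, tolerance = 1e-8)
  # largest-magnitude loading of each component is positive
  for (j in 1:2) {
    expect_gt(a$rotation[which.max(abs(a$rotation[, j])), j], 0)
  }
  expect_error(run_pca(x[1:2, ]), "at least 3")
})
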