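# Clinical scoring, exact tests and the synthetic cohort generator.

test_that("CONUT scoring matches the component bands and severity ranges", {
  r <- conut_score(c(40, 32, 36), c(2.0, 1.0, 1.3), c(5.0, 3.0, 3.8))
  expect_equal(r$score, c(0L, 6L, 2L))
  expect_equal(as.character(r$band), c("normal", "moderate", "light"))
  # any total of 3 lies in the light band, whatever its composition
  threes <- conut_score(c(34, 40, 40), c(1.7, 0.7, 1.6), c(4.0, 5.0, 2.4))
  expect_equal(threes$score, c(3L, 3L, 3L))
  expect_true(all(as.character(threes$band) == "light"))
  expect_warning(conut_score(70, 2, 5), "non-physiologic")
  expect_error(conut_score(-1, 2, 5), "positive")
})

test_that("CONUT score is monotone non-increasing in each input", {
  alb <- seq(20, 45, by = 2.5)
  lym <- seq(0.4, 2.4, by = 0.2)
  cho <- seq(1.8, 5.4, by = 0.4)
  expect_true(all(diff(conut_score(alb, 1.0, 3.0)$score) <= 0))
  expect_true(all(diff(conut_score(32, lym, 3.0)$score) <= 0))
  expect_true(all(diff(conut_score(32, 1.0, cho)$score) <= 0))
})

test_that("incidence reproduces the printed rounding convention", {
  expect_equal(incidence(1, 48), 2.1)
  expect_equal(incidence(9, 25), 36)
  expect_equal(incidence(0, 17), 0)
  expect_error(incidence(5, 0))
  expect_error(incidence(6, 5))
})

# independent oracle: enumerate every table with the observed margins and
# sum the probabilities of those no more probable than the observed one
fisher_enum <- function(t) {
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1]); n <- sum(t)
  xs <- max(0, c1 - r2):min(c1, r1)
  logp <- lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
    lfactorial(n) - lfactorial(xs) - lfactorial(r1 - xs) -
    lfactorial(c1 - xs) - lfactorial(r2 - c1 + xs)
  p <- exp(logp)
  pobs <- p[xs == t[1, 1]]
  sum(p[p <= pobs * (1 + 1e-7)])
}

test_that("Fisher's exact test agrees with enumeration and stats::fisher.test", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2)), 1 / 3, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    t <- matrix(stats::rmultinom(1, n, prob = stats::runif(4, 0.05, 1)), 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    p <- fisher_exact(t)
    expect_equal(p, fisher_enum(t), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(t)$p.value, tolerance = 1e-9)
  }
})

test_that("chi-square statistic matches the closed form and stats::chisq.test", {
  expect_equal(chi_square(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  t <- matrix(c(1, 9, 47, 16), 2)
  expect_equal(chi_square(t)$statistic, 16.0, tolerance = 0.01)
  # (suppress the reference implementation's small-expected-count warnings)
  expect_equal(chi_square(t)$statistic,
               unname(suppressWarnings(stats::chisq.test(t, correct = FALSE))$statistic),
               tolerance = 1e-10)
  expect_equal(chi_square(t, yates = TRUE)$statistic,
               unname(suppressWarnings(stats::chisq.test(t, correct = TRUE))$statistic),
               tolerance = 1e-10)
  # invariance under row and column swaps
  expect_equal(chi_square(t[2:1, ])$statistic, chi_square(t)$statistic)
  expect_equal(chi_square(t[, 2:1])$statistic, chi_square(t)$statistic)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("rebuilt tables reproduce every printed percentage and p-bound", {
  rep <- rebuild_tables()
  expect_true(all(rep$percentages$match))
  expect_true(all(rep$tests$consistent))
  dge <- rep$tests[rep$tests$label == "dge", ]
  expect_lt(dge$p_fisher, 0.001)
})

test_that("synthetic cohorts reproduce the categorical marginals exactly", {
  co <- generate_cohort(3)
  expect_equal(nrow(co), 73L)
  spgj <- co[co$group == "SPGJ", ]; cgj <- co[co$group == "CGJ", ]
  expect_equal(c(nrow(spgj), nrow(cgj)), c(48L, 25L))
  expect_equal(c(sum(spgj$dge), sum(cgj$dge)), c(1L, 9L))
  expect_equal(c(sum(spgj$complication), sum(cgj$complication)), c(2L, 12L))
  expect_equal(as.vector(table(cgj$gooss_post)), c(3L, 4L, 8L, 10L))
  expect_equal(as.vector(table(spgj$gooss_post)[c("2", "3")]), c(5L, 43L))
  expect_equal(sum(spgj$sex == "M"), 36L)
  expect_equal(sum(cgj$disease == "gastric cancer"), 20L)
  # laboratory values are consistent with the assigned CONUT band
  bands <- conut_score(co$albumin, co$lymphocytes, co$cholesterol)$band
  expect_equal(as.character(bands), as.character(co$conut_band))
  # the DGE contrast recomputed from the cohort matches the printed bound
  t <- table(co$group, co$dge)[c("SPGJ", "CGJ"), c("TRUE", "FALSE")]
  expect_lt(fisher_exact(t), 0.001)
})

test_that("cohort generation is deterministic per seed and respects medians", {
  expect_identical(generate_cohort(7), generate_cohort(7))
  expect_false(identical(generate_cohort(7), generate_cohort(8)))
  cnt <- goo_study_counts()
  for (seed in c(2, 5)) {
    co <- generate_cohort(seed)
    for (grp in c("SPGJ", "CGJ")) {
      tg <- cnt$continuous$time_to_gas[[grp]]
      med <- stats::median(co$time_to_gas[co$group == grp])
      expect_gte(med, tg[2]); expect_lte(med, tg[3])
    }
  }
})

test_that("degenerate zero-event marginals give a null exact test", {
  cnt <- goo_study_counts()
  cnt$categorical$dge$SPGJ <- 0L; cnt$categorical$dge$CGJ <- 0L
  cnt$graded$dge_grade$SPGJ <- c(48L, 0L, 0L, 0L)
  cnt$graded$dge_grade$CGJ <- c(25L, 0L, 0L, 0L)
  co <- generate_cohort(1, cohort_spec(cnt))
  t <- matrix(c(sum(co$dge[co$group == "SPGJ"]), sum(co$dge[co$group == "CGJ"]),
                48 - sum(co$dge[co$group == "SPGJ"]),
                25 - sum(co$dge[co$group == "CGJ"])), 2)
  expect_equal(fisher_exact(t), 1)
  # infeasible marginals are refused
  bad <- goo_study_counts(); bad$categorical$dge$CGJ <- 40L
  expect_error(cohort_spec(bad), "infeasible")
})
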