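test_that("ICC separates agreement from consistency", {
  perfect <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(icc(perfect, "one_way")$icc, 1, tolerance = 1e-12)

  biased <- cbind(a = c(1, 2, 3), b = c(2, 3, 4))
  expect_equal(icc(biased, "two_way_mixed")$icc, 1, tolerance = 1e-9)
  expect_lt(icc(biased, "one_way")$icc, 1)
})

test_that("ICC matches an explicit mean-squares oracle on random matrices", {
  set.seed(99)
  for (rep in 1:5) {
    m <- matrix(rnorm(12), nrow = 6, ncol = 2)
    n <- nrow(m); k <- ncol(m)
    grand <- mean(m)
    subj <- rowMeans(m)
    rep_means <- colMeans(m)
    ss_between <- k * sum((subj - grand)^2)
    ss_within <- sum((m - subj)^2)
    ss_rep <- n * sum((rep_means - grand)^2)
    ss_err <- sum((sweep(sweep(m, 1, subj), 2, rep_means) + grand)^2)
    bms <- ss_between / (n - 1)
    wms <- ss_within / (n * (k - 1))
    ems <- ss_err / ((n - 1) * (k - 1))
    expect_equal(icc(m, "one_way")$icc,
                 (bms - wms) / (bms + (k - 1) * wms), tolerance = 1e-9)
    expect_equal(icc(m, "two_way_mixed")$icc,
                 (bms - ems) / (bms + (k - 1) * ems), tolerance = 1e-9)
  }
})

test_that("ICC is invariant to affine rescaling; ICC(3,1) to column shifts", {
  set.seed(7)
  m <- matrix(rnorm(20, sd = 2), nrow = 10)
  for (model in c("one_way", "two_way_mixed")) {
    expect_equal(icc(3 * m + 5, model)$icc, icc(m, model)$icc,
                 tolerance = 1e-9)
  }
  shifted <- sweep(m, 2, c(0, -1.7))
  expect_equal(icc(shifted, "two_way_mixed")$icc,
               icc(m, "two_way_mixed")$icc, tolerance = 1e-9)
  # when a systematic column bias dominates the residual, the one-way model
  # cannot exceed ICC(3,1)
  base <- rnorm(10, sd = 2)
  biased <- cbind(base + rnorm(10, sd = 0.3),
                  base + 1.7 + rnorm(10, sd = 0.3))
  expect_lte(icc(biased, "one_way")$icc,
             icc(biased, "two_way_mixed")$icc + 1e-12)
})

test_that("degenerate matrices are flagged, not crashed", {
  flat <- matrix(c(1, 1, 1, 1, 1, 1), nrow = 3)
  expect_warning(res <- icc(flat, "one_way"), "degenerate")
  expect_true(res$degenerate)
  expect_error(icc(matrix(rnorm(4), 2, 2)), "at least 3 subjects")
  withmiss <- rbind(c(1, 2), c(2, NA), c(3, 3.2), c(4, 4.1))
  expect_warning(res2 <- icc(withmiss, "one_way"), "dropped")
  expect_equal(res2$n, 3)
})

test_that("SEM follows SD * sqrt(1 - ICC)", {
  m <- cbind(c(1, 2, 3, 4), c(1.2, 2.1, 2.9, 4.2))
  expect_equal(sem_measurement(m, 1), 0)
  expect_equal(sem_measurement(m, 0), sd(as.vector(m)), tolerance = 1e-12)
  i <- icc(m, "one_way")
  expect_equal(sem_measurement(m, i),
               sd(as.vector(m)) * sqrt(1 - i$icc), tolerance = 1e-12)
})

test_that("agreement bands reproduce the published thresholds at boundaries", {
  expect_equal(reliability_band(c(0.76, 0.75, 0.749, 0.4, 0.399, -0.2)),
               c("excellent", "excellent", "moderate-to-high",
                 "moderate-to-high", "low", "low"))
})

test_that("heteroskedasticity screen recovers proportional spread", {
  mu <- seq(1, 10, length.out = 20)
  m <- cbind(mu - 0.05 * mu, mu + 0.05 * mu)   # |diff| proportional to mean
  h <- heteroskedasticity(m)
  expect_equal(h$r, 1, tolerance = 1e-9)
  expect_lt(h$p, 1e-6)

  set.seed(3)
  n <- 1000
  base <- rnorm(n, 10, 2)
  hom <- cbind(base + rnorm(n, sd = 0.3), base + rnorm(n, sd = 0.3))
  expect_lt(abs(heteroskedasticity(hom)$r), 0.1)

  flat <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_warning(hd <- heteroskedasticity(flat), "degenerate")
  expect_equal(hd$r, 0)
})

test_that("Mann-Whitney U agrees with the reference implementation", {
  set.seed(11)
  a <- rnorm(12); b <- rnorm(15, mean = 0.5)
  got <- group_difference(a, b, n_tests = 1)
  refw <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = FALSE))
  expect_equal(got$U, unname(refw$statistic), tolerance = 1e-9)
  # manual rank-sum oracle for U
  ranks <- rank(c(a, b))
  U_manual <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  expect_equal(got$U, U_manual, tolerance = 1e-9)

  # disjoint supports give an extreme U
  lo <- 1:10; hi <- 101:110
  expect_equal(group_difference(lo, hi)$U, 0)
  expect_equal(group_difference(hi, lo)$U, 100)
  # identical groups: adjusted p near 1
  expect_gt(group_difference(1:10, 1:10, n_tests = 1)$p_adj, 0.9)
  # Bonferroni multiplies and caps
  g1 <- group_difference(a, b, n_tests = 8)
  expect_equal(g1$p_adj, min(1, g1$p * 8))
})

test_that("clinical correlations use the Fisher z test", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(clinical_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(clinical_correlation(x, -x)$r, -1)

  set.seed(5)
  a <- rnorm(30); b <- 0.6 * a + rnorm(30, sd = 0.5)
  got <- clinical_correlation(a, b)
  r_manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, r_manual, tolerance = 1e-12)
  z <- atanh(r_manual) * sqrt(30 - 3)
  expect_equal(got$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  expect_error(clinical_correlation(c(1, 1, 1, 1), c(1, 2, 3, 4)),
               "zero variance")
})

test_that("the reliability report mirrors the screening layout", {
  set.seed(21)
  long <- tidyr::expand_grid(subject = sprintf("S%02d", 1:8),
                             measure = c("StrT", "dstT"),
                             repeat_id = c("t1", "t2"))
  base <- stats::setNames(rnorm(8, 10), sprintf("S%02d", 1:8))
  long$value <- base[long$subject] + rnorm(nrow(long), sd = 0.1) +
    ifelse(long$measure == "dstT", 12, 0)
  rep_tbl <- reliability_report(long)
  expect_equal(nrow(rep_tbl), 2)
  expect_true(all(c("icc11", "icc31", "sem", "band") %in% names(rep_tbl)))
  expect_true(all(rep_tbl$icc11 > 0.9))
  expect_equal(rep_tbl$band, c("excellent", "excellent"))
})

test_that("a noise-free cohort yields perfect downstream reliability", {
  # two identical repeats per subject of a deterministic pipeline parameter
  specs <- cohort_specs(walker_spec(), n_subjects = 4, trials_per_session = 1,
                        sessions = 1, between_sd = 0.06, within_sd = 0,
                        seed = 31)
  strt <- vapply(specs$spec, function(sp) {
    compute_gait_parameters(generate_trial(sp)$trial)$StrT
  }, numeric(1))
  m <- cbind(t1 = strt, t2 = strt)
  expect_warning(i <- icc(m, "one_way"), NA)
  expect_equal(i$icc, 1, tolerance = 1e-9)
  expect_equal(sem_measurement(m, i), 0, tolerance = 1e-9)
})
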