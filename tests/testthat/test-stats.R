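test_that("exact Mann-Whitney p matches enumeration and wilcox.test", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_true(mw$exact)
  expect_equal(mw$p, 0.100, tolerance = 1e-12)

  set.seed(17)
  for (i in 1:30) {
    nA <- sample(3:6, 1); nB <- sample(3:6, 1)
    a <- round(rnorm(nA, 10, 3), 1)
    b <- round(rnorm(nB, 11, 3), 1)
    got <- mannWhitneyU(a, b)
    expect_true(got$exact)
    expect_equal(got$p, enumMwP(a, b), tolerance = 1e-12)
    if (!any(duplicated(c(a, b))))
      expect_equal(got$p,
                   suppressWarnings(wilcox.test(a, b)$p.value),
                   tolerance = 1e-12)
  }
  # tied data stays exact via enumeration
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  expect_equal(mannWhitneyU(a, b)$p, enumMwP(a, b), tolerance = 1e-12)
  # large-sample path approximates the exact enumeration
  set.seed(18)
  a <- rnorm(15); b <- rnorm(15, 0.5)
  exact <- mannWhitneyU(c(a, a[1:5]), b)  # n = 35 > 20 -> approx
  expect_false(exact$exact)
  expect_true(exact$p >= 0 && exact$p <= 1)
})

test_that("compareGroups picks the test by normality and handles identical samples", {
  set.seed(5)
  a <- rnorm(12, 10, 1)
  cmp <- compareGroups(a, a, labels = c("u", "t"))
  expect_gte(pValue(cmp), 0.99)
  expect_equal(cmp@percentDifference, 0)
  expect_equal(cmp@testUsed, "t_test")

  # heavy-tailed / skewed samples route to Mann-Whitney
  skA <- c(1, 1.1, 1.2, 1.3, 1.4, 1.2, 1.1, 30, 40, 55)
  skB <- skA * 1.1
  cmp2 <- compareGroups(skA, skB)
  expect_equal(cmp2@testUsed, "mann_whitney")
  expect_error(compareGroups(c(1, 2), c(3, 4, 5)), "at least 3")
})

test_that("group contrast at realistic diameter effect sizes is reliably detected", {
  # two-group power check: N(7.3, 1.5) vs N(8.9, 1.5), n = 50 per group
  hits <- 0L
  set.seed(29)
  for (r in 1:200) {
    a <- rnorm(50, 7.3, 1.5); b <- rnorm(50, 8.9, 1.5)
    if (pValue(compareGroups(a, b)) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.90)
})

test_that("type-I error of compareGroups sits near the nominal 5%", {
  set.seed(37)
  fp <- 0L
  for (r in 1:1000) {
    a <- rnorm(10, 100, 12); b <- rnorm(10, 100, 12)
    if (pValue(compareGroups(a, b)) < 0.05) fp <- fp + 1L
  }
  # binomial(1000, 0.05): 3 sd is about +/- 0.021
  expect_gt(fp / 1000, 0.05 - 0.022)
  expect_lt(fp / 1000, 0.05 + 0.022)
})

test_that("percent difference follows the reference-group convention", {
  expect_equal(percentDifference(100, 72.3), 27.7)
  expect_equal(percentDifference(5, 5), 0)
  expect_equal(percentDifference(10, 12), -20)
  expect_error(percentDifference(0, 1), "non-zero")
})

test_that("t-test p is invariant under a common affine transform", {
  set.seed(3)
  a <- rnorm(15, 4, 1); b <- rnorm(15, 5, 1)
  p1 <- pValue(compareGroups(a, b, policy = "t_test"))
  p2 <- pValue(compareGroups(3 * a + 7, 3 * b + 7, policy = "t_test"))
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("grid area fraction matches geometry oracles", {
  full <- matrix(TRUE, 80, 80)
  expect_equal(gridAreaFraction(full, 10, 1)@percentArea, 100)
  halfm <- matrix(FALSE, 80, 80); halfm[, 1:40] <- TRUE
  expect_equal(gridAreaFraction(halfm, 10, 1)@percentArea, 50)
  # disk of radius r in a frame of side 4r: area fraction pi/16
  r <- 30
  yy <- matrix(seq_len(4 * r), 4 * r, 4 * r)
  xx <- t(yy)
  disk <- (yy - 2 * r - 0.5)^2 + (xx - 2 * r - 0.5)^2 <= r^2
  est <- gridAreaFraction(disk, 12, 1)
  expect_equal(est@percentArea, 100 * pi / 16, tolerance = 0.02)
  expect_error(gridAreaFraction(full, 0.5, 1), "larger")
})

test_that("buildReport compares metrics per group and flags skipped ones", {
  set.seed(8)
  rec <- rbind(
    data.frame(group = "untreated", metric = "diameter_um",
               value = rnorm(20, 7.3, 1.2)),
    data.frame(group = "sltbi", metric = "diameter_um",
               value = rnorm(20, 8.9, 1.2)),
    data.frame(group = "untreated", metric = "velocity_um_s",
               value = rnorm(20, 180, 60)),
    data.frame(group = "sltbi", metric = "velocity_um_s",
               value = rnorm(20, 180, 60)),
    data.frame(group = "untreated", metric = "leakage",
               value = rnorm(2, 0.33, 0.05)))
  expect_warning(rep <- buildReport(rec, reference = "untreated"),
                 "skipped")
  expect_setequal(names(rep$comparisons),
                  c("diameter_um", "velocity_um_s"))
  expect_equal(rep$skipped, "leakage")
  expect_lt(pValue(rep$comparisons$diameter_um), 0.05)
  expect_gt(pValue(rep$comparisons$velocity_um_s), 0.05)
  expect_lt(rep$summary$percentDifference[
    rep$summary$metric == "diameter_um"], 0)  # increase => negative

  out <- file.path(tempdir(), "tvreport")
  rep2 <- suppressWarnings(buildReport(rec, reference = "untreated",
                                       outDir = out))
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "diameter_um.png")))
  expect_error(buildReport(rec[rec$group == "untreated", ]), "2 groups")
})
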