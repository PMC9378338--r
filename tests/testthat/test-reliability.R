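test_that("icc21 equals the ANOVA oracle on random tables", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:10, 1); k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k)
    expect_lt(abs(icc21(x)@icc - iccOracle(x)), 1e-10)
  }
})

test_that("icc21 handles agreement, location/scale shifts and degeneracy", {
  x <- cbind(1:6, 1:6)
  r <- icc21(x)
  expect_identical(r@icc, 1)
  expect_identical(c(r@ciLow, r@ciHigh), c(1, 1))
  ## frozen value for the fixed 4 x 2 example, from the ANOVA oracle
  tab <- matrix(c(1, 3, 5, 7, 2, 4, 6, 8), 4, 2)
  expect_equal(icc21(tab)@icc, iccOracle(tab), tolerance = 1e-12)
  ## invariance to affine rescaling of all ratings
  set.seed(3)
  y <- matrix(rnorm(12), 4, 3)
  expect_equal(icc21(y * 3.7 + 11)@icc, icc21(y)@icc, tolerance = 1e-10)
  expect_error(icc21(matrix(5, 4, 2)), "zero total variance")
  expect_error(icc21(matrix(rnorm(4), 2, 2)), "n >= 3")
  expect_error(icc21(cbind(c(1, NA, 3), c(2, 2, 2))), "complete")
})

test_that("icc21 estimate and CI behave correctly under simulation", {
  nRep <- 500
  hit <- 0; est <- numeric(nRep)
  ## small rater variance: with k = 2 raters the F-based CI covers the
  ## rater-conditional estimand (methods vignette)
  for (s in seq_len(nRep)) {
    set.seed(s)
    subj <- rnorm(200, 0, 3)
    x <- subj + matrix(rnorm(2, 0, sqrt(0.1)), 200, 2, byrow = TRUE) +
      matrix(rnorm(400, 0, sqrt(0.9)), 200, 2)
    r <- icc21(x)
    est[s] <- r@icc
    if (r@ciLow <= 0.9 && 0.9 <= r@ciHigh) hit <- hit + 1
  }
  expect_lt(abs(mean(est) - 0.9), 0.03)
  expect_gte(hit / nRep, 0.9)
})

test_that("rmsError implements the quadratic mean of differences", {
  expect_equal(rmsError(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_identical(rmsError(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsError(-5, 0), 5)
  expect_error(rmsError(numeric(0), numeric(0)), "empty")
  expect_error(rmsError(1:3, 1:2), "length")
})

test_that("the BMI consistency screen controls false rejections under the null", {
  params <- paste0("p", 1:6)
  falsePos <- 0
  nRuns <- 200
  for (run in seq_len(nRuns)) {
    set.seed(run)
    n <- 20
    bmi <- data.frame(subject = 1:n, bmi = rnorm(n, 21, 3))
    meas <- do.call(rbind, lapply(params, function(pp)
      data.frame(subject = rep(1:n, 2), rater = rep(1:2, each = n),
                 parameter = pp, value = 10 + rnorm(2 * n))))
    res <- consistencyVsBmi(meas, bmi, intrinsicParams = params[1:3])
    if (any(res$reject)) falsePos <- falsePos + 1
  }
  expect_lte(falsePos / nRuns, 0.05 + 0.03)
  ## perfect rank correlation is detected
  n <- 12
  bmi <- data.frame(subject = 1:n, bmi = 1:n)
  meas <- data.frame(subject = rep(1:n, 2), rater = rep(1:2, each = n),
                     parameter = "p", value = c(rep(0, n), (1:n) / 10))
  res <- consistencyVsBmi(meas, bmi, intrinsicParams = character(0))
  expect_equal(res$rho, 1)
  expect_error(consistencyVsBmi(meas[meas$subject < 4, ], bmi),
               "fewer than 4")
})

test_that("Holm step-down matches hand execution and dominates Bonferroni", {
  p <- c(0.001, 0.04, 0.2)
  ph <- p.adjust(p, "holm")
  expect_identical(ph <= 0.05, c(TRUE, FALSE, FALSE))  # 0.04 > 0.05/2
  set.seed(9)
  for (i in 1:20) {
    pv <- runif(8)^2
    expect_gte(sum(p.adjust(pv, "holm") <= 0.05),
               sum(p.adjust(pv, "bonferroni") <= 0.05))
  }
})

test_that("compareIccSets handles degenerate and powered cases", {
  a <- c(0.9, 0.92, 0.95)
  r <- compareIccSets(a, a)
  expect_identical(r$t, 0); expect_identical(r$p, 1)
  r2 <- compareIccSets(a + 0.02, a)
  expect_identical(r2$t, Inf); expect_identical(r2$p, 0)
  ## power under a known mean shift
  nRep <- 500; sig <- 0
  for (s in seq_len(nRep)) {
    set.seed(s)
    b <- rnorm(36, 0.9, 0.03)
    a2 <- b + 0.02 + rnorm(36, 0, 0.03)
    if (compareIccSets(a2, b)$p < 0.05) sig <- sig + 1
  }
  expect_gt(sig / nRep, 0.9)
  expect_error(compareIccSets(1:3, 1:2), "equal lengths")
})

test_that("reliabilityReport reproduces the crossed-study layout", {
  des0 <- studyDesign(nSubjects = 8, sdSubject = 2, sdRater = 0, sdTrial = 0)
  st0 <- simulateRatingStudy(des0, seed = 1, mode = "proxy")
  rep0 <- reliabilityReport(st0)
  iccCols <- grep("^icc", names(rep0), value = TRUE)
  expect_true(all(abs(unlist(rep0[, iccCols]) - 1) < 1e-9))
  ## intra > inter ordering is reproduced when only raters disagree
  des1 <- studyDesign(nSubjects = 120, sdSubject = 3, sdRater = 1.5,
                      sdTrial = 0.3)
  st1 <- simulateRatingStudy(des1, seed = 7, mode = "proxy")
  rep1 <- reliabilityReport(st1)
  expect_gt(rep1$icc_intra_A_test_retest, rep1$icc_inter)
  expect_true(rep1$icc_inter_ci_low <= rep1$icc_inter &&
                rep1$icc_inter <= rep1$icc_inter_ci_high)
  ## constant parameter: zero grand SD, ICC skipped as NA
  stC <- st0; stC$value <- 5; stC$parameter <- "const"
  repC <- reliabilityReport(stC)
  expect_identical(repC$grand_sd, 0)
  expect_true(all(is.na(unlist(repC[, iccCols]))))
  expect_error(reliabilityReport(st0[, setdiff(names(st0), "rater")]),
               "rater")
})
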