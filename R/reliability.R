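## Reliability statistics: ICC(2,1) absolute agreement with 95% CI,
## RMS error, Spearman consistency-vs-BMI screen with Bonferroni-Holm, and
## paired comparison of ICC sets.

#' ICC(2,1): two-way random effects, absolute agreement, single rater
#'
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)), with MSR, MSC,
#' MSE the subject, rater and error mean squares of the two-way ANOVA
#' without replication; the 95% confidence interval uses the standard
#' F-quantile construction for absolute agreement (McGraw & Wong). Negative
#' estimates are reported as computed, not clamped.
#'
#' @param table n x k numeric matrix: n subjects (rows), k raters (columns);
#'   complete (no missing cells), n >= 3, k >= 2.
#' @param alpha confidence level complement (default 0.05 two-sided).
#' @return an \linkS4class{IccResult}.
#' @export
icc21 <- function(table, alpha = 0.05) {
  x <- as.matrix(table)
  if (any(is.na(x))) stop("complete crossed design required (no missing cells)")
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need n >= 3 subjects")
  if (k < 2) stop("need k >= 2 raters")
  gm <- mean(x)
  if (sum((x - gm)^2) < 1e-300) stop("zero total variance: ICC undefined")
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  SSR <- k * sum((rm_ - gm)^2)
  SSC <- n * sum((cm_ - gm)^2)
  SST <- sum((x - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  if (MSE <= 1e-12 * MSR && MSC <= MSE + 1e-12 * MSR) {
    ## raters agree exactly: degenerate CI at 1
    return(new("IccResult", icc = 1, ciLow = 1, ciHigh = 1,
               msr = MSR, msc = MSC, mse = MSE, n = n, k = k))
  }
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  new("IccResult", icc = icc, ciLow = min(lower, icc), ciHigh = max(upper, icc),
      msr = MSR, msc = MSC, mse = MSE, n = n, k = k)
}

#' Root-mean-squared (quadratic mean) error
#'
#' RMS = sqrt(mean((value - reference)^2)); the quadratic mean of the
#' differences, in the units of the input.
#'
#' @param values,reference equal-length numeric vectors.
#' @return RMS error.
#' @export
rmsError <- function(values, reference) {
  if (length(values) == 0) stop("empty input")
  if (length(values) != length(reference)) stop("length mismatch")
  sqrt(mean((values - reference)^2))
}

#' Spearman screen of measurement consistency against BMI
#'
#' For every parameter, computes the between-rater consistency per subject
#' (relative difference |rA - rB| / |mean| for intrinsic measures, absolute
#' difference for pose-dependent ones), correlates it with subject BMI
#' (Spearman), and applies the Bonferroni-Holm step-down correction across
#' the parameter family at alpha = 0.05.
#'
#' @param measurements long data.frame with columns subject, rater,
#'   parameter, value (one value per subject x rater x parameter; replicate
#'   scans should be averaged first).
#' @param bmi named numeric vector of per-subject BMI (names = subject ids)
#'   or a data.frame with columns subject, bmi.
#' @param intrinsicParams parameter names treated as intrinsic.
#' @param alpha family-wise error rate for the Holm correction.
#' @return data.frame: parameter, rho, p, pHolm, reject.
#' @export
consistencyVsBmi <- function(measurements, bmi,
                             intrinsicParams = c("spine_length_cm", "back_area_dm2",
                                                 "xsa_L2_dm2", "xsa_T8_dm2", "xsa_JN_dm2",
                                                 "xsv_L2_T8_L", "xsv_XP_JN_L", "xsv_PSIS_JN_L"),
                             alpha = 0.05) {
  if (is.data.frame(bmi)) bmi <- setNames(bmi$bmi, bmi$subject)
  params <- unique(measurements$parameter)
  res <- lapply(params, function(pp) {
    d <- measurements[measurements$parameter == pp, ]
    raters <- sort(unique(d$rater))
    if (length(raters) < 2) stop("two raters required per parameter")
    rA <- d[d$rater == raters[1], ]
    rB <- d[d$rater == raters[2], ]
    subj <- intersect(rA$subject, rB$subject)
    if (length(subj) < 4) stop("fewer than 4 subjects: p unreliable")
    a <- setNames(rA$value, rA$subject)[as.character(subj)]
    b <- setNames(rB$value, rB$subject)[as.character(subj)]
    cons <- if (pp %in% intrinsicParams) abs((a - b) / ((a + b) / 2)) else abs(a - b)
    ct <- suppressWarnings(cor.test(cons, bmi[as.character(subj)],
                                    method = "spearman", exact = FALSE))
    data.frame(parameter = pp, rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$pHolm <- p.adjust(out$p, method = "holm")
  out$reject <- out$pHolm <= alpha
  out
}

#' Paired two-tailed comparison of two sets of ICCs
#'
#' Paired t statistic over the element-wise differences, df = n - 1. By
#' convention, when the differences have zero variance the result is t = 0,
#' p = 1 for identical sets and |t| = Inf, p = 0 for a constant non-zero
#' shift.
#'
#' @param iccsA,iccsB equal-length numeric vectors of ICC estimates.
#' @param paired must be TRUE (only the paired design is supported).
#' @return list(t, df, p, meanDiff).
#' @export
compareIccSets <- function(iccsA, iccsB, paired = TRUE) {
  if (!paired) stop("only the paired comparison is supported")
  if (length(iccsA) != length(iccsB)) stop("equal lengths required")
  n <- length(iccsA)
  if (n < 2) stop("need n >= 2 pairs")
  d <- iccsA - iccsB
  if (sd(d) < 1e-14) {
    if (abs(mean(d)) < 1e-14)
      return(list(t = 0, df = n - 1, p = 1, meanDiff = 0))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0, meanDiff = mean(d)))
  }
  tt <- t.test(iccsA, iccsB, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanDiff = mean(d))
}

#' Per-parameter reliability report of a crossed rating study
#'
#' Reproduces the clinical reporting layout: for every parameter (and pose,
#' when present), intra-rater test-retest and remove-replace ICC(2,1) per
#' rater, inter-rater ICC with its 95% CI, and the grand mean/SD across all
#' scans. Scan selection follows the first-scan-per-placement policy:
#' test-retest pairs the two trials of placement 1; remove-replace pairs
#' trial 1 of each placement; inter-rater pairs trial 1 of placement 1
#' across raters.
#'
#' @param study long data.frame with columns subject, rater, placement,
#'   trial, parameter, value (optional pose).
#' @return data.frame with one row per parameter (x pose).
#' @export
reliabilityReport <- function(study) {
  need <- c("subject", "rater", "placement", "trial", "parameter", "value")
  miss <- setdiff(need, names(study))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!"pose" %in% names(study)) study$pose <- "all"
  keys <- unique(study[, c("parameter", "pose")])
  pick <- function(d, rater, placement, trial) {
    sel <- d[d$rater == rater & d$placement == placement & d$trial == trial, ]
    setNames(sel$value, sel$subject)
  }
  iccOf <- function(a, b) {
    subj <- intersect(names(a), names(b))
    if (length(subj) < 3) return(NULL)
    tryCatch(icc21(cbind(a[subj], b[subj])), error = function(e) NULL)
  }
  rows <- list()
  for (r in seq_len(nrow(keys))) {
    d <- study[study$parameter == keys$parameter[r] & study$pose == keys$pose[r], ]
    raters <- sort(unique(d$rater))
    out <- data.frame(parameter = keys$parameter[r], pose = keys$pose[r],
                      grand_mean = mean(d$value), grand_sd = sd(d$value))
    for (ri in seq_along(raters)) {
      tr <- iccOf(pick(d, raters[ri], 1, 1), pick(d, raters[ri], 1, 2))
      rr <- iccOf(pick(d, raters[ri], 1, 1), pick(d, raters[ri], 2, 1))
      out[[paste0("icc_intra_", LETTERS[ri], "_test_retest")]] <-
        if (is.null(tr)) NA_real_ else tr@icc
      out[[paste0("icc_intra_", LETTERS[ri], "_remove_replace")]] <-
        if (is.null(rr)) NA_real_ else rr@icc
    }
    if (length(raters) >= 2) {
      ir <- iccOf(pick(d, raters[1], 1, 1), pick(d, raters[2], 1, 1))
      out$icc_inter <- if (is.null(ir)) NA_real_ else ir@icc
      out$icc_inter_ci_low <- if (is.null(ir)) NA_real_ else ir@ciLow
      out$icc_inter_ci_high <- if (is.null(ir)) NA_real_ else ir@ciHigh
    }
    rows[[r]] <- out
  }
  do.call(rbind, rows)
}
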