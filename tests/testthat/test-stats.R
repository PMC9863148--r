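test_that("normalization maps identical samples onto themselves", {
  set.seed(7)
  v <- sort(2^rnorm(40, 10, 1))
  m <- cbind(s1 = v, s2 = v, s3 = v)
  rownames(m) <- paste0("a", seq_len(40))
  out <- robust_spline_normalize(m)
  expect_equal(out, m, tolerance = 1e-9)
})

test_that("normalization removes a global scale factor", {
  set.seed(8)
  a <- 2^rnorm(50, 10, 0.8)
  m <- cbind(A = a, B = 2 * a)
  rownames(m) <- paste0("a", seq_len(50))
  out <- robust_spline_normalize(m)
  ratio <- out[, "B"] / out[, "A"]
  expect_true(all(ratio > 0.95 & ratio < 1.05))
  # against the full quantile-normalization oracle: same target curve
  qn_ref <- rowMeans(cbind(sort(log2(a)), sort(log2(2 * a))))
  expect_equal(unname(sort(log2(out[, "A"]))[10:40]), qn_ref[10:40],
               tolerance = 0.05)
})

test_that("normalization preserves within-sample ranks exactly", {
  set.seed(9)
  m <- matrix(2^rnorm(200, 9, 1.2), 50, 4,
              dimnames = list(paste0("a", 1:50), paste0("s", 1:4)))
  out <- robust_spline_normalize(m)
  for (j in 1:4) expect_identical(rank(out[, j]), rank(m[, j]))
  # zeros are offset, output stays positive, single sample is skipped
  m0 <- m; m0[1, 1] <- 0
  expect_true(all(robust_spline_normalize(m0) > 0))
  expect_warning(one <- robust_spline_normalize(m[, 1, drop = FALSE]),
                 "skipped")
  expect_equal(one, m[, 1, drop = FALSE], ignore_attr = TRUE)
})

test_that("the background rule follows min + fraction * (max - min)", {
  bg <- background_spot_set(c(2, 4, 6, 102))
  expect_equal(bg$threshold, 7)
  expect_identical(bg$background, 1:3)
  bg2 <- background_spot_set(c(0, 10, 50, 100))
  expect_equal(bg2$threshold, 5)
  expect_identical(bg2$background, 1L)
  # degenerate constant input: everything is background
  bg3 <- background_spot_set(rep(4, 5))
  expect_true(bg3$degenerate)
  expect_identical(bg3$background, 1:5)
  expect_error(background_spot_set(c(1, 2), background_fraction = 1.2),
               "background_fraction")
})

test_that("detection p-values behave at the null, at extremes, and degenerately", {
  set.seed(10)
  b <- rnorm(40, 100, 5)
  # duplicates at the background mean: no evidence
  expect_gte(detection_pvalue(c(mean(b), mean(b)), b), 0.5)
  # far above background: overwhelming evidence
  expect_lt(detection_pvalue(c(600, 605), b), 1e-10)
  # single replicate: z-score path
  z <- (130 - mean(b)) / sd(b)
  expect_equal(detection_pvalue(130, b), pnorm(z, lower.tail = FALSE))
  # zero background variance: exact rule
  expect_identical(detection_pvalue(c(5, 6), rep(3, 10)), 0)
  expect_identical(detection_pvalue(c(1, 2), rep(3, 10)), 1)
  expect_error(detection_pvalue(c(1, 2), 3), "background")
})

test_that("detection is calibrated on blanks and sensitive at high SNR", {
  set.seed(11)
  hits_null <- hits_snr <- 0; n_rep <- 400
  for (r in seq_len(n_rep)) {
    b <- rnorm(30, 1000, 20)
    blank <- rnorm(2, 1000, 20)
    strong <- rnorm(2, 1000 + 10 * 20, 20)
    hits_null <- hits_null + (detection_pvalue(blank, b) < 0.05)
    hits_snr <- hits_snr + (detection_pvalue(strong, b) < 0.05)
  }
  expect_lt(hits_null / n_rep, 0.07)
  expect_gt(hits_snr / n_rep, 0.95)
})

test_that("moderated t reduces to the pooled t at d0 = 0 and to the fixed-variance statistic at d0 = Inf", {
  set.seed(12)
  for (r in 1:25) {
    m <- matrix(rnorm(30 * 6), 30, 6,
                dimnames = list(paste0("g", 1:30), NULL))
    gr <- rep(c("CKD", "control"), each = 3)
    fit0 <- fit_moderated_t(m, gr, prior_df = 0)
    ref_t <- apply(m, 1, function(x)
      stats::t.test(x[1:3], x[4:6], var.equal = TRUE)$statistic)
    ref_p <- apply(m, 1, function(x)
      stats::t.test(x[1:3], x[4:6], var.equal = TRUE)$p.value)
    expect_equal(unname(fit0$table$t), unname(ref_t), tolerance = 1e-10)
    expect_equal(unname(fit0$table$p), unname(ref_p), tolerance = 1e-10)
    s02 <- 0.5
    fitI <- fit_moderated_t(m, gr, prior_df = Inf, prior_var = s02)
    dif <- rowMeans(m[, 1:3]) - rowMeans(m[, 4:6])
    expect_equal(fitI$table$t, unname(dif) / sqrt(s02 * (2 / 3)), tolerance = 1e-8)
  }
})

test_that("identical sample variances are a fixed point of the shrinkage", {
  m <- matrix(0, 20, 4, dimnames = list(paste0("g", 1:20), NULL))
  set.seed(13)
  delta <- rnorm(20)
  # construct exact variance 1 in both groups for every analyte
  m[, 1] <- delta + 1 / sqrt(2); m[, 2] <- delta - 1 / sqrt(2)
  m[, 3] <- 1 / sqrt(2); m[, 4] <- -1 / sqrt(2)
  gr <- c("CKD", "CKD", "control", "control")
  fit <- fit_moderated_t(m, gr)
  expect_identical(fit$prior_df, Inf)
  expect_equal(unname(fit$table$s2_post), rep(1, 20), tolerance = 1e-12)
  ref_t <- delta / sqrt(1 * (1 / 2 + 1 / 2))
  expect_equal(fit$table$t, ref_t, tolerance = 1e-12)
})

test_that("prior parameters are recovered from scaled inverse-chi-square variances", {
  d0_true <- 4; s02_true <- 0.05
  d0_hat <- s02_hat <- numeric(40)
  set.seed(14)
  for (r in 1:40) {
    n_g <- 200
    sigma2 <- d0_true * s02_true / rchisq(n_g, d0_true)
    m <- matrix(rnorm(n_g * 6, sd = sqrt(rep(sigma2, 6))), n_g, 6,
                dimnames = list(paste0("g", 1:n_g), NULL))
    fit <- fit_moderated_t(m, rep(c("a", "b"), each = 3))
    d0_hat[r] <- fit$prior_df
    s02_hat[r] <- fit$prior_var
  }
  expect_gt(median(d0_hat), 2)
  expect_lt(median(d0_hat), 8)
  expect_lt(abs(median(s02_hat) - s02_true) / s02_true, 0.5)
})

test_that("moderated t agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(15)
  n_g <- 120
  sigma2 <- 4 * 0.05 / rchisq(n_g, 4)
  m <- matrix(rnorm(n_g * 6, sd = sqrt(rep(sigma2, 6))), n_g, 6,
              dimnames = list(paste0("g", 1:n_g), NULL))
  gr <- rep(c("CKD", "control"), each = 3)
  fit <- fit_moderated_t(m, gr)
  design <- cbind(1, gr == "CKD")
  lf <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(fit$prior_df, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior_var, lf$s2.prior, tolerance = 1e-6)
  expect_equal(unname(fit$table$t), unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(fit$table$p), unname(lf$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment matches hand-computed and brute-force values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(16)
  for (r in 1:60) {
    n <- sample(1:100, 1)
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # include heavy ties
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "NA")
})

test_that("composite DE calls gate on detection, ratio, p and FDR together", {
  # synthetic duplicate-level matrix with controlled statistics
  set.seed(17)
  base <- 2^rnorm(30, 8, 0.5)
  fold <- rep(1, 30)
  fold[1] <- 1.6; fold[2] <- 1.6; fold[3] <- 0.5
  mk <- function(f, eps) base * f * 2^matrix(rnorm(60, 0, eps), 30, 2)
  v <- cbind(mk(fold, 0.05), mk(1, 0.05))
  dimnames(v) <- list(paste0("a", 1:30),
                      c("ckd.d1", "ckd.d2", "ctl.d1", "ctl.d2"))
  det <- data.frame(analyte = rownames(v),
                    detect_p_ckd = 0.01, detect_p_control = 0.01)
  det$detect_p_ckd[2] <- 0.9; det$detect_p_control[2] <- 0.9
  de <- call_differential(v, det, de_criteria(),
                          groups = c("CKD", "CKD", "control", "control"))
  expect_s3_class(de, "de_result")
  expect_identical(de$call[de$analyte == "a1"], "up")
  # detection gate fails in both conditions
  expect_identical(de$call[de$analyte == "a2"], "ns")
  expect_identical(de$call[de$analyte == "a3"], "down")
  expect_true(all(de$call[4:30] == "ns"))
  # tightening a single gate flips the call: ratio gate above a1's 1.6-fold
  crit_tight <- de_criteria(ratio_up = 1.7)
  de2 <- call_differential(v, det, crit_tight,
                           groups = c("CKD", "CKD", "control", "control"))
  expect_identical(de2$call[de2$analyte == "a1"], "ns")
})

test_that("DE calls go through detection in at least one condition", {
  v <- matrix(c(80, 82, 40, 41), 1, 4,
              dimnames = list("a1", c("k1", "k2", "c1", "c2")))
  v <- rbind(v, a2 = c(60, 61, 60.5, 59.5))
  det <- data.frame(analyte = c("a1", "a2"),
                    detect_p_ckd = c(0.8, 0.5),
                    detect_p_control = c(0.01, 0.6))
  de <- call_differential(v, det, de_criteria(),
                          groups = c("CKD", "CKD", "control", "control"))
  # detected only in control still qualifies (ratio 2, strong t)
  expect_identical(de$call[de$analyte == "a1"], "up")
  expect_identical(de$call[de$analyte == "a2"], "ns")
})

test_that("null data produce almost no composite calls", {
  set.seed(18)
  frac <- replicate(25, {
    base <- 2^rnorm(100, 9, 0.8)
    v <- base * 2^matrix(rnorm(400, 0, 0.2), 100, 4)
    dimnames(v) <- list(paste0("a", 1:100), paste0("s", 1:4))
    det <- data.frame(analyte = rownames(v), detect_p_ckd = 0.01,
                      detect_p_control = 0.01)
    de <- call_differential(v, det, de_criteria(),
                            groups = c("CKD", "CKD", "control", "control"))
    mean(de$call != "ns")
  })
  expect_lte(mean(frac), 0.02)
})
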