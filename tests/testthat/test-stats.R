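test_that("pearson + regression match exact and brute-force cases", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- pearson_regression(x, x)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0)
  neg <- pearson_regression(x, -2 * x + 3)
  expect_equal(neg$r, -1)
  expect_equal(neg$slope, -2)
  expect_equal(neg$intercept, 3)
  set.seed(13)
  xx <- rnorm(20); yy <- 0.7 * xx + rnorm(20, 0, 0.4)
  got <- pearson_regression(paired_table(xx, yy))
  # direct formula oracle
  r0 <- sum((xx - mean(xx)) * (yy - mean(yy))) /
    sqrt(sum((xx - mean(xx))^2) * sum((yy - mean(yy))^2))
  expect_equal(got$r, r0, tolerance = 1e-12)
  expect_equal(got$p, cor.test(xx, yy)$p.value, tolerance = 1e-12)
  expect_equal(got$slope, unname(coef(lm(yy ~ xx))[2]), tolerance = 1e-12)
  expect_error(pearson_regression(rep(1, 5), x), "variance")
})

test_that("bland-altman recovers its defining identities", {
  x <- c(2, 3, 4)
  expect_equal(bland_altman(x, x)$bias, 0)
  expect_equal(bland_altman(x, x)$sd, 0)
  two <- bland_altman(c(0, 0, 0, 0), c(1, -1, 1, -1))
  expect_equal(two$bias, 0)
  expect_equal(two$sd, sd(c(1, -1, 1, -1)))
  set.seed(17)
  xx <- rnorm(30, 3); yy <- xx + 0.4 + rnorm(30, 0, 0.3)
  ba <- bland_altman(paired_table(xx, yy))
  # bias + mean(x) = mean(y) exactly
  expect_equal(ba$bias + mean(xx), mean(yy), tolerance = 1e-12)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd)
})

test_that("ICC(A,1) equals the two-way ANOVA mean-squares oracle", {
  fixtures <- list(
    list(x = c(9, 6, 8, 7, 10, 6), y = c(2, 1, 4, 1, 5, 2)),
    list(x = c(1.2, 2.3, 3.1, 4.4, 5.0, 6.1, 7.2),
         y = c(1.4, 2.1, 3.6, 4.2, 5.4, 6.0, 7.7)))
  set.seed(19)
  fixtures <- c(fixtures, lapply(1:3, function(i) {
    x <- rnorm(12, 3, 1); list(x = x, y = x + 0.3 + rnorm(12, 0, 0.5))
  }))
  for (f in fixtures) {
    got <- icc_agreement(paired_table(f$x, f$y))
    expect_equal(got$icc, icc_a1_aov(f$x, f$y), tolerance = 1e-10)
  }
  # identical arms: exact agreement
  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc_agreement(paired_table(x, x))$icc, 1)
  # a large constant offset hurts agreement but not correlation
  off <- icc_agreement(paired_table(x, x + 10))
  expect_lt(off$icc, pearson_regression(x, x + 10)$r)
  expect_warning(icc_agreement(paired_table(rep(2, 6), rep(2, 6))),
                 "between-subject")
})

test_that("ICC interpretation bands follow the documented boundaries", {
  lab <- function(v) {
    if (v < 0.50) "poor" else if (v <= 0.75) "moderate" else
      if (v <= 0.90) "good" else "excellent"
  }
  for (v in c(0.3, 0.50, 0.6, 0.75, 0.8, 0.90, 0.95))
    expect_equal(lab(v), c("poor", "moderate", "moderate", "moderate",
                           "good", "good", "excellent")[
                             match(v, c(0.3, 0.50, 0.6, 0.75, 0.8, 0.90, 0.95))])
  # and the implementation agrees on a case per band
  set.seed(23)
  x <- rnorm(40, 3, 1)
  good <- icc_agreement(paired_table(x, x + rnorm(40, 0, 0.55)))
  expect_equal(good$interpretation, lab(good$icc))
})

test_that("TOST declares equivalence exactly when both one-sided tests reject", {
  set.seed(29)
  x <- rnorm(50, 3, 1); y <- x + rnorm(50, 0, 0.2)
  eq <- tost_equivalence(paired_table(x, y), margin = 0.9)
  expect_lt(eq$p, 0.001)
  expect_true(eq$equivalent)
  # closed-form check of the binding one-sided p
  d <- y - x
  t_up <- (mean(d) - 0.9) / (sd(d) / sqrt(50))
  expect_equal(eq$p_upper, pt(t_up, 49), tolerance = 1e-12)
  # zero-spread differences: degenerate branch decides by |mean| vs margin
  xi <- as.numeric(1:20)       # offsets by powers of two stay exact
  at <- tost_equivalence(paired_table(xi, xi + 0.5), margin = 0.9)
  expect_true(at$degenerate)
  expect_true(at$equivalent)
  expect_false(tost_equivalence(paired_table(xi, xi + 1.25),
                                margin = 0.9)$equivalent)
  # mean difference exactly at the margin: binding t is 0, p = 0.5
  noise <- rnorm(50, 0, 0.3)
  d3 <- noise - mean(noise) + 0.9
  at3 <- tost_equivalence(paired_table(x, x + d3), margin = 0.9)
  expect_equal(at3$p, 0.5, tolerance = 1e-12)
  # symmetry: sign-flipping all differences leaves p unchanged
  flip <- tost_equivalence(paired_table(x, x - (y - x)), margin = 0.9)
  expect_equal(flip$p, eq$p, tolerance = 1e-12)
})

test_that("abnormality classification is boundary-inclusive", {
  thr <- abnormality_thresholds()
  expect_equal(thr$stress_mbf_le, 2.3)
  expect_equal(thr$mpr_le, 2.5)
  expect_true(classify_abnormal(2.3, thr$stress_mbf_le))
  expect_false(classify_abnormal(2.31, thr$stress_mbf_le))
  set.seed(31)
  v <- runif(100, 1, 4)
  expect_equal(classify_abnormal(v, 2.3), v <= 2.3)
})

test_that("ROC AUC equals the exhaustive pairwise-comparison count", {
  # perfect separation (lower = abnormal)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(c(1, 1.2, 3, 4), lab, "lower")$auc, 1)
  # ties get half credit, against the brute-force oracle
  s <- c(1, 2, 2, 3, 2, 4)
  l <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  got <- roc_auc(s, l, "lower")
  expect_equal(got$auc, auc_bruteforce(s, l, "lower"), tolerance = 1e-12)
  # agrees with the field-standard implementation
  skip_if_not_installed("pROC")
  set.seed(37)
  sc <- rnorm(60, 2.8, 0.9); lb <- sc + rnorm(60, 0, 0.8) <= 2.3
  mine <- roc_auc(sc, lb, "lower")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, direction = ">",
                                        quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-12)
  # orientation identity for tie-free scores
  expect_equal(roc_auc(sc, lb, "lower")$auc + roc_auc(-sc, lb, "lower")$auc,
               1, tolerance = 1e-12)
  expect_error(roc_auc(sc, rep(TRUE, 60)), "both classes")
})

test_that("label-independent scores give AUC near one half", {
  set.seed(41)
  sc <- rnorm(4000)
  lb <- rep(c(TRUE, FALSE), 2000)
  expect_equal(roc_auc(sc, lb, "lower")$auc, 0.5, tolerance = 0.03)
})

test_that("DeLong test handles identity, monotone transforms, and real contrasts", {
  set.seed(43)
  truth <- rnorm(60, 2.8, 0.9)
  lb <- truth <= 2.3
  sa <- truth + rnorm(60, 0, 0.5)
  ident <- delong_test(sa, sa, lb)
  expect_true(ident$degenerate)
  expect_equal(ident$p, 1)
  mono <- delong_test(sa, exp(sa / 2), lb)   # rank-preserving transform
  expect_equal(mono$auc_a, mono$auc_b)
  expect_equal(mono$p, 1)
  sb <- truth + rnorm(60, 0, 1.1)
  got <- delong_test(sa, sb, lb)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(lb, sa, direction = ">", quiet = TRUE)
  rb <- pROC::roc(lb, sb, direction = ">", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong")
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
})

test_that("ICC sample size reproduces the planning computation and is monotone", {
  expect_equal(icc_sample_size(0.20, 0.60, 0.05, 0.80, 2), 34L)
  # larger anticipated ICC, smaller study
  ns <- sapply(c(0.4, 0.5, 0.6, 0.7, 0.8), function(a)
    icc_sample_size(0.20, a))
  expect_true(all(diff(ns) < 0))
  # more power, bigger study
  expect_gt(icc_sample_size(0.20, 0.60, power = 0.90),
            icc_sample_size(0.20, 0.60, power = 0.80))
  expect_error(icc_sample_size(0.6, 0.2), "icc_null")
})

test_that("equivalence margins carry the pre-specified criteria", {
  m <- equivalence_margins()
  expect_equal(m$mbf_participant, 0.90)
  expect_equal(m$mpr_participant, 0.98)
  expect_equal(m$stress_mbf_vessel_segment, 1.43)
  expect_equal(m$mpr_vessel_segment, 2.80)
})
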