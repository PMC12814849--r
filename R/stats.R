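#' Pearson correlation with ordinary linear regression
#'
#' Product-moment correlation between the reference (`x`, PET) and test
#' (`y`, CMR) values, with the two-sided t-transform p-value, plus the
#' ordinary least-squares regression of y on x.
#'
#' @param pairs A [paired_table()] (or data.frame with columns `x`, `y`), or
#'   the reference vector when `y` is given.
#' @param y Test values (when `pairs` is a vector).
#' @return List: `r`, `p`, `slope`, `intercept`, `n`.
#' @export
pearson_regression <- function(pairs, y = NULL) {
  d <- .as_xy(pairs, y)
  n <- length(d$x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::var(d$x) == 0) stop("reference values have zero variance")
  r <- stats::cor(d$x, d$y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  slope <- stats::cov(d$x, d$y) / stats::var(d$x)
  list(r = r, p = p, slope = slope,
       intercept = mean(d$y) - slope * mean(d$x), n = n)
}

#' Bland-Altman agreement
#'
#' Mean and spread of the paired differences `d = y - x` with 95% limits of
#' agreement `bias +/- 1.96 sd`.
#'
#' @inheritParams pearson_regression
#' @return List: `bias`, `sd`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(pairs, y = NULL) {
  d <- .as_xy(pairs, y)
  if (length(d$x) < 3) stop("need at least 3 pairs")
  diffs <- d$y - d$x
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  list(bias = bias, sd = s, loa_low = bias - 1.96 * s,
       loa_high = bias + 1.96 * s, n = length(diffs))
}

#' Absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation (McGraw-Wong ICC(A,1), often written ICC(2,1)), computed from
#' the two-way ANOVA mean squares, with the F-based confidence interval
#' (Satterthwaite degrees of freedom). Unlike consistency forms, absolute
#' agreement penalises a systematic offset between the methods, which is
#' what method interchangeability requires.
#'
#' Interpretation bands: below 0.50 poor, 0.50-0.75 moderate (both
#' boundaries inclusive), above 0.75 up to 0.90 good (0.90 inclusive),
#' above 0.90 excellent.
#'
#' @inheritParams pearson_regression
#' @param conf Confidence level for the interval.
#' @return List: `icc`, `ci_low`, `ci_high`, `interpretation`, `n`, and the
#'   mean squares `msr`, `msc`, `mse`.
#' @export
icc_agreement <- function(pairs, y = NULL, conf = 0.95) {
  d <- .as_xy(pairs, y)
  n <- length(d$x)
  if (n < 5) stop("need at least 5 pairs")
  k <- 2
  m <- cbind(d$x, d$y)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr <= .Machine$double.eps * max(1, abs(grand))) {
    warning("zero between-subject variance; ICC degenerate")
    return(list(icc = 0, ci_low = NA_real_, ci_high = NA_real_,
                interpretation = "poor", n = n,
                msr = msr, msc = msc, mse = mse))
  }
  icc <- (msr - mse) / denom

  alpha <- 1 - conf
  if (mse <= 0 && msc <= 0) {        # arms identical: exact agreement
    ci <- c(1, 1)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    nu <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, nu)
    f_u <- stats::qf(1 - alpha / 2, nu, n - 1)
    ci <- c(
      n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr),
      n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr))
  }
  interp <- if (icc < 0.50) "poor" else if (icc <= 0.75) "moderate" else
    if (icc <= 0.90) "good" else "excellent"
  list(icc = icc, ci_low = ci[1], ci_high = ci[2],
       interpretation = interp, n = n, msr = msr, msc = msc, mse = mse)
}

#' Equivalence margins
#'
#' The pre-specified equivalence criteria, derived from the interstudy
#' variability of PET MBF measurements: 0.90 mL/min/g for MBF and 0.98 for
#' MPR at the participant level; 1.43 for stress MBF and 2.80 for MPR at
#' the vessel and segment levels.
#'
#' @return Named list of margins.
#' @export
equivalence_margins <- function() {
  list(mbf_participant = 0.90, mpr_participant = 0.98,
       stress_mbf_vessel_segment = 1.43, mpr_vessel_segment = 2.80)
}

#' Paired TOST equivalence test
#'
#' Two one-sided paired t-tests of the null hypotheses that the true mean
#' difference lies beyond -margin (lower test) or +margin (upper test);
#' both must reject for equivalence, so the reported p is the greater of
#' the two one-sided p-values and equivalence is declared at p < 0.05.
#'
#' @inheritParams pearson_regression
#' @param margin Equivalence margin (> 0), e.g. from
#'   [equivalence_margins()].
#' @param alpha Significance level for the equivalence call.
#' @return List: `p`, `p_lower`, `p_upper`, `t_lower`, `t_upper`, `df`,
#'   `mean_diff`, `equivalent`, `degenerate`.
#' @export
tost_equivalence <- function(pairs, y = NULL, margin, alpha = 0.05) {
  d <- .as_xy(pairs, y)
  if (margin <= 0) stop("margin must be > 0")
  n <- length(d$x)
  if (n < 3) stop("need at least 3 pairs")
  diffs <- d$y - d$x
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (s == 0) {
    eq <- abs(m) < margin
    return(list(p = if (eq) 0 else 1, p_lower = NA_real_,
                p_upper = NA_real_, t_lower = NA_real_, t_upper = NA_real_,
                df = n - 1, mean_diff = m, equivalent = eq,
                degenerate = TRUE))
  }
  se <- s / sqrt(n)
  t_lower <- (m + margin) / se     # H0: mu <= -margin vs Ha: mu > -margin
  t_upper <- (m - margin) / se     # H0: mu >= +margin vs Ha: mu < +margin
  p_lower <- stats::pt(t_lower, df = n - 1, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df = n - 1, lower.tail = TRUE)
  p <- max(p_lower, p_upper)
  list(p = p, p_lower = p_lower, p_upper = p_upper,
       t_lower = t_lower, t_upper = t_upper, df = n - 1, mean_diff = m,
       equivalent = p < alpha, degenerate = FALSE)
}

#' PET abnormality thresholds
#'
#' Reference-standard cut-offs for abnormal myocardial perfusion on
#' 15-O-water PET: stress MBF at or below 2.3 mL/min/g, MPR at or below
#' 2.5.
#'
#' @return Named list of thresholds.
#' @export
abnormality_thresholds <- function() {
  list(stress_mbf_le = 2.3, mpr_le = 2.5)
}

#' Classify abnormal perfusion
#'
#' Abnormal if and only if the value is at or below the threshold
#' (boundary inclusive).
#'
#' @param values Numeric PET values (stress MBF or MPR).
#' @param threshold Cut-off; abnormal when `value <= threshold`.
#' @return Logical vector, `TRUE` = abnormal.
#' @export
classify_abnormal <- function(values, threshold) {
  stopifnot(all(is.finite(values)))
  values <= threshold
}

#' ROC curve and AUC by the Mann-Whitney statistic
#'
#' Area under the ROC curve computed as the Mann-Whitney probability that a
#' randomly chosen abnormal case scores on the abnormal side of a randomly
#' chosen normal case, with ties credited 1/2. The orientation is explicit:
#' with `direction = "lower"` (the perfusion convention) a LOWER score
#' predicts abnormality; nothing is auto-flipped.
#'
#' @param scores Numeric scores (e.g. CMR stress MBF).
#' @param labels Logical (or 0/1) abnormality labels.
#' @param direction `"lower"` if low scores indicate abnormality,
#'   `"higher"` otherwise.
#' @return List: `auc`, `roc` (data.frame threshold/tpr/fpr), `direction`,
#'   `n_abnormal`, `n_normal`.
#' @export
roc_auc <- function(scores, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  s <- if (direction == "lower") -scores else scores
  pos <- s[labels]; neg <- s[!labels]
  rk <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(rk[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  roc <- data.frame(
    threshold = if (direction == "lower") -thr else thr,
    tpr = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)))
  list(auc = auc, roc = roc, direction = direction,
       n_abnormal = length(pos), n_normal = length(neg))
}

# DeLong placement values for one score vector (already oriented so that
# higher = abnormal).
.delong_placements <- function(s, labels) {
  pos <- s[labels]; neg <- s[!labels]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(pos, function(a) mean(psi(a, neg)), numeric(1))
  v01 <- vapply(neg, function(b) mean(psi(pos, b)), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two score sets measured on the
#' same cases, using the DeLong placement-value covariance and a two-sided
#' normal reference. A zero-variance AUC difference (e.g. identical or
#' rank-identical scores) is reported as p = 1 with a degeneracy flag.
#'
#' @param scores_a,scores_b Two score vectors on the same cases.
#' @param labels Logical abnormality labels shared by both.
#' @param direction Orientation, as in [roc_auc()].
#' @return List: `auc_a`, `auc_b`, `z`, `p`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  sa <- if (direction == "lower") -scores_a else scores_a
  sb <- if (direction == "lower") -scores_b else scores_b
  pa <- .delong_placements(sa, labels)
  pb <- .delong_placements(sb, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::var(pa$v10 - pb$v10)
  s01 <- stats::var(pa$v01 - pb$v01)
  v <- s10 / m + s01 / n
  d <- pa$auc - pb$auc
  if (v <= 0) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0,
                p = 1, degenerate = TRUE))
  }
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' ICC-based sample size
#'
#' Smallest number of subjects for which a study with `raters` repeated
#' measurements detects an intraclass correlation `icc_alt` against the
#' null `icc_null` with the stated power, by the Walter-Eliasziw-Donner
#' approximation:
#' `n = 1 + 2 k (z_{a/2} + z_b)^2 / ((k - 1) ln(C0)^2)` with
#' `C0 = F(icc_null) / F(icc_alt)`, `F(r) = (1 + (k-1) r) / (1 - r)`,
#' ceiling-rounded.
#'
#' @param icc_null Null-hypothesis ICC, in `[0, icc_alt)`.
#' @param icc_alt Anticipated ICC, in `(icc_null, 1)`.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param raters Number of repeated measurements per subject (>= 2).
#' @return Integer sample size.
#' @export
icc_sample_size <- function(icc_null, icc_alt, alpha = 0.05, power = 0.80,
                            raters = 2) {
  k <- raters
  if (k < 2) stop("raters must be >= 2")
  if (!(icc_null >= 0 && icc_null < icc_alt && icc_alt < 1))
    stop("need 0 <= icc_null < icc_alt < 1")
  fr <- function(r) (1 + (k - 1) * r) / (1 - r)
  c0 <- fr(icc_null) / fr(icc_alt)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  as.integer(ceiling(1 + 2 * k * (za + zb)^2 / ((k - 1) * log(c0)^2)))
}
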