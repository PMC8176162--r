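#' Empirical ROC curve with Hanley-McNeil inference
#'
#' Builds the empirical ROC curve of a continuous predictor against a binary
#' responder label. The positive-call convention is "score strictly greater
#' than the cutoff": at cutoff c, sensitivity = P(score > c | responder) and
#' specificity = P(score <= c | non-responder). Thresholds are the distinct
#' observed score values with a -Inf endpoint, so the curve runs from
#' (Se 1, Sp 0) to (Se 0, Sp 1). The AUC is computed by the trapezoidal rule
#' over the curve, which for the empirical ROC equals the tie-corrected
#' Mann-Whitney statistic U/(n_pos * n_neg) (ties count one half). The
#' standard error is the Hanley-McNeil closed form, the 95% CI is the normal
#' interval truncated to \[0, 1\], and `p_vs_null` tests AUC = 0.5 using the
#' Hanley-McNeil SE under the null.
#'
#' @param scores Numeric predictor values, one per patient.
#' @param labels Logical (or 0/1) responder indicator, same length.
#' @param predictor Name used in printing/reports.
#' @param conf_level Confidence level for the AUC CI (default 0.95).
#' @return An object of class `roc_curve`: list with `predictor`,
#'   `thresholds`, `sensitivity`, `specificity`, `auc`, `se_auc`, `ci`,
#'   `p_vs_null`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- empirical_roc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
#' r$auc # 0.75
empirical_roc <- function(scores, labels,
                          predictor = deparse(substitute(scores)),
                          conf_level = 0.95) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- as.numeric(sum(labels))
  n_neg <- as.numeric(sum(!labels))
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to build a ROC curve")
  pos <- sort(scores[labels])
  neg <- sort(scores[!labels])
  thr <- c(-Inf, sort(unique(scores)))
  # P(score > c) per class via counts of values <= c
  se <- 1 - findInterval(thr, pos) / n_pos
  sp <- findInterval(thr, neg) / n_neg
  auc <- trapezoid_auc(se, sp)
  se_auc <- hanley_mcneil_se(clamp_auc(auc, n_pos, n_neg), n_pos, n_neg)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se_auc), min(1, auc + z * se_auc))
  se_null <- hanley_mcneil_se(0.5, n_pos, n_neg)
  p_null <- 2 * stats::pnorm(-abs((auc - 0.5) / se_null))
  structure(list(predictor = predictor, thresholds = thr,
                 sensitivity = se, specificity = sp,
                 auc = auc, se_auc = se_auc, ci = ci,
                 conf_level = conf_level, p_vs_null = p_null,
                 n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = labels),
            class = "roc_curve")
}

# trapezoid over (FPR, TPR); points ordered by increasing threshold, i.e.
# decreasing FPR, so integrate in reverse
trapezoid_auc <- function(se, sp) {
  fpr <- 1 - sp
  o <- order(fpr, se)
  fpr <- fpr[o]
  tpr <- se[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# HM SE is undefined at the boundary; nudge a degenerate empirical AUC
# inward by half a concordance step
clamp_auc <- function(auc, n_pos, n_neg) {
  eps <- 0.5 / (n_pos * n_neg)
  min(max(auc, eps), 1 - eps)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: %s  (n+ = %g, n- = %g)\n", x$predictor, x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.3f  SE %.3f  %d%% CI %.3f-%.3f  p(vs 0.5) %.3g\n",
              x$auc, x$se_auc, round(100 * x$conf_level),
              x$ci[1], x$ci[2], x$p_vs_null))
  invisible(x)
}

#' Hanley-McNeil standard error of an empirical AUC
#'
#' SE(theta) = sqrt((theta(1-theta) + (n_pos-1)(Q1-theta^2)
#' + (n_neg-1)(Q2-theta^2)) / (n_pos n_neg)) with Q1 = theta/(2-theta) and
#' Q2 = 2 theta^2/(1+theta), the exponential-model approximation to the
#' variance of the Wilcoxon statistic.
#'
#' @param auc AUC estimate theta, strictly inside (0, 1).
#' @param n_pos,n_neg Class sizes.
#' @return Standard error.
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  if (any(auc <= 0 | auc >= 1))
    stop("`auc` must lie strictly inside (0, 1)")
  if (n_pos < 1 || n_neg < 1) stop("class sizes must be positive")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Confidence interval for an AUC
#'
#' Normal interval `auc +/- z * SE` with the Hanley-McNeil SE, truncated to
#' \[0, 1\].
#'
#' @param curve A [empirical_roc()] result.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
auc_ci <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "roc_curve"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(max(0, curve$auc - z * curve$se_auc),
    min(1, curve$auc + z * curve$se_auc))
}

#' Compare two AUCs by the Hanley-McNeil z-test
#'
#' z = (AUC_a - AUC_b) / sqrt(SE_a^2 + SE_b^2 - 2 r SE_a SE_b), two-sided
#' normal p. For unpaired curves r = 0 (two independent AUCs). For paired
#' curves (the same patients scored by two predictors) r is estimated as the
#' average of the within-class Spearman rank correlations between the two
#' predictors — the quantity Hanley and McNeil's correlation table is
#' entered with; see the methods vignette for why the table lookup is
#' replaced by this direct estimate. [permutation_auc_test()] provides a
#' resampling cross-check.
#'
#' @param curve_a,curve_b [empirical_roc()] results. For a paired
#'   comparison both must have been built from the same patients in the
#'   same order (identical labels).
#' @param paired Logical; default `FALSE`.
#' @return An `auc_comparison`: list with `auc_a`, `auc_b`,
#'   `correlation_r`, `z_statistic`, `p_value`.
#' @export
compare_aucs <- function(curve_a, curve_b, paired = FALSE) {
  stopifnot(inherits(curve_a, "roc_curve"), inherits(curve_b, "roc_curve"))
  if (paired) {
    if (is.null(curve_a$scores) || is.null(curve_b$scores))
      stop("paired comparison needs the per-patient scores on both curves")
    if (!identical(curve_a$labels, curve_b$labels))
      stop("paired comparison requires identical labels on both curves")
    lab <- curve_a$labels
    r_pos <- suppressWarnings(
      stats::cor(curve_a$scores[lab], curve_b$scores[lab],
                 method = "spearman"))
    r_neg <- suppressWarnings(
      stats::cor(curve_a$scores[!lab], curve_b$scores[!lab],
                 method = "spearman"))
    r <- mean(c(r_pos, r_neg), na.rm = TRUE)
    if (is.nan(r)) r <- 0
  } else {
    r <- 0
  }
  num <- curve_a$auc - curve_b$auc
  den <- sqrt(max(0, curve_a$se_auc^2 + curve_b$se_auc^2 -
                    2 * r * curve_a$se_auc * curve_b$se_auc))
  z <- if (den < 1e-12) {
    if (abs(num) < 1e-12) 0 else sign(num) * Inf
  } else num / den
  structure(list(auc_a = curve_a$auc, auc_b = curve_b$auc,
                 correlation_r = r, z_statistic = z,
                 p_value = 2 * stats::pnorm(-abs(z))),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC %.3f vs %.3f  (r = %.2f)  z = %.3f  p = %.4g\n",
              x$auc_a, x$auc_b, x$correlation_r, x$z_statistic, x$p_value))
  invisible(x)
}

#' Permutation test for a paired AUC difference
#'
#' Resampling cross-check for [compare_aucs()]: under the null that the two
#' predictors are exchangeable, each patient's pair of scores is swapped
#' independently with probability one half; the two-sided p-value is the
#' fraction of permuted |AUC differences| at least as large as observed
#' (with the +1 correction).
#'
#' @param scores_a,scores_b Paired predictor values.
#' @param labels Responder indicator.
#' @param B Number of permutations (default 2000).
#' @param seed Optional seed.
#' @return List with `observed` difference and `p_value`.
#' @export
permutation_auc_test <- function(scores_a, scores_b, labels, B = 2000,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.logical(labels)
  obs <- auc_statistic(scores_a, labels) - auc_statistic(scores_b, labels)
  n <- length(labels)
  exceed <- 0L
  for (b in seq_len(B)) {
    swap <- stats::runif(n) < 0.5
    a <- ifelse(swap, scores_b, scores_a)
    bb <- ifelse(swap, scores_a, scores_b)
    d <- auc_statistic(a, labels) - auc_statistic(bb, labels)
    if (abs(d) >= abs(obs) - 1e-12) exceed <- exceed + 1L
  }
  list(observed = obs, p_value = (exceed + 1) / (B + 1))
}

# tie-corrected Mann-Whitney AUC, rank-based (fast path, no curve object)
auc_statistic <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- as.numeric(sum(labels))
  n_neg <- as.numeric(sum(!labels))
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-optimal operating point of a ROC curve
#'
#' Selects the cutoff maximizing Youden's J = sensitivity + specificity - 1
#' (ties broken toward the smallest cutoff) and reports the operating-point
#' statistics there: sensitivity, specificity, positive and negative
#' predictive value (at the sample prevalence), each in percent with a Wald
#' 95% CI `p +/- 1.96 sqrt(p(1-p)/n)` truncated to \[0, 100\].
#'
#' @param curve A [empirical_roc()] result.
#' @return An `operating_point`: list with `cutoff`, `youden_j`, and for
#'   each of `sensitivity`, `specificity`, `ppv`, `npv` a vector
#'   `c(estimate, low, high)` in percent (NA when the denominator is zero),
#'   plus the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j > max(j) - 1e-12)[1]
  cutoff <- curve$thresholds[best]
  pos <- curve$scores[curve$labels]
  neg <- curve$scores[!curve$labels]
  tp <- sum(pos > cutoff)
  fn <- curve$n_pos - tp
  fp <- sum(neg > cutoff)
  tn <- curve$n_neg - fp
  structure(list(cutoff = cutoff,
                 youden_j = j[best],
                 sensitivity = wald_percent(tp, curve$n_pos),
                 specificity = wald_percent(tn, curve$n_neg),
                 ppv = wald_percent(tp, tp + fp),
                 npv = wald_percent(tn, tn + fn),
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "operating_point")
}

# Wald CI on the percent scale, truncated to [0, 100]; NA on empty denominator
wald_percent <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(estimate = NA_real_, low = NA_real_, high = NA_real_))
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(estimate = 100 * p,
    low = max(0, 100 * (p - half)),
    high = min(100, 100 * (p + half)))
}

#' @export
print.operating_point <- function(x, ...) {
  fmt <- function(v) if (anyNA(v)) "NA" else
    sprintf("%.0f (%.0f-%.0f)", v[1], v[2], v[3])
  cat(sprintf("cutoff > %g  J = %.2f\n", x$cutoff, x$youden_j))
  cat(sprintf("  Se %s  Sp %s  PPV %s  NPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' Predictive values from an operating point
#'
#' Positive and negative predictive values at the sample prevalence, from
#' the confusion counts implied by sensitivity, specificity and the class
#' sizes: PPV = TP/(TP+FP), NPV = TN/(TN+FN), with Wald 95% CIs in percent.
#' A zero denominator yields NA, never 0.
#'
#' @param sensitivity,specificity Fractions in \[0, 1\].
#' @param n_pos,n_neg Class sizes.
#' @return List with `ppv` and `npv`, each `c(estimate, low, high)` in
#'   percent.
#' @export
predictive_values <- function(sensitivity, specificity, n_pos, n_neg) {
  tp <- sensitivity * n_pos
  fn <- n_pos - tp
  tn <- specificity * n_neg
  fp <- n_neg - tn
  list(ppv = wald_percent(tp, tp + fp),
       npv = wald_percent(tn, tn + fn))
}

#' Sample size for detecting an AUC above a null value
#'
#' Smallest per-group size n such that the Hanley-McNeil inequality
#' `|auc_alt - auc_null| >= z_alpha * SE0 + z_power * SE1` holds, where SE0
#' is the Hanley-McNeil SE at the null AUC and SE1 at the alternative, both
#' evaluated at the candidate group sizes (`n_neg = ceiling(allocation *
#' n_pos)`). `z_alpha` uses alpha/2 for a two-sided test.
#'
#' @param auc_alt Alternative-hypothesis AUC.
#' @param auc_null Null AUC (default 0.5).
#' @param alpha Type I error (default 0.05).
#' @param power Desired power (default 0.90).
#' @param allocation Ratio n_neg / n_pos (default 1).
#' @param sided 1 or 2 (default 2).
#' @return List with `n_pos`, `n_neg`, `total`.
#' @export
#' @examples
#' sample_size_auc(0.8) # n_pos 17, total 34
sample_size_auc <- function(auc_alt, auc_null = 0.5, alpha = 0.05,
                            power = 0.90, allocation = 1.0, sided = 2) {
  if (!sided %in% c(1, 2)) stop("`sided` must be 1 or 2")
  if (auc_alt == auc_null)
    stop("auc_alt equals auc_null: no finite sample size detects a null ",
         "effect")
  z_a <- stats::qnorm(1 - alpha / sided)
  z_b <- stats::qnorm(power)
  delta <- abs(auc_alt - auc_null)
  for (n_pos in 2:100000) {
    n_neg <- ceiling(allocation * n_pos)
    se0 <- hanley_mcneil_se(auc_null, n_pos, n_neg)
    se1 <- hanley_mcneil_se(auc_alt, n_pos, n_neg)
    if (delta >= z_a * se0 + z_b * se1)
      return(list(n_pos = n_pos, n_neg = n_neg, total = n_pos + n_neg))
  }
  stop("no sample size up to 100000 per group satisfies the inequality")
}
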