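#' Compare a variable between responders and non-responders
#'
#' Test selection follows standard two-group reporting practice:
#' continuous variables are screened for normality per group (Shapiro-Wilk
#' at alpha = 0.05) and compared by Student's t-test (equal variances) when
#' both groups pass, by the Mann-Whitney U test otherwise; categorical
#' variables use the chi-square test without continuity correction unless
#' any expected cell count falls below 5, in which case Fisher's exact test
#' is substituted. `force_test` overrides the automatic choice.
#'
#' @param cohort Cohort data frame with a `group` column
#'   (`"responder"`/`"nonresponder"`).
#' @param variable Column name to compare.
#' @param type `"auto"` (numeric means continuous), `"continuous"` or
#'   `"categorical"`.
#' @param force_test Optional: one of `"students_t"`, `"mann_whitney"`,
#'   `"chi_square"`, `"fisher_exact"` to bypass the selection rule.
#' @return A `comparison_result`: list with `variable`, `test_used`,
#'   `statistic`, `p_value`, and per-group `summaries` (mean, sd, median,
#'   IQR for continuous; counts for categorical).
#' @export
compare_between_groups <- function(cohort, variable,
                                   type = c("auto", "continuous",
                                            "categorical"),
                                   force_test = NULL) {
  type <- match.arg(type)
  if (!variable %in% names(cohort)) stop("no column '", variable, "'")
  x <- cohort[[variable]]
  g <- cohort$group
  if (all(is.na(x))) stop("variable '", variable, "' is entirely missing")
  if (type == "auto")
    type <- if (is.numeric(x)) "continuous" else "categorical"

  if (type == "continuous") {
    a <- x[g == "responder"]
    b <- x[g == "nonresponder"]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    normal <- function(v) {
      if (length(v) < 3 || stats::sd(v) == 0) return(TRUE)
      stats::shapiro.test(v)$p.value >= 0.05
    }
    test <- if (!is.null(force_test)) force_test
            else if (normal(a) && normal(b)) "students_t" else "mann_whitney"
    if (test == "students_t") {
      ht <- stats::t.test(a, b, var.equal = TRUE)
    } else if (test == "mann_whitney") {
      ht <- suppressWarnings(stats::wilcox.test(a, b))
    } else stop("unknown continuous test '", test, "'")
    summaries <- lapply(list(responder = a, nonresponder = b), function(v)
      list(n = length(v), mean = mean(v), sd = stats::sd(v),
           median = stats::median(v),
           q1 = unname(stats::quantile(v, 0.25)),
           q3 = unname(stats::quantile(v, 0.75))))
  } else {
    tab <- table(factor(g, levels = c("responder", "nonresponder")), x)
    exp_counts <- suppressWarnings(stats::chisq.test(tab)$expected)
    test <- if (!is.null(force_test)) force_test
            else if (any(exp_counts < 5)) "fisher_exact" else "chi_square"
    if (test == "chi_square") {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    } else if (test == "fisher_exact") {
      ht <- stats::fisher.test(tab)
    } else stop("unknown categorical test '", test, "'")
    summaries <- list(table = tab)
  }
  structure(list(variable = variable, test_used = test,
                 statistic = unname(if (!is.null(ht$statistic))
                   ht$statistic else NA_real_),
                 p_value = ht$p.value, summaries = summaries),
            class = "comparison_result")
}

#' Compare a variable within a group before and after an intervention
#'
#' Paired pre/post comparison (e.g. before and after the PEEP challenge, or
#' before and after fluid loading): the paired t-test when the per-patient
#' differences pass the Shapiro-Wilk normality screen (alpha = 0.05), the
#' Wilcoxon signed-rank test otherwise. The reported change summary is the
#' mean and SD of (after - before).
#'
#' @param cohort Cohort data frame.
#' @param variable Variable stem, e.g. `"PPV"`; columns
#'   `<variable>_<t_before>` and `<variable>_<t_after>` must exist.
#' @param t_before,t_after Time-point labels, e.g. `"T1"`, `"T2"`.
#' @param group Optional: restrict to `"responder"` or `"nonresponder"`.
#' @param force_test Optional `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @return A `comparison_result` with the change summary in
#'   `summaries$change`.
#' @export
compare_within_group <- function(cohort, variable, t_before, t_after,
                                 group = NULL, force_test = NULL) {
  cb <- paste0(variable, "_", t_before)
  ca <- paste0(variable, "_", t_after)
  miss <- setdiff(c(cb, ca), names(cohort))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!is.null(group)) cohort <- cohort[cohort$group == group, , drop = FALSE]
  before <- cohort[[cb]]
  after <- cohort[[ca]]
  keep <- !is.na(before) & !is.na(after)
  before <- before[keep]
  after <- after[keep]
  if (length(before) < 2) stop("need at least two paired observations")
  d <- after - before
  normal <- if (stats::sd(d) == 0) TRUE
            else stats::shapiro.test(d)$p.value >= 0.05
  test <- if (!is.null(force_test)) force_test
          else if (normal) "paired_t" else "wilcoxon_signed_rank"
  if (test == "paired_t") {
    ht <- if (stats::sd(d) == 0)
      list(statistic = 0, p.value = 1)  # identical pre/post: no change
    else stats::t.test(after, before, paired = TRUE)
  } else if (test == "wilcoxon_signed_rank") {
    ht <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE))
    if (is.na(ht$p.value)) ht$p.value <- 1  # all differences zero
  } else stop("unknown paired test '", test, "'")
  structure(list(variable = variable, test_used = test,
                 t_before = t_before, t_after = t_after, group = group,
                 statistic = unname(if (!is.null(ht$statistic))
                   ht$statistic else NA_real_),
                 p_value = ht$p.value,
                 summaries = list(
                   before = list(mean = mean(before), sd = stats::sd(before)),
                   after = list(mean = mean(after), sd = stats::sd(after)),
                   change = list(mean = mean(d), sd = stats::sd(d)))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s, p = %.4g\n", x$variable, x$test_used, x$p_value))
  invisible(x)
}

#' Table of within-group changes for every variable at two time points
#'
#' Convenience wrapper producing a published-style change table: for each
#' variable stem present at both time points and each group, the pre/post
#' summaries, the mean change and the paired p-value.
#'
#' @inheritParams compare_within_group
#' @param variables Character vector of variable stems; default: every stem
#'   with both columns present.
#' @return Data frame with one row per (variable, group).
#' @export
change_table <- function(cohort, t_before, t_after, variables = NULL) {
  if (is.null(variables)) {
    stems <- sub(paste0("_", t_before, "$"), "",
                 grep(paste0("_", t_before, "$"), names(cohort),
                      value = TRUE))
    variables <- stems[paste0(stems, "_", t_after) %in% names(cohort)]
  }
  rows <- list()
  for (v in variables) {
    for (g in c("responder", "nonresponder")) {
      r <- compare_within_group(cohort, v, t_before, t_after, group = g)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = g,
        mean_before = r$summaries$before$mean,
        sd_before = r$summaries$before$sd,
        mean_after = r$summaries$after$mean,
        sd_after = r$summaries$after$sd,
        mean_change = r$summaries$change$mean,
        sd_change = r$summaries$change$sd,
        test = r$test_used, p_value = r$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' ROC summary table for a set of predictors
#'
#' One row per predictor in published diagnostic-table style: AUC with CI
#' and p-value against 0.5, the Youden-optimal cutoff and the
#' operating-point Se/Sp/PPV/NPV with Wald CIs (percent).
#'
#' @param cohort Cohort data frame with a logical `responder` column.
#' @param predictors Character vector of score columns; defaults to the six
#'   dynamic-index predictors `PPV_T1`, `PPV_T2`, `delta_ppv`, `SVV_T1`,
#'   `SVV_T2`, `delta_svv`.
#' @return Data frame, one row per predictor.
#' @export
roc_table <- function(cohort,
                      predictors = c("PPV_T1", "PPV_T2", "delta_ppv",
                                     "SVV_T1", "SVV_T2", "delta_svv")) {
  if (!"responder" %in% names(cohort))
    stop("cohort has no responder column; run classify_responder() first")
  miss <- setdiff(predictors, names(cohort))
  if (length(miss)) stop("missing predictors: ", paste(miss, collapse = ", "))
  rows <- lapply(predictors, function(p) {
    curve <- empirical_roc(cohort[[p]], cohort$responder, predictor = p)
    op <- youden_cutoff(curve)
    data.frame(predictor = p, auc = curve$auc, se_auc = curve$se_auc,
               ci_low = curve$ci[1], ci_high = curve$ci[2],
               p_vs_null = curve$p_vs_null, cutoff = op$cutoff,
               sens = op$sensitivity[["estimate"]],
               sens_low = op$sensitivity[["low"]],
               sens_high = op$sensitivity[["high"]],
               spec = op$specificity[["estimate"]],
               spec_low = op$specificity[["low"]],
               spec_high = op$specificity[["high"]],
               ppv = op$ppv[["estimate"]], ppv_low = op$ppv[["low"]],
               ppv_high = op$ppv[["high"]],
               npv = op$npv[["estimate"]], npv_low = op$npv[["low"]],
               npv_high = op$npv[["high"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
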