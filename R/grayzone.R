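#' Bootstrap distribution of Youden-optimal cutoffs
#'
#' Resamples patients with replacement, stratified by responder status
#' (every replicate keeps the original class sizes, so no replicate can lose
#' a class), and recomputes the Youden-optimal cutoff of the resampled ROC
#' curve. The spread of these cutoffs is the basis of the bootstrap gray
#' zone.
#'
#' @param scores Numeric predictor values.
#' @param labels Responder indicator.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed; fixed seed gives bit-identical output.
#' @return Numeric vector of B optimal cutoffs.
#' @export
bootstrap_thresholds <- function(scores, labels, B = 1000, seed = NULL) {
  if (B < 1) stop("`B` must be at least 1")
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg))
    stop("both classes must be present")
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(B), function(b) {
    p <- sample(pos, length(pos), replace = TRUE)
    q <- sample(neg, length(neg), replace = TRUE)
    curve <- empirical_roc(c(p, q),
                           rep(c(TRUE, FALSE), c(length(p), length(q))),
                           predictor = "boot")
    youden_cutoff(curve)$cutoff
  }, numeric(1))
}

#' Gray zone from the bootstrap cutoff distribution
#'
#' The inconclusive range is the central (by default 95%) interval of the
#' bootstrap distribution of optimal cutoffs: the 2.5th and 97.5th
#' percentiles, computed with the linear-interpolation quantile definition
#' (R type 7).
#'
#' @param thresholds Bootstrap cutoffs from [bootstrap_thresholds()].
#' @param level Central coverage of the interval (default 0.95).
#' @return A `gray_zone` object (method `"bootstrap_ci"`).
#' @export
gray_zone_from_bootstrap <- function(thresholds, level = 0.95) {
  if (!length(thresholds)) stop("no bootstrap thresholds supplied")
  a <- (1 - level) / 2
  q <- stats::quantile(thresholds, c(a, 1 - a), names = FALSE, type = 7)
  new_gray_zone("bootstrap_ci", q[1], q[2], n_bootstrap = length(thresholds))
}

#' Gray zone from sensitivity/specificity floors
#'
#' Splits the ROC curve into its sensitivity and specificity branches and
#' declares a cutoff inconclusive when it achieves neither Se >= `se_floor`
#' nor Sp >= `sp_floor`. Since Se is non-increasing and Sp non-decreasing in
#' the cutoff, the zone is the open interval between `low`, the largest
#' cutoff still keeping Se >= `se_floor`, and `high`, the smallest cutoff
#' reaching Sp >= `sp_floor`. If `high <= low` the criteria overlap and the
#' zone is empty (represented as a zero-width interval at the midpoint, so
#' that [count_inside()] counts exact ties only).
#'
#' @param curve A [empirical_roc()] result.
#' @param se_floor,sp_floor Floors in (0, 1\] (defaults 0.90, the usual
#'   "conclusive" requirement).
#' @return A `gray_zone` object (method `"split_curve"`).
#' @export
split_curve_zone <- function(curve, se_floor = 0.90, sp_floor = 0.90) {
  stopifnot(inherits(curve, "roc_curve"))
  if (se_floor <= 0 || se_floor > 1 || sp_floor <= 0 || sp_floor > 1)
    stop("floors must lie in (0, 1]")
  thr <- curve$thresholds
  ok_se <- curve$sensitivity >= se_floor - 1e-12
  ok_sp <- curve$specificity >= sp_floor - 1e-12
  low <- max(thr[ok_se])   # Se non-increasing: last cutoff meeting the floor
  high <- min(thr[ok_sp])  # Sp non-decreasing: first cutoff meeting it
  if (high <= low) {
    mid <- if (is.finite(low) && is.finite(high)) (low + high) / 2
           else if (is.finite(high)) high else low
    new_gray_zone("split_curve", mid, mid, empty = TRUE,
                  se_floor = se_floor, sp_floor = sp_floor)
  } else {
    new_gray_zone("split_curve", low, high,
                  se_floor = se_floor, sp_floor = sp_floor)
  }
}

new_gray_zone <- function(method, low, high, n_bootstrap = NA_integer_,
                          se_floor = NA_real_, sp_floor = NA_real_,
                          empty = FALSE) {
  structure(list(method = method, low = low, high = high,
                 width = high - low, empty = empty,
                 n_bootstrap = n_bootstrap,
                 se_floor = se_floor, sp_floor = sp_floor),
            class = "gray_zone")
}

#' @export
print.gray_zone <- function(x, ...) {
  lab <- if (x$method == "bootstrap_ci")
    sprintf("bootstrap 95%% CI of optimal cutoff (B = %d)", x$n_bootstrap)
  else
    sprintf("Se/Sp floors %.0f%%/%.0f%%", 100 * x$se_floor, 100 * x$sp_floor)
  if (x$empty)
    cat(sprintf("gray zone [%s]: empty (criteria overlap at %g)\n", lab,
                x$low))
  else
    cat(sprintf("gray zone [%s]: %.3g to %.3g (width %.3g)\n", lab,
                x$low, x$high, x$width))
  invisible(x)
}

#' Count patients inside a gray zone
#'
#' Closed-interval membership: patients with `low <= score <= high`. For an
#' empty (zero-width) zone only exact ties with the boundary are counted.
#'
#' @param scores Predictor values for the cohort.
#' @param zone A `gray_zone`.
#' @return Integer count.
#' @export
count_inside <- function(scores, zone) {
  stopifnot(inherits(zone, "gray_zone"))
  sum(scores >= zone$low & scores <= zone$high, na.rm = TRUE)
}

#' Full gray-zone report for one predictor
#'
#' Runs both constructions — the bootstrap CI of optimal thresholds and the
#' sensitivity/specificity split-curve zone — side by side (they answer the
#' same question by different routes and are not merged), together with the
#' number of cohort patients falling inside each.
#'
#' @inheritParams bootstrap_thresholds
#' @param se_floor,sp_floor Floors for the split-curve zone.
#' @return List with `bootstrap` and `split_curve` zones, their inside
#'   counts `n_inside_bootstrap` / `n_inside_split`, and the bootstrap
#'   `thresholds`.
#' @export
gray_zone_report <- function(scores, labels, B = 1000, seed = NULL,
                             se_floor = 0.90, sp_floor = 0.90) {
  thr <- bootstrap_thresholds(scores, labels, B = B, seed = seed)
  bz <- gray_zone_from_bootstrap(thr)
  curve <- empirical_roc(scores, labels, predictor = "predictor")
  sz <- split_curve_zone(curve, se_floor = se_floor, sp_floor = sp_floor)
  list(bootstrap = bz, split_curve = sz,
       n_inside_bootstrap = count_inside(scores, bz),
       n_inside_split = count_inside(scores, sz),
       thresholds = thr)
}
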