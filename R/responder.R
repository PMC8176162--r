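#' Percent change in stroke volume
#'
#' Signed percent change `100 * (sv_after - sv_before) / sv_before`, the
#' quantity the fluid-responder rule is applied to.
#'
#' @param sv_before Stroke volume before fluid loading (mL), positive.
#' @param sv_after Stroke volume after fluid loading (mL).
#' @return Percent change (vectorized).
#' @export
#' @examples
#' percent_sv_change(63.1, 77.2) # +22.3
percent_sv_change <- function(sv_before, sv_after) {
  if (any(!is.na(sv_before) & sv_before <= 0))
    stop("sv_before must be positive")
  100 * (sv_after - sv_before) / sv_before
}

#' Classify fluid responders from the stroke-volume response
#'
#' A patient is a fluid responder if stroke volume increased by at least
#' `threshold` percent after fluid loading (the boundary value exactly at
#' the threshold is a responder), and a non-responder otherwise. The
#' denominator is the pre-loading baseline (T3, after PEEP withdrawal).
#' Patients with a missing stroke volume at either time point are flagged
#' unclassifiable (`responder = NA`) rather than dropped; their count is
#' attached as attribute `n_unclassifiable`.
#'
#' @param cohort Cohort data frame.
#' @param threshold Percent increase defining a responder (default 10).
#' @param sv_before,sv_after Column names holding the stroke volumes
#'   (defaults `"SV_T3"`, `"SV_T4"`).
#' @return The cohort with the `responder` column set (overwritten if
#'   present) and a `sv_change_percent` column added.
#' @export
classify_responder <- function(cohort, threshold = 10,
                               sv_before = "SV_T3", sv_after = "SV_T4") {
  miss <- setdiff(c(sv_before, sv_after), names(cohort))
  if (length(miss))
    stop("cohort is missing stroke-volume columns: ",
         paste(miss, collapse = ", "))
  chg <- percent_sv_change(cohort[[sv_before]], cohort[[sv_after]])
  cohort$sv_change_percent <- chg
  cohort$responder <- chg >= threshold
  n_un <- sum(is.na(cohort$responder))
  if (n_un > 0)
    warning(n_un, " patient(s) unclassifiable (missing stroke volume); ",
            "responder set to NA")
  attr(cohort, "n_unclassifiable") <- n_un
  cohort
}
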