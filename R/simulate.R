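#' Packaged group distribution parameters
#'
#' Per-group, per-variable, per-time-point normal parameters (mean, sd) that
#' drive the synthetic cohort generator. The packaged defaults are the
#' published group summaries for a 40-patient one-lung-ventilation cohort
#' (18 fluid responders, 22 non-responders): hemodynamic and respiratory
#' variables at baseline (T1), during a 10 cmH2O PEEP challenge (T2), at the
#' second zero-PEEP baseline (T3) and after fluid loading (T4), plus the
#' within-patient changes `D12` (T2 - T1, PEEP challenge) and `D34`
#' (T4 - T3, fluid loading).
#'
#' Variables: `HR` (beats/min), `MAP` (mmHg), `HR_RR_ratio`, `Cdyn`
#' (mL/cmH2O), `PIP` (cmH2O), `CI` (L/min/m2), `SV` (mL), `PPV` (%),
#' `SVV` (%).
#'
#' @return A data frame with columns `group`, `variable`, `time_point`,
#'   `mean`, `sd`.
#' @export
default_distributions <- function() {
  path <- system.file("extdata", "group_distributions.csv",
                      package = "peepchallenge", mustWork = TRUE)
  read_distribution_spec(path)
}

#' Read and validate a distribution-spec CSV
#'
#' @param path CSV with columns `group,variable,time_point,mean,sd`.
#' @return Validated data frame.
#' @export
read_distribution_spec <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "variable", "time_point", "mean", "sd")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("distribution spec is missing columns: ", paste(miss, collapse = ", "))
  if (!all(d$group %in% c("responder", "nonresponder")))
    stop("group must be 'responder' or 'nonresponder'")
  if (!all(d$time_point %in% c("T1", "T2", "T3", "T4", "D12", "D34")))
    stop("time_point must be one of T1, T2, T3, T4, D12, D34")
  if (anyNA(d$mean) || anyNA(d$sd)) stop("mean/sd must not be missing")
  if (any(d$sd < 0)) stop("sd must be non-negative")
  key <- paste(d$group, d$variable, d$time_point)
  if (anyDuplicated(key))
    stop("duplicate (group, variable, time_point) keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  d
}

dist_lookup <- function(dists, group, variable, time_point) {
  i <- which(dists$group == group & dists$variable == variable &
               dists$time_point == time_point)
  if (!length(i)) return(NULL)
  list(mean = dists$mean[i], sd = dists$sd[i])
}

#' Generate a synthetic patient cohort
#'
#' Draws one row per patient from per-group normal distributions. For every
#' variable that has both a baseline row (`T1`/`T3`) and a change row
#' (`D12`/`D34`) in `dists`, the post value is *derived* as
#' baseline draw + change draw, so the within-patient change follows the
#' published "Change" column distribution exactly while the post value
#' remains consistent with the baseline (deltas are computed, never drawn
#' independently of the levels). Variables with only a marginal row at some
#' time point are drawn directly from that marginal. PPV and SVV are drawn
#' jointly with correlation `rho` within each draw block (levels at
#' T1/T3, changes D12/D34), reflecting that both indices track the same
#' cyclic preload variation.
#'
#' PPV and SVV levels are truncated below at `truncate_at` (they are
#' strictly positive physiological percentages); the number of truncated
#' draws is recorded in the `n_truncated` attribute. Deltas are computed
#' after truncation so that `delta_ppv == PPV_T2 - PPV_T1` holds exactly.
#'
#' Responder labels are assigned by group membership (the groups *are*
#' defined by the published summaries). Use [end_to_end_cohort()] to
#' re-derive labels from the simulated stroke-volume response instead.
#'
#' @param n_responders,n_nonresponders Group sizes (defaults 18 and 22).
#' @param dists Distribution spec, as from [default_distributions()].
#' @param rho Within-patient correlation between PPV and SVV draws,
#'   in (-1, 1); default 0.6.
#' @param seed Optional integer seed for reproducibility.
#' @param truncate_at Lower truncation bound for PPV/SVV levels (default
#'   0.1 percent).
#' @return A data frame, one row per patient: `patient_id`, `group`,
#'   one column per (variable, time point) present or derivable, plus
#'   `delta_ppv`, `delta_svv` (when PPV/SVV at T1 and T2 exist) and a
#'   logical `responder` column. Attribute `n_truncated` counts truncated
#'   PPV/SVV draws.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' aggregate(delta_svv ~ group, cohort, mean)
generate_cohort <- function(n_responders = 18, n_nonresponders = 22,
                            dists = default_distributions(), rho = 0.6,
                            seed = NULL, truncate_at = 0.1) {
  if (n_responders < 1 || n_nonresponders < 1)
    stop("both groups need at least one patient")
  if (!(rho > -1 && rho < 1)) stop("`rho` must be in (-1, 1)")
  if (!is.null(seed)) set.seed(seed)
  resp <- draw_group(dists, "responder", n_responders, rho, truncate_at)
  nonr <- draw_group(dists, "nonresponder", n_nonresponders, rho, truncate_at)
  cols <- union(names(resp$data), names(nonr$data))
  for (cn in cols) {
    if (is.null(resp$data[[cn]])) resp$data[[cn]] <- NA_real_
    if (is.null(nonr$data[[cn]])) nonr$data[[cn]] <- NA_real_
  }
  out <- rbind(resp$data[cols], nonr$data[cols])
  out <- cbind(
    data.frame(patient_id = sprintf("P%03d", seq_len(nrow(out))),
               group = rep(c("responder", "nonresponder"),
                           c(n_responders, n_nonresponders)),
               stringsAsFactors = FALSE),
    out)
  out$responder <- out$group == "responder"
  rownames(out) <- NULL
  attr(out, "n_truncated") <- resp$n_truncated + nonr$n_truncated
  out
}

# draw all variables for one group; PPV/SVV jointly per block
draw_group <- function(dists, group, n, rho, truncate_at) {
  g <- dists[dists$group == group, , drop = FALSE]
  if (!nrow(g)) stop("no distribution rows for group '", group, "'")
  vars <- unique(g$variable)
  draws <- list()
  # blocks drawn jointly for PPV/SVV where both present
  blocks <- c(T1 = "T1", D12 = "D12", T2 = "T2",
              T3 = "T3", D34 = "D34", T4 = "T4")
  for (tp in blocks) {
    p <- dist_lookup(g, group, "PPV", tp)
    s <- dist_lookup(g, group, "SVV", tp)
    if (!is.null(p) && !is.null(s)) {
      z1 <- stats::rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
      draws[[paste0("PPV_", tp)]] <- p$mean + p$sd * z1
      draws[[paste0("SVV_", tp)]] <- s$mean + s$sd * z2
    } else {
      if (!is.null(p)) draws[[paste0("PPV_", tp)]] <-
          stats::rnorm(n, p$mean, p$sd)
      if (!is.null(s)) draws[[paste0("SVV_", tp)]] <-
          stats::rnorm(n, s$mean, s$sd)
    }
  }
  for (v in setdiff(vars, c("PPV", "SVV"))) {
    for (tp in blocks) {
      d <- dist_lookup(g, group, v, tp)
      if (!is.null(d)) draws[[paste0(v, "_", tp)]] <-
          stats::rnorm(n, d$mean, d$sd)
    }
  }
  # derive post values from baseline + change where both exist
  out <- list()
  for (v in vars) {
    for (pair in list(c("T1", "D12", "T2"), c("T3", "D34", "T4"))) {
      base <- draws[[paste0(v, "_", pair[1])]]
      chg <- draws[[paste0(v, "_", pair[2])]]
      post <- draws[[paste0(v, "_", pair[3])]]
      if (!is.null(base)) out[[paste0(v, "_", pair[1])]] <- base
      if (!is.null(base) && !is.null(chg)) {
        out[[paste0(v, "_", pair[3])]] <- base + chg
      } else if (!is.null(post)) {
        out[[paste0(v, "_", pair[3])]] <- post
      }
    }
  }
  # truncate strictly positive indices, then compute deltas
  n_trunc <- 0L
  for (cn in grep("^(PPV|SVV)_T[1-4]$", names(out), value = TRUE)) {
    low <- out[[cn]] < truncate_at
    n_trunc <- n_trunc + sum(low)
    out[[cn]][low] <- truncate_at
  }
  df <- as.data.frame(out)
  if (!is.null(df$PPV_T1) && !is.null(df$PPV_T2))
    df$delta_ppv <- df$PPV_T2 - df$PPV_T1
  if (!is.null(df$SVV_T1) && !is.null(df$SVV_T2))
    df$delta_svv <- df$SVV_T2 - df$SVV_T1
  list(data = df, n_truncated = n_trunc)
}

#' Simulate a beat-level series with prescribed respiratory modulation
#'
#' Beats are placed on a regular grid at the heart period 60/`heart_rate`;
#' pulse pressure and stroke volume are sinusoidally modulated at the
#' respiratory frequency with depth chosen so that the modulation envelope
#' yields exactly the target PPV/SVV:
#' `PP_i = baseline_pp * (1 + target_ppv/200 * sin(2*pi*t_i/T_resp + phase))`
#' plus optional Gaussian noise, and analogously for stroke volume (both
#' indices share the respiratory phase, as they share the driving cycle).
#' Cycle marks sit at multiples of the respiratory period. With zero noise
#' and beats sampled at the modulation extremes, the computed per-cycle PPV
#' equals `target_ppv`; with few beats per cycle the discrete sampling
#' under-reads the envelope (as a bedside monitor does).
#'
#' @param target_ppv,target_svv Target indices in percent, in \[0, 100).
#' @param baseline_pp Mean pulse pressure, mmHg.
#' @param baseline_sv Mean stroke volume, mL.
#' @param heart_rate Beats per minute.
#' @param resp_rate Respiratory cycles per minute; `heart_rate/resp_rate`
#'   must be at least 2 (at least two beats per cycle, else the cycle cannot
#'   be resolved).
#' @param noise_sd Gaussian noise SD as a fraction of the baseline value.
#' @param n_cycles Number of respiratory cycles to simulate.
#' @param phase `"random"` draws a uniform phase offset; `"aligned"` pins
#'   the first beat to the modulation maximum (exact index recovery when the
#'   beats-per-cycle ratio is an even integer).
#' @param seed Optional integer seed.
#' @return A [beat_series()].
#' @export
#' @examples
#' b <- generate_beats(target_ppv = 12, target_svv = 10, heart_rate = 80,
#'                     resp_rate = 10, phase = "aligned")
#' averaged_reading(b, k = 3)
generate_beats <- function(target_ppv, target_svv,
                           baseline_pp = 50, baseline_sv = 70,
                           heart_rate = 75, resp_rate = 12.5,
                           noise_sd = 0, n_cycles = 5,
                           phase = c("random", "aligned"), seed = NULL) {
  phase <- match.arg(phase)
  if (heart_rate / resp_rate < 2)
    stop("heart_rate/resp_rate must be at least 2 to resolve a cycle")
  if (target_ppv < 0 || target_ppv >= 100 || target_svv < 0 ||
      target_svv >= 100)
    stop("target indices must lie in [0, 100)")
  if (n_cycles < 1) stop("`n_cycles` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  t_resp <- 60 / resp_rate
  t_beat <- 60 / heart_rate
  marks <- (0:n_cycles) * t_resp
  n_beats <- floor(n_cycles * t_resp / t_beat - 1e-9) + 1L
  t <- (seq_len(n_beats) - 1L) * t_beat
  phi <- if (phase == "aligned") pi / 2 else stats::runif(1, 0, 2 * pi)
  mod <- sin(2 * pi * t / t_resp + phi)
  pp <- baseline_pp * (1 + target_ppv / 200 * mod)
  sv <- baseline_sv * (1 + target_svv / 200 * mod)
  if (noise_sd > 0) {
    pp <- pp + stats::rnorm(n_beats, 0, noise_sd * baseline_pp)
    sv <- sv + stats::rnorm(n_beats, 0, noise_sd * baseline_sv)
  }
  if (any(pp <= 0) || any(sv <= 0))
    stop("noise level produced non-positive pulse pressures or stroke ",
         "volumes; reduce noise_sd")
  beat_series(t, pp, sv, marks)
}

#' Generate a cohort whose indices are computed from simulated beats
#'
#' Integration path: patient-level targets for PPV/SVV at T1 and T2 are
#' drawn from the group distributions (as in [generate_cohort()]); for each
#' patient and time point a beat series is simulated with those targets and
#' the dynamic indices are *computed* from the beats via
#' [averaged_reading()], replacing the drawn targets. Deltas are then
#' recomputed from the computed values. Responder labels are either carried
#' from group membership (`label_mode = "group"`) or re-derived from the
#' simulated T3 to T4 stroke-volume change (`label_mode = "derived"`,
#' the rule used at the bedside).
#'
#' @inheritParams generate_cohort
#' @param beat_template Named list of arguments passed to [generate_beats()]
#'   (e.g. `heart_rate`, `resp_rate`, `noise_sd`, `n_cycles`, `phase`);
#'   targets are supplied per patient.
#' @param k Cycles averaged per reading (default 3).
#' @param label_mode `"group"` or `"derived"` (see above).
#' @param responder_threshold Percent stroke-volume increase defining a
#'   responder when `label_mode = "derived"` (default 10).
#' @return A cohort data frame as from [generate_cohort()], with PPV/SVV at
#'   T1/T2 replaced by beat-computed values and an attribute
#'   `index_targets` holding the drawn targets.
#' @export
end_to_end_cohort <- function(n_responders = 18, n_nonresponders = 22,
                              dists = default_distributions(), rho = 0.6,
                              beat_template = list(), k = 3,
                              label_mode = c("group", "derived"),
                              responder_threshold = 10, seed = NULL) {
  label_mode <- match.arg(label_mode)
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(n_responders, n_nonresponders, dists, rho,
                            seed = NULL)
  targets <- cohort[, intersect(c("PPV_T1", "PPV_T2", "SVV_T1", "SVV_T2"),
                                names(cohort)), drop = FALSE]
  if (!all(c("PPV_T1", "PPV_T2", "SVV_T1", "SVV_T2") %in% names(cohort)))
    stop("distribution spec must provide PPV and SVV at T1 and T2")
  if (is.null(beat_template$n_cycles)) beat_template$n_cycles <- k + 1
  for (i in seq_len(nrow(cohort))) {
    for (tp in c("T1", "T2")) {
      args <- c(list(target_ppv = cohort[[paste0("PPV_", tp)]][i],
                     target_svv = cohort[[paste0("SVV_", tp)]][i]),
                beat_template)
      reading <- averaged_reading(do.call(generate_beats, args), k = k,
                                  time_point = tp)
      cohort[[paste0("PPV_", tp)]][i] <- reading$ppv
      cohort[[paste0("SVV_", tp)]][i] <- reading$svv
    }
  }
  cohort$delta_ppv <- cohort$PPV_T2 - cohort$PPV_T1
  cohort$delta_svv <- cohort$SVV_T2 - cohort$SVV_T1
  if (label_mode == "derived") {
    cohort <- classify_responder(cohort, threshold = responder_threshold)
  }
  attr(cohort, "index_targets") <- targets
  cohort
}

#' Write / read the cohort CSV schema
#'
#' One row per patient; columns `patient_id`, `group`, the per-time-point
#' variables, `delta_ppv`, `delta_svv` and `responder`.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `read_cohort` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "group") %in% names(d)))
    stop("cohort CSV must have patient_id and group columns")
  if ("responder" %in% names(d)) d$responder <- as.logical(d$responder)
  d
}
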