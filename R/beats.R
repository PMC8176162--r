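#' Construct a beat-level hemodynamic series
#'
#' A `beat_series` holds per-beat pulse pressure and stroke volume together
#' with the start times of the respiratory cycles that segment the record.
#' It is the raw substrate from which pulse pressure variation (PPV) and
#' stroke volume variation (SVV) are computed.
#'
#' @param beat_time Numeric vector of beat times in seconds, strictly
#'   increasing.
#' @param pulse_pressure Numeric vector of per-beat pulse pressures in mmHg,
#'   all positive; same length as `beat_time`.
#' @param stroke_volume Numeric vector of per-beat stroke volumes in mL, all
#'   positive; same length as `beat_time`.
#' @param cycle_marks Numeric vector of respiratory-cycle start times in
#'   seconds, strictly increasing, at least two (consecutive marks bound one
#'   cycle window).
#'
#' @return An object of class `beat_series`.
#' @export
#' @examples
#' b <- beat_series(c(0.5, 1.5, 2.5, 3.5), c(50, 60, 50, 40),
#'                  c(70, 75, 70, 65), cycle_marks = c(0, 4))
#' segment_cycles(b)
beat_series <- function(beat_time, pulse_pressure, stroke_volume, cycle_marks) {
  beat_time <- as.numeric(beat_time)
  pulse_pressure <- as.numeric(pulse_pressure)
  stroke_volume <- as.numeric(stroke_volume)
  cycle_marks <- as.numeric(cycle_marks)
  n <- length(beat_time)
  if (n == 0L) stop("beat series is empty")
  if (length(pulse_pressure) != n || length(stroke_volume) != n)
    stop("beat_time, pulse_pressure and stroke_volume must have equal length")
  if (anyNA(beat_time) || anyNA(pulse_pressure) || anyNA(stroke_volume))
    stop("beat series contains missing values")
  if (n > 1L && any(diff(beat_time) <= 0))
    stop("beat_time must be strictly increasing")
  if (any(pulse_pressure <= 0)) stop("pulse_pressure must be positive")
  if (any(stroke_volume <= 0)) stop("stroke_volume must be positive")
  if (length(cycle_marks) < 2L)
    stop("at least two cycle_marks are required to bound a cycle window")
  if (any(diff(cycle_marks) <= 0))
    stop("cycle_marks must be strictly increasing")
  structure(list(beat_time = beat_time,
                 pulse_pressure = pulse_pressure,
                 stroke_volume = stroke_volume,
                 cycle_marks = cycle_marks),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats over %.1f s, %d respiratory cycles\n",
              length(x$beat_time), diff(range(x$beat_time)),
              length(x$cycle_marks) - 1L))
  invisible(x)
}

#' Assign beats to respiratory-cycle windows
#'
#' Each window is the half-open interval `[mark_k, mark_{k+1})`: a beat
#' falling exactly on a mark belongs to the later cycle. Windows holding
#' fewer than two beats cannot yield a max/min variation and are flagged
#' invalid; they are excluded from index computation but reported so callers
#' can see them.
#'
#' @param beats A [beat_series()].
#' @return A list with `windows` (list of integer beat-index vectors, one per
#'   cycle) and `valid` (logical, `TRUE` where the window holds at least two
#'   beats).
#' @export
segment_cycles <- function(beats) {
  if (!inherits(beats, "beat_series")) stop("`beats` must be a beat_series")
  marks <- beats$cycle_marks
  k <- length(marks) - 1L
  idx <- findInterval(beats$beat_time, marks)
  windows <- lapply(seq_len(k), function(w) which(idx == w &
    beats$beat_time < marks[w + 1L]))
  valid <- vapply(windows, function(w) length(w) >= 2L, logical(1))
  list(windows = windows, valid = valid)
}

variation_percent <- function(values, what = "value") {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("at least two beats are needed to compute a variation")
  if (anyNA(values) || any(values <= 0))
    stop(sprintf("all %ss must be positive and non-missing", what))
  hi <- max(values)
  lo <- min(values)
  100 * (hi - lo) / ((hi + lo) / 2)
}

#' Pulse pressure variation over one respiratory cycle
#'
#' PPV = 100 * (PPmax - PPmin) / ((PPmax + PPmin) / 2), the percent swing of
#' beat-to-beat pulse pressure across a respiratory cycle. Always in
#' \[0, 200) for positive pulse pressures.
#'
#' @param pulse_pressures Numeric vector of per-beat pulse pressures (mmHg)
#'   within one cycle; at least two, all positive.
#' @return PPV in percent.
#' @export
#' @examples
#' ppv_one_cycle(c(60, 40)) # 40
ppv_one_cycle <- function(pulse_pressures) {
  variation_percent(pulse_pressures, "pulse pressure")
}

#' Stroke volume variation over one respiratory cycle
#'
#' SVV = 100 * (SVmax - SVmin) / ((SVmax + SVmin) / 2); the same functional
#' form as [ppv_one_cycle()] applied to stroke volumes.
#'
#' @param stroke_volumes Numeric vector of per-beat stroke volumes (mL)
#'   within one cycle; at least two, all positive.
#' @return SVV in percent.
#' @export
svv_one_cycle <- function(stroke_volumes) {
  variation_percent(stroke_volumes, "stroke volume")
}

#' Average dynamic indices over consecutive respiratory cycles
#'
#' Computes per-cycle PPV and SVV and averages them over the first run of
#' `k` consecutive valid cycle windows, mirroring bedside practice of
#' recording the index over several consecutive respiratory cycles and
#' averaging. Windows with fewer than two beats are invalid and break a run.
#'
#' @param beats A [beat_series()].
#' @param k Number of consecutive valid cycles to average (default 3).
#' @param time_point Label for the reading, one of `"T1"`, `"T2"`, `"T3"`,
#'   `"T4"`.
#' @return A `dynamic_index_reading`: list with `ppv`, `svv` (percent),
#'   `n_cycles_averaged` and `time_point`.
#' @export
averaged_reading <- function(beats, k = 3, time_point = "T1") {
  if (!inherits(beats, "beat_series")) stop("`beats` must be a beat_series")
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be at least 1")
  time_point <- match.arg(time_point, c("T1", "T2", "T3", "T4"))
  seg <- segment_cycles(beats)
  start <- first_valid_run(seg$valid, k)
  if (is.na(start)) {
    runs <- rle(seg$valid)
    longest <- max(c(0L, runs$lengths[runs$values]))
    stop(sprintf(paste0("need %d consecutive valid respiratory cycles but the",
                        " longest valid run has %d (of %d windows)"),
                 k, longest, length(seg$valid)))
  }
  use <- seg$windows[start:(start + k - 1L)]
  ppv <- mean(vapply(use, function(w) ppv_one_cycle(beats$pulse_pressure[w]),
                     numeric(1)))
  svv <- mean(vapply(use, function(w) svv_one_cycle(beats$stroke_volume[w]),
                     numeric(1)))
  structure(list(ppv = ppv, svv = svv, n_cycles_averaged = k,
                 time_point = time_point),
            class = "dynamic_index_reading")
}

# index of the first run of k consecutive TRUEs, or NA
first_valid_run <- function(valid, k) {
  if (length(valid) < k) return(NA_integer_)
  for (i in seq_len(length(valid) - k + 1L)) {
    if (all(valid[i:(i + k - 1L)])) return(i)
  }
  NA_integer_
}

#' @export
print.dynamic_index_reading <- function(x, ...) {
  cat(sprintf("<%s> PPV %.1f%%  SVV %.1f%%  (mean of %d cycles)\n",
              x$time_point, x$ppv, x$svv, x$n_cycles_averaged))
  invisible(x)
}

#' Change in dynamic indices induced by a PEEP challenge
#'
#' The PEEP-challenge deltas are the signed differences between the reading
#' during the challenge (T2) and the zero-PEEP baseline (T1):
#' delta PPV = PPV(T2) - PPV(T1), and likewise for SVV. They are not clamped
#' at zero; a negative delta is meaningful (indices can fall under PEEP in
#' non-responders).
#'
#' @param t1 A `dynamic_index_reading` labeled `"T1"`.
#' @param t2 A `dynamic_index_reading` labeled `"T2"`.
#' @return An `index_delta`: list with `delta_ppv` and `delta_svv` in
#'   percentage points.
#' @export
peep_delta <- function(t1, t2) {
  if (!inherits(t1, "dynamic_index_reading") ||
      !inherits(t2, "dynamic_index_reading"))
    stop("both arguments must be dynamic_index_reading objects")
  if (!identical(t1$time_point, "T1") || !identical(t2$time_point, "T2"))
    stop(sprintf("expected readings labeled T1 and T2, got %s and %s",
                 t1$time_point, t2$time_point))
  structure(list(delta_ppv = t2$ppv - t1$ppv,
                 delta_svv = t2$svv - t1$svv),
            class = "index_delta")
}

#' Read a beat-level CSV record
#'
#' Expects columns `beat_time_s`, `pulse_pressure_mmHg`, `stroke_volume_mL`.
#' Respiratory-cycle segmentation comes either from a `resp_cycle_id` column
#' (consecutive integer cycle labels; marks are placed at the first beat of
#' each cycle, with a closing mark one median beat-interval after the last
#' beat) or from `marks`: a numeric vector of cycle start times, or the path
#' of a CSV with a `cycle_start_s` column. Non-monotone beat times are
#' rejected.
#'
#' @param path CSV file path.
#' @param marks Optional cycle marks (numeric vector or CSV path); ignored
#'   when the file has a `resp_cycle_id` column.
#' @return A [beat_series()].
#' @export
read_beat_series <- function(path, marks = NULL) {
  d <- utils::read.csv(path)
  need <- c("beat_time_s", "pulse_pressure_mmHg", "stroke_volume_mL")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("beat CSV is missing columns: ", paste(miss, collapse = ", "))
  if ("resp_cycle_id" %in% names(d)) {
    id <- d$resp_cycle_id
    if (is.unsorted(id)) stop("resp_cycle_id must be non-decreasing")
    starts <- d$beat_time_s[!duplicated(id)]
    gap <- if (nrow(d) > 1L) stats::median(diff(d$beat_time_s)) else 1
    cm <- c(starts, d$beat_time_s[nrow(d)] + gap)
  } else if (is.character(marks)) {
    m <- utils::read.csv(marks)
    if (!"cycle_start_s" %in% names(m))
      stop("marks CSV must have a cycle_start_s column")
    cm <- m$cycle_start_s
  } else if (is.numeric(marks)) {
    cm <- marks
  } else {
    stop("provide cycle marks via a resp_cycle_id column or `marks`")
  }
  beat_series(d$beat_time_s, d$pulse_pressure_mmHg, d$stroke_volume_mL, cm)
}
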