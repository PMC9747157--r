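#' Condition raw EMG: band-pass filter and full-wave rectify
#'
#' Zero-phase (forward-backward) Butterworth band-pass followed by
#' rectification. When the upper edge reaches or exceeds Nyquist the filter
#' degenerates to a high-pass at `band[1]` (a 5-1000 Hz band at 2 kHz
#' sampling is effectively high-pass). `band = NULL` skips filtering and
#' only rectifies, for signals that are already conditioned.
#'
#' @param x Raw EMG signal (uV).
#' @param fs Sampling rate (Hz).
#' @param band Length-2 numeric `c(low, high)` in Hz, or `NULL`.
#' @param order Butterworth order (default 4).
#' @return Rectified signal, same length as `x`, all values `>= 0`.
#' @export
condition_emg <- function(x, fs, band = c(5, 1000), order = 4) {
  if (!is.null(band)) {
    if (band[1] >= band[2]) stop("band_low must be < band_high")
    bf <- if (band[2] >= fs / 2) {
      signal::butter(order, band[1] / (fs / 2), type = "high")
    } else {
      signal::butter(order, band / (fs / 2), type = "pass")
    }
    x <- signal::filtfilt(bf, x)
  }
  abs(x)
}

# EMG StTA window in ms: [-30, +70); baseline [-30, -10).
EMG_WINDOW_MS <- c(-30, 70)
BASELINE_MS <- c(-30, -10)

# Sample index (1-based) of the signal sample covering trigger time + lag.
# Lag sample i of a window [a, b) ms covers a + i/fs (design convention).
window_indices <- function(trigger_s, fs, window_ms) {
  a <- as.integer(round(window_ms[1] / 1000 * fs))
  n <- as.integer(round(diff(window_ms) / 1000 * fs))
  as.integer(round(trigger_s * fs)) + 1L + a + 0:(n - 1L)
}

window_lags_ms <- function(fs, window_ms) {
  n <- round(diff(window_ms) / 1000 * fs)
  window_ms[1] + (0:(n - 1)) / fs * 1000
}

#' Extract peristimulus sweeps for one muscle and hold state
#'
#' One row per assigned trigger, covering `[-30, +70)` ms around the
#' trigger. The per-sweep background is the mean over the `[-30, -10)` ms
#' pre-stimulus window, the study's index of motoneuron-pool excitability
#' at stimulus arrival.
#'
#' @param rec A `session_recording` (EMG assumed already rectified;
#'   see [condition_emg()]).
#' @param muscle Muscle name.
#' @param assignment A `trigger_assignment` from [assign_triggers()].
#' @param hold_state `"center"` or one of `"0"`..`"315"`.
#' @param window_ms Sweep window (ms relative to trigger), default
#'   `c(-30, 70)`.
#' @return A `sweep_set`: list with `muscle`, `hold_state`, `sweeps`
#'   (n_triggers x n_samples matrix), `background_uv` (per-sweep), `lags_ms`,
#'   `fs`. Zero assigned triggers yield an empty `sweep_set`
#'   (`n_triggers = 0`), not an error.
#' @export
extract_sweeps <- function(rec, muscle, assignment, hold_state,
                           window_ms = EMG_WINDOW_MS) {
  if (!muscle %in% names(rec$emg)) stop("unknown muscle: ", muscle)
  trg <- assigned_triggers(assignment, hold_state)
  fs <- rec$sampling_rate_hz
  lags <- window_lags_ms(fs, window_ms)
  n <- round(diff(window_ms) / 1000 * fs)
  if (length(trg) == 0) {
    sw <- matrix(numeric(0), nrow = 0, ncol = n)
    bg <- numeric(0)
  } else {
    idx <- vapply(trg, window_indices, integer(n), fs = fs, window_ms = window_ms)
    sw <- matrix(rec$emg[[muscle]][idx], nrow = length(trg), ncol = n, byrow = TRUE)
    bl <- lags >= BASELINE_MS[1] & lags < BASELINE_MS[2]
    bg <- rowMeans(sw[, bl, drop = FALSE])
  }
  structure(list(muscle = muscle, hold_state = as.character(hold_state),
                 sweeps = sw, background_uv = bg, lags_ms = lags, fs = fs),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %s / %s: %d sweeps x %d samples, mean background %.2f uV\n",
              x$muscle, x$hold_state, nrow(x$sweeps), ncol(x$sweeps),
              if (nrow(x$sweeps)) mean(x$background_uv) else NA))
  invisible(x)
}

#' Stimulus-triggered average of a sweep set
#'
#' The per-lag mean across sweeps, with baseline mean and SD measured from
#' the `[-30, -10)` ms lags of the averaged trace (not of individual
#' sweeps).
#'
#' @param sweeps A `sweep_set` with at least one sweep.
#' @return An `stta`: list with `trace` (uV per lag), `lags_ms`,
#'   `baseline_mean`, `baseline_sd`, `n_triggers`, `fs`, `muscle`,
#'   `hold_state`.
#' @export
compute_stta <- function(sweeps) {
  if (nrow(sweeps$sweeps) < 1) stop("empty sweep set: no assigned triggers")
  trace <- colMeans(sweeps$sweeps)
  bl <- sweeps$lags_ms >= BASELINE_MS[1] & sweeps$lags_ms < BASELINE_MS[2]
  structure(list(trace = trace, lags_ms = sweeps$lags_ms,
                 baseline_mean = mean(trace[bl]),
                 baseline_sd = stats::sd(trace[bl]),
                 n_triggers = nrow(sweeps$sweeps), fs = sweeps$fs,
                 muscle = sweeps$muscle, hold_state = sweeps$hold_state),
            class = "stta")
}

#' Manually assemble an `stta` object
#'
#' For traces not derived from a `sweep_set` (tests, external averages).
#' Baseline statistics are computed from the `[-30,-10)` ms lags unless
#' given explicitly.
#'
#' @param trace Mean trace (uV per lag).
#' @param fs Sampling rate (Hz).
#' @param lags_ms Lag times; default the standard `[-30, 70)` ms grid.
#' @param baseline_mean,baseline_sd Optional overrides.
#' @param n_triggers Sweep count annotation.
#' @return An `stta`.
#' @export
as_stta <- function(trace, fs, lags_ms = NULL, baseline_mean = NULL,
                    baseline_sd = NULL, n_triggers = NA_integer_) {
  if (is.null(lags_ms)) lags_ms <- window_lags_ms(fs, EMG_WINDOW_MS)
  stopifnot(length(trace) == length(lags_ms))
  bl <- lags_ms >= BASELINE_MS[1] & lags_ms < BASELINE_MS[2]
  structure(list(trace = trace, lags_ms = lags_ms,
                 baseline_mean = if (is.null(baseline_mean)) mean(trace[bl]) else baseline_mean,
                 baseline_sd = if (is.null(baseline_sd)) stats::sd(trace[bl]) else baseline_sd,
                 n_triggers = n_triggers, fs = fs,
                 muscle = NA_character_, hold_state = NA_character_),
            class = "stta")
}

#' @export
print.stta <- function(x, ...) {
  cat(sprintf("<stta> %s / %s: n = %s, baseline %.3f +/- %.3f uV\n",
              x$muscle, x$hold_state, x$n_triggers,
              x$baseline_mean, x$baseline_sd))
  invisible(x)
}

#' Detect post-stimulus effects in an StTA
#'
#' A facilitation is a maximal run of consecutive lags (inside the search
#' window, outside the `[0, 2)` ms stimulus-artifact mask) where the trace
#' exceeds `mean + k_sd * SD` of the baseline, sustained for at least
#' `min_duration_ms`; suppression is the analogue below `mean - k_sd * SD`.
#' The magnitude is the area between the trace and the crossed threshold
#' line (uV·ms); onset is the first lag of the run. The first effect (the
#' one with the shortest onset latency; ties broken toward the larger area)
#' is the effect carried into all downstream analyses.
#'
#' @param stta An `stta`.
#' @param k_sd Threshold in baseline SDs (default 3).
#' @param min_duration_ms Minimum sustained duration (default 1 ms).
#' @param search_window_ms Lags searched, default `c(2, 70)` (half-open).
#' @param area_reference `"threshold"` (default; area measured from the
#'   `k_sd` bound) or `"baseline"` (from the baseline mean).
#' @return List with `effects` (data frame of class `pste_table`: columns
#'   `effect_type`, `onset_ms`, `duration_ms`, `area_uv_ms`, `threshold_uv`)
#'   and `first` (one-row data frame or `NULL`).
#' @export
detect_pste <- function(stta, k_sd = 3, min_duration_ms = 1,
                        search_window_ms = c(2, 70),
                        area_reference = c("threshold", "baseline")) {
  area_reference <- match.arg(area_reference)
  if (!is.finite(stta$baseline_sd)) stop("baseline SD is not finite")
  if (stta$baseline_sd == 0)
    stop("degenerate baseline: SD is zero, detection undefined")
  dt_ms <- 1000 / stta$fs
  min_len <- ceiling(min_duration_ms * stta$fs / 1000)
  sel <- which(stta$lags_ms >= search_window_ms[1] &
               stta$lags_ms < search_window_ms[2] &
               !(stta$lags_ms >= 0 & stta$lags_ms < 2))
  hi <- stta$baseline_mean + k_sd * stta$baseline_sd
  lo <- stta$baseline_mean - k_sd * stta$baseline_sd
  rows <- list()
  for (side in c("Facilitation", "Suppression")) {
    thr <- if (side == "Facilitation") hi else lo
    above <- if (side == "Facilitation") stta$trace[sel] > hi else stta$trace[sel] < lo
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      run <- sel[starts[k]:ends[k]]
      # a run must be contiguous in the underlying lag grid
      if (any(diff(run) != 1L)) {
        segs <- split(run, cumsum(c(1L, diff(run) != 1L)))
      } else segs <- list(run)
      for (seg in segs) {
        if (length(seg) < min_len) next
        ref <- if (area_reference == "threshold") thr else stta$baseline_mean
        rows[[length(rows) + 1L]] <- data.frame(
          effect_type = side,
          onset_ms = stta$lags_ms[seg[1]],
          duration_ms = length(seg) * dt_ms,
          area_uv_ms = sum(abs(stta$trace[seg] - ref)) * dt_ms,
          threshold_uv = thr)
      }
    }
  }
  effects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(effect_type = character(0), onset_ms = numeric(0),
               duration_ms = numeric(0), area_uv_ms = numeric(0),
               threshold_uv = numeric(0))
  effects <- effects[order(effects$onset_ms, -effects$area_uv_ms), , drop = FALSE]
  rownames(effects) <- NULL
  class(effects) <- c("pste_table", "data.frame")
  list(effects = effects,
       first = if (nrow(effects)) effects[1, , drop = FALSE] else NULL)
}

#' Classify a muscle's output type over the eight targets
#'
#' Given the first post-stimulus effect per peripheral target, the muscular
#' condition is `"Facilitation"` if only facilitation occurs,
#' `"Suppression"` if only suppression, `"No response"` if neither; when
#' both occur across targets the dominant type (the larger per-type sum of
#' areas over the eight targets) carries a plus symbol:
#' `"Facilitation+ and Suppression"` or `"Facilitation and Suppression+"`
#' (ties favour facilitation).
#'
#' @param first_effects Named list over the 8 target labels (`"0"`..`"315"`),
#'   each `NULL` or a one-row effect data frame (as from [detect_pste()]).
#' @return List: `output_type`, `facilitation_sum`, `suppression_sum`
#'   (uV·ms), `per_target` (data frame of target, effect_type, area).
#' @export
classify_output_type <- function(first_effects) {
  if (length(first_effects) != 8)
    stop("need first-effect results for the 8 peripheral targets")
  tab <- do.call(rbind, lapply(names(first_effects), function(k) {
    fe <- first_effects[[k]]
    if (is.null(fe)) data.frame(target = k, effect_type = "None", area_uv_ms = 0)
    else data.frame(target = k, effect_type = fe$effect_type,
                    area_uv_ms = fe$area_uv_ms)
  }))
  fsum <- sum(tab$area_uv_ms[tab$effect_type == "Facilitation"])
  ssum <- sum(tab$area_uv_ms[tab$effect_type == "Suppression"])
  has_f <- any(tab$effect_type == "Facilitation")
  has_s <- any(tab$effect_type == "Suppression")
  output_type <-
    if (!has_f && !has_s) "No response"
    else if (has_f && !has_s) "Facilitation"
    else if (!has_f && has_s) "Suppression"
    else if (fsum >= ssum) "Facilitation+ and Suppression"
    else "Facilitation and Suppression+"
  list(output_type = output_type, facilitation_sum = fsum,
       suppression_sum = ssum, per_target = tab)
}
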