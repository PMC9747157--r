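#' Construct a session recording
#'
#' A `session_recording` bundles the synchronized channels of one experiment:
#' multichannel EMG, the two wrist-torque axes (x = flexion-extension,
#' y = radial-ulnar), the stimulus trigger train, and the behavioural event
#' list of the eight-target torque-tracking task. All signal channels share
#' the same length and sampling rate; trigger times are seconds from the
#' start of the recording.
#'
#' Angle convention: 0 deg = +x (extension), 90 deg = +y (radial),
#' counterclockwise, degrees in `[0, 360)`.
#'
#' @param sampling_rate_hz Sampling rate in Hz (positive scalar).
#' @param emg Named list (or data.frame) of rectifiable EMG signals in
#'   microvolts, one element per muscle; all of equal length.
#' @param torque_x,torque_y Torque signals in N·m, same length as the EMG.
#' @param trigger_times_s Strictly increasing stimulus times in seconds,
#'   all within `[0, T/fs)`.
#' @param events Data frame of task events with columns `state`
#'   (`center_hold`, `peripheral_hold`, `movement`, `intertrial`),
#'   `target_angle_deg` (one of 0, 45, ..., 315 for peripheral holds, `NA`
#'   otherwise), `start_s`, `end_s`. Events must be non-overlapping.
#' @param metadata Free-form named list (animal, electrode id, stimulus
#'   current, electrode/muscle categories, ...).
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(sampling_rate_hz, emg, torque_x, torque_y,
                              trigger_times_s, events = empty_events(),
                              metadata = list()) {
  emg <- lapply(emg, as.numeric)
  rec <- structure(list(
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    emg = emg,
    torque_x = as.numeric(torque_x),
    torque_y = as.numeric(torque_y),
    trigger_times_s = as.numeric(trigger_times_s),
    events = as.data.frame(events),
    metadata = metadata
  ), class = "session_recording")
  validate_session(rec)
  rec
}

#' Empty event table
#' @return Zero-row event data frame with the canonical columns.
#' @export
empty_events <- function() {
  data.frame(state = character(0), target_angle_deg = numeric(0),
             start_s = numeric(0), end_s = numeric(0))
}

HOLD_STATES <- c("center_hold", "peripheral_hold", "movement", "intertrial")
TARGET_ANGLES <- seq(0, 315, by = 45)

#' Validate a session recording
#'
#' Checks every structural invariant: equal channel lengths, strictly
#' increasing in-range triggers, positive sampling rate, unique muscle
#' names, finite samples, and well-formed non-overlapping events.
#'
#' @param rec A `session_recording`.
#' @return `rec`, invisibly; stops with a format error naming the offending
#'   field otherwise.
#' @export
validate_session <- function(rec) {
  if (!is.numeric(rec$sampling_rate_hz) || length(rec$sampling_rate_hz) != 1 ||
      !is.finite(rec$sampling_rate_hz) || rec$sampling_rate_hz <= 0)
    stop("session format error: sampling_rate_hz must be a positive number")
  nm <- names(rec$emg)
  if (length(rec$emg) == 0 || is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    stop("session format error: emg must be a named list with unique muscle names")
  len <- vapply(rec$emg, length, integer(1))
  T <- length(rec$torque_x)
  if (any(len != T) || length(rec$torque_y) != T)
    stop("session format error: length mismatch across channels (emg/torque)")
  for (m in nm)
    if (anyNA(rec$emg[[m]]) || any(!is.finite(rec$emg[[m]])))
      stop(sprintf("session format error: non-finite sample in emg channel '%s'", m))
  if (any(!is.finite(rec$torque_x)) || any(!is.finite(rec$torque_y)))
    stop("session format error: non-finite sample in torque")
  tr <- rec$trigger_times_s
  if (length(tr)) {
    if (anyNA(tr) || any(!is.finite(tr)))
      stop("session format error: non-finite trigger time")
    if (any(diff(tr) <= 0))
      stop("session format error: non-increasing triggers")
    if (tr[1] < 0 || tr[length(tr)] >= T / rec$sampling_rate_hz)
      stop("session format error: trigger time outside recording")
  }
  validate_events(rec$events)
  invisible(rec)
}

validate_events <- function(ev) {
  need <- c("state", "target_angle_deg", "start_s", "end_s")
  if (!all(need %in% names(ev)))
    stop("session format error: events missing columns ",
         paste(setdiff(need, names(ev)), collapse = ", "))
  if (nrow(ev) == 0) return(invisible(ev))
  if (!all(ev$state %in% HOLD_STATES))
    stop("session format error: unknown event state")
  if (any(ev$start_s >= ev$end_s))
    stop("session format error: event with start_s >= end_s")
  ph <- ev$state == "peripheral_hold"
  if (any(is.na(ev$target_angle_deg[ph])) ||
      !all(ev$target_angle_deg[ph] %in% TARGET_ANGLES))
    stop("session format error: peripheral_hold requires target_angle_deg in {0,45,...,315}")
  o <- order(ev$start_s)
  # tolerance absorbs floating-point rounding of abutting epoch boundaries
  if (any(ev$start_s[o][-1] < ev$end_s[o][-nrow(ev)] - 1e-9))
    stop("session format error: overlapping events")
  invisible(ev)
}

#' @export
print.session_recording <- function(x, ...) {
  T <- length(x$torque_x)
  cat(sprintf("<session_recording> %d channels, T = %d samples (%.2f s at %g Hz)\n",
              length(x$emg), T, T / x$sampling_rate_hz, x$sampling_rate_hz))
  cat("  muscles:", paste(names(x$emg), collapse = ", "), "\n")
  cat(sprintf("  triggers: %d   events: %d\n",
              length(x$trigger_times_s), nrow(x$events)))
  invisible(x)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a session to a directory
#'
#' On-disk layout: `metadata.json` (sampling rate, channel names/units,
#' metadata map), `emg.csv` (one column per muscle), `torque.csv`
#' (`torque_x`, `torque_y`), `triggers.csv` (`time_s`), `events.csv`
#' (`state`, `target_angle_deg`, `start_s`, `end_s`). Numeric values are
#' written as 17-significant-digit decimal text, so a read/write round trip
#' is lossless for 64-bit floating point.
#'
#' @param rec A valid `session_recording`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(rec, path) {
  validate_session(rec)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("unwritable path: ", path)
  meta <- list(sampling_rate_hz = rec$sampling_rate_hz,
               emg_channels = as.list(names(rec$emg)),
               units = list(emg = "uV", torque = "N.m"),
               precision = "float64 decimal text, 17 significant digits",
               metadata = rec$metadata)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emg_dt <- data.table::as.data.table(lapply(rec$emg, fmt17))
  data.table::fwrite(emg_dt, file.path(path, "emg.csv"), quote = FALSE)
  data.table::fwrite(
    data.table::data.table(torque_x = fmt17(rec$torque_x),
                           torque_y = fmt17(rec$torque_y)),
    file.path(path, "torque.csv"), quote = FALSE)
  data.table::fwrite(
    data.table::data.table(time_s = fmt17(rec$trigger_times_s)),
    file.path(path, "triggers.csv"), quote = FALSE)
  ev <- rec$events
  data.table::fwrite(
    data.table::data.table(state = ev$state,
                           target_angle_deg = ifelse(is.na(ev$target_angle_deg),
                                                     "", fmt17(ev$target_angle_deg)),
                           start_s = fmt17(ev$start_s), end_s = fmt17(ev$end_s)),
    file.path(path, "events.csv"), quote = FALSE)
  invisible(path)
}

#' Read a session from a directory
#'
#' Inverse of [write_session()]; validates all invariants on load.
#'
#' @param path Session directory.
#' @return A `session_recording`.
#' @export
read_session <- function(path) {
  need <- c("metadata.json", "emg.csv", "torque.csv", "triggers.csv", "events.csv")
  miss <- need[!file.exists(file.path(path, need))]
  if (length(miss))
    stop("session format error: missing file(s): ", paste(miss, collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "metadata.json"), simplifyVector = TRUE)
  emg <- data.table::fread(file.path(path, "emg.csv"), colClasses = "numeric",
                           data.table = FALSE)
  torque <- data.table::fread(file.path(path, "torque.csv"), colClasses = "numeric",
                              data.table = FALSE)
  trg <- data.table::fread(file.path(path, "triggers.csv"), colClasses = "numeric",
                           data.table = FALSE)
  ev <- data.table::fread(file.path(path, "events.csv"), data.table = FALSE,
                          colClasses = list(character = "state"), fill = TRUE)
  if (nrow(ev)) {
    ev$target_angle_deg <- suppressWarnings(as.numeric(ev$target_angle_deg))
  } else {
    ev <- empty_events()
  }
  session_recording(
    sampling_rate_hz = meta$sampling_rate_hz,
    emg = as.list(emg),
    torque_x = torque$torque_x, torque_y = torque$torque_y,
    trigger_times_s = if (nrow(trg)) trg$time_s else numeric(0),
    events = ev,
    metadata = if (is.null(meta$metadata)) list() else as.list(meta$metadata))
}

#' Per-state hold intervals
#'
#' Collects the task's hold intervals keyed by hold state: `"center"` for
#' center holds and `"0"`, `"45"`, ..., `"315"` for the eight peripheral
#' targets. Intervals within each state are disjoint and sorted.
#'
#' @param events Event data frame (see [session_recording()]).
#' @return Named list of two-column matrices (`start_s`, `end_s`).
#' @export
segment_hold_states <- function(events) {
  validate_events(events)
  out <- list()
  if (nrow(events) == 0) return(out)
  hold <- events[events$state %in% c("center_hold", "peripheral_hold"), , drop = FALSE]
  if (nrow(hold) == 0) return(out)
  key <- ifelse(hold$state == "center_hold", "center",
                as.character(hold$target_angle_deg))
  for (k in unique(key)) {
    h <- hold[key == k, , drop = FALSE]
    h <- h[order(h$start_s), , drop = FALSE]
    out[[k]] <- cbind(start_s = h$start_s, end_s = h$end_s)
  }
  # stable key order: center first, then angles ascending
  ang <- suppressWarnings(sort(as.numeric(setdiff(names(out), "center"))))
  out[c(intersect("center", names(out)), as.character(ang))]
}

#' Assign stimulus triggers to hold states
#'
#' A trigger at time `t` is assigned to a hold state iff its full analysis
#' window `[t - pre_window_ms, t + post_window_ms]` lies entirely inside one
#' hold interval of that state (containment rule, avoiding contamination
#' from adjacent movement epochs). With `rule = "trigger_inside"` only the
#' trigger time itself must fall in the hold.
#'
#' @param rec A `session_recording`.
#' @param post_window_ms,pre_window_ms Analysis window extents in ms
#'   (defaults 70 and 30, the EMG StTA window; torque analyses pass
#'   `post_window_ms = 150`).
#' @param rule `"containment"` (default) or `"trigger_inside"`.
#' @return Data frame of class `trigger_assignment` with one row per
#'   trigger: `time_s`, `hold_state` (`"center"`, `"0"`..`"315"`, or `NA`),
#'   `excluded` (logical), `reason` (`""`, `"outside hold"`,
#'   `"window exits hold"`).
#' @export
assign_triggers <- function(rec, post_window_ms = 70, pre_window_ms = 30,
                            rule = c("containment", "trigger_inside")) {
  rule <- match.arg(rule)
  stopifnot(post_window_ms > 0, pre_window_ms > 0)
  holds <- segment_hold_states(rec$events)
  tr <- rec$trigger_times_s
  hold_state <- rep(NA_character_, length(tr))
  reason <- rep("outside hold", length(tr))
  pre <- pre_window_ms / 1000
  post <- post_window_ms / 1000
  for (k in names(holds)) {
    iv <- holds[[k]]
    for (i in seq_len(nrow(iv))) {
      inside <- tr >= iv[i, 1] & tr < iv[i, 2]
      if (!any(inside)) next
      if (rule == "containment") {
        ok <- inside & (tr - pre >= iv[i, 1]) & (tr + post <= iv[i, 2])
        reason[inside & !ok] <- "window exits hold"
      } else {
        ok <- inside
      }
      hold_state[ok] <- k
      reason[ok] <- ""
    }
  }
  structure(data.frame(time_s = tr, hold_state = hold_state,
                       excluded = is.na(hold_state), reason = reason,
                       stringsAsFactors = FALSE),
            class = c("trigger_assignment", "data.frame"))
}

#' Trigger times assigned to one hold state
#' @param assignment A `trigger_assignment`.
#' @param hold_state `"center"` or one of `"0"`, `"45"`, ..., `"315"`.
#' @return Numeric vector of trigger times (seconds).
#' @export
assigned_triggers <- function(assignment, hold_state) {
  assignment$time_s[!assignment$excluded &
                    assignment$hold_state == as.character(hold_state)]
}
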