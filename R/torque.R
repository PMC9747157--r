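# Torque StTA window in ms: [-30, +150); baseline [-30, -10).
TORQUE_WINDOW_MS <- c(-30, 150)

#' Stimulus-triggered average of the wrist torques
#'
#' Per-axis mean sweep over `[-30, +150)` ms around each assigned trigger.
#' Assignment should use the torque window (`post_window_ms = 150`).
#'
#' @param rec A `session_recording`.
#' @param assignment A `trigger_assignment`.
#' @param hold_state `"center"` or one of `"0"`..`"315"`.
#' @param window_ms Sweep window, default `c(-30, 150)`.
#' @return A `torque_stta`: list `trace_x`, `trace_y`, `lags_ms`,
#'   `n_triggers`, `fs`, `hold_state`; baseline statistics are filled in by
#'   [detrend_stta()].
#' @export
compute_torque_stta <- function(rec, assignment, hold_state,
                                window_ms = TORQUE_WINDOW_MS) {
  trg <- assigned_triggers(assignment, hold_state)
  if (length(trg) == 0) stop("no assigned triggers for hold state ", hold_state)
  fs <- rec$sampling_rate_hz
  n <- round(diff(window_ms) / 1000 * fs)
  idx <- vapply(trg, window_indices, integer(n), fs = fs, window_ms = window_ms)
  mean_sweep <- function(sig) {
    colMeans(matrix(sig[idx], nrow = length(trg), ncol = n, byrow = TRUE))
  }
  structure(list(trace_x = mean_sweep(rec$torque_x),
                 trace_y = mean_sweep(rec$torque_y),
                 lags_ms = window_lags_ms(fs, window_ms),
                 n_triggers = length(trg), fs = fs,
                 hold_state = as.character(hold_state),
                 detrended = FALSE),
            class = "torque_stta")
}

#' @export
print.torque_stta <- function(x, ...) {
  cat(sprintf("<torque_stta> hold %s: n = %d, %s\n", x$hold_state, x$n_triggers,
              if (isTRUE(x$detrended))
                sprintf("detrended (orders x=%d, y=%d)", x$order_x, x$order_y)
              else "raw"))
  invisible(x)
}

# Polynomial fit of one trace; order chosen in 1..4 by BIC on an ordinary
# least-squares fit, final coefficients refit robustly (Tukey bisquare
# IRLS — redescending, so the evoked transient inside the fit window gets
# zero weight rather than dragging the baseline).
fit_trend <- function(trace, t, fit_mask, orders, robust) {
  n <- sum(fit_mask)
  # floor the RSS so numerically exact fits (rss ~ machine noise) compare
  # by the parsimony penalty alone
  floor_rss <- 1e-20 * max(sum(trace[fit_mask]^2), .Machine$double.xmin)
  bics <- vapply(orders, function(p) {
    X <- stats::poly(t[fit_mask], degree = p, raw = TRUE)
    f <- stats::lm.fit(cbind(1, X), trace[fit_mask])
    rss <- max(sum(f$residuals^2), floor_rss)
    n * log(rss / n) + (p + 2) * log(n)
  }, numeric(1))
  p <- orders[which.min(bics)]
  Xf <- cbind(1, stats::poly(t[fit_mask], degree = p, raw = TRUE))
  ols <- stats::lm.fit(Xf, trace[fit_mask])
  # an (essentially) exact OLS fit leaves nothing for the robust refit
  if (sum(ols$residuals^2) <= floor_rss) robust <- FALSE
  co <- if (robust) {
    fit <- tryCatch(MASS::rlm(Xf, trace[fit_mask], psi = MASS::psi.bisquare,
                              maxit = 100),
                    error = function(e) NULL)
    if (is.null(fit)) ols$coefficients else fit$coefficients
  } else ols$coefficients
  Xall <- cbind(1, stats::poly(t, degree = p, raw = TRUE))
  list(order = p, trend = as.vector(Xall %*% co))
}

#' Detrend a torque StTA
#'
#' Fits each axis with a polynomial of order 1-4 (order chosen by BIC) and
#' subtracts it, then recomputes the baseline mean and SD from the
#' `[-30, -10)` ms lags of the residual. `fit_window = "full"` (default)
#' fits the whole trace with redescending robust regression (Tukey
#' bisquare) so the evoked response is rejected rather than absorbed;
#' `fit_window = "baseline"` fits only the pre-trigger lags and
#' extrapolates.
#'
#' @param stta A raw `torque_stta`.
#' @param orders Candidate polynomial orders (default `1:4`).
#' @param fit_window `"full"` or `"baseline"`.
#' @return The `torque_stta` with detrended traces and added fields
#'   `order_x`, `order_y`, `baseline_mean_x/y`, `baseline_sd_x/y`,
#'   `detrended = TRUE`.
#' @export
detrend_stta <- function(stta, orders = 1:4, fit_window = c("full", "baseline")) {
  fit_window <- match.arg(fit_window)
  t <- stta$lags_ms / 1000
  mask <- if (fit_window == "full") rep(TRUE, length(t)) else stta$lags_ms < 0
  if (!any(mask)) stop("empty fit window")
  robust <- fit_window == "full"
  fx <- fit_trend(stta$trace_x, t, mask, orders, robust)
  fy <- fit_trend(stta$trace_y, t, mask, orders, robust)
  stta$trace_x <- stta$trace_x - fx$trend
  stta$trace_y <- stta$trace_y - fy$trend
  stta$order_x <- fx$order; stta$order_y <- fy$order
  bl <- stta$lags_ms >= BASELINE_MS[1] & stta$lags_ms < BASELINE_MS[2]
  stta$baseline_mean_x <- mean(stta$trace_x[bl])
  stta$baseline_sd_x <- stats::sd(stta$trace_x[bl])
  stta$baseline_mean_y <- mean(stta$trace_y[bl])
  stta$baseline_sd_y <- stats::sd(stta$trace_y[bl])
  stta$detrended <- TRUE
  stta
}

#' Detect an evoked torque in a detrended StTA
#'
#' The evoked torque is significant when either torque axis (or both)
#' deviates from its baseline mean by at least `k_sd` baseline SDs anywhere
#' in the search window (boundary inclusive). Its magnitude and direction
#' are the distance and angle from the baseline trajectory average
#' `(mu_x, mu_y)` to the farthest point of the trajectory within the search
#' window.
#'
#' @param stta A detrended `torque_stta`.
#' @param k_sd Detection threshold in baseline SDs (default 10).
#' @param search_window_ms Lags searched, default `c(0, 150)` (half-open).
#' @return An `evoked_torque`: list `significant`, `magnitude_nm`,
#'   `direction_deg` (`[0, 360)`), `time_ms` (lag of the farthest point),
#'   `peak_z_x`, `peak_z_y`, `n_triggers`, `hold_state`. When not
#'   significant, magnitude and direction are `NA` (no evoked vector).
#' @export
detect_evoked_torque <- function(stta, k_sd = 10, search_window_ms = c(0, 150)) {
  if (!isTRUE(stta$detrended)) stop("detrend the torque StTA first")
  if (stta$baseline_sd_x == 0 || stta$baseline_sd_y == 0)
    stop("degenerate baseline: zero SD on a torque axis")
  sel <- stta$lags_ms >= search_window_ms[1] & stta$lags_ms < search_window_ms[2]
  zx <- (stta$trace_x[sel] - stta$baseline_mean_x) / stta$baseline_sd_x
  zy <- (stta$trace_y[sel] - stta$baseline_mean_y) / stta$baseline_sd_y
  peak_z_x <- max(abs(zx)); peak_z_y <- max(abs(zy))
  significant <- peak_z_x >= k_sd || peak_z_y >= k_sd
  dx <- stta$trace_x[sel] - stta$baseline_mean_x
  dy <- stta$trace_y[sel] - stta$baseline_mean_y
  d2 <- dx^2 + dy^2
  i <- which.max(d2)
  out <- list(significant = significant,
              magnitude_nm = if (significant) sqrt(d2[i]) else NA_real_,
              direction_deg = if (significant)
                (atan2(dy[i], dx[i]) * 180 / pi) %% 360 else NA_real_,
              time_ms = if (significant) stta$lags_ms[sel][i] else NA_real_,
              peak_z_x = peak_z_x, peak_z_y = peak_z_y,
              n_triggers = stta$n_triggers, hold_state = stta$hold_state)
  class(out) <- "evoked_torque"
  out
}

#' @export
print.evoked_torque <- function(x, ...) {
  if (x$significant)
    cat(sprintf("<evoked_torque> hold %s: %.4g N.m at %.1f deg (t = %.1f ms, z = %.1f/%.1f)\n",
                x$hold_state, x$magnitude_nm, x$direction_deg, x$time_ms,
                x$peak_z_x, x$peak_z_y))
  else
    cat(sprintf("<evoked_torque> hold %s: not significant (z = %.1f/%.1f)\n",
                x$hold_state, x$peak_z_x, x$peak_z_y))
  invisible(x)
}

#' Normalize an evoked-torque direction by the voluntary direction
#'
#' The Normalized Torque: evoked direction minus the direction of
#' voluntary torque production, wrapped to `(-180, 180]`. 0 deg means the
#' stimulus boosts the voluntary direction; 180 deg opposes it.
#'
#' @param evoked_dir_deg,voluntary_dir_deg Angles in degrees.
#' @return Normalized direction in `(-180, 180]`.
#' @export
normalized_torque_direction <- function(evoked_dir_deg, voluntary_dir_deg) {
  if (any(!is.finite(evoked_dir_deg)) || any(!is.finite(voluntary_dir_deg)))
    stop("undefined direction")
  wrap_angle(evoked_dir_deg - voluntary_dir_deg)
}
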