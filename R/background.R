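#' Bin peristimulus sweeps by background EMG level
#'
#' Pools the sweeps of the eight peripheral hold states, sorts them by
#' per-sweep background EMG, and splits them into `n_bins` levels of
#' near-equal count (any remainder goes to the lowest bins, so counts
#' differ by at most one). Each level is averaged as an StTA in its own
#' right and its first post-stimulus effect detected with the bin's own
#' baseline statistics. Center-hold sweeps, when given, form a separate
#' point excluded from correlation.
#'
#' @param sweep_sets List of `sweep_set`s over the 8 peripheral targets
#'   (same muscle).
#' @param n_bins Number of background levels (default 5).
#' @param center_sweeps Optional center-hold `sweep_set`.
#' @param k_sd,min_duration_ms Detection parameters passed to
#'   [detect_pste()].
#' @param effect_type `NULL` (default): each bin reports its first detected
#'   effect of any type. Or `"Facilitation"`/`"Suppression"`: each bin
#'   reports the largest-area segment of that type (zero if none) — the
#'   level-wise magnitude of a condition whose effect type is already
#'   established from the per-target StTAs, robust to the sub-microvolt
#'   threshold crossings that binning on a noisy background estimate
#'   induces in the bin's own baseline.
#' @return A `bin_series`: data frame with one row per bin (`bin`, `n`,
#'   `background_uv`, `effect_type`, `area_uv_ms`, `onset_ms`), plus
#'   attributes `center` (the center-hold row or `NULL`) and `muscle`.
#' @export
bin_by_background <- function(sweep_sets, n_bins = 5, center_sweeps = NULL,
                              k_sd = 3, min_duration_ms = 1,
                              effect_type = NULL) {
  X <- do.call(rbind, lapply(sweep_sets, function(s) s$sweeps))
  bg <- unlist(lapply(sweep_sets, function(s) s$background_uv))
  if (length(bg) < n_bins) stop("too few sweeps: need at least one per bin")
  s1 <- sweep_sets[[1]]
  ord <- order(bg)
  sizes <- bin_sizes(length(bg), n_bins)
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1L
  measure_bin <- function(rows, label) {
    sub <- structure(list(muscle = s1$muscle, hold_state = label,
                          sweeps = X[rows, , drop = FALSE],
                          background_uv = bg[rows],
                          lags_ms = s1$lags_ms, fs = s1$fs),
                     class = "sweep_set")
    st <- compute_stta(sub)
    det <- detect_pste(st, k_sd = k_sd, min_duration_ms = min_duration_ms)
    fe <- pick_bin_effect(det, effect_type)
    data.frame(bin = label, n = length(rows), background_uv = mean(bg[rows]),
               effect_type = if (is.null(fe)) "None" else fe$effect_type,
               area_uv_ms = if (is.null(fe)) 0 else fe$area_uv_ms,
               onset_ms = if (is.null(fe)) NA_real_ else fe$onset_ms,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(n_bins), function(i)
    measure_bin(ord[starts[i]:stops[i]], as.character(i))))
  out$bin <- as.integer(out$bin)
  attr(out, "center") <- if (!is.null(center_sweeps) && nrow(center_sweeps$sweeps))
    measure_bin_external(center_sweeps, k_sd, min_duration_ms, effect_type) else NULL
  attr(out, "muscle") <- s1$muscle
  class(out) <- c("bin_series", "data.frame")
  out
}

measure_bin_external <- function(sweeps, k_sd, min_duration_ms,
                                 effect_type = NULL) {
  st <- compute_stta(sweeps)
  det <- detect_pste(st, k_sd = k_sd, min_duration_ms = min_duration_ms)
  fe <- pick_bin_effect(det, effect_type)
  data.frame(bin = "center", n = nrow(sweeps$sweeps),
             background_uv = mean(sweeps$background_uv),
             effect_type = if (is.null(fe)) "None" else fe$effect_type,
             area_uv_ms = if (is.null(fe)) 0 else fe$area_uv_ms,
             onset_ms = if (is.null(fe)) NA_real_ else fe$onset_ms,
             stringsAsFactors = FALSE)
}

# NULL type: the first PStE. Typed query: the dominant (largest-area)
# segment of that type.
pick_bin_effect <- function(det, effect_type) {
  if (is.null(effect_type)) return(det$first)
  sub <- det$effects[det$effects$effect_type == effect_type, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  sub[which.max(sub$area_uv_ms), , drop = FALSE]
}

# Equal-count split of n into k bins, remainder to the lowest bins.
bin_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  base + c(rep(1L, rem), rep(0L, k - rem))
}

#' Correlate effect magnitude with background EMG over bins
#'
#' Two-sided Pearson correlation between the per-bin background EMG and the
#' per-bin effect area. A condition whose bins all show the same effect
#' type is classified by that type; bins of mixed type (`"Faci/Supp"`) are
#' correlated separately per type over the bins where that type occurs
#' (at least 3 such bins required).
#'
#' @param series A `bin_series` from [bin_by_background()].
#' @return List `classification` (`"Facilitation"`, `"Suppression"`,
#'   `"Faci/Supp"`, or `"No response"`) and `correlations`, a data frame
#'   with one row per effect type present: `effect_type`, `n_bins`, `r`,
#'   `p_value`.
#' @export
correlate_pste_background <- function(series) {
  present <- setdiff(unique(series$effect_type), "None")
  classification <- if (length(present) == 0) "No response"
  else if (length(present) == 1) present
  else "Faci/Supp"
  rows <- lapply(present, function(tp) {
    sub <- series[series$effect_type == tp, , drop = FALSE]
    if (nrow(sub) < 3 || stats::sd(sub$background_uv) == 0 ||
        stats::sd(sub$area_uv_ms) == 0)
      return(data.frame(effect_type = tp, n_bins = nrow(sub),
                        r = NA_real_, p_value = NA_real_))
    ct <- stats::cor.test(sub$background_uv, sub$area_uv_ms,
                          alternative = "two.sided", method = "pearson")
    data.frame(effect_type = tp, n_bins = nrow(sub),
               r = unname(ct$estimate), p_value = ct$p.value)
  })
  correlations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(effect_type = character(0), n_bins = integer(0),
               r = numeric(0), p_value = numeric(0))
  list(classification = classification, correlations = correlations)
}
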