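#' Analysis pipeline configuration
#'
#' Collects every tunable analysis parameter with the study's defaults:
#' 100 ms EMG StTA window (30 pre / 70 post), 180 ms torque window (30 pre
#' / 150 post), 3 SD EMG detection with >= 1 ms duration, 10 SD torque
#' detection, 1000 shuffles for PD significance, 5 background levels.
#'
#' @param band EMG conditioning band in Hz (`c(5, 1000)`), or `NULL` when
#'   the stored EMG is already conditioned/rectified (the synthetic
#'   generator's output is).
#' @param emg_window_ms,torque_window_ms StTA windows (ms re trigger).
#' @param k_sd_emg,k_sd_torque Detection thresholds (baseline SDs).
#' @param min_duration_ms Minimum sustained EMG effect duration.
#' @param n_shuffles Shuffle repetitions for PD significance.
#' @param alpha Significance level.
#' @param significance_mode `"resultant"` or `"literal"` (see
#'   [pd_shuffle_test()]).
#' @param n_bins Background-EMG levels for the magnitude relation.
#' @param detrend_fit_window `"full"` or `"baseline"` (see
#'   [detrend_stta()]).
#' @param detrend_orders Candidate polynomial orders.
#' @param voluntary_direction `"target"` (commanded target angle; default)
#'   or `"measured"` (mean hold torque angle) for torque normalization.
#' @param trigger_rule `"containment"` or `"trigger_inside"` (see
#'   [assign_triggers()]).
#' @param seed Integer seed for the shuffle tests.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(band = NULL,
                            emg_window_ms = c(-30, 70),
                            torque_window_ms = c(-30, 150),
                            k_sd_emg = 3, k_sd_torque = 10,
                            min_duration_ms = 1,
                            n_shuffles = 1000, alpha = 0.05,
                            significance_mode = "resultant",
                            n_bins = 5,
                            detrend_fit_window = "full",
                            detrend_orders = 1:4,
                            voluntary_direction = "target",
                            trigger_rule = "containment",
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  stopifnot(cfg$k_sd_emg > 0, cfg$k_sd_torque > 0, cfg$n_bins >= 2,
            cfg$alpha > 0, cfg$alpha < 1)
  if (cfg$n_shuffles < 1) stop("n_shuffles must be >= 1")
  cfg
}

#' Run the full analysis pipeline on a session
#'
#' Orchestrates trigger assignment, per-muscle EMG StTAs and post-stimulus
#' effect detection over the eight peripheral targets and the center hold,
#' directional tuning with shuffle significance (background EMG and each
#' effect type) and PD normalization, background-level binning with the
#' magnitude correlation, torque StTAs with detrending and evoked-torque
#' extraction, and output-type classification with the per-condition area
#' sums. Deterministic for a fixed config + seed.
#'
#' @param session A `session_recording`, or a path readable by
#'   [read_session()].
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory: writes `pste.csv`, `tuning.csv`,
#'   `background_dependence.csv`, `evoked_torque.csv`,
#'   `population_stats.csv` and `run.json`.
#' @return List of the result tables (`pste`, `tuning`,
#'   `background_dependence`, `evoked_torque`, `population`), invisibly
#'   written to `out_dir` when given.
#' @export
run_pipeline <- function(session, cfg = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  rec <- if (is.character(session)) read_session(session) else session
  validate_session(rec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  if (!is.null(cfg$band))
    rec$emg <- lapply(rec$emg, condition_emg, fs = rec$sampling_rate_hz,
                      band = cfg$band)
  else
    rec$emg <- lapply(rec$emg, abs)

  stage <- function(name, expr) {
    t1 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    message(sprintf("stage %-22s %6.2f s", name,
                    as.numeric(Sys.time() - t1, units = "secs")))
    r
  }

  asg_emg <- stage("assign_triggers(emg)", assign_triggers(
    rec, post_window_ms = cfg$emg_window_ms[2],
    pre_window_ms = -cfg$emg_window_ms[1], rule = cfg$trigger_rule))
  asg_tq <- stage("assign_triggers(torque)", assign_triggers(
    rec, post_window_ms = cfg$torque_window_ms[2],
    pre_window_ms = -cfg$torque_window_ms[1], rule = cfg$trigger_rule))

  states <- c("center", as.character(TARGET_ANGLES))
  muscles <- names(rec$emg)

  emg_res <- stage("emg_stta", {
    lapply(muscles, function(m) {
      per_state <- lapply(states, function(st) {
        sw <- extract_sweeps(rec, m, asg_emg, st, window_ms = cfg$emg_window_ms)
        if (nrow(sw$sweeps) == 0) return(list(sweeps = sw, stta = NULL, det = NULL))
        stta <- compute_stta(sw)
        det <- detect_pste(stta, k_sd = cfg$k_sd_emg,
                           min_duration_ms = cfg$min_duration_ms,
                           search_window_ms = c(2, cfg$emg_window_ms[2]))
        list(sweeps = sw, stta = stta, det = det)
      })
      names(per_state) <- states
      per_state
    })
  })
  names(emg_res) <- muscles

  pste_rows <- list()
  for (m in muscles) for (st in states) {
    r <- emg_res[[m]][[st]]
    if (is.null(r$det) || is.null(r$det$first)) {
      pste_rows[[length(pste_rows) + 1L]] <- data.frame(
        muscle = m, hold_state = st, effect_type = "None",
        onset_ms = NA_real_, duration_ms = NA_real_, area_uv_ms = 0,
        n_triggers = nrow(r$sweeps$sweeps),
        background_uv = if (nrow(r$sweeps$sweeps)) mean(r$sweeps$background_uv) else NA_real_)
    } else {
      fe <- r$det$first
      pste_rows[[length(pste_rows) + 1L]] <- data.frame(
        muscle = m, hold_state = st, effect_type = fe$effect_type,
        onset_ms = fe$onset_ms, duration_ms = fe$duration_ms,
        area_uv_ms = fe$area_uv_ms, n_triggers = r$stta$n_triggers,
        background_uv = mean(r$sweeps$background_uv))
    }
  }
  pste <- do.call(rbind, pste_rows)

  tuning <- stage("directional_tuning", {
    rows <- list()
    for (m in muscles) {
      per <- emg_res[[m]]
      bg_vals <- unlist(lapply(as.character(TARGET_ANGLES), function(a)
        per[[a]]$sweeps$background_uv))
      bg_ang <- unlist(lapply(as.character(TARGET_ANGLES), function(a)
        rep(as.numeric(a), length(per[[a]]$sweeps$background_uv))))
      bg_pd <- pd_shuffle_test(bg_vals, bg_ang, n_reps = cfg$n_shuffles,
                               alpha = cfg$alpha, mode = cfg$significance_mode)
      rows[[length(rows) + 1L]] <- data.frame(
        muscle = m, source = "background EMG", pd_deg = bg_pd$pd_deg,
        r_bar = bg_pd$r_bar, p = bg_pd$p_value,
        significant = bg_pd$significant, normalized_pd_deg = NA_real_)
      for (tp in c("Facilitation", "Suppression")) {
        sweep_sets <- lapply(as.character(TARGET_ANGLES), function(a) per[[a]]$sweeps)
        names(sweep_sets) <- as.character(TARGET_ANGLES)
        wins <- lapply(as.character(TARGET_ANGLES), function(a) {
          fe <- per[[a]]$det$first
          if (!is.null(fe) && fe$effect_type == tp)
            c(fe$onset_ms, fe$onset_ms + fe$duration_ms) else NULL
        })
        names(wins) <- as.character(TARGET_ANGLES)
        if (sum(!vapply(wins, is.null, logical(1))) < 2) next
        pd <- pste_pd_shuffle_test(sweep_sets, wins, effect_type = tp,
                                   k_sd = cfg$k_sd_emg, n_reps = cfg$n_shuffles,
                                   alpha = cfg$alpha, mode = cfg$significance_mode)
        rows[[length(rows) + 1L]] <- data.frame(
          muscle = m, source = tp, pd_deg = pd$pd_deg, r_bar = pd$r_bar,
          p = pd$p_value, significant = pd$significant,
          normalized_pd_deg = if (is.finite(pd$pd_deg) && is.finite(bg_pd$pd_deg))
            normalized_spinal_pd(pd$pd_deg, bg_pd$pd_deg) else NA_real_)
      }
    }
    do.call(rbind, rows)
  })

  bgdep <- stage("background_dependence", {
    rows <- list()
    for (m in muscles) {
      per <- emg_res[[m]]
      sweep_sets <- lapply(as.character(TARGET_ANGLES), function(a) per[[a]]$sweeps)
      total <- sum(vapply(sweep_sets, function(s) nrow(s$sweeps), integer(1)))
      if (total < cfg$n_bins) next
      # level-wise magnitudes for each effect type the condition shows
      types <- unique(unlist(lapply(as.character(TARGET_ANGLES), function(a) {
        fe <- per[[a]]$det$first
        if (is.null(fe)) NULL else fe$effect_type
      })))
      if (!length(types)) next
      classification <- if (length(types) == 2) "Faci/Supp" else types
      for (tp in types) {
        ser <- bin_by_background(sweep_sets, n_bins = cfg$n_bins,
                                 center_sweeps = per[["center"]]$sweeps,
                                 k_sd = cfg$k_sd_emg,
                                 min_duration_ms = cfg$min_duration_ms,
                                 effect_type = tp)
        cr <- correlate_pste_background(ser)
        cri <- cr$correlations[cr$correlations$effect_type == tp, , drop = FALSE]
        for (i in seq_len(nrow(ser))) {
          rows[[length(rows) + 1L]] <- data.frame(
            muscle = m, bin = ser$bin[i], n = ser$n[i],
            background_uv = ser$background_uv[i], effect_type = tp,
            area_uv_ms = ser$area_uv_ms[i],
            r = if (nrow(cri)) cri$r else NA_real_,
            p = if (nrow(cri)) cri$p_value else NA_real_,
            classification = classification)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  torque <- stage("torque_analysis", {
    rows <- list()
    for (a in as.character(TARGET_ANGLES)) {
      if (length(assigned_triggers(asg_tq, a)) == 0) next
      st <- compute_torque_stta(rec, asg_tq, a, window_ms = cfg$torque_window_ms)
      st <- detrend_stta(st, orders = cfg$detrend_orders,
                         fit_window = cfg$detrend_fit_window)
      ev <- detect_evoked_torque(st, k_sd = cfg$k_sd_torque,
                                 search_window_ms = c(0, cfg$torque_window_ms[2]))
      vol <- if (cfg$voluntary_direction == "target") as.numeric(a)
      else measured_hold_direction(rec, a)
      rows[[length(rows) + 1L]] <- data.frame(
        hold_state = a, significant = ev$significant,
        magnitude_nm = ev$magnitude_nm, direction_deg = ev$direction_deg,
        normalized_direction_deg = if (ev$significant)
          normalized_torque_direction(ev$direction_deg, vol) else NA_real_,
        order_x = st$order_x, order_y = st$order_y,
        n_triggers = ev$n_triggers)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  population <- stage("population_stats", {
    rows <- lapply(muscles, function(m) {
      per <- emg_res[[m]]
      fe <- lapply(as.character(TARGET_ANGLES), function(a) per[[a]]$det$first)
      names(fe) <- as.character(TARGET_ANGLES)
      cls <- classify_output_type(fe)
      data.frame(muscle = m, output_type = cls$output_type,
                 facilitation_sum_uv_ms = cls$facilitation_sum,
                 suppression_sum_uv_ms = cls$suppression_sum)
    })
    do.call(rbind, rows)
  })

  res <- list(pste = pste, tuning = tuning, background_dependence = bgdep,
              evoked_torque = torque, population = population)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res)) {
      if (is.null(res[[nm]])) next
      fn <- if (nm == "population") "population_stats" else nm
      data.table::fwrite(res[[nm]], file.path(out_dir, paste0(fn, ".csv")))
    }
    cfg_echo <- cfg
    class(cfg_echo) <- NULL
    jsonlite::write_json(
      list(config = cfg_echo, seed = cfg$seed,
           package_version = as.character(utils::packageVersion("stimtune")),
           n_triggers = length(rec$trigger_times_s),
           muscles = muscles,
           elapsed_s = as.numeric(Sys.time() - t0, units = "secs")),
      file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, force = TRUE)
  }
  invisible(res)
}

# Mean torque direction during the hold intervals of one target.
measured_hold_direction <- function(rec, hold_state) {
  iv <- segment_hold_states(rec$events)[[as.character(hold_state)]]
  fs <- rec$sampling_rate_hz
  idx <- unlist(lapply(seq_len(nrow(iv)), function(i)
    (floor(iv[i, 1] * fs) + 1L):min(ceiling(iv[i, 2] * fs), length(rec$torque_x))))
  (atan2(mean(rec$torque_y[idx]), mean(rec$torque_x[idx])) * 180 / pi) %% 360
}

#' Generate and write a synthetic session
#'
#' Wraps [generate_session()] and [write_session()]; the ground truth is
#' written as `truth.json` beside the session files.
#'
#' @param gen_cfg A [generator_config()].
#' @param out_path Session directory to create.
#' @return The `generate_session()` result, invisibly.
#' @export
simulate_session <- function(gen_cfg, out_path) {
  g <- generate_session(gen_cfg)
  write_session(g$session, out_path)
  jsonlite::write_json(g$truth, file.path(out_path, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(g)
}
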