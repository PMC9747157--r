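test_that("condition_emg rectifies and filters as specified", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  # constant input: high-pass kills it
  out <- condition_emg(rep(5, length(t)), fs, band = c(5, 1000))
  expect_true(all(out >= 0))
  expect_lt(mean(out[200:3800]), 0.05)
  # 50 Hz unit sine: rectified mean = 2/pi
  s <- sin(2 * pi * 50 * t)
  out <- condition_emg(s, fs, band = c(5, 1000))
  expect_equal(mean(out[500:3500]), 2 / pi, tolerance = 0.02)
  # pass-through mode: pure rectification
  x <- abs(rnorm(1000))
  expect_identical(condition_emg(x, fs, band = NULL), x)
  expect_error(condition_emg(x, fs, band = c(100, 50)), "band_low")
})

test_that("sweep extraction yields 200 samples with 40 baseline lags at 2 kHz", {
  rec <- tiny_session()
  asg <- assign_triggers(rec)
  sw <- extract_sweeps(rec, "m1", asg, "90")
  expect_equal(ncol(sw$sweeps), 200)
  expect_equal(sum(sw$lags_ms >= -30 & sw$lags_ms < -10), 40)
  expect_equal(sw$lags_ms[1], -30)
  expect_equal(sw$lags_ms[200], 69.5)
  # all-constant EMG: background equals the constant
  expect_true(all(sw$background_uv == 10))
  # zero assigned triggers: flagged empty set, not an error
  sw0 <- extract_sweeps(rec, "m1", asg, "45")
  expect_equal(nrow(sw0$sweeps), 0)
  expect_error(compute_stta(sw0), "empty sweep set")
  expect_error(extract_sweeps(rec, "nope", asg, "90"), "unknown muscle")
})

test_that("compute_stta is the per-lag mean with baseline stats from the trace", {
  rec <- tiny_session()
  rec$emg$m1 <- rep(c(0, 2), length.out = length(rec$emg$m1))
  # two constant-sweep signals: build directly
  sw <- structure(list(muscle = "m1", hold_state = "90",
                       sweeps = rbind(rep(0, 200), rep(2, 200)),
                       background_uv = c(0, 2),
                       lags_ms = -30 + (0:199) * 0.5, fs = 2000),
                  class = "sweep_set")
  st <- compute_stta(sw)
  expect_true(all(st$trace == 1))
  expect_equal(st$baseline_mean, 1)
  expect_equal(st$baseline_sd, 0)
  expect_error(detect_pste(st), "degenerate baseline")
})

test_that("detect_pste reproduces the hand-computed facilitation example", {
  fs <- 2000
  lags <- -30 + (0:199) / fs * 1000
  trace <- rep(10, 200)
  trace[lags >= 4 & lags < 6] <- c(20, 24, 24, 20)
  st <- as_stta(trace, fs, baseline_mean = 10, baseline_sd = 2)
  det <- detect_pste(st, k_sd = 3)
  expect_equal(nrow(det$effects), 1)
  fe <- det$first
  expect_equal(fe$effect_type, "Facilitation")
  expect_equal(fe$onset_ms, 4.0)
  expect_equal(fe$duration_ms, 2.0)
  expect_equal(fe$area_uv_ms, 12)  # (4+8+8+4) * 0.5 above the 16 uV bound
})

test_that("sub-millisecond excursions and flat traces yield no effect", {
  fs <- 2000
  lags <- -30 + (0:199) / fs * 1000
  trace <- rep(10, 200)
  st <- as_stta(trace, fs, baseline_mean = 10, baseline_sd = 2)
  expect_null(detect_pste(st)$first)
  trace[lags == 10] <- 30  # one sample = 0.5 ms < 1 ms minimum
  st <- as_stta(trace, fs, baseline_mean = 10, baseline_sd = 2)
  expect_null(detect_pste(st)$first)
  # the [0, 2) ms artifact mask carries no detection
  trace <- rep(10, 200)
  trace[lags >= 0 & lags < 2] <- 100
  st <- as_stta(trace, fs, baseline_mean = 10, baseline_sd = 2)
  expect_null(detect_pste(st)$first)
})

test_that("detection equals the brute-force per-sample oracle on random traces", {
  fs <- 2000
  lags <- -30 + (0:199) / fs * 1000
  set.seed(7)
  for (i in 1:300) {
    mu <- runif(1, 5, 20)
    sdev <- runif(1, 0.5, 3)
    trace <- mu + rnorm(200, sd = sdev * runif(1, 0.5, 2))
    # sprinkle structured excursions to exercise runs of all lengths
    n_b <- sample(0:3, 1)
    for (b in seq_len(n_b)) {
      at <- sample(60:190, 1)
      len <- sample(1:8, 1)
      idx <- at:min(at + len - 1, 200)
      trace[idx] <- trace[idx] + sample(c(-1, 1), 1) * runif(1, 2, 8) * sdev
    }
    st <- as_stta(trace, fs, baseline_mean = mu, baseline_sd = sdev)
    got <- detect_pste(st)$effects
    want <- naive_detect(trace, lags, mu, sdev, fs)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$effect_type, want$effect_type)
      expect_equal(got$onset_ms, want$onset_ms)
      expect_equal(got$duration_ms, want$duration_ms)
      expect_equal(got$area_uv_ms, want$area_uv_ms)
    }
  }
})

test_that("area is invariant to adding a constant to the whole trace", {
  fs <- 2000
  set.seed(11)
  trace <- 10 + rnorm(200, sd = 1)
  trace[120:130] <- trace[120:130] + 8
  st1 <- as_stta(trace, fs)
  st2 <- as_stta(trace + 37.5, fs)
  d1 <- detect_pste(st1)$effects
  d2 <- detect_pste(st2)$effects
  expect_equal(d1$area_uv_ms, d2$area_uv_ms)
  expect_equal(d1$onset_ms, d2$onset_ms)
})

test_that("the first effect is the earliest-onset segment, ties to larger area", {
  fs <- 2000
  lags <- -30 + (0:199) / fs * 1000
  trace <- rep(10, 200)
  trace[lags >= 5 & lags < 7] <- 2     # suppression first
  trace[lags >= 20 & lags < 24] <- 25  # later facilitation
  st <- as_stta(trace, fs, baseline_mean = 10, baseline_sd = 2)
  det <- detect_pste(st)
  expect_equal(nrow(det$effects), 2)
  expect_equal(det$first$effect_type, "Suppression")
  expect_equal(det$first$onset_ms, 5.0)
})

test_that("output-type classification covers all five categories", {
  mk <- function(tp, area) if (is.na(tp)) NULL else
    data.frame(effect_type = tp, onset_ms = 5, duration_ms = 2,
               area_uv_ms = area, threshold_uv = 1)
  lbl <- as.character(seq(0, 315, 45))
  all_f <- setNames(lapply(1:8, function(i) mk("Facilitation", 10)), lbl)
  expect_equal(classify_output_type(all_f)$output_type, "Facilitation")
  all_s <- setNames(lapply(1:8, function(i) mk("Suppression", 10)), lbl)
  expect_equal(classify_output_type(all_s)$output_type, "Suppression")
  none <- setNames(lapply(1:8, function(i) NULL), lbl)
  expect_equal(classify_output_type(none)$output_type, "No response")
  mixed <- setNames(c(lapply(1:5, function(i) mk("Facilitation", 10)),
                      lapply(1:3, function(i) mk("Suppression", 10 / 3))), lbl)
  cls <- classify_output_type(mixed)
  expect_equal(cls$output_type, "Facilitation+ and Suppression")
  expect_equal(cls$facilitation_sum, 50)
  expect_equal(cls$suppression_sum, 10)
  mixed2 <- setNames(c(lapply(1:2, function(i) mk("Facilitation", 1)),
                       lapply(1:6, function(i) mk("Suppression", 20))), lbl)
  expect_equal(classify_output_type(mixed2)$output_type,
               "Facilitation and Suppression+")
  expect_error(classify_output_type(all_f[1:7]), "8 peripheral targets")
})
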