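test_that("wrap_angle maps to (-180, 180] with the boundary closed above", {
  expect_equal(wrap_angle(270 - 315), -45)
  expect_equal(wrap_angle(-190), 170)
  expect_equal(wrap_angle(180), 180)
  expect_equal(wrap_angle(-180), 180)
  expect_equal(wrap_angle(725), 5)
  expect_error(wrap_angle(NaN), "non-finite")
})

test_that("preferred direction by vector summation matches the oracle", {
  ang <- seq(0, 315, by = 45)
  # all mass at 90
  m <- c(0, 0, 1, 0, 0, 0, 0, 0)
  pd <- preferred_direction(m, ang)
  expect_equal(pd$pd_deg, 90)
  expect_equal(pd$r_bar, 1)
  # symmetric curve about 135
  m <- c(1, 2, 3, 4, 3, 2, 1, 0)
  expect_equal(preferred_direction(m, ang)$pd_deg, 135)
  expect_equal(naive_pd(m, ang), 135)
  # balanced curve: undefined PD
  expect_true(is.na(preferred_direction(rep(1, 8), ang)$pd_deg))
  expect_true(is.na(preferred_direction(rep(0, 8), ang)$pd_deg))
  # random curves agree with the loop oracle; |R| <= sum(m)
  set.seed(5)
  for (i in 1:50) {
    m <- runif(8)
    pd <- preferred_direction(m, ang)
    expect_equal(pd$pd_deg, naive_pd(m, ang))
    expect_lte(pd$resultant_length, sum(m) + 1e-12)
  }
})

test_that("PD is equivariant under rotation of all angles", {
  set.seed(8)
  ang <- seq(0, 315, by = 45)
  m <- runif(8)
  base <- preferred_direction(m, ang)$pd_deg
  for (delta in c(10, 45, 123, 270)) {
    rot <- preferred_direction(m, (ang + delta) %% 360)$pd_deg
    expect_equal(wrap_angle(rot - base - delta), 0, tolerance = 1e-9)
  }
})

test_that("shuffle PD test flags tuned data and spares untuned data", {
  set.seed(21)
  ang <- rep(seq(0, 315, by = 45), each = 50)
  # strongly tuned per-trigger magnitudes
  tuned <- (1 + 0.8 * cos((ang - 90) * pi / 180)) * abs(rnorm(length(ang))) * sqrt(pi / 2)
  r <- pd_shuffle_test(tuned, ang, n_reps = 500)
  expect_true(r$significant)
  expect_lt(abs(wrap_angle(r$pd_deg - 90)), 25)
  # untuned
  flat <- abs(rnorm(length(ang)))
  hits <- sum(replicate(40, {
    flat <- abs(rnorm(length(ang)))
    pd_shuffle_test(flat, ang, n_reps = 200)$significant
  }))
  expect_lte(hits, 8)  # ~5% expected; 8/40 leaves wide Monte-Carlo slack
  expect_error(pd_shuffle_test(1:5, rep(0, 5)), "2 directions")
  expect_error(pd_shuffle_test(tuned, ang, n_reps = 0), "n_reps")
})

test_that("literal shuffle mode accepts/rejects by the sorted-angle interval", {
  set.seed(22)
  ang <- rep(seq(0, 315, by = 45), each = 30)
  tuned <- (1 + 0.9 * cos((ang - 180) * pi / 180)) * abs(rnorm(length(ang)))
  r <- pd_shuffle_test(tuned, ang, n_reps = 500, mode = "literal")
  expect_equal(r$mode, "literal")
  expect_type(r$significant, "logical")
})

test_that("sweep-based PStE shuffle test recovers tuned facilitation", {
  cfg <- quick_cfg(n_trials_per_target = 20, g0 = 0, g1 = 1, s = 0)
  g <- generate_session(cfg)
  asg <- assign_triggers(g$session)
  lbl <- as.character(seq(0, 315, by = 45))
  sweep_sets <- lapply(lbl, function(a) extract_sweeps(g$session, "ECR", asg, a))
  names(sweep_sets) <- lbl
  wins <- lapply(lbl, function(a) {
    fe <- detect_pste(compute_stta(sweep_sets[[a]]))$first
    if (!is.null(fe) && fe$effect_type == "Facilitation")
      c(fe$onset_ms, fe$onset_ms + fe$duration_ms) else NULL
  })
  names(wins) <- lbl
  r <- pste_pd_shuffle_test(sweep_sets, wins, "Facilitation", n_reps = 200)
  expect_true(r$significant)
  expect_lt(abs(wrap_angle(r$pd_deg - 0)), 30)  # ECR true PD = 0
})

test_that("Rayleigh test matches closed-form anchors and handles balance", {
  r <- rayleigh_test(rep(45, 8))
  expect_equal(r$r_bar, 1)
  expect_equal(r$Z, 8)
  expect_lt(r$p_value, 0.001)
  r0 <- rayleigh_test(c(0, 90, 180, 270))
  expect_equal(r0$r_bar, 0, tolerance = 1e-12)
  expect_gt(r0$p_value, 0.99)
  expect_error(rayleigh_test(10), "n >= 2")
})

test_that("V-test matches its closed form and is one-sided", {
  v <- v_test(rep(0, 10), 0)
  expect_equal(v$u, sqrt(20))
  expect_lt(v$p_value, 1e-4)
  v2 <- v_test(rep(180, 10), 0)
  expect_lt(v2$V, 0)
  expect_gt(v2$p_value, 0.5)
  expect_error(v_test(5, 0), "n >= 2")
})

test_that("circular median equals the exhaustive-search oracle", {
  expect_equal(circular_median(c(0, 0, 90)), 0)
  expect_equal(circular_median(123), 123)
  set.seed(14)
  for (i in 1:30) {
    a <- runif(15, 0, 360)
    got <- circular_median(a)
    cost <- sapply(a, function(cand) sum(abs(wrap_angle(a - cand))))
    expect_equal(min(abs(wrap_angle(got - a[abs(cost - min(cost)) < 1e-9]))), 0)
    expect_equal(sum(abs(wrap_angle(a - got))), min(cost))
  }
  # wrap-around cluster: median stays in the cluster, not at its antipode
  a <- c(350, 355, 0, 5, 10)
  expect_equal(circular_median(a), 0)
})

test_that("normalized spinal PD is the wrapped PD difference", {
  expect_equal(normalized_spinal_pd(270, 315), -45)
  expect_equal(normalized_spinal_pd(10, 350), 20)
  expect_equal(normalized_spinal_pd(90, 90), 0)
})
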