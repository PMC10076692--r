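test_that("grip force series averages the two digits' normal forces", {
  expect_equal(unique(grip_force_series(flat_trial(4, 4))$force_N), 4)
  expect_equal(unique(grip_force_series(flat_trial(2, 6))$force_N), 4)
  expect_equal(unique(grip_force_series(flat_trial(0, 4))$force_N), 2)
  expect_equal(unique(grip_force_series(flat_trial(2, 6), "sum")$force_N), 8)
})

test_that("a missing digit is reported by name", {
  t <- seq(0, 6, by = 1 / 500)
  forces <- tibble::tibble(time_s = t, digit = "thumb", fn_N = 4,
                           ft1_N = 0, ft2_N = 0)
  expect_error(grip_trial(forces), "index")
})

test_that("baseline statistics are the sample mean and n-1 SD", {
  tr <- flat_trial(0.5)
  bl <- baseline_stats(grip_force_series(tr), cue_grip = 2)
  expect_equal(bl$mean, 0.5)
  expect_equal(bl$sd, 0)

  s3 <- tibble::tibble(time_s = c(1.7, 1.8, 1.9, rep(2.5, 7)),
                       force_N = c(1, 2, 3, rep(0, 7)))
  expect_error(baseline_stats(s3, cue_grip = 2), "at least 10")

  s10 <- tibble::tibble(time_s = seq(1.55, 2.0, by = 0.05),
                        force_N = c(1, 2, 3, rep(2, 7)))
  bl10 <- baseline_stats(s10, cue_grip = 2.01)
  expect_equal(bl10$mean, mean(s10$force_N))
  expect_equal(bl10$sd, sd(s10$force_N))

  # seeded draw against an independent two-pass oracle
  set.seed(11)
  x <- rnorm(2500, 1, 0.3)
  s <- tibble::tibble(time_s = seq_len(2500) / 500, force_N = x)
  bl_big <- baseline_stats(s, cue_grip = 5.001, window_s = 5.01)
  m_oracle <- sum(x) / length(x)
  sd_oracle <- sqrt(sum((x - m_oracle)^2) / (length(x) - 1))
  expect_equal(bl_big$mean, m_oracle, tolerance = 1e-12)
  expect_equal(bl_big$sd, sd_oracle, tolerance = 1e-12)
})

test_that("onset detection finds a clean step within one sample", {
  cfg <- grip_config()
  step <- function(t) ifelse(t >= 2.2, 1, 0)
  tr <- shaped_trial(step)
  series <- grip_force_series(tr)
  rt <- detect_onset(series, 2, baseline_mean = 0, baseline_sd = 0.01,
                     config = cfg)
  expect_lt(abs(rt - 0.2), 1 / 500 + 1e-9)

  # never exceeds threshold: invalid, no exception
  expect_true(is.na(detect_onset(grip_force_series(flat_trial(0)), 2,
                                 0, 0.01, cfg)))
  # already above threshold at the cue
  expect_lt(detect_onset(grip_force_series(flat_trial(4)), 2, 0, 0.01,
                         cfg), 1 / 500 + 1e-9)
})

test_that("offset detection mirrors onset on a decaying trace", {
  cfg <- grip_config()
  b <- 0; hold <- 4; tau <- 0.08
  thr <- b + 3 * 0.01
  # decay start chosen so the threshold crossing lands at cue_rest + 0.35
  t_cross <- 4 + 0.35
  t_start <- t_cross - tau * log((hold - b) / thr)
  decay <- function(t) ifelse(t < t_start, hold,
                              b + (hold - b) * exp(-(t - t_start) / tau))
  tr <- shaped_trial(decay)
  rx <- detect_offset(grip_force_series(tr), 4, b, 0.01, cfg)
  expect_lt(abs(rx - 0.35), 1 / 500 + 1e-9)

  # already at baseline at the rest cue
  expect_lt(detect_offset(grip_force_series(flat_trial(0)), 4, 0, 0.01,
                          cfg), 1 / 500 + 1e-9)
  # never returns within the search horizon
  expect_true(is.na(detect_offset(grip_force_series(flat_trial(4)), 4,
                                  0, 0.01, cfg)))
})

test_that("onset/offset agree with a linear-scan oracle on random traces", {
  cfg <- grip_config()
  set.seed(202)
  for (i in 1:50) {
    rt_true <- runif(1, 0.1, 1.2)
    rx_true <- runif(1, 0.3, 1.4)
    spec <- cohort_spec(n_participants = 1, seed = 1,
                        trial_noise_sd = runif(1, 0, 0.05))
    tr <- synthesize_trial(spec, reaction_s = rt_true,
                           relaxation_s = rx_true, magnitude_N = 0.5,
                           direction_deg = 10)
    series <- grip_force_series(tr)
    bl <- baseline_stats(series, 2, cfg$baseline_window_s)
    thr <- bl$mean + 3 * max(bl$sd, cfg$sd_floor_N)
    sustain_n <- as.integer(round(cfg$sustain_s * 500))
    on_oracle <- scan_crossing(series$force_N, series$time_s, 2, thr,
                               TRUE, sustain_n, cfg$max_latency_s)
    off_oracle <- scan_crossing(series$force_N, series$time_s, 4, thr,
                                FALSE, sustain_n, cfg$max_latency_s)
    on <- detect_onset(series, 2, bl$mean, bl$sd, cfg)
    off <- detect_offset(series, 4, bl$mean, bl$sd, cfg)
    expect_equal(on, on_oracle, tolerance = 1 / 500)
    expect_equal(off, off_oracle, tolerance = 1 / 500)
  }
})

test_that("peak strength is the maximum of the combined series", {
  ramp <- function(t) pmax(0, 30 - 15 * abs(t - 3))
  tr <- shaped_trial(ramp, trial_kind = "max_grip")
  expect_equal(peak_strength(tr), 30)
  expect_equal(peak_strength(flat_trial(10, trial_kind = "max_grip")), 10)
  set.seed(5)
  noisy <- function(t) pmax(0, 25 - 10 * abs(t - 3)) + runif(length(t))
  set.seed(5)
  tr2 <- shaped_trial(noisy, trial_kind = "max_grip")
  expect_equal(peak_strength(tr2),
               max(grip_force_series(tr2)$force_N))
  expect_error(peak_strength(flat_trial(4)), "max_grip")
})

test_that("magnitude error is |target - mean hold force|", {
  cfg <- grip_config()
  s5 <- grip_force_series(flat_trial(5))
  expect_equal(magnitude_error(s5, 2, 4, onset_s = 0.2, cfg), 1)
  s4 <- grip_force_series(flat_trial(4))
  expect_equal(magnitude_error(s4, 2, 4, onset_s = 0.2, cfg), 0)
  # linear ramp symmetric about 4 N across the hold window averages to 4
  lo <- 2 + 0.2 + cfg$transient_s
  ramp <- function(t) 3 + 2 * (t - lo) / (4 - lo)
  sr <- grip_force_series(shaped_trial(ramp))
  expect_equal(magnitude_error(sr, 2, 4, onset_s = 0.2, cfg),
               0, tolerance = 1e-3)
  expect_true(is.na(magnitude_error(s5, 2, 4, onset_s = NA_real_, cfg)))
})

test_that("direction error matches the analytic angle", {
  make_dir_trial <- function(fn, ft1, ft2) {
    t <- seq(0, 6, by = 1 / 500)
    forces <- dplyr::bind_rows(
      tibble::tibble(time_s = t, digit = "thumb", fn_N = fn, ft1_N = ft1,
                     ft2_N = ft2),
      tibble::tibble(time_s = t, digit = "index", fn_N = fn, ft1_N = ft1,
                     ft2_N = ft2)
    )
    grip_trial(forces, cue_grip = 2, cue_rest = 4)
  }
  expect_equal(direction_error(make_dir_trial(5, 0, 0), 0.1), 0)
  expect_equal(direction_error(make_dir_trial(4, 3, 0), 0.1),
               atan(3 / 4) * 180 / pi, tolerance = 1e-10)
  expect_equal(direction_error(make_dir_trial(0, 5, 0), 0.1), 90)
  # all samples below the magnitude floor: no angle defined
  expect_true(is.na(direction_error(make_dir_trial(0.01, 0.01, 0), 0.1)))
})

test_that("direction error is invariant to shear rotation and scaling", {
  base <- c(fn = 4, ft1 = 2, ft2 = 1)
  ang <- function(fn, ft1, ft2) {
    t <- seq(0, 6, by = 1 / 500)
    forces <- dplyr::bind_rows(
      tibble::tibble(time_s = t, digit = "thumb", fn_N = fn, ft1_N = ft1,
                     ft2_N = ft2),
      tibble::tibble(time_s = t, digit = "index", fn_N = fn, ft1_N = ft1,
                     ft2_N = ft2)
    )
    direction_error(grip_trial(forces, cue_grip = 2, cue_rest = 4), 0.1)
  }
  ref <- ang(base["fn"], base["ft1"], base["ft2"])
  for (phi in c(0.3, 1.2, 2.9)) {
    rot1 <- cos(phi) * base["ft1"] - sin(phi) * base["ft2"]
    rot2 <- sin(phi) * base["ft1"] + cos(phi) * base["ft2"]
    expect_equal(ang(base["fn"], rot1, rot2), ref, tolerance = 1e-10)
  }
  for (sc in c(0.5, 3)) {
    expect_equal(ang(sc * base["fn"], sc * base["ft1"], sc * base["ft2"]),
                 ref, tolerance = 1e-10)
  }
})

test_that("metrics are invariant to a joint time shift", {
  spec <- cohort_spec(n_participants = 1, seed = 9, trial_noise_sd = 0)
  tr <- synthesize_trial(spec, reaction_s = 0.4, relaxation_s = 0.6,
                         magnitude_N = 0.7, direction_deg = 15)
  m0 <- trial_metrics(tr)
  shift <- 1.5
  shifted <- tibble::as_tibble(tr)
  shifted$time_s <- shifted$time_s + shift
  tr2 <- grip_trial(shifted, cue_grip = attr(tr, "cue_grip") + shift,
                    cue_rest = attr(tr, "cue_rest") + shift)
  m1 <- trial_metrics(tr2)
  expect_equal(m1$reaction_s, m0$reaction_s, tolerance = 1e-9)
  expect_equal(m1$relaxation_s, m0$relaxation_s, tolerance = 1e-9)
  expect_equal(m1$magnitude_N, m0$magnitude_N, tolerance = 1e-9)
  expect_equal(m1$direction_deg, m0$direction_deg, tolerance = 1e-9)
})

test_that("paretic ratios behave as p / (p + q)", {
  mk_summary <- function(p_strength, q_strength) {
    tibble::tibble(
      hand = c("paretic", "nonparetic"),
      mean_strength_N = c(p_strength, q_strength),
      mean_reaction_s = c(0.6, 0.4),
      mean_relaxation_s = c(0.5, 0.5),
      mean_magnitude_N = c(0.4, 0.4),
      mean_direction_deg = c(10, 10)
    )
  }
  r <- performance_ratios(mk_summary(10, 10))
  expect_equal(r$ratio_strength, 0.5)
  expect_equal(r$ratio_reaction, 0.6)
  r0 <- performance_ratios(mk_summary(0, 20))
  expect_equal(r0$ratio_strength, 0)
  expect_warning(rz <- performance_ratios(mk_summary(0, 0)), "zero")
  expect_true(is.na(rz$ratio_strength))
  # monotone in the paretic value, bounded in [0, 1]
  vals <- sapply(seq(0, 40, by = 5), function(p) {
    performance_ratios(mk_summary(p, 10))$ratio_strength
  })
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("repetitions average per hand and invalid metrics are excluded", {
  metrics <- tibble::tibble(
    hand = c("paretic", "paretic", "nonparetic"),
    trial_kind = "target_grip",
    strength_N = NA_real_,
    reaction_s = c(0.4, NA, 0.3),
    relaxation_s = c(0.5, 0.7, 0.4),
    magnitude_N = c(1, 3, 2),
    direction_deg = c(10, 20, 5)
  )
  s <- summarize_trials(metrics)
  p <- s[s$hand == "paretic", ]
  expect_equal(p$mean_reaction_s, 0.4)
  expect_equal(p$n_reaction_s, 1)
  expect_equal(p$mean_relaxation_s, 0.6)
  expect_true(is.na(p$mean_strength_N))
})
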