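test_that("envelope is rectification plus smoothing", {
  fs <- 8000
  cfg <- csp_config()
  const <- emg_trace(rep(-0.3, 4000), fs, stim_time = 200)
  expect_equal(compute_envelope(const, cfg), rep(0.3, 4000))
  zero <- emg_trace(numeric(4000), fs, stim_time = 200)
  expect_equal(compute_envelope(zero, cfg), numeric(4000))
  # rectified fast sine averages to 2/pi of its amplitude (a frequency
  # incommensurate with fs, so samples slide through all phases)
  t <- (0:3999) / fs
  sine <- emg_trace(sin(2 * pi * 1237 * t), fs, stim_time = 200)
  env <- compute_envelope(sine, cfg)
  expect_equal(mean(env[100:3900]), 2 / pi, tolerance = 0.01)
  expect_error(compute_envelope(emg_trace(1:10 / 10, fs, 0), cfg), "window")
})

test_that("baseline statistics use the pre-stimulus window", {
  fs <- 8000
  cfg <- csp_config()
  const <- emg_trace(rep(0.2, 4800), fs, stim_time = 200)
  bl <- baseline_stats(const, cfg)
  expect_equal(bl$mean, 0.2)
  expect_equal(bl$sd, 0)
  expect_equal(bl$rms, 0.2)
  expect_equal(bl$n, 800L)  # 100 ms at 8 kHz
  expect_error(baseline_stats(const, csp_config(baseline_window = c(-300, -10))),
               "window")
})

test_that("MEP amplitude and duration are recovered at the published scale", {
  cfg <- csp_config()
  res <- t(vapply(1:20, function(s) {
    sw <- synthesize_emg_trial(emg_params(), seed = 1000 + s)
    m <- detect_mep(sw$trace, cfg)
    c(m$mep_amp_pp, m$mep_duration,
      m$mep_onset - sw$truth$true_mep_onset)
  }, numeric(3)))
  expect_lt(abs(median(res[, 1]) - 0.49) / 0.49, 0.05)
  expect_lte(abs(median(res[, 2]) - 35), 3)
  expect_lte(abs(median(res[, 3])), 3)
})

test_that("a sweep without an MEP raises a detection error", {
  p <- emg_params(mep_amp_pp = 0, silence_floor = 1, csp_duration = 0)
  sw <- synthesize_emg_trial(p, seed = 77)
  expect_error(detect_mep(sw$trace, csp_config()), "no MEP")
})

test_that("noise-free silent period is recovered to within the smoothing window", {
  p <- emg_params(silence_floor = 0, csp_duration = 120)
  sw <- synthesize_emg_trial(p, seed = 6)
  cfg <- csp_config()
  m <- detect_mep(sw$trace, cfg)
  csp <- detect_csp(sw$trace, cfg, m$mep_offset)
  expect_lte(abs(csp$csp_abs - (sw$truth$true_csp_end - m$mep_offset)),
             cfg$smoothing_window)
  expect_equal(csp$csp_end - m$mep_offset, csp$csp_abs)
})

test_that("detect_csp matches the exhaustive scan oracle sample for sample", {
  cfg <- csp_config()
  set.seed(31)
  csp_true <- runif(30, 50, 200)
  for (k in seq_along(csp_true)) {
    sw <- synthesize_emg_trial(emg_params(csp_duration = csp_true[k]),
                               seed = 2000 + k)
    tr <- sw$trace
    env <- compute_envelope(tr, cfg)
    bl <- baseline_stats(tr, cfg, env)
    m <- detect_mep(tr, cfg, bl)
    got <- detect_csp(tr, cfg, m$mep_offset, bl, env)
    th <- max(bl$mean - cfg$k_sd * bl$sd, cfg$csp_floor_frac * bl$mean, 0)
    start_i <- as.integer(round(m$mep_offset * tr$fs / 1000)) + 1L
    want_i <- oracle_csp_scan(env, start_i, th, 80L)
    expect_identical(as.integer(round(got$csp_end * tr$fs / 1000)) + 1L,
                     want_i)
  }
})

test_that("an unterminated silent period raises", {
  # silence to the end of the sweep: no sustained return exists
  p <- emg_params(duration = 400, csp_duration = 140, recovery_ramp = 2000)
  sw <- synthesize_emg_trial(p, seed = 8)
  cfg <- csp_config()
  m <- detect_mep(sw$trace, cfg)
  expect_error(detect_csp(sw$trace, cfg, m$mep_offset), "unterminated")
})

test_that("detection is invariant to rescaling the sweep", {
  cfg <- csp_config()
  sw <- synthesize_emg_trial(emg_params(), seed = 9)
  m1 <- detect_mep(sw$trace, cfg)
  c1 <- detect_csp(sw$trace, cfg, m1$mep_offset)
  scaled <- emg_trace(sw$trace$samples * 3.7, sw$trace$fs,
                      sw$trace$stim_time, sw$trace$metadata)
  m2 <- detect_mep(scaled, cfg)
  c2 <- detect_csp(scaled, cfg, m2$mep_offset)
  expect_identical(m1$mep_onset, m2$mep_onset)
  expect_identical(m1$mep_offset, m2$mep_offset)
  expect_identical(c1$csp_end, c2$csp_end)
  expect_equal(m2$mep_amp_pp, 3.7 * m1$mep_amp_pp)
})

test_that("trial feature extraction rejects instead of failing", {
  cfg <- csp_config()
  mvc <- default_mvc()

  nominal <- extract_trial_features(
    synthesize_emg_trial(emg_params(), seed = 10)$trace, cfg, mvc)
  expect_false(nominal$rejected)
  expect_gt(nominal$csp_abs, 0)

  weak <- emg_params(tonic_rms = 0.0167)  # ~10% MVC contraction
  r_weak <- extract_trial_features(
    synthesize_emg_trial(weak, seed = 11)$trace, cfg, mvc)
  expect_true(r_weak$rejected)
  expect_match(r_weak$reject_reason, "contraction out of band")

  no_mep <- emg_params(mep_amp_pp = 0, silence_floor = 1, csp_duration = 0)
  r_none <- extract_trial_features(
    synthesize_emg_trial(no_mep, seed = 77)$trace, cfg, mvc)
  expect_true(r_none$rejected)
  expect_match(r_none$reject_reason, "no MEP")
})

test_that("participant summaries are invariant to pulse order", {
  cfg <- csp_config()
  mvc <- default_mvc()
  feats <- do.call(rbind, lapply(1:6, function(k) {
    extract_trial_features(
      synthesize_emg_trial(emg_params(), seed = 3000 + k)$trace, cfg, mvc)
  }))
  a <- summarize_emg(feats)
  b <- summarize_emg(feats[sample(nrow(feats)), ])
  expect_equal(a, b)
})

test_that("per-pulse CSP errors are small at the default noise level", {
  cohort <- generate_population(
    population_params(n_participants = 3L, pulses_per_participant = 10L),
    seed = 55)
  cfg <- csp_config()
  errs <- unlist(lapply(cohort$participants, function(p) {
    mvc <- compute_mvc(p$mvc_traces)
    vapply(seq_along(p$sweeps), function(k) {
      f <- extract_trial_features(p$sweeps[[k]], cfg, mvc)
      if (f$rejected) return(NA_real_)
      f$csp_abs - p$sweep_truths[[k]]$true_csp
    }, numeric(1))
  }))
  expect_lte(median(abs(errs), na.rm = TRUE), 5)
})
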