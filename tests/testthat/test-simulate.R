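test_that("simulation is bit-reproducible given (params, protocol, seed)", {
  proto <- train_protocol(n = 10)
  pars <- default_params()
  r1 <- simulate_recording(pars, proto, seed = 11)
  r2 <- simulate_recording(pars, proto, seed = 11)
  expect_identical(r1$force, r2$force)
  expect_identical(r1$ground_truth, r2$ground_truth)
  r3 <- simulate_recording(pars, proto, seed = 12)
  expect_false(identical(r1$force, r3$force))
})

test_that("ground-truth beat count equals stimuli minus refractory-blocked stimuli", {
  ## 2 Hz pacing against a 700 ms fixed refractory period: 2:1 block
  proto <- train_protocol(hz = 2, n = 30)
  pars <- tissue_params(rp_min = 700, rp_max = 700, noise_sd = 0)
  rec <- simulate_recording(pars, proto, seed = 1)
  gt <- rec$ground_truth
  expect_identical(sum(gt$activated), 15L)
  ## and with no refractoriness limit, all stimuli activate
  pars2 <- tissue_params(rp_min = 100, rp_max = 100, noise_sd = 0)
  gt2 <- simulate_recording(pars2, proto, seed = 1)$ground_truth
  expect_identical(sum(gt2$activated), 30L)
})

test_that("zero-amplitude tissue yields no beats above noise", {
  proto <- train_protocol(n = 12)
  ## noiseless: literally nothing to detect
  pars0 <- tissue_params(amplitude_base = 0, noise_sd = 0)
  an0 <- analyze_recording(simulate_recording(pars0, proto, seed = 3))
  expect_identical(nrow(an0$beats), 0L)
  ## with sensor noise: nothing resembling a contraction, never "beating"
  pars <- tissue_params(amplitude_base = 0, noise_sd = 5)
  an <- analyze_recording(simulate_recording(pars, proto, seed = 3))
  expect_false(classify_beating(an$beats))
  if (nrow(an$beats)) expect_lt(max(an$beats$F_amp, na.rm = TRUE), 20)
})

test_that("noiseless 0.5 Hz train: raw-sample amplitudes equal amplitude_base exactly", {
  proto <- train_protocol(n = 6)
  pars <- tissue_params(amplitude_base = 300, noise_sd = 0)
  rec <- simulate_recording(pars, proto, seed = 1)
  ## every twitch peaks at diastolic + amplitude on the raw 400 Hz stream
  expect_equal(max(rec$force), 500 + 300)
  for (t_s in rec$stimulus_times) {
    seg <- rec$force[rec$time_s >= t_s & rec$time_s < t_s + 1]
    expect_equal(max(seg) - min(seg), 300)
  }
})

test_that("restitution disabled: S2-derived RP and 1/f_max period agree within one ladder step", {
  pars <- tissue_params(rp_min = 350, rp_max = 350, noise_sd = 2)
  rec <- simulate_recording(pars, s1s2_protocol(), seed = 5)
  tr <- denoise(downsample_mean(rec))
  rp <- refractory_period(detect_capture_s2(tr, estimate_noise(tr)))
  frec <- simulate_recording(pars, frequency_protocol(), seed = 5)
  ftr <- denoise(downsample_mean(frec))
  fm <- max_frequency(ftr, estimate_noise(ftr))
  expect_identical(rp$flag, "measured")
  expect_identical(fm$flag, "measured")
  ## RP 400 ms <-> f_max 2.5 Hz: the 1/f_max period (400 ms) equals RP
  ladder <- c(750, 500, 400, 300, 275, 250, 240, 230, 220, 210,
              200, 190, 180, 170, 160, 150, 140, 130, 120, 110, 100)
  i_rp <- match(rp$rp_ms, ladder)
  expect_true(abs(1000 / fm$f_max_hz - rp$rp_ms) <=
                rp$rp_ms - ladder[i_rp + 1])
})

test_that("restitution reproduces long S2 RP with high steady-state f_max (control pattern)", {
  pars <- tissue_params(noise_sd = 2)   # rp_min 150, rp_max 380, strong restitution
  rec <- simulate_recording(pars, s1s2_protocol(), seed = 6)
  tr <- denoise(downsample_mean(rec))
  rp <- refractory_period(detect_capture_s2(tr, estimate_noise(tr)))
  expect_identical(rp$rp_ms, 400)
  frec <- simulate_recording(pars, frequency_protocol(), seed = 6)
  ftr <- denoise(downsample_mean(frec))
  fm <- max_frequency(ftr, estimate_noise(ftr))
  expect_identical(fm$f_max_hz, 5)
  expect_identical(fm$flag, "at_max")
})

test_that("overlong protocols and invalid parameters are refused", {
  proto <- train_protocol(n = 10)
  expect_error(simulate_recording(default_params(), proto, max_duration_s = 5),
               "exceeds")
  expect_error(tissue_params(noise_sd = -1), "noise_sd")
  expect_error(tissue_params(rp_min = 0), "rp_min")
  expect_error(tissue_params(restitution_tau = -5), "restitution_tau")
})

test_that("recordings round-trip through the CSV/JSON schema", {
  stem <- file.path(withr::local_tempdir(), "rec")
  proto <- with_rocker(train_protocol(n = 6), data.frame(start_s = 1, end_s = 3))
  rec <- simulate_recording(default_params(), proto, seed = 2)
  write_recording(rec, stem)
  back <- read_recording(stem)
  expect_equal(back$force, rec$force)
  expect_equal(back$stimulus_times, rec$stimulus_times)
  expect_equal(back$sample_rate, rec$sample_rate)
  expect_equal(back$rocker_intervals$start_s, 1)
  expect_equal(back$ground_truth$activated, rec$ground_truth$activated)
})

test_that("photometry shares the activation sequence and applies the clock offset", {
  proto <- train_protocol(n = 8)
  pars <- tissue_params(noise_sd = 0)
  ca <- simulate_photometry(pars, proto, seed = 1, clock_offset_s = 0.25)
  expect_equal(ca$stimulus_times, proto$stimuli$time_s - 0.25)
  expect_true(all(ca$ground_truth$activated))
})
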