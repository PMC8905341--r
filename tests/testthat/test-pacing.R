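test_that("the S1-S2 builder realizes the printed protocol structure", {
  p <- s1s2_protocol()
  s2 <- p$stimuli[p$stimuli$type == "S2", ]
  expect_identical(nrow(s2), 63L)                       # 21 steps x 3 S2
  expect_identical(length(unique(s2$step)), 21L)
  expect_equal(sort(unique(s2$interval_ms), decreasing = TRUE),
               c(750, 500, 400, 300, 275, 250, 240, 230, 220, 210,
                 200, 190, 180, 170, 160, 150, 140, 130, 120, 110, 100))
  ## each S2 sits at its interval after an S1 anchor on the unshifted grid
  s1 <- p$stimuli[p$stimuli$type == "S1", ]
  for (i in sample(nrow(s2), 10)) {
    anchor <- s2$time_s[i] - s2$interval_ms[i] / 1000
    expect_true(any(abs(s1$time_s - anchor) < 1e-9))
  }
  ## at least three intervening S1 beats between consecutive S2s of a step
  one <- s2[s2$step == 4, ]
  between <- s1$time_s > one$time_s[1] & s1$time_s < one$time_s[2]
  expect_gte(sum(between), 3L)
  ## per-step constant train runs at the corresponding frequency
  tr <- p$stimuli[p$stimuli$type == "train" & p$stimuli$step == 2, ]  # 500 ms
  expect_equal(unique(tr$freq_hz), 2)
  expect_identical(nrow(tr), 12L)                       # 6 s at 2 Hz
  ## empty ladder -> baseline-only script
  p0 <- s1s2_protocol(s2_ladder_ms = numeric())
  expect_true(all(p0$stimuli$type == "S1"))
})

test_that("S2 intervals map to pacing frequencies as 1000/interval", {
  expect_equal(s2_interval_to_frequency(500), 2)
  expect_equal(s2_interval_to_frequency(1000), 1)
  expect_equal(s2_interval_to_frequency(200), 5)
  expect_error(s2_interval_to_frequency(0), "> 0")
})

test_that("the frequency ladder lasts 25 beats per step", {
  p <- frequency_protocol()
  tr <- p$stimuli[p$stimuli$type == "train", ]
  expect_equal(sort(unique(tr$freq_hz)),
               c(0.2, 0.5, 0.75, 1.0, 1.5, 2.0, 2.5, 3, 3.5, 4.0, 4.5, 5.0))
  for (k in unique(tr$step)) {
    s <- tr[tr$step == k, ]
    expect_identical(nrow(s), 25L)
    ## 25 beats at 5 Hz span 5 s; at 1 Hz, 25 s
    expect_equal(diff(range(s$time_s)), 24 / s$freq_hz[1])
  }
})

test_that("S2 capture analysis applies the all-three rule and the prefix RP rule", {
  proto <- s1s2_protocol()
  run <- function(thr) {
    pars <- tissue_params(rp_min = thr, rp_max = thr, noise_sd = 5)
    rec <- simulate_recording(pars, proto, seed = 1)
    tr <- denoise(downsample_mean(rec))
    nz <- estimate_noise(tr)
    list(cap = detect_capture_s2(tr, nz), noise = nz)
  }
  r350 <- run(350)
  expect_identical(refractory_period(r350$cap)$rp_ms, 400)
  ## steps 750, 500, 400 captured; 300 not
  head4 <- r350$cap[match(c(750, 500, 400, 300), r350$cap$interval_ms), ]
  expect_identical(head4$captured, c(TRUE, TRUE, TRUE, FALSE))
  r450 <- run(450)
  expect_identical(refractory_period(r450$cap)$rp_ms, 500)
})

test_that("censoring flags cover both ends of the ladder and partial capture fails a step", {
  ct <- data.frame(step = 1:3, interval_ms = c(750, 500, 400), n_s2 = 3,
                   n_captured = 3, captured = TRUE, evaluable = TRUE)
  expect_identical(refractory_period(ct)$flag, "below_min")
  ct$captured[1] <- FALSE
  expect_identical(refractory_period(ct)$flag, "above_max")
  ## 2 of 3 S2 captured -> step not captured by the all-three rule
  ct2 <- data.frame(step = 1:2, interval_ms = c(750, 500), n_s2 = 3,
                    n_captured = c(3, 2), captured = c(TRUE, FALSE),
                    evaluable = TRUE)
  expect_identical(refractory_period(ct2)$rp_ms, 750)
  ## unevaluable step before the first failure blocks the measurement
  ct3 <- data.frame(step = 1:3, interval_ms = c(750, 500, 400), n_s2 = c(3, 1, 3),
                    n_captured = c(3, 1, 0), captured = c(TRUE, TRUE, FALSE),
                    evaluable = c(TRUE, FALSE, TRUE))
  expect_identical(refractory_period(ct3)$flag, "unevaluable")
})

test_that("zero-amplitude tissue captures no S2 step", {
  pars <- tissue_params(amplitude_base = 0, noise_sd = 5)
  rec <- simulate_recording(pars, s1s2_protocol(), seed = 2)
  tr <- denoise(downsample_mean(rec))
  cap <- detect_capture_s2(tr, estimate_noise(tr))
  expect_false(any(cap$captured))
  expect_identical(refractory_period(cap)$flag, "above_max")
})

test_that("f_max applies the last-five rule with both censoring flags", {
  proto <- frequency_protocol()
  run <- function(pars, seed = 1) {
    rec <- simulate_recording(pars, proto, seed = seed)
    tr <- denoise(downsample_mean(rec))
    max_frequency(tr, estimate_noise(tr))
  }
  ## 2:1 alternating block from 3 Hz upward -> f_max 2.5
  fm <- run(tissue_params(rp_min = 350, rp_max = 350, noise_sd = 5))
  expect_identical(fm$f_max_hz, 2.5)
  expect_identical(fm$flag, "measured")
  ## full capture everywhere -> 5 Hz with at_max
  fm2 <- run(tissue_params(rp_min = 120, rp_max = 120, noise_sd = 5))
  expect_identical(fm2$f_max_hz, 5)
  expect_identical(fm2$flag, "at_max")
  ## no captured train at all
  fm3 <- run(tissue_params(amplitude_base = 0, noise_sd = 5))
  expect_identical(fm3$flag, "below_min")
})

test_that("trains shorter than five stimuli are unevaluable for f_max", {
  proto <- frequency_protocol(freq_hz = c(0.5, 1), beats_per_step = 4)
  rec <- simulate_recording(tissue_params(noise_sd = 2), proto, seed = 1)
  tr <- denoise(downsample_mean(rec))
  fm <- max_frequency(tr, estimate_noise(tr))
  expect_identical(fm$flag, "unevaluable")
})

test_that("RP percent change uses the standard percent-difference arithmetic and refuses censored input", {
  expect_equal(rp_percent_change(400, 500), 25)
  expect_equal(rp_percent_change(400, 400), 0)
  expect_equal(rp_percent_change(200, 300), 50)
  expect_error(rp_percent_change(list(rp_ms = NA, flag = "below_min"), 400),
               "censored")
})

test_that("RP quantization: any capture threshold in (300, 400] reports 400 ms", {
  proto <- s1s2_protocol()
  for (thr in c(310, 360, 400)) {
    for (seed in 1:2) {
      pars <- tissue_params(rp_min = thr, rp_max = thr, noise_sd = 5)
      rec <- simulate_recording(pars, proto, seed = seed)
      tr <- denoise(downsample_mean(rec))
      rp <- refractory_period(detect_capture_s2(tr, estimate_noise(tr)))
      expect_identical(rp$rp_ms, 400)
    }
  }
})

test_that("raising the tissue's refractory parameters never shortens RP or raises f_max", {
  proto <- s1s2_protocol()
  fproto <- frequency_protocol()
  rps <- numeric(); fms <- numeric()
  for (thr in c(250, 350, 450)) {
    pars <- tissue_params(rp_min = thr, rp_max = thr, noise_sd = 2)
    tr <- denoise(downsample_mean(simulate_recording(pars, proto, seed = 3)))
    rps <- c(rps, refractory_period(detect_capture_s2(tr, estimate_noise(tr)))$rp_ms)
    ftr <- denoise(downsample_mean(simulate_recording(pars, fproto, seed = 3)))
    fms <- c(fms, max_frequency(ftr, estimate_noise(ftr))$f_max_hz)
  }
  expect_true(all(diff(rps) >= 0))
  expect_true(all(diff(fms) <= 0))
})

test_that("protocols round-trip through the controller text format", {
  p <- s1s2_protocol(s2_ladder_ms = c(750, 500, 400))
  p <- with_rocker(p, data.frame(start_s = c(0, 50), end_s = c(10, 60)))
  path <- tempfile(fileext = ".txt")
  write_protocol(p, path)
  q <- read_protocol(path)
  expect_equal(q$stimuli$time_s, p$stimuli$time_s)
  expect_equal(q$stimuli$type, p$stimuli$type)
  expect_equal(q$stimuli$interval_ms, p$stimuli$interval_ms)
  expect_equal(q$rocker, p$rocker)
  expect_identical(q$kind, "s1s2")
})
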