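flat_noise <- function(sd = 5, maxamp = 20)
  structure(list(sd = sd, max_amplitude = maxamp, n_windows = 10L),
            class = "noise_estimate")

test_that("a flat trace contains no beats", {
  rec <- structure(list(sample_rate = 200, force = rep(500, 1000),
                        time_s = (0:999) / 200, stimulus_times = seq(1, 4),
                        rocker_intervals = NULL), class = "force_recording")
  expect_identical(nrow(detect_beats(rec, flat_noise())), 0L)
})

test_that("noiseless twitch trains are detected one beat per stimulus", {
  proto <- train_protocol(n = 10)
  pars <- tissue_params(amplitude_base = 300, noise_sd = 0)
  rec <- denoise(downsample_mean(simulate_recording(pars, proto, seed = 1)))
  b <- detect_beats(rec, flat_noise(5, 20))
  expect_identical(nrow(b), 10L)
  expect_equal(sum(!is.na(b$stimulus_time)), 10L)
})

test_that("peaks exactly at the minimum height are not detected (strict inequality)", {
  ## twitch height above local minimum exactly equal to maxamp + sd
  proto <- train_protocol(n = 5)
  pars <- tissue_params(amplitude_base = 25, noise_sd = 0)
  rec <- denoise(downsample_mean(simulate_recording(pars, proto, seed = 1)))
  amp_filtered <- max(rec$force) - min(rec$force)
  b_eq <- detect_beats(rec, flat_noise(sd = amp_filtered, maxamp = 0))
  expect_identical(nrow(b_eq), 0L)
  b_below <- detect_beats(rec, flat_noise(sd = amp_filtered - 1e-9, maxamp = 0))
  expect_identical(nrow(b_below), 5L)
})

test_that("oracle equivalence: noiseless detected beat count equals ground-truth activations", {
  for (seed in 1:3) {
    proto <- train_protocol(hz = 2, n = 25)
    pars <- tissue_params(rp_min = 600, rp_max = 600, noise_sd = 0)  # 2:1 block
    rec <- simulate_recording(pars, proto, seed = seed)
    an <- analyze_recording(rec, noise = flat_noise(2, 10))
    expect_identical(nrow(an$beats), sum(rec$ground_truth$activated))
  }
})

test_that("measured kinetics recover the generator's analytic crossing times", {
  proto <- train_protocol(n = 100)
  pars <- tissue_params(amplitude_base = 300, ttp90_true = 150,
                        ttr90_true = 250, noise_sd = 2)
  rec <- simulate_recording(pars, proto, seed = 1)
  an <- analyze_recording(rec)
  b <- an$beats[isTRUE_v(an$beats$measurable), ]
  expect_gte(nrow(b), 99)
  expect_lte(abs(median(b$TTP90) - 150), 5)
  expect_lte(abs(median(b$TTR90) - 250), 5)
  expect_lte(abs(median(b$CD90) - 400), 10)
  ## CD90 identity holds for every measured beat
  expect_equal(b$CD90, b$TTP90 + b$TTR90)
})

test_that("symmetric twitches measure TTP90 == TTR90", {
  proto <- train_protocol(n = 8)
  pars <- tissue_params(ttp90_true = 200, ttr90_true = 200, noise_sd = 0)
  an <- analyze_recording(simulate_recording(pars, proto, seed = 1),
                          noise = flat_noise(2, 10))
  b <- an$beats
  expect_true(all(abs(b$TTP90 - b$TTR90) <= 5))
})

test_that("amplitude is invariant to a constant trace offset; F_D is not", {
  proto <- train_protocol(n = 6)
  rec <- simulate_recording(tissue_params(noise_sd = 0), proto, seed = 1)
  an1 <- analyze_recording(rec, noise = flat_noise(2, 10))
  rec$force <- rec$force + 123
  an2 <- analyze_recording(rec, noise = flat_noise(2, 10))
  expect_equal(an2$beats$F_amp, an1$beats$F_amp, tolerance = 1e-12)
  expect_equal(an2$beats$F_D, an1$beats$F_D + 123, tolerance = 1e-12)
})

test_that("fused beats without a 10% crossing are flagged unmeasurable and excluded", {
  ## long twitches at fast pacing never return to 10% between stimuli
  proto <- train_protocol(hz = 4, n = 30, start_s = 1)
  pars <- tissue_params(ttp90_true = 300, ttr90_true = 500,
                        rp_min = 100, rp_max = 100, noise_sd = 0,
                        ffr_slope = 0, diastolic_force = 0)
  an <- analyze_recording(simulate_recording(pars, proto, seed = 1),
                          noise = flat_noise(1, 4))
  b <- an$beats[an$beats$peak_time > 2 & an$beats$peak_time < 6, ]
  expect_true(any(!b$measurable))
  s <- summarize_period(an$beats, n_stimuli = 30, pacing_hz = 4)
  expect_identical(s$n_beats, sum(isTRUE_v(an$beats$measurable)))
})

test_that("beating classification uses a strict 50 uN rule", {
  b <- data.frame(F_amp = c(10, 50), measurable = TRUE)
  expect_false(classify_beating(b))
  b2 <- data.frame(F_amp = c(10, 60), measurable = TRUE)
  expect_true(classify_beating(b2))
  expect_false(classify_beating(b2[0, ]))
})

test_that("period summaries average per-beat parameters and keep capture bookkeeping", {
  b <- data.frame(F_amp = c(100, 300, 100, 300), F_D = 500, TTP90 = 150,
                  TTR90 = 250, CD90 = 400, measurable = TRUE)
  s <- summarize_period(b, n_stimuli = 8, pacing_hz = 1)
  expect_equal(s$F_amp, 200)
  expect_identical(s$n_beats, 4L)
  expect_identical(s$n_stimuli, 8L)
  s0 <- summarize_period(b[0, ], n_stimuli = 8, pacing_hz = 1)
  expect_identical(s0$n_beats, 0L)
  expect_true(is.na(s0$F_amp))
})
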