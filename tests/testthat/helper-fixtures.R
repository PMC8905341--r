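## shared fixtures: small protocols and a sample-level crossing oracle

## plain constant-rate stimulation train (for beat-analysis tests)
train_protocol <- function(hz = 0.5, n = 20, start_s = 2) {
  iv <- 1 / hz
  trabkit:::.new_protocol(
    data.frame(time_s = start_s + iv * (seq_len(n) - 1), type = "S1",
               step = 0L, interval_ms = 1000 * iv, freq_hz = hz),
    NULL, "train")
}

## independent oracle: sample-level 10% crossing times of a waveform,
## the same first-occurrence rule the analysis defines, applied directly
## to raw samples (no filtering, no detection machinery)
measure_wave <- function(w, dt_ms) {
  p <- which.max(w)
  amp <- max(w) - min(w)
  thr <- min(w) + 0.1 * amp
  pre <- which(w[seq_len(p)] <= thr)
  post <- which(w[seq(p, length(w))] <= thr)
  list(amp = amp,
       ttp90 = (p - max(pre)) * dt_ms,
       ttr90 = (min(post) - 1) * dt_ms)
}

default_params <- function(...) tissue_params(noise_sd = 5, ...)
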