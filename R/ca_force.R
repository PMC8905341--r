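#' Synchronize force and Ca2+ photometry recordings
#'
#' The two acquisition systems record the same electrical stimulation pulses
#' on unsynchronized clocks. The offset between the clocks is estimated by
#' matching the two stimulus timestamp sequences: a robust initial offset
#' (median of near-diagonal pairwise differences) is refined by pairing each
#' photometry event with its nearest force event and taking the
#' least-squares (mean) offset over the pairs. A missing event in either log
#' leaves the remaining pairs intact. The fluorescence trace is then
#' resampled onto the force time base by linear interpolation.
#'
#' @param force_rec a \code{force_recording} (any stage of filtering).
#' @param ca_rec a \code{ca_recording} (see [simulate_photometry()]) or any
#'   list with \code{time_s}, \code{fluorescence}, \code{stimulus_times}.
#' @param min_fraction minimum fraction of the shorter event list that must
#'   pair up; below this the sequences are considered unmatched.
#' @return an \code{aligned_pair}: list with \code{time_s}, \code{force},
#'   \code{ca}, \code{stimulus_times} (force clock), \code{offset_s}
#'   (photometry clock + offset = force clock), \code{jitter_ms} (largest
#'   pairing residual) and \code{n_pairs}.
#' @export
synchronize <- function(force_rec, ca_rec, min_fraction = 0.8) {
  f_ev <- force_rec$stimulus_times
  c_ev <- ca_rec$stimulus_times
  if (length(f_ev) < 2 || length(c_ev) < 2)
    stop("both recordings need at least 2 stimulus timestamps")
  ## consensus offset: near-diagonal pairwise differences are candidate
  ## offsets; keep the one pairing the most events
  k <- min(length(f_ev), length(c_ev))
  d <- c(f_ev[seq_len(k)] - c_ev[seq_len(k)],
         if (k > 3) f_ev[seq_len(k - 1)] - c_ev[2:k],
         if (k > 3) f_ev[2:k] - c_ev[seq_len(k - 1)])
  tol <- 0.45 * min(diff(f_ev))
  cands <- unique(round(d / tol)) * tol
  score <- vapply(cands, function(o)
    sum(vapply(c_ev + o, function(t) min(abs(f_ev - t)) <= tol, logical(1))),
    integer(1))
  off0 <- cands[which.max(score)]
  j <- vapply(c_ev + off0, function(t) which.min(abs(f_ev - t)), integer(1))
  resid <- f_ev[j] - (c_ev + off0)
  ok <- abs(resid) <= tol & !duplicated(j)
  if (sum(ok) < max(2, min_fraction * k))
    stop("stimulus sequences could not be matched (", sum(ok), " of ", k,
         " events paired); check the event logs")
  offset <- mean(f_ev[j[ok]] - c_ev[ok])
  jitter_ms <- max(abs(f_ev[j[ok]] - (c_ev[ok] + offset))) * 1000
  ca_on_force <- stats::approx(ca_rec$time_s + offset, ca_rec$fluorescence,
                               xout = force_rec$time_s, rule = 2)$y
  structure(list(time_s = force_rec$time_s, force = force_rec$force,
                 ca = ca_on_force, stimulus_times = f_ev,
                 sample_rate = force_rec$sample_rate,
                 stim_table = force_rec$stim_table,
                 rocker_intervals = force_rec$rocker_intervals,
                 offset_s = offset, jitter_ms = jitter_ms, n_pairs = sum(ok)),
            class = "aligned_pair")
}

## view one channel of an aligned pair as a force_recording so the beat
## machinery (10% threshold rule) applies identically to both signals
.as_recording <- function(aligned, signal = c("force", "ca")) {
  signal <- match.arg(signal)
  structure(list(sample_rate = aligned$sample_rate, time_s = aligned$time_s,
                 force = if (signal == "force") aligned$force else aligned$ca,
                 stimulus_times = aligned$stimulus_times,
                 stim_table = aligned$stim_table,
                 rocker_intervals = aligned$rocker_intervals,
                 ground_truth = NULL),
            class = "force_recording")
}

## per-beat amplitudes of one channel, measured with the beat machinery
.channel_beats <- function(aligned, signal, noise = NULL) {
  rec <- .as_recording(aligned, signal)
  if (rec$sample_rate == 400) rec <- downsample_mean(rec)
  rec <- denoise(rec)
  if (is.null(noise)) noise <- estimate_noise(rec)
  measure_beats(rec, detect_beats(rec, noise))
}

#' Normalize per-beat amplitudes to the first 0.5 Hz beat
#'
#' Measures per-beat amplitudes of the chosen channel with the same beat
#' machinery as force (diastolic offset subtraction via \code{F_D}, 10\%
#' threshold), then divides by the amplitude of the beat elicited by the
#' first stimulus. Scale-invariant for the Ca channel by construction.
#'
#' @param aligned an \code{aligned_pair} from [synchronize()].
#' @param signal \code{"force"} or \code{"ca"}.
#' @param noise optional \code{noise_estimate} for the channel.
#' @return the measured beat table with an extra column \code{norm_amp};
#'   attribute \code{first_amp} holds the normalizing amplitude.
#' @export
normalize_to_first <- function(aligned, signal = c("force", "ca"), noise = NULL) {
  signal <- match.arg(signal)
  beats <- .channel_beats(aligned, signal, noise)
  if (!nrow(beats)) stop("no beats detected in ", signal, " channel")
  first <- beats[order(beats$peak_time), ][1, ]
  if (!isTRUE(first$measurable) ||
      !isTRUE(all.equal(first$stimulus_time, aligned$stimulus_times[1])))
    stop("first-stimulus beat not measurable above noise; cannot normalize")
  beats$norm_amp <- beats$F_amp / first$F_amp
  attr(beats, "first_amp") <- first$F_amp
  beats
}

#' Force and Ca2+ frequency response
#'
#' Groups the normalized per-beat amplitudes of both channels by the pacing
#' frequency of their eliciting stimulus and reports the mean normalized
#' amplitude per frequency together with the capture fraction
#' (beats per stimulus).
#'
#' @param aligned an \code{aligned_pair}.
#' @return data frame: \code{freq_hz}, \code{force_amp}, \code{ca_amp}
#'   (normalized), \code{capture_fraction}, \code{n_stimuli}.
#' @export
frequency_response <- function(aligned) {
  fb <- normalize_to_first(aligned, "force")
  cb <- normalize_to_first(aligned, "ca")
  st <- aligned$stim_table
  per_freq <- function(beats) {
    f <- st$freq_hz[match(beats$stimulus_time, st$time_s)]
    tapply(beats$norm_amp, f, mean)
  }
  fa <- per_freq(fb); ca <- per_freq(cb)
  freqs <- sort(unique(st$freq_hz))
  n_st <- vapply(freqs, function(f) sum(st$freq_hz == f), integer(1))
  n_cap <- vapply(freqs, function(f)
    sum(st$freq_hz[match(fb$stimulus_time, st$time_s)] == f, na.rm = TRUE),
    integer(1))
  data.frame(freq_hz = freqs,
             force_amp = as.numeric(fa[as.character(freqs)]),
             ca_amp = as.numeric(ca[as.character(freqs)]),
             capture_fraction = n_cap / n_st,
             n_stimuli = n_st)
}

#' Post-rest potentiation ratio
#'
#' Ratio of the amplitude of the first beat after a pacing pause to the mean
#' amplitude of the last captured beats before the pause, computed for both
#' channels.
#'
#' @param aligned an \code{aligned_pair}.
#' @param pause_s minimum stimulus gap counting as rest, s.
#' @param n_pre number of pre-rest beats anchoring the comparison.
#' @return list with \code{force_ratio}, \code{ca_ratio}, \code{pause_s}.
#' @export
post_rest_ratio <- function(aligned, pause_s = 4, n_pre = 3) {
  st <- aligned$stimulus_times
  gaps <- diff(st)
  ## the rest pause: first gap >= pause_s that follows faster pacing
  g <- which(gaps >= pause_s & c(TRUE, utils::head(gaps, -1) < pause_s))
  if (!length(g)) stop("no pacing pause >= ", pause_s, " s in the protocol")
  g <- g[1]
  t_rest_end <- st[g + 1]
  ratio_for <- function(signal) {
    beats <- .channel_beats(aligned, signal)
    beats <- beats[isTRUE_v(beats$measurable), ]
    post <- beats[beats$stimulus_time >= t_rest_end, ]
    if (!nrow(post)) stop("post-rest beat not detected in ", signal, " channel")
    pre <- beats[beats$stimulus_time <= st[g], ]
    pre <- utils::tail(pre[order(pre$peak_time), ], n_pre)
    if (!nrow(pre)) stop("no pre-rest beats found")
    post$F_amp[1] / mean(pre$F_amp)
  }
  list(force_ratio = ratio_for("force"), ca_ratio = ratio_for("ca"),
       pause_s = gaps[g])
}
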