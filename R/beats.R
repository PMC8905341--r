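#' Detect contractions in a filtered force trace
#'
#' Finds local maxima whose height above the local diastolic level exceeds
#' (strictly) the minimum peak height, defined as the maximum noise
#' amplitude plus one standard deviation of the noise. The local diastolic
#' level is the minimum force within +/- 50\% of the local stimulus interval
#' around the candidate peak. Peaks inside rocker-on spans are discarded.
#' Each beat is associated with the nearest preceding stimulus when the peak
#' falls within that stimulus' interval; when two candidates fall within one
#' stimulus interval the higher one is kept (ties: earlier).
#'
#' @param rec a filtered \code{force_recording} (see [denoise()]).
#' @param noise a \code{noise_estimate} from [estimate_noise()].
#' @param default_window_s half-window used where no stimulus interval is
#'   defined, s.
#' @return data frame of candidate beats: \code{peak_index},
#'   \code{peak_time}, \code{F_max}, \code{stimulus_time} (NA if
#'   unassociated), \code{interval_ms} (local stimulus interval); kinetic
#'   parameters unfilled (see [measure_beats()]).
#' @export
detect_beats <- function(rec, noise, default_window_s = 1) {
  stopifnot(inherits(rec, "force_recording"), inherits(noise, "noise_estimate"))
  x <- rec$force
  n <- length(x)
  if (n < 3) return(.empty_beats())
  h <- noise$max_amplitude + noise$sd
  ## strict rise before, fall-or-plateau after: first sample of any plateau
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(.empty_beats())
  t_cand <- rec$time_s[cand]
  cand <- cand[!.in_rocker_on(t_cand, rec$rocker_intervals)]
  if (!length(cand)) return(.empty_beats())
  t_cand <- rec$time_s[cand]

  st <- rec$stimulus_times
  iv_ms <- .local_interval_ms(t_cand, st, default_window_s)
  j <- if (length(st)) findInterval(t_cand, st) else rep(0L, length(cand))
  stim_t <- ifelse(j >= 1, st[pmax(j, 1L)], NA_real_)

  keep <- logical(length(cand))
  F_max <- x[cand]
  fs <- rec$sample_rate
  for (k in seq_along(cand)) {
    half <- 0.5 * iv_ms[k] / 1000
    i0 <- max(1L, cand[k] - round(half * fs))
    i1 <- min(n, cand[k] + round(half * fs))
    keep[k] <- (F_max[k] - min(x[i0:i1])) > h
  }
  b <- data.frame(peak_index = cand, peak_time = t_cand, F_max = F_max,
                  stimulus_time = stim_t, interval_ms = iv_ms)[keep, , drop = FALSE]
  if (!nrow(b)) return(.empty_beats())
  ## one beat per stimulus interval: keep the higher peak, ties earlier
  key <- ifelse(is.na(b$stimulus_time), paste0("u", seq_len(nrow(b))),
                format(b$stimulus_time, digits = 12))
  ord <- order(key, -b$F_max, b$peak_time)
  b <- b[ord, ][!duplicated(key[ord]), , drop = FALSE]
  b <- b[order(b$peak_time), , drop = FALSE]
  rownames(b) <- NULL
  b$F_D <- b$F_amp <- b$TTP90 <- b$TTR90 <- b$CD90 <- NA_real_
  b$measurable <- NA
  b
}

.empty_beats <- function() {
  data.frame(peak_index = integer(), peak_time = numeric(), F_max = numeric(),
             stimulus_time = numeric(), interval_ms = numeric(),
             F_D = numeric(), F_amp = numeric(), TTP90 = numeric(),
             TTR90 = numeric(), CD90 = numeric(), measurable = logical())
}

## local stimulus interval (ms) at given times: interval of the surrounding
## stimulus pair, falling back to the neighbouring one or a default
.local_interval_ms <- function(t, st, default_window_s) {
  if (length(st) < 2) return(rep(default_window_s * 2000, length(t)))
  j <- findInterval(t, st)
  iv <- numeric(length(t))
  for (k in seq_along(t)) {
    jk <- j[k]
    iv[k] <- if (jk >= 1 && jk < length(st)) (st[jk + 1] - st[jk]) * 1000
             else if (jk >= length(st)) (st[length(st)] - st[length(st) - 1]) * 1000
             else (st[2] - st[1]) * 1000
  }
  iv
}

#' Measure one detected beat
#'
#' Fills the per-beat contraction parameters: the diastolic force \code{F_D}
#' is the minimum force within +/- 50\% of the stimulus interval around the
#' peak (clipped to the surrounding rocker-off span); \code{F_amp = F_max -
#' F_D}; \code{TTP90} is the time from the last sample at or below
#' \code{F_D + 0.1 F_amp} before the peak to the peak, \code{TTR90} from the
#' peak to the first such sample after it, and \code{CD90 = TTP90 + TTR90}.
#' Crossing times are reported at sample resolution (no interpolation). A
#' beat without a 10\% crossing inside its window (fused beats) is flagged
#' unmeasurable.
#'
#' @param rec the filtered \code{force_recording} the beat was detected in.
#' @param beat one row of the [detect_beats()] table.
#' @param interval_ms stimulus interval defining the analysis window, ms.
#' @return the row with \code{F_D}, \code{F_amp}, \code{TTP90},
#'   \code{TTR90}, \code{CD90} and \code{measurable} filled.
#' @export
measure_beat <- function(rec, beat, interval_ms = beat$interval_ms) {
  x <- rec$force
  n <- length(x)
  fs <- rec$sample_rate
  p <- beat$peak_index
  half <- round(0.5 * (interval_ms / 1000) * fs)
  i0 <- max(1L, p - half)
  i1 <- min(n, p + half)
  ## keep the window inside the rocker-off span containing the peak
  rk <- rec$rocker_intervals
  if (!is.null(rk) && nrow(rk)) {
    tp <- rec$time_s[p]
    for (j in seq_len(nrow(rk))) {
      if (rk$end_s[j] <= tp) i0 <- max(i0, round(rk$end_s[j] * fs) + 1L)
      if (rk$start_s[j] > tp) i1 <- min(i1, round(rk$start_s[j] * fs))
    }
  }
  seg <- x[i0:i1]
  F_D <- min(seg)
  F_amp <- x[p] - F_D
  thr <- F_D + 0.1 * F_amp
  pre <- which(x[i0:p] <= thr)
  post <- which(x[p:i1] <= thr)
  beat$F_D <- F_D
  beat$F_amp <- F_amp
  if (!length(pre) || !length(post)) {
    beat$measurable <- FALSE
    return(beat)
  }
  beat$TTP90 <- (p - (i0 + max(pre) - 1L)) / fs * 1000
  beat$TTR90 <- ((p + min(post) - 1L) - p) / fs * 1000
  beat$CD90 <- beat$TTP90 + beat$TTR90
  beat$measurable <- TRUE
  beat
}

#' Measure all detected beats
#'
#' @param rec the filtered \code{force_recording}.
#' @param beats the [detect_beats()] table.
#' @return the table with parameters filled for every beat.
#' @export
measure_beats <- function(rec, beats) {
  if (!nrow(beats)) return(beats)
  for (k in seq_len(nrow(beats)))
    beats[k, ] <- measure_beat(rec, beats[k, ])
  beats
}

#' Classify a recording as beating or non-beating
#'
#' A preparation counts as beating iff any measured contraction amplitude
#' strictly exceeds the screening threshold (default 50 uN, the sensor-noise
#' screen applied when bringing trabeculae into culture).
#'
#' @param beats a measured beat table.
#' @param threshold screening threshold, uN.
#' @return logical.
#' @export
classify_beating <- function(beats, threshold = 50) {
  if (!nrow(beats)) return(FALSE)
  any(beats$F_amp > threshold, na.rm = TRUE)
}

#' Summarize beats within an analysis period
#'
#' Arithmetic means of the per-beat parameters over the measurable beats of
#' one analyzed period (e.g. the six contractions recorded while the rocker
#' was stopped), with bookkeeping of stimulus and beat counts for capture
#' analysis.
#'
#' @param beats measured beat table restricted to the period.
#' @param n_stimuli number of stimuli delivered in the period.
#' @param pacing_hz nominal pacing rate of the period, Hz.
#' @return one-row data frame with means, \code{n_beats} and
#'   \code{n_stimuli}; means are NA when no beat was measurable.
#' @export
summarize_period <- function(beats, n_stimuli = NA_integer_, pacing_hz = NA_real_) {
  n_stimuli <- as.integer(n_stimuli)
  m <- beats[isTRUE_v(beats$measurable), , drop = FALSE]
  if (!nrow(m)) {
    return(data.frame(pacing_hz = pacing_hz, F_amp = NA_real_, F_D = NA_real_,
                      TTP90 = NA_real_, TTR90 = NA_real_, CD90 = NA_real_,
                      n_beats = 0L, n_stimuli = n_stimuli))
  }
  data.frame(pacing_hz = pacing_hz,
             F_amp = mean(m$F_amp), F_D = mean(m$F_D),
             TTP90 = mean(m$TTP90), TTR90 = mean(m$TTR90), CD90 = mean(m$CD90),
             n_beats = nrow(m), n_stimuli = n_stimuli)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Full beat analysis of a raw recording
#'
#' Convenience wrapper running the complete conditioning and measurement
#' chain: downsample to 200 Hz, denoise, estimate the noise level, detect
#' and measure beats.
#'
#' @param rec a raw 400 Hz \code{force_recording} (a 200 Hz recording is
#'   accepted as-is).
#' @param noise optional precomputed \code{noise_estimate}.
#' @return list with \code{trace} (the filtered recording), \code{noise}
#'   and \code{beats} (measured table).
#' @export
analyze_recording <- function(rec, noise = NULL) {
  if (rec$sample_rate == 400) rec <- downsample_mean(rec)
  rec <- denoise(rec)
  if (is.null(noise)) noise <- estimate_noise(rec)
  beats <- measure_beats(rec, detect_beats(rec, noise))
  list(trace = rec, noise = noise, beats = beats)
}
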