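#' Simulate a twitch-force recording
#'
#' Generates the 400 Hz force stream a cultivated trabecula would produce
#' under a given stimulation protocol. Excitation follows the restitution
#' model documented in [tissue_params()]: a stimulus elicits an activation
#' iff the time since the last activation is at least the current refractory
#' period \eqn{RP(DI)}. Each activation superimposes a twitch waveform
#' ([make_twitch()]) scaled by the force-frequency relationship (anchored at
#' 0.5 Hz), post-rest potentiation and, when enabled, alternans near the
#' capture limit. Gaussian sensor noise is added throughout and a
#' low-frequency agitation artifact (sinusoid at the rocker frequency plus
#' slow wander) during rocker-on spans. The full ground truth (activation
#' times, per-beat amplitude and kinetics, blocked stimuli) is recorded.
#'
#' @param params a [tissue_params()] object.
#' @param protocol a \code{pacing_protocol}.
#' @param seed integer seed; output is bit-reproducible given
#'   (params, protocol, seed).
#' @param sample_rate device stream rate, Hz (400).
#' @param max_duration_s refuse protocols longer than this (guards against
#'   runaway memory use).
#' @return an object of class \code{force_recording}: list with
#'   \code{sample_rate}, \code{time_s}, \code{force} (uN),
#'   \code{stimulus_times} (s), \code{stim_table}, \code{rocker_intervals}
#'   and \code{ground_truth} (data frame with one row per stimulus:
#'   \code{stimulus_time}, \code{activated}, \code{activation_time},
#'   \code{amplitude}, \code{ttp90}, \code{ttr90}).
#' @export
simulate_recording <- function(params, protocol, seed = 1L,
                               sample_rate = 400, max_duration_s = 7200) {
  stopifnot(inherits(params, "tissue_params"), inherits(protocol, "pacing_protocol"))
  dur <- protocol$duration_s
  if (dur > max_duration_s)
    stop("protocol duration ", round(dur), " s exceeds max_duration_s")
  set.seed(as.integer(seed))

  st <- protocol$stimuli$time_s
  act <- .simulate_activations(params, st)

  n <- floor(dur * sample_rate)
  time_s <- (seq_len(n) - 1) / sample_rate
  force <- rep(params$diastolic_force, n)
  dt_ms <- 1000 / sample_rate

  if (params$amplitude_base > 0 && any(act$activated)) {
    tw_unit <- make_twitch(1, params$ttp90_true, params$ttr90_true, dt_ms)
    pk <- attr(tw_unit, "peak_index")
    for (i in which(act$activated)) {
      i0 <- round(st[i] * sample_rate) + 1L
      idx <- i0:min(n, i0 + length(tw_unit) - 1L)
      force[idx] <- force[idx] + act$amplitude[i] * tw_unit[seq_along(idx)]
    }
  }

  if (params$noise_sd > 0)
    force <- force + stats::rnorm(n, 0, params$noise_sd)

  rocker <- protocol$rocker
  if (nrow(rocker) && params$rocker_artifact_amp > 0) {
    phase <- stats::runif(2, 0, 2 * pi)
    art <- params$rocker_artifact_amp *
      sin(2 * pi * params$rocker_artifact_freq * time_s + phase[1]) +
      0.5 * params$rocker_artifact_amp * sin(2 * pi * 0.15 * time_s + phase[2])
    on <- rep(FALSE, n)
    for (j in seq_len(nrow(rocker)))
      on <- on | (time_s >= rocker$start_s[j] & time_s < rocker$end_s[j])
    force[on] <- force[on] + art[on]
  }

  gt <- data.frame(stimulus_time = st,
                   type = protocol$stimuli$type,
                   step = protocol$stimuli$step,
                   activated = act$activated,
                   amplitude = act$amplitude,
                   ttp90 = ifelse(act$activated, params$ttp90_true, NA_real_),
                   ttr90 = ifelse(act$activated, params$ttr90_true, NA_real_))

  structure(list(sample_rate = sample_rate, time_s = time_s, force = force,
                 stimulus_times = st, stim_table = protocol$stimuli,
                 rocker_intervals = rocker, ground_truth = gt,
                 params = params, seed = as.integer(seed)),
            class = "force_recording")
}

## capture + amplitude bookkeeping shared by force and photometry simulation
.simulate_activations <- function(params, st) {
  n <- length(st)
  activated <- logical(n)
  amplitude <- rep(NA_real_, n)
  last_act <- -Inf; prev_di <- Inf
  alt_state <- FALSE
  rp_span <- params$rp_max - params$rp_min
  for (i in seq_len(n)) {
    coupling_ms <- (st[i] - last_act) * 1000
    rp_now <- params$rp_min + rp_span * (1 - exp(-prev_di / params$restitution_tau))
    if (coupling_ms >= rp_now) {
      activated[i] <- TRUE
      a <- params$amplitude_base
      if (is.finite(coupling_ms)) {
        f_inst <- 1000 / coupling_ms
        a <- a * max(0.05, 1 + params$ffr_slope * (f_inst - 0.5))
        if ((st[i] - last_act) >= params$post_rest_pause_s)
          a <- a * params$post_rest_gain
        if (params$alternans && coupling_ms < 1.25 * rp_now) {
          alt_state <- !alt_state
          if (alt_state) a <- a * params$alternans_ratio
        } else alt_state <- FALSE
      }
      amplitude[i] <- a
      prev_di <- coupling_ms
      last_act <- st[i]
    }
  }
  list(activated = activated, amplitude = amplitude)
}

#' Simulate a Ca2+ photometry recording
#'
#' Produces the fluorescence trace the photometry rig would record alongside
#' a force recording: the same activation sequence (identical excitation
#' model and seed-independent capture logic), but calcium-transient kinetics
#' (faster rise, exponential-like decay), arbitrary fluorescence units, an
#' independent sample rate and an acquisition-clock offset. The stimulus
#' timestamps in the returned object are expressed on the photometry clock
#' (true times minus \code{clock_offset_s}), emulating two unsynchronized
#' acquisition systems.
#'
#' @param params a [tissue_params()] object (capture model and FFR are
#'   shared with the force channel).
#' @param protocol a \code{pacing_protocol}.
#' @param seed integer seed.
#' @param sample_rate photometry sampling rate, Hz.
#' @param clock_offset_s offset of the photometry clock relative to the
#'   force clock, s.
#' @param ca_amp,ca_baseline transient amplitude and diastolic level, a.u.
#' @param ca_ttp90,ca_ttr90 transient kinetics, ms.
#' @param noise_sd fluorescence noise sd, a.u.
#' @param drop_events indices of stimulus timestamps to omit from the
#'   photometry event log (emulates missed trigger captures).
#' @return an object of class \code{ca_recording} with fields
#'   \code{sample_rate}, \code{time_s}, \code{fluorescence},
#'   \code{stimulus_times}, \code{ground_truth}, \code{clock_offset_s}.
#' @export
simulate_photometry <- function(params, protocol, seed = 1L,
                                sample_rate = 1000, clock_offset_s = 0,
                                ca_amp = 1, ca_baseline = 0.2,
                                ca_ttp90 = 80, ca_ttr90 = 220,
                                noise_sd = 0.01, drop_events = integer()) {
  stopifnot(inherits(params, "tissue_params"), inherits(protocol, "pacing_protocol"))
  set.seed(as.integer(seed) + 1203L)
  st <- protocol$stimuli$time_s
  act <- .simulate_activations(params, st)
  n <- floor(protocol$duration_s * sample_rate)
  time_s <- (seq_len(n) - 1) / sample_rate
  x <- rep(ca_baseline, n)
  dt_ms <- 1000 / sample_rate
  tw <- make_twitch(1, ca_ttp90, ca_ttr90, dt_ms)
  for (i in if (params$amplitude_base > 0) which(act$activated) else integer()) {
    i0 <- round(st[i] * sample_rate) + 1L
    idx <- i0:min(n, i0 + length(tw) - 1L)
    ## Ca amplitude tracks the same relative modulation as force
    x[idx] <- x[idx] + ca_amp * (act$amplitude[i] / params$amplitude_base) * tw[seq_along(idx)]
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  ev <- st
  if (length(drop_events)) ev <- ev[-drop_events]
  structure(list(sample_rate = sample_rate,
                 time_s = time_s - clock_offset_s,
                 fluorescence = x,
                 stimulus_times = ev - clock_offset_s,
                 ground_truth = data.frame(stimulus_time = st,
                                           activated = act$activated,
                                           amplitude = act$amplitude),
                 clock_offset_s = clock_offset_s),
            class = "ca_recording")
}

#' @export
print.force_recording <- function(x, ...) {
  cat(sprintf("<force_recording> %.1f s at %g Hz, %d stimuli, %d activations\n",
              length(x$force) / x$sample_rate, x$sample_rate,
              length(x$stimulus_times), sum(x$ground_truth$activated)))
  invisible(x)
}

#' Write / read a force recording as CSV + JSON sidecar
#'
#' The trace goes to \code{<stem>_trace.csv} (columns \code{time_s},
#' \code{force_uN}), events to \code{<stem>_events.csv} (stimulus times and
#' rocker intervals in long form) and the ground truth (when present) plus
#' metadata to \code{<stem>_truth.json}. Real device exports with the same
#' trace/event schema can be read back identically (the sidecar is optional).
#'
#' @param rec a \code{force_recording}.
#' @param stem path stem (no extension).
#' @return \code{write_recording}: the stem, invisibly.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "force_recording"))
  utils::write.csv(data.frame(time_s = rec$time_s, force_uN = rec$force),
                   paste0(stem, "_trace.csv"), row.names = FALSE)
  ev <- rbind(
    data.frame(event = "stimulus", start_s = rec$stimulus_times,
               end_s = NA_real_, type = rec$stim_table$type,
               step = rec$stim_table$step,
               interval_ms = rec$stim_table$interval_ms),
    if (nrow(rec$rocker_intervals))
      data.frame(event = "rocker_on", start_s = rec$rocker_intervals$start_s,
                 end_s = rec$rocker_intervals$end_s, type = NA, step = NA,
                 interval_ms = NA))
  utils::write.csv(ev, paste0(stem, "_events.csv"), row.names = FALSE)
  jsonlite::write_json(list(schema = "trabkit/recording/v1",
                            sample_rate = rec$sample_rate, seed = rec$seed,
                            ground_truth = rec$ground_truth),
                       paste0(stem, "_truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(stem)
}

#' @rdname write_recording
#' @param stem path stem used by [write_recording()].
#' @return \code{read_recording}: a \code{force_recording} (with
#'   \code{ground_truth = NULL} if no sidecar exists).
#' @export
read_recording <- function(stem) {
  tr <- utils::read.csv(paste0(stem, "_trace.csv"))
  ev <- utils::read.csv(paste0(stem, "_events.csv"))
  stim <- ev[ev$event == "stimulus", ]
  rock <- ev[ev$event == "rocker_on", c("start_s", "end_s")]
  sr <- round(1 / stats::median(diff(tr$time_s)))
  gt <- NULL; seed <- NA_integer_
  js <- paste0(stem, "_truth.json")
  if (file.exists(js)) {
    meta <- jsonlite::read_json(js, simplifyVector = TRUE)
    sr <- meta$sample_rate
    gt <- as.data.frame(meta$ground_truth)
    seed <- meta$seed
  }
  structure(list(sample_rate = sr, time_s = tr$time_s, force = tr$force_uN,
                 stimulus_times = stim$start_s,
                 stim_table = data.frame(time_s = stim$start_s, type = stim$type,
                                         step = stim$step,
                                         interval_ms = stim$interval_ms,
                                         freq_hz = 1000 / stim$interval_ms),
                 rocker_intervals = rock, ground_truth = gt,
                 params = NULL, seed = seed),
            class = "force_recording")
}
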