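#' Stimulation protocols
#'
#' Builders for the stimulation schedules used on the culture platform:
#' the S1-S2 extrastimulus protocol for the refractory period, the
#' frequency ladder for the force-frequency relationship and maximum
#' captured frequency, and a shorter imaging variant with a post-rest beat.
#'
#' A protocol is a list with a stimulus table (\code{time_s}, \code{type}
#' one of \code{"S1"}, \code{"S2"}, \code{"train"}, \code{step},
#' \code{interval_ms}, \code{freq_hz}), a rocker schedule (data frame of
#' intervals during which the agitation rocker is ON; empty = rocker
#' stopped throughout), the pulse shape descriptor (3 ms negative pulse,
#' 1 ms pause, 3 ms positive pulse) and the total duration.
#'
#' @name protocols
NULL

.default_s2_ladder <- c(750, 500, 400, 300, 275, 250, 240, 230, 220, 210,
                        200, 190, 180, 170, 160, 150, 140, 130, 120, 110, 100)
.default_freq_ladder <- c(0.2, 0.5, 0.75, 1.0, 1.5, 2.0, 2.5, 3, 3.5, 4.0, 4.5, 5.0)

.new_protocol <- function(stim, rocker, kind) {
  stim <- stim[order(stim$time_s), , drop = FALSE]
  rownames(stim) <- NULL
  if (any(diff(stim$time_s) <= 0)) stop("protocol stimuli must be strictly increasing in time")
  if (is.null(rocker)) rocker <- data.frame(start_s = numeric(), end_s = numeric())
  structure(list(stimuli = stim,
                 rocker = rocker,
                 pulse = c(neg_ms = 3, pause_ms = 1, pos_ms = 3),
                 duration_s = max(stim$time_s) + 3,
                 kind = kind),
            class = "pacing_protocol")
}

#' @describeIn protocols pacing frequency equivalent to an S2 coupling
#'   interval: \code{1000 / interval_ms} (500 ms corresponds to 2 Hz).
#' @param interval_ms S2 beat interval in ms.
#' @export
s2_interval_to_frequency <- function(interval_ms) {
  if (any(!is.finite(interval_ms)) || any(interval_ms <= 0))
    stop("s2_interval_to_frequency: interval must be > 0")
  1000 / interval_ms
}

#' @describeIn protocols S1-S2 protocol: 0.5 Hz baseline pacing; per ladder
#'   step, after a settling train three S2 extrastimuli are delivered, each
#'   at the S2 interval after a regular S1 with the S1 grid continuing
#'   unshifted and consecutive S2 anchors separated by 3 intervening S1
#'   beats; after another settling train a 6 s constant train at the
#'   frequency corresponding to the S2 interval follows.
#' @param s2_ladder_ms decreasing S2 intervals, ms.
#' @param baseline_ms S1 interval, ms (2000 = 0.5 Hz).
#' @param settle_s duration of regular pacing before the S2 block and before
#'   the constant train, s.
#' @param train_s duration of the per-step constant-frequency train, s.
#' @param n_s2 S2 extrastimuli per ladder step.
#' @export
s1s2_protocol <- function(s2_ladder_ms = .default_s2_ladder,
                          baseline_ms = 2000, settle_s = 22,
                          train_s = 6, n_s2 = 3) {
  if (length(s2_ladder_ms) && any(diff(s2_ladder_ms) >= 0))
    stop("s2 ladder must be strictly decreasing")
  if (any(s2_ladder_ms <= 0)) stop("s2 intervals must be > 0")
  b <- baseline_ms / 1000
  n_settle <- ceiling(settle_s / b)
  rows <- list()
  cursor <- 0
  add <- function(time_s, type, step, interval_ms, freq_hz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      time_s = time_s, type = type, step = step,
      interval_ms = interval_ms, freq_hz = freq_hz)
  }
  ## opening baseline train (also serves noise estimation)
  s1 <- cursor + b * seq_len(n_settle)
  add(s1, "S1", 0L, baseline_ms, 1000 / baseline_ms)
  cursor <- s1[length(s1)]
  for (k in seq_along(s2_ladder_ms)) {
    iv <- s2_ladder_ms[k]
    ## S2 block: anchors every 4th S1 (3 intervening S1 beats between S2s)
    n_anchor_span <- (n_s2 - 1L) * 4L + 1L
    s1 <- cursor + b * seq_len(n_anchor_span)
    anchors <- s1[1L + 4L * (seq_len(n_s2) - 1L)]
    add(s1, "S1", k, baseline_ms, 1000 / baseline_ms)
    add(anchors + iv / 1000, "S2", k, iv, NA_real_)
    cursor <- s1[length(s1)]
    ## settle, then the constant-frequency train for this step
    s1 <- cursor + b * seq_len(n_settle)
    add(s1, "S1", k, baseline_ms, 1000 / baseline_ms)
    cursor <- s1[length(s1)]
    f <- s2_interval_to_frequency(iv)
    n_train <- max(1L, round(train_s * f))
    tr <- cursor + b + (iv / 1000) * (seq_len(n_train) - 1L)
    add(tr, "train", k, iv, f)
    cursor <- tr[length(tr)] + b
  }
  .new_protocol(do.call(rbind, rows), NULL, "s1s2")
}

#' @describeIn protocols frequency-ladder protocol: after a 0.5 Hz lead-in,
#'   successive constant trains at increasing frequencies, each lasting a
#'   fixed number of beats (25 beats: 25 s at 1 Hz, 5 s at 5 Hz).
#' @param freq_hz increasing pacing frequencies, Hz.
#' @param beats_per_step stimuli per frequency step.
#' @param lead_in_s duration of 0.5 Hz pacing before the ladder, s.
#' @export
frequency_protocol <- function(freq_hz = .default_freq_ladder,
                               beats_per_step = 25, lead_in_s = 24) {
  if (length(freq_hz) && any(diff(freq_hz) <= 0))
    stop("frequency ladder must be strictly increasing")
  if (any(freq_hz <= 0)) stop("frequencies must be > 0")
  rows <- list()
  lead <- 2 * seq_len(ceiling(lead_in_s / 2))
  rows[[1]] <- data.frame(time_s = lead, type = "S1", step = 0L,
                          interval_ms = 2000, freq_hz = 0.5)
  cursor <- lead[length(lead)]
  for (k in seq_along(freq_hz)) {
    f <- freq_hz[k]
    tr <- cursor + (1 / f) * seq_len(beats_per_step)
    rows[[length(rows) + 1L]] <- data.frame(time_s = tr, type = "train",
                                            step = k, interval_ms = 1000 / f,
                                            freq_hz = f)
    cursor <- tr[length(tr)]
  }
  .new_protocol(do.call(rbind, rows), NULL, "frequency")
}

#' @describeIn protocols imaging variant used during simultaneous Ca2+ and
#'   force registration: fewer frequency steps with a fixed number of pulses
#'   each, then a rest pause followed by slow pacing to elicit the post-rest
#'   beat.
#' @param pulses_per_step stimuli per frequency step (imaging variant).
#' @param rest_s pause after the last fast stimulus, s.
#' @param post_rest_hz,post_rest_beats slow pacing after the pause.
#' @export
ffr_protocol <- function(freq_hz = c(0.5, 0.75, 1.0, 1.5, 2.0, 2.5, 3.0),
                         pulses_per_step = 12, rest_s = 5,
                         post_rest_hz = 0.2, post_rest_beats = 4) {
  if (any(diff(freq_hz) <= 0)) stop("frequencies must be strictly increasing")
  rows <- list()
  cursor <- 2
  for (k in seq_along(freq_hz)) {
    f <- freq_hz[k]
    tr <- cursor + (1 / f) * (seq_len(pulses_per_step) - 1L)
    rows[[length(rows) + 1L]] <- data.frame(time_s = tr, type = "train",
                                            step = k, interval_ms = 1000 / f,
                                            freq_hz = f)
    cursor <- tr[length(tr)] + 1 / f
  }
  pr <- max(do.call(rbind, rows)$time_s) + rest_s + (1 / post_rest_hz) * (seq_len(post_rest_beats) - 1L)
  rows[[length(rows) + 1L]] <- data.frame(time_s = pr, type = "train",
                                          step = length(freq_hz) + 1L,
                                          interval_ms = 1000 / post_rest_hz,
                                          freq_hz = post_rest_hz)
  .new_protocol(do.call(rbind, rows), NULL, "ffr")
}

#' Attach a rocker agitation schedule to a protocol
#'
#' @param protocol a \code{pacing_protocol}.
#' @param on_intervals data frame or 2-column matrix of (start_s, end_s)
#'   spans during which the rocker is ON. Analysis only uses rocker-off
#'   periods.
#' @return the protocol with the rocker schedule set.
#' @export
with_rocker <- function(protocol, on_intervals) {
  stopifnot(inherits(protocol, "pacing_protocol"))
  on_intervals <- as.data.frame(on_intervals)
  names(on_intervals) <- c("start_s", "end_s")
  if (nrow(on_intervals) && any(on_intervals$end_s <= on_intervals$start_s))
    stop("rocker intervals must have end > start")
  protocol$rocker <- on_intervals
  protocol
}

#' @export
print.pacing_protocol <- function(x, ...) {
  cat(sprintf("<pacing_protocol: %s> %d stimuli, %.1f s, %d rocker-on spans\n",
              x$kind, nrow(x$stimuli), x$duration_s, nrow(x$rocker)))
  invisible(x)
}

#' Serialize a protocol to the controller text command format
#'
#' One command per line. Grammar:
#' \preformatted{
#' PULSE NEG_MS=3 PAUSE_MS=1 POS_MS=3
#' ROCKER_ON START_S=<t> END_S=<t>
#' TRAIN START_S=<t> INTERVAL_MS=<i> COUNT=<n> TYPE=<S1|train> STEP=<k>
#' S2 START_S=<t> S2_MS=<i> STEP=<k>
#' }
#' \code{TRAIN} lines encode runs of equally spaced stimuli; \code{S2} lines
#' encode single extrastimuli with their coupling interval.
#'
#' @param protocol a \code{pacing_protocol}.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "pacing_protocol"))
  st <- protocol$stimuli
  lines <- sprintf("PULSE NEG_MS=%g PAUSE_MS=%g POS_MS=%g",
                   protocol$pulse[["neg_ms"]], protocol$pulse[["pause_ms"]],
                   protocol$pulse[["pos_ms"]])
  if (nrow(protocol$rocker))
    lines <- c(lines, sprintf("ROCKER_ON START_S=%.6g END_S=%.6g",
                              protocol$rocker$start_s, protocol$rocker$end_s))
  ## group consecutive equally spaced non-S2 stimuli into TRAIN commands
  ns2 <- st[st$type != "S2", , drop = FALSE]
  if (nrow(ns2)) {
    grp <- cumsum(c(TRUE, abs(diff(ns2$time_s) * 1000 - ns2$interval_ms[-1]) > 1e-6 |
                      diff(ns2$step) != 0 | ns2$type[-1] != ns2$type[-nrow(ns2)]))
    for (g in split(seq_len(nrow(ns2)), grp)) {
      r <- ns2[g, ]
      lines <- c(lines, sprintf(
        "TRAIN START_S=%.6f INTERVAL_MS=%.6g COUNT=%d TYPE=%s STEP=%d",
        r$time_s[1], r$interval_ms[1], nrow(r), r$type[1], r$step[1]))
    }
  }
  s2 <- st[st$type == "S2", , drop = FALSE]
  if (nrow(s2))
    lines <- c(lines, sprintf("S2 START_S=%.6f S2_MS=%.6g STEP=%d",
                              s2$time_s, s2$interval_ms, s2$step))
  writeLines(c(sprintf("# trabkit protocol v1 kind=%s", protocol$kind), lines), path)
  invisible(path)
}

#' Read a protocol from the controller text command format
#'
#' @param path file written by [write_protocol()].
#' @return a \code{pacing_protocol}.
#' @export
read_protocol <- function(path) {
  lines <- readLines(path)
  kind <- sub(".*kind=", "", lines[1])
  lines <- lines[!grepl("^#", lines)]
  field <- function(line, key) {
    m <- regmatches(line, regexec(paste0(key, "=([-0-9.eE]+)"), line))[[1]]
    if (length(m) < 2) NA_real_ else as.numeric(m[2])
  }
  rows <- list(); rocker <- list()
  for (ln in lines) {
    if (startsWith(ln, "TRAIN")) {
      t0 <- field(ln, "START_S"); iv <- field(ln, "INTERVAL_MS")
      n <- field(ln, "COUNT"); stp <- field(ln, "STEP")
      ty <- sub(".*TYPE=([^ ]+).*", "\\1", ln)
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = t0 + (iv / 1000) * (seq_len(n) - 1L), type = ty,
        step = as.integer(stp), interval_ms = iv,
        freq_hz = if (ty == "S1") 1000 / iv else 1000 / iv)
    } else if (startsWith(ln, "S2")) {
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = field(ln, "START_S"), type = "S2",
        step = as.integer(field(ln, "STEP")),
        interval_ms = field(ln, "S2_MS"), freq_hz = NA_real_)
    } else if (startsWith(ln, "ROCKER_ON")) {
      rocker[[length(rocker) + 1L]] <- data.frame(
        start_s = field(ln, "START_S"), end_s = field(ln, "END_S"))
    }
  }
  rk <- if (length(rocker)) do.call(rbind, rocker) else NULL
  .new_protocol(do.call(rbind, rows), rk, kind)
}
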