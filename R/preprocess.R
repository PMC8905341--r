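#' Downsample a 400 Hz recording to 200 Hz with a mean filter
#'
#' Each output sample is the mean of two consecutive input samples; an odd
#' trailing sample is dropped (with a message). Stimulus times and rocker
#' intervals are unchanged.
#'
#' @param rec a \code{force_recording} at 400 Hz.
#' @return the recording at 200 Hz.
#' @export
downsample_mean <- function(rec) {
  stopifnot(inherits(rec, "force_recording"))
  if (rec$sample_rate != 400)
    stop("downsample_mean expects the 400 Hz device stream")
  n <- length(rec$force)
  if (n %% 2 == 1) {
    message("downsample_mean: dropping odd trailing sample")
    n <- n - 1L
  }
  m <- matrix(rec$force[seq_len(n)], nrow = 2)
  rec$force <- colMeans(m)
  rec$sample_rate <- 200
  rec$time_s <- (seq_len(ncol(m)) - 1) / 200
  rec
}

## centered moving median with truncated windows at the edges
.moving_median <- function(x, radius) {
  k <- 2L * radius + 1L
  y <- stats::runmed(x, k, endrule = "keep")
  n <- length(x)
  for (i in seq_len(min(radius, n))) {
    y[i] <- stats::median(x[1:min(n, i + radius)])
    j <- n - i + 1L
    y[j] <- stats::median(x[max(1L, j - radius):n])
  }
  y
}

## centered moving mean with truncated windows at the edges (O(n) via cumsum)
.moving_mean <- function(x, radius) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - radius, 1L)
  hi <- pmin(seq_len(n) + radius, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Denoise a 200 Hz force trace
#'
#' Applies a central moving median filter of radius 10 samples followed by a
#' central moving mean filter of radius 5 samples (21- and 11-sample
#' windows at 200 Hz). Edge windows are truncated, so the series length is
#' preserved. Both filters leave constants unchanged and the median filter
#' rejects isolated spikes.
#'
#' @param rec a \code{force_recording} at 200 Hz (see [downsample_mean()]).
#' @param median_radius,mean_radius filter radii in samples.
#' @return the recording with the filtered trace and \code{filtered = TRUE}.
#' @export
denoise <- function(rec, median_radius = 10L, mean_radius = 5L) {
  stopifnot(inherits(rec, "force_recording"))
  if (rec$sample_rate != 200)
    stop("denoise expects a 200 Hz trace; run downsample_mean() first")
  if (length(rec$force) < 2L * median_radius + 1L)
    stop("trace shorter than the median filter window")
  rec$force <- .moving_mean(.moving_median(rec$force, median_radius), mean_radius)
  rec$filtered <- TRUE
  rec
}

#' Estimate the sensor noise level
#'
#' Pools the 200 ms windows directly before each stimulus delivered at slow
#' pacing (preceding inter-stimulus interval >= 1000 ms, i.e. <= 1 Hz)
#' during rocker-off periods; in these windows the trace contains only
#' sensor noise because contractions are always over well before the next
#' slow stimulus. Windows crossing a rocker transition are shortened to
#' their rocker-off part and discarded if less than half the nominal length
#' remains. The estimate is the pooled standard deviation of the
#' mean-removed windows and the largest within-window peak-to-peak
#' excursion.
#'
#' @param rec a (typically filtered) \code{force_recording}.
#' @param window_s pre-stimulus window length, s.
#' @param max_rate_hz only stimuli at pacing at or below this rate qualify.
#' @return a list with \code{sd}, \code{max_amplitude} (both uN) and
#'   \code{n_windows}, of class \code{noise_estimate}.
#' @export
estimate_noise <- function(rec, window_s = 0.2, max_rate_hz = 1) {
  stopifnot(inherits(rec, "force_recording"))
  st <- rec$stimulus_times
  if (!length(st)) stop("no stimuli in recording; supply a fallback noise level")
  prev_iv <- c(Inf, diff(st))              # first stimulus: infinite rest before
  ok <- prev_iv >= 1 / max_rate_hz
  fs <- rec$sample_rate
  resid <- list(); maxamp <- 0; n_win <- 0L
  for (t1 in st[ok]) {
    t0 <- t1 - window_s
    if (t0 < 0) next
    span <- .clip_to_rocker_off(t0, t1, rec$rocker_intervals)
    if (is.null(span) || (span[2] - span[1]) < window_s / 2) next
    idx <- which(rec$time_s >= span[1] & rec$time_s < span[2])
    if (length(idx) < 4) next
    w <- rec$force[idx]
    resid[[length(resid) + 1L]] <- w - mean(w)
    maxamp <- max(maxamp, max(w) - min(w))
    n_win <- n_win + 1L
  }
  if (n_win == 0L)
    stop("no qualifying pre-stimulus window (rocker off, pacing <= 1 Hz); ",
         "supply a fallback noise level")
  r <- unlist(resid)
  sd_pooled <- sqrt(sum(r^2) / max(1L, length(r) - n_win))
  structure(list(sd = sd_pooled, max_amplitude = maxamp, n_windows = n_win),
            class = "noise_estimate")
}

## largest sub-interval of [t0, t1] not overlapping any rocker-on interval,
## keeping the end anchored at t1 where possible (window purity over count)
.clip_to_rocker_off <- function(t0, t1, rocker) {
  if (is.null(rocker) || !nrow(rocker)) return(c(t0, t1))
  for (j in seq_len(nrow(rocker))) {
    a <- rocker$start_s[j]; b <- rocker$end_s[j]
    if (a < t1 && b > t0) {            # overlap
      if (b >= t1) t1 <- min(t1, a)    # rocker covers the end
      else t0 <- max(t0, b)            # rocker covers the start
    }
  }
  if (t1 <= t0) NULL else c(t0, t1)
}

## TRUE for times inside any rocker-on interval
.in_rocker_on <- function(t, rocker) {
  if (is.null(rocker) || !nrow(rocker)) return(rep(FALSE, length(t)))
  on <- rep(FALSE, length(t))
  for (j in seq_len(nrow(rocker)))
    on <- on | (t >= rocker$start_s[j] & t < rocker$end_s[j])
  on
}
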