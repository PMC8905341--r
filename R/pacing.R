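#' Capture analysis of S1-S2 and frequency-ladder recordings
#'
#' Shared capture rule: a stimulus is captured iff, within the open window
#' between it and the next stimulus, the trace contains a local maximum
#' whose rise above the preceding within-window minimum strictly exceeds the
#' minimum peak height (maximum noise amplitude + 1 noise SD) -- the same
#' peak rule the beat detector uses, applied to one inter-stimulus window.
#' The window excludes the stimulus instants themselves, so the stimulation
#' artifact and the preceding beat's peak never count.
#'
#' @name capture
NULL

## capture test in the open window (t0, t1)
.captured_in_window <- function(rec, t0, t1, h) {
  idx <- which(rec$time_s > t0 & rec$time_s < t1)
  if (length(idx) < 3) return(FALSE)
  x <- rec$force[idx]
  n <- length(x)
  loc <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(loc)) return(FALSE)
  cummin_x <- cummin(x)
  any(x[loc] - cummin_x[loc] > h)
}

#' @describeIn capture per-ladder-step S2 capture table. For each S2
#'   stimulus the window up to the following stimulus is tested; a ladder
#'   step is captured iff all of its S2 stimuli are captured.
#' @param rec a filtered \code{force_recording} of an S1-S2 protocol with
#'   its stimulus table.
#' @param noise a \code{noise_estimate}.
#' @return data frame: \code{step}, \code{interval_ms}, \code{n_s2},
#'   \code{n_captured}, \code{captured}, \code{evaluable}.
#' @export
detect_capture_s2 <- function(rec, noise) {
  st <- rec$stim_table
  if (is.null(st) || !any(st$type == "S2"))
    stop("recording has no S2 stimuli in its stimulus table")
  h <- noise$max_amplitude + noise$sd
  steps <- sort(unique(st$step[st$type == "S2"]))
  out <- lapply(steps, function(k) {
    s2 <- st[st$type == "S2" & st$step == k, ]
    n_cap <- 0L
    for (t0 in s2$time_s) {
      nxt <- st$time_s[st$time_s > t0]
      t1 <- if (length(nxt)) min(nxt) else t0 + s2$interval_ms[1] / 1000 * 2
      if (.captured_in_window(rec, t0, t1, h)) n_cap <- n_cap + 1L
    }
    data.frame(step = k, interval_ms = s2$interval_ms[1], n_s2 = nrow(s2),
               n_captured = n_cap, captured = n_cap == nrow(s2),
               evaluable = nrow(s2) >= 1L)
  })
  do.call(rbind, out)
}

#' @describeIn capture refractory period from an S2 capture table: the
#'   ladder interval immediately preceding the first not-captured step. If
#'   every step is captured the RP lies below the shortest tested interval
#'   (censoring flag \code{"below_min"}); if already the first (longest)
#'   interval fails it lies above the longest (\code{"above_max"}).
#' @param capture_table result of [detect_capture_s2()], ordered by
#'   decreasing interval.
#' @return list with \code{rp_ms} (NA when censored) and \code{flag}
#'   (\code{"measured"}, \code{"below_min"}, \code{"above_max"} or
#'   \code{"unevaluable"}).
#' @export
refractory_period <- function(capture_table) {
  ct <- capture_table[order(-capture_table$interval_ms), , drop = FALSE]
  if (!nrow(ct)) stop("empty capture table")
  fail <- which(!ct$captured)
  if (!length(fail))
    return(list(rp_ms = NA_real_, flag = "below_min"))
  f1 <- fail[1]
  if (any(!ct$evaluable[seq_len(f1)]))
    return(list(rp_ms = NA_real_, flag = "unevaluable"))
  if (f1 == 1L)
    return(list(rp_ms = NA_real_, flag = "above_max"))
  list(rp_ms = ct$interval_ms[f1 - 1L], flag = "measured")
}

#' @describeIn capture maximum captured frequency from constant-frequency
#'   trains: per frequency the last five stimuli are tested individually
#'   (window up to the next stimulus, or one interval after the last);
#'   the frequency is captured iff all five are. \code{f_max} is the last
#'   captured frequency before the first non-captured one; full capture
#'   everywhere flags \code{"at_max"}, no captured train \code{"below_min"}.
#' @param n_last number of train-final stimuli that must each be captured.
#' @return \code{max_frequency}: list with \code{f_max_hz}, \code{flag} and
#'   the per-frequency capture table.
#' @export
max_frequency <- function(rec, noise, n_last = 5L) {
  st <- rec$stim_table
  if (is.null(st) || !any(st$type == "train"))
    stop("recording has no constant-frequency trains in its stimulus table")
  h <- noise$max_amplitude + noise$sd
  tr <- st[st$type == "train", ]
  steps <- unique(tr$step)
  tab <- lapply(steps, function(k) {
    s <- tr[tr$step == k, ]
    f <- s$freq_hz[1]
    if (nrow(s) < n_last)
      return(data.frame(step = k, freq_hz = f, captured = NA, evaluable = FALSE))
    last5 <- utils::tail(s$time_s, n_last)
    cap <- vapply(last5, function(t0) {
      nxt <- st$time_s[st$time_s > t0]
      t1 <- if (length(nxt)) min(nxt) else t0 + s$interval_ms[1] / 1000
      .captured_in_window(rec, t0, t1, h)
    }, logical(1))
    data.frame(step = k, freq_hz = f, captured = all(cap), evaluable = TRUE)
  })
  tab <- do.call(rbind, tab)
  tab <- tab[order(tab$freq_hz), , drop = FALSE]
  ev <- tab[tab$evaluable, , drop = FALSE]
  if (!nrow(ev)) return(list(f_max_hz = NA_real_, flag = "unevaluable", table = tab))
  fail <- which(!ev$captured)
  if (!length(fail))
    return(list(f_max_hz = max(ev$freq_hz), flag = "at_max", table = tab))
  if (fail[1] == 1L)
    return(list(f_max_hz = NA_real_, flag = "below_min", table = tab))
  list(f_max_hz = ev$freq_hz[fail[1] - 1L], flag = "measured", table = tab)
}

#' @describeIn capture percent change of the refractory period between two
#'   measured (uncensored) values: \code{100 (rp_after - rp_before) /
#'   rp_before}.
#' @param rp_before,rp_after refractory periods in ms, or the lists returned
#'   by [refractory_period()].
#' @export
rp_percent_change <- function(rp_before, rp_after) {
  unwrap <- function(x) {
    if (is.list(x)) {
      if (!identical(x$flag, "measured")) stop("censored RP cannot be compared")
      x$rp_ms
    } else x
  }
  b <- unwrap(rp_before); a <- unwrap(rp_after)
  if (!is.finite(b) || !is.finite(a)) stop("censored RP cannot be compared")
  100 * (a - b) / b
}
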