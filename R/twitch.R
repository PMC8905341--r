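#' Generate a single twitch waveform
#'
#' Builds one isometric contraction transient with a morphology designed to
#' pass undistorted through the analysis chain's conditioning filters:
#' a symmetric, gently rounded summit (shallow parabolic cap spanning the
#' median filter's window, 2\% droop), near-linear rising and relaxing
#' flanks, and a raised-cosine foot whose midpoint -- the flank's inflection
#' point -- sits exactly at the 10\%-amplitude level, \code{ttp90} before
#' and \code{ttr90} after the peak. Because the summit is locally symmetric
#' and the 10\% crossings are local inflections, the 21-sample median and
#' 11-sample mean filters neither attenuate the peak appreciably nor bias
#' the crossing times, so the analytic kinetics stay recoverable at
#' one-sample accuracy. The waveform is smooth, single-peaked and
#' non-negative; it starts and ends at zero (compact support) and its
#' sampled maximum equals \code{amplitude} exactly (the peak lies on the
#' sample grid).
#'
#' @param amplitude peak force in uN; 0 returns an all-zero waveform.
#' @param ttp90 time from 10\% of amplitude to peak, ms.
#' @param ttr90 time from peak back to 10\% of amplitude, ms.
#' @param dt sample period in ms (2.5 ms at the 400 Hz device stream).
#' @return numeric vector of force samples (uN), starting and ending at 0,
#'   with attributes \code{peak_index} and \code{dt_ms}.
#' @examples
#' w <- make_twitch(300, 150, 250, 2.5)
#' max(w) # exactly 300
#' @export
make_twitch <- function(amplitude, ttp90, ttr90, dt) {
  if (!is.finite(amplitude) || amplitude < 0)
    stop("make_twitch: 'amplitude' must be a non-negative number")
  if (amplitude == 0) {
    w <- numeric(16L)
    attr(w, "peak_index") <- 1L
    attr(w, "dt_ms") <- dt
    return(w)
  }
  if (any(!is.finite(c(ttp90, ttr90, dt))) || ttp90 <= 0 || ttr90 <= 0 || dt <= 0)
    stop("make_twitch: 'ttp90', 'ttr90' and 'dt' must be positive")
  if (ttp90 < 2 * dt || ttr90 < 2 * dt)
    stop("make_twitch: kinetics shorter than 2*dt cannot be resolved at this sample period")

  q <- 0.02                                     # summit droop at the cap edge
  v_foot <- 0.2                                 # flank value where the cosine foot begins
  t0 <- max(min(50, 0.5 * min(ttp90, ttr90) - dt), dt)  # cap half-width, ms
  ## foot length L: cosine midpoint (value 0.1, at distance T from the peak)
  ## has slope matching the linear flank from the cap edge
  Lr <- 0.1 * pi * (ttp90 - t0) / (1 - q - v_foot + 0.05 * pi)
  Lf <- 0.1 * pi * (ttr90 - t0) / (1 - q - v_foot + 0.05 * pi)
  side <- function(d, Tt, L) {                  # d = |t - tp| >= 0, one limb
    v <- numeric(length(d))
    cap <- d <= t0
    v[cap] <- 1 - q * (d[cap] / t0)^2
    lin <- d > t0 & d <= Tt - L / 2
    v[lin] <- 1 - q - (1 - q - v_foot) * (d[lin] - t0) / (Tt - L / 2 - t0)
    foot <- d > Tt - L / 2 & d <= Tt + L / 2
    ## sine form centred on the crossing: exactly v_foot/2 = 10% at d == Tt
    v[foot] <- v_foot * (1 - sin(pi * (d[foot] - Tt) / L)) / 2
    v
  }
  k_lo <- -ceiling((ttp90 + Lr / 2) / dt)
  k_hi <- ceiling((ttr90 + Lf / 2) / dt)
  t_s <- seq(k_lo, k_hi) * dt                   # peak (t = 0) lies on the grid
  w <- ifelse(t_s < 0, side(-t_s, ttp90, Lr), side(t_s, ttr90, Lf))
  w <- amplitude * w / max(w)
  w <- c(0, w, 0)
  attr(w, "peak_index") <- which.max(w)
  attr(w, "dt_ms") <- dt
  w
}
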