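#' Ground-truth tissue parameters for the simulator
#'
#' Bundles the physiology of a simulated trabecula: twitch amplitude and
#' kinetics, device preload, a restitution-based refractoriness model, the
#' force-frequency relationship (FFR), post-rest potentiation, alternans
#' behaviour near the capture limit, and sensor/rocker noise.
#'
#' Refractoriness follows
#' \deqn{RP(DI) = rp_{min} + (rp_{max} - rp_{min})(1 - e^{-DI/\tau})}
#' where \eqn{DI} is the diastolic (coupling) interval that preceded the last
#' activation. A stimulus elicits a contraction iff the time since the last
#' activation is at least the current RP. With \code{rp_min == rp_max} the
#' tissue has a fixed refractory period (restitution disabled).
#'
#' @param amplitude_base twitch amplitude at 0.5 Hz pacing, uN.
#' @param ttp90_true,ttr90_true true 10\%-crossing kinetics, ms.
#' @param diastolic_force device preload, uN (default 500).
#' @param rp_min,rp_max refractory period bounds, ms.
#' @param restitution_tau restitution time constant, ms.
#' @param ffr_slope fractional amplitude change per Hz relative to 0.5 Hz
#'   (negative = negative FFR).
#' @param post_rest_gain amplitude factor (>= 1) applied to the first beat
#'   after a pause of at least \code{post_rest_pause_s}.
#' @param post_rest_pause_s pause duration qualifying as rest, s.
#' @param alternans_ratio amplitude fraction of the weak beat when alternans
#'   is active (only if \code{alternans = TRUE}).
#' @param alternans whether mechanical alternans is produced near the capture
#'   limit (coupling interval < 1.25 x current RP).
#' @param noise_sd Gaussian sensor noise sd, uN.
#' @param rocker_artifact_amp,rocker_artifact_freq amplitude (uN) and
#'   frequency (Hz) of the agitation artifact added while the rocker is on
#'   (default 1 Hz, i.e. 60 rpm).
#' @param drug optional modifier list with any of \code{amplitude_factor},
#'   \code{kinetics_factor}, \code{rp_shift} (fractional RP change, e.g.
#'   +0.25), \code{alternans}. See [drug_preset()].
#' @return an object of class \code{tissue_params}.
#' @export
tissue_params <- function(amplitude_base = 300,
                          ttp90_true = 150,
                          ttr90_true = 250,
                          diastolic_force = 500,
                          rp_min = 150,
                          rp_max = 380,
                          restitution_tau = 1800,
                          ffr_slope = -0.1,
                          post_rest_gain = 1.3,
                          post_rest_pause_s = 4,
                          alternans_ratio = 0.4,
                          alternans = FALSE,
                          noise_sd = 5,
                          rocker_artifact_amp = 40,
                          rocker_artifact_freq = 1,
                          drug = NULL) {
  p <- list(amplitude_base = amplitude_base, ttp90_true = ttp90_true,
            ttr90_true = ttr90_true, diastolic_force = diastolic_force,
            rp_min = rp_min, rp_max = rp_max, restitution_tau = restitution_tau,
            ffr_slope = ffr_slope, post_rest_gain = post_rest_gain,
            post_rest_pause_s = post_rest_pause_s,
            alternans_ratio = alternans_ratio, alternans = alternans,
            noise_sd = noise_sd, rocker_artifact_amp = rocker_artifact_amp,
            rocker_artifact_freq = rocker_artifact_freq)
  if (!is.null(drug)) {
    if (!is.list(drug)) stop("'drug' must be a list (see drug_preset())")
    p$amplitude_base <- p$amplitude_base * (drug$amplitude_factor %||% 1)
    kf <- drug$kinetics_factor %||% 1
    p$ttp90_true <- p$ttp90_true * kf
    p$ttr90_true <- p$ttr90_true * kf
    rs <- drug$rp_shift %||% 0
    p$rp_min <- p$rp_min * (1 + rs)
    p$rp_max <- p$rp_max * (1 + rs)
    if (isTRUE(drug$alternans)) p$alternans <- TRUE
  }
  with(p, {
    if (amplitude_base < 0) stop("amplitude_base must be >= 0")
    if (!(rp_min > 0 && rp_min <= rp_max)) stop("need 0 < rp_min <= rp_max")
    if (restitution_tau <= 0) stop("restitution_tau must be > 0")
    if (ttp90_true <= 0 || ttr90_true <= 0) stop("kinetics must be > 0")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (post_rest_gain < 1) stop("post_rest_gain must be >= 1")
    if (alternans_ratio < 0 || alternans_ratio > 1)
      stop("alternans_ratio must be in [0, 1]")
  })
  structure(p, class = "tissue_params")
}

#' Drug modifier presets
#'
#' Convenience modifier sets for the simulator. \code{"isoprenaline"}
#' emulates beta-adrenergic stimulation (inotropy, faster kinetics, shorter
#' refractory period); \code{"dofetilide"} emulates IKr block (longer
#' refractory period, mild inotropy, alternans near the capture limit). All
#' factors can be overridden.
#'
#' @param name \code{"isoprenaline"} or \code{"dofetilide"}.
#' @param ... overrides for individual factors.
#' @return a modifier list for the \code{drug} argument of [tissue_params()].
#' @export
drug_preset <- function(name = c("isoprenaline", "dofetilide"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    isoprenaline = list(amplitude_factor = 2.15, kinetics_factor = 0.63,
                        rp_shift = -0.30, alternans = FALSE),
    dofetilide   = list(amplitude_factor = 1.2, kinetics_factor = 1,
                        rp_shift = 0.25, alternans = TRUE))
  utils::modifyList(base, list(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
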