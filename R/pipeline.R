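#' Convert spring-wire deflection to force
#'
#' The cultivation chamber registers contraction as deflection of a flexible
#' spring wire; force is deflection times the spring constant
#' (approximately 25 mN/mm for the standard wire). Output is in uN:
#' 0.02 mm x 25 mN/mm = 0.5 mN = 500 uN, the standard diastolic preload.
#'
#' @param deflection_mm deflection in mm.
#' @param spring_mN_per_mm spring constant in mN/mm.
#' @return force in uN.
#' @export
deflection_to_force <- function(deflection_mm, spring_mN_per_mm = 25) {
  if (any(spring_mN_per_mm <= 0)) stop("spring constant must be > 0")
  deflection_mm * spring_mN_per_mm * 1000
}

.default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = c("beats", "pacing", "ca", "confocal", "qpcr", "viability", "stats"),
    screen_threshold_uN = 50,       # beating screen
    preload_uN = 500,               # diastolic preload
    spring_mN_per_mm = 25,
    s2_ladder_ms = .default_s2_ladder,
    freq_ladder_hz = .default_freq_ladder,
    k_sd = c(WGA = 1, Cx43 = 3, DAPI = 2),
    aact_content = 0.075,
    tissue = list(),                # tissue_params() overrides for simulation
    volume_dim = c(64, 64, 32),
    n_pairs = 8
  )
}

#' Validate and complete a pipeline configuration
#'
#' Defaults equal the platform's standard operating values: 50 uN beating
#' screen, 500 uN preload, 25 mN/mm spring constant, the printed S2 and
#' frequency ladders, mode + (1, 3, 2) SD channel thresholds and the 7.5\%
#' myocyte classification content. Unknown keys are rejected by name.
#'
#' @param config named list of overrides, or a path to a YAML file.
#' @return the completed configuration list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config)
}

#' Run the simulate-then-analyze pipeline
#'
#' Generates one synthetic dataset per requested stage (force recordings
#' under the S1-S2 and frequency protocols, a synchronized Ca2+/force pair,
#' a confocal volume, qPCR Ct tables, MTT/Bradford plate readings) and runs
#' the corresponding analyses, writing per-stage CSV outputs, a combined
#' JSON report and a reproducibility manifest (seed, package version,
#' configuration hash) into \code{out_dir}.
#'
#' @param config see [run_config()].
#' @return the report list, invisibly if \code{out_dir} is set.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- run_config(config)
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  params <- do.call(tissue_params, cfg$tissue)
  report <- list()

  if ("beats" %in% cfg$stages) {
    proto <- frequency_protocol(cfg$freq_ladder_hz)
    rec <- simulate_recording(params, proto, seed = seed)
    an <- analyze_recording(rec)
    baseline <- an$beats[!is.na(an$beats$stimulus_time) &
                           an$beats$stimulus_time <= 24, , drop = FALSE]
    report$beats <- list(
      beating = classify_beating(an$beats, cfg$screen_threshold_uN),
      noise = unclass(an$noise),
      baseline_summary = summarize_period(baseline, n_stimuli = sum(rec$stim_table$step == 0),
                                          pacing_hz = 0.5),
      n_beats = nrow(an$beats))
    report$ffr <- do.call(rbind, lapply(split(an$beats, an$beats$interval_ms),
      function(b) summarize_period(b, pacing_hz = 1000 / b$interval_ms[1])))
    if (!is.null(cfg$out_dir))
      utils::write.csv(an$beats, file.path(cfg$out_dir, "beats.csv"), row.names = FALSE)
  }

  if ("pacing" %in% cfg$stages) {
    proto <- s1s2_protocol(cfg$s2_ladder_ms)
    rec <- simulate_recording(params, proto, seed = seed + 1L)
    tr <- denoise(downsample_mean(rec))
    noise <- estimate_noise(tr)
    cap <- detect_capture_s2(tr, noise)
    rp <- refractory_period(cap)
    fproto <- frequency_protocol(cfg$freq_ladder_hz)
    frec <- simulate_recording(params, fproto, seed = seed + 2L)
    ftr <- denoise(downsample_mean(frec))
    fm <- max_frequency(ftr, estimate_noise(ftr))
    report$pacing <- list(capture_table = cap, rp_ms = rp$rp_ms, rp_flag = rp$flag,
                          f_max_hz = fm$f_max_hz, f_max_flag = fm$flag)
    if (!is.null(cfg$out_dir))
      utils::write.csv(cap, file.path(cfg$out_dir, "s2_capture.csv"), row.names = FALSE)
  }

  if ("ca" %in% cfg$stages) {
    proto <- ffr_protocol()
    frec <- downsample_mean(simulate_recording(params, proto, seed = seed + 3L))
    carec <- simulate_photometry(params, proto, seed = seed + 3L, clock_offset_s = 0.25)
    al <- synchronize(frec, carec)
    fr <- frequency_response(al)
    pr <- post_rest_ratio(al)
    report$ca_force <- list(offset_s = al$offset_s, jitter_ms = al$jitter_ms,
                            frequency_response = fr,
                            post_rest = pr[c("force_ratio", "ca_ratio")])
    if (!is.null(cfg$out_dir))
      utils::write.csv(fr, file.path(cfg$out_dir, "frequency_response.csv"),
                       row.names = FALSE)
  }

  if ("confocal" %in% cfg$stages) {
    sv <- simulate_volume(dim_vox = cfg$volume_dim, seed = seed + 4L)
    seg <- segment_stack(sv$stack, k_sd = cfg$k_sd, aact_content = cfg$aact_content)
    report$confocal <- list(fractions = seg$fractions,
                            truth_fractions = sv$truth$fractions,
                            n_segments = nrow(seg$classes),
                            n_myocyte_segments = sum(seg$classes$myocyte))
    if (!is.null(cfg$out_dir))
      utils::write.csv(seg$fractions, file.path(cfg$out_dir, "volume_fractions.csv"),
                       row.names = FALSE)
  }

  if ("qpcr" %in% cfg$stages) {
    genes <- c(CACNA1C = 0.7, ATP2A2 = 0.5, GJA1 = 1.0, KCNJ4 = 0.5, KCNJ2 = 3.0)
    eff <- stats::setNames(rep(1.95, length(genes) + 2),
                           c(names(genes), "EEF2", "HPRT1"))
    ctab <- simulate_ct_table(genes, eff, replicate_sd = 0.15,
                              n_pairs = cfg$n_pairs, seed = seed + 5L)
    est_eff <- vapply(unique(ctab$dilution_series$gene), function(g) {
      ds <- ctab$dilution_series[ctab$dilution_series$gene == g, ]
      qpcr_efficiency(ds$ct, ds$dilution)$E
    }, numeric(1))
    ratios <- vapply(names(genes), function(g)
      expression_ratio(ctab$samples, g, efficiencies = est_eff)$ratio, numeric(1))
    report$qpcr <- list(true_ratios = genes, estimated_ratios = ratios,
                        efficiencies = est_eff)
  }

  if ("viability" %in% cfg$stages) {
    pl <- simulate_plate(seed = seed + 6L)
    prot <- bradford_quantify(pl$standards$conc, pl$standards$absorbance,
                              0.1 * pl$plate$protein_true)
    rel <- mtt_relative_absorbance(pl$plate$a595, prot$protein)
    report$viability <- list(
      relative_absorbance = data.frame(group = pl$plate$group, rel = rel),
      group_means = tapply(rel, pl$plate$group, mean))
  }

  if ("stats" %in% cfg$stages && !is.null(report$viability)) {
    v <- report$viability$relative_absorbance
    p <- welch_t(v$rel[v$group == "fresh"], v$rel[v$group == "cultured"])
    report$stats <- list(viability_welch_p = as.numeric(p))
    if (!is.null(report$qpcr)) {
      report$stats$qpcr_note <- "per-gene paired tests require per-sample data; see expression_ratio"
    }
  }

  manifest <- list(package = "trabkit",
                   version = as.character(utils::packageVersion("trabkit")),
                   seed = seed,
                   config_hash = rlang::hash(cfg),
                   timestamp = format(Sys.time(), tz = "UTC"))
  report$manifest <- manifest
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "columns", na = "null")
    return(invisible(report))
  }
  report
}
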