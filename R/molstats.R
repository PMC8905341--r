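#' qPCR amplification efficiency from a template dilution series
#'
#' Least-squares regression of mean Ct on log10 relative template amount;
#' the per-cycle amplification factor is \code{E = 10^(-1/slope)}. A perfect
#' doubling assay has slope -3.3219 and E = 2.
#'
#' @param ct Ct values of the dilution series (replicates averaged).
#' @param dilution relative template amounts (e.g. \code{c(1, 1/5, 1/25,
#'   1/125, 1/625)}).
#' @return list with \code{E}, \code{slope}, \code{r_squared}.
#' @export
qpcr_efficiency <- function(ct, dilution) {
  if (length(ct) != length(dilution) || length(ct) < 3)
    stop("need at least 3 dilution points")
  fit <- stats::lm(ct ~ log10(dilution))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("non-negative slope of Ct vs log10(template): Ct values are not ",
         "monotone in template amount; check the dilution series")
  list(E = 10^(-1 / slope), slope = slope, r_squared = .r2(fit, ct))
}

#' Efficiency-corrected relative expression ratio
#'
#' Pfaffl-style ratio of a target gene between a treatment group and the
#' control group, normalized to reference genes:
#' \deqn{ratio = \frac{E_t^{\Delta Ct_t}}{\mathrm{geomean}_r\, E_r^{\Delta Ct_r}}}
#' with \eqn{\Delta Ct = \overline{Ct}_{control} - \overline{Ct}_{treated}}
#' computed on per-group mean Cts (triplicates averaged per sample first),
#' so upregulation in the treated group gives ratio > 1. Two reference
#' genes are combined by the geometric mean.
#'
#' @param ct_table data frame with columns \code{gene}, \code{sample},
#'   \code{group} (\code{"fresh"} control / \code{"cultured"} treated) and
#'   \code{ct} (replicate-averaged Ct per sample).
#' @param target target gene name.
#' @param reference reference gene names (default EEF2 and HPRT1).
#' @param efficiencies named per-gene amplification efficiencies.
#' @param control,treated group labels.
#' @return list with \code{ratio}, \code{dct_target}, \code{dct_reference}
#'   (named), and the sign convention in \code{convention}.
#' @export
expression_ratio <- function(ct_table, target,
                             reference = c("EEF2", "HPRT1"),
                             efficiencies,
                             control = "fresh", treated = "cultured") {
  need <- c(target, reference)
  if (!all(need %in% names(efficiencies)))
    stop("missing efficiency for: ",
         paste(setdiff(need, names(efficiencies)), collapse = ", "))
  if (!all(need %in% ct_table$gene))
    stop("missing Ct measurements for: ",
         paste(setdiff(need, unique(ct_table$gene)), collapse = ", "))
  dct <- function(gene) {
    g <- ct_table[ct_table$gene == gene, ]
    m_ctrl <- mean(g$ct[g$group == control])
    m_trt <- mean(g$ct[g$group == treated])
    if (!is.finite(m_ctrl) || !is.finite(m_trt))
      stop("group means undefined for gene ", gene)
    m_ctrl - m_trt
  }
  dct_t <- dct(target)
  dct_r <- vapply(reference, dct, numeric(1))
  num <- efficiencies[[target]]^dct_t
  den <- exp(mean(log(mapply(function(g, d) efficiencies[[g]]^d, reference, dct_r))))
  list(ratio = num / den, dct_target = dct_t, dct_reference = dct_r,
       convention = "dCt = Ct(control) - Ct(treated); upregulation => ratio > 1")
}

#' Simulate a qPCR Ct table with dilution series
#'
#' Generates replicate-averaged Ct values under the exponential
#' amplification model \code{Ct = Ct0 - log(template) / log(E)}: paired
#' fresh/cultured samples per gene (cultured template scaled by the true
#' ratio, reference genes unchanged) plus a per-gene dilution series
#' (1, 1:5, 1:25, 1:125, 1:625 by default).
#'
#' @param true_ratios named fold changes (cultured / fresh) for the target
#'   genes.
#' @param efficiencies named per-gene efficiencies in (1, 2].
#' @param reference reference gene names (simulated at ratio 1).
#' @param replicate_sd Gaussian Ct noise sd.
#' @param n_pairs paired samples per group.
#' @param dilution dilution series template amounts.
#' @param ct0 baseline Ct at template 1.
#' @param seed integer seed.
#' @return list with \code{samples} (data frame gene/sample/group/ct) and
#'   \code{dilution_series} (gene/dilution/ct).
#' @export
simulate_ct_table <- function(true_ratios, efficiencies,
                              reference = c("EEF2", "HPRT1"),
                              replicate_sd = 0.1, n_pairs = 8,
                              dilution = c(1, 1/5, 1/25, 1/125, 1/625),
                              ct0 = 22, seed = 1L) {
  genes <- c(names(true_ratios), reference)
  if (!all(genes %in% names(efficiencies)))
    stop("every gene needs an efficiency")
  E <- unlist(efficiencies)[genes]
  if (any(E <= 1 | E > 2))
    stop("efficiencies must lie in (1, 2]")
  if (replicate_sd < 0) stop("replicate_sd must be >= 0")
  set.seed(as.integer(seed))
  ratios <- c(true_ratios, stats::setNames(rep(1, length(reference)), reference))
  rows <- list()
  for (g in genes) {
    for (s in seq_len(n_pairs)) {
      base_tpl <- exp(stats::rnorm(1, 0, 0.15))   # biological sample scatter
      for (grp in c("fresh", "cultured")) {
        tpl <- base_tpl * if (grp == "cultured") ratios[[g]] else 1
        ct <- ct0 - log(tpl) / log(E[[g]]) +
          stats::rnorm(1, 0, replicate_sd / sqrt(3))  # mean of triplicates
        rows[[length(rows) + 1L]] <- data.frame(gene = g, sample = s,
                                                group = grp, ct = ct)
      }
    }
  }
  dil <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g, dilution = dilution,
               ct = ct0 - log(dilution) / log(E[[g]]) +
                 stats::rnorm(length(dilution), 0, replicate_sd / sqrt(3)))))
  list(samples = do.call(rbind, rows), dilution_series = dil)
}

#' Bradford protein quantification via a BSA standard curve
#'
#' Linear regression of standard absorbance on concentration; sample
#' absorbances are inverted through the fit. Values outside the standard
#' range are reported with an extrapolation flag.
#'
#' @param standard_conc standard concentrations (e.g. mg/ml).
#' @param standard_abs their absorbances.
#' @param sample_abs sample absorbances to quantify.
#' @return data frame: \code{absorbance}, \code{protein},
#'   \code{extrapolated}; fit in attributes \code{slope}, \code{intercept},
#'   \code{r_squared}.
#' @export
bradford_quantify <- function(standard_conc, standard_abs, sample_abs) {
  if (length(standard_conc) < 3) stop("need at least 3 standards")
  if (stats::sd(standard_conc) == 0) stop("degenerate standard curve")
  fit <- stats::lm(standard_abs ~ standard_conc)
  b <- unname(stats::coef(fit))
  if (!is.finite(b[2]) || b[2] == 0) stop("singular standard-curve fit")
  conc <- (sample_abs - b[1]) / b[2]
  out <- data.frame(absorbance = sample_abs, protein = conc,
                    extrapolated = sample_abs < min(standard_abs) |
                      sample_abs > max(standard_abs))
  attr(out, "slope") <- b[2]
  attr(out, "intercept") <- b[1]
  attr(out, "r_squared") <- .r2(fit, standard_abs)
  out
}

## R^2 without summary.lm's perfect-fit warning
.r2 <- function(fit, y) {
  tot <- sum((y - mean(y))^2)
  if (tot == 0) return(NA_real_)
  1 - sum(stats::residuals(fit)^2) / tot
}

#' MTT relative absorbance
#'
#' Formazan absorbance divided by total protein: the viability indicator
#' normalized for tissue amount.
#'
#' @param a595 formazan absorbance at 595 nm.
#' @param protein_mg total protein, mg.
#' @return relative absorbance per mg.
#' @export
mtt_relative_absorbance <- function(a595, protein_mg) {
  if (any(!is.finite(protein_mg)) || any(protein_mg <= 0))
    stop("protein must be > 0")
  a595 / protein_mg
}

#' Simulate MTT / Bradford plate readings
#'
#' Paired fresh/cultured trabeculae with configurable relative viability:
#' per-sample protein content, formazan absorbance proportional to
#' viability x protein, and a BSA standard dilution series.
#'
#' @param n_pairs sample pairs.
#' @param viability_cultured viability of cultured relative to fresh (1 =
#'   preserved).
#' @param protein_mean,protein_sd per-trabecula protein, mg.
#' @param abs_per_mg formazan absorbance per mg protein at viability 1.
#' @param noise_sd absorbance noise sd.
#' @param seed integer seed.
#' @return list with \code{plate} (sample/group/a595/protein_true) and
#'   \code{standards} (conc/absorbance, slope 0.1 per mg/ml).
#' @export
simulate_plate <- function(n_pairs = 5, viability_cultured = 1,
                           protein_mean = 1.2, protein_sd = 0.3,
                           abs_per_mg = 0.5, noise_sd = 0.02, seed = 1L) {
  set.seed(as.integer(seed))
  rows <- list()
  for (s in seq_len(n_pairs)) {
    for (grp in c("fresh", "cultured")) {
      prot <- max(0.2, stats::rnorm(1, protein_mean, protein_sd))
      viab <- if (grp == "cultured") viability_cultured else 1
      a <- abs_per_mg * viab * prot + stats::rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(sample = s, group = grp,
                                              a595 = a, protein_true = prot)
    }
  }
  conc <- c(0.25, 0.5, 1, 2, 4, 8)
  list(plate = do.call(rbind, rows),
       standards = data.frame(conc = conc,
                              absorbance = 0.1 * conc +
                                stats::rnorm(length(conc), 0, noise_sd / 4)))
}

#' Statistical tests used for group comparisons
#'
#' Thin wrappers fixing the conventions used throughout: paired two-sided t
#' test for within-trabecula comparisons, Welch's (unequal-variance)
#' two-sided t test for between-trabeculae comparisons, and Holm-Bonferroni
#' step-down correction for multiple comparisons of one parameter. Pairs
#' with zero variance and equal means return p = 1 (degenerate case, with a
#' message).
#'
#' @param x,y numeric samples (equal length >= 2 for the paired test).
#' @return the p-value; the full \code{htest} object in attribute
#'   \code{test}.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired test needs equal lengths")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    message("paired_t: zero variance of differences; p = 1 by convention")
    return(structure(1, test = NULL))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  structure(unname(ht$p.value), test = ht)
}

#' @rdname paired_t
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 observations per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      message("welch_t: zero variance and equal means; p = 1 by convention")
      return(structure(1, test = NULL))
    }
    return(structure(0, test = NULL))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  structure(unname(ht$p.value), test = ht)
}

#' @rdname paired_t
#' @param p vector of raw p-values.
#' @return \code{holm_adjust}: adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  if (!length(p)) stop("need at least one p-value")
  stats::p.adjust(p, method = "holm")
}
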