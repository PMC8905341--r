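test_that("qPCR efficiency is recovered from exact dilution series", {
  ## Ct = 20 - log2(template): perfect doubling assay
  e <- qpcr_efficiency(c(20.00, 22.32, 24.64, 26.97), c(1, 1/5, 1/25, 1/125))
  expect_equal(e$E, 2, tolerance = 0.005)
  ## slope -log2(10) = -3.3219 corresponds exactly to E = 2
  dil <- c(1, 0.1, 0.01, 0.001)
  e2 <- qpcr_efficiency(20 - 3.321928 * log10(dil), dil)
  expect_equal(e2$E, 2, tolerance = 1e-6)
  ## generator round trip at E = 1.9, no noise
  ct <- simulate_ct_table(c(G = 1), c(G = 1.9, EEF2 = 1.9, HPRT1 = 1.9),
                          replicate_sd = 0, seed = 1)
  ds <- ct$dilution_series[ct$dilution_series$gene == "G", ]
  expect_equal(qpcr_efficiency(ds$ct, ds$dilution)$E, 1.9, tolerance = 0.01)
})

test_that("non-monotone dilution series are refused", {
  expect_error(qpcr_efficiency(c(20, 19, 18), c(1, 0.2, 0.04)), "monotone")
  expect_error(qpcr_efficiency(c(20, 21), c(1, 0.2)), "3 dilution points")
})

test_that("expression ratios follow the efficiency-corrected normalization arithmetic", {
  eff <- c(T1 = 2, EEF2 = 2, HPRT1 = 2)
  tab <- function(d_target, d_ref) {
    do.call(rbind, lapply(c("T1", "EEF2", "HPRT1"), function(g) {
      shift <- if (g == "T1") d_target else d_ref
      rbind(data.frame(gene = g, sample = 1:4, group = "fresh", ct = 24),
            data.frame(gene = g, sample = 1:4, group = "cultured", ct = 24 - shift))
    }))
  }
  expect_equal(expression_ratio(tab(0, 0), "T1", efficiencies = eff)$ratio, 1)
  ## target one cycle earlier in cultured, references unchanged -> 2-fold
  expect_equal(expression_ratio(tab(1, 0), "T1", efficiencies = eff)$ratio, 2)
  ## references one cycle earlier, target unchanged -> 0.5
  expect_equal(expression_ratio(tab(0, 1), "T1", efficiencies = eff)$ratio, 0.5)
  ## invariance to a global Ct shift
  t2 <- tab(1, 0); t2$ct <- t2$ct + 3.7
  expect_equal(expression_ratio(t2, "T1", efficiencies = eff)$ratio, 2)
  ## missing reference measurements are refused
  expect_error(expression_ratio(tab(1, 0)[1:8, ], "T1", efficiencies = eff),
               "missing Ct")
})

test_that("simulated Ct tables reproduce known expression ratios end to end", {
  eff <- c(UP = 2, DOWN = 2, FLAT = 2, EEF2 = 2, HPRT1 = 2)
  ct <- simulate_ct_table(c(UP = 2, DOWN = 0.5, FLAT = 1), eff,
                          replicate_sd = 0, seed = 3)
  for (g in c("UP", "DOWN", "FLAT")) {
    r <- expression_ratio(ct$samples, g, efficiencies = eff)$ratio
    expect_equal(r, c(UP = 2, DOWN = 0.5, FLAT = 1)[[g]], tolerance = 1e-9)
  }
  expect_error(simulate_ct_table(c(G = 1), c(G = 2.5, EEF2 = 2, HPRT1 = 2)),
               "efficiencies")
})

test_that("Bradford quantification inverts the standard curve and flags extrapolation", {
  std_c <- 1:5; std_a <- 0.1 * std_c
  out <- bradford_quantify(std_c, std_a, c(0.25, 0.55, 0.3))
  expect_equal(out$protein, c(2.5, 5.5, 3))
  expect_identical(out$extrapolated, c(FALSE, TRUE, FALSE))
  ## a sample matching a standard returns that standard's concentration
  expect_equal(bradford_quantify(std_c, std_a, 0.3)$protein, 3)
  expect_error(bradford_quantify(c(1, 1, 1), c(0.1, 0.1, 0.1), 0.2), "degenerate")
})

test_that("MTT relative absorbance is formazan per mg protein", {
  expect_equal(mtt_relative_absorbance(0.8, 2), 0.4)
  expect_equal(mtt_relative_absorbance(0, 3), 0)
  expect_error(mtt_relative_absorbance(0.5, 0), "> 0")
  ## equal simulated viability in both groups -> comparable group means
  pl <- simulate_plate(n_pairs = 30, viability_cultured = 1, seed = 4)
  rel <- mtt_relative_absorbance(pl$plate$a595, pl$plate$protein_true)
  m <- tapply(rel, pl$plate$group, mean)
  expect_lt(abs(m[["fresh"]] - m[["cultured"]]) / m[["fresh"]], 0.05)
})

test_that("Holm adjustment matches the hand-calculated step-down values", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  ## order preserved, never below raw, monotone in the sorted order
  set.seed(5)
  p <- runif(7)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(holm_adjust(numeric()), "at least one")
})

test_that("paired and Welch tests follow the stated conventions", {
  x <- c(1.2, 2.3, 3.1, 4.5, 5.0)
  y <- x + c(0.4, 0.5, 0.3, 0.6, 0.5)
  p <- paired_t(x, y)
  expect_equal(as.numeric(p), t.test(x - y)$p.value)
  expect_message(pz <- paired_t(x, x), "zero variance")
  expect_equal(as.numeric(pz), 1)
  expect_error(paired_t(x, y[-1]), "equal lengths")
  pw <- welch_t(x, y)
  expect_equal(as.numeric(pw), t.test(x, y, var.equal = FALSE)$p.value)
  expect_message(welch_t(c(2, 2, 2), c(2, 2, 2)), "equal means")
})

test_that("paired t maintains its nominal type-I error rate at n = 8", {
  set.seed(1203)
  n_sim <- 4000
  hits <- 0L
  for (i in seq_len(n_sim)) {
    x <- rnorm(8); y <- rnorm(8)
    if (paired_t(x, y) < 0.05) hits <- hits + 1L
  }
  rate <- hits / n_sim
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})
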