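#!/usr/bin/env Rscript
## Generate the synthetic raw datasets every later step analyzes: force
## recordings under the S1-S2 and frequency-ladder protocols (control and
## drug-modified tissue), a synchronized Ca2+/force pair, a 4-channel
## confocal volume, qPCR Ct tables and MTT/Bradford plate readings.
## Everything is written under results/data/ in the same plain-text formats
## a real rig would export (CSV traces + event logs, TIFF volumes).

suppressPackageStartupMessages(library(trabkit))
seed <- 20240101L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

ctrl <- tissue_params(noise_sd = 5)                       # restitution control
dofe <- tissue_params(drug = drug_preset("dofetilide"), noise_sd = 5)
iso  <- tissue_params(drug = drug_preset("isoprenaline"), noise_sd = 5)

cat("Simulating S1-S2 recordings (control / dofetilide)...\n")
s1s2 <- s1s2_protocol()
write_protocol(s1s2, "results/data/s1s2_protocol.txt")
write_recording(simulate_recording(ctrl, s1s2, seed = seed),
                "results/data/s1s2_control")
write_recording(simulate_recording(dofe, s1s2, seed = seed + 1L),
                "results/data/s1s2_dofetilide")

cat("Simulating frequency-ladder recordings (control / dofetilide / iso)...\n")
freq <- frequency_protocol()
write_recording(simulate_recording(ctrl, freq, seed = seed + 2L),
                "results/data/freq_control")
write_recording(simulate_recording(dofe, freq, seed = seed + 3L),
                "results/data/freq_dofetilide")
write_recording(simulate_recording(iso, freq, seed = seed + 4L),
                "results/data/freq_isoprenaline")

cat("Simulating confocal volume...\n")
sv <- simulate_volume(seed = seed)
write_volume(sv$stack, "results/data/confocal_volume.tif")
jsonlite::write_json(sv$truth$fractions, "results/data/confocal_truth.json",
                     auto_unbox = TRUE, digits = NA)

cat("Simulating qPCR Ct tables and viability plate...\n")
genes <- c(CACNA1C = 0.8, ATP2A2 = 0.5, GJA1 = 1.0, KCNJ4 = 0.5, KCNJ2 = 3.0)
eff <- setNames(rep(1.95, length(genes) + 2), c(names(genes), "EEF2", "HPRT1"))
ct <- simulate_ct_table(genes, eff, replicate_sd = 0.15, n_pairs = 8,
                        seed = seed + 5L)
write.csv(ct$samples, "results/data/qpcr_samples.csv", row.names = FALSE)
write.csv(ct$dilution_series, "results/data/qpcr_dilutions.csv", row.names = FALSE)
pl <- simulate_plate(n_pairs = 5, viability_cultured = 1, seed = seed + 6L)
write.csv(pl$plate, "results/data/plate_mtt.csv", row.names = FALSE)
write.csv(pl$standards, "results/data/plate_bsa_standards.csv", row.names = FALSE)

cat("Done: synthetic datasets under results/data/\n")
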