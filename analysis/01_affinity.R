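#!/usr/bin/env Rscript
# Affinity stage: simulate fixed-PQR FRET titrations at the packaged
# per-lectin (Kd, Fmax) values, refit them with the Hill isotherm, and
# demonstrate the apparent-Kd floor of the conventional fixed-QD design.

suppressMessages(library(qdfret))
seed <- 1L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

dir.create("results", showWarnings = FALSE)
aff <- affinity_temperature_table()
tbl <- utils::read.csv(system.file("extdata", "affinity_vs_temperature.csv",
                                   package = "qdfret"), comment.char = "#")

# geometric dilution series, wide enough to saturate the weakest binder
conc <- 10^seq(log10(0.2e-9), log10(400e-9), length.out = 14)

cat("== Titration simulation and Hill refits (noise_sd = 0.05, triplicate) ==\n")
rows <- list()
for (i in seq_len(nrow(tbl))) {
  pqr <- if (tbl$lectin[i] == "DC-SIGNR") 10 else 1
  g <- gen_titration(tbl$kd_nM[i] * 1e-9, tbl$fmax[i], pqr, conc,
                     noise_sd = 0.05, seed = seed + i,
                     lectin = tbl$lectin[i])
  f <- fit_hill(g$series)
  rows[[i]] <- data.frame(
    lectin = tbl$lectin[i], temperature_C = tbl$temperature_C[i],
    kd_true_nM = tbl$kd_nM[i], kd_fit_nM = f$Kd * 1e9,
    kd_se_nM = f$Kd_sd * 1e9, fmax_true = tbl$fmax[i], fmax_fit = f$Fmax,
    r_squared = f$r_squared)
  cat(sprintf("  %-10s %2d C: Kd %6.2f -> %6.2f nM (R2 %.4f)\n",
              tbl$lectin[i], tbl$temperature_C[i], tbl$kd_nM[i],
              f$Kd * 1e9, f$r_squared))
}
fits <- do.call(rbind, rows)
utils::write.csv(fits, "results/affinity_fits.csv", row.names = FALSE)
cat(sprintf("  max |Kd bias| across fits: %.1f%%\n",
            100 * max(abs(fits$kd_fit_nM / fits$kd_true_nM - 1))))

cat("\n== Apparent-Kd floor of a fixed-QD titration (C_QD = 10 nM, N = 4) ==\n")
grid <- 10^seq(-10, -3, length.out = 500)
floor_rows <- lapply(c(0.01, 0.1, 1, 10, 100, 1000) * 1e-9, function(kd) {
  data.frame(kd_true_nM = kd * 1e9,
             kd_apparent_nM = apparent_kd_fixed_qd(kd, 10e-9, 4, grid) * 1e9)
})
floor_tbl <- do.call(rbind, floor_rows)
print(floor_tbl, row.names = FALSE)
cat("  strong binders are pinned at C_QD x N x 50% = 20 nM;\n")
cat("  the fixed-PQR ratiometric design has no such floor.\n")
utils::write.csv(floor_tbl, "results/kd_floor.csv", row.names = FALSE)
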