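#!/usr/bin/env Rscript
# Kinetics stage: regenerate stopped-flow FRET-ratio traces from the
# packaged per-lectin rate parameters, push them through preprocessing
# (background subtraction, triplicate averaging, block smoothing for the
# weak binder) and the association/dissociation fitters, then reconcile
# the rates with the equilibrium affinities.

suppressMessages(library(qdfret))
seed <- 1L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])
dir.create("results", showWarnings = FALSE)

kin <- kinetic_parameter_table()
x0 <- 20e-9

cat("== Synthetic stopped-flow round trip (channel noise sd = 2, triplicate) ==\n")
rows <- list()
for (i in seq_len(nrow(kin))) {
  lec <- kin$lectin[i]
  block <- if (lec == "DC-SIGNR") 5L else 1L  # smooth the weak binder

  ga <- gen_kinetic_trace("association",
                          list(y_max = kin$assoc_y_max[i],
                               k_on = kin$assoc_k_on_1e7[i] * 1e7,
                               a = kin$assoc_a_1e3[i] * 1e-3),
                          x0 = x0, noise_sd = 2, seed = seed + i)
  fa <- fit_association(preprocess_trace(ga$sample_channels,
                                         ga$background_channels,
                                         smoothing_block = block, x0 = x0,
                                         direction = "association"))
  gd <- gen_kinetic_trace("dissociation",
                          list(y_0 = kin$dissoc_y_0[i],
                               y_eq = kin$dissoc_y_eq[i],
                               k_off_prime = kin$dissoc_k_off_prime[i],
                               a = kin$dissoc_a_1e3[i] * 1e-3),
                          x0 = x0, noise_sd = 2, seed = seed + 100 + i)
  fd <- fit_dissociation(preprocess_trace(gd$sample_channels,
                                          gd$background_channels,
                                          smoothing_block = block, x0 = x0,
                                          direction = "dissociation"))
  rows[[i]] <- data.frame(
    lectin = lec,
    k_on_fit_1e7 = fa$k_on / 1e7, t_half_assoc_s = fa$t_half,
    drift_class = fa$drift_class,
    k_off_prime_fit = fd$k_off_prime, t_half_dissoc_s = fd$t_half)
  cat(sprintf(
    "  %-10s k_on %5.2fe7 /M/s (t1/2 %5.2f s, %s); k_off' %5.2f /s (t1/2 %5.3f s)\n",
    lec, fa$k_on / 1e7, fa$t_half, fa$drift_class, fd$k_off_prime,
    fd$t_half))
}
fits <- do.call(rbind, rows)
utils::write.csv(fits, "results/kinetic_fits.csv", row.names = FALSE)

cat("\n== Derived-rate reconciliation with equilibrium affinity (20 C) ==\n")
aff <- affinity_temperature_table()
kd20 <- with(aff[aff$temperature_K == 293.15, ], stats::setNames(Kd, lectin))
summ <- kinetic_summary(kin, x0 = x0, Kd_equilibrium = kd20)
print(transform(summ,
                Kd_prime_nM = Kd_prime_M * 1e9, Kd_prime_M = NULL,
                t_half_assoc_s = round(t_half_assoc_s, 3),
                t_half_dissoc_s = round(t_half_dissoc_s, 3)),
      row.names = FALSE)
cat("  competition Kd' sits ~2 orders of magnitude above the equilibrium\n")
cat("  Kd for the strong binders (rebinding is blocked by the competitor);\n")
cat("  the equilibrium-consistent natural k_off is ~0.03-0.05 /s.\n")
utils::write.csv(summ, "results/kinetic_summary.csv", row.names = FALSE)
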