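#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth.
#
# Emulates the raw material of a helix-dynamics study: per-residue TEDOR
# buildup curves, 15N spinlock / inversion-recovery decay series, a helix
# structure with {S_CaHa, R1, R1rho} observables generated from known 3D
# GAF parameters, a rocking trajectory, and water z-paths with a scheduled
# number of membrane crossings. Everything downstream (02-05) reads only
# these files.

suppressMessages(library(gafdyn))
seed <- 0L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cat("== simulate: seed", seed, "==\n")

## TEDOR buildups for 5 residues with different one-bond couplings
d1_true <- c(920, 950, 985, 1010, 940)
for (i in seq_along(d1_true)) {
  cv <- gen_tedor_curve(D1 = d1_true[i], D2 = 150, gamma = 15,
                        noise = 0.05, seed = seed + i)
  utils::write.table(cv, sprintf("results/data/tedor_res%02d.tsv", i),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}
jsonlite::write_json(list(D1 = d1_true, D2 = 150, gamma = 15, noise = 0.05),
                     "results/data/tedor_truth.json", auto_unbox = TRUE)
cat("wrote", length(d1_true), "TEDOR curves (D1 =",
    paste(d1_true, collapse = ", "), "Hz)\n")

## relaxation decay series for 5 residues, with rates generated from
## per-residue simple model-free truths so stage 3 can invert them back
cfg <- spectrometer_config()
s2_true <- c(0.96, 0.94, 0.95, 0.93, 0.955)
tau_true <- c(40, 55, 60, 75, 85) * 1e-9
r1_true <- r1rho_true <- numeric(length(s2_true))
for (i in seq_along(s2_true)) {
  r1_true[i] <- r1_model(s2_true[i], tau_true[i], cfg)
  r1rho_true[i] <- r1rho_model(s2_true[i], tau_true[i], cfg)
}
for (i in seq_along(r1rho_true)) {
  sl <- gen_decay_curve(r1rho_true[i], M0 = 10, mode = "spinlock",
                        noise = 0.02, seed = seed + 100 + i)
  ir <- gen_decay_curve(r1_true[i], M0 = 10, mode = "inversion_recovery",
                        noise = 0.02, seed = seed + 200 + i)
  utils::write.table(sl, sprintf("results/data/spinlock_res%02d.tsv", i),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(ir, sprintf("results/data/recovery_res%02d.tsv", i),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}
jsonlite::write_json(list(R1rho = r1rho_true, R1 = r1_true,
                          S2 = s2_true, tau_c_ns = tau_true * 1e9,
                          noise = 0.02),
                     "results/data/rates_truth.json", auto_unbox = TRUE)
cat("wrote", length(r1rho_true), "spinlock and recovery series\n")

## GAF helix: structure + measurement table from known collective motion
gen <- gen_gaf_helix(n_res = 20, truth = gaf_params(c(8, 12, 6), 60e-9),
                     seed = seed)
write_structure_pdb(gen$structure, "results/data/helix.pdb")
write_measurement_table(gen$table, "results/data/helix_observables.tsv")
jsonlite::write_json(list(sigma_deg = c(8, 12, 6), tau_c_ns = 60,
                          delta_deg = c(0, 0), noise_s = 0.02,
                          noise_r = 0.05),
                     "results/data/gaf_truth.json", auto_unbox = TRUE)
cat("wrote helix.pdb + observables for 20 residues",
    "(truth sigma = 8, 12, 6 deg; tau_c = 60 ns)\n")

## rocking trajectory (Ca only) for the collective-motion observables
rock <- gen_rocking_trajectory(n_res = 20, rock_sd_deg = 10,
                               tau_corr_ns = 50, dt_ns = 1, n_frames = 5000,
                               atom_noise = 0.5, seed = seed)
write_trajectory_pdb(rock, "results/data/rocking.pdb")
jsonlite::write_json(attr(rock, "truth"), "results/data/rocking_truth.json",
                     auto_unbox = TRUE)
cat("wrote 5000-frame rocking trajectory (10 deg RMS, 50 ns)\n")

## water z-paths: 12 scheduled crossings plus same-side excursions in 100 ns
set.seed(seed)
types <- c(rep("up", 9), rep("down", 3), rep("bounce_lo", 4),
           rep("bounce_hi", 2))
sch <- data.frame(molecule = seq_along(types),
                  t_start_ns = round(seq(4, 88, length.out = length(types))),
                  duration_ns = 6, type = types)
z <- gen_water_paths(sch, total_ns = 100, dt_ns = 0.1)
utils::write.table(round(z, 4), "results/data/water_z.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
jsonlite::write_json(attr(z, "truth")["n_crossings"],
                     "results/data/water_truth.json", auto_unbox = TRUE)
cat("wrote water z-paths:", attr(z, "truth")$n_crossings,
    "scheduled crossings in 100 ns\n")
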