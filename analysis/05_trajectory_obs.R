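#!/usr/bin/env Rscript
# Stage 5: trajectory observables of collective motion and water transfer.
#
# Dynamic cross-correlation at short vs long windows (collectivity emerges
# only when the window exceeds the rocking correlation time), helix
# orientation fluctuation, water permeation counting, and hydrogen-bond
# occupancy on a constructed binding fixture.

suppressMessages(library(gafdyn))

cat("== trajectory observables ==\n")
rock <- read_trajectory("results/data/rocking.pdb", dt_ns = 1)

D_short <- dcc_matrix(rock, window_ns = 2)      # << 50 ns correlation time
D_long <- dcc_matrix(rock, window_ns = 2500)    # >> correlation time
utils::write.table(round(unclass(D_long), 4), "results/dcc_long_window.tsv",
                   sep = "\t", quote = FALSE)
utils::write.table(round(unclass(D_short), 4), "results/dcc_short_window.tsv",
                   sep = "\t", quote = FALSE)
cat(sprintf("DCC mean off-diagonal: %.2f (2-ns windows) vs %.2f (2500-ns windows)\n",
            mean(D_short[upper.tri(D_short)], na.rm = TRUE),
            mean(D_long[upper.tri(D_long)], na.rm = TRUE)))

ang <- helix_angle_series(rock, c(1, 20))
utils::write.table(data.frame(frame = seq_along(ang), angle_deg = round(ang, 3)),
                   "results/helix_angles.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat(sprintf("helix tilt RMS %.1f deg (generator: 10 deg), max %.1f deg\n",
            attr(ang, "rms_deg"), max(ang)))

z <- as.matrix(utils::read.table("results/data/water_z.tsv", header = TRUE,
                                 sep = "\t"))
pr <- count_permeations(z, -15, 15, dt_ns = 0.1)
truth <- jsonlite::read_json("results/data/water_truth.json",
                             simplifyVector = TRUE)
cat(sprintf("permeation: %d events counted (%d scheduled), %.1f per 100 ns\n",
            pr$events, truth$n_crossings, pr$rate_per_100ns))
jsonlite::write_json(list(events = pr$events, scheduled = truth$n_crossings,
                          rate_per_100ns = pr$rate_per_100ns,
                          event_times_ns = pr$event_times,
                          directions = pr$directions),
                     "results/permeation.json", auto_unbox = TRUE, digits = 4)

# hydrogen bonds: donor with 3 partners binding in disjoint thirds of 90 ns
nf <- 900
donor <- matrix(rep(c(0, 0, 0), each = nf), nf)
hyd <- matrix(rep(c(1, 0, 0), each = nf), nf)
acc <- array(NA_real_, c(nf, 3, 3))
for (p in 1:3) { acc[, p, 1] <- 0; acc[, p, 2] <- 9; acc[, p, 3] <- 0 }
for (p in 1:3) {
  w <- ((p - 1) * 300 + 1):(p * 300)
  acc[w, p, 1] <- 2.5; acc[w, p, 2] <- 0
}
hb <- hb_occupancy(donor, hyd, acc, dt_ns = 0.1)
cat(sprintf("hydrogen bonds: occupancy %.2f, %d distinct partners, %.3f partners/ns\n",
            hb$occupancy, hb$n_partners, hb$frequency_per_ns))
utils::write.table(
  data.frame(partner = 1:3, occupancy = hb$per_partner),
  "results/hb_report.tsv", sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote results/dcc_*.tsv, helix_angles.tsv, permeation.json, hb_report.tsv\n")
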