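#!/usr/bin/env Rscript
# Camera calibration: recover the EMCCD gain and offset from the simulated
# multi-level series via the I*dt = 2G*SNR^2 + offset line, and calibrate
# the changepoint LLR threshold tables (four-channel for orientation
# transitions, single-channel for bleach detection).

library(polstates)

out <- "results/02_calibrate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

calib <- read.csv("results/01_simulate/calibration_series.csv")
fit <- fit_gain_offset(calib)
cat(sprintf("Camera fit: G = %.1f (true 146), offset = %.1f (true 220).\n",
            fit$G, fit$offset))
write.csv(data.frame(G = fit$G, offset = fit$offset),
          file.path(out, "camera_fit.csv"), row.names = FALSE)

cp4 <- calibrate_threshold_table(snr = 7, n_sim = 2000, seed = 11)
cp1 <- calibrate_threshold_table(snr = 7, n_sim = 2000, seed = 12, h = 1)
write.csv(cp4$threshold_table, file.path(out, "thresholds_4ch.csv"),
          row.names = FALSE)
write.csv(cp1$threshold_table, file.path(out, "thresholds_1ch.csv"),
          row.names = FALSE)
cat(sprintf("LLR threshold at 720 frames (4 channels, 5%% FP): %.1f\n",
            polstates:::threshold_for_length(cp4, 720)))
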