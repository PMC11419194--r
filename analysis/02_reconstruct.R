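#!/usr/bin/env Rscript
# Reconstruct subject 1 from the exported raw data: noise covariance from
# the signal-free tail, pre-whitening, AUC-based sensitivity maps,
# matched-filter combination.  Reports the key reconstruction diagnostics.

suppressPackageStartupMessages(library(hp13c))

raw <- read_study("scratch/study-phantom-01")
stopifnot(length(raw$channels) == 3L)

ncov <- estimate_noise_covariance(raw$channels$pyruvate, n_last_frames = 5)
white <- lapply(raw$channels, prewhiten, nc = ncov)
sens <- estimate_sensitivity(white$pyruvate)
combined <- lapply(white, combine_channels, s = sens)

off_diag <- ncov$matrix; diag(off_diag) <- 0
summary <- data.frame(
  n_channels = nrow(ncov$matrix),
  noise_window_frames = length(ncov$source_window),
  mean_channel_variance = mean(Re(diag(ncov$matrix))),
  max_offdiag_correlation = max(Mod(off_diag)) / mean(Re(diag(ncov$matrix))),
  support_mask_voxels = sum(sens$support_mask),
  combined_frames = dim(combined$pyruvate$data)[3]
)
utils::write.csv(summary, "results/recon_summary.csv", row.names = FALSE)
cat("Reconstruction diagnostics (results/recon_summary.csv):\n")
print(summary)
cat(sprintf("\nSensitivity support covers %d voxels; channel noise correlation up to %.2f\n",
            summary$support_mask_voxels, summary$max_offdiag_correlation))
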