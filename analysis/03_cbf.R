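#!/usr/bin/env Rscript
# Ciliary beat frequency by FFT on synthetic beating-cilia recordings.
#
# Three ROIs per condition are simulated at each condition's generating
# median frequency (100 fps, 1024 frames, SNR 5 — the recording geometry
# of a high-speed CBF acquisition), estimated with the 1-20 Hz band, and
# summarized as group medians. Recovery of the generating frequency to
# within one spectral bin validates the estimator.

suppressPackageStartupMessages(library(aliprint))
dir.create("results", showWarnings = FALSE)

conditions <- data.frame(group = c("30-pass", "40-pass", "50-pass", "manual"),
                         f0 = c(6.34, 8.34, 8.83, 8.17))

rows <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
  f <- vapply(1:3, function(r) {
    g <- gen_cilia_trace(f0 = conditions$f0[i], frame_rate = 100,
                         n_frames = 1024, snr = 5, seed = 100 * i + r)
    cbf_fft(g$trace, band = c(1, 20))$frequency
  }, numeric(1))
  data.frame(group = conditions$group[i], roi = 1:3,
             true_f0 = conditions$f0[i], cbf_hz = f)
}))
print(rows)

summ <- summarize_cbf(rows$cbf_hz, rows$group)
summ$true_f0 <- conditions$f0[match(summ$group, conditions$group)]
summ$abs_error <- abs(summ$median - summ$true_f0)
cat("\nGroup medians:\n")
print(summ)
stopifnot(all(summ$abs_error < 0.1))

write.csv(rows, "results/cbf_estimates.csv", row.names = FALSE)
write.csv(summ, "results/cbf_group_medians.csv", row.names = FALSE)
cat("\nWrote results/cbf_estimates.csv, results/cbf_group_medians.csv\n")
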