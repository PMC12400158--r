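#!/usr/bin/env Rscript
# Generate the synthetic study material: 18 batches (9 Henan, 9 Hubei)
# of dried mugwort leaf with region-dependent contents planted at the
# seven marker compounds, the corresponding HPLC-UV chromatograms,
# calibration series for the eight quantified compounds, and MS2
# spectra of every rule-library compound. Everything downstream (02-05)
# reads from results/.

library(herbqc)
seed <- 0
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

sim <- simulate_batch_set(seed = seed)
write_peak_table(sim$table, "results/simulated/peak_table_true.csv")
write.csv(sim$truth, "results/simulated/ground_truth.csv", row.names = FALSE)
cat(sprintf("simulated %d batches x %d common peaks (seed %d)\n",
            length(sim$table$batch_ids), length(sim$table$peak_ids), seed))

tmpl <- chrom_template()
dir.create("results/simulated/chromatograms", showWarnings = FALSE)
for (b in sim$table$batch_ids) {
  ch <- simulate_chromatogram(sim$truth[sim$truth$batch == b, ], tmpl)
  write_chromatogram(ch,
                     file.path("results/simulated/chromatograms",
                               paste0(b, ".csv")))
}
cat(sprintf("wrote %d chromatograms (reference peak at %.1f min, sigma %.2f min)\n",
            length(sim$table$batch_ids),
            tmpl$retention_times[match("11", tmpl$peak_ids)],
            tmpl$peak_width_sigma))

info <- default_peak_info()
quant <- info$compound[info$peak_id %in% c("11", "1", "2", "3", "4", "8",
                                           "15", "17")]
cal_rows <- list()
for (cmp in quant) {
  cal <- simulate_calibration(cmp, noise_cv = 0, seed = seed)
  cal_rows[[cmp]] <- data.frame(compound = cmp, cal)
}
write.csv(do.call(rbind, cal_rows), "results/simulated/calibration.csv",
          row.names = FALSE)
cat(sprintf("wrote 7-level calibration series for %d compounds\n",
            length(quant)))

spectra <- lapply(names(default_fragment_rules()), simulate_ms2,
                  polarity = "negative", abundance_noise_cv = 0,
                  seed = seed)
write_mgf(spectra, "results/simulated/spectra.mgf")
cat(sprintf("wrote %d negative-mode MS2 spectra to spectra.mgf\n",
            length(spectra)))
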