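#!/usr/bin/env Rscript
# Calibration model building and optimization.
#
# Reads the simulated calibration data from results/ (run 01 and 02
# first), scans 1-10 latent variables by venetian-blinds cross-validation
# for PCR and PLS, fits CLS with intercept, PCR, PLS and the per-analyte
# GA-PLS, and writes the fitted-model summaries and LV/GA traces.

library(duospec)

out <- "results"
spectra <- read_spectra(file.path(out, "calibration_spectra.csv"))
conc <- read_concentrations(file.path(out, "calibration_design.csv"))

scan_pls <- select_latent(spectra, conc, max_lv = 10, method = "pls")
scan_pcr <- select_latent(spectra, conc, max_lv = 10, method = "pcr")
cat("Latent-variable selection (venetian blinds, 5 splits, one-SE rule):\n")
cat("  PLS:", paste(scan_pls$analytes, "=", scan_pls$chosen,
                    collapse = ", "), "\n")
cat("  PCR:", paste(scan_pcr$analytes, "=", scan_pcr$chosen,
                    collapse = ", "), "\n")
write.csv(data.frame(lv = scan_pls$lv_grid, scan_pls$rmsecv),
          file.path(out, "lv_scan_pls.csv"), row.names = FALSE)
write.csv(data.frame(lv = scan_pcr$lv_grid, scan_pcr$rmsecv),
          file.path(out, "lv_scan_pcr.csv"), row.names = FALSE)

models <- list(
  CLS = fit_cls(spectra, conc, intercept = TRUE),
  PCR = fit_pcr(spectra, conc, n_latent = max(scan_pcr$chosen)),
  PLS = fit_pls(spectra, conc, n_latent = scan_pls$chosen),
  `GA-PLS` = fit_ga_pls(spectra, conc,
                        cfg = ga_config(population_size = 20,
                                        max_generations = 25),
                        seed = 20240904))

for (m in names(models)) print(models[[m]])
ga <- models$`GA-PLS`
for (a in names(ga$ga_per_analyte)) {
  g <- ga$ga_per_analyte[[a]]
  cat(sprintf("GA (%s): %.0f%% of wavelengths discarded after %d generations\n",
              a, 100 * g$reduction_fraction, g$generations_run))
}
write.csv(ga$ga$fitness_trace, file.path(out, "ga_trace.csv"),
          row.names = FALSE)

pred <- lapply(models, predict, spectra = spectra)
cat("Calibration RMSEC (ug/mL):\n")
for (m in names(models)) {
  r <- vapply(c("LCZ", "MLK"), function(a)
    core_stats(paired_outcomes(conc[[a]], pred[[m]][[a]]))$rmse, numeric(1))
  cat(sprintf("  %-7s LCZ %.4f  MLK %.4f\n", m, r[1], r[2]))
}
dir.create("scratch", showWarnings = FALSE)
saveRDS(models, file.path("scratch", "models.rds"))
cat("Models cached in scratch/models.rds\n")
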