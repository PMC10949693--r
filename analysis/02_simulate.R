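#!/usr/bin/env Rscript
# Synthetic UV-vis spectra for the designed mixtures.
#
# The measured montelukast/levocetirizine spectra are not public, so the
# study runs on a Beer-Lambert stand-in: sum-of-Gaussian pure-component
# profiles with strong overlap below 250 nm, additive Gaussian absorbance
# noise of 0.002 AU, acquisition over 200-400 nm at 1 nm and trimming to
# the 210-400 nm working range (191 points). Spectra CSVs go to results/.

library(duospec)

out <- "results"
dir.create(out, showWarnings = FALSE)

sc <- default_scenario()
cal_design <- brereton_design(low = c(10, 10), high = c(30, 30),
                              analytes = sc$analytes)
val_design <- lhs_design(n_strata = 13, low = c(10, 10), high = c(30, 30),
                         analytes = sc$analytes, seed = 20240901)

cal <- simulate_scenario(cal_design, sc, seed = 20240902)
val <- simulate_scenario(val_design, sc, seed = 20240903)

write_spectra(cal$spectra, file.path(out, "calibration_spectra.csv"))
write_spectra(val$spectra, file.path(out, "validation_spectra.csv"))

p1 <- pure_spectrum(sc$pures[[1]], sc$grid)
p2 <- pure_spectrum(sc$pures[[2]], sc$grid)
cosine <- sum(p1 * p2) / sqrt(sum(p1^2) * sum(p2^2))
cat("Scenario:", paste(sc$analytes, collapse = " + "),
    sprintf("| pure-spectrum cosine overlap %.2f\n", cosine))
cat(sprintf("Calibration matrix: %d x %d (%g-%g nm), peak absorbances %.2f-%.2f AU\n",
            nrow(cal$spectra$absorbance), ncol(cal$spectra$absorbance),
            cal$spectra$grid$start_nm, cal$spectra$grid$end_nm,
            min(apply(cal$spectra$absorbance, 1, max)),
            max(apply(cal$spectra$absorbance, 1, max))))
cat("Noise: additive Gaussian,", sc$sigma_abs, "AU\n")
cat("Wrote calibration_spectra.csv and validation_spectra.csv\n")
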