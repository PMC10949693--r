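#!/usr/bin/env Rscript
# Quantitative sustainability assessment of the spectrophotometric method.
#
# The scoring inputs below are illustrative for a direct UV-vis method
# with aqueous solvent and no derivatization: a low-power benchtop
# spectrophotometer, high throughput, minimal reagents. They demonstrate
# the calculators; they are not the original assessment's (unpublished)
# worksheet.

library(duospec)

out <- "results"
dir.create(out, showWarnings = FALSE)

# Carbon footprint: spectrophotometer + sonicator share per sample.
usages <- list(
  list(power_kw = 0.08, hours = 0.05, emission_factor = 0.5),   # UV-vis scan
  list(power_kw = 0.35, hours = 0.01, emission_factor = 0.5))   # extraction
cf <- carbon_footprint(usages)
cat(sprintf("Carbon footprint: %.4f kg CO2 eq per sample\n", cf))

# BAGI blueness: ten practicality criteria scored 1-10.
bagi_criteria <- c(
  analysis_type = 10, n_analytes = 10, instrumentation = 10,
  throughput = 9, sample_prep = 8, samples_per_hour = 9,
  reagents = 10, preconcentration = 10, automation = 7, sample_amount = 8)
bagi <- bagi_score(bagi_criteria)
cat(sprintf("BAGI blueness score: %.1f / 100\n", bagi))

# RGB12 whiteness: red = validation, green = environment, blue = economy.
rgb <- rgb12_whiteness(red = c(85, 95, 90, 95),
                       green = c(95, 95, 90, 95),
                       blue = c(95, 90, 95, 90))
cat(sprintf("RGB12: red %.1f, green %.1f, blue %.1f -> whiteness %.1f\n",
            rgb$red, rgb$green, rgb$blue, rgb$whiteness))

jsonlite::write_json(
  list(carbon_kg_co2_per_sample = cf,
       bagi = list(criteria = as.list(bagi_criteria), score = bagi),
       rgb12 = rgb),
  file.path(out, "sustainability.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("Wrote", file.path(out, "sustainability.json"), "\n")
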