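#!/usr/bin/env Rscript
# External validation and full figures of merit.
#
# Predicts the 13-mixture LHS validation set with the four fitted models
# (run 03 first), assembles the complete merit report per model and
# analyte (RMSEC/RMSECV/RMSEP, R2, Q2, SEC, RRMSEP, BCMSEP, LOD, LOQ,
# recoveries), runs the triplicate precision study at 15/20/25 ug/mL, the
# spiked standard-addition check, and the one-way ANOVA comparing the
# models' validation recoveries.

library(duospec)

out <- "results"
sc <- default_scenario()
models <- readRDS(file.path("scratch", "models.rds"))
cal_sp <- read_spectra(file.path(out, "calibration_spectra.csv"))
cal_c <- read_concentrations(file.path(out, "calibration_design.csv"))
val_sp <- read_spectra(file.path(out, "validation_spectra.csv"))
val_c <- read_concentrations(file.path(out, "validation_design.csv"))

rows <- list(); recoveries <- list()
for (m in names(models)) {
  pc <- predict(models[[m]], cal_sp)
  pv <- predict(models[[m]], val_sp)
  cvp <- duospec:::cv_predictions(models[[m]], cal_sp, cal_c,
                                  "venetian_blinds", 5)
  prec <- duospec:::precision_study(models[[m]], sc, c(15, 20, 25),
                                    seed = 20240905)
  for (a in c("LCZ", "MLK")) {
    rep <- merit_report(
      calibration = paired_outcomes(cal_c[[a]], pc[[a]], "calibration"),
      cv = paired_outcomes(cal_c[[a]], cvp[[a]], "cross_validation"),
      prediction = paired_outcomes(val_c[[a]], pv[[a]], "prediction"),
      recovery_found = pv[[a]], recovery_nominal = val_c[[a]])
    recoveries[[m]] <- c(recoveries[[m]], 100 * pv[[a]] / val_c[[a]])
    rows[[paste(m, a)]] <- data.frame(
      model = m, analyte = a,
      rmsec = rep$rmsec, r2 = rep$r2, sec = rep$sec, rmsecv = rep$rmsecv,
      q2 = rep$q2, rmsep = rep$rmsep, rrmsep_pct = rep$rrmsep_pct,
      bcmsep = rep$bcmsep, lod = rep$lod, loq = rep$loq,
      mean_recovery_pct = rep$recovery$overall$mean_recovery_pct,
      max_rsd_pct = max(prec$per_level$rsd_pct[prec$per_level$analyte == a]))
  }
}
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write.csv(tab, file.path(out, "merit_table.csv"), row.names = FALSE)
print(tab, digits = 4)

cat(sprintf("\nAll models: min R2/Q2 = %.5f | max RMSEP = %.3f ug/mL | max RRMSEP = %.3f%% | max %%RSD = %.3f%%\n",
            min(tab$r2, tab$q2), max(tab$rmsep), max(tab$rrmsep_pct),
            max(tab$max_rsd_pct)))

aov_res <- anova_oneway(recoveries)
cat(sprintf("\nOne-way ANOVA of model recoveries: F = %.3f, critical F(0.05) = %.3f, p = %.3f\n",
            aov_res$f, aov_res$f_critical, aov_res$p))
cat(if (aov_res$f < aov_res$f_critical)
  "No significant difference between the models' recoveries.\n" else
  "Models differ significantly in recovery.\n")

sa <- standard_addition(base = c(LCZ = 10, MLK = 10),
                        additions = c(5, 10, 15), model = models$`GA-PLS`,
                        scenario = sc, seed = 20240906)
write.csv(sa, file.path(out, "standard_addition.csv"), row.names = FALSE)
cat(sprintf("\nStandard addition (GA-PLS): mean recovery %.2f%% (range %.2f-%.2f%%)\n",
            mean(sa$recovery_pct), min(sa$recovery_pct),
            max(sa$recovery_pct)))
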