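# End-to-end orchestration at desk scale: design -> simulate -> preprocess
# -> fit CLS/PCR/PLS/GA-PLS -> validate on the LHS set -> figures of merit,
# ANOVA across models and the sustainability block.

#' Default pipeline configuration
#'
#' Bundles every tunable of the full workflow. A single master seed is
#' expanded into independent per-stage seeds (design, calibration noise,
#' validation noise, GA, cross-validation) by fixed offsets, so one integer
#' reproduces the whole run.
#'
#' @param seed Master integer seed.
#' @param scenario Synthetic scenario, as \code{\link{default_scenario}}.
#' @param n_strata Validation strata / sample count.
#' @param max_lv Largest latent-variable count scanned for PCR/PLS.
#' @param cv_scheme,cv_splits Cross-validation used for latent-variable
#'   selection and Q2.
#' @param ga GA configuration for the GA-PLS stage; the default is a
#'   desk-scale configuration (population 20, 25 generations) with the
#'   reference mutation, window and convergence settings.
#' @param cls_window CLS smoothing window (\code{NULL}, width in nm, or
#'   \code{"auto"}).
#' @param precision_levels Concentrations (ug/mL) at which triplicate
#'   precision is simulated.
#' @param sustainability Optional list with \code{usages} (for
#'   \code{\link{carbon_footprint}}), \code{bagi} (ten criteria) and
#'   \code{rgb12} (red/green/blue score vectors).
#' @return A \code{run_config} list.
#' @export
run_config <- function(seed = 1, scenario = default_scenario(),
                       n_strata = 13, max_lv = 10,
                       cv_scheme = "venetian_blinds", cv_splits = 5,
                       ga = ga_config(population_size = 20,
                                      max_generations = 25),
                       cls_window = NULL,
                       precision_levels = c(15, 20, 25),
                       sustainability = NULL) {
  list(seed = as.integer(seed), scenario = scenario, n_strata = n_strata,
       max_lv = max_lv, cv_scheme = cv_scheme, cv_splits = cv_splits,
       ga = ga, cls_window = cls_window,
       precision_levels = precision_levels,
       sustainability = sustainability)
}

# Expand one master seed into independent stage seeds by scrambling through
# the RNG, so nearby master seeds share no stage seed.
stage_seeds <- function(seed) {
  pool <- withr_seed(seed, sample.int(.Machine$integer.max - 1L, 6))
  stats::setNames(as.list(pool),
                  c("design", "cal_noise", "val_noise", "ga", "cv",
                    "precision"))
}

#' Run the full desk-scale workflow
#'
#' Executes, in order: calibration design generation, LHS validation design,
#' synthetic spectrum simulation, trimming to the working range,
#' latent-variable selection, fitting of the four models (CLS with
#' intercept, PCR, PLS, GA-PLS), prediction of the validation set,
#' figures-of-merit reports per model and analyte, triplicate precision at
#' the configured levels, one-way ANOVA of the models' validation
#' recoveries, and the sustainability block when configured. Identical
#' configuration and seed give an identical report.
#'
#' @param cfg A \code{\link{run_config}}.
#' @param out_dir Optional directory; when given, the report JSON, merit
#'   CSV, designs, LV-scan and GA-trace tables are written there.
#' @return A \code{run_report} list: \code{models}, \code{merits} (one
#'   \code{merit_report} per model per analyte), \code{merit_table} (flat
#'   data frame), \code{lv_scan}, \code{ga}, \code{anova},
#'   \code{precision}, \code{sustainability}, \code{provenance}.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL) {
  seeds <- stage_seeds(cfg$seed)
  sc <- cfg$scenario
  cal_design <- brereton_design(low = c(10, 10), high = c(30, 30),
                                analytes = sc$analytes)
  val_design <- lhs_design(n_strata = cfg$n_strata, low = c(10, 10),
                           high = c(30, 30), analytes = sc$analytes,
                           seed = seeds$design)
  cal <- simulate_scenario(cal_design, sc, seed = seeds$cal_noise)
  val <- simulate_scenario(val_design, sc, seed = seeds$val_noise)

  scan_pls <- select_latent(cal$spectra, cal$concentrations,
                            max_lv = cfg$max_lv, method = "pls",
                            scheme = cfg$cv_scheme, n_splits = cfg$cv_splits,
                            seed = seeds$cv)
  scan_pcr <- select_latent(cal$spectra, cal$concentrations,
                            max_lv = cfg$max_lv, method = "pcr",
                            scheme = cfg$cv_scheme, n_splits = cfg$cv_splits,
                            seed = seeds$cv)

  models <- list(
    CLS = fit_cls(cal$spectra, cal$concentrations, intercept = TRUE,
                  window_nm = cfg$cls_window),
    PCR = fit_pcr(cal$spectra, cal$concentrations,
                  n_latent = max(scan_pcr$chosen)),
    PLS = fit_pls(cal$spectra, cal$concentrations,
                  n_latent = scan_pls$chosen),
    `GA-PLS` = fit_ga_pls(cal$spectra, cal$concentrations, cfg = cfg$ga,
                          seed = seeds$ga, scheme = cfg$cv_scheme,
                          n_splits = cfg$cv_splits))

  merits <- list(); rows <- list(); recoveries <- list()
  precision <- list()
  for (m in names(models)) {
    pred_cal <- predict(models[[m]], cal$spectra)
    pred_val <- predict(models[[m]], val$spectra)
    cvp <- cv_predictions(models[[m]], cal$spectra, cal$concentrations,
                          cfg$cv_scheme, cfg$cv_splits)
    prec <- precision_study(models[[m]], sc, cfg$precision_levels,
                            seed = seeds$precision)
    precision[[m]] <- prec
    for (a in sc$analytes) {
      rep <- merit_report(
        calibration = paired_outcomes(cal$concentrations[[a]], pred_cal[[a]],
                                      "calibration"),
        cv = paired_outcomes(cal$concentrations[[a]], cvp[[a]],
                             "cross_validation"),
        prediction = paired_outcomes(val$concentrations[[a]], pred_val[[a]],
                                     "prediction"),
        recovery_found = pred_val[[a]],
        recovery_nominal = val$concentrations[[a]])
      merits[[paste(m, a, sep = ".")]] <- rep
      recoveries[[m]] <- c(recoveries[[m]],
                           100 * pred_val[[a]] / val$concentrations[[a]])
      rows[[paste(m, a)]] <- data.frame(
        model = m, analyte = a, n_latent = lv_of(models[[m]], a),
        rmsec = rep$rmsec, r2 = rep$r2, sec = rep$sec,
        rmsecv = rep$rmsecv, q2 = rep$q2, rmsep = rep$rmsep,
        rrmsep_pct = rep$rrmsep_pct, bcmsep = rep$bcmsep,
        lod = rep$lod, loq = rep$loq,
        mean_recovery_pct = rep$recovery$overall$mean_recovery_pct,
        max_rsd_pct = max(prec$per_level$rsd_pct[prec$per_level$analyte == a]))
    }
  }
  merit_table <- do.call(rbind, rows)
  rownames(merit_table) <- NULL
  anova <- anova_oneway(recoveries)
  sust <- NULL
  if (!is.null(cfg$sustainability)) {
    s <- cfg$sustainability
    sust <- list()
    if (!is.null(s$usages)) sust$carbon_kg_co2 <- carbon_footprint(s$usages)
    if (!is.null(s$bagi)) sust$bagi <- bagi_score(s$bagi)
    if (!is.null(s$rgb12)) {
      sust$rgb12 <- rgb12_whiteness(s$rgb12$red, s$rgb12$green, s$rgb12$blue)
    }
  }
  report <- structure(list(
    models = models, merits = merits, merit_table = merit_table,
    lv_scan = list(pls = scan_pls, pcr = scan_pcr),
    ga = models$`GA-PLS`$ga, anova = anova, precision = precision,
    designs = list(calibration = cal_design, validation = val_design),
    sustainability = sust,
    provenance = list(seed = cfg$seed, stage_seeds = seeds,
                      n_strata = cfg$n_strata,
                      package_version = as.character(
                        utils::packageVersion("duospec")))),
    class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

lv_of <- function(model, analyte) {
  if (is.na(model$n_latent[1])) return(NA_integer_)
  if (length(model$n_latent) > 1) {
    model$n_latent[match(analyte, model$analytes)]
  } else model$n_latent
}

# Cross-validated predictions of the calibration set for an already-chosen
# model complexity (used for Q2/RMSECV reporting).
cv_predictions <- function(model, spectra, C, scheme, n_splits) {
  Cm <- conc_matrix(C)
  n <- nrow(Cm)
  folds <- cv_folds(n, scheme, n_splits)
  out <- matrix(NA_real_, n, ncol(Cm), dimnames = list(NULL, colnames(Cm)))
  wl_all <- grid_wavelengths(spectra$grid)
  masks <- if (!is.null(model$masks)) model$masks
           else wl_all %in% round(model$wavelengths, 8)
  for (f in unique(folds)) {
    tr <- folds != f
    sub <- spectral_matrix(spectra$absorbance[tr, , drop = FALSE],
                           spectra$grid, spectra$sample_ids[tr])
    Ctr <- Cm[tr, , drop = FALSE]
    fold_model <- switch(model$method,
      CLS = fit_cls(sub, Ctr, intercept = model$intercept,
                    window_nm = model$window_nm),
      PCR = fit_pcr(sub, Ctr, n_latent = model$n_latent),
      PLS = fit_pls(sub, Ctr, n_latent = model$n_latent),
      `GA-PLS` = fit_pls_masked(sub, Ctr, masks, model$n_latent))
    te <- spectral_matrix(spectra$absorbance[!tr, , drop = FALSE],
                          spectra$grid, spectra$sample_ids[!tr])
    pred <- predict(fold_model, te)
    out[!tr, ] <- as.matrix(pred[colnames(Cm)])
  }
  as.data.frame(out)
}

# Triplicate precision at fixed concentration levels: simulate three
# independent noisy replicates per level (same concentration for both
# analytes), predict, and report %RSD per level per analyte.
precision_study <- function(model, scenario, levels, seed, n_rep = 3) {
  conc <- data.frame(sample_id = paste0("p", seq_along(rep(levels, each = n_rep))))
  for (a in scenario$analytes) conc[[a]] <- rep(levels, each = n_rep)
  design <- structure(list(role = "validation", concentrations = conc,
                           analytes = scenario$analytes),
                      class = "mixture_design")
  sim <- simulate_scenario(design, scenario, seed = seed)
  pred <- predict(model, sim$spectra)
  rows <- list()
  for (a in scenario$analytes) {
    rec <- recovery_rsd(pred[[a]], conc[[a]], groups = conc[[a]])
    rows[[a]] <- cbind(analyte = a, rec$per_level)
  }
  per_level <- do.call(rbind, rows)
  rownames(per_level) <- NULL
  list(levels = levels, n_rep = n_rep, per_level = per_level)
}

#' Standard-addition recovery study
#'
#' Mirrors the spiked standard-addition accuracy check: a base sample is
#' measured, known amounts are added, and the recovery of each spike is
#' 100 (found_total - found_base) / added.
#'
#' @param base Named base concentrations (ug/mL) per analyte.
#' @param additions Spike levels (ug/mL), each applied to both analytes.
#' @param model A fitted \code{calibration_model}.
#' @param scenario Scenario used to simulate the spiked spectra.
#' @param n_rep Replicates per spike level.
#' @param seed Integer RNG seed.
#' @return Data frame with analyte, added level, replicate, found base and
#'   total, and recovery (\%); negative recoveries are flagged in an
#'   attribute.
#' @export
standard_addition <- function(base, additions, model,
                              scenario = default_scenario(), n_rep = 3,
                              seed) {
  if (any(additions <= 0)) stop("spike additions must be > 0")
  analytes <- scenario$analytes
  base <- base[analytes]
  lv <- rep(additions, each = n_rep)
  conc <- data.frame(sample_id = c("base", paste0("spk", seq_along(lv))))
  for (a in analytes) conc[[a]] <- c(base[[a]], base[[a]] + lv)
  design <- structure(list(role = "validation", concentrations = conc,
                           analytes = analytes), class = "mixture_design")
  sim <- simulate_scenario(design, scenario, seed = seed)
  pred <- predict(model, sim$spectra)
  rows <- list()
  for (a in analytes) {
    found_base <- pred[[a]][1]
    found_tot <- pred[[a]][-1]
    rows[[a]] <- data.frame(analyte = a, added = lv,
                            replicate = rep(seq_len(n_rep),
                                            times = length(additions)),
                            found_base = found_base, found_total = found_tot,
                            recovery_pct = 100 * (found_tot - found_base) / lv)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  neg <- stats::aggregate(recovery_pct ~ analyte + added, out,
                          function(r) all(r < 0))
  attr(out, "negative_recovery_flag") <- any(neg$recovery_pct)
  out
}

#' Write a run report to disk
#'
#' @param report A \code{run_report}.
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$merit_table,
                   file.path(out_dir, "merit_table.csv"), row.names = FALSE)
  write_design(report$designs$calibration,
               file.path(out_dir, "calibration_design.csv"))
  write_design(report$designs$validation,
               file.path(out_dir, "validation_design.csv"))
  for (nm in names(report$lv_scan)) {
    sc <- report$lv_scan[[nm]]
    utils::write.csv(data.frame(lv = sc$lv_grid, sc$rmsecv),
                     file.path(out_dir, paste0("lv_scan_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(report$ga$fitness_trace,
                   file.path(out_dir, "ga_trace.csv"), row.names = FALSE)
  json <- list(merit_table = report$merit_table,
               chosen_lv = lapply(report$lv_scan, `[[`, "chosen"),
               ga = list(reduction_fraction = report$ga$reduction_fraction,
                         generations_run = report$ga$generations_run),
               anova = report$anova[c("f", "p", "f_critical")],
               sustainability = report$sustainability,
               provenance = report$provenance)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$merit_table[c("model", "analyte", "n_latent", "rmsec", "r2",
                        "q2", "rmsep", "rrmsep_pct")])
  invisible(x)
}
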