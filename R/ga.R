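# Genetic-algorithm wavelength selection feeding a refined PLS model
# (GA-PLS). Chromosomes switch contiguous windows of wavelengths on or off;
# fitness is the cross-validated RMSECV of a PLS model restricted to the
# active wavelengths.

#' Genetic-algorithm configuration
#'
#' Parameters of the wavelength-selection GA. The reference configuration
#' used for the montelukast channel of the published optimization is
#' population 40, 65 generations, mutation rate 0.005, 15\% of windows
#' active at initialization, window width 2 variables, 80\% convergence
#' threshold, double (two-point) crossover, at most 3 latent variables, and
#' random-subset cross-validation with 5 subsets and 2 iterations per
#' generation (\code{ga_config_reference()}); the levocetirizine channel
#' differs only in population 36 and 52 generations.
#'
#' @param population_size Number of chromosomes (>= 4).
#' @param max_generations Generation cap.
#' @param mutation_rate Per-gene mutation probability in (0, 1).
#' @param init_fraction Expected fraction of windows active in each initial
#'   chromosome, in (0, 1].
#' @param window_width Wavelengths per window gene (>= 1); the grid is tiled
#'   by non-overlapping contiguous windows, a trailing remainder forming a
#'   narrower window.
#' @param convergence_fraction Stop early when at least this fraction of the
#'   population is identical to the current best chromosome.
#' @param crossover \code{"double"} (two-point, default) or
#'   \code{"single"}.
#' @param max_latent Largest latent-variable count used inside the fitness
#'   evaluation.
#' @param cv_subsets Number of random cross-validation subsets.
#' @param cv_iterations Random-split repetitions per generation (fresh
#'   splits each generation, averaged).
#' @return A \code{ga_config} list.
#' @export
ga_config <- function(population_size = 40, max_generations = 65,
                      mutation_rate = 0.005, init_fraction = 0.15,
                      window_width = 2, convergence_fraction = 0.8,
                      crossover = c("double", "single"), max_latent = 3,
                      cv_subsets = 5, cv_iterations = 2) {
  crossover <- match.arg(crossover)
  if (population_size < 4) stop("population_size must be >= 4")
  if (mutation_rate <= 0 || mutation_rate >= 1) {
    stop("mutation_rate must be in (0, 1)")
  }
  if (init_fraction <= 0 || init_fraction > 1) {
    stop("init_fraction must be in (0, 1]")
  }
  if (window_width < 1) stop("window_width must be >= 1")
  if (convergence_fraction <= 0 || convergence_fraction > 1) {
    stop("convergence_fraction must be in (0, 1]")
  }
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 mutation_rate = mutation_rate,
                 init_fraction = init_fraction,
                 window_width = as.integer(window_width),
                 convergence_fraction = convergence_fraction,
                 crossover = crossover, max_latent = as.integer(max_latent),
                 cv_subsets = as.integer(cv_subsets),
                 cv_iterations = as.integer(cv_iterations)),
            class = "ga_config")
}

#' @rdname ga_config
#' @param analyte \code{1} for the montelukast column of the reference
#'   optimization, \code{2} for levocetirizine.
#' @export
ga_config_reference <- function(analyte = 1) {
  if (analyte == 1) ga_config(population_size = 40, max_generations = 65)
  else ga_config(population_size = 36, max_generations = 52)
}

# Tile p wavelengths into contiguous windows of cfg width; returns the
# window index of each wavelength.
window_map <- function(p, width) {
  rep(seq_len(ceiling(p / width)), each = width, length.out = p)
}

#' Run the genetic-algorithm wavelength selection
#'
#' Chromosomes encode the on/off state of contiguous wavelength windows.
#' Fitness of a chromosome is the mean RMSECV of a PLS model (best count up
#' to \code{max_latent} latent variables) on the active wavelengths, under
#' random-subset cross-validation with fresh splits each generation.
#' Parents are drawn with probability proportional to fitness rank (lower
#' RMSECV, better rank); offspring undergo single- or two-point crossover
#' and per-gene mutation. One elite chromosome survives unchanged each
#' generation, which makes the best-fitness trace non-increasing. The run
#' stops at \code{max_generations} or as soon as the convergence fraction
#' of the population equals the best chromosome. All randomness derives
#' from \code{seed}, so a fixed seed reproduces the mask exactly.
#'
#' @param spectra Calibration \code{\link{spectral_matrix}}.
#' @param C Concentration table; in per-analyte mode only the
#'   \code{analyte} column drives the fitness.
#' @param cfg A \code{\link{ga_config}}.
#' @param analyte Analyte name or index the fitness targets; \code{NULL}
#'   averages the RMSECV over all analytes (joint fitness).
#' @param seed Integer RNG seed (required).
#' @return A \code{ga_result}: \code{selected_mask} (logical per
#'   wavelength), \code{selected_wavelengths}, \code{fitness_trace} (best
#'   and median RMSECV per generation), \code{generations_run},
#'   \code{reduction_fraction} (fraction of wavelengths discarded) and
#'   \code{config}.
#' @export
run_ga <- function(spectra, C, cfg = ga_config(), analyte = NULL, seed) {
  stopifnot(inherits(spectra, "spectral_matrix"), inherits(cfg, "ga_config"))
  if (missing(seed)) stop("seed must be supplied")
  Cm <- conc_matrix(C)
  if (nrow(Cm) != nrow(spectra$absorbance)) {
    stop("spectra and concentrations are not row-aligned")
  }
  targets <- if (is.null(analyte)) seq_len(ncol(Cm)) else analyte
  if (is.character(targets)) targets <- match(targets, colnames(Cm))
  if (anyNA(targets)) stop("unknown analyte")
  A <- spectra$absorbance
  p <- ncol(A)
  wmap <- window_map(p, cfg$window_width)
  ng <- max(wmap)
  withr_seed(seed, {
    pop <- matrix(stats::runif(cfg$population_size * ng) < cfg$init_fraction,
                  cfg$population_size, ng)
    pop <- t(apply(pop, 1, repair_chromosome))
    best_trace <- med_trace <- numeric(0)
    best_chrom <- NULL; best_fit <- Inf
    gen <- 0L
    repeat {
      gen <- gen + 1L
      fit <- apply(pop, 1, ga_fitness, A = A, Cm = Cm, targets = targets,
                   wmap = wmap, cfg = cfg)
      # elitism: carry the best-ever chromosome, so the trace cannot rise
      if (min(fit) < best_fit) {
        best_fit <- min(fit)
        best_chrom <- pop[which.min(fit), ]
      }
      best_trace <- c(best_trace, best_fit)
      med_trace <- c(med_trace, stats::median(fit))
      share <- mean(apply(pop, 1, identical, y = best_chrom))
      if (gen >= cfg$max_generations || share >= cfg$convergence_fraction) {
        break
      }
      # rank-proportionate selection: lower RMSECV gets higher weight
      w <- rank(-fit, ties.method = "first")
      prob <- w / sum(w)
      newpop <- matrix(FALSE, cfg$population_size, ng)
      newpop[1, ] <- best_chrom
      i <- 2L
      while (i <= cfg$population_size) {
        par <- sample.int(cfg$population_size, 2, prob = prob)
        kids <- ga_crossover(pop[par[1], ], pop[par[2], ], cfg$crossover)
        for (kid in kids) {
          if (i > cfg$population_size) break
          flip <- stats::runif(ng) < cfg$mutation_rate
          kid[flip] <- !kid[flip]
          newpop[i, ] <- repair_chromosome(kid)
          i <- i + 1L
        }
      }
      pop <- newpop
    }
    mask <- best_chrom[wmap]
    structure(list(selected_mask = mask,
                   selected_wavelengths = grid_wavelengths(spectra$grid)[mask],
                   fitness_trace = data.frame(generation = seq_len(gen),
                                              best = best_trace,
                                              median = med_trace),
                   generations_run = gen,
                   reduction_fraction = 1 - mean(mask),
                   best_rmsecv = best_fit,
                   config = cfg, analytes = colnames(Cm)[targets]),
              class = "ga_result")
  })
}

repair_chromosome <- function(chrom) {
  if (!any(chrom)) chrom[sample.int(length(chrom), 1)] <- TRUE
  chrom
}

ga_crossover <- function(a, b, type) {
  ng <- length(a)
  if (ng < 3) return(list(a, b))
  if (type == "single") {
    cut <- sample.int(ng - 1L, 1)
    list(c(a[1:cut], b[(cut + 1):ng]), c(b[1:cut], a[(cut + 1):ng]))
  } else {
    cuts <- sort(sample.int(ng - 1L, 2))
    mid <- (cuts[1] + 1):cuts[2]
    k1 <- a; k1[mid] <- b[mid]
    k2 <- b; k2[mid] <- a[mid]
    list(k1, k2)
  }
}

# Mean cross-validated RMSECV of a PLS model on the chromosome's active
# wavelengths (best LV count up to cfg$max_latent), averaged over the
# target analytes and cv_iterations fresh random splits.
ga_fitness <- function(chrom, A, Cm, targets, wmap, cfg) {
  cols <- chrom[wmap]
  Asub <- A[, cols, drop = FALSE]
  n <- nrow(Asub)
  max_lv <- min(cfg$max_latent, ncol(Asub), n - ceiling(n / cfg$cv_subsets) - 1L)
  max_lv <- max(max_lv, 1L)
  total <- 0
  for (it in seq_len(cfg$cv_iterations)) {
    folds <- sample(((seq_len(n) - 1L) %% cfg$cv_subsets) + 1L)
    for (j in targets) {
      sq <- cv_sqerr_path(Asub, Cm[, j], folds, max_lv, method = "pls")
      total <- total + min(sqrt(colMeans(sq)))
    }
  }
  total / (cfg$cv_iterations * length(targets))
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(paste0("<ga_result> %d/%d wavelengths kept (%.0f%% reduction)",
                     " after %d generations, best RMSECV %.4g\n"),
              sum(x$selected_mask), length(x$selected_mask),
              100 * x$reduction_fraction, x$generations_run, x$best_rmsecv))
  invisible(x)
}

#' Fit a GA-PLS model
#'
#' Runs the genetic-algorithm wavelength selection once per analyte (each
#' analyte's fitness is its own cross-validated error, mirroring the
#' per-analyte GA optimizations), restricts the spectra to each analyte's
#' mask, re-runs cross-validated latent-variable selection (capped at the
#' GA's \code{max_latent}) and fits the per-analyte PLS models on their
#' selected wavelengths. With \code{per_analyte = FALSE} a single GA run
#' with joint fitness (mean RMSECV over analytes) supplies one shared mask.
#'
#' @inheritParams run_ga
#' @param scheme,n_splits Cross-validation used for the final
#'   latent-variable selection.
#' @param per_analyte Run one GA per analyte (default) or one joint GA.
#' @return A \code{calibration_model} with \code{method = "GA-PLS"} on the
#'   union of the analyte masks; the per-analyte GA results are attached as
#'   \code{$ga} (first analyte's result, for the joint trace) and
#'   \code{$ga_per_analyte}, the per-analyte masks as \code{$masks}, and
#'   the latent-variable scans as \code{$lv_scan}.
#' @export
fit_ga_pls <- function(spectra, C, cfg = ga_config(), seed,
                       scheme = "venetian_blinds", n_splits = 5,
                       per_analyte = TRUE) {
  Cm <- conc_matrix(C)
  analytes <- colnames(Cm)
  if (per_analyte) {
    gas <- lapply(seq_along(analytes), function(j) {
      run_ga(spectra, C, cfg, analyte = analytes[j],
             seed = seed + 1000L * (j - 1L))
    })
  } else {
    gas <- rep(list(run_ga(spectra, C, cfg, analyte = NULL, seed = seed)),
               length(analytes))
  }
  masks <- lapply(gas, `[[`, "selected_mask")
  names(masks) <- analytes
  scans <- lapply(seq_along(analytes), function(j) {
    sub <- subset_spectra(spectra, masks[[j]])
    sel <- select_latent(sub, C[c("sample_id", analytes[j])],
                         max_lv = cfg$max_latent, method = "pls",
                         scheme = scheme, n_splits = n_splits, seed = seed)
    sel
  })
  chosen <- vapply(scans, function(s) s$chosen[1], integer(1))
  model <- fit_pls_masked(spectra, C, masks, chosen)
  model$method <- "GA-PLS"
  model$ga <- gas[[1]]
  model$ga_per_analyte <- stats::setNames(gas, analytes)
  model$lv_scan <- list(
    lv_grid = scans[[1]]$lv_grid,
    rmsecv = vapply(scans, function(s) s$rmsecv[, 1], scans[[1]]$rmsecv[, 1]),
    se_min = vapply(scans, function(s) s$se_min[1], numeric(1)),
    chosen = chosen, analytes = analytes)
  colnames(model$lv_scan$rmsecv) <- analytes
  names(model$lv_scan$se_min) <- analytes
  model
}

# A spectral_matrix restricted to a (possibly non-contiguous) wavelength
# mask. The grid object is kept for provenance; downstream model fitting
# only touches $absorbance.
subset_spectra <- function(spectra, mask) {
  structure(list(absorbance = spectra$absorbance[, mask, drop = FALSE],
                 grid = spectra$grid, sample_ids = spectra$sample_ids,
                 wavelengths = grid_wavelengths(spectra$grid)[mask]),
            class = c("spectral_subset", "spectral_matrix"))
}

# PLS1 fits restricted to per-analyte wavelength masks, embedded in a
# coefficient matrix over the union of the masks so prediction is a single
# linear map; masks may also be a single shared logical vector.
fit_pls_masked <- function(spectra, C, masks, n_latent) {
  Cm <- conc_matrix(C)
  analytes <- colnames(Cm)
  if (is.logical(masks)) masks <- rep(list(masks), length(analytes))
  masks <- rep_len(masks, length(analytes))
  n_latent <- rep_len(as.integer(n_latent), length(analytes))
  union_mask <- Reduce(`|`, masks)
  wl <- grid_wavelengths(spectra$grid)[union_mask]
  A_union <- spectra$absorbance[, union_mask, drop = FALSE]
  x_mean <- colMeans(A_union)
  y_mean <- colMeans(Cm)
  B <- matrix(0, sum(union_mask), length(analytes),
              dimnames = list(NULL, analytes))
  for (j in seq_along(analytes)) {
    keep <- masks[[j]][union_mask]
    Aj <- A_union[, keep, drop = FALSE]
    Xc <- sweep(Aj, 2, colMeans(Aj))
    kj <- min(n_latent[j], ncol(Aj), nrow(Aj) - 1L)
    B[keep, j] <- pls1_coef_path(Xc, Cm[, j] - y_mean[j], kj)[, kj]
  }
  new_calibration_model(
    "PLS", coefficients = B,
    intercepts = y_mean - drop(x_mean %*% B),
    wavelengths = wl, analytes = analytes, n_latent = n_latent,
    extra = list(x_mean = x_mean, masks = masks))
}
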