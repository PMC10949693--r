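#' Gaussian absorption band and pure-component model
#'
#' Pure-component UV absorptivity profiles are represented as sums of
#' Gaussian bands: \code{amplitude * exp(-(lambda - center)^2 / (2 width^2))}
#' in AU per ug/mL. These stand in for measured molar-absorptivity spectra
#' and let the generator place overlapping bands deliberately.
#'
#' @param center_nm Band center (nm).
#' @param width_nm Gaussian sigma (nm), > 0.
#' @param amplitude Peak absorptivity (AU per ug/mL), >= 0.
#' @return \code{gaussian_band} returns a band record;
#'   \code{pure_component_model} bundles one or more bands under an analyte
#'   name.
#' @export
gaussian_band <- function(center_nm, width_nm, amplitude) {
  if (width_nm <= 0) stop("width_nm must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(center_nm = center_nm, width_nm = width_nm,
                 amplitude = amplitude), class = "gaussian_band")
}

#' @rdname gaussian_band
#' @param analyte Analyte name.
#' @param bands List of \code{gaussian_band} objects (at least one).
#' @export
pure_component_model <- function(analyte, bands) {
  if (inherits(bands, "gaussian_band")) bands <- list(bands)
  if (length(bands) < 1) stop("at least one band is required")
  stopifnot(all(vapply(bands, inherits, logical(1), "gaussian_band")))
  structure(list(analyte = analyte, bands = bands),
            class = "pure_component_model")
}

#' Evaluate a pure-component spectrum on a grid
#'
#' @param model A \code{\link{pure_component_model}}.
#' @param grid A \code{\link{wavelength_grid}}.
#' @return Numeric vector of unit-concentration absorptivities (AU per
#'   ug/mL), one per grid point; non-negative by construction.
#' @export
pure_spectrum <- function(model, grid) {
  stopifnot(inherits(model, "pure_component_model"))
  wl <- grid_wavelengths(grid)
  s <- numeric(length(wl))
  for (b in model$bands) {
    s <- s + b$amplitude * exp(-(wl - b$center_nm)^2 / (2 * b$width_nm^2))
  }
  s
}

#' Simulate Beer-Lambert mixture spectra
#'
#' Each mixture spectrum is the concentration-weighted sum of the pure
#' component spectra (Beer-Lambert linear mixing) plus an optional constant
#' per-sample baseline offset and additive homoscedastic Gaussian absorbance
#' noise:
#' \deqn{a_i(\lambda) = \sum_k c_{ik}\, s_k(\lambda) + b_i +
#'       \epsilon_{i\lambda}, \quad \epsilon \sim N(0, \sigma^2).}
#'
#' @param design A \code{mixture_design} whose analytes match \code{pures}.
#' @param pures List of two \code{\link{pure_component_model}}s.
#' @param grid A \code{\link{wavelength_grid}}.
#' @param sigma_abs Noise standard deviation (AU), >= 0.
#' @param baseline_sd If > 0, each sample receives a constant offset drawn
#'   from N(0, baseline_sd^2) AU; default 0 (no baseline).
#' @param seed Integer RNG seed (required when \code{sigma_abs > 0} or
#'   \code{baseline_sd > 0}).
#' @return A \code{\link{spectral_matrix}}, one row per design mixture.
#' @export
simulate_mixtures <- function(design, pures, grid, sigma_abs = 0.002,
                              baseline_sd = 0, seed = NULL) {
  stopifnot(inherits(design, "mixture_design"))
  if (sigma_abs < 0) stop("sigma_abs must be >= 0")
  pure_names <- vapply(pures, `[[`, character(1), "analyte")
  if (!setequal(pure_names, design$analytes)) {
    stop("pure-component analytes do not match the design analytes")
  }
  pures <- pures[match(design$analytes, pure_names)]
  C <- as.matrix(design$concentrations[design$analytes])
  if (any(C < 0)) stop("negative concentrations in the design")
  S <- vapply(pures, pure_spectrum, numeric(grid_points(grid)), grid = grid)
  A <- C %*% t(S)
  if (sigma_abs > 0 || baseline_sd > 0) {
    if (is.null(seed)) stop("seed must be supplied for stochastic simulation")
    noise <- withr_seed(seed, {
      b <- if (baseline_sd > 0) stats::rnorm(nrow(A), 0, baseline_sd) else
        numeric(nrow(A))
      e <- if (sigma_abs > 0) {
        matrix(stats::rnorm(length(A), 0, sigma_abs), nrow(A), ncol(A))
      } else matrix(0, nrow(A), ncol(A))
      list(b = b, e = e)
    })
    A <- A + noise$b + noise$e
  }
  spectral_matrix(A, grid, sample_ids = design$concentrations$sample_id)
}

#' Default two-drug simulation scenario
#'
#' A deterministic stand-in for the montelukast (MLK) / levocetirizine (LCZ)
#' system: both analytes absorb strongly and overlap below ~250 nm and MLK
#' carries an additional resolved band in the high 200s nm. Over the
#' standard 25-mixture calibration design (10--30 ug/mL) the noiseless
#' mixture spectra peak between roughly 0.45 and 1.34 AU, and the two pure
#' spectra have cosine overlap about 0.68 on the 210--400 nm working grid.
#' Band positions and absorptivities are fixed package constants; no claim
#' of spectral realism for the real drugs is made.
#'
#' @return A list with \code{grid} (200--400 nm at 1 nm, the acquisition
#'   grid), \code{working_range} (c(210, 400), the modeling window),
#'   \code{analytes}, \code{pures}, \code{sigma_abs} (0.002 AU) and
#'   \code{baseline_sd} (0).
#' @export
default_scenario <- function() {
  list(
    grid = wavelength_grid(200, 400, 1),
    working_range = c(210, 400),
    analytes = c("LCZ", "MLK"),
    pures = list(
      pure_component_model("LCZ", list(gaussian_band(231, 11, 0.026))),
      pure_component_model("MLK", list(gaussian_band(222, 12, 0.022),
                                       gaussian_band(285, 14, 0.016)))
    ),
    sigma_abs = 0.002,
    baseline_sd = 0
  )
}

#' Simulate a complete calibration or validation data set
#'
#' Convenience wrapper: simulates a design under a scenario on the
#' acquisition grid and trims to the working range.
#'
#' @param design A \code{mixture_design}.
#' @param scenario A scenario list as from \code{\link{default_scenario}}.
#' @param seed Integer RNG seed.
#' @return A list with \code{spectra} (trimmed \code{spectral_matrix}) and
#'   \code{concentrations} (the design's concentration table).
#' @export
simulate_scenario <- function(design, scenario = default_scenario(), seed) {
  sp <- simulate_mixtures(design, scenario$pures, scenario$grid,
                          sigma_abs = scenario$sigma_abs,
                          baseline_sd = scenario$baseline_sd, seed = seed)
  sp <- trim_spectra(sp, scenario$working_range[1], scenario$working_range[2])
  list(spectra = sp, concentrations = design$concentrations)
}
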