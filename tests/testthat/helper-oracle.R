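# Brute-force loop re-implementations of the merit statistics, used as
# independent oracles, plus the printed design fixtures.

oracle_stats <- function(y, yh) {
  n <- length(y)
  rss <- 0; for (i in seq_len(n)) rss <- rss + (y[i] - yh[i])^2
  ybar <- sum(y) / n
  ssx <- 0; for (i in seq_len(n)) ssx <- ssx + (y[i] - ybar)^2
  bias <- 0; for (i in seq_len(n)) bias <- bias + (y[i] - yh[i]) / n
  sec <- 0; for (i in seq_len(n)) sec <- sec + (y[i] - yh[i] - bias)^2
  list(rss = rss, ssx = ssx, r2 = 1 - rss / ssx, rmse = sqrt(rss / n),
       bias = bias, sec = sqrt(sec / (n - 1)),
       rrmsep = (1 / n) * sqrt(rss) / ybar * 100,
       bcmsep = rss / n - bias^2)
}

oracle_anova <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - gm)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  df1 <- length(groups) - 1
  df2 <- length(all) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

oracle_boxcar <- function(x, w) {
  half <- (w - 1) / 2
  out <- numeric(length(x))
  for (j in seq_along(x)) {
    lo <- max(1, j - half); hi <- min(length(x), j + half)
    out[j] <- mean(x[lo:hi])
  }
  out
}

# The printed 25-run calibration block: mix number, first analyte (LCZ),
# second analyte (MLK), ug/mL.
table1_calibration <- function() {
  m <- matrix(c(
    20, 20,  20, 10,  10, 10,  10, 30,  30, 15,
    15, 30,  30, 20,  20, 15,  15, 15,  15, 25,
    25, 30,  30, 25,  25, 20,  20, 30,  30, 30,
    30, 10,  10, 25,  25, 10,  10, 20,  20, 25,
    25, 25,  25, 15,  15, 10,  10, 15,  15, 20), ncol = 2, byrow = TRUE)
  colnames(m) <- c("LCZ", "MLK")
  m
}

# The printed 13-mixture LHS validation block (fixture only: its seed is
# unknown, so it cannot be regenerated).
table1_validation <- function() {
  m <- matrix(c(
    19, 16,  22, 27,  13, 12,  22, 13,  18, 26,
    11, 22,  16, 29,  17, 21,  27, 11,  27, 24,
    13, 27,  29, 19,  23, 21), ncol = 2, byrow = TRUE)
  colnames(m) <- c("LCZ", "MLK")
  m
}

# Simple spectral fixtures built in code.
toy_spectra <- function(values, start = 200, step = 1) {
  values <- as.matrix(values)
  spectral_matrix(values,
                  wavelength_grid(start, start + (ncol(values) - 1) * step,
                                  step))
}

# GA stress scenario: analyte signal confined to 240-300 nm, out-of-band
# channels carrying empty-detector noise (0.05 AU vs 0.002 AU in-band).
ga_stress_data <- function(seed) {
  grid <- wavelength_grid(210, 400, 1)
  wl <- grid_wavelengths(grid)
  pures <- list(
    pure_component_model("A", list(gaussian_band(255, 8, 0.025))),
    pure_component_model("B", list(gaussian_band(275, 8, 0.025))))
  d <- brereton_design(analytes = c("A", "B"))
  sp <- simulate_mixtures(d, pures, grid, sigma_abs = 0.002, seed = seed)
  inside <- wl >= 240 & wl <= 300
  A <- sp$absorbance
  set.seed(seed + 7)
  noise <- matrix(stats::rnorm(length(A), 0, 0.05), nrow(A), ncol(A))
  noise[, inside] <- 0
  list(spectra = spectral_matrix(A + noise, grid, sp$sample_ids),
       concentrations = d$concentrations, inside = inside)
}
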