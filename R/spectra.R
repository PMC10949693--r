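#' Wavelength grid
#'
#' A closed, uniformly spaced wavelength axis. Both endpoints are included,
#' so a 210--400 nm grid at 1 nm resolution has 191 points.
#'
#' @param start_nm First wavelength (nm).
#' @param end_nm Last wavelength (nm); must exceed \code{start_nm}.
#' @param step_nm Increment (nm); the span must be an integer multiple of it.
#' @return An object of class \code{wavelength_grid}.
#' @examples
#' g <- wavelength_grid(210, 400, 1)
#' grid_points(g)   # 191
#' @export
wavelength_grid <- function(start_nm, end_nm, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm))
  if (!(start_nm < end_nm)) stop("start_nm must be < end_nm")
  if (step_nm <= 0) stop("step_nm must be > 0")
  k <- (end_nm - start_nm) / step_nm
  if (abs(k - round(k)) > 1e-8) {
    stop("grid span (", end_nm - start_nm,
         " nm) is not an integer multiple of step_nm (", step_nm, " nm)")
  }
  structure(list(start_nm = start_nm, end_nm = end_nm, step_nm = step_nm),
            class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @param grid A \code{wavelength_grid}.
#' @export
grid_points <- function(grid) {
  as.integer(round((grid$end_nm - grid$start_nm) / grid$step_nm)) + 1L
}

#' @rdname wavelength_grid
#' @export
grid_wavelengths <- function(grid) {
  seq(grid$start_nm, grid$end_nm, by = grid$step_nm)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start_nm, x$end_nm, x$step_nm, grid_points(x)))
  invisible(x)
}

#' Spectral matrix
#'
#' Sample-by-wavelength absorbance block (AU) bound to a uniform wavelength
#' grid. Rows are samples, columns are wavelengths.
#'
#' @param absorbance Numeric matrix of absorbances (AU), samples in rows.
#' @param grid A \code{\link{wavelength_grid}} whose point count matches
#'   \code{ncol(absorbance)}.
#' @param sample_ids Character vector of row labels; defaults to the
#'   rownames of \code{absorbance} or \code{"s1"..."sn"}.
#' @return An object of class \code{spectral_matrix}.
#' @export
spectral_matrix <- function(absorbance, grid, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (!inherits(grid, "wavelength_grid")) stop("grid must be a wavelength_grid")
  if (ncol(absorbance) != grid_points(grid)) {
    stop("absorbance has ", ncol(absorbance), " columns but the grid has ",
         grid_points(grid), " points")
  }
  if (!all(is.finite(absorbance))) stop("absorbance contains non-finite values")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(absorbance)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(absorbance)))
  }
  if (length(sample_ids) != nrow(absorbance)) {
    stop("sample_ids length does not match the number of rows")
  }
  dimnames(absorbance) <- list(sample_ids, format_wl(grid_wavelengths(grid)))
  structure(list(absorbance = absorbance, grid = grid,
                 sample_ids = as.character(sample_ids)),
            class = "spectral_matrix")
}

format_wl <- function(wl) format(wl, trim = TRUE, scientific = FALSE)

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("<spectral_matrix> %d samples x %d wavelengths (%g-%g nm)\n",
              nrow(x$absorbance), ncol(x$absorbance),
              x$grid$start_nm, x$grid$end_nm))
  invisible(x)
}

#' @export
dim.spectral_matrix <- function(x) dim(x$absorbance)

#' Read and write wide-format spectra CSV
#'
#' The on-disk dialect is a wide CSV with header
#' \code{wavelength_nm,<sample_id_1>,...} and one row per wavelength. The
#' wavelength column must be strictly increasing and uniformly spaced.
#'
#' @param path Path to a CSV file.
#' @return \code{read_spectra} returns a \code{\link{spectral_matrix}};
#'   \code{write_spectra} returns \code{path} invisibly.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("spectra CSV needs a wavelength column plus samples")
  wl <- df[[1]]
  if (!is.numeric(wl)) stop("wavelength column is not numeric in ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric absorbance values in column '", names(df)[-1][bad],
         "' of ", path)
  }
  steps <- diff(wl)
  if (any(steps <= 0)) {
    stop("wavelength column not strictly increasing at row ",
         which(steps <= 0)[1] + 1)
  }
  if (length(unique(round(steps, 8))) > 1) {
    bad <- which(abs(steps - steps[1]) > 1e-8)[1]
    stop("non-uniform wavelength grid at row ", bad + 1,
         " (step ", steps[bad], " nm, expected ", steps[1], " nm)")
  }
  grid <- wavelength_grid(wl[1], wl[length(wl)], steps[1])
  spectral_matrix(t(vals), grid, sample_ids = colnames(vals))
}

#' @rdname read_spectra
#' @param spectra A \code{\link{spectral_matrix}}.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectral_matrix"))
  df <- data.frame(wavelength_nm = grid_wavelengths(spectra$grid),
                   t(spectra$absorbance), check.names = FALSE)
  colnames(df) <- c("wavelength_nm", spectra$sample_ids)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trim a spectral matrix to a wavelength window
#'
#' Retains exactly the columns with \code{lo <= lambda <= hi}; both bounds
#' must sit on grid points. Trimming the standard 200--400 nm acquisition
#' range to the 210--400 nm working range leaves 191 points.
#'
#' @param spectra A \code{\link{spectral_matrix}}.
#' @param lo,hi Window bounds (nm), inclusive.
#' @return A \code{\link{spectral_matrix}} on the trimmed grid.
#' @export
trim_spectra <- function(spectra, lo, hi) {
  stopifnot(inherits(spectra, "spectral_matrix"))
  g <- spectra$grid
  if (lo >= hi) stop("lo must be < hi")
  if (lo < g$start_nm || hi > g$end_nm) {
    stop("trim window [", lo, ", ", hi, "] outside grid [",
         g$start_nm, ", ", g$end_nm, "]")
  }
  wl <- grid_wavelengths(g)
  on_grid <- function(x) min(abs(wl - x)) < 1e-8
  if (!on_grid(lo) || !on_grid(hi)) {
    near <- function(x) wl[order(abs(wl - x))[1:2]]
    stop("trim bounds must lie on grid points; nearest to (", lo, ", ", hi,
         ") are (", paste(near(lo), collapse = "/"), ") and (",
         paste(near(hi), collapse = "/"), ") nm")
  }
  keep <- wl >= lo - 1e-8 & wl <= hi + 1e-8
  spectral_matrix(spectra$absorbance[, keep, drop = FALSE],
                  wavelength_grid(lo, hi, g$step_nm),
                  sample_ids = spectra$sample_ids)
}

#' Mean-center a spectral matrix
#'
#' Removes the per-wavelength column mean and stores it so the same centering
#' can be applied to later samples (and inverted). Centering on a single
#' sample is rejected: the stored means would be the sample itself.
#'
#' @param spectra A \code{\link{spectral_matrix}} with at least two samples.
#' @return A list with elements \code{spectra} (centered matrix) and
#'   \code{state} (a \code{preprocess_state} holding the removed means).
#' @export
mean_center <- function(spectra) {
  stopifnot(inherits(spectra, "spectral_matrix"))
  if (nrow(spectra$absorbance) < 2) {
    stop("mean centering needs >= 2 samples")
  }
  mu <- colMeans(spectra$absorbance)
  centered <- sweep(spectra$absorbance, 2, mu)
  state <- structure(list(column_means = mu, grid = spectra$grid),
                     class = "preprocess_state")
  list(spectra = spectral_matrix(centered, spectra$grid, spectra$sample_ids),
       state = state)
}

#' @rdname mean_center
#' @param state A \code{preprocess_state} from \code{mean_center}.
#' @param reverse If \code{TRUE}, add the stored means back instead of
#'   removing them.
#' @export
apply_centering <- function(spectra, state, reverse = FALSE) {
  stopifnot(inherits(spectra, "spectral_matrix"),
            inherits(state, "preprocess_state"))
  if (ncol(spectra$absorbance) != length(state$column_means)) {
    stop("stored means do not match the wavelength count")
  }
  adj <- sweep(spectra$absorbance, 2, state$column_means,
               FUN = if (reverse) "+" else "-")
  spectral_matrix(adj, spectra$grid, spectra$sample_ids)
}

#' Moving-window (boxcar) smoothing
#'
#' Each point is replaced by the unweighted mean of an odd-width window
#' centered on it; near the spectrum edges the window is truncated to the
#' available points rather than padded, so no absorbance is invented
#' outside the grid.
#'
#' @param spectra A \code{\link{spectral_matrix}}.
#' @param window_nm Window width (nm); must be an odd multiple of the grid
#'   step.
#' @return A smoothed \code{\link{spectral_matrix}} on the same grid.
#' @export
moving_window_smooth <- function(spectra, window_nm) {
  stopifnot(inherits(spectra, "spectral_matrix"))
  step <- spectra$grid$step_nm
  w <- window_nm / step
  if (abs(w - round(w)) > 1e-8) {
    stop("window_nm must be a multiple of the grid step (", step, " nm)")
  }
  w <- as.integer(round(w))
  if (w < 1 || w %% 2L == 0L) {
    stop("window must be an odd number of grid steps; nearest odd widths are ",
         (w - 1) * step, " and ", (w + 1) * step, " nm")
  }
  half <- (w - 1L) %/% 2L
  A <- spectra$absorbance
  p <- ncol(A)
  out <- A
  if (half > 0L) {
    cs <- cbind(0, t(apply(A, 1, cumsum)))
    for (j in seq_len(p)) {
      lo <- max(1L, j - half)
      hi <- min(p, j + half)
      out[, j] <- (cs[, hi + 1L] - cs[, lo]) / (hi - lo + 1L)
    }
  }
  spectral_matrix(out, spectra$grid, spectra$sample_ids)
}
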