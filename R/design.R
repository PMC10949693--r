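# Canonical coded sequence of the five-level, two-analyte cyclic
# (Brereton-style) calibration design. The second analyte's code at run i is
# the first analyte's code at run i + 1 (cyclically), which makes the two
# coded columns balanced (each level 5x), zero-sum and mutually orthogonal.
.brereton5_codes <- c(0, 0, -2, -2, 2, -1, 2, 0, -1, -1, 1, 2, 1,
                      0, 2, 2, -2, 1, -2, 0, 1, 1, -1, -2, -1)

#' Five-level cyclic calibration design for two analytes
#'
#' Generates the 25-run multilevel calibration design in which each analyte
#' takes five equally spaced coded levels (-2, -1, 0, +1, +2), every level
#' occurs exactly five times per analyte, and the two coded columns are
#' orthogonal. Codes map to concentrations by
#' \code{c = center + code * step} with \code{center = (low + high)/2} and
#' \code{step = (high - low)/4}. Over a 10--30 ug/mL range for both analytes
#' the first run is the (20, 20) center point.
#'
#' @param low,high Numeric length-2 vectors of per-analyte concentration
#'   bounds (ug/mL). Scalars are recycled.
#' @param analytes Character length-2 analyte names.
#' @param n_levels Number of levels; only 5 is supported.
#' @return A \code{mixture_design} with \code{role = "calibration"}:
#'   a list holding \code{concentrations} (25 x 2 data frame, ug/mL),
#'   \code{coded} (25 x 2 integer level codes) and \code{analytes}.
#' @examples
#' d <- brereton_design(low = 10, high = 30)
#' head(d$concentrations)
#' @export
brereton_design <- function(low = c(10, 10), high = c(30, 30),
                            analytes = c("analyte1", "analyte2"),
                            n_levels = 5) {
  if (!identical(as.integer(n_levels), 5L)) {
    stop("unsupported design: only the five-level two-analyte cyclic design ",
         "is implemented")
  }
  if (length(analytes) != 2) {
    stop("unsupported design: exactly two analytes are supported")
  }
  low <- rep_len(as.numeric(low), 2)
  high <- rep_len(as.numeric(high), 2)
  if (any(low >= high)) stop("degenerate range: low must be < high per analyte")
  c1 <- .brereton5_codes
  c2 <- c(c1[-1], c1[1])
  coded <- cbind(c1, c2)
  colnames(coded) <- analytes
  center <- (low + high) / 2
  step <- (high - low) / (n_levels - 1)
  conc <- sweep(sweep(coded, 2, step, `*`), 2, center, `+`)
  conc <- as.data.frame(conc)
  conc <- cbind(sample_id = paste0("cal", seq_len(nrow(conc))), conc)
  structure(list(role = "calibration", concentrations = conc,
                 coded = as.data.frame(coded), analytes = analytes,
                 low = low, high = high, n_levels = 5L),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("<mixture_design> %s set: %d mixtures of %s\n",
              x$role, nrow(x$concentrations),
              paste(x$analytes, collapse = " + ")))
  invisible(x)
}

#' Latin hypercube validation design
#'
#' Stratified Latin hypercube sampling over a two-analyte concentration
#' space: each analyte's range is divided into \code{n_strata} equal-width
#' strata and exactly one sample is drawn uniformly from each stratum, with
#' the stratum order permuted independently per analyte. A prime stratum
#' count (such as the default 13) avoids periodic resonance between the two
#' analytes' stratifications and is recommended, though not enforced.
#'
#' Rounding the sampled concentrations is a lossy post-step (off by
#' default): it can collapse distinct samples onto equal values, which is
#' recorded as a warning in the design metadata rather than silently
#' accepted.
#'
#' @param n_strata Number of strata (>= 2), which is also the sample count.
#' @param low,high Per-analyte concentration bounds (ug/mL); scalars recycle.
#' @param analytes Character length-2 analyte names.
#' @param seed Integer RNG seed; required for reproducibility.
#' @param round_to Decimal places to round concentrations to, or \code{NULL}
#'   (default) for no rounding.
#' @return A \code{mixture_design} with \code{role = "validation"} holding
#'   \code{concentrations} (pre-rounding values kept in
#'   \code{concentrations_raw} when rounding is requested) and
#'   \code{strata} (per-analyte stratum index of each sample).
#' @export
lhs_design <- function(n_strata = 13, low = c(10, 10), high = c(30, 30),
                       analytes = c("analyte1", "analyte2"),
                       seed, round_to = NULL) {
  if (n_strata < 2) stop("n_strata must be >= 2")
  if (missing(seed)) stop("seed must be supplied for a reproducible design")
  low <- rep_len(as.numeric(low), 2)
  high <- rep_len(as.numeric(high), 2)
  if (any(high - low <= 0)) stop("stratum width must be positive")
  n_strata <- as.integer(n_strata)
  u <- withr_seed(seed, lhs::randomLHS(n_strata, 2L))
  conc_raw <- sweep(sweep(u, 2, high - low, `*`), 2, low, `+`)
  colnames(conc_raw) <- analytes
  strata <- apply(u, 2, function(x) as.integer(ceiling(x * n_strata)))
  colnames(strata) <- analytes
  conc <- conc_raw
  warn <- character(0)
  if (!is.null(round_to)) {
    conc <- round(conc_raw, round_to)
    for (a in analytes) {
      if (anyDuplicated(conc[, a])) {
        warn <- c(warn, paste0("rounding collapsed samples of ", a,
                               " onto equal values"))
      }
    }
  }
  conc <- as.data.frame(conc)
  conc <- cbind(sample_id = paste0("val", seq_len(nrow(conc))), conc)
  out <- structure(list(role = "validation", concentrations = conc,
                        strata = as.data.frame(strata), analytes = analytes,
                        low = low, high = high, n_strata = n_strata,
                        seed = as.integer(seed), warnings = warn),
                   class = "mixture_design")
  if (!is.null(round_to)) {
    out$concentrations_raw <- as.data.frame(conc_raw)
    for (w in warn) warning(w, call. = FALSE)
  }
  out
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Design coverage diagnostics
#'
#' Reports how well a design covers the concentration space: the Pearson
#' correlation of the coded calibration columns (zero for the canonical
#' cyclic design), the per-analyte stratum occupancy histogram for
#' validation designs, and the minimum pairwise Euclidean distance between
#' mixtures.
#'
#' @param design A \code{\link{brereton_design}} or \code{\link{lhs_design}}
#'   result.
#' @return A list with \code{coded_correlation} (calibration only),
#'   \code{stratum_occupancy} (validation only), \code{min_pair_distance}
#'   and \code{flags}.
#' @export
coverage_diagnostics <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  conc <- as.matrix(design$concentrations[design$analytes])
  if (nrow(conc) == 0) stop("design is empty")
  flags <- character(0)
  out <- list()
  if (design$role == "calibration") {
    coded <- as.matrix(design$coded)
    if (stats::sd(coded[, 1]) == 0 || stats::sd(coded[, 2]) == 0) {
      out$coded_correlation <- NaN
      flags <- c(flags, "degenerate coded column: correlation undefined")
    } else {
      out$coded_correlation <- stats::cor(coded[, 1], coded[, 2])
    }
  }
  if (design$role == "validation") {
    occ <- lapply(design$analytes, function(a) {
      tabulate(design$strata[[a]], nbins = design$n_strata)
    })
    names(occ) <- design$analytes
    out$stratum_occupancy <- occ
  }
  if (nrow(conc) < 2) {
    out$min_pair_distance <- NA_real_
    flags <- c(flags, "single-sample design: pairwise distance undefined")
  } else {
    out$min_pair_distance <- min(stats::dist(conc))
  }
  out$flags <- flags
  out
}

#' Concentration-table CSV I/O
#'
#' Writes or reads the concentrations dialect used throughout the workflow:
#' header \code{sample_id,<analyte_1>,<analyte_2>}, one row per mixture.
#' For calibration designs the coded levels are written to a sidecar file
#' \code{<path>_coded.csv}.
#'
#' @param design A \code{mixture_design}.
#' @param path Output CSV path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "mixture_design"))
  utils::write.csv(design$concentrations, path, row.names = FALSE,
                   quote = FALSE)
  if (design$role == "calibration") {
    side <- sub("\\.csv$", "", path)
    utils::write.csv(cbind(sample_id = design$concentrations$sample_id,
                           design$coded),
                     paste0(side, "_coded.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_design
#' @return \code{read_concentrations} returns a data frame with a
#'   \code{sample_id} column followed by one numeric column per analyte.
#' @export
read_concentrations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("concentrations CSV must start with a sample_id column")
  }
  for (j in seq_len(ncol(df))[-1]) {
    if (!is.numeric(df[[j]])) stop("non-numeric concentration column: ",
                                   names(df)[j])
  }
  df
}
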