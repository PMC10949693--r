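# Multivariate calibration models: CLS with intercept, PCR, PLS (NIPALS,
# PLS1 per analyte by default), plus cross-validated selection of the number
# of latent variables and of the CLS smoothing window.

conc_matrix <- function(C, analytes = NULL) {
  if (is.data.frame(C) && "sample_id" %in% names(C)) {
    C <- C[setdiff(names(C), "sample_id")]
  }
  C <- as.matrix(C)
  if (!is.null(analytes)) C <- C[, analytes, drop = FALSE]
  storage.mode(C) <- "double"
  C
}

new_calibration_model <- function(method, coefficients, intercepts,
                                  wavelengths, analytes, n_latent = NA_integer_,
                                  extra = list()) {
  structure(c(list(method = method, coefficients = coefficients,
                   intercepts = intercepts, wavelengths = wavelengths,
                   analytes = analytes, n_latent = n_latent), extra),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s: %d analytes on %d wavelengths%s\n",
              x$method, length(x$analytes), length(x$wavelengths),
              if (!is.na(x$n_latent[1]))
                paste0(", ", paste(x$n_latent, collapse = "/"), " LV") else ""))
  invisible(x)
}

#' Classical least squares calibration with intercept
#'
#' First stage: estimate the pure-component absorptivity profiles S (and,
#' when \code{intercept = TRUE}, a wavelength-wise offset row) by least
#' squares from the bilinear model \code{A = C S}. Second stage (at
#' prediction): regress each new spectrum on the estimated profiles, with a
#' free per-sample offset when the intercept is on, and read the
#' concentrations off the regression coefficients. The intercept absorbs
#' constant baseline shifts and subtle background effects that otherwise
#' bias plain CLS.
#'
#' A moving-window smoothing step may be applied before fitting:
#' \code{window_nm} may be a fixed odd width, \code{"auto"} to scan odd
#' widths of 5--29 nm by venetian-blinds cross-validation and keep the
#' RMSECV-minimizing width, or \code{NULL} for no smoothing.
#'
#' @param spectra Calibration \code{\link{spectral_matrix}}.
#' @param C Concentration table (data frame with \code{sample_id} plus one
#'   column per analyte, or a plain matrix), row-aligned with
#'   \code{spectra}.
#' @param intercept Include the offset row (default \code{TRUE}).
#' @param window_nm Smoothing window: \code{NULL}, an odd width in nm, or
#'   \code{"auto"}.
#' @return A \code{calibration_model} with \code{method = "CLS"}.
#' @export
fit_cls <- function(spectra, C, intercept = TRUE, window_nm = NULL) {
  stopifnot(inherits(spectra, "spectral_matrix"))
  Cm <- conc_matrix(C)
  analytes <- colnames(Cm)
  n <- nrow(spectra$absorbance)
  if (nrow(Cm) != n) stop("spectra and concentrations are not row-aligned")
  if (n < ncol(Cm) + 1) stop("need at least n_analytes + 1 samples")
  if (qr(Cm)$rank < ncol(Cm)) {
    stop("rank-deficient concentration table: collinear analytes (",
         paste(analytes, collapse = ", "), ")")
  }
  if (identical(window_nm, "auto")) {
    widths <- seq(5, 29, by = 2) * spectra$grid$step_nm
    cv_err <- vapply(widths, function(w) {
      sm <- moving_window_smooth(spectra, w)
      mean(cls_cv_rmse(sm, Cm, intercept))
    }, numeric(1))
    window_nm <- widths[which.min(cv_err)]
  }
  sp_fit <- if (!is.null(window_nm)) moving_window_smooth(spectra, window_nm)
            else spectra
  X <- if (intercept) cbind(`(offset)` = 1, Cm) else Cm
  S <- solve(crossprod(X), crossprod(X, sp_fit$absorbance))
  profiles <- S[colnames(Cm), , drop = FALSE]
  if (any(apply(profiles, 1, function(r) all(abs(r) < 1e-12)))) {
    stop("degenerate (all-zero) estimated pure profile")
  }
  new_calibration_model(
    "CLS", coefficients = t(profiles),
    intercepts = stats::setNames(rep(0, length(analytes)), analytes),
    wavelengths = grid_wavelengths(sp_fit$grid), analytes = analytes,
    extra = list(pure_profiles = S, intercept = intercept,
                 window_nm = window_nm, grid = sp_fit$grid))
}

# Venetian-blinds RMSECV of a CLS model, one value per analyte.
cls_cv_rmse <- function(spectra, Cm, intercept, n_splits = 5) {
  n <- nrow(Cm)
  folds <- ((seq_len(n) - 1L) %% n_splits) + 1L
  sq <- matrix(NA_real_, n, ncol(Cm))
  for (f in seq_len(n_splits)) {
    tr <- folds != f
    X <- if (intercept) cbind(1, Cm[tr, , drop = FALSE]) else
      Cm[tr, , drop = FALSE]
    S <- solve(crossprod(X), crossprod(X, spectra$absorbance[tr, , drop = FALSE]))
    pred <- cls_invert(spectra$absorbance[!tr, , drop = FALSE], S, intercept,
                       ncol(Cm))
    sq[!tr, ] <- (pred - Cm[!tr, , drop = FALSE])^2
  }
  sqrt(colMeans(sq))
}

# Second-stage CLS least squares: subtract the estimated background
# spectrum, then regress each spectrum on the pure profiles plus a free
# per-sample constant (the intercept), which absorbs baseline shifts.
cls_invert <- function(A, S, intercept, k) {
  profiles <- S[(nrow(S) - k + 1):nrow(S), , drop = FALSE]
  if (intercept) {
    A <- sweep(A, 2, S[1, ])
    D <- cbind(1, t(profiles))                 # p x (1 + k) design
  } else {
    D <- t(profiles)
  }
  est <- solve(crossprod(D), crossprod(D, t(A)))
  t(est[(nrow(est) - k + 1):nrow(est), , drop = FALSE])
}

#' Principal component regression
#'
#' Mean-centers spectra and concentrations on the calibration set, takes
#' the top \code{n_latent} principal components of the centered spectra
#' (via SVD) and regresses the centered concentrations on the scores.
#' Prediction projects new (training-centered) spectra onto the loadings
#' and un-centers.
#'
#' @inheritParams fit_cls
#' @param n_latent Number of principal components to retain.
#' @return A \code{calibration_model} with \code{method = "PCR"}.
#' @export
fit_pcr <- function(spectra, C, n_latent) {
  stopifnot(inherits(spectra, "spectral_matrix"))
  Cm <- conc_matrix(C)
  A <- spectra$absorbance
  if (nrow(Cm) != nrow(A)) stop("spectra and concentrations are not row-aligned")
  n_latent <- as.integer(n_latent)
  x_mean <- colMeans(A); y_mean <- colMeans(Cm)
  Xc <- sweep(A, 2, x_mean); Yc <- sweep(Cm, 2, y_mean)
  sv <- svd(Xc)
  pos <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
  if (n_latent < 1 || n_latent > pos) {
    stop("n_latent = ", n_latent, " exceeds the rank (", pos,
         ") of the centered spectra")
  }
  idx <- seq_len(n_latent)
  # B = V_k D_k^{-1} U_k' Yc maps centered spectra to centered concentrations
  B <- sv$v[, idx, drop = FALSE] %*%
    (crossprod(sv$u[, idx, drop = FALSE], Yc) / sv$d[idx])
  new_calibration_model(
    "PCR", coefficients = B,
    intercepts = y_mean - drop(x_mean %*% B),
    wavelengths = grid_wavelengths(spectra$grid), analytes = colnames(Cm),
    n_latent = n_latent,
    extra = list(x_mean = x_mean, grid = spectra$grid))
}

# NIPALS PLS1 on centered data. Returns the p x max_lv matrix whose k-th
# column is the regression vector using the first k latent variables.
pls1_coef_path <- function(Xc, yc, max_lv) {
  p <- ncol(Xc)
  W <- P <- matrix(0, p, max_lv)
  q <- numeric(max_lv)
  Bpath <- matrix(0, p, max_lv)
  X <- Xc; y <- yc
  for (k in seq_len(max_lv)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {                # no covariance left: freeze remaining
      if (k > 1) for (j in k:max_lv) Bpath[, j] <- Bpath[, k - 1]
      break
    }
    w <- w / nw
    t <- X %*% w
    tt <- sum(t^2)
    pk <- crossprod(X, t) / tt
    qk <- sum(y * t) / tt
    W[, k] <- w; P[, k] <- pk; q[k] <- qk
    X <- X - tcrossprod(t, pk)
    y <- y - qk * t
    Wk <- W[, 1:k, drop = FALSE]
    Bpath[, k] <- Wk %*% solve(crossprod(P[, 1:k, drop = FALSE], Wk),
                               q[1:k])
  }
  Bpath
}

#' Partial least squares regression (NIPALS)
#'
#' Latent variables are extracted sequentially by the covariance criterion:
#' each weight vector maximizes the covariance between the spectral scores
#' and the (current, deflated) concentration residual, and the spectra are
#' deflated after each latent variable. By default PLS1 is run
#' independently per analyte; \code{mode = "pls2"} extracts joint latent
#' variables against the full concentration block.
#'
#' @inheritParams fit_pcr
#' @param n_latent Number of latent variables. A vector (one per analyte)
#'   is accepted in PLS1 mode.
#' @param mode \code{"pls1"} (default) or \code{"pls2"}.
#' @param max_iter,tol Iteration cap and convergence tolerance for the
#'   PLS2 inner loop.
#' @return A \code{calibration_model} with \code{method = "PLS"}.
#' @export
fit_pls <- function(spectra, C, n_latent, mode = c("pls1", "pls2"),
                    max_iter = 500, tol = 1e-10) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectra, "spectral_matrix"))
  Cm <- conc_matrix(C)
  A <- spectra$absorbance
  if (nrow(Cm) != nrow(A)) stop("spectra and concentrations are not row-aligned")
  x_mean <- colMeans(A); y_mean <- colMeans(Cm)
  Xc <- sweep(A, 2, x_mean); Yc <- sweep(Cm, 2, y_mean)
  rank_cap <- min(nrow(A) - 1L, ncol(A))
  n_latent <- as.integer(n_latent)
  if (any(n_latent < 1) || any(n_latent > rank_cap)) {
    stop("n_latent must be in 1..", rank_cap)
  }
  if (mode == "pls1") {
    n_latent <- rep_len(n_latent, ncol(Cm))
    B <- matrix(0, ncol(A), ncol(Cm), dimnames = list(NULL, colnames(Cm)))
    for (j in seq_len(ncol(Cm))) {
      path <- pls1_coef_path(Xc, Yc[, j], n_latent[j])
      B[, j] <- path[, n_latent[j]]
    }
  } else {
    n_latent <- n_latent[1]
    B <- pls2_coefs(Xc, Yc, n_latent, max_iter, tol)
    colnames(B) <- colnames(Cm)
  }
  new_calibration_model(
    "PLS", coefficients = B,
    intercepts = y_mean - drop(x_mean %*% B),
    wavelengths = grid_wavelengths(spectra$grid), analytes = colnames(Cm),
    n_latent = n_latent,
    extra = list(x_mean = x_mean, grid = spectra$grid, mode = mode))
}

pls2_coefs <- function(Xc, Yc, max_lv, max_iter, tol) {
  p <- ncol(Xc); m <- ncol(Yc)
  W <- P <- matrix(0, p, max_lv); Q <- matrix(0, m, max_lv)
  X <- Xc; Y <- Yc
  for (k in seq_len(max_lv)) {
    u <- Y[, which.max(colSums(Y^2))]
    w_old <- rep(Inf, p)
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u); w <- w / sqrt(sum(w^2))
      t <- X %*% w
      qv <- crossprod(Y, t) / sum(t^2)
      u <- Y %*% qv / sum(qv^2)
      if (sqrt(sum((w - w_old)^2)) < tol) break
      if (it == max_iter) stop("PLS latent variable ", k, " did not converge")
      w_old <- w
    }
    t <- X %*% w; tt <- sum(t^2)
    pk <- crossprod(X, t) / tt
    qk <- crossprod(Y, t) / tt
    W[, k] <- w; P[, k] <- pk; Q[, k] <- qk
    X <- X - tcrossprod(t, pk)
    Y <- Y - tcrossprod(t, qk)
  }
  W %*% solve(crossprod(P, W), t(Q))
}

#' Cross-validation fold assignment
#'
#' @param n Number of samples.
#' @param scheme \code{"venetian_blinds"} (deterministic interleaved
#'   folds), \code{"leave_one_out"}, or \code{"random_subsets"}.
#' @param n_splits Number of folds for the split schemes.
#' @param seed RNG seed (random subsets only).
#' @return Integer fold id per sample.
#' @export
cv_folds <- function(n, scheme = c("venetian_blinds", "leave_one_out",
                                   "random_subsets"),
                     n_splits = 5, seed = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
    venetian_blinds = {
      if (n_splits < 2) stop("n_splits must be >= 2")
      if (n < n_splits) stop("fewer samples than splits")
      ((seq_len(n) - 1L) %% n_splits) + 1L
    },
    leave_one_out = seq_len(n),
    random_subsets = {
      if (n_splits < 2) stop("n_splits must be >= 2")
      if (n < n_splits) stop("fewer samples than splits")
      if (is.null(seed)) stop("random_subsets needs a seed")
      withr_seed(seed, sample(((seq_len(n) - 1L) %% n_splits) + 1L))
    })
}

# Cross-validated squared prediction errors for PLS1/PCR over 1..max_lv.
# Returns n x max_lv matrix of squared errors for one analyte.
cv_sqerr_path <- function(A, y, folds, max_lv, method = "pls") {
  n <- nrow(A)
  sq <- matrix(NA_real_, n, max_lv)
  for (f in unique(folds)) {
    tr <- folds != f
    Xtr <- A[tr, , drop = FALSE]; ytr <- y[tr]
    x_mean <- colMeans(Xtr); y_mean <- mean(ytr)
    Xc <- sweep(Xtr, 2, x_mean)
    kmax <- min(max_lv, sum(tr) - 1L, ncol(A))
    Bp <- if (method == "pls") {
      pls1_coef_path(Xc, ytr - y_mean, kmax)
    } else {
      sv <- svd(Xc)
      pos <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
      kk <- min(kmax, pos)
      out <- matrix(0, ncol(A), kmax)
      bj <- 0
      for (k in seq_len(kk)) {
        bj <- bj + sv$v[, k] * (sum(sv$u[, k] * (ytr - y_mean)) / sv$d[k])
        out[, k] <- bj
      }
      if (kk < kmax && kk > 0) for (k in (kk + 1):kmax) out[, k] <- out[, kk]
      out
    }
    Xte <- sweep(A[!tr, , drop = FALSE], 2, x_mean)
    pred <- Xte %*% Bp + y_mean
    if (ncol(Bp) < max_lv) {
      pred <- cbind(pred, pred[, rep(ncol(Bp), max_lv - ncol(Bp)),
                               drop = FALSE])
    }
    sq[!tr, ] <- (pred - y[!tr])^2
  }
  sq
}

#' Cross-validated latent-variable selection
#'
#' Scans latent-variable counts 1..\code{max_lv}, computes RMSECV per
#' analyte under the requested cross-validation scheme, and chooses the
#' smallest count whose RMSECV is within one standard error (across folds)
#' of the global minimum — the first-parsimonious rule that balances model
#' fit and complexity.
#'
#' @inheritParams fit_pcr
#' @param max_lv Largest latent-variable count scanned (default 10).
#' @param method \code{"pls"} (default) or \code{"pcr"}.
#' @param scheme,n_splits,n_iterations,seed Cross-validation configuration;
#'   \code{n_iterations} > 1 repeats (random-subsets scheme) with fresh
#'   splits and averages.
#' @return An \code{lv_scan}: list with \code{lv_grid}, \code{rmsecv}
#'   (max_lv x analyte matrix, ug/mL), \code{se_min} (per analyte) and
#'   \code{chosen} (named integer per analyte).
#' @export
select_latent <- function(spectra, C, max_lv = 10,
                          method = c("pls", "pcr"),
                          scheme = "venetian_blinds", n_splits = 5,
                          n_iterations = 1, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(spectra, "spectral_matrix"))
  Cm <- conc_matrix(C)
  A <- spectra$absorbance
  n <- nrow(A)
  max_lv <- min(max_lv, n - ceiling(n / max(n_splits, 2)) - 1L, ncol(A))
  rmsecv <- matrix(NA_real_, max_lv, ncol(Cm),
                   dimnames = list(NULL, colnames(Cm)))
  se_min <- chosen <- stats::setNames(numeric(ncol(Cm)), colnames(Cm))
  for (j in seq_len(ncol(Cm))) {
    acc <- 0
    fold_rmse <- NULL
    for (it in seq_len(n_iterations)) {
      it_seed <- if (is.null(seed)) NULL else seed + 1000L * (it - 1L)
      folds <- cv_folds(n, scheme, n_splits, seed = it_seed)
      sq <- cv_sqerr_path(A, Cm[, j], folds, max_lv, method)
      acc <- acc + sq
      fr <- matrix(vapply(sort(unique(folds)), function(f) {
        sqrt(colMeans(sq[folds == f, , drop = FALSE]))
      }, numeric(max_lv)), nrow = max_lv)
      fold_rmse <- rbind(fold_rmse, t(fr))
    }
    rmsecv[, j] <- sqrt(colMeans(acc / n_iterations))
    kmin <- which.min(rmsecv[, j])
    se_min[j] <- stats::sd(fold_rmse[, kmin]) / sqrt(nrow(fold_rmse))
    chosen[j] <- which(rmsecv[, j] <= rmsecv[kmin, j] + se_min[j])[1]
  }
  structure(list(lv_grid = seq_len(max_lv), rmsecv = rmsecv,
                 se_min = se_min, chosen = as.integer(chosen),
                 analytes = colnames(Cm), method = method, scheme = scheme),
            class = "lv_scan")
}

#' @export
print.lv_scan <- function(x, ...) {
  cat(sprintf("<lv_scan> %s, %s CV: chosen LVs %s\n", toupper(x$method),
              x$scheme, paste(x$analytes, "=", x$chosen, collapse = ", ")))
  invisible(x)
}

#' Predict concentrations from spectra
#'
#' Applies the model's stored preprocessing (smoothing window for CLS,
#' training-set centering for PCR/PLS — validation spectra are never
#' re-centered on themselves), restricts the input to the model's retained
#' wavelengths (so spectra on a wider acquisition grid are accepted), and
#' returns the per-sample concentration estimates.
#'
#' @param object A \code{calibration_model}.
#' @param spectra A \code{\link{spectral_matrix}} whose grid contains every
#'   retained wavelength.
#' @param ... Unused.
#' @return Data frame: \code{sample_id} plus one column per analyte
#'   (ug/mL).
#' @export
predict.calibration_model <- function(object, spectra, ...) {
  stopifnot(inherits(spectra, "spectral_matrix"))
  if (nrow(spectra$absorbance) == 0) {
    out <- data.frame(sample_id = character(0))
    for (a in object$analytes) out[[a]] <- numeric(0)
    return(out)
  }
  if (object$method == "CLS" && !is.null(object$window_nm)) {
    # smooth on the model's contiguous grid so trim and predict commute
    if (!isTRUE(all.equal(grid_wavelengths(spectra$grid),
                          object$wavelengths))) {
      spectra <- trim_spectra(spectra, min(object$wavelengths),
                              max(object$wavelengths))
    }
    spectra <- moving_window_smooth(spectra, object$window_nm)
  }
  wl_in <- grid_wavelengths(spectra$grid)
  idx <- match(round(object$wavelengths, 8), round(wl_in, 8))
  if (anyNA(idx)) {
    stop("input grid is missing model wavelengths: ",
         paste(utils::head(object$wavelengths[is.na(idx)], 5), collapse = ", "),
         if (sum(is.na(idx)) > 5) " ..." else "", " nm")
  }
  A <- spectra$absorbance[, idx, drop = FALSE]
  pred <- if (object$method == "CLS") {
    cls_invert(A, object$pure_profiles, object$intercept,
               length(object$analytes))
  } else {
    sweep(A %*% object$coefficients, 2, object$intercepts, `+`)
  }
  colnames(pred) <- object$analytes
  cbind(data.frame(sample_id = spectra$sample_ids), as.data.frame(pred))
}
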