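# Figures of merit for calibration/validation of the multivariate models.
# All error statistics follow the printed reporting equations: RMSE with a
# 1/n denominator, SEC with n-1, RRMSEP with a 1/n prefactor inside the
# percentage (a deliberate deviation from the conventional 1/sqrt(n) form,
# which is available behind a flag), BCMSEP as the bias-corrected mean
# squared error, and LOD/LOQ as 3.3 and 10 sigma/S from the
# measured-vs-predicted regression line.

#' Paired observed/predicted outcomes
#'
#' @param y_observed Reference concentrations (ug/mL).
#' @param y_predicted Model outputs (ug/mL), same length.
#' @param context \code{"calibration"}, \code{"cross_validation"} or
#'   \code{"prediction"}; tags which RMSE flavour the pair feeds (RMSEC,
#'   RMSECV, RMSEP).
#' @return A \code{paired_outcomes} list.
#' @export
paired_outcomes <- function(y_observed, y_predicted,
                            context = c("calibration", "cross_validation",
                                        "prediction")) {
  context <- match.arg(context)
  y_observed <- as.numeric(y_observed)
  y_predicted <- as.numeric(y_predicted)
  if (length(y_observed) != length(y_predicted) || length(y_observed) < 1) {
    stop("y_observed and y_predicted must have equal length >= 1")
  }
  if (!all(is.finite(y_observed)) || !all(is.finite(y_predicted))) {
    stop("non-finite values in paired outcomes")
  }
  structure(list(y_observed = y_observed, y_predicted = y_predicted,
                 context = context), class = "paired_outcomes")
}

#' Core goodness-of-fit statistics
#'
#' RSS = sum((y - yhat)^2); SSX = sum((y - mean(y))^2); R2 = 1 - RSS/SSX;
#' RMSE = sqrt(RSS/n); bias = mean(y - yhat). With constant observed
#' values SSX is zero and R2 is undefined: it is returned as \code{NA} with
#' a flag rather than an error.
#'
#' @param p A \code{\link{paired_outcomes}}.
#' @return List with \code{rss}, \code{ssx}, \code{r2}, \code{rmse},
#'   \code{bias}, \code{n} and \code{flags}.
#' @export
core_stats <- function(p) {
  stopifnot(inherits(p, "paired_outcomes"))
  y <- p$y_observed; yh <- p$y_predicted
  n <- length(y)
  rss <- sum((y - yh)^2)
  flags <- character(0)
  if (n < 2) {
    ssx <- NA_real_; r2 <- NA_real_
    flags <- c(flags, "n < 2: SSX and R2 undefined")
  } else {
    ssx <- sum((y - mean(y))^2)
    if (ssx == 0) {
      r2 <- NA_real_
      flags <- c(flags, "constant observed values: R2 undefined")
    } else r2 <- 1 - rss / ssx
  }
  list(rss = rss, ssx = ssx, r2 = r2, rmse = sqrt(rss / n),
       bias = sum(y - yh) / n, n = n, flags = flags)
}

#' Cross-validated predictive ability
#'
#' PRESS = sum((y - yhat_CV)^2); Q2 = 1 - PRESS/SSX, where SSX comes from
#' the calibration set.
#'
#' @param p A \code{\link{paired_outcomes}} holding cross-validated
#'   predictions.
#' @param ssx Total sum of squares of the calibration concentrations.
#' @return List with \code{press} and \code{q2}.
#' @export
q2_press <- function(p, ssx) {
  stopifnot(inherits(p, "paired_outcomes"))
  press <- sum((p$y_observed - p$y_predicted)^2)
  q2 <- if (is.na(ssx) || ssx == 0) NA_real_ else 1 - press / ssx
  list(press = press, q2 = q2)
}

#' Precision statistics: SEC, RRMSEP\%, BCMSEP
#'
#' SEC = sqrt(sum((y - yhat - bias)^2)/(n - 1));
#' RRMSEP\% = (1/n) sqrt(sum((y - yhat)^2)) / mean(y) * 100 — note the 1/n
#' prefactor of the reporting convention used here (set
#' \code{conventional = TRUE} for the usual sqrt(mean squared error)/mean
#' form); BCMSEP = sum((y - yhat)^2)/n - bias^2, which is algebraically the
#' variance of the residuals and hence non-negative.
#'
#' @param p A \code{\link{paired_outcomes}} with n >= 2.
#' @param conventional Use the conventional RMSEP/mean form for the
#'   relative error instead of the 1/n-prefactor form.
#' @return List with \code{bias}, \code{sec}, \code{rrmsep_pct},
#'   \code{bcmsep} and \code{flags}.
#' @export
precision_stats <- function(p, conventional = FALSE) {
  stopifnot(inherits(p, "paired_outcomes"))
  y <- p$y_observed; yh <- p$y_predicted
  n <- length(y)
  if (n < 2) stop("precision statistics need n >= 2")
  bias <- sum(y - yh) / n
  sec <- sqrt(sum((y - yh - bias)^2) / (n - 1))
  flags <- character(0)
  ybar <- mean(y)
  rrmsep <- if (ybar == 0) {
    flags <- c(flags, "mean observed value is zero: RRMSEP undefined")
    NA_real_
  } else if (conventional) {
    sqrt(sum((y - yh)^2) / n) / ybar * 100
  } else {
    (1 / n) * sqrt(sum((y - yh)^2)) / ybar * 100
  }
  bcmsep <- sum((y - yh)^2) / n - bias^2
  list(bias = bias, sec = sec, rrmsep_pct = rrmsep, bcmsep = bcmsep,
       flags = flags)
}

#' Regression line of measured on predicted concentrations
#'
#' Ordinary least squares of the experimentally known concentrations
#' (y axis) on the model predictions (x axis). \code{sigma} is the
#' residual standard error with an n - 2 denominator.
#'
#' @param y_measured Reference concentrations (ug/mL).
#' @param y_predicted Model predictions (ug/mL).
#' @return A \code{regression_line}: \code{slope}, \code{intercept},
#'   \code{sigma}.
#' @export
regression_line <- function(y_measured, y_predicted) {
  if (length(y_measured) < 3) stop("regression line needs n >= 3")
  fit <- stats::lm(y_measured ~ y_predicted)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 sigma = summary(fit)$sigma),
            class = "regression_line")
}

#' Limits of detection and quantification
#'
#' LOD = 3.3 sigma / S and LOQ = 10 sigma / S, where sigma is the standard
#' error of the measured-vs-predicted regression and S its slope, so
#' LOQ/LOD = 10/3.3 exactly.
#'
#' @param line A \code{\link{regression_line}} (or any list with
#'   \code{slope} and \code{sigma}).
#' @return List with \code{lod} and \code{loq} (ug/mL).
#' @export
lod_loq <- function(line) {
  if (line$slope == 0) stop("zero slope: LOD/LOQ undefined")
  if (line$sigma < 0) stop("sigma must be >= 0")
  list(lod = 3.3 * line$sigma / line$slope,
       loq = 10 * line$sigma / line$slope)
}

#' Recovery and precision of replicate determinations
#'
#' Recovery = 100 * found / nominal per determination; per replicate group
#' the mean recovery and \%RSD (= 100 * sd / mean, n - 1 denominator) are
#' reported, plus the overall mean and SD of all recoveries.
#'
#' @param found Found concentrations (ug/mL).
#' @param nominal Nominal concentrations (ug/mL), > 0, recycled.
#' @param groups Replicate-group labels (e.g. the concentration level);
#'   defaults to a single group.
#' @return List with \code{per_level} (data frame: group, n,
#'   mean_recovery_pct, rsd_pct) and \code{overall} (mean and SD of all
#'   recoveries, \%).
#' @export
recovery_rsd <- function(found, nominal, groups = NULL) {
  found <- as.numeric(found)
  nominal <- rep_len(as.numeric(nominal), length(found))
  if (any(nominal <= 0)) stop("nominal concentrations must be > 0")
  if (length(found) < 1) stop("no determinations supplied")
  if (is.null(groups)) groups <- rep("all", length(found))
  rec <- 100 * found / nominal
  per <- do.call(rbind, lapply(split(rec, groups), function(r) {
    data.frame(n = length(r), mean_recovery_pct = mean(r),
               rsd_pct = if (length(r) > 1) 100 * stats::sd(r) / mean(r)
                         else NA_real_)
  }))
  per <- cbind(group = rownames(per), per)
  rownames(per) <- NULL
  list(per_level = per,
       overall = list(mean_recovery_pct = mean(rec),
                      sd_pct = if (length(rec) > 1) stats::sd(rec)
                               else NA_real_))
}

#' One-way ANOVA across models' recoveries
#'
#' Standard one-way analysis of variance comparing the recovery
#' distributions of several models; a computed F below the critical F at
#' alpha = 0.05 means no significant difference between models.
#'
#' @param groups Named list of numeric vectors (recoveries per model),
#'   each of length >= 2.
#' @param alpha Significance level for the critical F (default 0.05).
#' @return List with \code{f}, \code{p}, \code{f_critical}, \code{df} and
#'   \code{flags}.
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups))))
  tab <- stats::anova(stats::aov(value ~ group, data = df))
  f <- tab$`F value`[1]
  flags <- character(0)
  if (!is.finite(f)) {
    flags <- "zero within-group variance with unequal means: F infinite"
  }
  list(f = f, p = tab$`Pr(>F)`[1],
       f_critical = stats::qf(1 - alpha, tab$Df[1], tab$Df[2]),
       df = tab$Df, flags = flags)
}

#' Full figures-of-merit report for one model and analyte
#'
#' Aggregates the individual statistics into a single serializable record:
#' calibration fit (RMSEC, R2, SEC, bias), cross-validated predictive
#' ability (RMSECV, PRESS, Q2), external prediction (RMSEP, RRMSEP, BCMSEP,
#' bias), sensitivity (LOD, LOQ from the measured-vs-predicted line on the
#' prediction set) and accuracy/precision (mean recovery, \%RSD).
#'
#' @param calibration,cv,prediction \code{\link{paired_outcomes}} for the
#'   three contexts (\code{cv} and \code{prediction} may be \code{NULL}).
#' @param recovery_found,recovery_nominal,recovery_groups Optional inputs
#'   forwarded to \code{\link{recovery_rsd}}.
#' @param conventional_rrmsep Forwarded to \code{\link{precision_stats}}.
#' @return A \code{merit_report} list; \code{as_json} ready via
#'   \code{jsonlite}.
#' @export
merit_report <- function(calibration, cv = NULL, prediction = NULL,
                         recovery_found = NULL, recovery_nominal = NULL,
                         recovery_groups = NULL,
                         conventional_rrmsep = FALSE) {
  cal <- core_stats(calibration)
  calp <- precision_stats(calibration, conventional_rrmsep)
  rep <- list(
    n_calibration = cal$n, rss = cal$rss, ssx = cal$ssx, r2 = cal$r2,
    rmsec = cal$rmse, bias_cal = cal$bias, sec = calp$sec,
    flags = cal$flags)
  if (!is.null(cv)) {
    q <- q2_press(cv, cal$ssx)
    rep$press <- q$press
    rep$q2 <- q$q2
    rep$rmsecv <- core_stats(cv)$rmse
  }
  if (!is.null(prediction)) {
    pr <- core_stats(prediction)
    prp <- precision_stats(prediction, conventional_rrmsep)
    line <- regression_line(prediction$y_observed, prediction$y_predicted)
    ll <- lod_loq(line)
    rep <- c(rep, list(n_prediction = pr$n, rmsep = pr$rmse,
                       bias_pred = pr$bias, rrmsep_pct = prp$rrmsep_pct,
                       bcmsep = prp$bcmsep, slope = line$slope,
                       intercept = line$intercept, sigma = line$sigma,
                       lod = ll$lod, loq = ll$loq))
  }
  if (!is.null(recovery_found)) {
    rec <- recovery_rsd(recovery_found, recovery_nominal, recovery_groups)
    rep$recovery <- rec
  }
  structure(rep, class = "merit_report")
}

#' @export
print.merit_report <- function(x, ...) {
  cat("<merit_report>\n")
  cat(sprintf("  calibration: n=%d  RMSEC=%.4g  R2=%.4f  SEC=%.4g\n",
              x$n_calibration, x$rmsec, x$r2, x$sec))
  if (!is.null(x$q2)) {
    cat(sprintf("  cross-val:   RMSECV=%.4g  Q2=%.4f\n", x$rmsecv, x$q2))
  }
  if (!is.null(x$rmsep)) {
    cat(sprintf("  prediction:  n=%d  RMSEP=%.4g  RRMSEP=%.4g%%  LOD=%.4g\n",
                x$n_prediction, x$rmsep, x$rrmsep_pct, x$lod))
  }
  invisible(x)
}
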