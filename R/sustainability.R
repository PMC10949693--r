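# Quantitative sustainability calculators: carbon footprint of instrument
# electricity use, BAGI blueness (practical applicability) and RGB12
# whiteness (overall sustainability).

#' Carbon footprint of instrument usage
#'
#' Sum over instruments of power (kW) x analysis time (h) x grid emission
#' factor (kg CO2 per kWh), reported as kg CO2 equivalent per sample.
#'
#' @param usages A list of usage records, each with \code{power_kw},
#'   \code{hours} and \code{emission_factor}; a single record may be passed
#'   directly.
#' @return Carbon footprint (kg CO2 eq).
#' @examples
#' carbon_footprint(list(power_kw = 0.1, hours = 0.5, emission_factor = 0.4))
#' @export
carbon_footprint <- function(usages) {
  if (!is.null(usages$power_kw)) usages <- list(usages)
  if (length(usages) == 0) stop("at least one instrument usage is required")
  vals <- vapply(usages, function(u) {
    v <- c(u$power_kw, u$hours, u$emission_factor)
    if (length(v) != 3 || any(!is.finite(v))) {
      stop("each usage needs power_kw, hours and emission_factor")
    }
    if (any(v < 0)) stop("usage fields must be >= 0")
    prod(v)
  }, numeric(1))
  sum(vals)
}

#' BAGI blueness score
#'
#' The blue applicability grade index condenses ten practicality criteria
#' (analysis type, number of analytes, instrumentation, sample throughput,
#' sample preparation, samples per hour, reagents, preconcentration,
#' degree of automation, sample amount), each scored 1 (worst) to 10
#' (best), into their geometric mean. The mean is rescaled by 10 onto the
#' 10--100 reporting scale, so ten equal scores s yield 10 s.
#'
#' @param criteria Numeric vector of exactly ten scores in [1, 10].
#' @return BAGI score on the 10--100 scale.
#' @examples
#' bagi_score(rep(9, 10))  # 90
#' @export
bagi_score <- function(criteria) {
  criteria <- as.numeric(criteria)
  if (length(criteria) != 10) stop("BAGI needs exactly ten criteria scores")
  if (any(criteria < 1 | criteria > 10)) {
    stop("criteria scores must lie in [1, 10]")
  }
  10 * exp(mean(log(criteria)))
}

#' RGB12 whiteness
#'
#' The whiteness model scores a method on twelve algorithms in three color
#' groups — red (validation: scope, accuracy, LOD, precision/LOQ), green
#' (environmental: toxicity, waste/reagents, energy, bio-impacts) and blue
#' (practical/economic: practicality, cost, time, requirements) — each on
#' 0--100. Each color score is the (optionally weighted) mean of its four
#' algorithms and whiteness is the mean of the three color scores.
#'
#' @param red,green,blue Numeric length-4 vectors of scores in [0, 100].
#' @param weights Optional length-4 weights applied within each color
#'   group; default uniform.
#' @return List with \code{red}, \code{green}, \code{blue} and
#'   \code{whiteness}, all on 0--100.
#' @examples
#' rgb12_whiteness(rep(80, 4), rep(90, 4), rep(100, 4))$whiteness  # 90
#' @export
rgb12_whiteness <- function(red, green, blue, weights = NULL) {
  chk <- function(x, nm) {
    x <- as.numeric(x)
    if (length(x) != 4) stop(nm, " needs exactly four scores")
    if (any(x < 0 | x > 100)) stop(nm, " scores must lie in [0, 100]")
    x
  }
  red <- chk(red, "red"); green <- chk(green, "green")
  blue <- chk(blue, "blue")
  if (is.null(weights)) weights <- rep(1, 4)
  if (length(weights) != 4 || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be four non-negative values")
  }
  wmean <- function(x) sum(x * weights) / sum(weights)
  r <- wmean(red); g <- wmean(green); b <- wmean(blue)
  list(red = r, green = g, blue = b, whiteness = mean(c(r, g, b)))
}
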