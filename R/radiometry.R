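## Radiometric chain: counts -> object radiance -> temperature, and its
## exact algebraic inverse (forward model) used for simulation.
##
## Unit conventions, centralized here: the water-vapour polynomial takes the
## air temperature in degrees Celsius; the path-radiance terms take
## temperatures in Kelvin; output temperatures are degrees Celsius. "log"
## is the natural logarithm throughout.

KELVIN0 <- 273.15

#' Water vapour pressure from ambient conditions
#'
#' Cubic-exponential parameterization of the saturated water vapour
#' pressure, scaled by the relative humidity.
#'
#' @param TaC air temperature, degrees Celsius.
#' @param RH relative humidity fraction in [0, 1].
#' @return Water vapour pressure (dimensionless input to the atmospheric
#'   transmission model).
#' @examples
#' waterVapourPressure(22.4, 0.58)  # ~ 11.43
#' @export
waterVapourPressure <- function(TaC, RH) {
  if (any(RH < 0) || any(RH > 1)) stop("RH must lie in [0, 1]")
  RH * exp(1.5587 + 0.06939 * TaC - 0.00027816 * TaC^2 +
           0.00000068455 * TaC^3)
}

#' Atmospheric transmission along the measurement path
#'
#' Two-exponential atmospheric transmission in the distance and water
#' vapour pressure. The default "sqrt" form uses the square roots of both
#' the distance and the vapour pressure inside the exponentials (the
#' standard LWIR atmospheric model); the "linear" form uses the literal
#' products and is kept switchable via the params' \code{atmFormula}.
#'
#' @param params a \linkS4class{RadiometricParams}.
#' @param Wp water vapour pressure, see \code{\link{waterVapourPressure}};
#'   computed from the params when missing.
#' @return transmission tau, clamped to (0, 1].
#' @export
atmTransmission <- function(params, Wp = waterVapourPressure(params@TaC,
                                                             params@RH)) {
  d <- params@distanceM
  if (params@atmFormula == "sqrt") {
    e1 <- exp(-sqrt(d) * (params@alpha1 + params@beta1 * sqrt(Wp)))
    e2 <- exp(-sqrt(d) * (params@alpha2 + params@beta2 * sqrt(Wp)))
  } else {
    e1 <- exp(-d * (params@alpha1 + params@beta1 * Wp))
    e2 <- exp(-d * (params@alpha2 + params@beta2 * Wp))
  }
  tau <- params@Xatm * e1 + (1 - params@Xatm) * e2
  min(max(tau, .Machine$double.eps), 1)
}

## Planck radiance of a blackbody at temperature T (Kelvin), camera units.
planckRadiance <- function(TK, params) {
  params@PR1 / (params@PR2 * (exp(params@PB / TK) - params@PF)) - params@PO
}

#' Path radiances: atmosphere, optics window, reflected
#'
#' The three additive radiance terms of the measurement equation, each with
#' its emissivity/transmission prefactor. The atmosphere radiates at the
#' air temperature, the window at its own temperature, and the reflected
#' term at the reflected (background) temperature; all in Kelvin.
#'
#' @param params a \linkS4class{RadiometricParams}.
#' @param tau atmospheric transmission, see \code{\link{atmTransmission}}.
#' @return named list with Ratm, Ropt, Rrefl (camera radiance units).
#' @export
pathRadiances <- function(params, tau = atmTransmission(params)) {
  eps <- params@emissivity
  if (tau <= 0 || eps <= 0)
    stop("singular configuration: tau and emissivity must be > 0")
  TaK <- params@TaC + KELVIN0
  Ratm <- (1 - tau) / (eps * tau) * planckRadiance(TaK, params)
  Ropt <- (1 - params@Wt) / (eps * tau * params@Wt) *
    planckRadiance(params@TwK, params)
  Rrefl <- (1 - eps) / eps * planckRadiance(params@TrK, params)
  list(Ratm = Ratm, Ropt = Ropt, Rrefl = Rrefl)
}

#' Object radiance from vignette-corrected counts
#'
#' @param counts vignette-corrected radiometric signal (scalar, vector or
#'   matrix).
#' @param params a \linkS4class{RadiometricParams}.
#' @param tau atmospheric transmission.
#' @param radiances path radiances, see \code{\link{pathRadiances}}.
#' @return object radiance, same shape as \code{counts}.
#' @export
countsToObjectRadiance <- function(counts, params,
                                   tau = atmTransmission(params),
                                   radiances = pathRadiances(params, tau)) {
  denom <- params@emissivity * tau * params@Wt
  if (denom == 0) stop("emissivity * tau * Wt must be non-zero")
  counts / denom - radiances$Ratm - radiances$Ropt - radiances$Rrefl
}

#' Invert the Planck calibration to temperature
#'
#' T = PB / log(PR1 / (PR2 (Robject + PO)) + PF) - 273.15. The logarithm
#' argument must exceed 1 (positive absolute temperature); offending pixels
#' are reported, not clipped.
#'
#' @param Robject object radiance (scalar, vector or matrix).
#' @param params a \linkS4class{RadiometricParams}.
#' @return temperature in degrees Celsius, same shape as \code{Robject}.
#' @export
planckInvert <- function(Robject, params) {
  arg <- params@PR1 / (params@PR2 * (Robject + params@PO)) + params@PF
  bad <- !is.finite(arg) | arg <= 1
  if (any(bad)) {
    idx <- which(bad)
    stop(sprintf(
      "out-of-range radiance at %d pixel(s) (first offenders: %s): log argument <= 1",
      length(idx), paste(head(idx, 5), collapse = ", ")))
  }
  out <- params@PB / log(arg) - KELVIN0
  if (is.matrix(Robject)) dim(out) <- dim(Robject)
  out
}

#' Forward radiometric model: temperature to counts
#'
#' Exact algebraic inverse of the counts-to-temperature chain; used to
#' render Planck-consistent synthetic scenes and for round-trip testing.
#'
#' @param TC temperature in degrees Celsius (scalar, vector or matrix).
#' @param params a \linkS4class{RadiometricParams}.
#' @param tau atmospheric transmission.
#' @param radiances path radiances.
#' @return radiometric counts, same shape as \code{TC}.
#' @export
planckForward <- function(TC, params, tau = atmTransmission(params),
                          radiances = pathRadiances(params, tau)) {
  Robject <- planckRadiance(TC + KELVIN0, params)
  out <- params@emissivity * tau * params@Wt *
    (Robject + radiances$Ratm + radiances$Ropt + radiances$Rrefl)
  if (is.matrix(TC)) dim(out) <- dim(TC)
  out
}

#' Local sensitivity of counts to temperature
#'
#' Numerical derivative d counts / d T at a given temperature; used to
#' express detector noise (NETD, Kelvin-equivalent) in count units.
#'
#' @param TC temperature, degrees Celsius.
#' @param params a \linkS4class{RadiometricParams}.
#' @param dT finite-difference step, degrees.
#' @return derivative in counts per degree.
#' @export
countsPerDegree <- function(TC, params, dT = 1e-3) {
  (planckForward(TC + dT, params) - planckForward(TC - dT, params)) / (2 * dT)
}

#' Full conversion of a radiometric frame to temperature
#'
#' Composition of the whole chain: vignetting correction by elementwise
#' division, water vapour pressure, atmospheric transmission, path
#' radiances, object radiance, and Planck inversion.
#'
#' @param frame a \linkS4class{RadiometricFrame}.
#' @param gain a \linkS4class{GainField}, or NULL to skip the vignetting
#'   correction (the output is then flagged as uncorrected).
#' @param params a \linkS4class{RadiometricParams}.
#' @param plausibleRange length-2 numeric; a warning is raised when
#'   temperatures fall outside it (default c(-40, 150) degC).
#' @return a \linkS4class{TemperatureImage}.
#' @export
frameToTemperature <- function(frame, gain, params,
                               plausibleRange = c(-40, 150)) {
  if (!is.null(gain)) {
    frame <- applyGainCorrection(frame, gain)
    corrected <- TRUE
  } else corrected <- FALSE
  tau <- atmTransmission(params)
  rads <- pathRadiances(params, tau)
  Robj <- countsToObjectRadiance(frame@counts, params, tau, rads)
  TC <- planckInvert(Robj, params)
  if (min(TC) < plausibleRange[1] || max(TC) > plausibleRange[2])
    warning(sprintf("temperatures outside plausible range [%g, %g] degC",
                    plausibleRange[1], plausibleRange[2]))
  new("TemperatureImage", values = TC, params = params,
      vignetteCorrected = corrected)
}
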