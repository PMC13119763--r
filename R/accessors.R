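## Constructors, accessors and show methods.

#' Construct a RadiometricFrame
#'
#' @param counts numeric matrix (height x width) of detector counts.
#' @param timestamp numeric, seconds since epoch.
#' @param cameraId character camera identifier.
#' @return A \linkS4class{RadiometricFrame}.
#' @export
RadiometricFrame <- function(counts, timestamp = 0, cameraId = "unknown") {
  new("RadiometricFrame", counts = as.matrix(counts),
      timestamp = as.numeric(timestamp), cameraId = cameraId)
}

#' Construct an AcquisitionMeta
#'
#' @param distanceM camera-to-object distance in metres (default 0.5 per the
#'   bedside protocol).
#' @param airTempC ambient air temperature, degrees Celsius.
#' @param relHumidity relative humidity fraction in [0, 1].
#' @param label patient/session identifier.
#' @param datetime ISO-8601 datetime string.
#' @param extra named list escrow for unmapped metadata tags.
#' @return An \linkS4class{AcquisitionMeta}.
#' @export
AcquisitionMeta <- function(distanceM = 0.5, airTempC = 22,
                            relHumidity = 0.5, label = "unlabelled",
                            datetime = "", extra = list()) {
  new("AcquisitionMeta", distanceM = distanceM, airTempC = airTempC,
      relHumidity = relHumidity, label = label, datetime = datetime,
      extra = extra)
}

#' Construct a RadiometricParams set
#'
#' Defaults correspond to a typical consumer LWIR camera calibration
#' (Planck constants of the order PB ~ 1428 K, PR1 ~ 17096) under the
#' clinical protocol: skin emissivity 0.98, 0.5 m working distance, indoor
#' ambient conditions. Window and reflected temperatures default to the
#' ambient air temperature (standard reflected-temperature practice when
#' the metadata does not provide them).
#'
#' @param PB,PR1,PR2,PO,PF Planck calibration constants.
#' @param emissivity object emissivity in (0, 1].
#' @param Wt window transmission in (0, 1].
#' @param Xatm,alpha1,alpha2,beta1,beta2 atmospheric transmission constants.
#' @param distanceM camera-to-object distance, metres.
#' @param TaC air temperature, degrees Celsius.
#' @param TwK,TrK window and reflected temperatures, Kelvin; default to
#'   TaC + 273.15.
#' @param RH relative humidity fraction.
#' @param atmFormula "sqrt" (default) or "linear"; see
#'   \code{\link{atmTransmission}}.
#' @return A \linkS4class{RadiometricParams}.
#' @export
radiometricParams <- function(PB = 1428, PR1 = 17096, PR2 = 0.04635,
                              PO = -732, PF = 1, emissivity = 0.98,
                              Wt = 1, Xatm = 1.9, alpha1 = 0.006569,
                              alpha2 = 0.01262, beta1 = -0.002276,
                              beta2 = -0.00667, distanceM = 0.5,
                              TaC = 22, TwK = TaC + 273.15,
                              TrK = TaC + 273.15, RH = 0.5,
                              atmFormula = "sqrt") {
  new("RadiometricParams", PB = PB, PR1 = PR1, PR2 = PR2, PO = PO, PF = PF,
      emissivity = emissivity, Wt = Wt, Xatm = Xatm, alpha1 = alpha1,
      alpha2 = alpha2, beta1 = beta1, beta2 = beta2, distanceM = distanceM,
      TaC = TaC, TwK = TwK, TrK = TrK, RH = RH, atmFormula = atmFormula)
}

#' Construct a FlatFieldSequence
#'
#' @param frames list of \linkS4class{RadiometricFrame} (same shape).
#' @param epoch numeric timestamp of the flat-field epoch.
#' @return A \linkS4class{FlatFieldSequence}.
#' @export
FlatFieldSequence <- function(frames, epoch = 0) {
  new("FlatFieldSequence", frames = frames, epoch = as.numeric(epoch))
}

#' Construct a CameraIntrinsics
#'
#' @param fx,fy focal lengths (pixels).
#' @param cx,cy principal point (pixels).
#' @param width,height image size (pixels).
#' @param k1,k2,k3 radial distortion coefficients.
#' @param p1,p2 tangential distortion coefficients.
#' @return A \linkS4class{CameraIntrinsics}.
#' @export
CameraIntrinsics <- function(fx, fy, cx, cy, width, height,
                             k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  new("CameraIntrinsics", fx = fx, fy = fy, cx = cx, cy = cy,
      k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2,
      width = as.integer(width), height = as.integer(height))
}

#' Construct an Affine2D
#'
#' @param linear 2 x 2 matrix.
#' @param translation length-2 numeric vector.
#' @return An \linkS4class{Affine2D}.
#' @export
Affine2D <- function(linear = diag(2), translation = c(0, 0)) {
  new("Affine2D", linear = linear, translation = as.numeric(translation))
}

#' @describeIn RadiometricFrame-class detector counts matrix
#' @param object a RadiometricFrame
#' @export
setMethod("counts", "RadiometricFrame", function(object) object@counts)

#' @export
setMethod("gainValues", "GainField", function(object) object@values)

#' @export
setMethod("tempValues", "TemperatureImage", function(object) object@values)

#' @export
setMethod("epoch", "GainField", function(object) object@epoch)

#' @export
setMethod("epoch", "FlatFieldSequence", function(object) object@epoch)

#' @export
setMethod("frameDim", "RadiometricFrame",
          function(object) dim(object@counts))

#' @export
setMethod("frameDim", "GainField", function(object) dim(object@values))

#' @export
setMethod("provenance", "PatientRecord", function(object) object@provenance)

#' @export
setMethod("artifacts", "PatientRecord", function(object) object@artifacts)

#' @export
setMethod("matchedPairs", "CorrespondenceSet", function(object) object@pairs)

#' Apply a 2D affine map to points
#'
#' @param transform an \linkS4class{Affine2D}.
#' @param pts n x 2 matrix of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
setMethod("mapPoints", "Affine2D", function(transform, pts) {
  pts <- rbind(pts)
  t(transform@linear %*% t(pts[, 1:2, drop = FALSE]) + transform@translation)
})

setMethod("show", "RadiometricFrame", function(object) {
  d <- dim(object@counts)
  cat(sprintf("RadiometricFrame %dx%d px, counts [%0.1f, %0.1f], camera '%s'\n",
              d[2], d[1], min(object@counts), max(object@counts),
              object@cameraId))
})

setMethod("show", "GainField", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "GainField %dx%d px, range [%.4f, %.4f], %s-normalized, epoch %.0f\n",
    d[2], d[1], min(object@values), max(object@values),
    object@normalizer, object@epoch))
})

setMethod("show", "TemperatureImage", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "TemperatureImage %dx%d px, [%.2f, %.2f] degC, vignette-corrected: %s\n",
    d[2], d[1], min(object@values), max(object@values),
    object@vignetteCorrected))
})

setMethod("show", "CorrespondenceSet", function(object) {
  cat(sprintf(
    "CorrespondenceSet: %d pairs, residual RMS %.3f px, rho_x=%.3f rho_y=%.3f\n",
    nrow(object@pairs),
    if (length(object@residuals)) sqrt(mean(object@residuals^2)) else NA,
    object@rhoX, object@rhoY))
})

setMethod("show", "PatientRecord", function(object) {
  cat(sprintf("PatientRecord '%s': %d provenance steps, %d artifacts\n",
              object@meta@label, length(object@provenance),
              length(object@artifacts)))
})

setMethod("show", "GainStabilityReport", function(object) {
  cat(sprintf("GainStabilityReport over %d epochs, max off-diagonal RMS %.4g\n",
              length(object@epochs),
              if (length(object@epochs) > 1)
                max(object@rms[upper.tri(object@rms)]) else 0))
})

## Parameter list <-> RadiometricParams (used by JSON I/O)
paramsToList <- function(p) {
  list(PB = p@PB, PR1 = p@PR1, PR2 = p@PR2, PO = p@PO, PF = p@PF,
       emissivity = p@emissivity, Wt = p@Wt, Xatm = p@Xatm,
       alpha1 = p@alpha1, alpha2 = p@alpha2, beta1 = p@beta1,
       beta2 = p@beta2, distanceM = p@distanceM, TaC = p@TaC,
       TwK = p@TwK, TrK = p@TrK, RH = p@RH, atmFormula = p@atmFormula)
}

paramsFromList <- function(x) {
  known <- names(formals(radiometricParams))
  do.call(radiometricParams, x[intersect(names(x), known)])
}
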