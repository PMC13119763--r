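## Central S4 classes. Images are numeric matrices (height x width);
## coordinates are 0-based, x = column, y = row, pixel centre at integers.

#' RadiometricFrame: raw detector counts
#'
#' A single radiometric frame of detector digital units as produced by an
#' LWIR microbolometer, together with its acquisition epoch and camera
#' identity. Counts are dimensionless, finite and non-negative.
#'
#' @slot counts numeric matrix (height x width) of detector counts.
#' @slot timestamp numeric, seconds since epoch.
#' @slot cameraId character scalar.
#' @exportClass RadiometricFrame
setClass("RadiometricFrame",
  representation(counts = "matrix", timestamp = "numeric",
                 cameraId = "character"),
  prototype(timestamp = 0, cameraId = "unknown"))

setValidity("RadiometricFrame", function(object) {
  c0 <- object@counts
  if (length(c0) == 0L) return("counts must be a non-empty matrix")
  if (!is.numeric(c0)) return("counts must be numeric")
  if (any(!is.finite(c0))) return("all counts must be finite")
  if (any(c0 < 0)) return("all counts must be >= 0")
  if (length(object@timestamp) != 1L) return("timestamp must be scalar")
  TRUE
})

#' AcquisitionMeta: ambient conditions and session identity
#'
#' @slot distanceM camera-to-object distance in metres (protocol default 0.5).
#' @slot airTempC ambient air temperature, degrees Celsius.
#' @slot relHumidity relative humidity as a fraction in [0, 1].
#' @slot label patient/session identifier.
#' @slot datetime ISO-8601 datetime string.
#' @slot extra named list escrow for unmapped metadata tags.
#' @exportClass AcquisitionMeta
setClass("AcquisitionMeta",
  representation(distanceM = "numeric", airTempC = "numeric",
                 relHumidity = "numeric", label = "character",
                 datetime = "character", extra = "list"),
  prototype(distanceM = 0.5, airTempC = 22, relHumidity = 0.5,
            label = "unlabelled", datetime = "", extra = list()))

setValidity("AcquisitionMeta", function(object) {
  if (object@distanceM <= 0) return("distanceM must be > 0")
  if (object@relHumidity < 0 || object@relHumidity > 1)
    return("relHumidity must lie in [0, 1]")
  if (!is.finite(object@airTempC)) return("airTempC must be finite")
  TRUE
})

#' RadiometricParams: Planck, optics and atmosphere constants
#'
#' All constants of the radiometric chain: the camera's Planck calibration
#' (PB, PR1, PR2, PO, PF), the object emissivity, the window transmission,
#' the atmospheric transmission constants, and the scene conditions
#' (distance, air temperature, window and reflected temperatures, relative
#' humidity). Defaults mirror typical consumer LWIR calibration metadata and
#' the clinical protocol (emissivity 0.98 for skin, 0.5 m distance).
#'
#' @slot PB Planck B constant (Kelvin).
#' @slot PR1,PR2,PO,PF Planck calibration constants (camera units).
#' @slot emissivity object emissivity in (0, 1].
#' @slot Wt window transmission in (0, 1].
#' @slot Xatm,alpha1,alpha2,beta1,beta2 atmospheric transmission constants.
#' @slot distanceM camera-to-object distance, metres.
#' @slot TaC air temperature, degrees Celsius.
#' @slot TwK window temperature, Kelvin.
#' @slot TrK reflected (background) temperature, Kelvin.
#' @slot RH relative humidity fraction in [0, 1].
#' @slot atmFormula "sqrt" (default; square roots of distance and vapour
#'   pressure inside the exponentials) or "linear" (literal products).
#' @exportClass RadiometricParams
setClass("RadiometricParams",
  representation(PB = "numeric", PR1 = "numeric", PR2 = "numeric",
                 PO = "numeric", PF = "numeric", emissivity = "numeric",
                 Wt = "numeric", Xatm = "numeric", alpha1 = "numeric",
                 alpha2 = "numeric", beta1 = "numeric", beta2 = "numeric",
                 distanceM = "numeric", TaC = "numeric", TwK = "numeric",
                 TrK = "numeric", RH = "numeric", atmFormula = "character"))

setValidity("RadiometricParams", function(object) {
  if (object@PB <= 0 || object@PR1 <= 0 || object@PR2 <= 0)
    return("PB, PR1, PR2 must be > 0")
  if (object@emissivity <= 0 || object@emissivity > 1)
    return("emissivity must lie in (0, 1]")
  if (object@Wt <= 0 || object@Wt > 1) return("Wt must lie in (0, 1]")
  if (object@RH < 0 || object@RH > 1) return("RH must lie in [0, 1]")
  if (object@distanceM < 0) return("distanceM must be >= 0")
  if (!object@atmFormula %in% c("sqrt", "linear"))
    return("atmFormula must be 'sqrt' or 'linear'")
  TRUE
})

#' GainField: unit-level multiplicative vignetting gain
#'
#' A strictly positive, smooth multiplicative gain field normalized so that
#' its central tendency (mean or median) is 1, floored at a small epsilon.
#'
#' @slot values numeric matrix of positive gains.
#' @slot epoch numeric timestamp of the flat-field epoch.
#' @slot normalizer "mean" or "median".
#' @slot floor small positive lower bound applied to the gain.
#' @exportClass GainField
setClass("GainField",
  representation(values = "matrix", epoch = "numeric",
                 normalizer = "character", floor = "numeric"),
  prototype(epoch = 0, normalizer = "median", floor = 1e-6))

setValidity("GainField", function(object) {
  v <- object@values
  if (length(v) == 0L) return("values must be non-empty")
  if (any(!is.finite(v))) return("gain values must be finite")
  if (min(v) < object@floor) return("gain values must be >= floor")
  if (!object@normalizer %in% c("mean", "median"))
    return("normalizer must be 'mean' or 'median'")
  if (object@floor <= 0) return("floor must be > 0")
  TRUE
})

#' FlatFieldSequence: one epoch of flat-field frames
#'
#' @slot frames list of RadiometricFrame, all the same shape.
#' @slot epoch numeric timestamp of the epoch.
#' @exportClass FlatFieldSequence
setClass("FlatFieldSequence",
  representation(frames = "list", epoch = "numeric"),
  prototype(epoch = 0))

setValidity("FlatFieldSequence", function(object) {
  if (length(object@frames) < 1L) return("need at least one frame")
  if (!all(vapply(object@frames, is, logical(1), "RadiometricFrame")))
    return("frames must all be RadiometricFrame objects")
  dims <- vapply(object@frames, function(f) dim(f@counts), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all frames must share the same shape")
  TRUE
})

#' GainStabilityReport: inter-epoch log-gain RMS matrix
#'
#' @slot rms symmetric K x K matrix of RMS log-gain differences between
#'   epochs; zero diagonal.
#' @slot epochs numeric vector of the K epoch timestamps.
#' @exportClass GainStabilityReport
setClass("GainStabilityReport",
  representation(rms = "matrix", epochs = "numeric"))

setValidity("GainStabilityReport", function(object) {
  r <- object@rms
  if (nrow(r) != ncol(r)) return("rms must be square")
  if (length(object@epochs) != nrow(r))
    return("epochs length must match rms dimension")
  if (any(abs(diag(r)) > 1e-12)) return("rms diagonal must be zero")
  if (max(abs(r - t(r))) > 1e-12) return("rms must be symmetric")
  if (any(r < -1e-12)) return("rms entries must be >= 0")
  TRUE
})

#' TemperatureImage: temperatures in degrees Celsius
#'
#' @slot values numeric matrix of temperatures (degrees C).
#' @slot params the RadiometricParams used for the inversion.
#' @slot vignetteCorrected logical flag.
#' @exportClass TemperatureImage
setClass("TemperatureImage",
  representation(values = "matrix", params = "RadiometricParams",
                 vignetteCorrected = "logical"),
  prototype(vignetteCorrected = FALSE))

setValidity("TemperatureImage", function(object) {
  if (any(!is.finite(object@values)))
    return("all temperatures must be finite")
  TRUE
})

#' CameraIntrinsics: pinhole + Brown-Conrady distortion model
#'
#' @slot fx,fy focal lengths in pixels (> 0).
#' @slot cx,cy principal point in pixels (inside the image).
#' @slot k1,k2,k3 radial distortion coefficients.
#' @slot p1,p2 tangential distortion coefficients.
#' @slot width,height image size in pixels.
#' @exportClass CameraIntrinsics
setClass("CameraIntrinsics",
  representation(fx = "numeric", fy = "numeric", cx = "numeric",
                 cy = "numeric", k1 = "numeric", k2 = "numeric",
                 k3 = "numeric", p1 = "numeric", p2 = "numeric",
                 width = "integer", height = "integer"),
  prototype(k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0))

setValidity("CameraIntrinsics", function(object) {
  if (object@fx <= 0 || object@fy <= 0) return("fx, fy must be > 0")
  if (object@cx < 0 || object@cx > object@width - 1 ||
      object@cy < 0 || object@cy > object@height - 1)
    return("principal point must lie inside the image")
  TRUE
})

#' Affine2D: planar affine map
#'
#' Maps a point p to linear %*% p + translation. Hypotheses accepted by the
#' matcher always have det(linear) > 0 (reflections are physically
#' impossible for rigidly mounted, nearly parallel cameras).
#'
#' @slot linear 2 x 2 numeric matrix.
#' @slot translation numeric 2-vector (pixels).
#' @exportClass Affine2D
setClass("Affine2D",
  representation(linear = "matrix", translation = "numeric"),
  prototype(linear = diag(2), translation = c(0, 0)))

setValidity("Affine2D", function(object) {
  if (!all(dim(object@linear) == c(2L, 2L))) return("linear must be 2 x 2")
  if (length(object@translation) != 2L)
    return("translation must have length 2")
  TRUE
})

#' CorrespondenceSet: matched IR/VIS marker pairs and the fitted map
#'
#' @slot pairs integer matrix with columns ir, vis (1-based indices into the
#'   detection lists); one-to-one on both sides.
#' @slot transform Affine2D mapping LWIR coordinates to VIS coordinates.
#' @slot residuals numeric per-pair distances (VIS pixels).
#' @slot rhoX,rhoY Spearman rank correlations of matched x and y coordinates.
#' @slot seed integer RNG seed used by the matcher.
#' @slot diagnostics list of rejection counters and settings.
#' @exportClass CorrespondenceSet
setClass("CorrespondenceSet",
  representation(pairs = "matrix", transform = "Affine2D",
                 residuals = "numeric", rhoX = "numeric", rhoY = "numeric",
                 seed = "numeric", diagnostics = "list"),
  prototype(rhoX = NA_real_, rhoY = NA_real_, seed = NA_real_,
            diagnostics = list()))

setValidity("CorrespondenceSet", function(object) {
  p <- object@pairs
  if (nrow(p) > 0) {
    if (ncol(p) != 2L) return("pairs must have two columns (ir, vis)")
    if (anyDuplicated(p[, 1L]) || anyDuplicated(p[, 2L]))
      return("pairs must be one-to-one on both sides")
    if (length(object@residuals) != nrow(p))
      return("residuals must have one entry per pair")
    if (any(object@residuals < 0)) return("residuals must be >= 0")
  }
  for (r in c(object@rhoX, object@rhoY))
    if (!is.na(r) && (r < -1 - 1e-12 || r > 1 + 1e-12))
      return("rank correlations must lie in [-1, 1]")
  TRUE
})

#' PatientRecord: append-only processing record for one session
#'
#' @slot meta AcquisitionMeta.
#' @slot params RadiometricParams.
#' @slot provenance list of processing-step descriptors (name, parameters,
#'   timestamp), append-only.
#' @slot artifacts named character map from role (raw/corrected/temperature/
#'   vis/registered/...) to file path; paths unique.
#' @slot schemaVersion character record-schema version.
#' @exportClass PatientRecord
setClass("PatientRecord",
  representation(meta = "AcquisitionMeta", params = "RadiometricParams",
                 provenance = "list", artifacts = "character",
                 schemaVersion = "character"),
  prototype(provenance = list(), artifacts = character(0),
            schemaVersion = "1"))

setValidity("PatientRecord", function(object) {
  a <- object@artifacts
  if (length(a) && anyDuplicated(a)) return("artifact paths must be unique")
  if (length(a) && (is.null(names(a)) || any(names(a) == "")))
    return("artifacts must be named by role")
  TRUE
})

#' SceneTruth: full ground truth of a simulated bimodal scene
#'
#' @slot gain true GainField applied to the LWIR counts.
#' @slot tMap ground-truth temperature map (degrees C).
#' @slot irCenters,visCenters true marker centres (n x 2, 0-based x, y).
#' @slot visToLwir true plane-induced VIS -> LWIR affine map.
#' @slot params RadiometricParams used by the forward model.
#' @slot mmPerPxLwir,mmPerPxVis metric scale of each camera at the marker
#'   plane (mm per pixel).
#' @slot seed integer seed that regenerates the scene bit-exactly.
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(gain = "GainField", tMap = "matrix", irCenters = "matrix",
                 visCenters = "matrix", visToLwir = "Affine2D",
                 params = "RadiometricParams", mmPerPxLwir = "numeric",
                 mmPerPxVis = "numeric", seed = "numeric"))
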