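## Synthetic-scene generators: every input the pipeline consumes, with
## known ground truth. All generators are deterministic under their seed
## (RNG state is saved and restored).
##
## Fixture geometry (fixed design choices): LWIR 160x120 with a 54-degree
## horizontal field of view and VIS 640x480 with a 71.5-degree field of
## view, both at a 0.5 m working distance -- so a 10 mm marker hole spans
## about 9 VIS pixels and its diffuse thermal imprint 10-15 LWIR pixels,
## the regime the detectors are designed for. The two pinholes share
## nearly parallel axes with a small (4, 12) mm baseline.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Default fixture camera geometry
#'
#' @return list with LWIR and VIS pinhole intrinsics
#'   (\linkS4class{CameraIntrinsics}), working distance (m) and baseline
#'   (m).
#' @export
fixtureGeometry <- function() {
  fL <- 80 / tan(27 * pi / 180)     # 54 deg over 160 px
  fV <- 320 / tan(35.75 * pi / 180) # 71.5 deg over 640 px
  list(
    lwir = CameraIntrinsics(fx = fL, fy = fL, cx = 79.5, cy = 59.5,
                            width = 160, height = 120),
    vis = CameraIntrinsics(fx = fV, fy = fV, cx = 319.5, cy = 239.5,
                           width = 640, height = 480),
    distanceM = 0.5,
    baselineM = c(0.004, 0.012))
}

#' Synthetic smooth gain field (tilt + radial quartic)
#'
#' Emulates the vignetting observed on low-cost LWIR cameras: a planar
#' tilt (optics/detector misalignment) combined with a radial quartic
#' fall-off, normalized to unit median. The raw modulation is bounded by
#' the amplitude, so amplitude 0.1 yields a max/min ratio of at most
#' (1.1/0.9) = 1.222.
#'
#' @param shape c(height, width) in pixels (default LWIR 120 x 160).
#' @param amplitude modulation amplitude in (0, 0.5); 0.1 means +/- 10
#'   percent.
#' @param seed integer seed (tilt direction and tilt/radial mix).
#' @param epoch timestamp carried by the gain.
#' @return a \linkS4class{GainField} (the simulation ground truth).
#' @export
makeGain <- function(shape = c(120, 160), amplitude = 0.1, seed = 1,
                     epoch = 0) {
  stopifnot(amplitude >= 0, amplitude < 0.5)
  withSeed(seed, {
    h <- shape[1]; w <- shape[2]
    u <- matrix(rep(seq(-1, 1, length.out = w), each = h), h, w)
    v <- matrix(rep(seq(-1, 1, length.out = h), times = w), h, w)
    theta <- runif(1, 0, 2 * pi)
    mix <- runif(1, 0.4, 0.8)          # tilt fraction
    tilt <- (u * cos(theta) + v * sin(theta)) / sqrt(2)
    rho <- sqrt(u^2 + v^2) / sqrt(2)
    radial <- 1 - 2 * rho^4
    raw <- mix * tilt + (1 - mix) * radial   # |raw| <= 1
    g <- 1 + amplitude * raw
    g <- g / median(g)
    new("GainField", values = pmax(g, 1e-6), epoch = as.numeric(epoch),
        normalizer = "median", floor = 1e-6)
  })
}

#' Synthetic flat-field stack
#'
#' Frames = gain x level + i.i.d. Gaussian noise. When \code{noiseSd} is
#' not given it is derived from a noise-equivalent temperature difference
#' (NETD, default 70 mK) through the local slope of the forward Planck
#' model at the flat-field temperature.
#'
#' @param gain true \linkS4class{GainField}.
#' @param levelCounts flat-field signal level in counts.
#' @param Nk number of frames.
#' @param seed integer seed.
#' @param noiseSd noise standard deviation in counts, or NULL to derive
#'   from \code{netdK}.
#' @param params \linkS4class{RadiometricParams} used for the NETD
#'   conversion.
#' @param netdK NETD in Kelvin (default 0.070).
#' @param epoch timestamp for the sequence.
#' @return a \linkS4class{FlatFieldSequence}.
#' @export
makeFlatStack <- function(gain, levelCounts, Nk = 16, seed = 1,
                          noiseSd = NULL, params = radiometricParams(),
                          netdK = 0.070, epoch = gain@epoch) {
  stopifnot(Nk >= 1)
  if (is.null(noiseSd)) {
    T0 <- planckInvert(countsToObjectRadiance(levelCounts, params), params)
    noiseSd <- netdK * countsPerDegree(T0, params)
  }
  g <- gain@values
  withSeed(seed, {
    frames <- lapply(seq_len(Nk), function(n) {
      counts <- g * levelCounts +
        matrix(rnorm(length(g), sd = noiseSd), nrow(g), ncol(g))
      RadiometricFrame(pmax(counts, 0), timestamp = epoch + n)
    })
    FlatFieldSequence(frames, epoch = epoch)
  })
}

#' Smooth synthetic temperature scene
#'
#' A smooth field spanning the requested range: a random-direction ramp
#' plus a few broad Gaussian bumps, rescaled exactly to [tMin, tMax].
#' Serves as the ground-truth temperature map for radiometric round-trip
#' experiments.
#'
#' @param shape c(height, width) pixels.
#' @param tMin,tMax temperature range, degC (defaults 28 and 35).
#' @param seed integer seed.
#' @return numeric matrix of temperatures.
#' @export
makeTemperatureScene <- function(shape = c(120, 160), tMin = 28, tMax = 35,
                                 seed = 1) {
  withSeed(seed, {
    h <- shape[1]; w <- shape[2]
    u <- matrix(rep(seq(-1, 1, length.out = w), each = h), h, w)
    v <- matrix(rep(seq(-1, 1, length.out = h), times = w), h, w)
    theta <- runif(1, 0, 2 * pi)
    f <- 0.6 * (u * cos(theta) + v * sin(theta))
    for (b in 1:3) {
      cu <- runif(1, -0.6, 0.6); cv <- runif(1, -0.6, 0.6)
      s <- runif(1, 0.3, 0.6); a <- runif(1, -1, 1)
      f <- f + a * exp(-((u - cu)^2 + (v - cv)^2) / (2 * s^2))
    }
    tMin + (tMax - tMin) * (f - min(f)) / (max(f) - min(f))
  })
}

#' Synthetic bimodal (VIS + LWIR) marker scene with ground truth
#'
#' Renders coplanar 10 mm markers seen by the two fixture cameras: white
#' disks on dark strips in the VIS image, and diffuse thermal hills
#' (Gaussian, amplitude 3-6 degC, sigma ~14 mm) added to a foot-like warm
#' background (broad anisotropic Gaussian blobs at ~31.5 degC over a ~23
#' degC ambient field with a gentle tilt) in the temperature map. LWIR
#' counts are rendered through the forward Planck model, optionally
#' degraded by a vignetting gain and NETD-scaled noise. The truth records
#' the exact marker centres in both images, the plane-induced VIS -> LWIR
#' affine map, and the metric scales.
#'
#' @param nMarkers number of markers (>= 3, default 8).
#' @param seed integer seed.
#' @param parallaxOffsetM out-of-plane displacement of the markers along
#'   the optical axis, metres (default 0: coplanar with the sole plane).
#' @param gain optional \linkS4class{GainField} (120 x 160) applied to the
#'   counts; NULL for none.
#' @param noiseNetdK LWIR noise as NETD in Kelvin (default 0.070; 0
#'   disables).
#' @param params \linkS4class{RadiometricParams} for the forward model.
#' @param hillAmplitude length-2 range of marker hill amplitudes, degC.
#' @param hillSigmaM thermal hill scale, metres (default 0.0143, i.e.
#'   about 4.5 LWIR px).
#' @return list with \code{vis} (640 x 480 matrix in [0, 1]), \code{frame}
#'   (\linkS4class{RadiometricFrame} 120 x 160), and \code{truth}
#'   (\linkS4class{SceneTruth}).
#' @export
makeBimodalScene <- function(nMarkers = 8, seed = 1, parallaxOffsetM = 0,
                             gain = NULL, noiseNetdK = 0.070,
                             params = radiometricParams(),
                             hillAmplitude = c(3, 6),
                             hillSigmaM = 0.0143) {
  stopifnot(nMarkers >= 3)
  geom <- fixtureGeometry()
  Z <- geom$distanceM
  bx <- geom$baselineM[1]; by <- geom$baselineM[2]
  L <- geom$lwir; V <- geom$vis
  withSeed(seed, {
    ## marker world layout: two vertical strips flanking the feet on the
    ## sole plane (markers sit on flat ambient background, not on the
    ## feet's thermal flanks), jittered to break the grid symmetries
    base <- rbind(
      cbind(-0.21, seq(-0.12, 0.12, length.out = ceiling(nMarkers / 2))),
      cbind(0.21, seq(-0.12, 0.12, length.out = floor(nMarkers / 2))))
    base <- base[seq_len(nMarkers), , drop = FALSE]
    ## jitter: generous in x (breaks the mirror symmetry of the strip
    ## layout, so a left-right flip cannot be re-explained by any
    ## orientation-preserving affine), modest in y (keeps neighbouring
    ## thermal hills from merging)
    world <- base + cbind(runif(nMarkers, -0.016, 0.016),
                          runif(nMarkers, -0.008, 0.008))
    zM <- Z + parallaxOffsetM

    ## projections (0-based pixel coordinates)
    irC <- cbind(L@fx * world[, 1] / zM + L@cx,
                 L@fy * world[, 2] / zM + L@cy)
    visC <- cbind(V@fx * (world[, 1] - bx) / zM + V@cx,
                  V@fy * (world[, 2] - by) / zM + V@cy)

    ## temperature map on the LWIR grid
    h <- L@height; w <- L@width
    px <- matrix(rep(0:(w - 1), each = h), h, w)
    py <- matrix(rep(0:(h - 1), times = w), h, w)
    X <- (px - L@cx) * Z / L@fx      # world coords of the sole plane
    Y <- (py - L@cy) * Z / L@fy
    tilt <- runif(1, -0.5, 0.5)
    tMap <- 23 + tilt * X / 0.25     # ambient field with a gentle tilt
    ## two foot-like plateaus (~31.5 degC): supergaussian profile -- flat
    ## warm interior much wider than the detector's structuring element
    ## (so the opening keeps the foot in the background) with steep edges
    ## and negligible tails at the marker strips
    for (s in c(-1, 1)) {
      d2 <- (X - s * 0.075)^2 / 0.05^2 + Y^2 / 0.10^2
      tMap <- tMap + 8.5 * exp(-0.25 * d2^2)
    }
    amp <- runif(nMarkers, hillAmplitude[1], hillAmplitude[2])
    sigPx <- hillSigmaM * L@fx / zM
    for (i in seq_len(nMarkers)) {
      tMap <- tMap + amp[i] *
        exp(-((px - irC[i, 1])^2 + (py - irC[i, 2])^2) / (2 * sigPx^2))
    }

    ## LWIR counts through the forward model (+ gain, + NETD noise)
    counts <- planckForward(tMap, params)
    if (!is.null(gain)) counts <- counts * gain@values
    if (noiseNetdK > 0) {
      sdC <- noiseNetdK * countsPerDegree(median(tMap), params)
      counts <- counts + matrix(rnorm(length(counts), sd = sdC), h, w)
    }
    frame <- RadiometricFrame(pmax(counts, 0), timestamp = 0,
                              cameraId = "fixture")

    ## VIS image: dark scene, matte-black strips, anti-aliased white disks
    vh <- V@height; vw <- V@width
    vis <- matrix(0.25, vh, vw)
    stripHalf <- 0.02 * V@fx / Z     # 2 cm wide vertical strips
    vxCols <- c(-0.21, 0.21) - bx    # strip columns in VIS world coords
    for (xx in vxCols) {
      c0 <- round(V@fx * xx / Z + V@cx - stripHalf)
      c1 <- round(V@fx * xx / Z + V@cx + stripHalf)
      vis[, max(1, c0 + 1):min(vw, c1 + 1)] <- 0.05
    }
    rDisk <- 0.005 * V@fx / zM       # 10 mm diameter
    for (i in seq_len(nMarkers)) {
      cx <- visC[i, 1]; cy <- visC[i, 2]
      rows <- max(1, floor(cy - rDisk - 2) + 1):min(vh, ceiling(cy + rDisk + 2) + 1)
      cols <- max(1, floor(cx - rDisk - 2) + 1):min(vw, ceiling(cx + rDisk + 2) + 1)
      dd <- sqrt(outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, "+"))
      cov <- pmin(pmax(rDisk + 0.5 - dd, 0), 1)
      vis[rows, cols] <- vis[rows, cols] * (1 - cov) + 0.95 * cov
    }

    ## plane-induced VIS -> LWIR affine truth (exact for the sole plane)
    lin <- diag(c(L@fx / V@fx, L@fy / V@fy))
    tr <- c(L@cx - L@fx / V@fx * V@cx + L@fx * bx / Z,
            L@cy - L@fy / V@fy * V@cy + L@fy * by / Z)
    truth <- new("SceneTruth",
                 gain = if (is.null(gain))
                   new("GainField", values = matrix(1, h, w), epoch = 0,
                       normalizer = "median", floor = 1e-6) else gain,
                 tMap = tMap, irCenters = irC, visCenters = visC,
                 visToLwir = Affine2D(lin, tr), params = params,
                 mmPerPxLwir = 1000 * Z / L@fx,
                 mmPerPxVis = 1000 * Z / V@fx,
                 seed = as.numeric(seed))
    list(vis = vis, frame = frame, truth = truth)
  })
}
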