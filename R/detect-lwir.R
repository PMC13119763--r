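## Detection of thermal-marker imprints ("thermal hills") in temperature
## images: grayscale morphological background removal, hard thresholding
## of the relief, binary cleaning, component filtering by area/
## circularity/peak relief, and relief-weighted barycentres.

#' Configuration for thermal-hill detection
#'
#' Defaults follow the expected marker imprint of 10-15 pixels diameter:
#' radius range [5, 7.5] px, relief threshold 2 degC, area slack factors
#' 0.4 and 2.5 (admitting irregular boundaries), permissive circularity
#' 0.20 suited to diffuse hills, area-opening floor 20 px, closing radius
#' 2 px, and a structuring-element radius of about twice the expected
#' marker radius.
#'
#' @param dTmin relief threshold, degrees C (default 2).
#' @param rmin,rmax expected marker radius range, pixels (defaults 5, 7.5).
#' @param alphaMin,alphaMax area slack factors (alphaMin < 1 < alphaMax).
#' @param tauCirc circularity threshold (default 0.20).
#' @param areaOpenMin area-opening size, pixels (default 20).
#' @param closeRadius closing disc radius, pixels (default 2).
#' @param seRadius opening structuring-element radius, pixels (default
#'   2 * (rmin + rmax) / 2, rounded).
#' @param epsCirc small constant guarding the circularity denominator.
#' @return named list of settings; area bounds Amin = alphaMin pi rmin^2
#'   and Amax = alphaMax pi rmax^2 are derived fields.
#' @export
lwirDetectConfig <- function(dTmin = 2, rmin = 5, rmax = 7.5,
                             alphaMin = 0.4, alphaMax = 2.5,
                             tauCirc = 0.20, areaOpenMin = 20,
                             closeRadius = 2,
                             seRadius = round((rmin + rmax)),
                             epsCirc = 1e-9) {
  stopifnot(rmin < rmax, alphaMin < 1, alphaMax > 1)
  list(dTmin = dTmin, rmin = rmin, rmax = rmax, alphaMin = alphaMin,
       alphaMax = alphaMax, tauCirc = tauCirc, areaOpenMin = areaOpenMin,
       closeRadius = closeRadius, seRadius = seRadius, epsCirc = epsCirc,
       Amin = alphaMin * pi * rmin^2, Amax = alphaMax * pi * rmax^2)
}

#' Morphological background / relief decomposition
#'
#' Background = grayscale opening (erosion then dilation) of the
#' temperature image with a disc structuring element whose radius is about
#' twice the expected marker radius; relief = T - background. Opening is
#' anti-extensive, so the relief is non-negative everywhere: large-scale
#' structures (the foot) stay in the background while localized warm
#' patches survive in the relief.
#'
#' @param T numeric matrix of temperatures (degC) or a
#'   \linkS4class{TemperatureImage}.
#' @param seRadius structuring-element radius, pixels.
#' @return list with \code{background}, \code{relief} (matrices) and
#'   \code{seRadius}.
#' @export
morphologicalBackground <- function(T, seRadius = 12) {
  tm <- if (is(T, "TemperatureImage")) T@values else T
  bg <- grayMorph(tm, seRadius, "open")
  bg <- pmin(bg, tm)     # guard tiny numerical overshoot of the filter
  dim(bg) <- dim(tm)
  list(background = bg, relief = tm - bg, seRadius = seRadius)
}

#' Threshold the relief and clean the binary mask
#'
#' Hard threshold at dTmin, then area opening (removes specks), closing
#' with a small disc (connects fragmented parts), and hole filling, in
#' that order.
#'
#' @param relief numeric matrix of relief temperatures (degC).
#' @param cfg settings from \code{\link{lwirDetectConfig}}.
#' @return logical matrix mask.
#' @export
thresholdAndClean <- function(relief, cfg = lwirDetectConfig()) {
  mask <- relief >= cfg$dTmin
  if (!any(mask)) return(mask)
  mask <- areaOpen(mask, cfg$areaOpenMin)
  if (any(mask)) mask <- binaryClose(mask, cfg$closeRadius)
  if (any(mask)) mask <- fillHoles(mask)
  mask
}

#' Filter connected components by marker plausibility
#'
#' 8-connected components are retained when (i) their area lies within
#' [alphaMin pi rmin^2, alphaMax pi rmax^2], (ii) their circularity
#' 4 pi A / (P^2 + eps) reaches tauCirc, and (iii) their peak relief
#' reaches dTmin (hills that crept through the mask cleaning but lack
#' contrast are dropped here).
#'
#' @param mask logical matrix from \code{\link{thresholdAndClean}}.
#' @param relief numeric matrix of relief temperatures.
#' @param cfg settings from \code{\link{lwirDetectConfig}}.
#' @return list of retained components, each with fields \code{pixels}
#'   (logical matrix), \code{area}, \code{perimeter}, \code{circularity},
#'   \code{peakRelief}, \code{eqDiameter}, \code{bbox}.
#' @export
filterComponents <- function(mask, relief, cfg = lwirDetectConfig()) {
  lab <- label8(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  stats <- componentStats(lab, weights = relief)
  out <- list()
  for (k in seq_len(n)) {
    st <- stats[[k]]
    if (st$area < cfg$Amin || st$area > cfg$Amax) next
    circ <- 4 * pi * st$area / (st$perimeter^2 + cfg$epsCirc)
    if (circ < cfg$tauCirc) next
    peak <- max(relief[lab == k])
    if (peak < cfg$dTmin) next
    out[[length(out) + 1L]] <- list(
      pixels = lab == k, area = st$area, perimeter = st$perimeter,
      circularity = circ, peakRelief = peak,
      eqDiameter = st$eqDiameter, bbox = st$bbox)
  }
  out
}

#' Relief-weighted barycentre of a component
#'
#' Sub-pixel centre estimate: mean of the component's 0-based pixel
#' coordinates weighted by the relief. Pixels near the hill summit
#' dominate, making the estimate robust to diffuse boundaries and moderate
#' anisotropy. When all weights vanish the unweighted centroid is returned
#' with a warning.
#'
#' @param component logical matrix selecting the component's pixels.
#' @param relief numeric matrix of weights (same shape).
#' @return numeric c(x, y), 0-based.
#' @export
weightedBarycenter <- function(component, relief) {
  idx <- which(component, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty component")
  x <- idx[, 2L] - 1; y <- idx[, 1L] - 1
  w <- relief[idx]
  if (sum(w) <= 0) {
    warning("all-zero weights; falling back to unweighted centroid")
    w <- rep(1, length(x))
  }
  c(x = sum(x * w) / sum(w), y = sum(y * w) / sum(w))
}

#' Detect thermal-marker imprints in a temperature image
#'
#' Composition of \code{\link{morphologicalBackground}},
#' \code{\link{thresholdAndClean}}, \code{\link{filterComponents}} and
#' \code{\link{weightedBarycenter}}. The input should be vignette
#' corrected; detection is invariant to additive constants and to smooth
#' backgrounds whose curvature scale is well above the structuring
#' element.
#'
#' @param T numeric matrix of temperatures (degC) or a
#'   \linkS4class{TemperatureImage}.
#' @param cfg settings from \code{\link{lwirDetectConfig}}.
#' @return data.frame with columns x, y, radius_px, score (peak relief,
#'   degC), modality (possibly empty).
#' @export
detectLwirMarkers <- function(T, cfg = lwirDetectConfig()) {
  tm <- if (is(T, "TemperatureImage")) T@values else T
  dec <- morphologicalBackground(tm, cfg$seRadius)
  mask <- thresholdAndClean(dec$relief, cfg)
  comps <- filterComponents(mask, dec$relief, cfg)
  if (length(comps) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      radius_px = numeric(0), score = numeric(0),
                      modality = character(0)))
  ctr <- t(vapply(comps, function(co)
    weightedBarycenter(co$pixels, dec$relief), numeric(2)))
  data.frame(
    x = ctr[, 1], y = ctr[, 2],
    radius_px = vapply(comps, function(co) co$eqDiameter / 2, numeric(1)),
    score = vapply(comps, function(co) co$peakRelief, numeric(1)),
    modality = "LWIR")
}
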