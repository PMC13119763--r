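## End-to-end session processing: decode -> vignetting correction ->
## temperature -> undistortion -> marker detection (both modalities) ->
## constrained matching -> transform fit -> warp + fuse. Every stage
## appends its parameters to the provenance; artifacts are written under
## the session output directory and never mutated by later stages.

#' Default session configuration
#'
#' Mirrors every tunable default of the stage modules; values can be
#' overridden via a YAML file (\code{\link{loadSessionConfig}}) or
#' programmatically.
#'
#' @param sigma flat-field smoothing scale (px).
#' @param qlo,qhi flat-field clamp quantiles.
#' @param normalizer gain normalizer ("median" or "mean").
#' @param gainFloor gain floor epsilon.
#' @param rmsMax master-vs-interpolated stability threshold.
#' @param vis \code{\link{visDetectConfig}} list.
#' @param lwir \code{\link{lwirDetectConfig}} list.
#' @param match \code{\link{matchConfig}} list.
#' @param family registration family ("affine", "projective", "poly2").
#' @param fuseMode "edges" or "alpha".
#' @param seed RNG seed for the matcher.
#' @return nested named list.
#' @export
sessionConfig <- function(sigma = 4, qlo = 0.02, qhi = 0.98,
                          normalizer = "median", gainFloor = 1e-6,
                          rmsMax = 0.01, vis = visDetectConfig(),
                          lwir = lwirDetectConfig(), match = matchConfig(),
                          family = "affine", fuseMode = "edges", seed = 1) {
  list(sigma = sigma, qlo = qlo, qhi = qhi, normalizer = normalizer,
       gainFloor = gainFloor, rmsMax = rmsMax, vis = vis, lwir = lwir,
       match = match, family = family, fuseMode = fuseMode, seed = seed)
}

#' Load a session configuration YAML, merged over the defaults
#'
#' @param path YAML file; keys mirror \code{\link{sessionConfig}}.
#' @return nested named list.
#' @export
loadSessionConfig <- function(path) {
  user <- read_yaml(path)
  cfg <- sessionConfig()
  deepMerge <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        deepMerge(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  deepMerge(cfg, user)
}

configHash <- function(config) {
  s <- as.character(toJSON(config, auto_unbox = TRUE, digits = NA))
  # small stable fingerprint (polynomial rolling hash)
  v <- utf8ToInt(s)
  h <- 0
  for (start in seq(1, length(v), by = 1000)) {
    blk <- v[start:min(length(v), start + 999)]
    h <- (h * 31 + sum(blk * (seq_along(blk) %% 97 + 1))) %% 2147483647
  }
  sprintf("%d", h)
}

#' Run a full processing session
#'
#' @param containerPath radiometric container (see
#'   \code{\link{readRadiometricJPEG}}).
#' @param gains list of per-epoch \linkS4class{GainField}s (the master /
#'   interpolation rule of \code{\link{selectGain}} picks the model), or a
#'   single GainField.
#' @param outDir output directory (created if needed).
#' @param config settings from \code{\link{sessionConfig}}.
#' @param intrinsicsLwir,intrinsicsVis optional
#'   \linkS4class{CameraIntrinsics}; NULL skips undistortion (the
#'   zero-distortion fixture case).
#' @return the enriched \linkS4class{PatientRecord} (also written to
#'   record.json in outDir). On a stage failure the partial record is
#'   preserved on disk and the error names the stage.
#' @export
runSession <- function(containerPath, gains, outDir,
                       config = sessionConfig(),
                       intrinsicsLwir = NULL, intrinsicsVis = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is(gains, "GainField")) gains <- list(gains)
  record <- NULL
  finish <- function(rec) {
    writeRecord(rec, file.path(outDir, "record.json"))
    rec
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(record)) finish(record)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  hash <- configHash(config)

  ## 1. decode
  dec <- stage("decode", readRadiometricJPEG(containerPath))
  record <- initRecord(dec$meta, dec$params)
  record <- appendStep(record, "decode",
                       list(path = containerPath, configHash = hash))
  rawPath <- file.path(outDir, "raw_counts.tiff")
  writeCountsTIFF(dec$frame@counts, rawPath)
  record <- addArtifact(record, "raw", rawPath)

  ## 2. vignetting correction
  sel <- stage("vignetting",
               selectGain(gains, dec$frame@timestamp, config$rmsMax))
  corr <- stage("vignetting", applyGainCorrection(dec$frame, sel$gain))
  record <- appendStep(record, "vignetting",
                       list(method = sel$method, rmsMax = config$rmsMax,
                            floor = sel$gain@floor,
                            normalizer = sel$gain@normalizer))
  corrPath <- file.path(outDir, "corrected_counts.tiff")
  writeScaledTIFF(corr@counts, corrPath, role = "corrected")
  record <- addArtifact(record, "corrected", corrPath)

  ## 3. temperature inversion
  tImg <- stage("temperature",
                frameToTemperature(corr, NULL, dec$params))
  tImg@vignetteCorrected <- TRUE
  record <- appendStep(record, "temperature",
                       list(atmFormula = dec$params@atmFormula,
                            emissivity = dec$params@emissivity))
  tPath <- file.path(outDir, "temperature.tiff")
  writeScaledTIFF(tImg@values, tPath, role = "temperature_degC")
  record <- addArtifact(record, "temperature", tPath)

  ## 4. undistortion (both modalities; identity when no intrinsics given)
  tVals <- tImg@values
  vis <- dec$vis
  visValid <- NULL
  if (!is.null(intrinsicsLwir)) {
    u <- stage("undistort", undistortImage(tVals, intrinsicsLwir))
    tVals <- u$image
    tVals[is.na(tVals)] <- min(tVals, na.rm = TRUE)
  }
  if (!is.null(intrinsicsVis) && !is.null(vis)) {
    u <- stage("undistort", undistortImage(vis, intrinsicsVis))
    vis <- u$image
    visValid <- u$valid
  }
  record <- appendStep(record, "undistort",
                       list(lwir = !is.null(intrinsicsLwir),
                            vis = !is.null(intrinsicsVis)))

  ## 5-6. marker detection
  lwirDet <- stage("detect_lwir", detectLwirMarkers(tVals, config$lwir))
  record <- appendStep(record, "detect_lwir",
                       c(config$lwir[c("dTmin", "rmin", "rmax", "tauCirc")],
                         list(n = nrow(lwirDet))))
  if (is.null(vis)) stop("stage 'detect_vis' failed: no visible image")
  visDet <- stage("detect_vis",
                  detectVisMarkers(vis, config$vis, validMask = visValid))
  record <- appendStep(record, "detect_vis",
                       c(config$vis[c("r", "w", "minCircularity")],
                         list(n = nrow(visDet))))
  lwirCsv <- file.path(outDir, "markers_lwir.csv")
  visCsv <- file.path(outDir, "markers_vis.csv")
  writeDetectionsCSV(lwirDet, lwirCsv)
  writeDetectionsCSV(visDet, visCsv)
  record <- addArtifact(record, "markers_lwir", lwirCsv)
  record <- addArtifact(record, "markers_vis", visCsv)

  ## 7. matching
  corrSet <- stage("match",
                   ransacMatch(as.matrix(lwirDet[, c("x", "y")]),
                               as.matrix(visDet[, c("x", "y")]),
                               config$match, seed = config$seed))
  if (nrow(corrSet@pairs) == 0L) {
    finish(record)
    stop(sprintf("stage 'match' failed: no-match (%s)",
                 corrSet@diagnostics$reason %||% "constraints rejected all hypotheses"),
         call. = FALSE)
  }
  record <- appendStep(record, "match",
                       list(seed = config$seed,
                            nPairs = nrow(corrSet@pairs),
                            rhoX = corrSet@rhoX, rhoY = corrSet@rhoY))
  corrPathJ <- file.path(outDir, "correspondences.json")
  writeCorrespondenceJSON(corrSet, corrPathJ)
  record <- addArtifact(record, "correspondences", corrPathJ)

  ## 8. registration + fusion
  trans <- stage("register", fitTransform(
    as.matrix(visDet[corrSet@pairs[, 2], c("x", "y")]),
    as.matrix(lwirDet[corrSet@pairs[, 1], c("x", "y")]),
    family = config$family))
  warped <- stage("register",
                  warpVisToLwir(vis, trans, dim(tVals)))
  fused <- fuseOverlay(tVals, warped$image, mode = config$fuseMode)
  record <- appendStep(record, "register",
                       list(family = config$family,
                            residualRms = sqrt(mean(trans@residuals^2)),
                            mmPerPixel = tryCatch(mmPerPixel(visDet),
                                                  error = function(e) NA)))
  fusedPath <- file.path(outDir, "fused.png")
  writePNG(fused, fusedPath)
  record <- addArtifact(record, "registered", fusedPath)

  finish(record)
}
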