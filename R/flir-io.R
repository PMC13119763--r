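## Raster file I/O. Counts rasters go to 16-bit TIFF; real-valued rasters
## (temperatures in degC, gains) go to 32-bit float TIFF scaled into
## [0, 1] with the affine offset/scale recorded in a JSON sidecar, read
## back transparently.

sidecarPath <- function(path) paste0(path, ".json")

#' Write / read a counts raster (16-bit TIFF)
#'
#' @param counts integer-valued matrix in [0, 65535].
#' @param path .tiff path.
#' @return the path (writer) or the counts matrix (reader).
#' @export
writeCountsTIFF <- function(counts, path) {
  v <- round(counts)
  if (min(v) < 0 || max(v) > 65535) stop("counts out of uint16 range")
  writeTIFF(v / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeCountsTIFF
#' @export
readCountsTIFF <- function(path) {
  round(readTIFF(path) * 65535)
}

#' Write / read a real-valued raster (scaled float TIFF + JSON sidecar)
#'
#' Stores (x - offset) / scale as 32-bit float in [0, 1]; the sidecar
#' records offset, scale and an optional role tag so the reader restores
#' the physical values.
#'
#' @param x numeric matrix (e.g. temperatures in degC, or a gain field).
#' @param path .tiff path; the sidecar goes to path + ".json".
#' @param role free-text role tag stored in the sidecar.
#' @return the path (writer) or the matrix (reader).
#' @export
writeScaledTIFF <- function(x, path, role = "raster") {
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  writeTIFF((x - lo) / scale, path, bits.per.sample = 32L)
  write_json(list(offset = lo, scale = scale, role = role,
                  height = nrow(x), width = ncol(x)),
             sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeScaledTIFF
#' @export
readScaledTIFF <- function(path) {
  sc <- read_json(sidecarPath(path), simplifyVector = TRUE)
  readTIFF(path) * sc$scale + sc$offset
}

#' Write / read a gain field (scaled float TIFF + metadata sidecar)
#'
#' @param gain a \linkS4class{GainField}.
#' @param path .tiff path.
#' @return the path (writer) or a \linkS4class{GainField} (reader).
#' @export
writeGainTIFF <- function(gain, path) {
  lo <- min(gain@values); hi <- max(gain@values)
  scale <- if (hi > lo) hi - lo else 1
  writeTIFF((gain@values - lo) / scale, path, bits.per.sample = 32L)
  write_json(list(offset = lo, scale = scale, role = "gain",
                  epoch = gain@epoch, normalizer = gain@normalizer,
                  floor = gain@floor),
             sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGainTIFF
#' @export
readGainTIFF <- function(path) {
  sc <- read_json(sidecarPath(path), simplifyVector = TRUE)
  v <- readTIFF(path) * sc$scale + sc$offset
  new("GainField", values = pmax(v, sc$floor), epoch = sc$epoch,
      normalizer = sc$normalizer, floor = sc$floor)
}

#' Write / read marker detections (CSV)
#'
#' Interchange schema shared by both modalities: x, y, radius_px, score,
#' modality.
#'
#' @param detections detection data.frame.
#' @param path .csv path.
#' @export
writeDetectionsCSV <- function(detections, path) {
  write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDetectionsCSV
#' @export
readDetectionsCSV <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a correspondence set to JSON
#'
#' Pairs, the 2 x 3 affine (row-major), residuals, rank correlations,
#' seed and diagnostics.
#'
#' @param corr a \linkS4class{CorrespondenceSet}.
#' @param path .json path.
#' @export
writeCorrespondenceJSON <- function(corr, path) {
  A <- cbind(corr@transform@linear, corr@transform@translation)
  write_json(list(pairs = unname(corr@pairs),
                  affine_row_major = as.vector(t(A)),
                  residuals = corr@residuals,
                  rho_x = corr@rhoX, rho_y = corr@rhoY,
                  seed = corr@seed, diagnostics = corr@diagnostics),
             path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
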