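## Radiometric JPEG-style container: a JPEG marker stream whose APP1
## segments carry a chunked FLIR-style payload holding (i) the 16-bit
## radiometric image -- either as a raw block with an endianness flag or
## as an embedded 16-bit grayscale PNG, auto-detected by magic bytes --
## (ii) a JSON parameter record, and (iii) the visible image as 8-bit
## PNG. This mirrors how consumer radiometric JPEGs embed their payloads;
## the reader normalizes byte order to the host and is side-effect free.

APP1_VENDOR <- as.raw(c(0x46, 0x4C, 0x49, 0x52, 0x00, 0x01))  # "FLIR\0\1"

u16be <- function(x) as.raw(c(x %/% 256, x %% 256))
u32be <- function(x) as.raw(c(x %/% 16777216, (x %/% 65536) %% 256,
                              (x %/% 256) %% 256, x %% 256))
rdU16be <- function(b, i) 256 * as.integer(b[i]) + as.integer(b[i + 1])
rdU32be <- function(b, i) {
  v <- as.integer(b[i:(i + 3)])
  ((v[1] * 256 + v[2]) * 256 + v[3]) * 256 + v[4]
}

## ---- CRC32 / Adler32 (needed by the PNG encoder) ----

crcTable <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L)
          bitwXor(-306674912L, bitwShiftR(c, 1))  # 0xEDB88320
        else bitwShiftR(c, 1)
      }
      t[n + 1] <- c
    }
    tab <<- t
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crcTable()
  crc <- -1L
  v <- as.integer(bytes)
  for (b in v) {
    crc <- bitwXor(bitwShiftR(crc, 8),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  x <- as.numeric(crc)
  if (x < 0) x <- x + 4294967296
  u32be(x)
}

## memCompress(type = "gzip") emits an RFC 1950 zlib stream (78 9c header
## + Adler32 trailer), which is exactly what PNG's IDAT requires.
zlibCompress <- function(bytes) {
  memCompress(bytes, type = "gzip")
}

## ---- minimal 16-bit grayscale PNG encoder ----
## (8/16-bit PNG *reading* is handled by png::readPNG; no installed
## package writes 16-bit grayscale, hence this encoder.)

pngChunk <- function(type, data) {
  t <- charToRaw(type)
  c(u32be(length(data)), t, data, crc32(c(t, data)))
}

writePNG16 <- function(counts) {
  h <- nrow(counts); w <- ncol(counts)
  v <- round(t(counts))            # row-major scan order
  if (min(v) < 0 || max(v) > 65535) stop("counts out of uint16 range")
  hi <- as.raw(v %/% 256); lo <- as.raw(v %% 256)
  pix <- as.raw(rbind(hi, lo))     # big-endian sample interleave
  dim(pix) <- NULL
  rows <- matrix(pix, nrow = 2 * w)
  scan <- as.raw(rbind(as.raw(0), rows))   # filter byte 0 per row
  dim(scan) <- NULL
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16, 0, 0, 0, 0)))
  c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
    pngChunk("IHDR", ihdr),
    pngChunk("IDAT", zlibCompress(scan)),
    pngChunk("IEND", raw(0)))
}

## ---- raw 16-bit block dialect ----

RAW16_MAGIC <- charToRaw("IR16")

writeRaw16 <- function(counts, byteOrder = c("little", "big")) {
  byteOrder <- match.arg(byteOrder)
  v <- as.integer(round(t(counts)))   # row-major
  if (min(v) < 0 || max(v) > 65535) stop("counts out of uint16 range")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(RAW16_MAGIC, con)
  writeBin(charToRaw(if (byteOrder == "little") "L" else "B"), con)
  writeBin(c(ncol(counts), nrow(counts)), con, size = 2,
           endian = byteOrder)
  writeBin(v, con, size = 2, endian = byteOrder)
  rawConnectionValue(con)
}

readRaw16 <- function(bytes) {
  if (!identical(bytes[1:4], RAW16_MAGIC)) stop("not a raw16 block")
  byteOrder <- if (rawToChar(bytes[5]) == "L") "little" else "big"
  con <- rawConnection(bytes[-(1:5)], "rb")
  on.exit(close(con))
  wh <- readBin(con, integer(), n = 2, size = 2, endian = byteOrder,
                signed = FALSE)
  v <- readBin(con, integer(), n = wh[1] * wh[2], size = 2,
               endian = byteOrder, signed = FALSE)
  matrix(v, nrow = wh[2], ncol = wh[1], byrow = TRUE)
}

## ---- TLV record layer ----

tlv <- function(type, data) c(charToRaw(type), u32be(length(data)), data)

parseTlv <- function(bytes) {
  out <- list()
  i <- 1L
  n <- length(bytes)
  while (i + 7L <= n) {
    type <- rawToChar(bytes[i:(i + 3L)])
    len <- rdU32be(bytes, i + 4L)
    out[[type]] <- if (len > 0) bytes[(i + 8L):(i + 7L + len)] else raw(0)
    i <- i + 8L + len
  }
  out
}

## ---- container write / read ----

#' Write a synthetic radiometric container
#'
#' Produces a JPEG-marker-stream file whose APP1 segments embed the
#' radiometric payload (raw 16-bit block or 16-bit PNG), the parameter
#' JSON, and the visible image (8-bit PNG), in the FLIR-style chunked
#' layout that \code{\link{readRadiometricJPEG}} decodes. Counts are
#' stored at full 16-bit depth (values must be integers in [0, 65535]).
#'
#' @param frame a \linkS4class{RadiometricFrame} (integer-valued counts).
#' @param vis visible image matrix/array in [0, 1], or NULL.
#' @param params a \linkS4class{RadiometricParams}.
#' @param meta an \linkS4class{AcquisitionMeta}.
#' @param path output file path.
#' @param payload "raw" (default) or "png" radiometric payload dialect.
#' @param byteOrder "little" or "big" (raw dialect only).
#' @return the path, invisibly.
#' @export
writeFixtureContainer <- function(frame, vis, params, meta, path,
                                  payload = c("raw", "png"),
                                  byteOrder = c("little", "big")) {
  payload <- match.arg(payload)
  byteOrder <- match.arg(byteOrder)
  thrm <- if (payload == "raw") writeRaw16(frame@counts, byteOrder)
          else writePNG16(frame@counts)
  prms <- charToRaw(as.character(toJSON(list(
    params = paramsToList(params),
    meta = list(distanceM = meta@distanceM, airTempC = meta@airTempC,
                relHumidity = meta@relHumidity, label = meta@label,
                datetime = meta@datetime, extra = meta@extra),
    timestamp = frame@timestamp, cameraId = frame@cameraId),
    auto_unbox = TRUE, digits = I(17))))  # 17 significant digits: doubles
                                          # survive the trip bit-exactly
  body <- c(tlv("PRMS", prms), tlv("THRM", thrm))
  if (!is.null(vis))
    body <- c(body, tlv("VISP", writePNG(vis)))
  ## chunk into APP1 segments
  chunkSize <- 60000L
  nChunks <- max(1L, ceiling(length(body) / chunkSize))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xFF, 0xD8)), con)                      # SOI
  for (k in seq_len(nChunks)) {
    part <- body[((k - 1L) * chunkSize + 1L):min(length(body),
                                                 k * chunkSize)]
    seg <- c(APP1_VENDOR, as.raw(c(k - 1L, nChunks)), part)
    writeBin(as.raw(c(0xFF, 0xE1)), con)
    writeBin(u16be(length(seg) + 2L), con)
    writeBin(seg, con)
  }
  writeBin(as.raw(c(0xFF, 0xD9)), con)                      # EOI
  invisible(path)
}

#' Write a plain (non-radiometric) JPEG stub
#'
#' Minimal JPEG marker stream without any radiometric payload; used as
#' the negative fixture for the decoder.
#'
#' @param path output path.
#' @export
writePlainJpegStub <- function(path) {
  con <- file(path, "wb")
  on.exit(close(con))
  jfif <- c(charToRaw("JFIF"), as.raw(c(0, 1, 1, 0, 0, 1, 0, 1, 0, 0)))
  writeBin(as.raw(c(0xFF, 0xD8, 0xFF, 0xE0)), con)
  writeBin(u16be(length(jfif) + 2L), con)
  writeBin(jfif, con)
  writeBin(as.raw(c(0xFF, 0xD9)), con)
  invisible(path)
}

#' Decode a radiometric camera container
#'
#' Parses the JPEG marker stream, reassembles the vendor APP1 payload,
#' and decodes: counts at full 16-bit depth with byte order normalized to
#' the host (raw block) or via the embedded 16-bit PNG; every
#' \linkS4class{RadiometricParams} field from the metadata; the visible
#' image at native resolution. Files without a radiometric payload raise
#' a "non-radiometric image" error; Planck tags without a documented
#' default raise an "incomplete metadata" error naming the tag. Window
#' and reflected temperatures missing from the metadata default to the
#' ambient air temperature (standard reflected-temperature practice),
#' recorded in the returned meta's escrow.
#'
#' @param path file path.
#' @return list with \code{frame} (\linkS4class{RadiometricFrame}),
#'   \code{vis} (matrix or NULL), \code{params}
#'   (\linkS4class{RadiometricParams}), \code{meta}
#'   (\linkS4class{AcquisitionMeta}).
#' @export
readRadiometricJPEG <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 4L ||
      !identical(bytes[1:2], as.raw(c(0xFF, 0xD8))))
    stop("non-radiometric image: not a JPEG stream")
  ## walk the marker segments, collecting vendor APP1 chunks
  i <- 3L
  chunks <- list()
  n <- length(bytes)
  while (i + 3L <= n) {
    if (bytes[i] != as.raw(0xFF)) break
    marker <- bytes[i + 1L]
    if (marker == as.raw(0xD9)) break       # EOI
    len <- rdU16be(bytes, i + 2L)
    segStart <- i + 4L
    segEnd <- i + 1L + len
    if (marker == as.raw(0xE1) && segEnd <= n &&
        segEnd - segStart + 1L >= 8L &&
        identical(bytes[segStart:(segStart + 5L)], APP1_VENDOR)) {
      idx <- as.integer(bytes[segStart + 6L])
      chunks[[idx + 1L]] <- bytes[(segStart + 8L):segEnd]
    }
    i <- segEnd + 1L
  }
  if (length(chunks) == 0L)
    stop("non-radiometric image: no radiometric payload found")
  body <- do.call(c, chunks)
  rec <- parseTlv(body)
  if (is.null(rec$THRM))
    stop("non-radiometric image: payload lacks a thermal record")
  countsM <- if (identical(rec$THRM[1:4], RAW16_MAGIC)) {
    readRaw16(rec$THRM)
  } else if (identical(rec$THRM[1:4],
                       as.raw(c(0x89, 0x50, 0x4E, 0x47)))) {
    round(readPNG(rec$THRM) * 65535)
  } else stop("unrecognized thermal payload dialect")
  if (is.null(rec$PRMS)) stop("incomplete metadata: missing PRMS record")
  info <- fromJSON(rawToChar(rec$PRMS), simplifyVector = TRUE)
  p <- lapply(info$params, function(v) if (is.character(v)) v
              else as.numeric(v))
  for (tag in c("PB", "PR1", "PR2", "PO", "PF"))
    if (is.null(p[[tag]]))
      stop("incomplete metadata: missing Planck tag ", tag)
  defaults <- list(emissivity = 0.98, Wt = 1, Xatm = 1.9,
                   alpha1 = 0.006569, alpha2 = 0.01262,
                   beta1 = -0.002276, beta2 = -0.00667,
                   distanceM = 0.5, TaC = 22, RH = 0.5,
                   atmFormula = "sqrt")
  for (tag in names(defaults))
    if (is.null(p[[tag]])) p[[tag]] <- defaults[[tag]]
  extra <- info$meta$extra
  if (is.null(extra)) extra <- list()
  ## reflected/window temperatures fall back to ambient, logged in escrow
  if (is.null(p$TwK)) {
    p$TwK <- p$TaC + 273.15
    extra$TwK_defaulted <- "ambient"
  }
  if (is.null(p$TrK)) {
    p$TrK <- p$TaC + 273.15
    extra$TrK_defaulted <- "ambient"
  }
  params <- paramsFromList(p)
  meta <- AcquisitionMeta(
    distanceM = info$meta$distanceM %||% 0.5,
    airTempC = info$meta$airTempC %||% p$TaC,
    relHumidity = info$meta$relHumidity %||% p$RH,
    label = info$meta$label %||% "unlabelled",
    datetime = info$meta$datetime %||% "",
    extra = as.list(extra))
  vis <- if (!is.null(rec$VISP)) readPNG(rec$VISP) else NULL
  list(frame = RadiometricFrame(countsM,
                                timestamp = info$timestamp %||% 0,
                                cameraId = info$cameraId %||% "unknown"),
       vis = vis, params = params, meta = meta)
}
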