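smallFrame <- function() {
  set.seed(17)
  RadiometricFrame(matrix(sample(0:65535, 20 * 30, replace = TRUE), 20, 30),
                   timestamp = 1000, cameraId = "ioTest")
}

test_that("decoder round-trips parameters bit-exactly (both dialects)", {
  fr <- smallFrame()
  p <- radiometricParams(PB = 1428, PR1 = 17096, PR2 = 0.046352,
                         PO = -7432, TaC = 22.4, RH = 0.58)
  meta <- AcquisitionMeta(distanceM = 0.5, airTempC = 22.4,
                          relHumidity = 0.58, label = "pt-007",
                          datetime = "2026-02-03T10:00:00")
  for (payload in c("raw", "png")) for (bo in c("little", "big")) {
    if (payload == "png" && bo == "big") next
    f <- tempfile(fileext = ".jpg")
    writeFixtureContainer(fr, NULL, p, meta, f, payload = payload,
                          byteOrder = bo)
    r <- readRadiometricJPEG(f)
    expect_equal(r$frame@counts, fr@counts, ignore_attr = TRUE)
    for (s in c("PB", "PR1", "PR2", "PO", "PF", "emissivity", "Wt",
                "Xatm", "alpha1", "alpha2", "beta1", "beta2", "TaC",
                "TwK", "TrK", "RH"))
      expect_identical(slot(r$params, s), slot(p, s))
    expect_identical(r$meta@label, "pt-007")
    expect_identical(r$frame@timestamp, 1000)
    # rereading leaves the file untouched (idempotent, side-effect free)
    before <- readBin(f, raw(), file.size(f))
    invisible(readRadiometricJPEG(f))
    expect_identical(readBin(f, raw(), file.size(f)), before)
  }
})

# same-length byte substitution (keeps every segment/record length valid)
rawRename <- function(path, from, to) {
  stopifnot(nchar(from) == nchar(to))
  bytes <- readBin(path, raw(), file.size(path))
  pat <- charToRaw(from)
  hits <- which(bytes == pat[1])
  for (i in hits) {
    if (i + length(pat) - 1 <= length(bytes) &&
        identical(bytes[i:(i + length(pat) - 1)], pat)) {
      bytes[i:(i + length(pat) - 1)] <- charToRaw(to)
    }
  }
  writeBin(bytes, path)
}

test_that("non-radiometric and incomplete files produce named errors", {
  f <- tempfile(fileext = ".jpg")
  writePlainJpegStub(f)
  expect_error(readRadiometricJPEG(f), "non-radiometric")
  expect_error(readRadiometricJPEG(tempfile()), "not found")
  # a payload whose JSON record lacks a Planck tag names the tag
  fr <- smallFrame()
  p <- radiometricParams()
  f2 <- tempfile(fileext = ".jpg")
  writeFixtureContainer(fr, NULL, p, AcquisitionMeta(), f2)
  rawRename(f2, '"PR1":', '"PRx":')
  expect_error(readRadiometricJPEG(f2), "PR1")
})

test_that("missing window/reflected temperatures default to ambient", {
  fr <- smallFrame()
  p <- radiometricParams(TaC = 24)
  f <- tempfile(fileext = ".jpg")
  writeFixtureContainer(fr, NULL, p, AcquisitionMeta(airTempC = 24), f)
  rawRename(f, '"TwK":', '"TwX":')
  rawRename(f, '"TrK":', '"TrX":')
  r <- readRadiometricJPEG(f)
  expect_equal(r$params@TwK, 24 + 273.15)
  expect_equal(r$params@TrK, 24 + 273.15)
  expect_equal(r$meta@extra$TwK_defaulted, "ambient")
})

test_that("raster I/O: counts and scaled float TIFFs round-trip", {
  set.seed(18)
  counts <- matrix(sample(0:65535, 600, replace = TRUE), 20, 30)
  f <- tempfile(fileext = ".tiff")
  writeCountsTIFF(counts, f)
  expect_equal(readCountsTIFF(f), counts, ignore_attr = TRUE)
  tm <- matrix(runif(600, -5, 42), 20, 30)
  f2 <- tempfile(fileext = ".tiff")
  writeScaledTIFF(tm, f2, role = "temperature_degC")
  expect_equal(readScaledTIFF(f2), tm, tolerance = 1e-5,
               ignore_attr = TRUE)
  g <- makeGain(shape = c(20, 30), amplitude = 0.1, seed = 6)
  f3 <- tempfile(fileext = ".tiff")
  writeGainTIFF(g, f3)
  g2 <- readGainTIFF(f3)
  expect_equal(g2@values, g@values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(g2@normalizer, g@normalizer)
})

test_that("records: validation, append-only provenance, JSON round trip", {
  meta <- AcquisitionMeta(distanceM = 0.5, airTempC = 22, relHumidity = 0.6,
                          label = "pt-1", datetime = "2026-01-01T08:00:00")
  p <- radiometricParams()
  rec <- initRecord(meta, p)
  expect_length(provenance(rec), 0)
  expect_error(initRecord(AcquisitionMeta(relHumidity = 1.3), p),
               "relHumidity")
  expect_error(initRecord(AcquisitionMeta(distanceM = -1), p), "distanceM")
  rec <- appendStep(rec, "vignetting",
                    list(sigma = 4, qlo = 0.02, qhi = 0.98))
  rec <- appendStep(rec, "temperature", list(atmFormula = "sqrt"))
  expect_length(provenance(rec), 2)
  expect_equal(provenance(rec)[[1]]$name, "vignetting")
  expect_equal(provenance(rec)[[1]]$parameters$sigma, 4)
  expect_equal(provenance(rec)[[2]]$name, "temperature")
  rec <- addArtifact(rec, "raw", "raw.tiff")
  expect_error(addArtifact(rec, "other", "raw.tiff"), "unique")
  f <- tempfile(fileext = ".json")
  writeRecord(rec, f)
  back <- readRecord(f)
  expect_equal(back@meta@label, "pt-1")
  expect_equal(back@meta@relHumidity, 0.6)
  expect_equal(back@params@PB, p@PB)
  expect_length(provenance(back), 2)
  expect_equal(provenance(back)[[1]]$parameters$qhi, 0.98)
  expect_equal(unname(artifacts(back)["raw"]), "raw.tiff")
})
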