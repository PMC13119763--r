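## Patient processing record: append-only provenance, artifact registry,
## and lossless JSON (de)serialization. The record is a JSON sidecar (no
## DICOM: the thermography modality lacks settled object definitions).

#' Initialize a patient record
#'
#' @param meta an \linkS4class{AcquisitionMeta} (validated on
#'   construction).
#' @param params a \linkS4class{RadiometricParams}.
#' @return a \linkS4class{PatientRecord} with empty provenance.
#' @export
initRecord <- function(meta, params) {
  validObject(meta)
  validObject(params)
  new("PatientRecord", meta = meta, params = params,
      provenance = list(), artifacts = character(0))
}

#' Append a processing step to the provenance
#'
#' Prior entries are never touched; each descriptor carries the step name,
#' the parameters used (retrievable verbatim) and a timestamp.
#'
#' @param record a \linkS4class{PatientRecord}.
#' @param name step name (e.g. "vignetting").
#' @param parameters named list of the parameters the step used.
#' @param timestamp numeric; defaults to the current time.
#' @return the updated record.
#' @export
appendStep <- function(record, name, parameters = list(),
                       timestamp = as.numeric(Sys.time())) {
  step <- list(name = name, parameters = parameters, timestamp = timestamp)
  record@provenance <- c(record@provenance, list(step))
  record
}

#' Register an artifact path under a role
#'
#' @param record a \linkS4class{PatientRecord}.
#' @param role artifact role (raw/corrected/temperature/vis/registered/...).
#' @param path file path (must be unique within the record).
#' @return the updated record.
#' @export
addArtifact <- function(record, role, path) {
  a <- record@artifacts
  a[role] <- path
  record@artifacts <- a
  validObject(record)
  record
}

#' Write / read the patient record (JSON)
#'
#' Lossless round trip of meta, params, provenance and artifacts, with a
#' schema version.
#'
#' @param record a \linkS4class{PatientRecord}.
#' @param path .json path.
#' @return the path (writer) or a \linkS4class{PatientRecord} (reader).
#' @export
writeRecord <- function(record, path) {
  m <- record@meta
  write_json(list(
    schema_version = record@schemaVersion,
    meta = list(distanceM = m@distanceM, airTempC = m@airTempC,
                relHumidity = m@relHumidity, label = m@label,
                datetime = m@datetime, extra = m@extra),
    params = paramsToList(record@params),
    provenance = record@provenance,
    artifacts = as.list(record@artifacts)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRecord
#' @export
readRecord <- function(path) {
  x <- read_json(path, simplifyVector = FALSE)
  num <- function(v) if (is.null(v)) numeric(0) else as.numeric(v)
  meta <- AcquisitionMeta(
    distanceM = x$meta$distanceM, airTempC = x$meta$airTempC,
    relHumidity = x$meta$relHumidity, label = x$meta$label,
    datetime = x$meta$datetime, extra = x$meta$extra)
  params <- paramsFromList(lapply(x$params, function(v)
    if (is.character(v)) v else as.numeric(v)))
  prov <- lapply(x$provenance, function(s)
    list(name = s$name, parameters = s$parameters,
         timestamp = num(s$timestamp)))
  arts <- unlist(x$artifacts)
  if (is.null(arts)) arts <- character(0)
  new("PatientRecord", meta = meta, params = params, provenance = prov,
      artifacts = arts, schemaVersion = x$schema_version %||% "1")
}
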