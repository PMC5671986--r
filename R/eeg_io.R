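# EEG input/output: EDF/EDF+ reading and writing, delimited-text matrix
# containers with a JSON sidecar, and referencing conventions.
#
# The EDF reader supports the signal layout used by standard EDF and EDF+
# continuous files: 16-bit little-endian samples, per-signal digital to
# physical scaling, and annotation channels (label "EDF Annotations")
# which are skipped when building the data matrix.

.EDF_ANNOT_LABEL <- "EDF Annotations"

.trimField <- function(x) sub("[[:space:]]+$", "", sub("^[[:space:]]+", "", x))

.readAscii <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  if (length(raw) < n) stop("unexpected end of file: corrupt EDF header")
  rawToChar(raw)
}

.splitFields <- function(s, width, ns) {
  vapply(seq_len(ns), function(i) {
    .trimField(substr(s, (i - 1L) * width + 1L, i * width))
  }, character(1L))
}

# Format a number into a fixed-width ASCII EDF header field.
.edfNumField <- function(x, width) {
  for (digits in seq(width - 1L, 1L)) {
    s <- formatC(x, digits = digits, format = "g", flag = "-")
    s <- .trimField(s)
    if (nchar(s) <= width) return(formatC(s, width = -width))
  }
  stop("value does not fit in EDF header field: ", x)
}

.edfTextField <- function(s, width) {
  s <- substr(s, 1L, width)
  formatC(s, width = -width)
}

#' Read an EDF/EDF+ file into an EEGRecording
#'
#' Parses the EDF header, applies the digital-to-physical scaling of each
#' signal, and drops annotation/event channels (label `"EDF Annotations"`)
#' from the data matrix. The sampling rate is taken from the file header
#' (samples per record / record duration) and must be identical across
#' signal channels.
#'
#' @param path path to an EDF or EDF+ file.
#' @param subjectID,condition optional metadata tags attached to the
#'   returned recording.
#' @return an [EEGRecording-class] with `reference = "as_recorded"`.
#' @seealso [writeEDF()] for the matching writer, [readMatrix()] for the
#'   plain-text container.
#' @export
readEDF <- function(path, subjectID = "unknown", condition = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  version <- .trimField(.readAscii(con, 8L))
  if (!identical(version, "0")) {
    stop("not an EDF file (unsupported version field): ", path)
  }
  .readAscii(con, 80L)                       # patient id
  .readAscii(con, 80L)                       # recording id
  .readAscii(con, 8L); .readAscii(con, 8L)   # start date / time
  headerBytes <- suppressWarnings(as.integer(.trimField(.readAscii(con, 8L))))
  .readAscii(con, 44L)                       # reserved ("EDF+C" etc.)
  nRecords <- suppressWarnings(as.integer(.trimField(.readAscii(con, 8L))))
  recDuration <- suppressWarnings(as.numeric(.trimField(.readAscii(con, 8L))))
  ns <- suppressWarnings(as.integer(.trimField(.readAscii(con, 4L))))
  if (is.na(ns) || ns < 1L || is.na(headerBytes) || is.na(recDuration)) {
    stop("corrupt EDF header: ", path)
  }

  labels <- .splitFields(.readAscii(con, 16L * ns), 16L, ns)
  .readAscii(con, 80L * ns)                  # transducer
  .readAscii(con, 8L * ns)                   # physical dimension
  physMin <- as.numeric(.splitFields(.readAscii(con, 8L * ns), 8L, ns))
  physMax <- as.numeric(.splitFields(.readAscii(con, 8L * ns), 8L, ns))
  digMin <- as.numeric(.splitFields(.readAscii(con, 8L * ns), 8L, ns))
  digMax <- as.numeric(.splitFields(.readAscii(con, 8L * ns), 8L, ns))
  .readAscii(con, 80L * ns)                  # prefiltering
  spr <- as.integer(.splitFields(.readAscii(con, 8L * ns), 8L, ns))
  .readAscii(con, 32L * ns)                  # reserved

  if (any(is.na(spr)) || any(spr < 1L)) stop("corrupt EDF header: ", path)
  isAnnot <- labels == .EDF_ANNOT_LABEL
  if (all(isAnnot)) {
    stop("empty input: EDF file contains no signal channels (only annotations)")
  }

  if (is.na(nRecords) || nRecords < 0L) {
    # unknown record count: infer from file size
    dataBytes <- file.info(path)$size - headerBytes
    nRecords <- as.integer(dataBytes / (2L * sum(spr)))
  }

  sigIdx <- which(!isAnnot)
  if (any(digMax[sigIdx] == digMin[sigIdx])) {
    stop("corrupt EDF header: zero digital range")
  }
  sfreqs <- spr[sigIdx] / recDuration
  if (length(unique(sfreqs)) != 1L) {
    stop("signal channels have differing sampling rates; not supported")
  }

  samples <- readBin(con, "integer", n = sum(spr) * nRecords, size = 2L,
                     endian = "little", signed = TRUE)
  if (length(samples) < sum(spr) * nRecords) {
    stop("corrupt EDF file: truncated data records")
  }

  scl <- (physMax - physMin) / (digMax - digMin)
  data <- matrix(0, nrow = length(sigIdx), ncol = spr[sigIdx[1L]] * nRecords)
  offsets <- c(0L, cumsum(spr))
  for (r in seq_len(nRecords)) {
    base <- (r - 1L) * sum(spr)
    for (ci in seq_along(sigIdx)) {
      s <- sigIdx[ci]
      dig <- samples[(base + offsets[s] + 1L):(base + offsets[s] + spr[s])]
      data[ci, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (dig - digMin[s]) * scl[s] + physMin[s]
    }
  }
  EEGRecording(data, sfreq = sfreqs[1L], channelNames = labels[sigIdx],
               subjectID = subjectID, condition = condition,
               reference = "as_recorded")
}

#' Write an EEGRecording to an EDF file
#'
#' Writes a single-data-record EDF file with 16-bit samples. The physical
#' range of each channel is taken from the data, so the round trip through
#' [readEDF()] is exact up to the 16-bit quantization of the container
#' (exact for integer-valued data within the digital range).
#'
#' @param rec an [EEGRecording-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  X <- rec@data
  nc <- nrow(X)
  Tn <- ncol(X)

  digMin <- -32767; digMax <- 32767
  physMin <- apply(X, 1L, min)
  physMax <- apply(X, 1L, max)
  flat <- physMax - physMin < .Machine$double.eps
  physMax[flat] <- physMin[flat] + 1
  # integer-valued channels get an identity mapping for exact round trips
  isInt <- apply(X, 1L, function(v) all(v == round(v)) &&
                   min(v) >= digMin && max(v) <= digMax)
  physMin[isInt] <- digMin
  physMax[isInt] <- digMax

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s) writeBin(charToRaw(s), con)

  headerBytes <- 256L + 256L * nc
  wr(.edfTextField("0", 8L))
  wr(.edfTextField(rec@subjectID, 80L))
  wr(.edfTextField(paste("Startdate 01-JAN-2000", rec@condition), 80L))
  wr(.edfTextField("01.01.00", 8L))
  wr(.edfTextField("00.00.00", 8L))
  wr(.edfNumField(headerBytes, 8L))
  wr(.edfTextField("", 44L))
  wr(.edfNumField(1L, 8L))                       # one data record
  wr(.edfNumField(Tn / rec@sfreq, 8L))           # record duration (s)
  wr(.edfNumField(nc, 4L))

  for (ch in rec@channelNames) wr(.edfTextField(ch, 16L))
  for (i in seq_len(nc)) wr(.edfTextField("", 80L))
  for (i in seq_len(nc)) wr(.edfTextField("uV", 8L))
  for (i in seq_len(nc)) wr(.edfNumField(physMin[i], 8L))
  for (i in seq_len(nc)) wr(.edfNumField(physMax[i], 8L))
  for (i in seq_len(nc)) wr(.edfNumField(digMin, 8L))
  for (i in seq_len(nc)) wr(.edfNumField(digMax, 8L))
  for (i in seq_len(nc)) wr(.edfTextField("", 80L))
  for (i in seq_len(nc)) wr(.edfNumField(Tn, 8L))
  for (i in seq_len(nc)) wr(.edfTextField("", 32L))

  # header fields are re-read before scaling so that writer/reader use
  # identical (8-character) physical ranges
  pMin <- as.numeric(.trimField(vapply(physMin, .edfNumField, "", width = 8L)))
  pMax <- as.numeric(.trimField(vapply(physMax, .edfNumField, "", width = 8L)))
  for (i in seq_len(nc)) {
    scl <- (pMax[i] - pMin[i]) / (digMax - digMin)
    dig <- round((X[i, ] - pMin[i]) / scl + digMin)
    dig <- as.integer(pmin(pmax(dig, digMin), digMax))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' that each column of the data matrix has zero mean. The global field
#' power is invariant under this operation; it is applied as the package's
#' internal convention. Idempotent.
#'
#' @param rec an [EEGRecording-class] with at least 2 channels.
#' @return the re-referenced [EEGRecording-class] (`reference = "average"`).
#' @export
rereferenceAverage <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  X <- rec@data
  if (nrow(X) < 2L) stop("average reference requires at least 2 channels")
  X <- sweep(X, 2L, colMeans(X))
  initialize(rec, data = X, reference = "average")
}

.sidecarPath <- function(path) paste0(path, ".json")

#' Write an EEGRecording to a delimited-text container
#'
#' The data matrix is written as CSV (channels as rows, first column the
#' channel name) with a JSON sidecar (`<path>.json`) holding the sampling
#' rate and metadata, so the round trip through [readMatrix()] is lossless
#' up to the printed precision (15 significant digits).
#'
#' @param rec an [EEGRecording-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  df <- data.frame(channel = rec@channelNames,
                   format(rec@data, digits = 15, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("channel", paste0("t", seq_len(ncol(rec@data))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(sfreq = rec@sfreq, channel_names = rec@channelNames,
               subject_id = rec@subjectID, condition = rec@condition,
               reference = rec@reference)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an EEGRecording from a delimited-text container
#'
#' Reads a CSV written by [writeMatrix()] (channels as rows). Metadata is
#' taken from the JSON sidecar when present; `sfreq` and `channelNames`
#' arguments override/supply it otherwise.
#'
#' @param path CSV path.
#' @param sfreq sampling rate in Hz (required if no sidecar is present).
#' @param channelNames expected channel names; validated against the file.
#' @return an [EEGRecording-class].
#' @export
readMatrix <- function(path, sfreq = NULL, channelNames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"channel" %in% names(df)) stop("malformed matrix file: ", path)
  fileNames <- as.character(df$channel)
  X <- as.matrix(df[, setdiff(names(df), "channel"), drop = FALSE])
  storage.mode(X) <- "double"

  meta <- NULL
  if (file.exists(.sidecarPath(path))) {
    meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  }
  if (is.null(sfreq)) sfreq <- meta$sfreq
  if (is.null(sfreq)) stop("sfreq not given and no JSON sidecar found")
  if (!is.null(channelNames)) {
    if (length(channelNames) != nrow(X)) {
      stop("channelNames length (", length(channelNames),
           ") does not match the number of rows (", nrow(X), ")")
    }
    if (!identical(as.character(channelNames), fileNames)) {
      stop("channel name mismatch between file and supplied channelNames")
    }
  }
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite values in matrix file at [channel,timepoint]: ",
         paste(sprintf("[%d,%d]", bad[, 1L], bad[, 2L]), collapse = " "))
  }
  EEGRecording(X, sfreq = sfreq, channelNames = fileNames,
               subjectID = if (!is.null(meta$subject_id)) meta$subject_id
                           else "unknown",
               condition = if (!is.null(meta$condition)) meta$condition
                           else "unknown",
               reference = if (!is.null(meta$reference)) meta$reference
                           else "as_recorded")
}
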