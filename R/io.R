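## Recording input/output.
##
## Two on-disk representations are supported:
##  * a minimal WFDB-compatible subset: a text header <record>.hea, a
##    16-bit little-endian signal file <record>.dat (format 16, single
##    signal) and a plain-text per-minute annotation file <record>.apn
##    with one N/A symbol per line (a text rendering of the apnea
##    annotation convention; the binary MIT annotation format is not
##    implemented);
##  * a CSV fallback: <record>.csv with a single `sample_value` column
##    and the same text annotation file.
## Amplitudes are stored with the header's gain (ADC units per mV) and
## returned in mV; synthetic data round-trips within quantization.

.WFDB_GAIN <- 200       # ADC units per mV, the Apnea-ECG convention
.WFDB_FMT <- 16L

#' Read an ECG recording with per-minute apnea annotations
#'
#' Reads a WFDB-style record (pass the `.hea` header path) or a CSV
#' fallback (pass a `.csv` with one `sample_value` column), plus a text
#' annotation file holding one `N`/`A` symbol per minute. Annotation
#' `i` is aligned to the half-open sample window
#' `[(i-1)*60*fs, i*60*fs)`; any trailing partial minute of signal is
#' discarded. A sampling rate other than 100 Hz triggers a warning
#' (the classifier expects 6000-sample minutes); no resampling is
#' performed.
#'
#' @param signalPath path to `<record>.hea` (WFDB-style) or
#'   `<record>.csv` (fallback).
#' @param annotationPath path to the annotation file; defaults to
#'   `<record>.apn` next to the signal file.
#' @param referenceAhi optional reference AHI to attach.
#' @return An [ECGRecording-class].
#' @seealso [writeRecording()]
#' @export
readRecording <- function(signalPath, annotationPath = NULL,
                          referenceAhi = NA_real_) {
  if (!file.exists(signalPath))
    stop("signal file not found: ", signalPath)
  base <- sub("\\.[^.]+$", "", signalPath)
  if (is.null(annotationPath)) annotationPath <- paste0(base, ".apn")
  if (!file.exists(annotationPath))
    stop("annotation file not found: ", annotationPath)

  ext <- tolower(tools::file_ext(signalPath))
  if (ext == "hea") {
    hdr <- .readHeader(signalPath)
    datPath <- file.path(dirname(signalPath), hdr$fileName)
    if (!file.exists(datPath)) stop("signal file not found: ", datPath)
    raw <- readBin(datPath, what = "integer", size = 2L,
                   n = hdr$nSamples, endian = "little", signed = TRUE)
    if (length(raw) < hdr$nSamples)
      stop("signal file shorter than header declares: ", datPath)
    signal <- (raw - hdr$baseline) / hdr$gain
    fs <- hdr$fs
    id <- hdr$recordId
  } else if (ext == "csv") {
    tab <- utils::read.csv(signalPath)
    if (!"sample_value" %in% names(tab))
      stop("CSV fallback requires a 'sample_value' column: ", signalPath)
    signal <- as.numeric(tab$sample_value)
    fs <- 100
    id <- basename(base)
  } else {
    stop("unrecognised signal file extension '", ext,
         "' (expected .hea or .csv)")
  }

  if (fs != 100)
    warning(sprintf(
      "record %s: sampling rate is %g Hz, not the expected 100 Hz; not resampling",
      id, fs))

  labels <- .readAnnotations(annotationPath)
  ECGRecording(id, fs, signal, labels, referenceAhi)
}

#' Write an ECG recording with per-minute apnea annotations
#'
#' Emits either a WFDB-compatible pair (`<id>.hea` text header plus
#' `<id>.dat` 16-bit little-endian samples, gain 200 ADC units/mV) or a
#' CSV fallback (`<id>.csv` with a `sample_value` column), plus in both
#' cases a text annotation file `<id>.apn` with one symbol per minute.
#' Output is readable by [readRecording()].
#'
#' @param rec an [ECGRecording-class] with at least one whole minute of
#'   signal.
#' @param outDir output directory (created if missing).
#' @param format `"wfdb"` or `"csv"`.
#' @return Invisibly, a named character vector of the file paths
#'   written.
#' @export
writeRecording <- function(rec, outDir, format = c("wfdb", "csv")) {
  stopifnot(is(rec, "ECGRecording"))
  format <- match.arg(format)
  if (length(rec@signal) == 0L)
    stop("refusing to write an empty recording: ", rec@recordId)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)

  id <- rec@recordId
  apnPath <- file.path(outDir, paste0(id, ".apn"))
  writeLines(rec@minuteLabels, apnPath)

  if (format == "wfdb") {
    datPath <- file.path(outDir, paste0(id, ".dat"))
    heaPath <- file.path(outDir, paste0(id, ".hea"))
    adc <- as.integer(pmax(pmin(round(rec@signal * .WFDB_GAIN),
                                32767), -32768))
    writeBin(adc, datPath, size = 2L, endian = "little")
    writeLines(c(
      sprintf("%s 1 %g %d", id, rec@fs, length(adc)),
      sprintf("%s.dat %d %d 16 0 %d 0 0 ECG",
              id, .WFDB_FMT, .WFDB_GAIN, adc[1L])
    ), heaPath)
    out <- c(header = heaPath, signal = datPath, annotation = apnPath)
  } else {
    csvPath <- file.path(outDir, paste0(id, ".csv"))
    utils::write.csv(data.frame(sample_value = rec@signal), csvPath,
                     row.names = FALSE)
    out <- c(signal = csvPath, annotation = apnPath)
  }
  invisible(out)
}

#' Write a synthetic cohort to disk
#'
#' Writes each recording of a cohort with [writeRecording()] and a
#' `truth.csv` table (record_id, minute, label, reference_ahi).
#'
#' @param cohort a list of [ECGRecording-class] objects (e.g. from
#'   [generateCohort()]).
#' @param outDir output directory.
#' @param format passed to [writeRecording()].
#' @return Invisibly, the path of the truth table.
#' @export
writeCohort <- function(cohort, outDir, format = c("wfdb", "csv")) {
  format <- match.arg(format)
  truth <- do.call(rbind, lapply(cohort, function(rec) {
    writeRecording(rec, outDir, format)
    data.frame(record_id = recordId(rec),
               minute = seq_along(minuteLabels(rec)) - 1L,
               label = minuteLabels(rec),
               reference_ahi = referenceAhi(rec))
  }))
  truthPath <- file.path(outDir, "truth.csv")
  utils::write.csv(truth, truthPath, row.names = FALSE)
  invisible(truthPath)
}

#' Read every recording in a directory
#'
#' Scans `dir` for `.hea` (or, failing that, `.csv`) files and reads
#' each with [readRecording()]. Reference AHI values are attached from
#' a `truth.csv` if one is present.
#'
#' @param dir directory containing record files.
#' @return A list of [ECGRecording-class] objects, named by record id.
#' @export
readCohort <- function(dir) {
  heas <- list.files(dir, pattern = "\\.hea$", full.names = TRUE)
  if (!length(heas))
    heas <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  heas <- heas[basename(heas) != "truth.csv"]
  if (!length(heas)) stop("no .hea or .csv records found in ", dir)
  truthPath <- file.path(dir, "truth.csv")
  ref <- NULL
  if (file.exists(truthPath)) {
    tr <- utils::read.csv(truthPath)
    ref <- tapply(tr$reference_ahi, tr$record_id, function(x) x[1L])
  }
  recs <- lapply(heas, function(p) {
    id <- sub("\\.[^.]+$", "", basename(p))
    readRecording(p, referenceAhi =
                    if (!is.null(ref) && id %in% names(ref))
                      unname(ref[id]) else NA_real_)
  })
  names(recs) <- vapply(recs, recordId, character(1))
  recs
}

.readHeader <- function(heaPath) {
  lines <- readLines(heaPath, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("malformed header: ", heaPath)
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  sig <- strsplit(trimws(lines[2L]), "\\s+")[[1L]]
  if (length(top) < 4L || length(sig) < 3L)
    stop("malformed header: ", heaPath)
  fmt <- as.integer(sub("x.*$", "", sig[2L]))
  if (!identical(fmt, .WFDB_FMT))
    stop("unsupported WFDB signal format ", sig[2L], " in ", heaPath,
         " (only format 16 is supported)")
  gain <- as.numeric(sub("\\(.*", "", sig[3L]))
  if (!is.finite(gain) || gain == 0) gain <- .WFDB_GAIN
  baseline <- 0
  if (grepl("\\(", sig[3L]))
    baseline <- as.numeric(sub(".*\\(([^)]*)\\).*", "\\1", sig[3L]))
  list(recordId = top[1L], fs = as.numeric(top[3L]),
       nSamples = as.integer(top[4L]), fileName = sig[1L],
       gain = gain, baseline = baseline)
}

.readAnnotations <- function(annotationPath) {
  labels <- trimws(readLines(annotationPath, warn = FALSE))
  labels <- labels[nzchar(labels)]
  bad <- setdiff(unique(labels), .APNEA_ALPHABET)
  if (length(bad))
    stop(sprintf("annotation symbol(s) outside {N, A} in %s: %s",
                 annotationPath, paste(bad, collapse = ", ")))
  labels
}
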