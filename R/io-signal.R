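#' Read a multichannel signal file
#'
#' Loads an intracranial recording from either an EDF file or a delimited
#' numeric matrix (channels as columns, one header row of channel labels).
#' Units are passed through unchanged. Channels containing NaN after load are
#' rejected as artifact channels (dropped with a warning) so that a valid
#' [EcogRecording-class] never carries missing samples.
#'
#' @param path path to the file.
#' @param format `"edf"` or `"delimited"`; `"auto"` (default) decides by file
#'   extension (`.edf` vs anything else).
#' @param rate sampling rate in Hz; required for delimited input, ignored for
#'   EDF (taken from the header).
#' @param sep field separator for delimited input (default `","`).
#' @return An [EcogRecording-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(A = sin(1:100), B = cos(1:100)), f, row.names = FALSE)
#' rec <- readSignal(f, rate = 1000)
#' @export
readSignal <- function(path, format = c("auto", "edf", "delimited"),
                       rate = NULL, sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("signal file not found: '%s'", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  raw <- if (format == "edf") readEdf(path) else {
    if (is.null(rate)) stopf("'rate' is required for delimited signal input")
    readDelimitedSignal(path, rate = rate, sep = sep)
  }
  bad <- apply(raw$mat, 1L, anyNA)
  if (any(bad)) {
    warnf("dropping %d channel(s) with NaN samples as artifact: %s",
          sum(bad), paste(raw$ids[bad], collapse = ", "))
    raw$mat <- raw$mat[!bad, , drop = FALSE]
    raw$ids <- raw$ids[!bad]
  }
  ecogRecording(raw$mat, rate = raw$rate, channelIds = raw$ids)
}

readDelimitedSignal <- function(path, rate, sep = ",") {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stopf("'rate' must be a single positive number")
  nf <- utils::count.fields(path, sep = sep)
  if (length(nf) < 2L) stopf("'%s' has no data rows", path)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stopf("ragged delimited file '%s': row %d has %d field(s), expected %d",
          path, bad, nf[bad], nf[1L])
  }
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         check.names = FALSE, colClasses = "numeric")
  list(mat = t(as.matrix(d)), rate = rate, ids = colnames(d))
}

trimAscii <- function(x) sub("\\s+$", "", sub("^\\s+", "", x))

## Minimal EDF/EDF+ reader: ASCII header, per-signal headers, little-endian
## int16 records rescaled to physical units. All signals must share one
## sampling rate; EDF+ annotation channels are skipped.
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readStr <- function(n) trimAscii(rawToChar(readBin(con, "raw", n)))
  readStr(8)                      # version
  readStr(80); readStr(80)        # patient / recording id
  readStr(8); readStr(8)          # start date / time
  headerBytes <- suppressWarnings(as.integer(readStr(8)))
  readStr(44)                     # reserved
  nRecords <- suppressWarnings(as.integer(readStr(8)))
  recDur <- suppressWarnings(as.numeric(readStr(8)))
  ns <- suppressWarnings(as.integer(readStr(4)))
  if (is.na(ns) || ns < 1L || is.na(nRecords) || is.na(recDur) ||
      is.na(headerBytes))
    stopf("'%s' does not have a valid EDF header", path)
  fld <- function(w) vapply(seq_len(ns), function(i) readStr(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)                 # transducer, physical dimension
  physMin <- as.numeric(fld(8)); physMax <- as.numeric(fld(8))
  digMin <- as.numeric(fld(8)); digMax <- as.numeric(fld(8))
  fld(80)                         # prefiltering
  spr <- as.integer(fld(8))       # samples per record, per signal
  fld(32)                         # reserved
  if (anyNA(c(physMin, physMax, digMin, digMax, spr)))
    stopf("'%s': malformed EDF signal headers", path)
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (!any(keep)) stopf("'%s' contains no data signals", path)
  if (length(unique(spr[keep])) != 1L)
    stopf("'%s': signals have differing sampling rates; not supported", path)
  if (recDur <= 0) stopf("'%s': non-positive record duration", path)
  rate <- spr[keep][1L] / recDur
  if (rate <= 0) stopf("'%s': non-positive sampling rate", path)

  seek(con, headerBytes)
  perRec <- sum(spr)
  raw <- readBin(con, "integer", n = perRec * nRecords, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < perRec * nRecords)
    stopf("'%s': truncated EDF data section", path)
  offs <- c(0L, cumsum(spr))
  out <- matrix(0, nrow = sum(keep), ncol = spr[keep][1L] * nRecords)
  scale <- (physMax - physMin) / (digMax - digMin)
  row <- 0L
  for (s in seq_len(ns)) {
    if (!keep[s]) next
    row <- row + 1L
    idx <- as.vector(outer(seq_len(spr[s]) + offs[s],
                           (seq_len(nRecords) - 1L) * perRec, `+`))
    out[row, ] <- physMin[s] + (raw[idx] - digMin[s]) * scale[s]
  }
  list(mat = out, rate = rate, ids = labels[keep])
}
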