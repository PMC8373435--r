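#' @include AllClasses.R
NULL

#' Construct an EEGRecording
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param rate sampling rate in Hz.
#' @param channels ordered channel names (defaults to rownames of
#'   \code{samples}).
#' @param participant participant identifier.
#' @param group group label: HC, MCI, AD or unknown.
#' @param run run index, 1 or 2.
#' @return an [EEGRecording-class] object.
#' @export
eegRecording <- function(samples, rate, channels = rownames(samples),
                         participant = "unknown", group = "unknown",
                         run = 1L) {
  samples <- as.matrix(samples)
  if (is.null(channels))
    channels <- paste0("CH", seq_len(nrow(samples)))
  storage.mode(samples) <- "double"
  rownames(samples) <- channels
  new("EEGRecording", participant = as.character(participant),
      group = as.character(group), run = as.integer(run),
      samples = samples, rate = as.numeric(rate),
      channels = as.character(channels))
}

#' Raw sample matrix of a recording
#'
#' @param rec an [EEGRecording-class].
#' @return channels x time numeric matrix in microvolts.
#' @export
recordingSamples <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  rec@samples
}

unitScaleToMicrovolts <- function(unit) {
  switch(tolower(trimws(unit)),
         "uv" = 1, "µv" = 1, "microvolt" = 1, "microvolts" = 1,
         "mv" = 1e3, "millivolt" = 1e3,
         "v" = 1e6, "volt" = 1e6,
         stop(sprintf("unrecognized amplitude unit '%s'", unit)))
}

#' Write a recording in the package array format
#'
#' The array format is a plain CSV sample matrix (one row per channel, no
#' header) plus a YAML sidecar \code{<base>.yaml} holding \code{rate_hz},
#' \code{channels}, \code{units} (always uV) and the participant metadata.
#'
#' @param rec an [EEGRecording-class].
#' @param base output path without extension; \code{<base>.csv} and
#'   \code{<base>.yaml} are written.
#' @param digits significant digits kept in the CSV (default 17,
#'   enough for a bit-exact double round trip).
#' @return \code{base}, invisibly.
#' @export
writeRecordingArray <- function(rec, base, digits = 17) {
  stopifnot(is(rec, "EEGRecording"))
  csv <- paste0(base, ".csv")
  con <- file(csv, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(rec@samples)))
    writeLines(paste(formatC(rec@samples[i, ], digits = digits,
                             format = "g"), collapse = ","), con)
  yaml::write_yaml(list(rate_hz = rec@rate,
                        channels = as.list(rec@channels),
                        units = "uV",
                        participant = rec@participant,
                        group = rec@group,
                        run = rec@run),
                   paste0(base, ".yaml"))
  invisible(base)
}

readRecordingArray <- function(base) {
  csv <- paste0(base, ".csv"); side <- paste0(base, ".yaml")
  if (!file.exists(csv)) stop(sprintf("sample file not found: %s", csv))
  if (!file.exists(side)) stop(sprintf("sidecar file not found: %s", side))
  meta <- yaml::read_yaml(side)
  if (is.null(meta$rate_hz) || !is.finite(as.numeric(meta$rate_hz)))
    stop(sprintf("unreadable sampling rate in %s", side))
  rows <- readLines(csv)
  samples <- do.call(rbind, lapply(strsplit(rows, ","), as.numeric))
  channels <- as.character(unlist(meta$channels))
  if (length(channels) != nrow(samples))
    stop(sprintf("sidecar lists %d channels but matrix has %d rows",
                 length(channels), nrow(samples)))
  scale <- unitScaleToMicrovolts(if (is.null(meta$units)) "uV" else meta$units)
  eegRecording(samples * scale, rate = as.numeric(meta$rate_hz),
               channels = channels,
               participant = if (is.null(meta$participant)) "unknown" else meta$participant,
               group = if (is.null(meta$group)) "unknown" else meta$group,
               run = if (is.null(meta$run)) 1L else as.integer(meta$run))
}

padTo <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as an EDF (European Data Format) file
#'
#' Minimal EDF writer: one data record spanning the whole recording, 16-bit
#' samples, physical range set per channel from the data.  EDF quantizes
#' amplitudes to 16 bits, so round trips are close but not bit-identical
#' (unlike the array format).
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  ns <- nrow(rec@samples); nsamp <- ncol(rec@samples)
  physMin <- apply(rec@samples, 1, min)
  physMax <- apply(rec@samples, 1, max)
  flat <- physMax - physMin < 1e-9
  physMin[flat] <- physMin[flat] - 1; physMax[flat] <- physMax[flat] + 1
  digMin <- -32768; digMax <- 32767
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- paste0(
    padTo("0", 8), padTo(rec@participant, 80),
    padTo(sprintf("run %d group %s", rec@run, rec@group), 80),
    padTo("01.01.20", 8), padTo("00.00.00", 8),
    padTo(256 * (1 + ns), 8), padTo("", 44), padTo(1, 8),
    padTo(format(nsamp / rec@rate, digits = 7), 8), padTo(ns, 4))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  fields <- list(
    vapply(rec@channels, padTo, "", width = 16),
    rep(padTo("", 80), ns),
    rep(padTo("uV", 8), ns),
    vapply(format(physMin, digits = 7), padTo, "", width = 8),
    vapply(format(physMax, digits = 7), padTo, "", width = 8),
    rep(padTo(digMin, 8), ns),
    rep(padTo(digMax, 8), ns),
    rep(padTo("", 80), ns),
    rep(padTo(nsamp, 8), ns),
    rep(padTo("", 32), ns))
  for (f in fields) {
    s <- paste(f, collapse = "")
    writeChar(s, con, nchars = nchar(s), eos = NULL)
  }
  for (i in seq_len(ns)) {
    dig <- round((rec@samples[i, ] - physMin[i]) /
                   (physMax[i] - physMin[i]) * (digMax - digMin) + digMin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

readAscii <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

#' Read an EDF (European Data Format) recording
#'
#' Supports plain EDF with identical sample counts per record and converts
#' physical units to microvolts (uV/mV/V dimensions recognized; anything
#' else is assumed to already be microvolts).
#'
#' @param path EDF file path.
#' @param participant,group,run metadata overrides; participant defaults to
#'   the EDF patient field.
#' @return an [EEGRecording-class] object.
#' @export
readEDF <- function(path, participant = NULL, group = "unknown", run = 1L) {
  if (!file.exists(path)) stop(sprintf("EDF file not found: %s", path))
  con <- file(path, open = "rb")
  on.exit(close(con))
  readAscii(con, 8)                      # version
  patient <- readAscii(con, 80)
  readAscii(con, 80); readAscii(con, 8); readAscii(con, 8)
  readAscii(con, 8); readAscii(con, 44)
  nRec <- as.integer(readAscii(con, 8))
  recDur <- as.numeric(readAscii(con, 8))
  ns <- as.integer(readAscii(con, 4))
  if (!is.finite(ns) || ns < 1) stop("unreadable EDF signal count")
  rd <- function(w) vapply(seq_len(ns), function(i) readAscii(con, w), "")
  labels <- rd(16); rd(80); physDim <- rd(8)
  physMin <- as.numeric(rd(8)); physMax <- as.numeric(rd(8))
  digMin <- as.numeric(rd(8)); digMax <- as.numeric(rd(8))
  rd(80); sampPerRec <- as.integer(rd(8)); rd(32)
  if (!is.finite(recDur) || recDur <= 0)
    stop("unreadable EDF record duration (cannot derive sampling rate)")
  if (length(unique(sampPerRec)) != 1L)
    stop("EDF files with per-signal sampling rates are not supported")
  nsamp <- sampPerRec[1]
  out <- matrix(0, nrow = ns, ncol = nsamp * nRec)
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp, size = 2, signed = TRUE,
                     endian = "little")
      phys <- physMin[i] + (dig - digMin[i]) /
        (digMax[i] - digMin[i]) * (physMax[i] - physMin[i])
      out[i, ((r - 1) * nsamp + 1):(r * nsamp)] <- phys
    }
  }
  scale <- vapply(physDim, function(u) {
    tryCatch(unitScaleToMicrovolts(u), error = function(e) 1)
  }, numeric(1))
  out <- out * scale
  eegRecording(out, rate = nsamp / recDur, channels = trimws(labels),
               participant = if (is.null(participant)) patient else participant,
               group = group, run = run)
}

#' Read a recording from EDF or the package array format
#'
#' Dispatches on the file extension: \code{.edf} goes to [readEDF()],
#' anything else is treated as an array-format base path (or its
#' \code{.csv}/\code{.yaml} component) and goes to the array reader.  When a
#' montage is supplied, all montage electrodes must be present among the
#' channels.
#'
#' @param path file path.
#' @param participant,group,run optional metadata overrides.
#' @param montage optional [ScalpMontage-class] used to validate channel
#'   coverage.
#' @return an [EEGRecording-class] object.
#' @export
readRecording <- function(path, participant = NULL, group = NULL, run = NULL,
                          montage = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    rec <- readEDF(path, participant = participant,
                   group = if (is.null(group)) "unknown" else group,
                   run = if (is.null(run)) 1L else as.integer(run))
  } else {
    base <- sub("\\.(csv|yaml)$", "", path)
    rec <- readRecordingArray(base)
    if (!is.null(participant)) rec@participant <- as.character(participant)
    if (!is.null(group)) rec@group <- as.character(group)
    if (!is.null(run)) rec@run <- as.integer(run)
    validObject(rec)
  }
  if (!is.null(montage)) {
    need <- montageElectrodes(montage)
    missing <- setdiff(need, rec@channels)
    if (length(missing) > 0L)
      stop(sprintf("recording is missing %d montage channel(s): %s",
                   length(missing), paste(missing, collapse = ", ")))
  }
  rec
}

#' Read or write a cohort manifest
#'
#' A manifest CSV has columns \code{participant}, \code{group}, \code{run1},
#' \code{run2}: one row per participant, with the source paths of the two
#' resting-state runs.
#'
#' @param path CSV path.
#' @param manifest data frame with the four columns above.
#' @return \code{readManifest}: the manifest data frame.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "group", "run1", "run2")
  if (!all(need %in% names(m)))
    stop(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")))
  bad <- setdiff(unique(m$group), GROUP_LEVELS)
  if (length(bad) > 0L)
    stop(sprintf("manifest has unknown group label(s): %s",
                 paste(bad, collapse = ", ")))
  if (anyDuplicated(m$participant))
    stop("manifest lists a participant more than once")
  m
}

#' @rdname readManifest
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
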