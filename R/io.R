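#' Write an EEG recording as EDF
#'
#' Minimal continuous European Data Format writer: one 1-second data
#' record per second of signal, identical physical scaling across
#' channels, 16-bit samples. The recording is truncated to a whole number
#' of seconds (with a message) when needed. Annotations are not written.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer fs")
  fs <- as.integer(round(fs))
  data <- recording$data
  ns <- nrow(data)
  nrec <- floor(ncol(data) / fs)
  if (nrec < 1) stop("recording shorter than one EDF record (1 s)")
  if (nrec * fs < ncol(data)) {
    message("truncating ", ncol(data) - nrec * fs,
            " trailing sample(s) to a whole number of EDF records")
    data <- data[, seq_len(nrec * fs), drop = FALSE]
  }
  pmax_ <- max(1, ceiling(max(abs(data))))
  dig <- round(data / pmax_ * 32767)
  pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.20", 8), pad("00.00.00", 8),
    pad(256L * (1L + ns), 8), pad("", 44), pad(nrec, 8), pad(1, 8),
    pad(ns, 4)), con, eos = NULL)
  writeChar(paste0(
    paste(pad(paste("EEG", recording$channel_labels), 16), collapse = ""),
    paste(rep(pad("AgAgCl electrode", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(rep(pad(-pmax_, 8), ns), collapse = ""),
    paste(rep(pad(pmax_, 8), ns), collapse = ""),
    paste(rep(pad(-32767L, 8), ns), collapse = ""),
    paste(rep(pad(32767L, 8), ns), collapse = ""),
    paste(rep(pad("HP:0.3Hz LP:30Hz", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")), con, eos = NULL)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG recording
#'
#' Counterpart of [write_edf()]: continuous 16-bit EDF with equal sampling
#' rates across signals; annotation channels are ignored. Channel labels
#' are mapped to the 10-20 set by stripping an `EEG` prefix and reference
#' suffixes.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rs <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rs(8)
  if (version != "0") stop("malformed EDF header: bad version field")
  rs(80); rs(80); rs(8); rs(8)
  hdr_bytes <- as.integer(rs(8)); rs(44)
  nrec <- as.integer(rs(8)); recdur <- as.numeric(rs(8))
  ns <- as.integer(rs(4))
  if (is.na(ns) || ns < 1 || is.na(nrec) || nrec < 1)
    stop("malformed EDF header: bad record counts")
  fld <- function(w) vapply(seq_len(ns), function(i) rs(w), character(1))
  labels <- fld(16); fld(80)
  fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr)))
    stop("malformed EDF header: non-numeric signal fields")
  keep <- !grepl("Annotations", labels)
  labels <- sub("^EEG[ _]*", "", labels)
  labels <- sub("-(A1|A2|Cz|REF|Ref)$", "", labels)
  if (length(unique(spr[keep])) != 1)
    stop("EDF reader requires equal sampling rates across signals")
  fs <- spr[keep][1] / recdur
  data <- matrix(0, sum(keep), nrec * spr[keep][1])
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                     signed = TRUE)
      if (!keep[i]) next
      j <- sum(keep[seq_len(i)])
      phys <- pmin_[i] + (raw - dmin[i]) * (pmax_[i] - pmin_[i]) /
        (dmax[i] - dmin[i])
      data[j, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  eeg_recording(data, fs, labels[keep])
}

#' Read an EEG matrix from CSV
#'
#' One column per channel; the header row carries the 10-20 labels.
#'
#' @param path CSV path.
#' @param fs sampling rate in Hz (CSV carries no rate metadata).
#' @return An [eeg_recording()].
#' @export
read_eeg_csv <- function(path, fs) {
  d <- read.csv(path, check.names = FALSE)
  eeg_recording(t(as.matrix(d)), fs, names(d))
}

#' @rdname read_eeg_csv
#' @param recording an [eeg_recording()] to write.
#' @export
write_eeg_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  d <- as.data.frame(t(recording$data))
  names(d) <- recording$channel_labels
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a TCD waveform from CSV
#'
#' Expects columns `time` (seconds, strictly increasing, uniform) and
#' `velocity` (cm/s).
#'
#' @param path CSV path.
#' @param side,depth waveform metadata, see [tcd_waveform()].
#' @return A [tcd_waveform()].
#' @export
read_waveform_csv <- function(path, side = "affected", depth = 55) {
  d <- read.csv(path)
  miss <- setdiff(c("time", "velocity"), names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  dt <- diff(d$time)
  if (any(dt <= 0)) stop("`time` must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt)) stop("`time` must be uniform")
  tcd_waveform(d$velocity, fs = 1 / mean(dt), side = side, depth = depth)
}

.COHORT_REQUIRED <- c("id", "gcs", "vessel", "event", "time")

#' Read a cohort table from CSV
#'
#' Validates the minimal data dictionary (`id`, `gcs`, `vessel`, `event`,
#' `time`) and coerces types; any further columns are kept as-is.
#'
#' @param path CSV path.
#' @return A data frame, one row per patient.
#' @export
read_cohort_csv <- function(path) {
  d <- read.csv(path)
  miss <- setdiff(.COHORT_REQUIRED, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  d$event <- as.logical(d$event)
  d$vessel <- factor(d$vessel, levels = intersect(
    c("proximal_ica", "tica", "mca"), unique(d$vessel)))
  if (any(!is.finite(d$time)) || any(d$time <= 0))
    stop("`time` must be positive and finite")
  d
}

#' @rdname read_cohort_csv
#' @param cohort cohort data frame to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
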