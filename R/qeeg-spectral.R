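#' EEG recording container
#'
#' Bundles a multichannel scalp EEG with its sampling rate and montage
#' metadata. Channels are rows of `data`; labels must be unique names from
#' the 16-channel International 10-20 set (Fp1, Fp2, F3, F4, F7, F8, C3, C4,
#' T3, T4, T5, T6, P3, P4, O1, O2).
#'
#' @param data numeric matrix of voltages in microvolts, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one 10-20 label per row of `data`.
#' @param reference reference electrode label (informational).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data),
                          reference = "Cz") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (is.null(channel_labels)) stop("channel labels are required")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("need one channel label per row of `data`")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  unknown <- setdiff(channel_labels, .ALL_CHANNELS)
  if (length(unknown))
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be > 0")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  invisible(x)
}

#' Frequency-band definitions
#'
#' The four classical EEG bands on the 1-30 Hz analysis grid. The printed
#' clinical band edges (delta 1-3, theta 4-7, alpha 8-13, beta 14-30 Hz)
#' leave the half-integer bins between bands unassigned at 0.5 Hz
#' resolution, so bins are assigned by half-open intervals
#' delta \[1,4), theta \[4,8), alpha \[8,14), beta \[14,30.5): the bands then
#' exactly partition the grid and relative powers sum to 1.
#'
#' @param delta,theta,alpha,beta numeric length-2 vectors `c(lo, hi)` in Hz;
#'   each band covers grid bins with `lo <= f < hi`.
#' @return A data frame with columns `name`, `lo`, `hi`.
#' @export
default_bands <- function(delta = c(1, 4), theta = c(4, 8),
                          alpha = c(8, 14), beta = c(14, 30.5)) {
  b <- data.frame(
    name = c("delta", "theta", "alpha", "beta"),
    lo = c(delta[1], theta[1], alpha[1], beta[1]),
    hi = c(delta[2], theta[2], alpha[2], beta[2])
  )
  if (any(b$lo >= b$hi)) stop("band edges must satisfy lo < hi")
  b
}

#' Automated artifact-free segment selection
#'
#' Screens a recording in consecutive 2-s epochs and stitches the earliest
#' clean epochs into a segment of the requested length. An epoch is rejected
#' when any channel exceeds `amp_limit` in absolute amplitude, or when every
#' channel is flat (peak-to-peak below `flat_limit`). This is an automated
#' surrogate for the manual selection of artifact-free 5-minute segments
#' used in bedside QEEG practice.
#'
#' @param recording an [eeg_recording()].
#' @param target_len desired total length in seconds (default 300 = 5 min).
#' @param amp_limit amplitude rejection threshold in microvolts.
#' @param flat_limit flatline threshold in microvolts peak-to-peak.
#' @param epoch_s epoch length in seconds used for screening.
#' @return An `eeg_recording` of exactly `target_len` seconds.
#' @export
select_segments <- function(recording, target_len = 300, amp_limit = 100,
                            flat_limit = 1, epoch_s = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  nsamp <- ncol(recording$data)
  if (nsamp < target_len * fs)
    stop("insufficient artifact-free data: recording shorter than target length")
  ep <- round(epoch_s * fs)
  n_ep <- floor(nsamp / ep)
  need <- ceiling(target_len * fs / ep)
  keep <- logical(n_ep)
  for (i in seq_len(n_ep)) {
    idx <- ((i - 1L) * ep + 1L):(i * ep)
    seg <- recording$data[, idx, drop = FALSE]
    amp_ok <- max(abs(seg)) <= amp_limit
    p2p <- apply(seg, 1, function(v) diff(range(v)))
    flat <- all(p2p < flat_limit)
    keep[i] <- amp_ok && !flat
  }
  good <- which(keep)
  if (length(good) < need)
    stop("insufficient artifact-free data: ", length(good), " clean epochs, ",
         need, " required")
  take <- good[seq_len(need)]
  idx <- unlist(lapply(take, function(i) ((i - 1L) * ep + 1L):(i * ep)))
  idx <- idx[seq_len(round(target_len * fs))]
  eeg_recording(recording$data[, idx, drop = FALSE], fs,
                recording$channel_labels, recording$reference)
}

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Welch power spectral density
#'
#' Averaged modified periodogram per channel: 2-s Hamming-windowed segments
#' with 50% overlap, constant detrending per segment, one-sided spectrum
#' with window-power normalization, restricted to the 1-30 Hz grid at
#' 0.5 Hz resolution. Powers integrate (sum times the 0.5 Hz bin width) to
#' the in-band signal variance (Parseval).
#'
#' @param recording an [eeg_recording()].
#' @param window_s segment length in seconds; `fs * window_s` must be a
#'   whole number of samples.
#' @param overlap fractional overlap between consecutive segments.
#' @param fmin,fmax analysis band edges in Hz.
#' @return An object of class `spectral_estimate`: list with `freqs` (Hz),
#'   `psd` (channels x frequencies matrix, uV^2/Hz), `fs`, `channel_labels`.
#' @export
welch_psd <- function(recording, window_s = 2, overlap = 0.5,
                      fmin = 1, fmax = 30) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  L <- fs * window_s
  if (abs(L - round(L)) > 1e-9)
    stop("fs * window_s must be an integer number of samples")
  L <- as.integer(round(L))
  nsamp <- ncol(recording$data)
  if (nsamp < L) stop("recording shorter than one window")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, nsamp - L + 1L, by = step)
  w <- .hamming(L)
  U <- sum(w^2)
  half <- L %/% 2L + 1L
  freqs <- (0:(half - 1L)) * fs / L
  psd <- matrix(0, nrow(recording$data), half)
  for (ch in seq_len(nrow(recording$data))) {
    segs <- vapply(starts, function(s) {
      seg <- recording$data[ch, s:(s + L - 1L)]
      seg <- seg - mean(seg)
      Mod(fft(seg * w)[seq_len(half)])^2 / (fs * U)
    }, numeric(half))
    P <- rowMeans(segs)
    P[2:(half - 1L)] <- 2 * P[2:(half - 1L)]  # one-sided, DC/Nyquist kept once
    psd[ch, ] <- P
  }
  keep <- freqs >= fmin & freqs <= fmax
  structure(
    list(freqs = freqs[keep],
         psd = psd[, keep, drop = FALSE],
         fs = fs, channel_labels = recording$channel_labels),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d channels, %g-%g Hz at %g Hz resolution\n",
              nrow(x$psd), min(x$freqs), max(x$freqs), diff(x$freqs[1:2])))
  invisible(x)
}

#' Absolute and relative band powers
#'
#' Sums PSD bins into the band partition, averages across channels (global
#' indices, one value per recording), and normalizes by total in-band power.
#' The bands must partition the analysis grid: each frequency bin assigned
#' to exactly one band.
#'
#' @param spec a `spectral_estimate` from [welch_psd()].
#' @param bands band partition data frame, see [default_bands()].
#' @return An object of class `band_powers`: list with `absolute` (uV^2,
#'   averaged across channels), `relative` (fractions summing to 1), and
#'   `per_channel` absolute powers (channels x bands).
#' @export
relative_band_powers <- function(spec, bands = default_bands()) {
  stopifnot(inherits(spec, "spectral_estimate"))
  df <- diff(spec$freqs[1:2])
  assign <- lapply(seq_len(nrow(bands)), function(i)
    which(spec$freqs >= bands$lo[i] & spec$freqs < bands$hi[i]))
  counts <- tabulate(unlist(assign), nbins = length(spec$freqs))
  if (any(counts > 1)) stop("overlapping band definitions")
  if (any(counts == 0))
    stop("bands do not partition the analysis grid (unassigned bins at ",
         paste(spec$freqs[counts == 0], collapse = ", "), " Hz)")
  per_channel <- vapply(assign, function(idx)
    rowSums(spec$psd[, idx, drop = FALSE]) * df, numeric(nrow(spec$psd)))
  per_channel <- matrix(per_channel, nrow = nrow(spec$psd),
                        dimnames = list(spec$channel_labels, bands$name))
  absolute <- colMeans(per_channel)
  total <- sum(absolute)
  if (total <= 0) stop("zero total power in the analysis band")
  structure(
    list(absolute = absolute, relative = absolute / total,
         per_channel = per_channel),
    class = "band_powers"
  )
}

#' @export
print.band_powers <- function(x, ...) {
  cat("<band_powers> relative:",
      paste(sprintf("%s %.3f", names(x$relative), x$relative), collapse = ", "),
      "\n")
  invisible(x)
}

#' Spectral slowing ratios
#'
#' The delta/alpha ratio (DAR) and the (delta+theta)/(alpha+beta) ratio
#' (DTABR), computed from absolute band powers. Higher values indicate more
#' EEG slowing. A zero fast-band denominator is flagged with a warning and
#' the ratio reported as `Inf`.
#'
#' @param band_powers a `band_powers` object or a named numeric vector with
#'   elements `delta`, `theta`, `alpha`, `beta`.
#' @return A list with elements `dar` and `dtabr`.
#' @export
spectral_ratios <- function(band_powers) {
  p <- if (inherits(band_powers, "band_powers")) band_powers$absolute
       else band_powers
  if (!all(c("delta", "theta", "alpha", "beta") %in% names(p)))
    stop("band powers must be named delta/theta/alpha/beta")
  if (any(p < 0)) stop("band powers must be nonnegative")
  dar <- if (p[["alpha"]] > 0) p[["delta"]] / p[["alpha"]] else {
    warning("silent fast-band: zero alpha power, DAR reported as Inf")
    Inf
  }
  ab <- p[["alpha"]] + p[["beta"]]
  dtabr <- if (ab > 0) (p[["delta"]] + p[["theta"]]) / ab else {
    warning("silent fast-band: zero alpha+beta power, DTABR reported as Inf")
    Inf
  }
  list(dar = dar, dtabr = dtabr)
}

.homologous_pairs <- function(labels) {
  pairs <- lapply(seq_along(.LEFT_CHANNELS), function(i)
    c(.LEFT_CHANNELS[i], .RIGHT_CHANNELS[i]))
  keep <- vapply(pairs, function(p) any(p %in% labels), logical(1))
  pairs[keep]
}

#' Brain symmetry index
#'
#' Pairwise-derived BSI: the mean over homologous channel pairs and
#' frequency bins of `|(R - L) / (R + L)|`, where L and R are the left and
#' right PSD values. 0 means spectrally identical hemispheres, 1 maximal
#' asymmetry. Bins where both sides are exactly zero are skipped. The
#' frequency range is whatever `spec` carries (1-30 Hz from [welch_psd()]
#' by default, matching the recording filter band).
#'
#' @param spec a `spectral_estimate`.
#' @param pairs list of length-2 character vectors `c(left, right)`;
#'   defaults to the 8 homologous 10-20 pairs.
#' @return BSI value in \[0, 1\].
#' @export
compute_bsi <- function(spec, pairs = NULL) {
  stopifnot(inherits(spec, "spectral_estimate"))
  if (is.null(pairs)) {
    pairs <- .homologous_pairs(spec$channel_labels)
    if (!length(pairs)) stop("no homologous channel pairs in recording")
  }
  labs <- spec$channel_labels
  ratios <- c()
  for (p in pairs) {
    miss <- setdiff(p, labs)
    if (length(miss))
      stop("missing homologue channel: ", paste(miss, collapse = ", "))
    L <- spec$psd[match(p[1], labs), ]
    R <- spec$psd[match(p[2], labs), ]
    s <- R + L
    ok <- s > 0
    ratios <- c(ratios, abs((R[ok] - L[ok]) / s[ok]))
  }
  if (!length(ratios)) stop("all bins zero on all pairs; BSI undefined")
  mean(ratios)
}

#' Full QEEG index panel for one recording
#'
#' Pipeline composition: artifact screening ([select_segments()]), Welch PSD
#' ([welch_psd()]), band powers, slowing ratios and brain symmetry index,
#' returned as one record per patient.
#'
#' @inheritParams select_segments
#' @inheritParams welch_psd
#' @param bands band partition, see [default_bands()].
#' @return An object of class `qeeg_indices`: list with `rdp`, `rtp`, `rap`,
#'   `rbp` (relative powers), `dar`, `dtabr`, `bsi`.
#' @export
compute_qeeg_indices <- function(recording, target_len = 300,
                                 amp_limit = 100, flat_limit = 1,
                                 window_s = 2, overlap = 0.5,
                                 bands = default_bands()) {
  seg <- select_segments(recording, target_len = target_len,
                         amp_limit = amp_limit, flat_limit = flat_limit,
                         epoch_s = window_s)
  spec <- welch_psd(seg, window_s = window_s, overlap = overlap)
  bp <- relative_band_powers(spec, bands = bands)
  ratios <- spectral_ratios(bp)
  structure(
    list(rdp = unname(bp$relative["delta"]),
         rtp = unname(bp$relative["theta"]),
         rap = unname(bp$relative["alpha"]),
         rbp = unname(bp$relative["beta"]),
         dar = ratios$dar, dtabr = ratios$dtabr,
         bsi = compute_bsi(spec)),
    class = "qeeg_indices"
  )
}

#' @export
print.qeeg_indices <- function(x, ...) {
  cat(sprintf(paste0("<qeeg_indices> RDP %.3f RTP %.3f RAP %.3f RBP %.3f | ",
                     "DAR %.2f DTABR %.2f BSI %.3f\n"),
              x$rdp, x$rtp, x$rap, x$rbp, x$dar, x$dtabr, x$bsi))
  invisible(x)
}

#' @export
as.data.frame.qeeg_indices <- function(x, ...) {
  data.frame(rdp = x$rdp, rtp = x$rtp, rap = x$rap, rbp = x$rbp,
             dar = x$dar, dtabr = x$dtabr, bsi = x$bsi)
}
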