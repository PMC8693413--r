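#' Specification for a synthetic EEG recording
#'
#' Describes a band-structured multichannel EEG: each channel is a sum of
#' band-limited Gaussian noise components whose expected share of 1-30 Hz
#' power matches `band_targets` for that channel's hemisphere, plus optional
#' high-amplitude transient artifacts.
#'
#' `band_targets` is either a single named vector
#' `c(delta=, theta=, alpha=, beta=)` applied to both hemispheres, or a list
#' `list(left=, right=)` of two such vectors (left channels Fp1, F3, F7, C3,
#' T3, T5, P3, O1 and their right homologues), enabling controlled
#' asymmetry and hence a known brain-symmetry-index ordering. Targets must
#' be nonnegative and sum to at most 1 per hemisphere; because the four
#' analysis bands partition the 1-30 Hz grid, targets are renormalized to
#' sum to 1 when generating.
#'
#' @param n_channels 16 (full montage) or any even prefix of it.
#' @param fs sampling rate in Hz; must exceed twice the highest band edge.
#' @param duration recording length in seconds.
#' @param band_targets per-hemisphere relative power targets (see Details).
#' @param artifact_rate transient-artifact events per minute.
#' @param amplitude overall root-mean-square signal amplitude in
#'   microvolts; the default keeps physiologic peaks comfortably inside
#'   the +/-100 uV artifact-rejection limit, which injected artifacts
#'   (300 uV bursts) deliberately exceed.
#' @param seed integer seed; the recording is deterministic given the spec.
#' @return An object of class `eeg_sim_spec`.
#' @export
eeg_sim_spec <- function(n_channels = 16, fs = 250, duration = 300,
                         band_targets = c(delta = 0.25, theta = 0.25,
                                          alpha = 0.25, beta = 0.25),
                         artifact_rate = 0, amplitude = 15, seed = NULL) {
  if (!is.list(band_targets))
    band_targets <- list(left = band_targets, right = band_targets)
  if (!all(c("left", "right") %in% names(band_targets)))
    stop("band_targets list must have elements `left` and `right`")
  for (h in c("left", "right")) {
    tg <- band_targets[[h]]
    if (!all(c("delta", "theta", "alpha", "beta") %in% names(tg)))
      stop("band targets must be named delta/theta/alpha/beta")
    tg <- tg[c("delta", "theta", "alpha", "beta")]
    if (any(tg < 0)) stop("band targets must be nonnegative")
    if (sum(tg) > 1 + 1e-9) stop("band targets must sum to at most 1")
    if (sum(tg) <= 0) stop("band targets must not all be zero")
    band_targets[[h]] <- tg
  }
  if (fs <= 2 * 30) stop("fs must exceed twice the highest band edge (30 Hz)")
  if (n_channels < 2 || n_channels %% 2 != 0 || n_channels > 16)
    stop("n_channels must be an even number between 2 and 16")
  if (duration <= 0) stop("duration must be positive")
  if (artifact_rate < 0) stop("artifact_rate must be nonnegative")
  structure(
    list(n_channels = n_channels, fs = fs, duration = duration,
         band_targets = band_targets, artifact_rate = artifact_rate,
         amplitude = amplitude, seed = seed),
    class = "eeg_sim_spec"
  )
}

# Order-4 Butterworth band-pass filters at the synthesis band edges.
.band_filters <- function(fs, edges = list(delta = c(1, 4), theta = c(4, 8),
                                           alpha = c(8, 14), beta = c(14, 30))) {
  lapply(edges, function(e) signal::butter(4, e / (fs / 2), type = "pass"))
}

# Power gain of a zero-phase (filtfilt) application of an ARMA filter:
# |H(f)|^4, evaluated on a frequency grid.
.filtfilt_power_gain <- function(filt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- outer(z, seq_along(filt$b) - 1, "^") %*% filt$b
  den <- outer(z, seq_along(filt$a) - 1, "^") %*% filt$a
  Mod(num / den)^4
}

# Solve for per-component variances so the expected share of 1-30 Hz power
# in each analysis band equals the (renormalized) targets. White noise
# through a zero-phase Butterworth filter has PSD proportional to |H|^4;
# the 4x4 system maps component variances to band powers. Negative
# solutions (degenerate targets such as a single active band) are clipped
# to zero and the result renormalized.
.calibrate_band_variances <- function(targets, fs,
                                      bands = default_bands()) {
  filts <- .band_filters(fs)
  fgrid <- seq(0.5, fs / 2, by = 0.5)
  G <- vapply(filts, function(bf) .filtfilt_power_gain(bf, fgrid, fs),
              numeric(length(fgrid)))
  A <- t(vapply(seq_len(nrow(bands)), function(i) {
    idx <- fgrid >= bands$lo[i] & fgrid < bands$hi[i]
    colSums(G[idx, , drop = FALSE])
  }, numeric(ncol(G))))
  A <- sweep(A, 2, colSums(G), "/")
  tg <- targets / sum(targets)
  v <- tryCatch(solve(A, tg), error = function(e) tg)
  v[v < 0] <- 0
  if (sum(v) <= 0) v <- tg
  v / sum(v)
}

#' Generate a synthetic EEG recording
#'
#' Each channel is the sum of four band-limited Gaussian noise components
#' (white noise filtered with zero-phase order-4 Butterworth band-passes at
#' the band edges), with component variances calibrated so the expected
#' relative band powers on the 1-30 Hz analysis grid match the hemisphere's
#' targets. Optional transient artifacts are high-amplitude (300 uV) tapered
#' bursts 0.5 s long, injected at `artifact_rate` events per minute across
#' all channels. Deterministic given `spec$seed`.
#'
#' @param spec an [eeg_sim_spec()].
#' @return An [eeg_recording()].
#' @export
simulate_eeg <- function(spec) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  .with_seed(spec$seed, {
    fs <- spec$fs
    n <- round(spec$duration * fs)
    labels <- .ALL_CHANNELS[seq_len(spec$n_channels)]
    filts <- .band_filters(fs)
    vars <- lapply(spec$band_targets, .calibrate_band_variances, fs = fs)
    data <- matrix(0, spec$n_channels, n)
    for (ch in seq_along(labels)) {
      hemi <- if (labels[ch] %in% .LEFT_CHANNELS) "left" else "right"
      v <- vars[[hemi]]
      x <- numeric(n)
      for (b in seq_along(filts)) {
        if (v[b] <= 0) next
        comp <- signal::filtfilt(filts[[b]], rnorm(n))
        x <- x + comp / sd(comp) * sqrt(v[b])
      }
      data[ch, ] <- x * spec$amplitude
    }
    if (spec$artifact_rate > 0) {
      k <- rpois(1, spec$artifact_rate * spec$duration / 60)
      if (k > 0) {
        wlen <- round(0.5 * fs)
        burst <- 300 * (0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1)))
        for (j in seq_len(k)) {
          start <- sample.int(n - wlen, 1)
          idx <- start:(start + wlen - 1L)
          data[, idx] <- data[, idx] +
            matrix(burst, spec$n_channels, wlen, byrow = TRUE) *
            sample(c(-1, 1), 1)
        }
      }
    }
    eeg_recording(data, fs, labels)
  })
}
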