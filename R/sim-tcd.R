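#' Specification for a synthetic TCD velocity envelope
#'
#' Parameterizes a periodic transcranial Doppler velocity envelope by its
#' systolic and end-diastolic velocities, heart rate, and a TIBI-grade
#' waveform morphology template:
#' grade 0 absent flow (all-zero envelope); grade 1 minimal flow (narrow
#' systolic spikes, no diastolic flow); grade 2 blunted (delayed systolic
#' upstroke, slow decay); grades 3-5 share the normal morphology (a sharp
#' upstroke and exponential diastolic decay) -- the dampened/stenotic
#' distinction is carried by the velocities themselves relative to the
#' contralateral side.
#'
#' Each cycle carries a short systolic plateau (3% of the cycle) and an
#' end-diastolic plateau (final 5%), so sampled waveforms attain `vs` and
#' `vd` exactly and noiseless envelope extraction round-trips exactly.
#'
#' @param vs systolic velocity, cm/s.
#' @param vd end-diastolic velocity, cm/s (`vs >= vd >= 0`).
#' @param heart_rate beats per minute.
#' @param morphology TIBI-grade template, integer 0-5.
#' @param duration seconds.
#' @param fs sampling rate of the envelope, Hz.
#' @param noise_sd additive Gaussian noise, cm/s.
#' @param seed integer seed.
#' @return An object of class `tcd_sim_spec`.
#' @export
tcd_sim_spec <- function(vs = 84, vd = 42, heart_rate = 75, morphology = 5,
                         duration = 10, fs = 200, noise_sd = 0, seed = NULL) {
  if (vd < 0 || vs < vd) stop("need vs >= vd >= 0")
  if (heart_rate <= 0) stop("heart_rate must be positive")
  if (!morphology %in% 0:5) stop("morphology must be a TIBI grade 0-5")
  if (duration <= 0 || fs <= 0) stop("duration and fs must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(
    list(vs = vs, vd = vd, heart_rate = heart_rate, morphology = morphology,
         duration = duration, fs = fs, noise_sd = noise_sd, seed = seed),
    class = "tcd_sim_spec"
  )
}

#' TCD waveform container
#'
#' @param velocity numeric vector of envelope velocities, cm/s.
#' @param fs sampling rate, Hz.
#' @param side `"affected"` or `"unaffected"`.
#' @param depth insonation depth, mm.
#' @return An object of class `tcd_waveform`.
#' @export
tcd_waveform <- function(velocity, fs, side = "affected", depth = 55) {
  velocity <- as.numeric(velocity)
  if (any(!is.finite(velocity))) stop("velocity must be finite")
  if (fs <= 0) stop("fs must be positive")
  side <- match.arg(side, c("affected", "unaffected"))
  structure(list(velocity = velocity, fs = fs, side = side, depth = depth),
            class = "tcd_waveform")
}

#' @export
print.tcd_waveform <- function(x, ...) {
  cat(sprintf("<tcd_waveform> %s side, depth %g mm, %.1f s @ %g Hz\n",
              x$side, x$depth, length(x$velocity) / x$fs, x$fs))
  invisible(x)
}

# Normalized cycle shape s(u) on u in [0,1): 0 at end-diastole, 1 at the
# systolic peak. Upstroke is a raised cosine of duration `a` cycles;
# decay is exponential with shape `k`, reaching 0 at the diastolic plateau.
.tcd_cycle_shape <- function(u, grade) {
  s <- numeric(length(u))
  if (grade == 0) return(s)
  if (grade == 1) {
    ctr <- 0.12; w <- 0.08; top <- 0.015
    s[abs(u - ctr) <= top / 2] <- 1
    sl <- u > ctr - w & u < ctr - top / 2
    s[sl] <- (1 + cos(pi * (u[sl] - (ctr - top / 2)) / (w - top / 2))) / 2
    sr <- u > ctr + top / 2 & u < ctr + w
    s[sr] <- (1 + cos(pi * (u[sr] - (ctr + top / 2)) / (w - top / 2))) / 2
    return(s)
  }
  a <- if (grade == 2) 0.35 else 0.09
  k <- if (grade == 2) 2 else 4
  top <- 0.03
  dia <- 0.95
  i1 <- u < a
  s[i1] <- (1 - cos(pi * u[i1] / a)) / 2
  s[u >= a & u < a + top] <- 1
  i3 <- u >= a + top & u < dia
  s[i3] <- (exp(-k * (u[i3] - a - top) / (dia - a - top)) - exp(-k)) /
    (1 - exp(-k))
  s
}

#' Generate a synthetic TCD velocity envelope
#'
#' Periodic envelope with per-cycle maximum `vs` and end-diastolic minimum
#' `vd`, morphology per the TIBI template in the spec, plus additive
#' Gaussian noise. Deterministic given `spec$seed`.
#'
#' @param spec a [tcd_sim_spec()].
#' @param side,depth passed to [tcd_waveform()].
#' @return A [tcd_waveform()].
#' @export
simulate_tcd_waveform <- function(spec, side = "affected", depth = 55) {
  stopifnot(inherits(spec, "tcd_sim_spec"))
  .with_seed(spec$seed, {
    tt <- (0:(round(spec$duration * spec$fs) - 1)) / spec$fs
    Tc <- 60 / spec$heart_rate
    u <- (tt %% Tc) / Tc
    s <- .tcd_cycle_shape(u, spec$morphology)
    v <- if (spec$morphology %in% c(0, 1)) spec$vs * s
         else spec$vd + (spec$vs - spec$vd) * s
    if (spec$noise_sd > 0) v <- v + rnorm(length(v), 0, spec$noise_sd)
    tcd_waveform(v, spec$fs, side = side, depth = depth)
  })
}
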