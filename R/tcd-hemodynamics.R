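#' TCD velocity measures
#'
#' Container for per-side envelope summary measures. `vm` follows the
#' time-weighted clinical convention `(vs + 2 vd) / 3` and `pi` the Gosling
#' pulsatility index `(vs - vd) / vm`.
#'
#' @param vs,vd,vm velocities in cm/s.
#' @param pi pulsatility index (dimensionless).
#' @param acceleration_time systolic acceleration time, s.
#' @param no_flow logical, `TRUE` for an absent-flow (all-zero) envelope.
#' @return An object of class `tcd_measures`.
#' @export
tcd_measures <- function(vs, vd, vm = (vs + 2 * vd) / 3,
                         pi = if (vm > 0) (vs - vd) / vm else 0,
                         acceleration_time = NA_real_, no_flow = FALSE) {
  if (!no_flow && (vs < vm - 1e-9 || vm < vd - 1e-9))
    stop("need vs >= vm >= vd when flow is present")
  if (pi < 0) stop("pi must be nonnegative")
  structure(list(vs = vs, vd = vd, vm = vm, pi = pi,
                 acceleration_time = acceleration_time, no_flow = no_flow),
            class = "tcd_measures")
}

#' @export
print.tcd_measures <- function(x, ...) {
  if (x$no_flow) cat("<tcd_measures> no flow\n")
  else cat(sprintf("<tcd_measures> Vs %.1f Vd %.1f Vm %.1f PI %.2f AT %.3f s\n",
                   x$vs, x$vd, x$vm, x$pi, x$acceleration_time))
  invisible(x)
}

#' Extract velocity measures from a TCD envelope
#'
#' Segments the envelope into cardiac cycles by systolic peak detection and
#' reports across-cycle medians of: systolic velocity (per-cycle envelope
#' maximum), end-diastolic velocity (minimum before the next upstroke),
#' mean velocity `(vs + 2 vd) / 3`, Gosling pulsatility index
#' `(vs - vd) / vm`, and the systolic acceleration time (diastolic foot to
#' peak). Noise is estimated from the median-filter residual; when present,
#' diastolic measures are taken on a lightly smoothed copy and the systolic
#' value as the mean over the detected systolic plateau, keeping the
#' noiseless round-trip exact and the noisy one unbiased.
#'
#' An all-zero envelope returns zero measures flagged `no_flow`; fewer than
#' 3 detectable cycles with nonzero flow is an error.
#'
#' @param waveform a [tcd_waveform()].
#' @return A [tcd_measures()].
#' @export
extract_envelope_measures <- function(waveform) {
  stopifnot(inherits(waveform, "tcd_waveform"))
  v <- waveform$velocity
  fs <- waveform$fs
  if (max(abs(v)) < 1e-9)
    return(tcd_measures(0, 0, 0, 0, NA_real_, no_flow = TRUE))
  if (diff(range(v)) < 1e-9) {  # zero-pulsatility flow: vs = vd = v
    val <- median(v)
    return(tcd_measures(val, val, val, 0, NA_real_))
  }
  noise <- mad(v - runmed(v, 7))
  noisy <- noise > 1e-6
  vsm <- v
  if (noisy) {
    vsm <- as.numeric(stats::filter(v, rep(1 / 15, 15), sides = 2))
    vsm[is.na(vsm)] <- v[is.na(vsm)]
  }
  vmax <- max(vsm); vmin <- min(vsm)
  thr <- vmin + 0.6 * (vmax - vmin)
  cand <- which(diff(sign(diff(vsm))) < 0) + 1L
  cand <- cand[vsm[cand] >= thr]
  peaks <- integer(0)
  for (p in cand[order(-vsm[cand])])
    if (!length(peaks) || all(abs(peaks - p) > 0.25 * fs))
      peaks <- c(peaks, p)
  peaks <- sort(peaks)
  if (length(peaks) < 3) stop("unreadable waveform: fewer than 3 cardiac cycles")
  vs_i <- vd_i <- at_i <- numeric(0)
  for (j in seq_len(length(peaks) - 1L)) {
    iv <- (peaks[j] + 1L):peaks[j + 1L]
    vdj <- min(vsm[iv])
    amp <- vsm[peaks[j + 1L]] - vdj
    low <- iv[vsm[iv] <= vdj + 0.05 * amp & iv < peaks[j + 1L]]
    foot <- if (length(low)) max(low) else iv[which.min(vsm[iv])]
    vs_i[j] <- if (noisy) {
      top <- iv[vsm[iv] >= vdj + 0.985 * amp]
      mean(v[top])
    } else max(v[iv])
    vd_i[j] <- vdj
    at_i[j] <- (peaks[j + 1L] - foot) / fs
  }
  vs <- median(vs_i); vd <- max(0, median(vd_i))
  vm <- (vs + 2 * vd) / 3
  tcd_measures(vs, vd, vm, if (vm > 0) (vs - vd) / vm else 0, median(at_i))
}

#' TIBI flow grading
#'
#' Grades an affected-side Doppler waveform on the 6-level Thrombolysis in
#' Brain Ischemia scale from its envelope measures, optionally compared
#' with the contralateral side:
#'
#' * 0 absent: no flow;
#' * 1 minimal: systolic spikes without diastolic flow
#'   (`vd <= 0` or `vd < 0.1 vs`);
#' * 2 blunted: delayed upstroke (acceleration time above
#'   `at_threshold`), positive diastolic flow, PI < 1.2;
#' * 3 dampened: normal upstroke but mean velocity more than 30% below
#'   the contralateral side;
#' * 4 stenotic: mean velocity >= 80 cm/s and >= 30% above the
#'   contralateral side;
#' * 5 normal: otherwise.
#'
#' Comparative rules (3 and 4) are skipped when no contralateral measures
#' are supplied.
#'
#' @param affected a [tcd_measures()] for the affected side.
#' @param contralateral optional [tcd_measures()] for the other side.
#' @param at_threshold delayed-upstroke threshold in seconds.
#' @param stenotic_vm absolute mean-velocity threshold for grade 4, cm/s.
#' @param asymmetry fractional side-to-side asymmetry for grades 3/4.
#' @return Integer TIBI grade, 0-5.
#' @export
classify_tibi <- function(affected, contralateral = NULL,
                          at_threshold = 0.20, stenotic_vm = 80,
                          asymmetry = 0.30) {
  if (missing(affected) || is.null(affected))
    stop("affected-side measures are required")
  stopifnot(inherits(affected, "tcd_measures"))
  if (affected$no_flow || affected$vs <= 0) return(0L)
  if (affected$vd <= 0 || affected$vd < 0.1 * affected$vs) return(1L)
  if (!is.na(affected$acceleration_time) &&
      affected$acceleration_time > at_threshold &&
      affected$pi < 1.2) return(2L)
  if (!is.null(contralateral) && !contralateral$no_flow) {
    if (affected$vm < (1 - asymmetry) * contralateral$vm) return(3L)
    if (affected$vm >= stenotic_vm &&
        affected$vm >= (1 + asymmetry) * contralateral$vm) return(4L)
  }
  5L
}

#' Non-invasive vascular examination record
#'
#' Bundles the TIBI grades observed at a set of insonation depths along the
#' MCA/ICA axis with collateral-flow findings, as input to
#' [classify_offending_vessel()].
#'
#' @param tibi data frame with columns `depth` (mm) and `grade` (0-5).
#' @param acoa_crossfill cross-filling of the anterior communicating artery.
#' @param pcoa_collateral collateral flow in the posterior communicating
#'   artery.
#' @param oa_reversed reversed ophthalmic artery flow.
#' @param ipsilateral_mca_blunted blunted ipsilateral MCA waveform.
#' @param ipsilateral_mca_vm ipsilateral MCA mean velocity, cm/s.
#' @param carotid_compression_positive supporting carotid-compression test
#'   (never required; non-invasive default `NA`).
#' @return An object of class `vascular_exam`.
#' @export
vascular_exam <- function(tibi, acoa_crossfill = FALSE,
                          pcoa_collateral = FALSE, oa_reversed = FALSE,
                          ipsilateral_mca_blunted = FALSE,
                          ipsilateral_mca_vm = NA_real_,
                          carotid_compression_positive = NA) {
  tibi <- as.data.frame(tibi)
  if (!all(c("depth", "grade") %in% names(tibi)))
    stop("`tibi` needs columns depth and grade")
  if (!all(tibi$grade %in% 0:5)) stop("TIBI grades must be integers 0-5")
  if (any(tibi$depth <= 0)) stop("depths must be positive (mm)")
  if (!is.na(ipsilateral_mca_vm) && ipsilateral_mca_vm < 0)
    stop("velocities must be nonnegative")
  structure(
    list(tibi = tibi, acoa_crossfill = isTRUE(acoa_crossfill),
         pcoa_collateral = isTRUE(pcoa_collateral),
         oa_reversed = isTRUE(oa_reversed),
         ipsilateral_mca_blunted = isTRUE(ipsilateral_mca_blunted),
         ipsilateral_mca_vm = ipsilateral_mca_vm,
         carotid_compression_positive = carotid_compression_positive),
    class = "vascular_exam"
  )
}

.VESSELS <- c("proximal_ica", "tica", "mca", "indeterminate")

#' Rule-based offending-vessel classification
#'
#' Applies the diagnostic rules for locating the occluded or severely
#' stenosed artery responsible for a large hemispheric infarction, in
#' precedence order:
#'
#' 1. **TICA** (terminal internal carotid artery): abnormal spectrum (TIBI
#'    grade 0-4) at a depth of 60-70 mm, together with ACoA cross-filling
#'    or PCoA collateral flow (carotid compression results, when recorded,
#'    are supporting evidence only).
#' 2. **MCA**: abnormal spectrum at depths < 45 mm (M2 segment) or
#'    45-65 mm (M1 segment), when rule 1 is not met.
#' 3. **Proximal ICA**: ACoA cross-filling or PCoA collateral flow,
#'    together with reversed ophthalmic artery flow, or a blunted
#'    ipsilateral MCA with mean velocity > 20 cm/s.
#' 4. Otherwise **indeterminate** (with a warning when collateral findings
#'    are present but unexplained).
#'
#' TICA precedes MCA because its criterion is strictly more specific over
#' the overlapping 60-65 mm depth range.
#'
#' @param exam a [vascular_exam()].
#' @param abnormal_grade_max highest TIBI grade regarded as abnormal.
#' @return One of `"proximal_ica"`, `"tica"`, `"mca"`, `"indeterminate"`.
#' @export
classify_offending_vessel <- function(exam, abnormal_grade_max = 4) {
  stopifnot(inherits(exam, "vascular_exam"))
  tb <- exam$tibi
  abn <- tb$grade <= abnormal_grade_max
  collateral <- exam$acoa_crossfill || exam$pcoa_collateral
  tica_depth <- any(abn & tb$depth >= 60 & tb$depth <= 70)
  mca_depth <- any(abn & tb$depth < 45) |
    any(abn & tb$depth >= 45 & tb$depth <= 65)
  if (tica_depth && collateral) return("tica")
  if (mca_depth) return("mca")
  prox <- collateral &&
    (exam$oa_reversed ||
       (exam$ipsilateral_mca_blunted &&
          !is.na(exam$ipsilateral_mca_vm) && exam$ipsilateral_mca_vm > 20))
  if (prox) return("proximal_ica")
  if (collateral || exam$oa_reversed)
    warning("collateral findings present but no vessel rule satisfied; ",
            "returning indeterminate")
  "indeterminate"
}
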