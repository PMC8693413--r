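#' Specification for a synthetic survival cohort
#'
#' Describes a 90-day survival cohort with the covariate structure of a
#' large-hemispheric-infarction study: a binary coma-level-consciousness
#' indicator (GCS <= 8), a three-level offending-vessel category
#' (proximal ICA / terminal ICA / MCA), and a binary EEG-slowing indicator
#' (DTABR >= 3), each with stated prevalences, entering an exponential
#' proportional-hazards model with stated log hazard ratios and
#' administrative censoring at `censor_day`.
#'
#' Defaults reproduce the study conditions: prevalences 19/59 (GCS <= 8)
#' and (29, 8, 22)/59 (vessels); hazard ratios 3.228 (GCS <= 8), 3.830
#' (TICA vs proximal ICA) and 3.647 (DTABR >= 3), plus 1.64 for MCA vs
#' proximal ICA derived from the vessel-specific mortality fractions under
#' an exponential hazard. When `baseline_hazard` is `NULL` it is calibrated
#' so the expected 90-day mortality equals `target_mortality`
#' (22/59 ~ 37%).
#'
#' @param n number of patients.
#' @param prevalence_gcs_low fraction with GCS <= 8.
#' @param vessel_probs named probabilities for `proximal_ica`, `tica`,
#'   `mca`; must sum to 1.
#' @param prevalence_dtabr_high fraction with DTABR >= 3.
#' @param true_log_hr named log hazard ratios for `gcs_low`, `vessel_tica`,
#'   `vessel_mca`, `dtabr_high`.
#' @param baseline_hazard events/day for the reference patient, or `NULL`
#'   to calibrate against `target_mortality`.
#' @param target_mortality expected 90-day mortality used for calibration.
#' @param censor_day administrative censoring horizon, days.
#' @param seed integer seed.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n = 59,
                            prevalence_gcs_low = 19 / 59,
                            vessel_probs = c(proximal_ica = 29, tica = 8,
                                             mca = 22) / 59,
                            prevalence_dtabr_high = 0.45,
                            true_log_hr = log(c(gcs_low = 3.228,
                                                vessel_tica = 3.830,
                                                vessel_mca = 1.64,
                                                dtabr_high = 3.647)),
                            baseline_hazard = NULL,
                            target_mortality = 22 / 59,
                            censor_day = 90, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  probs <- c(prevalence_gcs_low, vessel_probs, prevalence_dtabr_high)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (abs(sum(vessel_probs) - 1) > 1e-9) stop("vessel_probs must sum to 1")
  need <- c("gcs_low", "vessel_tica", "vessel_mca", "dtabr_high")
  if (!all(need %in% names(true_log_hr)))
    stop("true_log_hr must name ", paste(need, collapse = ", "))
  if (!is.null(baseline_hazard) && baseline_hazard <= 0)
    stop("baseline_hazard must be positive")
  if (censor_day <= 0) stop("censor_day must be positive")
  structure(
    list(n = n, prevalence_gcs_low = prevalence_gcs_low,
         vessel_probs = vessel_probs,
         prevalence_dtabr_high = prevalence_dtabr_high,
         true_log_hr = true_log_hr[need],
         baseline_hazard = baseline_hazard,
         target_mortality = target_mortality,
         censor_day = censor_day, seed = seed),
    class = "cohort_sim_spec"
  )
}

#' Calibrate the baseline hazard to a target overall mortality
#'
#' Solves for the exponential baseline hazard at which the expected
#' `censor_day` mortality, marginalized over the spec's independent
#' covariate distribution, equals the spec's `target_mortality`.
#'
#' @param spec a [cohort_sim_spec()].
#' @return Baseline hazard in events/day.
#' @export
calibrate_baseline_hazard <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  grid <- expand.grid(gcs = 0:1, vessel = names(spec$vessel_probs),
                      dtabr = 0:1, stringsAsFactors = FALSE)
  p_g <- c(1 - spec$prevalence_gcs_low, spec$prevalence_gcs_low)
  p_d <- c(1 - spec$prevalence_dtabr_high, spec$prevalence_dtabr_high)
  w <- p_g[grid$gcs + 1] * spec$vessel_probs[grid$vessel] * p_d[grid$dtabr + 1]
  b <- spec$true_log_hr
  lp <- grid$gcs * b[["gcs_low"]] + grid$dtabr * b[["dtabr_high"]] +
    (grid$vessel == "tica") * b[["vessel_tica"]] +
    (grid$vessel == "mca") * b[["vessel_mca"]]
  f <- function(h0) sum(w * (1 - exp(-spec$censor_day * h0 * exp(lp)))) -
    spec$target_mortality
  uniroot(f, c(1e-8, 1), tol = 1e-12)$root
}

#' Generate a synthetic survival cohort
#'
#' Draws independent binary/categorical predictors from the spec's
#' prevalences, survival times from an exponential proportional-hazards
#' model `T ~ Exp(h0 exp(x'beta))`, and applies administrative censoring at
#' `censor_day` (`event = TRUE` iff death observed within the horizon;
#' censored patients carry `time = censor_day`). Auxiliary clinical columns
#' (age, sex, raw GCS/NIHSS scores consistent with their dichotomized
#' indicators, infarct side, onset-to-monitoring delay, and a DAR >= 4
#' indicator correlated with the DTABR one) are included for downstream
#' descriptive statistics; they carry no effect on the hazard beyond the
#' three true predictors. Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_sim_spec()].
#' @return A data frame, one row per patient.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  .with_seed(spec$seed, {
    n <- spec$n
    h0 <- spec$baseline_hazard %||% calibrate_baseline_hazard(spec)
    gcs_low <- runif(n) < spec$prevalence_gcs_low
    vessel <- factor(
      sample(names(spec$vessel_probs), n, replace = TRUE,
             prob = spec$vessel_probs),
      levels = names(spec$vessel_probs)
    )
    dtabr_high <- runif(n) < spec$prevalence_dtabr_high
    b <- spec$true_log_hr
    lp <- gcs_low * b[["gcs_low"]] + dtabr_high * b[["dtabr_high"]] +
      (vessel == "tica") * b[["vessel_tica"]] +
      (vessel == "mca") * b[["vessel_mca"]]
    tdeath <- rexp(n, rate = h0 * exp(lp))
    event <- tdeath <= spec$censor_day
    time <- pmin(tdeath, spec$censor_day)
    # auxiliary clinical covariates (no additional hazard effect)
    gcs <- ifelse(gcs_low, sample(3:8, n, TRUE), sample(9:15, n, TRUE))
    nihss_high <- runif(n) < 13 / 59
    nihss <- ifelse(nihss_high, sample(26:38, n, TRUE), sample(8:25, n, TRUE))
    dar_high <- ifelse(runif(n) < 0.85, dtabr_high, !dtabr_high)
    data.frame(
      id = seq_len(n),
      age = pmin(pmax(round(rnorm(n, 63, 11.2)), 30), 95),
      male = runif(n) < 40 / 59,
      gcs = gcs, gcs_low = gcs_low,
      nihss = nihss, nihss_high = nihss_high,
      vessel = vessel,
      dar_high = dar_high, dtabr_high = dtabr_high,
      infarct_side = sample(c("left", "right"), n, TRUE,
                            prob = c(35, 24) / 59),
      onset_to_monitoring_h = round(pmax(rnorm(n, 52.1, 38.6), 2), 1),
      event = event, time = time
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
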