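#' Logistic combination of prognostic predictors
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares / Newton-Raphson) returning the per-patient predicted mortality
#' probability as the combined prognostic score. Perfect separation or
#' non-convergence is detected and flagged; the function then falls back
#' to a rank-sum score (the count of positive predictor indicators) with a
#' warning.
#'
#' @param outcome logical or 0/1 outcome, both classes present.
#' @param predictors data frame of predictors (dichotomous indicators,
#'   ordered categories, or numeric).
#' @return A list with `score` (per patient), `coefficients`, `separation`
#'   flag, and the `glm` `model` (`NULL` after fallback).
#' @export
fit_logistic <- function(outcome, predictors) {
  outcome <- as.logical(outcome)
  if (length(unique(outcome)) < 2) stop("outcome must contain both classes")
  predictors <- as.data.frame(predictors)
  dat <- data.frame(.y = outcome, predictors, check.names = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE))
    sep <- TRUE
  if (sep) {
    warning("perfect separation or non-convergence; ",
            "falling back to a positive-predictor count score")
    mm <- model.matrix(~ ., data = predictors)[, -1, drop = FALSE]
    return(list(score = unname(rowSums(mm > 0)), coefficients = NULL,
                separation = TRUE, model = NULL))
  }
  list(score = unname(fitted(fit)), coefficients = coef(fit),
       separation = FALSE, model = fit)
}

#' Empirical ROC curve and AUROC
#'
#' Builds the empirical ROC over all distinct score thresholds (inclusive
#' rule: `score >= t` predicts the event) and computes the area under the
#' curve by the Mann-Whitney identity with ties counted 0.5, together with
#' its DeLong placement-value variance. The 95% confidence interval is
#' computed on the logit scale and back-transformed, clipped to \[0, 1\].
#' Higher scores must indicate higher event risk.
#'
#' @param score numeric prognostic score per patient.
#' @param outcome logical or 0/1 event indicator; both classes required.
#' @return An object of class `roc_curve`: list with `score`, `outcome`,
#'   `thresholds`, `sensitivity`, `specificity`, `auroc`, `var_auroc`,
#'   `ci`, and the underlying `pROC` object `roc`.
#' @export
roc_auc <- function(score, outcome) {
  outcome <- as.logical(outcome)
  if (length(score) != length(outcome)) stop("score/outcome length mismatch")
  if (length(unique(outcome)) < 2)
    stop("outcome must contain both classes")
  r <- pROC::roc(response = outcome, predictor = score,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  auroc <- as.numeric(pROC::auc(r))
  v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
  thresholds <- sort(unique(score))
  sens <- vapply(thresholds, function(t) mean(score[outcome] >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(score[!outcome] < t), numeric(1))
  ci <- if (v > 0 && auroc > 0 && auroc < 1) {
    se_logit <- sqrt(v) / (auroc * (1 - auroc))
    pmin(pmax(plogis(qlogis(auroc) + c(-1.96, 1.96) * se_logit), 0), 1)
  } else c(auroc, auroc)
  structure(
    list(score = score, outcome = outcome, thresholds = thresholds,
         sensitivity = sens, specificity = spec,
         auroc = auroc, var_auroc = v, ci = ci, roc = r),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUROC %.3f (95%% CI %.3f-%.3f), n = %d (%d events)\n",
              x$auroc, x$ci[1], x$ci[2], length(x$outcome), sum(x$outcome)))
  invisible(x)
}

#' DeLong comparison of two correlated ROC curves
#'
#' Two-sided DeLong test for paired ROC curves (same patients, same
#' outcomes). A curve compared with itself, or two curves with identical
#' scores, gives a difference of 0 and p = 1 by convention.
#'
#' @param roc_a,roc_b `roc_curve` objects from [roc_auc()] built on the
#'   same patients.
#' @return A list with `diff` (AUROC a minus b), `z`, `p`.
#' @export
delong_compare <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_curve"), inherits(roc_b, "roc_curve"))
  if (length(roc_a$outcome) != length(roc_b$outcome) ||
      any(roc_a$outcome != roc_b$outcome))
    stop("curves must be paired on the same patients and outcomes")
  d <- roc_a$auroc - roc_b$auroc
  if (isTRUE(all.equal(roc_a$score, roc_b$score)))
    return(list(diff = 0, z = 0, p = 1))
  rt <- pROC::roc.test(roc_a$roc, roc_b$roc, method = "delong",
                       paired = TRUE)
  z <- unname(rt$statistic)
  p <- rt$p.value
  if (!is.finite(z)) { z <- 0; p <- 1 }  # zero-variance difference
  list(diff = d, z = z, p = p)
}

#' Youden-optimal operating point
#'
#' The threshold maximizing Youden's J = sensitivity + specificity - 1 on
#' the empirical curve, with ties broken toward higher specificity.
#'
#' @param roc a `roc_curve` from [roc_auc()].
#' @return A list with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_operating_point <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[order(-roc$specificity[best], -roc$thresholds[best])][1]
  list(threshold = roc$thresholds[pick],
       sensitivity = roc$sensitivity[pick],
       specificity = roc$specificity[pick],
       youden = j[pick])
}
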