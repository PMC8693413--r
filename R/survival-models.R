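#' Cox proportional-hazards fit
#'
#' Fits a Cox model maximizing the Efron-tie partial likelihood (Efron
#' rather than Breslow because day-resolution survival times make ties
#' likely), and reports Wald statistics in the clinical style: hazard
#' ratios with `exp(beta +/- 1.96 SE)` confidence intervals and Wald
#' p-values. Constant covariates are dropped with a warning; monotone
#' likelihood (perfect separation) is flagged by a diverging-coefficient
#' warning. Factor covariates expand to indicator contrasts against their
#' first level (relevel beforehand to choose the clinical reference, e.g.
#' proximal ICA for the offending vessel).
#'
#' @param time survival times (> 0), days.
#' @param event logical or 0/1 event indicator (death observed).
#' @param covariates data frame of covariates.
#' @param ties `"efron"` or `"breslow"`.
#' @return An object of class `cox_fit`: list with `table` (term, beta, se,
#'   hr, lo, hi, p), `loglik` (at 0 and at the optimum), `score` (score
#'   test at beta = 0), `iter`, `n`, `nevent`, `ties`, and the underlying
#'   [survival::coxph()] `fit`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (sum(event) < 1) stop("at least one event is required")
  if (length(time) != length(event) || nrow(covariates) != length(time))
    stop("time, event and covariates must have matching lengths")
  const <- vapply(covariates, function(x) length(unique(x)) < 2, logical(1))
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[const], collapse = ", "))
    covariates <- covariates[, !const, drop = FALSE]
  }
  if (!ncol(covariates)) stop("no non-constant covariates to fit")
  dat <- data.frame(.time = time, .event = as.integer(event), covariates,
                    check.names = FALSE)
  form <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  diverging <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("coefficient may be infinite|Loglik converged",
                conditionMessage(w))) {
        diverging <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  if (diverging || any(abs(beta) > 15))
    warning("diverging coefficient(s) suggest monotone likelihood ",
            "(perfect separation)")
  z <- beta / se
  tab <- data.frame(
    term = names(beta), beta = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    lo = exp(unname(beta) - 1.96 * unname(se)),
    hi = exp(unname(beta) + 1.96 * unname(se)),
    p = 2 * pnorm(-abs(unname(z))), row.names = NULL
  )
  structure(
    list(table = tab, loglik = fit$loglik, score = unname(fit$score),
         iter = fit$iter, n = fit$n, nevent = fit$nevent, ties = ties,
         fit = fit),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, %s ties, %d iteration(s)\n",
              x$n, x$nevent, x$ties, x$iter))
  tab <- x$table
  tab$hr <- round(tab$hr, digits); tab$lo <- round(tab$lo, digits)
  tab$hi <- round(tab$hi, digits); tab$p <- signif(tab$p, digits)
  print(tab[, c("term", "hr", "lo", "hi", "p")], row.names = FALSE)
  invisible(x)
}

# Wald p per original covariate: factor blocks judged by their
# minimum-p indicator.
.block_pvalues <- function(fit, covariates) {
  asn <- attr(model.matrix(fit$fit), "assign")
  tl <- attr(terms(fit$fit), "term.labels")
  p <- fit$table$p
  vapply(seq_along(tl), function(i) min(p[asn == i]), numeric(1)) |>
    setNames(gsub("`", "", tl))
}

#' Backward stepwise elimination for the Cox model
#'
#' Iteratively refits the Cox model, removing the covariate with the
#' largest Wald p-value while it exceeds `alpha`. Factor covariates are
#' removed as whole blocks, judged by the minimum p among their indicator
#' contrasts. Ties are broken by column order, so the procedure is
#' deterministic given the input order.
#'
#' @inheritParams cox_fit
#' @param alpha retention threshold on the Wald p-value.
#' @return A list with `fit` (the final [cox_fit()], or `NULL` when every
#'   covariate was eliminated), `retained`, `dropped` (in removal order).
#' @export
backward_select <- function(time, event, covariates, alpha = 0.05,
                            ties = "efron") {
  covariates <- as.data.frame(covariates)
  if (!ncol(covariates)) stop("initial covariate set must be nonempty")
  dropped <- character(0)
  repeat {
    if (!ncol(covariates)) {
      message("all covariates eliminated; returning empty model")
      return(list(fit = NULL, retained = character(0), dropped = dropped))
    }
    fit <- cox_fit(time, event, covariates, ties = ties)
    bp <- .block_pvalues(fit, covariates)
    worst <- which.max(bp)
    if (bp[worst] <= alpha)
      return(list(fit = fit, retained = names(covariates),
                  dropped = dropped))
    dropped <- c(dropped, names(bp)[worst])
    covariates <- covariates[, setdiff(names(covariates), names(bp)[worst]),
                             drop = FALSE]
  }
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator, overall or per group. The median survival time
#' is the smallest time with survival at or below 0.5 and is reported as
#' `NA` ("not reached") when the curve stays above 0.5.
#'
#' @param time survival times (> 0).
#' @param event event indicator.
#' @param group optional grouping factor.
#' @return An object of class `km_curve`: list with `curves` (data frame:
#'   group, time, n_risk, n_event, surv) and `median` (named per group).
#' @export
km_fit <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop("times must be positive")
  dat <- data.frame(.time = time, .event = as.integer(event))
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(.time, .event) ~ 1, data = dat)
    groups <- factor(rep("all", length(fit$time)))
  } else {
    dat$.group <- factor(group)
    fit <- survival::survfit(survival::Surv(.time, .event) ~ .group,
                             data = dat)
    groups <- if (is.null(fit$strata)) factor(rep(levels(dat$.group)[1],
                                                  length(fit$time)))
              else factor(rep(gsub("^\\.group=", "", names(fit$strata)),
                              fit$strata))
  }
  curves <- data.frame(group = groups, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       surv = fit$surv)
  med <- vapply(split(curves, curves$group), function(d) {
    hit <- d$time[d$surv <= 0.5 + 1e-12]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  structure(list(curves = curves, median = med), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  med <- ifelse(is.na(x$median), "not reached", sprintf("%g d", x$median))
  cat("<km_curve> median survival:",
      paste(names(x$median), med, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Log-rank test
#'
#' Standard Mantel-Haenszel log-rank comparison of survival between
#' groups; the statistic is chi-squared with `groups - 1` degrees of
#' freedom.
#'
#' @inheritParams km_fit
#' @param group grouping factor with at least 2 non-empty levels.
#' @return A list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("need at least 2 non-empty groups")
  if (sum(event) < 1) stop("at least one event is required")
  dat <- data.frame(.time = time, .event = as.integer(event), .group = group)
  sd <- survival::survdiff(survival::Surv(.time, .event) ~ .group, data = dat)
  df <- nlevels(group) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = pchisq(unname(sd$chisq), df, lower.tail = FALSE))
}
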