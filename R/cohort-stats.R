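#' Pearson chi-squared test on a contingency table
#'
#' Uncorrected Pearson chi-squared test (no continuity correction), with
#' the expected counts reported so callers can flag cells with expected
#' count below 5. A Fisher exact test is available behind `fisher = TRUE`
#' for such tables.
#'
#' @param table an r x c matrix or table of nonnegative counts, r, c >= 2.
#' @param fisher use Fisher's exact test instead of Pearson chi-squared.
#' @return A list with `statistic`, `df`, `p`, `expected`, `method`.
#' @export
pearson_chi2 <- function(table, fisher = FALSE) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2 x 2")
  if (any(tab < 0) || sum(tab) <= 0) stop("counts must be nonnegative, total > 0")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    message("expected count below 5 in ", sum(expected < 5),
            " cell(s); consider `fisher = TRUE`")
  if (fisher) {
    ft <- fisher.test(tab)
    return(list(statistic = NA_real_, df = NA_integer_, p = ft$p.value,
                expected = expected, method = "fisher"))
  }
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       expected = expected, method = "pearson")
}

.shapiro_normal <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000 || sd(x) == 0) return(FALSE)
  shapiro.test(x)$p.value >= alpha
}

#' Two-group comparison with automatic test selection
#'
#' Compares a numeric variable between two groups the way clinical
#' baseline tables are built: Student's t-test (equal variances) when both
#' groups pass a Shapiro-Wilk normality screen at `normality_alpha`,
#' otherwise a two-sided Mann-Whitney U test (normal approximation with
#' tie correction, no continuity correction). The summary reports
#' mean (SD) or median (IQR) accordingly.
#'
#' @param x,y numeric samples for the two groups.
#' @param mode `"auto"`, `"t"` or `"mann_whitney"`.
#' @param normality_alpha Shapiro-Wilk screening level for `mode = "auto"`.
#' @return A list with `test`, `statistic`, `p`, and per-group `summary`
#'   strings.
#' @export
compare_groups <- function(x, y, mode = c("auto", "t", "mann_whitney"),
                           normality_alpha = 0.05) {
  mode <- match.arg(mode)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  if (mode == "auto")
    mode <- if (.shapiro_normal(x, normality_alpha) &&
                .shapiro_normal(y, normality_alpha)) "t" else "mann_whitney"
  if (mode == "t") {
    if (length(x) < 2 || length(y) < 2)
      stop("t-test requires at least 2 observations per group")
    if (sd(x) == 0 && sd(y) == 0) stop("zero variance in both samples")
    tt <- t.test(x, y, var.equal = TRUE)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         summary = c(sprintf("%.2f (%.2f)", mean(x), sd(x)),
                     sprintf("%.2f (%.2f)", mean(y), sd(y))))
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    p <- wt$p.value
    if (is.nan(p)) p <- 1  # identical samples: zero-variance rank sum
    list(test = "mann_whitney", statistic = unname(wt$statistic), p = p,
         summary = c(sprintf("%.2f (%.2f)", median(x), IQR(x)),
                     sprintf("%.2f (%.2f)", median(y), IQR(y))))
  }
}

#' Dichotomize a numeric variable at a clinical threshold
#'
#' Boundary handling follows the printed inequality exactly: for example
#' GCS <= 8 and DTABR >= 3 are inclusive, NIHSS > 25 strict. Missing
#' values propagate as `NA` with a logged count.
#'
#' @param records data frame of patient records.
#' @param variable column name to dichotomize.
#' @param threshold numeric cutoff.
#' @param direction one of `"le"` (<=), `"ge"` (>=), `"lt"` (<), `"gt"` (>).
#' @return Logical vector, one element per record.
#' @export
dichotomize <- function(records, variable, threshold,
                        direction = c("le", "ge", "lt", "gt")) {
  direction <- match.arg(direction)
  if (!variable %in% names(records)) stop("no column named `", variable, "`")
  v <- records[[variable]]
  if (!is.numeric(v)) stop("`", variable, "` is not numeric")
  out <- switch(direction,
                le = v <= threshold, ge = v >= threshold,
                lt = v < threshold, gt = v > threshold)
  if (anyNA(out))
    message(sum(is.na(out)), " missing value(s) in `", variable,
            "` excluded from dichotomization")
  out
}

#' Baseline comparison table
#'
#' Builds a clinical "Table 1"-style summary: each numeric variable is
#' compared between outcome groups with [compare_groups()], each logical or
#' factor variable with [pearson_chi2()] on its contingency table against
#' the outcome.
#'
#' @param cohort data frame with an `event` logical column.
#' @param variables character vector of column names to summarize.
#' @return Data frame with one row per variable: group summaries, test
#'   used, and p-value.
#' @export
summarize_cohort <- function(cohort, variables) {
  stopifnot("event" %in% names(cohort))
  g <- cohort$event
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop("no column named `", v, "`")
    if (is.numeric(x)) {
      cg <- compare_groups(x[g], x[!g])
      data.frame(variable = v, test = cg$test,
                 non_survivors = cg$summary[1], survivors = cg$summary[2],
                 p = cg$p)
    } else {
      tab <- table(factor(x), factor(g, levels = c(TRUE, FALSE)))
      ct <- suppressMessages(pearson_chi2(tab))
      fmt <- function(col) paste(sprintf("%s %d", rownames(tab), col),
                                 collapse = "; ")
      data.frame(variable = v, test = "chi2",
                 non_survivors = fmt(tab[, 1]), survivors = fmt(tab[, 2]),
                 p = ct$p)
    }
  })
  do.call(rbind, rows)
}
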