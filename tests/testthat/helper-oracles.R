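# Independent reference implementations used as oracles. These stay naive
# on purpose: direct loops and closed forms, no shared code with the
# package internals they check.

# Naive segmented-FFT Welch reference (double loop, no vectorization).
naive_welch <- function(x, fs, window_s = 2, overlap = 0.5,
                        fmin = 1, fmax = 30) {
  L <- round(fs * window_s)
  step <- round(L * (1 - overlap))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  U <- sum(w^2)
  starts <- seq(1, length(x) - L + 1, by = step)
  acc <- numeric(L %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- seg - mean(seg)
    X <- fft(seg * w)
    acc <- acc + Mod(X[1:(L %/% 2 + 1)])^2 / (fs * U)
  }
  P <- acc / length(starts)
  P[2:(L %/% 2)] <- 2 * P[2:(L %/% 2)]
  f <- (0:(L %/% 2)) * fs / L
  keep <- f >= fmin & f <= fmax
  list(f = f[keep], psd = P[keep])
}

# Double-loop brain symmetry index on a psd matrix with named rows.
naive_bsi <- function(psd, left, right) {
  vals <- c()
  for (m in seq_along(left)) {
    L <- psd[left[m], ]
    R <- psd[right[m], ]
    for (k in seq_along(L)) {
      s <- L[k] + R[k]
      if (s > 0) vals <- c(vals, abs((R[k] - L[k]) / s))
    }
  }
  mean(vals)
}

# Hand-written Efron-tie Cox partial log-likelihood for a single covariate.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(exp(beta * x[R]))
    sD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

# Two-stage grid maximizer for the likelihood above.
grid_max_beta <- function(time, event, x, lo = -4, hi = 4) {
  g1 <- seq(lo, hi, by = 1e-3)
  v1 <- vapply(g1, efron_loglik, numeric(1), time = time, event = event,
               x = x)
  b1 <- g1[which.max(v1)]
  g2 <- seq(b1 - 1e-3, b1 + 1e-3, by = 1e-6)
  v2 <- vapply(g2, efron_loglik, numeric(1), time = time, event = event,
               x = x)
  g2[which.max(v2)]
}

# Brute-force AUROC by pair counting (ties 0.5).
pair_count_auc <- function(score, outcome) {
  cases <- score[outcome]
  ctrls <- score[!outcome]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}

# Mann-Whitney U by pair counting.
pair_count_u <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# Fast rank-based AUC used inside the bootstrap oracle.
rank_auc <- function(score, outcome) {
  n1 <- sum(outcome)
  n0 <- sum(!outcome)
  r <- rank(score)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exhaustive TIBI oracle: a literal transcription of the grading rule
# table, evaluated independently of classify_tibi's control flow.
tibi_truth_table <- function(vs, vd, at, vm, cvm, pi) {
  if (vs <= 0) return(0L)
  if (vd <= 0 || vd < 0.1 * vs) return(1L)
  if (!is.na(at) && at > 0.20 && pi < 1.2) return(2L)
  if (!is.na(cvm)) {
    if (vm < 0.7 * cvm) return(3L)
    if (vm >= 80 && vm >= 1.3 * cvm) return(4L)
  }
  5L
}

fixture_measures <- function(vs, vd, at = 0.1, no_flow = FALSE) {
  vm <- (vs + 2 * vd) / 3
  tcd_measures(vs, vd, vm, if (vm > 0) (vs - vd) / vm else 0, at,
               no_flow = no_flow)
}
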