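# QEEG spectral branch: Welch estimator, band powers, slowing ratios,
# brain symmetry index, artifact screening.

make_recording <- function(f = NULL, amp = 1, duration = 10, fs = 250,
                           n_channels = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- duration * fs
    tt <- (0:(n - 1)) / fs
    data <- t(vapply(seq_len(n_channels), function(ch) {
      if (is.null(f)) rnorm(n) else amp * sin(2 * pi * f * tt + ch)
    }, numeric(n)))
    eeg_recording(data, fs, c("Fp1", "Fp2", "F3", "F4")[seq_len(n_channels)])
  })
}

test_that("welch_psd matches a naive segmented-FFT reference bin-by-bin", {
  rec <- make_recording(duration = 10, seed = 21)
  sp <- welch_psd(rec)
  for (ch in 1:2) {
    ref <- naive_welch(rec$data[ch, ], rec$fs)
    expect_equal(sp$freqs, ref$f)
    expect_lt(max(abs(sp$psd[ch, ] - ref$psd) / pmax(ref$psd, 1e-300)),
              1e-9)
  }
})

test_that("a pure sinusoid obeys Parseval and peaks at its frequency", {
  rec <- make_recording(f = 10, amp = 2, duration = 60)
  sp <- welch_psd(rec)
  total <- sum(sp$psd[1, ]) * 0.5
  expect_lt(abs(total - 2) / 2, 0.01)
  expect_equal(sp$freqs[which.max(sp$psd[1, ])], 10)
})

test_that("zero signal gives an identically zero spectrum", {
  rec <- eeg_recording(matrix(0, 2, 2500), 250, c("C3", "C4"))
  expect_true(all(welch_psd(rec)$psd == 0))
})

test_that("white noise is flat and carries the expected in-band power", {
  rec <- make_recording(duration = 1200, n_channels = 1, seed = 22)
  sp <- welch_psd(rec)
  p <- sp$psd[1, ]
  expect_lt(max(abs(p - mean(p)) / mean(p)), 0.10)
  expect_lt(abs(sum(p) * 0.5 - 29.5 / 125) / (29.5 / 125), 0.05)
})

test_that("welch_psd precondition and resolution contract hold", {
  rec <- make_recording(duration = 1)
  expect_error(welch_psd(rec), "shorter than one window")
  sp <- welch_psd(make_recording(duration = 4))
  expect_equal(diff(sp$freqs[1:2]), 0.5)
  expect_equal(range(sp$freqs), c(1, 30))
})

test_that("relative powers sum to one and respect the partition", {
  rec <- simulate_eeg(eeg_sim_spec(duration = 30, seed = 23))
  bp <- relative_band_powers(welch_psd(rec))
  expect_equal(sum(bp$relative), 1, tolerance = 1e-9)
  expect_true(all(abs(bp$relative - 0.25) < 0.02))
})

test_that("an alpha-band sinusoid is assigned almost entirely to alpha", {
  rec <- make_recording(f = 10, amp = 2, duration = 60)
  bp <- relative_band_powers(welch_psd(rec))
  expect_gte(bp$relative[["alpha"]], 0.99)
})

test_that("overlapping or gappy band definitions are rejected", {
  sp <- welch_psd(make_recording(duration = 4))
  overlap <- data.frame(name = c("delta", "theta", "alpha", "beta"),
                        lo = c(1, 3, 8, 14), hi = c(4, 8, 14, 30.5))
  expect_error(relative_band_powers(sp, overlap), "overlapping")
  gappy <- data.frame(name = c("delta", "theta", "alpha", "beta"),
                      lo = c(1, 4, 8, 14), hi = c(3, 8, 14, 30.5))
  expect_error(relative_band_powers(sp, gappy), "partition")
})

test_that("slowing ratios follow their defining arithmetic", {
  eq <- c(delta = 2, theta = 2, alpha = 2, beta = 2)
  expect_equal(spectral_ratios(eq), list(dar = 1, dtabr = 1))
  r <- spectral_ratios(c(delta = 6, theta = 2, alpha = 2, beta = 2))
  expect_equal(r$dar, 3)
  expect_equal(r$dtabr, 2)
  w <- capture_warnings(
    r0 <- spectral_ratios(c(delta = 1, theta = 1, alpha = 0, beta = 0)))
  expect_match(w, "silent fast-band", all = TRUE)
  expect_identical(r0$dar, Inf)
  expect_identical(r0$dtabr, Inf)
})

test_that("BSI identities: symmetry zero, unilateral silence one, oracle", {
  withr::with_seed(31, {
    psd <- matrix(rexp(16 * 59), 16, 59)
    labs <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4",
              "T3", "T4", "T5", "T6", "P3", "P4", "O1", "O2")
    left <- labs[seq(1, 15, 2)]; right <- labs[seq(2, 16, 2)]
    rownames(psd) <- labs
    mk <- function(m) structure(
      list(freqs = seq(1, 30, 0.5), psd = m, fs = 250,
           channel_labels = labs), class = "spectral_estimate")
    # mirrored hemispheres
    sym <- psd; sym[right, ] <- sym[left, ]
    expect_equal(compute_bsi(mk(sym)), 0)
    # one hemisphere silent
    silent <- psd; silent[right, ] <- 0
    expect_equal(compute_bsi(mk(silent)), 1)
    # brute-force double-loop oracle on arbitrary spectra
    expect_equal(compute_bsi(mk(psd)), naive_bsi(psd, left, right),
                 tolerance = 1e-12)
    # left/right exchange leaves the index unchanged
    swapped <- psd[c(matrix(seq_len(16), 2)[2:1, ]), ]
    rownames(swapped) <- labs
    expect_equal(compute_bsi(mk(swapped)), compute_bsi(mk(psd)),
                 tolerance = 1e-12)
  })
})

test_that("BSI names a missing homologue channel", {
  rec <- make_recording(duration = 4, n_channels = 2)
  sp <- welch_psd(rec)
  sp$psd <- sp$psd[1, , drop = FALSE]
  sp$channel_labels <- "Fp1"
  expect_error(compute_bsi(sp, pairs = list(c("Fp1", "Fp2"))), "Fp2")
})

test_that("segment selection keeps clean data verbatim and drops bursts", {
  rec <- simulate_eeg(eeg_sim_spec(duration = 40, seed = 24))
  keep <- select_segments(rec, target_len = 30, amp_limit = 1000)
  expect_identical(keep$data, rec$data[, 1:(30 * 250)])
  # inject one 500 uV burst into the third 2-s epoch
  bad <- rec
  bad$data[3, 1101:1200] <- 500
  out <- select_segments(bad, target_len = 30, amp_limit = 100)
  expect_lte(max(abs(out$data)), 100)
  # the remaining epochs shift forward by one epoch
  expect_identical(out$data[, 1:1000], bad$data[, 1:1000])
  expect_identical(out$data[, 1001:1500], bad$data[, 1501:2000])
})

test_that("segment selection errors when the recording is too short", {
  rec <- simulate_eeg(eeg_sim_spec(duration = 240, seed = 25))
  expect_error(select_segments(rec, target_len = 300),
               "insufficient artifact-free data")
})

test_that("the composed index panel reflects its generator regime", {
  healthy <- c(delta = 0.4184, theta = 0.1286, alpha = 0.2577,
               beta = 0.1953)
  rec <- simulate_eeg(eeg_sim_spec(duration = 70, band_targets = healthy,
                                   seed = 26))
  qi <- compute_qeeg_indices(rec, target_len = 60)
  expect_lt(qi$dtabr, 3)
  expect_lt(qi$bsi, 0.3)
  expect_equal(qi$rdp + qi$rtp + qi$rap + qi$rbp, 1, tolerance = 1e-9)
  # identical input gives identical indices
  expect_identical(qi, compute_qeeg_indices(rec, target_len = 60))
  # 2:1 left/right delta asymmetry raises the BSI
  slow <- c(delta = 0.6846, theta = 0.1003, alpha = 0.1315, beta = 0.0836)
  rec_a <- simulate_eeg(eeg_sim_spec(
    duration = 70, band_targets = list(left = slow, right = healthy),
    seed = 26))
  expect_gt(compute_qeeg_indices(rec_a, target_len = 60)$bsi, qi$bsi)
})
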