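# TCD branch: envelope measure extraction, TIBI grading, offending-vessel
# rules.

test_that("noiseless envelopes round-trip exactly", {
  wf <- simulate_tcd_waveform(tcd_sim_spec(vs = 90, vd = 30, noise_sd = 0))
  m <- extract_envelope_measures(wf)
  expect_equal(m$vs, 90)
  expect_equal(m$vd, 30)
  expect_equal(m$vm, 50)
  expect_equal(m$pi, 1.2)
  # heart rate with a non-integer number of samples per cycle
  wf2 <- simulate_tcd_waveform(tcd_sim_spec(vs = 90, vd = 30,
                                            heart_rate = 68))
  m2 <- extract_envelope_measures(wf2)
  expect_equal(m2$vs, 90)
  expect_equal(m2$vd, 30)
})

test_that("zero pulsatility gives pi = 0", {
  wf <- simulate_tcd_waveform(tcd_sim_spec(vs = 50, vd = 50))
  m <- extract_envelope_measures(wf)
  expect_equal(m$pi, 0)
  expect_equal(m$vs, 50)
})

test_that("noisy envelopes recover the generator truth within tolerance", {
  for (s in 1:20) {
    wf <- simulate_tcd_waveform(tcd_sim_spec(vs = 84, vd = 42,
                                             noise_sd = 1, seed = s))
    m <- extract_envelope_measures(wf)
    expect_lt(abs(m$vs - 84) / 84, 0.02)
    expect_lt(abs(m$vd - 42) / 42, 0.02)
    expect_lt(abs(m$vm - 56) / 56, 0.02)
    expect_lt(abs(m$pi - 0.75) / 0.75, 0.05)
  }
})

test_that("absent flow and unreadable waveforms are distinguished", {
  silent <- simulate_tcd_waveform(tcd_sim_spec(morphology = 0))
  m <- extract_envelope_measures(silent)
  expect_true(m$no_flow)
  expect_equal(classify_tibi(m), 0L)
  # two cycles only
  short <- simulate_tcd_waveform(tcd_sim_spec(duration = 1.5))
  expect_error(extract_envelope_measures(short), "unreadable waveform")
})

test_that("scaling a waveform leaves PI unchanged", {
  wf <- simulate_tcd_waveform(tcd_sim_spec(vs = 60, vd = 20))
  wf2 <- wf; wf2$velocity <- 3 * wf$velocity
  m1 <- extract_envelope_measures(wf)
  m2 <- extract_envelope_measures(wf2)
  expect_equal(m2$pi, m1$pi, tolerance = 1e-9)
  expect_equal(m2$vs, 3 * m1$vs, tolerance = 1e-9)
})

test_that("TIBI grading agrees with the exhaustive rule-table oracle", {
  cases <- expand.grid(
    vs = c(0, 40, 60, 90, 130),
    vd_frac = c(0, 0.05, 0.1, 0.3, 0.5),
    at = c(0.1, 0.2, 0.21, 0.3),
    cvm = c(NA, 30, 60, 64, 90)
  )
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    vd <- cs$vs * cs$vd_frac
    vm <- (cs$vs + 2 * vd) / 3
    pi <- if (vm > 0) (cs$vs - vd) / vm else 0
    aff <- fixture_measures(cs$vs, vd, at = cs$at)
    contra <- if (is.na(cs$cvm))
      NULL else fixture_measures(cs$cvm * 1.2, cs$cvm * 0.9)
    cvm_val <- if (is.null(contra)) NA else contra$vm
    expect_identical(
      classify_tibi(aff, contra),
      tibi_truth_table(cs$vs, vd, cs$at, vm, cvm_val, pi),
      info = paste("case", i))
  }
})

test_that("dampened and stenotic grades follow side-to-side comparison", {
  contra <- fixture_measures(90, 45)  # vm = 60
  expect_identical(classify_tibi(fixture_measures(45, 22.5), contra), 3L)
  expect_identical(classify_tibi(fixture_measures(150, 75), contra), 4L)
  expect_identical(classify_tibi(fixture_measures(90, 45), contra), 5L)
  expect_error(classify_tibi(NULL), "affected-side measures")
})

test_that("the worked offending-vessel classifications return as stated", {
  # abnormal spectrum at 62 mm with ACoA cross-filling: terminal ICA
  tica <- vascular_exam(data.frame(depth = 62, grade = 2L),
                        acoa_crossfill = TRUE)
  expect_identical(classify_offending_vessel(tica), "tica")
  # minimal flow at 50 mm (M1), no collaterals: MCA
  mca <- vascular_exam(data.frame(depth = 50, grade = 1L))
  expect_identical(classify_offending_vessel(mca), "mca")
  # normal intracranial spectrum, PCoA collateral + reversed OA: proximal ICA
  prox <- vascular_exam(data.frame(depth = c(40, 55, 65),
                                   grade = c(5L, 5L, 5L)),
                        pcoa_collateral = TRUE, oa_reversed = TRUE)
  expect_identical(classify_offending_vessel(prox), "proximal_ica")
})

test_that("the vessel rule engine is total and flags contradictions", {
  grades <- c(2L, 5L)
  combos <- expand.grid(g1 = grades, g2 = grades, g3 = grades,
                        acoa = c(TRUE, FALSE), oa = c(TRUE, FALSE),
                        blunted = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    exam <- vascular_exam(
      data.frame(depth = c(40, 55, 65), grade = c(cb$g1, cb$g2, cb$g3)),
      acoa_crossfill = cb$acoa, oa_reversed = cb$oa,
      ipsilateral_mca_blunted = cb$blunted, ipsilateral_mca_vm = 30)
    out <- withCallingHandlers(
      classify_offending_vessel(exam),
      warning = function(w) invokeRestart("muffleWarning"))
    expect_true(out %in% c("proximal_ica", "tica", "mca", "indeterminate"),
                info = paste("combo", i))
  }
  # collateral flag with nothing to explain it: indeterminate with warning
  odd <- vascular_exam(data.frame(depth = 55, grade = 5L),
                       pcoa_collateral = TRUE)
  expect_warning(out <- classify_offending_vessel(odd), "indeterminate")
  expect_identical(out, "indeterminate")
})

test_that("exam validation catches malformed inputs", {
  expect_error(vascular_exam(data.frame(depth = 55, grade = 9L)), "0-5")
  expect_error(vascular_exam(data.frame(d = 1)), "columns depth and grade")
})
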