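# Coherence, phase-locking value, and phase lag index kernels and their
# trial-level wrappers.

test_that("analytic extremes: constant-lag PLI/PLV and linear-dependence COH", {
  fs <- 250
  t <- (0:249) / fs
  x <- sin(2 * pi * 20 * t)
  y <- sin(2 * pi * 20 * t - pi / 4)
  ph <- phase_series(rbind(x, y))
  expect_equal(pli_matrix(ph)[1, 2], 1)
  expect_equal(plv_matrix(ph)[1, 2], 1, tolerance = 1e-6)
  # identical signals: phase difference exactly zero, sign(0) contributes 0
  ph0 <- phase_series(rbind(x, x))
  expect_equal(pli_matrix(ph0)[1, 2], 0)
  expect_equal(plv_matrix(ph0)[1, 2], 1, tolerance = 1e-9)
  # constant phase-difference series evaluated directly
  phc <- rbind(rep(0.4, 250), rep(0.4 - pi / 3, 250))
  expect_equal(plv_matrix(phc)[1, 2], 1, tolerance = 1e-12)
  # y = 2x: coherence 1 at every bin with power, band mean 1
  set.seed(3)
  xb <- rnorm(1000)
  expect_equal(coh_matrix(rbind(xb, 2 * xb), fs)[1, 2], 1, tolerance = 1e-9)
})

test_that("PLV is invariant to a global phase offset on one channel", {
  set.seed(8)
  ph <- matrix(runif(2 * 250, -pi, pi), 2)
  shifted <- ph
  shifted[1, ] <- shifted[1, ] + 1.1
  expect_equal(plv_matrix(ph)[1, 2], plv_matrix(shifted)[1, 2],
               tolerance = 1e-12)
})

test_that("null levels match small-sample theory", {
  # uniform independent phases, K = 250: PLV below 0.17 in >= 95% of runs
  set.seed(21)
  plvs <- replicate(100, {
    ph <- matrix(runif(2 * 250, -pi, pi), 2)
    plv_matrix(ph)[1, 2]
  })
  expect_gte(mean(plvs < 0.17), 0.95)
  # independent white noise, 3 Welch segments: band COH below the
  # Monte-Carlo null 99th percentile in >= 95% of runs
  null_coh <- replicate(300, {
    coh_matrix(matrix(rnorm(500), 2), 250)[1, 2]
  })
  crit <- quantile(null_coh, 0.99)
  fresh <- replicate(100, coh_matrix(matrix(rnorm(500), 2), 250)[1, 2])
  expect_gte(mean(fresh < crit), 0.95)
})

test_that("instantaneous mixing inflates PLV but not PLI", {
  set.seed(12)
  fs <- 250
  taps <- scalpnet:::fir_bandpass(fs, 13, 30)
  res <- replicate(60, {
    s <- scalpnet:::filtfilt_rows(taps, matrix(rnorm(4 * 1250), 4))
    # volume-conduction surrogate: both channels are real mixtures of the
    # same two independent sources; rows 3-4 are unmixed controls carrying
    # the finite-sample (autocorrelated narrowband, K = 250) null level
    x <- rbind(0.8 * s[1, ] + 0.2 * s[2, ], 0.4 * s[1, ] + 0.6 * s[2, ],
               s[3, ], s[4, ])
    ph <- phase_series(x)[, 501:750]
    c(plv_matrix(ph)[1, 2], pli_matrix(ph)[1, 2],
      plv_matrix(ph[3:4, ])[1, 2], pli_matrix(ph[3:4, ])[1, 2])
  })
  # PLV rises far above its null; PLI stays at its finite-sample null level
  expect_gt(median(res[1, ]), 0.5)
  expect_gt(median(res[1, ] - res[3, ]), 0.3)
  expect_lt(abs(median(res[2, ]) - median(res[4, ])), 0.05)
  expect_lt(median(res[2, ]), 0.25)
})

test_that("vectorised kernels match direct summation to 1e-12", {
  set.seed(31)
  ph <- matrix(runif(3 * 50, -pi, pi), 3)
  P <- plv_matrix(ph)
  L <- pli_matrix(ph)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(P[i, j], plv_direct(ph[i, ], ph[j, ]), tolerance = 1e-12)
      expect_equal(L[i, j], pli_direct(ph[i, ], ph[j, ]), tolerance = 1e-12)
    }
  }
})

test_that("all measures stay in [0,1], symmetric, zero-diagonal on epochs", {
  co <- tiny_cohort()
  ses <- co$sessions[[1]]
  rec <- beta_bandpass(reinsert_reference_channel(ses$eeg, co$montage))
  ep <- epoch_record(rec, tibble::tibble(sample = ses$truth$onsets,
                                         hand = ses$truth$hands))
  for (m in c("COH", "PLV", "PLI")) {
    ct <- connectivity_trials(ep, m, "ME")
    expect_true(all(ct >= 0 & ct <= 1))
    for (tr in seq_len(dim(ct)[3])) {
      A <- ct[, , tr]
      expect_equal(A, t(A))
      expect_true(all(diag(A) == 0))
    }
  }
})

test_that("trial averaging is the element-wise mean and keeps bounds", {
  a <- matrix(c(0, .2, .2, 0), 2)
  b <- matrix(c(0, .6, .6, 0), 2)
  ct <- array(c(a, b), dim = c(2, 2, 2))
  avg <- average_trials(ct)
  expect_equal(unclass(avg)[1, 2], 0.4)
  one <- average_trials(array(a, dim = c(2, 2, 1)))
  expect_equal(unclass(one), a, ignore_attr = TRUE)
  expect_error(average_trials(array(0, dim = c(2, 3, 1))), "square")
})

test_that("the pipeline's shared-phase builder matches subject_network", {
  co <- tiny_cohort()
  ses <- co$sessions[[2]]
  rec <- beta_bandpass(reinsert_reference_channel(ses$eeg, co$montage))
  ep <- epoch_record(rec, tibble::tibble(sample = ses$truth$onsets,
                                         hand = ses$truth$hands))
  tbl <- scalpnet:::accumulate_networks(ep, c("COH", "PLV", "PLI"),
                                        c("idle", "ME"), "left", subject = 2)
  for (k in seq_len(nrow(tbl))) {
    direct <- subject_network(ep, tbl$method[k], tbl$stage[k], tbl$hand[k],
                              subject = 2)
    expect_equal(unclass(tbl$network[[k]]), unclass(direct),
                 tolerance = 1e-12,
                 info = paste(tbl$method[k], tbl$stage[k]))
  }
})

test_that("flat channels yield zero connectivity rather than NaN", {
  set.seed(2)
  x <- rbind(rnorm(500), 0, rnorm(500))
  A <- coh_matrix(x, 250)
  expect_true(all(is.finite(A)))
  expect_true(all(A[2, ] == 0) && all(A[, 2] == 0))
})
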