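# Recording-reference handling, common average reference, and REST.

make_truth_session <- function(n_src = 48, n_samp = 300, seed = 5,
                               hemisphere = "upper") {
  mont <- montage_1010(62)
  lay <- source_layer(n_src, hemisphere = hemisphere)
  G <- compute_leadfield(mont, sphere_model(), lay)
  set.seed(seed)
  S <- matrix(rnorm(n_src * n_samp), n_src)
  list(montage = mont, G = G, S = S, vinf = unclass(G) %*% S)
}

test_that("the reference channel is re-inserted as zeros", {
  x <- make_truth_session(n_src = 10, n_samp = 50)
  rec <- apply_recording_reference(
    eeg_record(x$vinf, 250, rownames(x$G), "infinity"), "REF"
  )
  expect_equal(nrow(rec$data), 62)
  back <- reinsert_reference_channel(rec, x$montage)
  expect_equal(nrow(back$data), 63)
  expect_true(all(back$data[63, ] == 0))
  expect_error(reinsert_reference_channel(back, x$montage), "already")
  # pairwise channel differences are reference-invariant
  d_orig <- x$vinf[3, ] - x$vinf[17, ]
  d_ref <- back$data[3, ] - back$data[17, ]
  expect_lt(max(abs(d_orig - d_ref)), 1e-9)
})

test_that("CAR zeroes the channel mean and is idempotent", {
  set.seed(1)
  rec <- eeg_record(matrix(rnorm(200), 10), 250, paste0("ch", 1:10))
  car <- to_car(rec)
  expect_lt(max(abs(colMeans(car$data))), 1e-10)
  expect_equal(to_car(car)$data, car$data, tolerance = 1e-12)
  expect_equal(car$reference, "CAR")
  expect_error(to_car(eeg_record(matrix(1, 1, 10), 250, "a")), "2 channels")
})

test_that("CAR of noiseless simulated data equals the average-referenced gain", {
  x <- make_truth_session(n_src = 20, n_samp = 100)
  rec <- reinsert_reference_channel(
    apply_recording_reference(
      eeg_record(x$vinf, 250, rownames(x$G), "infinity"), "REF"
    ),
    x$montage
  )
  car <- to_car(rec)
  G_avg <- leadfield_convention(x$G, "average")
  expect_lt(max(abs(car$data - unclass(G_avg) %*% x$S)), 1e-9)
})

test_that("REST recovers infinity-referenced truth exactly when determined", {
  # identifiable regime: fewer layer dipoles than channels, all under the cap
  x <- make_truth_session(n_src = 48, n_samp = 300)
  rec <- reinsert_reference_channel(
    apply_recording_reference(
      eeg_record(x$vinf, 250, rownames(x$G), "infinity"), "REF"
    ),
    x$montage
  )
  rest <- to_rest(rec, x$G)
  rel <- sqrt(sum((rest$data - x$vinf)^2) / sum(x$vinf^2))
  expect_lt(rel, 1e-6)
  expect_equal(rest$reference, "REST")
})

test_that("REST is invariant to the input reference and self-consistent", {
  x <- make_truth_session(n_src = 30, n_samp = 120)
  rec <- reinsert_reference_channel(
    apply_recording_reference(
      eeg_record(x$vinf, 250, rownames(x$G), "infinity"), "REF"
    ),
    x$montage
  )
  r1 <- to_rest(rec, x$G)
  r2 <- to_rest(to_car(rec), x$G)
  expect_lt(max(abs(r1$data - r2$data)), 1e-9)
  # subtracting REST's own mean equals CAR of the REST output
  expect_equal(to_car(r1)$data,
               sweep(r1$data, 2, colMeans(r1$data)), tolerance = 1e-12)
  zero <- eeg_record(matrix(0, 63, 50), 250, rec$labels)
  expect_true(all(to_rest(zero, x$G)$data == 0))
  bad <- eeg_record(matrix(0, 10, 50), 250, paste0("x", 1:10))
  expect_error(to_rest(bad, x$G), "match")
})

test_that("REST tolerates noise and model mismatch (10 dB, off-layer sources)", {
  # dense sources below the assumed layer, full 300-dipole layer, white
  # sensor noise at 10 dB; fidelity judged in the analysis band, where the
  # band-limited sources actually live (broadband correlation would mostly
  # measure the white-noise floor, sqrt(SNR/(1+SNR)) ~ 0.95 at best)
  mont <- montage_1010(62)
  lay <- source_layer(300)
  G <- compute_leadfield(mont, sphere_model(), lay)
  spec <- session_spec(n_subjects = 2, n_trials_per_hand = 3,
                       noise_snr_db = 10, n_sources = 48,
                       source_radius = 0.8, subject_amp_sd = 0)
  ses <- simulate_session(spec, coupling_spec(integer(0), integer(0)),
                          montage = mont, layer = lay, leadfield = G,
                          seed = 3)
  rest <- to_rest(reinsert_reference_channel(ses$eeg, mont), G)
  taps <- scalpnet:::fir_bandpass(250, 13, 30)
  rb <- scalpnet:::filtfilt_rows(taps, rest$data)
  tb <- scalpnet:::filtfilt_rows(taps, ses$truth$scalp_noiseless)
  cors <- vapply(seq_len(nrow(tb)), function(i) {
    stats::cor(rb[i, ], tb[i, ])
  }, numeric(1))
  expect_gte(median(cors), 0.95)
  expect_gte(min(cors), 0.90)
})
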