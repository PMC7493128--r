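# Forward-model simulator: beta-band cortical sources with configurable
# zero-lag / lagged pairwise coupling, projected to the scalp through the
# spherical lead field, recorded against a physical reference electrode
# between CZ and CPZ, with EMG bursts marking self-paced movement onsets.

#' Session specification for the synthetic cohort
#'
#' Defaults emulate the study conditions: 17 right-handed subjects, 250 Hz,
#' self-paced movements more than 5 s apart, beta-band (13-30 Hz) sources.
#'
#' @param n_subjects Cohort size.
#' @param n_trials_per_hand Movements per hand per subject.
#' @param fs Sampling rate (Hz); must exceed twice the upper band edge.
#' @param trial_spacing Minimum inter-movement interval (s, >= 5).
#' @param noise_snr_db Sensor signal-to-noise ratio in dB (`Inf` = noiseless).
#' @param source_band Oscillatory band of the cortical sources (Hz).
#' @param n_channels Scalp montage size, 62 or 19 (the reference site is
#'   added on top).
#' @param n_sources Number of active cortical dipoles.
#' @param source_radius Radius of the active dipoles (default 0.78,
#'   a realistic cortical depth; the REST equivalent layer sits higher).
#' @param source_tilt_deg Tilt of each active dipole away from radial, in
#'   degrees (default 40; 0 = purely radial). Folded cortex produces
#'   orientation-diverse generators whose tangential components have
#'   near-zero mean over the cap.
#' @param strength_jitter_sd Log-normal sd of the per-subject coupling
#'   strength jitter.
#' @param subject_amp_sd Log-normal sd of per-subject, per-source amplitude
#'   scaling (default 0.15): subjects differ in how strongly each cortical
#'   generator expresses itself at the scalp. Because coupling strengths
#'   are mixing fractions within a source, amplitude jitter also modulates
#'   the carrier-to-background ratio at the sensors, so large values push
#'   whole cohorts between effect-size regimes.
#' @param erd_scale Amplitude scale applied to all sources during the MP and
#'   ME windows of each trial (1 = no event-related modulation; 0.5 emulates
#'   a 50 per cent beta amplitude drop, i.e. 75 per cent power ERD).
#' @return A `session_spec` list.
#' @export
session_spec <- function(n_subjects = 17L, n_trials_per_hand = 20L, fs = 250,
                         trial_spacing = 5.5, noise_snr_db = 10,
                         source_band = c(13, 30), n_channels = 62,
                         n_sources = 16L, source_radius = 0.78,
                         source_tilt_deg = 40,
                         strength_jitter_sd = 0.1, subject_amp_sd = 0.15,
                         erd_scale = 1) {
  if (trial_spacing < 5) abort("trial_spacing must be >= 5 s")
  if (fs <= 2 * source_band[2]) abort("fs must exceed twice the upper band edge")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_trials_per_hand = as.integer(n_trials_per_hand), fs = fs,
      trial_spacing = trial_spacing, noise_snr_db = noise_snr_db,
      source_band = source_band, n_channels = n_channels,
      n_sources = as.integer(n_sources), source_radius = source_radius,
      source_tilt_deg = source_tilt_deg,
      strength_jitter_sd = strength_jitter_sd,
      subject_amp_sd = subject_amp_sd, erd_scale = erd_scale
    ),
    class = "session_spec"
  )
}

#' Pairwise source-coupling specification
#'
#' Each row couples two sources with a phase-locked component of the given
#' strength and lag, active only inside the listed stage windows of trials of
#' the given hand. Zero-lag pairs emulate couplings that volume conduction
#' and common references also mimic; lagged pairs are the ones PLI retains.
#'
#' @param source_i,source_j Source indices (into the active source set).
#' @param type `"zero_lag"` or `"lagged"`.
#' @param phase_lag Phase lag in radians, in (-pi, pi]; must be away from 0
#'   mod pi for lagged pairs (0 is forced for zero-lag pairs).
#' @param strength Mixing weight in `[0, 1]` of the shared component.
#' @param stages Character vector, subset of `c("idle", "MP", "ME")`.
#' @param hand `"left"`, `"right"` or `"both"`.
#' @return A tibble with one row per coupled pair.
#' @export
coupling_spec <- function(source_i, source_j, type = "zero_lag",
                          phase_lag = 0, strength = 0.8, stages = "ME",
                          hand = "both") {
  df <- tibble(
    source_i = as.integer(source_i), source_j = as.integer(source_j),
    type = type, phase_lag = phase_lag, strength = strength,
    stages = if (is.list(stages)) stages else list(stages), hand = hand
  )
  if (!all(df$type %in% c("zero_lag", "lagged"))) abort("unknown coupling type")
  if (any(df$strength < 0 | df$strength > 1)) abort("strength must be in [0, 1]")
  if (any(df$phase_lag <= -pi | df$phase_lag > pi)) {
    abort("phase_lag must be in (-pi, pi]")
  }
  df$phase_lag[df$type == "zero_lag"] <- 0
  bad <- df$type == "lagged" &
    (abs(sin(df$phase_lag)) < 1e-6)
  if (any(bad)) abort("lagged pairs need phase_lag away from 0 mod pi")
  st <- unique(unlist(df$stages))
  if (!all(st %in% c("idle", "MP", "ME"))) {
    abort(sprintf("invalid stage name: %s",
                  paste(setdiff(st, c("idle", "MP", "ME")), collapse = ", ")))
  }
  if (!all(df$hand %in% c("left", "right", "both"))) abort("invalid hand")
  df
}

# Movement onsets: first one after 3.5 s of idle context, then gaps of
# trial_spacing plus uniform jitter up to 1 s. Hands are a seeded balanced
# shuffle.
simulate_onsets <- function(spec) {
  n <- 2L * spec$n_trials_per_hand
  gaps <- spec$trial_spacing + runif(n - 1, 0.05, 1)
  t0 <- 3.5 + runif(1, 0, 0.5)
  times <- cumsum(c(t0, gaps))
  hands <- sample(rep(c("left", "right"), spec$n_trials_per_hand))
  list(onsets = round(times * spec$fs), hands = hands)
}

# Raised-cosine windowed stage envelope over the whole session: 1 inside
# each [start_ms, end_ms) window around matching-hand onsets, 50 ms ramps.
stage_envelope <- function(n_samples, fs, onsets, hands, stages, hand,
                           windows = stage_windows(), ramp_ms = 50) {
  env <- numeric(n_samples)
  ramp_n <- max(1L, round(ramp_ms / 1000 * fs))
  ramp_up <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
  take <- if (hand == "both") rep(TRUE, length(onsets)) else hands == hand
  for (o in onsets[take]) {
    for (st in stages) {
      w <- windows[[st]]
      i0 <- o + round(w[1] / 1000 * fs)
      i1 <- o + round(w[2] / 1000 * fs) # half-open
      seg <- rep(1, i1 - i0)
      nr <- min(ramp_n, length(seg))
      seg[seq_len(nr)] <- pmax(seg[seq_len(nr)] * 0, ramp_up[seq_len(nr)])
      seg[length(seg) + 1 - seq_len(nr)] <-
        pmin(seg[length(seg) + 1 - seq_len(nr)], rev(ramp_up[seq_len(nr)]))
      idx <- (i0 + 1):i1
      ok <- idx >= 1 & idx <= n_samples
      env[idx[ok]] <- pmax(env[idx[ok]], seg[ok])
    }
  }
  env
}

#' Simulate coupled beta-band cortical sources
#'
#' Each source is band-limited filtered white noise at unit RMS. Coupled
#' pairs additionally share a band-limited noise carrier in the same band
#' (the second pair member receives the analytic-signal copy rotated by the
#' specified phase lag), crossfaded in and out of the active stage windows
#' with 50 ms raised-cosine ramps. With mixing weight a, a source inside an
#' active window is `sqrt(1 - a^2) * background + a * carrier`. A stochastic
#' carrier (rather than a pure tone) keeps the phase difference diffusing on
#' a realistic timescale — with a tone, the sign of the phase difference
#' persists across whole analysis windows and sign-based measures such as
#' the phase lag index acquire a large finite-sample bias that the measure
#' does not show on real oscillations.
#'
#' @param spec A [session_spec()].
#' @param coupling A [coupling_spec()] tibble (zero rows = pure null).
#' @param onsets,hands Movement onset samples and hand labels.
#' @param n_samples Session length in samples.
#' @return List with `sources` (n_sources x n_samples), and the envelope
#'   bookkeeping used by the ground truth.
#' @export
simulate_sources <- function(spec, coupling, onsets, hands, n_samples) {
  fs <- spec$fs
  taps <- fir_bandpass(fs, spec$source_band[1], spec$source_band[2])
  S <- matrix(rnorm(spec$n_sources * n_samples), spec$n_sources)
  S <- filtfilt_rows(taps, S)
  S <- S / sqrt(rowMeans(S^2))
  if (nrow(coupling) > 0) {
    if (max(coupling$source_i, coupling$source_j) > spec$n_sources) {
      abort("coupling references a source beyond n_sources")
    }
    for (r in seq_len(nrow(coupling))) {
      cp <- coupling[r, ]
      env <- stage_envelope(
        n_samples, fs, onsets, hands,
        stages = cp$stages[[1]], hand = cp$hand
      )
      nc <- filtfilt_rows(taps, matrix(rnorm(n_samples), 1))
      z <- analytic_rows(nc)[1, ]
      z <- z / sqrt(mean(Re(z)^2))
      ci <- Re(z)
      cj <- Re(z * exp(-1i * cp$phase_lag))
      a <- cp$strength * env
      i <- cp$source_i
      j <- cp$source_j
      S[i, ] <- sqrt(pmax(0, 1 - a^2)) * S[i, ] + a * ci
      S[j, ] <- sqrt(pmax(0, 1 - a^2)) * S[j, ] + a * cj
    }
  }
  if (spec$erd_scale != 1) {
    env <- stage_envelope(n_samples, fs, onsets, hands,
                          stages = c("MP", "ME"), hand = "both")
    scl <- 1 + (spec$erd_scale - 1) * env
    S <- S * rep(scl, each = nrow(S))
  }
  S
}

#' Project source activity to the scalp
#'
#' `data = gain x sources` plus spatially white Gaussian sensor noise scaled
#' so that total signal power over all channels sits at `noise_snr_db` above
#' the noise power.
#'
#' @param sources Sources x samples matrix.
#' @param leadfield Infinity-referenced gain (channels x sources).
#' @param fs Sampling rate for the resulting record.
#' @param noise_snr_db SNR in dB; `Inf` adds no noise.
#' @return List with the noisy `record` (reference `"infinity"`) and the
#'   `noiseless` channel matrix.
#' @export
project_to_scalp <- function(sources, leadfield, fs, noise_snr_db = Inf) {
  if (attr(leadfield, "convention") != "infinity") {
    abort("leadfield must be infinity-referenced")
  }
  if (ncol(leadfield) != nrow(sources)) {
    abort("leadfield / sources dimension mismatch")
  }
  clean <- unclass(leadfield) %*% sources
  noisy <- clean
  if (is.finite(noise_snr_db)) {
    p_sig <- mean(clean^2)
    sd_n <- sqrt(p_sig / 10^(noise_snr_db / 10))
    noisy <- clean + matrix(rnorm(length(clean), sd = sd_n), nrow(clean))
  }
  list(
    record = eeg_record(noisy, fs, labels = rownames(leadfield),
                        reference = "infinity"),
    noiseless = clean
  )
}

#' Apply the physical recording reference
#'
#' Subtracts the reference electrode's row from every channel and drops it
#' from the output, as a real amplifier does.
#'
#' @param record An infinity-referenced `eeg_record` containing `ref_label`.
#' @param ref_label Recording-reference channel label.
#' @return An `eeg_record` with reference `"electrode:<ref_label>"`.
#' @export
apply_recording_reference <- function(record, ref_label = "REF") {
  i <- match(toupper(ref_label), toupper(record$labels))
  if (is.na(i)) abort(sprintf("reference label %s not in record", ref_label))
  dat <- sweep(record$data, 2, record$data[i, ])
  dat <- dat[-i, , drop = FALSE]
  eeg_record(dat, record$fs, labels = record$labels[-i],
             reference = paste0("electrode:", ref_label))
}

#' Simulate bipolar EMG with movement bursts
#'
#' Baseline Gaussian noise on both arm channels plus a 6-50 Hz band-limited
#' burst of 0.5 s on the moving arm's channel at each onset, with amplitude
#' `burst_gain` times the baseline RMS. The burst carrier mixes a 35 Hz
#' tone (random phase per burst) with band-limited noise in equal power, and
#' starts at full amplitude: muscle bursts begin abruptly, and a sharp
#' energy rise is what gives the movement onset a well-defined time.
#'
#' @param spec A [session_spec()].
#' @param onsets,hands Onset samples and hand labels.
#' @param n_samples Session length in samples.
#' @param burst_gain Burst amplitude relative to baseline RMS (>= 5 for
#'   reliable detection).
#' @return An `eeg_record` with channels `EMG_left`, `EMG_right` and
#'   reference tag `"bipolar"`.
#' @export
simulate_emg <- function(spec, onsets, hands, n_samples, burst_gain = 8) {
  if (length(onsets) > 1 && any(diff(onsets) < spec$fs)) {
    abort("EMG bursts would overlap (onsets < 1 s apart)")
  }
  fs <- spec$fs
  dat <- matrix(rnorm(2 * n_samples), 2)
  taps <- fir_bandpass(fs, 6, 50, transition = 12)
  burst_n <- round(0.5 * fs)
  pad_n <- 3 * length(taps)
  ramp_n <- max(1L, round(0.05 * fs))
  envlp <- rep(1, burst_n)
  envlp[burst_n + 1 - seq_len(ramp_n)] <- seq(0, 1, length.out = ramp_n)
  tt <- (seq_len(burst_n) - 1) / fs
  for (k in seq_along(onsets)) {
    ch <- if (hands[k] == "left") 1L else 2L
    idx <- onsets[k] + seq_len(burst_n) - 1L
    idx <- idx[idx <= n_samples]
    noise <- filtfilt_rows(taps, matrix(rnorm(burst_n + 2 * pad_n), 1))[1, ]
    noise <- noise[pad_n + seq_len(burst_n)]
    noise <- noise / sqrt(mean(noise^2))
    tone <- sqrt(2) * sin(2 * pi * 35 * tt + runif(1, 0, 2 * pi))
    carrier <- sqrt(0.85) * tone + sqrt(0.15) * noise
    dat[ch, idx] <- dat[ch, idx] +
      burst_gain * (envlp * carrier)[seq_along(idx)]
  }
  eeg_record(dat, fs, labels = c("EMG_left", "EMG_right"),
             reference = "bipolar")
}

# Choose the layer dipoles hosting the active sources: named scalp targets
# first, padded with background dipoles spread over the upper layer.
resolve_anchors <- function(spec, layer, montage, source_targets = NULL) {
  anchors <- if (is.null(source_targets)) {
    source_anchors(layer, montage)
  } else {
    source_anchors(layer, montage, source_targets)
  }
  if (spec$n_sources <= length(anchors)) {
    return(anchors[seq_len(spec$n_sources)])
  }
  upper <- which(layer$positions[, 3] > 0.2 * layer$radius)
  extra <- setdiff(upper[round(seq(1, length(upper),
                                   length.out = spec$n_sources))], anchors)
  c(anchors, extra)[seq_len(spec$n_sources)]
}

# Lead field of the active simulated dipoles: anchor directions taken from
# the equivalent layer, scaled to the (deeper) active source radius. At the
# layer's own radius with zero tilt the anchor dipoles coincide with layer
# dipoles, putting simulated activity exactly in REST's assumed source
# space. By default each dipole is tilted away from radial by a fixed angle
# with a deterministic (golden-angle) azimuth per source: cortical
# generators sit in folded tissue with diverse orientations, and the
# tangential components this adds have near-zero mean over the electrode
# cap, which keeps the simulated common-mode realistic.
active_source_leadfield <- function(spec, montage, model, layer, anchors) {
  dirs <- layer$positions[anchors, , drop = FALSE] / layer$radius
  tilt <- spec$source_tilt_deg * pi / 180
  ori <- dirs
  if (tilt > 0) {
    for (i in seq_len(nrow(dirs))) {
      r <- dirs[i, ]
      # deterministic tangent frame per source
      up <- if (abs(r[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      t1 <- up - sum(up * r) * r
      t1 <- t1 / sqrt(sum(t1^2))
      t2 <- c(
        r[2] * t1[3] - r[3] * t1[2],
        r[3] * t1[1] - r[1] * t1[3],
        r[1] * t1[2] - r[2] * t1[1]
      )
      az <- (i - 1) * pi * (3 - sqrt(5))
      ori[i, ] <- cos(tilt) * r +
        sin(tilt) * (cos(az) * t1 + sin(az) * t2)
    }
  }
  act <- structure(
    list(positions = dirs * spec$source_radius, orientations = ori,
         radius = spec$source_radius, n = length(anchors)),
    class = "source_space"
  )
  compute_leadfield(montage, model, act, "infinity")
}

# Anchor the active simulated sources to layer dipoles under named scalp
# targets, so simulated activity lies exactly in REST's assumed source space.
source_anchors <- function(layer, montage,
                           targets = c("C3", "C4", "Cz", "F3", "F4", "P3",
                                       "P4", "O1", "O2", "T7", "T8", "Fz",
                                       "Fp1", "Fp2", "P7", "P8")) {
  pos <- montage_positions(montage)
  idx <- match(toupper(targets), toupper(rownames(pos)))
  if (anyNA(idx)) abort("source target label missing from montage")
  vapply(idx, function(i) {
    which.max(layer$positions %*% pos[i, ])
  }, integer(1))
}

#' Simulate one recording session
#'
#' Generates onsets, coupled sources, scalp projection, recording-reference
#' application, and EMG, returning the triple a real experiment would yield
#' plus the ground truth it would not.
#'
#' @param spec A [session_spec()].
#' @param coupling A [coupling_spec()] tibble.
#' @param montage,model,layer Head-model objects; defaults derive from the
#'   spec's channel count.
#' @param leadfield Optional precomputed infinity-referenced gain over the
#'   full layer (channels x layer dipoles); computed when missing.
#' @param source_targets Scalp labels anchoring the active sources.
#' @param seed Integer seed; the session is a pure function of it.
#' @return List with `eeg` (reference `"electrode:REF"`), `emg`, and `truth`
#'   (onsets, hands, sources, noiseless infinity-referenced scalp data,
#'   realised coupling table, anchor indices).
#' @export
simulate_session <- function(spec, coupling, montage = NULL, model = sphere_model(),
                             layer = source_layer(), leadfield = NULL,
                             active_leadfield = NULL, source_targets = NULL,
                             seed = 1L) {
  set.seed(seed)
  if (is.null(montage)) montage <- montage_1010(spec$n_channels)
  if (is.null(leadfield)) {
    leadfield <- compute_leadfield(montage, model, layer, "infinity")
  }
  on <- simulate_onsets(spec)
  n_samples <- max(on$onsets) + round(3 * spec$fs)
  anchors <- resolve_anchors(spec, layer, montage, source_targets)
  S <- simulate_sources(spec, coupling, on$onsets, on$hands, n_samples)
  if (spec$subject_amp_sd > 0) {
    S <- S * exp(rnorm(nrow(S), 0, spec$subject_amp_sd))
  }
  if (is.null(active_leadfield)) {
    active_leadfield <- active_source_leadfield(spec, montage, model, layer,
                                                anchors)
  }
  proj <- project_to_scalp(S, active_leadfield, spec$fs, spec$noise_snr_db)
  eeg <- apply_recording_reference(proj$record, reference_label(montage))
  emg <- simulate_emg(spec, on$onsets, on$hands, n_samples)
  truth <- structure(
    list(
      onsets = on$onsets, hands = on$hands, sources = S,
      scalp_noiseless = proj$noiseless, coupling = coupling,
      anchors = anchors, fs = spec$fs, seed = seed
    ),
    class = "ground_truth"
  )
  list(eeg = eeg, emg = emg, truth = truth)
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds derive deterministically from the master seed; coupling
#' strengths are jittered log-normally across subjects (sd
#' `spec$strength_jitter_sd`, capped at 1).
#'
#' @inheritParams simulate_session
#' @param master_seed Master seed for the whole cohort.
#' @return A list of class `cohort`: `sessions` (one [simulate_session()]
#'   result per subject), plus the shared `montage`, `model`, `layer`,
#'   `leadfield`, and `spec`.
#' @export
simulate_cohort <- function(spec, coupling, montage = NULL,
                            model = sphere_model(), layer = source_layer(),
                            source_targets = NULL, master_seed = 1L) {
  if (spec$n_subjects < 2) abort("paired tests need n_subjects >= 2")
  if (is.null(montage)) montage <- montage_1010(spec$n_channels)
  G <- compute_leadfield(montage, model, layer, "infinity")
  G_act <- active_source_leadfield(
    spec, montage, model, layer,
    resolve_anchors(spec, layer, montage, source_targets)
  )
  sessions <- lapply(seq_len(spec$n_subjects), function(s) {
    sseed <- derive_seed(master_seed, s)
    set.seed(sseed)
    cp <- coupling
    if (nrow(cp) > 0 && spec$strength_jitter_sd > 0) {
      cp$strength <- pmin(
        1, cp$strength * exp(rnorm(nrow(cp), 0, spec$strength_jitter_sd))
      )
    }
    simulate_session(spec, cp, montage, model, layer, leadfield = G,
                     active_leadfield = G_act,
                     source_targets = source_targets, seed = sseed)
  })
  structure(
    list(sessions = sessions, montage = montage, model = model,
         layer = layer, leadfield = G, spec = spec, master_seed = master_seed),
    class = "cohort"
  )
}
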