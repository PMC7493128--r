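# Adjacency-matrix construction: magnitude-squared coherence (Welch),
# phase-locking value, and phase lag index, per trial and stage, averaged
# into subject-level networks.
#
# All three measures are bounded in [0, 1]; matrices are symmetric with a
# zero diagonal. A channel that is flat inside the analysis window carries
# no phase or spectral information, so its edges are set to 0 rather than
# propagating 0/0.

new_conn_matrix <- function(A, method, labels, stage = NA, reference = NA,
                            hand = NA, subject = NA) {
  dimnames(A) <- list(labels, labels)
  structure(A,
    class = c("conn_matrix", "matrix"), method = method, stage = stage,
    reference = reference, hand = hand, subject = subject
  )
}

flat_channels <- function(x, tol = 1e-12) {
  sds <- apply(x, 1, sd)
  sds <= tol * max(sds, 1e-300)
}

zero_out <- function(A, flat) {
  A[flat, ] <- 0
  A[, flat] <- 0
  A
}

#' Connectivity kernels for a single window
#'
#' Low-level single-window estimators on a channels x samples matrix.
#' `coh_matrix()` computes Welch auto-/cross-spectra and averages the
#' per-bin magnitude-squared coherence `|S_xy|^2 / (S_xx S_yy)` over the
#' frequency bins inside `band`. `phase_series()` returns instantaneous
#' phases via the analytic signal. `plv_matrix()` is the modulus of the
#' mean unit phasor of the pairwise phase difference; `pli_matrix()` the
#' modulus of the mean sign of the phase difference (sign(0) contributes 0,
#' so zero-lag coupling is discarded).
#'
#' @param x Channels x samples numeric matrix.
#' @param fs Sampling rate (Hz).
#' @param band Frequency band in Hz (bins inside the closed interval are
#'   averaged).
#' @param seg_len,overlap Welch segmentation (>= 2 segments required).
#' @return `coh_matrix`, `plv_matrix`, `pli_matrix`: symmetric channels x
#'   channels matrix in `[0, 1]` with zero diagonal. `phase_series`: channels
#'   x samples phase matrix in (-pi, pi].
#' @export
coh_matrix <- function(x, fs, band = c(13, 30), seg_len = 125L,
                       overlap = 0.5) {
  nf <- floor(seg_len / 2) + 1L
  freq <- (seq_len(nf) - 1L) * fs / seg_len
  sel <- which(freq >= band[1] & freq <= band[2])
  if (length(sel) == 0) abort("no frequency bins inside the band")
  ws <- welch_cross_spectra(x, fs, seg_len, overlap, freq_sel = sel)
  bins <- seq_along(sel)
  C <- nrow(x)
  acc <- matrix(0, C, C)
  for (k in bins) {
    S <- ws$S[k, , ]
    auto <- Re(diag(S))
    denom <- outer(auto, auto)
    coh <- Mod(S)^2 / denom
    coh[denom <= 0] <- 0
    acc <- acc + coh
  }
  A <- acc / length(bins)
  A <- (A + t(A)) / 2
  A <- pmin(pmax(A, 0), 1)
  diag(A) <- 0
  zero_out(A, flat_channels(x))
}

#' @rdname coh_matrix
#' @export
phase_series <- function(x) {
  Arg(analytic_rows(x))
}

#' @rdname coh_matrix
#' @param phases Channels x samples matrix of instantaneous phases (from
#'   [phase_series()], windowed to the stage of interest).
#' @export
plv_matrix <- function(phases) {
  Z <- exp(1i * phases)
  A <- Mod(Z %*% Conj(t(Z))) / ncol(phases)
  A <- pmin(A, 1)
  diag(A) <- 0
  A
}

#' @rdname coh_matrix
#' @export
pli_matrix <- function(phases) {
  K <- ncol(phases)
  acc <- pli_sign_accum(cos(phases), sin(phases))
  A <- abs(acc) / K
  diag(A) <- 0
  A
}

# Fraction of per-channel power outside the band, for the band-limitation
# warning on phase measures.
out_of_band_fraction <- function(x, fs, band) {
  n <- ncol(x)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  pw <- Mod(t(stats::mvfft(t(x))))^2
  pw <- pw[, keep, drop = FALSE]
  f <- f[keep]
  inb <- f >= band[1] & f <= band[2]
  1 - sum(pw[, inb]) / sum(pw)
}

#' Per-trial connectivity matrices for a stage
#'
#' Builds one adjacency matrix per trial from an epoched recording. For the
#' phase measures (PLV, PLI) the analytic signal is computed on the full
#' epoch and then windowed to the stage, which avoids boundary bias inside
#' the 1 s windows; PLV/PLI expect band-limited input and warn otherwise.
#' COH estimates Welch spectra inside the stage window (125-sample segments,
#' 50 per cent overlap at 250 Hz: 3 segments, 2 Hz resolution) and averages
#' the bins inside `band`.
#'
#' @param epochs An `eeg_epochs` object (band-pass filtered for PLV/PLI).
#' @param method `"COH"`, `"PLV"`, or `"PLI"`.
#' @param stage `"idle"`, `"MP"`, or `"ME"`.
#' @param hand Optional hand filter (`"left"` / `"right"`).
#' @param band Analysis band (Hz).
#' @param seg_len,overlap Welch parameters for COH.
#' @return Channels x channels x trials array, class `conn_trials`, with
#'   method/stage/hand/reference metadata.
#' @export
connectivity_trials <- function(epochs, method = c("COH", "PLV", "PLI"),
                                stage = "ME", hand = NULL, band = c(13, 30),
                                seg_len = 125L, overlap = 0.5) {
  method <- match.arg(method)
  stg <- extract_stage(epochs, stage, hand)
  nt <- dim(stg)[1]
  C <- dim(stg)[2]
  keep <- if (is.null(hand)) seq_along(epochs$hand) else
    which(epochs$hand == hand)
  out <- array(0, dim = c(C, C, nt))
  if (method == "COH") {
    for (tr in seq_len(nt)) {
      x <- matrix(stg[tr, , ], C)
      out[, , tr] <- coh_matrix(x, epochs$fs, band, seg_len, overlap)
    }
  } else {
    w <- stage_windows()[[stage]]
    idx <- which(epochs$times_ms >= w[1] & epochs$times_ms < w[2])
    warned <- FALSE
    for (tr in seq_len(nt)) {
      full <- matrix(epochs$data[keep[tr], , ], C)
      if (!warned && out_of_band_fraction(full, epochs$fs, band) > 0.3) {
        warn("phase measures expect band-limited input; filter first")
        warned <- TRUE
      }
      flat <- flat_channels(matrix(stg[tr, , ], C))
      ph <- phase_series(full)[, idx, drop = FALSE]
      A <- if (method == "PLV") plv_matrix(ph) else pli_matrix(ph)
      out[, , tr] <- zero_out(A, flat)
    }
  }
  dimnames(out) <- list(epochs$labels, epochs$labels, NULL)
  structure(out,
    class = c("conn_trials", "array"), method = method, stage = stage,
    reference = epochs$reference, hand = if (is.null(hand)) "both" else hand,
    band = band
  )
}

#' Average per-trial matrices into a subject-level network
#'
#' Element-wise mean over trials; symmetry and the `[0, 1]` bounds are
#' preserved by convexity.
#'
#' @param ct A `conn_trials` array (or a plain C x C x trials array).
#' @param subject Optional subject identifier carried in the metadata.
#' @return A `conn_matrix`.
#' @export
average_trials <- function(ct, subject = NA) {
  stopifnot(length(dim(ct)) == 3)
  if (dim(ct)[1] != dim(ct)[2]) abort("trial matrices must be square")
  A <- apply(ct, c(1, 2), mean)
  new_conn_matrix(
    A,
    method = attr(ct, "method") %||% NA,
    labels = dimnames(ct)[[1]] %||% paste0("ch", seq_len(dim(ct)[1])),
    stage = attr(ct, "stage") %||% NA,
    reference = attr(ct, "reference") %||% NA,
    hand = attr(ct, "hand") %||% NA,
    subject = subject
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subject-level network in one call
#'
#' Convenience wrapper: [connectivity_trials()] then [average_trials()].
#'
#' @inheritParams connectivity_trials
#' @inheritParams average_trials
#' @return A `conn_matrix`.
#' @export
subject_network <- function(epochs, method, stage, hand = NULL,
                            band = c(13, 30), subject = NA) {
  average_trials(
    connectivity_trials(epochs, method, stage, hand, band),
    subject = subject
  )
}

# Shared-work builder used by the pipeline: computes subject-level average
# networks for every method x stage x hand cell of one epoched recording,
# computing the analytic phases of each trial once for both phase measures.
# Equivalent to subject_network() over the grid, just faster.
accumulate_networks <- function(epochs, methods, stages, hands,
                                band = c(13, 30), subject = NA) {
  C <- dim(epochs$data)[2]
  fs <- epochs$fs
  need_phase <- any(methods %in% c("PLV", "PLI"))
  sidx <- lapply(stages, function(st) {
    w <- stage_windows()[[st]]
    which(epochs$times_ms >= w[1] & epochs$times_ms < w[2])
  })
  names(sidx) <- stages
  out <- list()
  for (hand in hands) {
    trials <- which(epochs$hand == hand)
    if (length(trials) == 0) abort(sprintf("no %s-hand trials", hand))
    acc <- lapply(methods, function(m) {
      lapply(stages, function(s) matrix(0, C, C))
    })
    names(acc) <- methods
    for (m in methods) names(acc[[m]]) <- stages
    for (tr in trials) {
      full <- matrix(epochs$data[tr, , ], C)
      ph <- if (need_phase) phase_series(full) else NULL
      for (st in stages) {
        x <- full[, sidx[[st]], drop = FALSE]
        flat <- flat_channels(x)
        for (m in methods) {
          A <- switch(m,
            COH = coh_matrix(x, fs, band),
            PLV = zero_out(plv_matrix(ph[, sidx[[st]], drop = FALSE]), flat),
            PLI = zero_out(pli_matrix(ph[, sidx[[st]], drop = FALSE]), flat)
          )
          acc[[m]][[st]] <- acc[[m]][[st]] + A
        }
      }
    }
    for (m in methods) {
      for (st in stages) {
        A <- new_conn_matrix(acc[[m]][[st]] / length(trials), m,
                             epochs$labels, stage = st,
                             reference = epochs$reference, hand = hand,
                             subject = subject)
        out[[length(out) + 1L]] <- tibble(
          subject = subject, method = m, stage = st, hand = hand,
          network = list(A)
        )
      }
    }
  }
  bind_rows(out)
}

#' Write a connectivity matrix as TSV
#'
#' Channel labels appear as a header row and first column.
#'
#' @param A A `conn_matrix`.
#' @param path Output path.
#' @export
write_conn_matrix <- function(A, path) {
  df <- data.frame(channel = rownames(A), unclass(A), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
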