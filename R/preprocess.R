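# Beta-band filtering, epoching around EMG onsets, stage extraction, and the
# Hanning-taper time-frequency ERD check.

#' Stage windows relative to movement onset
#'
#' Idle, movement-preparation (MP) and movement-execution (ME) windows in ms
#' relative to EMG onset (0 ms), each 1000 ms long and half-open.
#'
#' @return Named list of `c(start_ms, end_ms)` pairs.
#' @export
stage_windows <- function() {
  list(idle = c(-3000, -2000), MP = c(-1000, 0), ME = c(0, 1000))
}

#' Band-pass filter a record into the beta band
#'
#' Zero-phase FIR 13-30 Hz band-pass applied to the continuous data before
#' epoching (filtering after segmentation would smear edge artifacts into
#' the stage windows).
#'
#' @param record An `eeg_record`.
#' @param band Band edges in Hz.
#' @return The filtered record.
#' @export
beta_bandpass <- function(record, band = c(13, 30)) {
  stopifnot(inherits(record, "eeg_record"))
  if (record$fs < 100) abort("fs too low for beta-band filtering")
  taps <- fir_bandpass(record$fs, band[1], band[2])
  eeg_record(filtfilt_rows(taps, record$data), record$fs, record$labels,
             record$reference)
}

#' Segment a continuous record into movement epochs
#'
#' Epochs span (-3000, 2000) ms around each EMG onset (half-open sample
#' convention: at 250 Hz, samples `[onset - 750, onset + 500)`). Onsets
#' lacking 3000 ms of history or 2000 ms of future are dropped with a
#' message.
#'
#' @param record An `eeg_record`.
#' @param onsets An `onset_list` tibble from [detect_onsets()] (or a ground
#'   truth: any data frame with `sample` and `hand`).
#' @return An `eeg_epochs` object (trials x channels x samples).
#' @export
epoch_record <- function(record, onsets) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  pre <- round(3 * fs)
  post <- round(2 * fs)
  n <- ncol(record$data)
  ok <- onsets$sample - pre >= 1 & onsets$sample + post - 1 <= n
  if (any(!ok)) {
    message(sprintf("dropping %d trial(s) lacking epoch context", sum(!ok)))
  }
  kept <- onsets[ok, ]
  if (nrow(kept) == 0) abort("no usable trials")
  nsamp <- pre + post
  dat <- array(0, dim = c(nrow(kept), nrow(record$data), nsamp))
  for (t in seq_len(nrow(kept))) {
    i0 <- kept$sample[t] - pre
    dat[t, , ] <- record$data[, i0:(i0 + nsamp - 1L)]
  }
  new_eeg_epochs(
    dat, fs,
    times_ms = (seq_len(nsamp) - 1 - pre) * 1000 / fs,
    hand = kept$hand, labels = record$labels, reference = record$reference
  )
}

#' Extract one stage window from epochs
#'
#' Half-open windows: at 250 Hz, idle = epoch samples `[0, 250)`, MP =
#' `[500, 750)`, ME = `[750, 1000)` (ME's first sample is movement onset,
#' 0 ms).
#'
#' @param epochs An `eeg_epochs` object.
#' @param stage `"idle"`, `"MP"`, or `"ME"`.
#' @param hand Optional filter: keep only trials of this hand.
#' @return Trials x channels x (fs) array with a `times_ms` attribute.
#' @export
extract_stage <- function(epochs, stage, hand = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  w <- stage_windows()[[stage]]
  if (is.null(w)) abort(sprintf("unknown stage '%s'", stage))
  fs <- epochs$fs
  idx <- which(epochs$times_ms >= w[1] & epochs$times_ms < w[2])
  keep <- if (is.null(hand)) {
    seq_along(epochs$hand)
  } else {
    which(epochs$hand == hand)
  }
  if (length(keep) == 0) abort("no trials for requested hand")
  out <- epochs$data[keep, , idx, drop = FALSE]
  attr(out, "times_ms") <- epochs$times_ms[idx]
  attr(out, "labels") <- epochs$labels
  attr(out, "fs") <- fs
  out
}

#' Time-frequency ERD/ERS map (sliding Hanning taper)
#'
#' Sliding-window Hanning-taper power per channel, frequency, and time,
#' averaged over trials and expressed as percent change relative to that
#' channel/frequency's mean power in the baseline window. Negative values
#' are event-related desynchronisation (ERD), positive event-related
#' synchronisation (ERS).
#'
#' @param epochs An `eeg_epochs` object (raw, not band-filtered).
#' @param freqs Frequency grid in Hz (default 13-30 Hz at 1 Hz).
#' @param baseline Baseline window in ms (default the idle stage, -3000 to
#'   -2000 ms).
#' @param window_ms Taper length (ms).
#' @param step_ms Hop between window centres (ms).
#' @return A `tfr_map`: list with `power` (channels x freqs x times array of
#'   percent change), `times_ms` (window centres), `freqs`, `labels`,
#'   `baseline`.
#' @export
tfr_erd <- function(epochs, freqs = 13:30, baseline = c(-3000, -2000),
                    window_ms = 500, step_ms = 50) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$fs
  nt <- dim(epochs$data)[1]
  nc <- dim(epochs$data)[2]
  ns <- dim(epochs$data)[3]
  wlen <- round(window_ms / 1000 * fs)
  if (wlen > ns) abort("taper window longer than the epoch")
  if (baseline[1] < epochs$times_ms[1] ||
      baseline[2] > epochs$times_ms[ns] + 1000 / fs) {
    abort("baseline outside the epoch")
  }
  step <- max(1L, round(step_ms / 1000 * fs))
  starts <- seq(1L, ns - wlen + 1L, by = step)
  centers_ms <- epochs$times_ms[starts] + (wlen / 2) * 1000 / fs
  win <- as.numeric(signal::hanning(wlen))
  tt <- (seq_len(wlen) - 1) / fs
  # complex exponential basis evaluated once: wlen x nf
  basis <- exp(-2i * pi * outer(tt, freqs)) * win
  pow <- array(0, dim = c(nc, length(freqs), length(starts)))
  for (tr in seq_len(nt)) {
    for (k in seq_along(starts)) {
      seg <- epochs$data[tr, , starts[k]:(starts[k] + wlen - 1L), drop = TRUE]
      if (nc == 1) seg <- matrix(seg, 1)
      coef <- seg %*% basis # nc x nf
      pow[, , k] <- pow[, , k] + Mod(coef)^2
    }
  }
  pow <- pow / nt
  in_base <- centers_ms >= baseline[1] & centers_ms <= baseline[2]
  if (!any(in_base)) abort("no taper windows fall inside the baseline")
  base_pow <- apply(pow[, , in_base, drop = FALSE], c(1, 2), mean)
  rel <- 100 * (pow / as.vector(base_pow) - 1)
  structure(
    list(power = rel, times_ms = centers_ms, freqs = freqs,
         labels = epochs$labels, baseline = baseline),
    class = "tfr_map"
  )
}

#' Export a TFR map as long-format TSV
#'
#' Columns: channel, freq, time_ms, percent_change.
#'
#' @param tfr A `tfr_map`.
#' @param path Output path.
#' @export
write_tfr <- function(tfr, path) {
  df <- expand.grid(
    channel = tfr$labels, freq = tfr$freqs, time_ms = tfr$times_ms,
    stringsAsFactors = FALSE
  )
  df$percent_change <- as.vector(tfr$power)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
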