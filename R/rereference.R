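# Re-referencing: common average reference and the reference electrode
# standardization technique (REST). REST maps average-referenced scalp data
# back towards potentials against a point at infinity via an equivalent
# dipole layer: T = G_inf %*% pinv(G_avg), applied to the average-referenced
# data, which makes the operation invariant to the input reference.

#' Re-insert the recording-reference channel as zeros
#'
#' A recording referenced at electrode r measured that electrode as zero and
#' dropped it; CAR and REST need the full channel set, so the row is
#' restored (all zeros) before re-referencing. After CAR/REST it carries a
#' meaningful signal.
#'
#' @param record An `eeg_record` with reference `"electrode:<r>"`.
#' @param montage Montage naming the reference site.
#' @return The record with the reference row appended.
#' @export
reinsert_reference_channel <- function(record, montage) {
  ref <- reference_label(montage)
  if (is.na(ref)) abort("montage declares no reference site")
  if (toupper(ref) %in% toupper(record$labels)) {
    abort(sprintf("channel %s already present", ref))
  }
  dat <- rbind(record$data, 0)
  eeg_record(dat, record$fs, labels = c(record$labels, ref),
             reference = record$reference)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean over all channels from every channel.
#' Idempotent; requires at least two channels. Re-insert the recording
#' reference first so the average runs over the full montage.
#'
#' @param record An `eeg_record`.
#' @return The record with reference tag `"CAR"`.
#' @export
to_car <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  if (nrow(record$data) < 2) abort("CAR needs at least 2 channels")
  dat <- sweep(record$data, 2, colMeans(record$data))
  eeg_record(dat, record$fs, record$labels, reference = "CAR")
}

#' REST transfer matrix
#'
#' `T = G_inf %*% pinv(G_avg)` with a truncated pseudoinverse (singular
#' values below `svd_tol` times the largest are discarded, the standard
#' stabilisation). Rows of the gain must match the record's channels.
#'
#' @param leadfield Infinity-referenced `leadfield` over the equivalent
#'   source layer.
#' @param svd_tol Relative singular-value truncation threshold.
#' @param cond_cap Warn when the retained condition number exceeds this.
#' @return Channels x channels transfer matrix.
#' @export
rest_transfer <- function(leadfield, svd_tol = 1e-4, cond_cap = 1e6) {
  if (attr(leadfield, "convention") != "infinity") {
    abort("REST needs the infinity-referenced gain")
  }
  G <- unclass(leadfield)
  Ga <- sweep(G, 2, colMeans(G))
  sv <- svd(Ga)
  keep <- sv$d > svd_tol * sv$d[1]
  if (sv$d[1] / min(sv$d[keep]) > cond_cap) {
    warn(sprintf(
      "REST transfer ill-conditioned: kept %d/%d singular values, condition %.2e",
      sum(keep), length(sv$d), sv$d[1] / min(sv$d[keep])
    ))
  }
  Tm <- G %*% (sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep]))
  rownames(Tm) <- rownames(G)
  colnames(Tm) <- rownames(G)
  Tm
}

#' Re-reference to approximate infinity (REST)
#'
#' Converts the record to the average reference, then applies the REST
#' transfer matrix. Because the first step discards the input reference,
#' the output is identical whether the input was electrode-referenced (with
#' the reference row re-inserted) or already CAR.
#'
#' @param record An `eeg_record` whose channels match the lead-field rows.
#' @param leadfield Infinity-referenced gain over the source layer, or a
#'   precomputed transfer matrix from [rest_transfer()].
#' @param svd_tol Passed to [rest_transfer()].
#' @return The record with reference tag `"REST"`.
#' @export
to_rest <- function(record, leadfield, svd_tol = 1e-4) {
  stopifnot(inherits(record, "eeg_record"))
  Tm <- if (is.matrix(leadfield) && !inherits(leadfield, "leadfield")) {
    leadfield
  } else {
    rest_transfer(leadfield, svd_tol)
  }
  if (nrow(Tm) != nrow(record$data) ||
      !identical(toupper(rownames(Tm)), toupper(record$labels))) {
    abort("record channels do not match the lead-field rows")
  }
  avg <- sweep(record$data, 2, colMeans(record$data))
  eeg_record(Tm %*% avg, record$fs, record$labels, reference = "REST")
}
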