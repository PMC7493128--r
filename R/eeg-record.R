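# Containers for continuous recordings and epoched data. Signals are kept in
# plain numeric matrices/arrays (channels x samples; trials x channels x
# samples) for speed; metadata rides along as list fields.

#' Construct a continuous multichannel record
#'
#' @param data Channels x samples numeric matrix (microvolts for EEG,
#'   arbitrary units for EMG).
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels (row names of `data` if missing).
#' @param reference Reference tag: `"infinity"`, `"CAR"`, `"REST"`, or
#'   `"electrode:<label>"`.
#' @return An `eeg_record`.
#' @export
eeg_record <- function(data, fs, labels = rownames(data),
                       reference = "infinity") {
  stopifnot(is.matrix(data), is.numeric(data))
  if (is.null(labels) || length(labels) != nrow(data)) {
    abort("labels must match the data rows")
  }
  rng <- range(data) # cheap full-matrix scan without a logical copy
  if (!is.finite(rng[1]) || !is.finite(rng[2])) {
    abort("non-finite values in record")
  }
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels, reference = reference),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record> %d channels x %d samples @ %g Hz, reference = %s\n",
    nrow(x$data), ncol(x$data), x$fs, x$reference
  ))
  invisible(x)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, [%g, %g) ms, reference = %s\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
    x$times_ms[1], x$times_ms[length(x$times_ms)] + 1000 / x$fs, x$reference
  ))
  invisible(x)
}

new_eeg_epochs <- function(data, fs, times_ms, hand, labels, reference) {
  stopifnot(length(dim(data)) == 3)
  structure(
    list(
      data = data, fs = fs, times_ms = times_ms, hand = hand,
      labels = labels, reference = reference
    ),
    class = "eeg_epochs"
  )
}

#' Write / read a record in the plain-text array container
#'
#' The container is a TSV matrix (channels x samples, one row per channel,
#' first column the channel label) next to a JSON sidecar
#' (`<path>.json`) holding `fs`, `labels`, and `reference`.
#'
#' @param x An `eeg_record`.
#' @param path Path of the TSV file.
#' @return `read_record()` returns an `eeg_record`.
#' @export
write_record <- function(x, path) {
  stopifnot(inherits(x, "eeg_record"))
  df <- data.frame(label = x$labels, x$data, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(
    list(fs = x$fs, labels = x$labels, reference = x$reference),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.table(path, sep = "\t", header = FALSE)
  df[[1]] <- as.character(df[[1]])
  dat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(dat) <- NULL
  eeg_record(dat, fs = meta$fs, labels = df[[1]], reference = meta$reference)
}
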