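# broom-style tidiers for the package's result objects.

#' Tidy a connectivity matrix into a long edge table
#'
#' @param x A `conn_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per upper-triangle edge: `chan_i`, `chan_j`,
#'   `weight`, plus the matrix metadata columns.
#' @export
tidy.conn_matrix <- function(x, ...) {
  labels <- rownames(x)
  out <- upper_pairs(labels)
  out$weight <- unclass(x)[upper.tri(x)]
  out$method <- attr(x, "method")
  out$stage <- attr(x, "stage")
  out$reference <- attr(x, "reference")
  out$hand <- attr(x, "hand")
  out[, c("chan_i", "chan_j", "weight", "method", "stage", "reference",
          "hand")]
}

#' @export
glance.conn_matrix <- function(x, ...) {
  w <- unclass(x)[upper.tri(x)]
  tibble(
    n_nodes = nrow(x), n_edges = length(w), mean_weight = mean(w),
    max_weight = max(w), method = attr(x, "method"),
    stage = attr(x, "stage"), reference = attr(x, "reference"),
    hand = attr(x, "hand")
  )
}

#' @export
tidy.edge_test_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "edge_test_result")
  out
}

#' @export
glance.edge_test_result <- function(x, ...) {
  tibble(
    n_edges = nrow(x), n_candidates = sum(x$candidate),
    n_significant = sum(x$significant),
    n_subjects = attr(x, "n_subjects"), alpha = attr(x, "alpha"),
    threshold = attr(x, "threshold")
  )
}

#' @export
tidy.path_length <- function(x, ...) {
  d <- x$distances
  out <- upper_pairs(rownames(d) %||% paste0("ch", seq_len(nrow(d))))
  out$distance <- d[upper.tri(d)]
  out
}

#' @export
glance.path_length <- function(x, ...) {
  tibble(L = x$L, L_finite = x$L_finite, n_nodes = x$n, rule = x$rule)
}

#' @export
glance.scalpnet_result <- function(x, ...) {
  x$edge_counts
}
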