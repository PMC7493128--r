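# The edge/node significance procedure: candidate edges by group-mean
# difference > 0.02, one-tailed paired t-tests across subjects, BH-FDR over
# the edge family, and the node-degree / path-length reference contrasts.

upper_pairs <- function(labels) {
  N <- length(labels)
  ij <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  tibble(
    i = ij[, 1], j = ij[, 2],
    chan_i = labels[ij[, 1]], chan_j = labels[ij[, 2]]
  )
}

# Stack the upper triangle of each subject's matrix into subjects x edges.
edge_values <- function(mats) {
  N <- nrow(mats[[1]])
  ut <- upper.tri(matrix(0, N, N))
  do.call(rbind, lapply(mats, function(A) as.matrix(unclass(A))[ut]))
}

#' Group-mean difference matrix between two stages
#'
#' Element-wise mean over subjects per stage, then stage minus idle.
#'
#' @param stage_mats,idle_mats Lists (one entry per subject, same order) of
#'   subject-level connectivity matrices.
#' @return Symmetric difference matrix.
#' @export
group_mean_diff <- function(stage_mats, idle_mats) {
  if (length(stage_mats) != length(idle_mats)) {
    abort("stage and idle lists must cover the same subjects")
  }
  ms <- Reduce(`+`, lapply(stage_mats, unclass)) / length(stage_mats)
  mi <- Reduce(`+`, lapply(idle_mats, unclass)) / length(idle_mats)
  as.matrix(ms - mi)
}

#' Candidate-edge mask
#'
#' Edges whose group-mean increase exceeds the threshold (strictly greater
#' than, so a difference of exactly 0.02 is excluded). Upper triangle only.
#'
#' @param diff Symmetric difference matrix.
#' @param threshold Mean-difference threshold.
#' @return Logical matrix, `TRUE` on candidate upper-triangle edges.
#' @export
candidate_edges <- function(diff, threshold = 0.02) {
  mask <- diff > threshold
  mask[!upper.tri(mask)] <- FALSE
  mask
}

#' One-tailed paired t-test per edge
#'
#' Classic paired t on the per-subject differences (stage minus idle), with
#' the one-tailed alternative "stage > idle" and `df = n - 1`. Degenerate
#' zero-variance differences are guarded: all-zero differences give p = 0.5,
#' constant non-zero differences give p = 0 or 1 by sign.
#'
#' @inheritParams group_mean_diff
#' @return Tibble with one row per upper-triangle edge: `i`, `j`, `chan_i`,
#'   `chan_j`, `diff` (mean paired difference), `t`, `p`.
#' @export
paired_t_one_tailed <- function(stage_mats, idle_mats) {
  if (length(stage_mats) < 2) abort("paired t needs >= 2 subjects")
  labels <- rownames(stage_mats[[1]]) %||%
    paste0("ch", seq_len(nrow(stage_mats[[1]])))
  D <- edge_values(stage_mats) - edge_values(idle_mats)
  n <- nrow(D)
  m <- colMeans(D)
  s <- apply(D, 2, sd)
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m > 0, Inf,
                                                    ifelse(m < 0, -Inf, 0)))
  p <- pt(t_stat, df = n - 1, lower.tail = FALSE)
  zero_var <- sum(s == 0)
  if (zero_var > 0) {
    message(sprintf("%d edge(s) with zero-variance paired differences", zero_var))
  }
  out <- upper_pairs(labels)
  out$diff <- m
  out$t <- t_stat
  out$p <- ifelse(s == 0 & m == 0, 0.5, p)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with monotonicity enforcement over the given
#' family of p-values.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values (`q >= p`).
#' @export
bhfdr <- function(p) {
  if (length(p) == 0) abort("empty p-value family")
  if (any(p < 0 | p > 1)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Edge-wise significance procedure between a movement stage and idle
#'
#' The full procedure on one method x reference x hand cell: group-mean
#' difference, candidate mask (`diff > threshold`), one-tailed paired
#' t-tests across subjects, BH-FDR over the edge family, and the final
#' significant set (candidate AND q < alpha).
#'
#' The FDR family defaults to all upper-triangle edges, with the candidate
#' mask applied afterwards as a conjunction; `fdr_family = "candidates"`
#' restricts the correction to the masked edges instead.
#'
#' @inheritParams group_mean_diff
#' @param threshold Candidate mean-difference threshold.
#' @param alpha FDR significance level.
#' @param fdr_family `"all"` or `"candidates"`.
#' @return Tibble of class `edge_test_result`: one row per edge with `diff`,
#'   `t`, `p`, `q`, `candidate`, `significant`; attributes `n_subjects`,
#'   `alpha`, `threshold`.
#' @export
edge_tests <- function(stage_mats, idle_mats, threshold = 0.02, alpha = 0.05,
                       fdr_family = c("all", "candidates")) {
  fdr_family <- match.arg(fdr_family)
  tt <- paired_t_one_tailed(stage_mats, idle_mats)
  gdiff <- group_mean_diff(stage_mats, idle_mats)
  mask <- candidate_edges(gdiff, threshold)
  tt$candidate <- mask[upper.tri(mask)]
  if (fdr_family == "all") {
    tt$q <- bhfdr(tt$p)
  } else {
    tt$q <- NA_real_
    if (any(tt$candidate)) tt$q[tt$candidate] <- bhfdr(tt$p[tt$candidate])
  }
  tt$significant <- tt$candidate & !is.na(tt$q) & tt$q < alpha
  class(tt) <- c("edge_test_result", class(tt))
  attr(tt, "n_subjects") <- length(stage_mats)
  attr(tt, "alpha") <- alpha
  attr(tt, "threshold") <- threshold
  tt
}

#' Significant-edge list and count
#'
#' @param result An `edge_test_result` from [edge_tests()].
#' @return The significant rows; the count is `nrow()` of the result.
#' @export
significant_edges <- function(result) {
  stopifnot(inherits(result, "edge_test_result"))
  result[result$significant, ]
}

#' Node-degree contrasts between references
#'
#' Per node, a paired t-test (two-tailed, uncorrected, across subjects)
#' between the weighted degrees under two references, for each requested
#' contrast.
#'
#' @param degrees_by_reference Named list (one entry per reference) of
#'   subjects x nodes degree matrices (same subject order).
#' @param contrasts List of 2-vectors of reference names; default all three
#'   pairwise contrasts in recording/CAR/REST order.
#' @param alpha Significance level.
#' @return Tibble of class `node_test_result`: `contrast`, `node`, `t`,
#'   `p`, `significant`.
#' @export
node_degree_tests <- function(degrees_by_reference, contrasts = NULL,
                              alpha = 0.05) {
  refs <- names(degrees_by_reference)
  if (is.null(contrasts)) {
    contrasts <- utils::combn(refs, 2, simplify = FALSE)
  }
  rows <- lapply(contrasts, function(ct) {
    X <- degrees_by_reference[[ct[1]]]
    Y <- degrees_by_reference[[ct[2]]]
    if (is.null(X) || is.null(Y) || nrow(X) != nrow(Y)) {
      abort("contrast references missing or subject counts differ")
    }
    D <- X - Y
    n <- nrow(D)
    m <- colMeans(D)
    s <- apply(D, 2, sd)
    t_stat <- ifelse(s > 0, m / (s / sqrt(n)), 0)
    p <- ifelse(s > 0, 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE), 1)
    tibble(
      contrast = paste(ct, collapse = " vs "),
      node = colnames(X) %||% paste0("ch", seq_len(ncol(X))),
      t = t_stat, p = p, significant = p < alpha
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("node_test_result", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Characteristic path length contrasts between references
#'
#' Paired two-tailed t-test per reference contrast, plus the mean and SD of
#' L per reference. Identical L vectors (zero-variance differences) are
#' guarded to p = 1 with a message.
#'
#' @param L_by_reference Named list of per-subject path-length vectors.
#' @param contrasts As in [node_degree_tests()].
#' @return List with `tests` (tibble: contrast, t, p) and `summary`
#'   (tibble: reference, mean_L, sd_L).
#' @export
path_length_test <- function(L_by_reference, contrasts = NULL) {
  refs <- names(L_by_reference)
  if (is.null(contrasts)) {
    contrasts <- utils::combn(refs, 2, simplify = FALSE)
  }
  tests <- bind_rows(lapply(contrasts, function(ct) {
    d <- L_by_reference[[ct[1]]] - L_by_reference[[ct[2]]]
    if (sd(d) == 0) {
      message(sprintf("identical path lengths in contrast %s vs %s",
                      ct[1], ct[2]))
      return(tibble(contrast = paste(ct, collapse = " vs "), t = 0, p = 1))
    }
    ht <- t.test(L_by_reference[[ct[1]]], L_by_reference[[ct[2]]],
                 paired = TRUE)
    tibble(contrast = paste(ct, collapse = " vs "),
           t = unname(ht$statistic), p = ht$p.value)
  }))
  summary <- tibble(
    reference = refs,
    mean_L = unname(vapply(L_by_reference, mean, numeric(1))),
    sd_L = unname(vapply(L_by_reference, sd, numeric(1)))
  )
  list(tests = tests, summary = summary)
}
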