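# Weighted graph measures on subject-level networks: node degree (weighted,
# no binarisation) and characteristic path length over all ordered pairs.

#' Weighted node degree
#'
#' `D_i = sum_{j != i} A_ij` on the full weighted network (no
#' thresholding or binarisation).
#'
#' @param A Symmetric connectivity matrix with zero diagonal.
#' @return A tibble (class `degree_vector`) with `node` and `degree`.
#' @export
node_degree <- function(A) {
  A <- as.matrix(unclass(A))
  if (max(abs(A - t(A))) > 1e-9) abort("adjacency matrix must be symmetric")
  D <- rowSums(A) - diag(A)
  out <- tibble(
    node = rownames(A) %||% paste0("ch", seq_len(nrow(A))),
    degree = unname(D)
  )
  class(out) <- c("degree_vector", class(out))
  out
}

#' Characteristic path length of a weighted network
#'
#' Edge weights (connectivity values in `[0, 1]`) are mapped to lengths by
#' the reciprocal rule `1 / w` (the standard brain-connectivity choice;
#' `"one_minus"` gives `1 - w`), with zero-weight edges treated as absent.
#' Shortest paths are computed over the weighted graph and `L` is the mean
#' of `d_ij` over ordered pairs `i != j`; `d_ij = Inf` for disconnected
#' pairs, in which case `L = Inf` and `L_finite` (mean over connected
#' pairs) is reported alongside.
#'
#' @param A Symmetric non-negative connectivity matrix, zero diagonal.
#' @param rule Weight-to-length mapping.
#' @return A list of class `path_length`: `L`, `L_finite`, `distances`
#'   (matrix), `n`, `rule`.
#' @export
char_path_length <- function(A, rule = c("reciprocal", "one_minus")) {
  rule <- match.arg(rule)
  A <- as.matrix(unclass(A))
  if (any(A < 0)) abort("negative weights are not allowed")
  if (max(abs(A - t(A))) > 1e-9) abort("adjacency matrix must be symmetric")
  N <- nrow(A)
  W <- switch(rule,
    reciprocal = ifelse(A > 0, 1 / A, 0),
    one_minus = ifelse(A > 0, 1 - A, 0)
  )
  W <- (W + t(W)) / 2 # exact symmetry (igraph requires it bitwise)
  g <- igraph::graph_from_adjacency_matrix(
    W, mode = "undirected", weighted = TRUE, diag = FALSE
  )
  d <- igraph::distances(g, algorithm = "dijkstra")
  diag(d) <- 0
  off <- d[row(d) != col(d)]
  L <- mean(off)
  structure(
    list(
      L = L, L_finite = mean(off[is.finite(off)]), distances = d, n = N,
      rule = rule
    ),
    class = "path_length"
  )
}

#' @export
print.path_length <- function(x, ...) {
  cat(sprintf(
    "<path_length> N = %d nodes, L = %s (finite-pair mean %.4g), rule = %s\n",
    x$n, format(x$L, digits = 4), x$L_finite, x$rule
  ))
  invisible(x)
}
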