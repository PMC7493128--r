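# Independent oracles and small fixtures shared across tests.

# Closed-form surface potential of a radial unit dipole at radius b (z-axis)
# inside a homogeneous unit sphere with insulating boundary, evaluated at
# surface points with polar angle gamma. Derived from the image-series sum
# 2b(x - b)/d^3 + 1/d - 1 over b, x = cos(gamma), d = sqrt(1 - 2bx + b^2).
homogeneous_sphere_potential <- function(b, cos_gamma, sigma = 1) {
  d <- sqrt(1 - 2 * b * cos_gamma + b^2)
  (1 / (4 * pi * sigma * b)) * (2 * b * (cos_gamma - b) / d^3 + 1 / d - 1)
}

# All-pairs shortest paths by plain Floyd-Warshall on a length matrix
# (Inf = absent edge), independent of igraph.
floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Brute-force Benjamini-Hochberg step-up adjustment: sort, scale by m/rank,
# cumulative minimum from the largest p down, cap at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    q[o[r]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# Direct high-precision PLV / PLI by scalar summation over samples.
plv_direct <- function(ph_i, ph_j) {
  s <- 0 + 0i
  for (k in seq_along(ph_i)) s <- s + exp(1i * (ph_i[k] - ph_j[k]))
  Mod(s) / length(ph_i)
}
pli_direct <- function(ph_i, ph_j) {
  s <- 0
  for (k in seq_along(ph_i)) s <- s + sign(sin(ph_i[k] - ph_j[k]))
  abs(s) / length(ph_i)
}

# A small cohort shared by the slower module tests (built lazily once).
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- session_spec(
        n_subjects = 2, n_trials_per_hand = 3, n_channels = 19,
        n_sources = 8, noise_snr_db = 20
      )
      cp <- coupling_spec(1L, 2L, "zero_lag", 0, 0.6, list(c("MP", "ME")),
                          "both")
      cache <<- simulate_cohort(spec, cp, master_seed = 77L)
    }
    cache
  }
})
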