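# Concentric three-shell spherical volume conductor and analytic lead fields.
#
# Potentials are expanded in Legendre series. For each harmonic order n the
# potential in shell k is A_k r^n + B_k r^(-(n+1)); matching potential and
# radial current at the shell interfaces and zero current at the scalp yields
# a small linear system whose solution gives the scalp-surface gain per order.
# Dipoles are differentiated analytically, so arbitrary orientations are
# supported (the default source layer is radial).

#' Three-shell spherical head model
#'
#' Radii are normalised to scalp = 1 and ordered brain < skull < scalp;
#' conductivities are relative (brain = scalp = 1, skull ~ 1/80 by
#' convention). `series_terms` truncates the Legendre expansion; terms decay
#' like (source radius)^n, so the default keeps the tail far below double
#' precision for the default geometry.
#'
#' @param radii Ascending shell radii (brain, skull, scalp).
#' @param conductivities Positive relative conductivities per shell.
#' @param series_terms Truncation order (>= 20).
#' @return A `sphere_model` object.
#' @export
sphere_model <- function(radii = c(0.87, 0.92, 1.0),
                         conductivities = c(1, 0.0125, 1),
                         series_terms = 200L) {
  if (length(radii) != 3 || any(diff(radii) <= 0)) {
    abort("radii must be 3 strictly increasing values")
  }
  if (length(conductivities) != 3 || any(conductivities <= 0)) {
    abort("conductivities must be 3 positive values")
  }
  if (series_terms < 20) abort("series_terms must be >= 20")
  structure(
    list(
      radii = radii, conductivities = conductivities,
      series_terms = as.integer(series_terms)
    ),
    class = "sphere_model"
  )
}

#' Quasi-uniform dipole source layer
#'
#' Places `n` dipoles on a Fibonacci lattice over the sphere of the given
#' radius (inside the brain shell), radially oriented by default. This layer
#' serves both as REST's equivalent-source space and as the anchor set for
#' simulated cortical sources.
#'
#' @param n Number of dipoles.
#' @param radius Layer radius (must be below the brain shell radius).
#' @param orientations Optional n x 3 matrix of unit orientations; default
#'   radial.
#' @param hemisphere `"full"` covers the whole sphere; `"upper"` restricts
#'   the lattice to z > 0, useful when the layer must be well seen by an
#'   upper-scalp electrode cap (deep lower-hemisphere dipoles are nearly
#'   invisible to it, which ill-conditions inverse operators).
#' @return A `source_space` object with `positions` (n x 3), `orientations`,
#'   `radius`, `n`.
#' @export
source_layer <- function(n = 300L, radius = 0.86, orientations = NULL,
                         hemisphere = c("full", "upper")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(n >= 1, radius > 0)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- if (hemisphere == "full") 1 - 2 * i / n else 1 - i / n
  s <- sqrt(pmax(0, 1 - z^2))
  unit <- cbind(s * cos(phi), s * sin(phi), z)
  if (is.null(orientations)) {
    orientations <- unit
  } else {
    stopifnot(is.matrix(orientations), all(dim(orientations) == c(n, 3)))
    orientations <- orientations / sqrt(rowSums(orientations^2))
  }
  structure(
    list(
      positions = unit * radius, orientations = orientations,
      radius = radius, n = as.integer(n)
    ),
    class = "source_space"
  )
}

# Scalp-surface gain F_n for a unit primary coefficient (layer-1 primary
# potential c r^-(n+1) with c = 1). Solved per order from the interface
# conditions with per-shell rescaled unknowns so every matrix entry stays
# bounded. Returns the vector F_1..F_nmax.
shell_gains <- function(model, nmax) {
  r1 <- model$radii[1]
  r2 <- model$radii[2]
  s <- model$conductivities
  vapply(seq_len(nmax), function(n) {
    rho_n <- (r1 / r2)^n
    rho_n1 <- (r1 / r2)^(n + 1)
    tau_n <- r2^n
    tau_n1 <- r2^(n + 1)
    c1 <- r1^-(n + 1)
    # unknowns: u1 = A1 r1^n, u2 = A2 r2^n, v2 = B2 r1^-(n+1),
    #           u3 = A3, v3 = B3 r2^-(n+1)
    M <- rbind(
      c(1, -rho_n, -1, 0, 0),
      c(s[1] * n, -s[2] * n * rho_n, s[2] * (n + 1), 0, 0),
      c(0, 1, rho_n1, -tau_n, -1),
      c(0, s[2] * n, -s[2] * (n + 1) * rho_n1, -s[3] * n * tau_n,
        s[3] * (n + 1)),
      c(0, 0, 0, n, -(n + 1) * tau_n1)
    )
    rhs <- c(-c1, s[1] * (n + 1) * c1, 0, 0, 0)
    sol <- solve(M, rhs)
    sol[4] + sol[5] * tau_n1
  }, numeric(1))
}

#' Compute the lead field of a spherical head model
#'
#' Returns the gain matrix (channels x sources) mapping unit dipole moments
#' to scalp potentials, computed against infinity and then transformed to the
#' requested reference convention.
#'
#' @param montage Electrode montage (unit-sphere positions).
#' @param model A [sphere_model()].
#' @param sources A [source_layer()].
#' @param convention `"infinity"`, `"average"`, or `"electrode"`.
#' @param electrode Channel label when `convention = "electrode"`.
#' @return Matrix with class `leadfield`, row names = channel labels,
#'   attribute `convention`.
#' @export
#' @examples
#' m <- montage_1010(19)
#' G <- compute_leadfield(m, sphere_model(), source_layer(64))
compute_leadfield <- function(montage, model = sphere_model(),
                              sources = source_layer(),
                              convention = c("infinity", "average",
                                             "electrode"),
                              electrode = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(montage, "montage"), inherits(model, "sphere_model"),
            inherits(sources, "source_space"))
  b <- sqrt(rowSums(sources$positions^2))
  if (any(b >= model$radii[1])) {
    abort("source outside the brain shell")
  }
  E <- montage_positions(montage) # nE x 3, unit rows
  phat <- sources$positions / b # nS x 3
  o <- sources$orientations # nS x 3 unit
  nE <- nrow(E)
  nS <- nrow(phat)
  x <- E %*% t(phat) # cos(angle electrode, source)
  x[x > 1] <- 1
  x[x < -1] <- -1
  Eo <- E %*% t(o) # e . o
  c_po <- rowSums(phat * o) # p . o per source
  Fn <- shell_gains(model, model$series_terms)
  G <- matrix(0, nE, nS)
  Pm1 <- matrix(1, nE, nS) # P_0
  P <- x # P_1
  dPm1 <- matrix(0, nE, nS) # P_0'
  dP <- matrix(1, nE, nS) # P_1'
  bpow <- rep(1, nS) # b^(n-1)
  last_rel <- 0
  for (n in seq_len(model$series_terms)) {
    term <- Fn[n] * (
      n * P * matrix(c_po * bpow, nE, nS, byrow = TRUE) +
        dP * (Eo - x * matrix(c_po, nE, nS, byrow = TRUE)) *
          matrix(bpow, nE, nS, byrow = TRUE)
    )
    G <- G + term
    if (n == model$series_terms) {
      last_rel <- max(abs(term)) / max(abs(G))
    }
    # Bonnet recurrences for P_{n+1} and P'_{n+1}
    Pp1 <- ((2 * n + 1) * x * P - n * Pm1) / (n + 1)
    dPp1 <- dPm1 + (2 * n + 1) * P
    Pm1 <- P
    P <- Pp1
    dPm1 <- dP
    dP <- dPp1
    bpow <- bpow * b
  }
  if (last_rel > 1e-8) {
    warn(sprintf(
      "Legendre series not converged: last-term relative contribution %.2e (%d terms)",
      last_rel, model$series_terms
    ))
  }
  G <- G / (4 * pi * model$conductivities[1])
  rownames(G) <- montage$label
  G <- structure(G, class = c("leadfield", "matrix"), convention = "infinity")
  leadfield_convention(G, convention, electrode)
}

#' Transform a lead field between reference conventions
#'
#' Average reference subtracts each column's channel mean (columns then sum
#' to zero); an electrode reference subtracts that electrode's row (its row
#' becomes zero). Transformations start from the infinity-referenced gain.
#'
#' @param G A `leadfield` (infinity convention).
#' @param convention Target convention.
#' @param electrode Channel label for `"electrode"`.
#' @return The transformed `leadfield`.
#' @export
leadfield_convention <- function(G, convention = c("infinity", "average",
                                                   "electrode"),
                                 electrode = NULL) {
  convention <- match.arg(convention)
  if (attr(G, "convention") != "infinity" && convention != "infinity") {
    abort("convention transforms start from an infinity-referenced gain")
  }
  out <- switch(convention,
    infinity = G,
    average = sweep(unclass(G), 2, colMeans(G)),
    electrode = {
      if (is.null(electrode)) abort("electrode label required")
      i <- match(toupper(electrode), toupper(rownames(G)))
      if (is.na(i)) abort(sprintf("electrode %s not in lead field", electrode))
      sweep(unclass(G), 2, G[i, ])
    }
  )
  tag <- if (convention == "electrode") {
    paste0("electrode:", electrode)
  } else {
    convention
  }
  structure(as.matrix(out),
    class = c("leadfield", "matrix"), convention = tag,
    dimnames = dimnames(G)
  )
}

#' Export a lead field as TSV
#'
#' One row per channel, channel labels in the first column, one column per
#' source dipole.
#'
#' @param G A `leadfield`.
#' @param path Output path.
#' @export
write_leadfield <- function(G, path) {
  df <- data.frame(channel = rownames(G), unclass(G), check.names = FALSE)
  colnames(df) <- c("channel", paste0("src", seq_len(ncol(G))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
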