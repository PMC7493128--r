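# Electrode montage handling. Positions live on the unit sphere (head radius
# normalised to 1), in a right-handed frame: +x right ear, +y nasion, +z vertex.

new_montage <- function(df, reference_label = NA_character_) {
  stopifnot(all(c("label", "x", "y", "z") %in% names(df)))
  if (anyDuplicated(df$label)) abort("duplicate channel labels in montage")
  if (nrow(df) < 2) abort("a montage needs at least 2 channels")
  nrm <- sqrt(df$x^2 + df$y^2 + df$z^2)
  if (any(nrm == 0)) abort("channel position at the origin cannot be projected")
  df$x <- df$x / nrm
  df$y <- df$y / nrm
  df$z <- df$z / nrm
  out <- as_tibble(df[, c("label", "x", "y", "z")])
  class(out) <- c("montage", class(out))
  attr(out, "reference_label") <- reference_label
  out
}

#' Montage accessors
#'
#' `montage_positions()` returns the n x 3 unit-norm position matrix (rows
#' named by channel label); `reference_label()` returns the label of the
#' physical recording-reference site, or `NA` if none is declared.
#'
#' @param m A montage (see [montage_1010()], [read_montage()]).
#' @return A numeric matrix, respectively a character scalar.
#' @export
montage_positions <- function(m) {
  stopifnot(inherits(m, "montage"))
  pos <- cbind(m$x, m$y, m$z)
  rownames(pos) <- m$label
  colnames(pos) <- c("x", "y", "z")
  pos
}

#' @rdname montage_positions
#' @export
reference_label <- function(m) attr(m, "reference_label")

# Point on the unit sphere from inclination (degrees from vertex) and azimuth
# (degrees clockwise from nasion towards the right ear).
sph_point <- function(incl, az) {
  i <- incl * pi / 180
  a <- az * pi / 180
  c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
}

# Points along the circle through three points of the unit sphere, at the
# given fractions of the arc from p1 to p2 passing through pm. Any circle
# through three points of a sphere lies on the sphere, so no re-projection is
# needed.
arc_points <- function(p1, pm, p2, fractions) {
  nrm <- function(v) v / sqrt(sum(v^2))
  crs <- function(a, b) {
    c(
      a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1]
    )
  }
  n <- nrm(crs(p2 - p1, pm - p1))
  ctr <- sum(n * p1) * n
  u1 <- p1 - ctr
  rho <- sqrt(sum(u1^2))
  e1 <- u1 / rho
  e2 <- crs(n, e1)
  ang <- function(p) atan2(sum((p - ctr) * e2), sum((p - ctr) * e1))
  am <- ang(pm)
  if (am < 0) {
    e2 <- -e2
    am <- -am
  }
  a2 <- ang(p2)
  if (a2 <= 0) a2 <- a2 + 2 * pi
  t(vapply(
    fractions,
    function(f) ctr + rho * (cos(f * a2) * e1 + sin(f * a2) * e2),
    numeric(3)
  ))
}

#' Idealised 10-10 / 10-20 scalp montages
#'
#' Builds an idealised spherical montage: the outer ring sits at 72 degrees
#' inclination (10 per cent of the nasion-inion arc above the ears), interior
#' rows are placed at equal arc fractions along the circle joining the two
#' ring electrodes of that row through its midline electrode. The 62-channel
#' layout is the extended 10-10 set used with 64-electrode caps (62 scalp
#' channels after the two EMG bipolars); `n_channels = 19` gives the classic
#' 10-20 subset for fast tests.
#'
#' The physical recording-reference site `"REF"` lies midway between CZ and
#' CPZ, re-projected to the sphere.
#'
#' @param n_channels 62 (default) or 19.
#' @param add_reference Include the `"REF"` site as a montage entry.
#' @return A montage tibble (label, x, y, z) with a `reference_label`
#'   attribute.
#' @export
#' @examples
#' m <- montage_1010(19)
#' head(m)
montage_1010 <- function(n_channels = 62, add_reference = TRUE) {
  n_channels <- match.arg(as.character(n_channels), c("62", "19"))
  ring_az <- c(
    Fpz = 0, Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, T8 = 90, TP8 = 108,
    P8 = 126, PO8 = 144, O2 = 162, Oz = 180, O1 = -162, PO7 = -144,
    P7 = -126, TP7 = -108, T7 = -90, FT7 = -72, F7 = -54, AF7 = -36,
    Fp1 = -18
  )
  ring <- t(vapply(ring_az, function(a) sph_point(72, a), numeric(3)))
  mid <- rbind(
    AFz = sph_point(54, 0), Fz = sph_point(36, 0), FCz = sph_point(18, 0),
    Cz = c(0, 0, 1), CPz = sph_point(18, 180), Pz = sph_point(36, 180),
    POz = sph_point(54, 180)
  )
  row_def <- list(
    F  = list(ends = c("F7", "F8"), mid = "Fz",
              labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    FC = list(ends = c("FT7", "FT8"), mid = "FCz",
              labels = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4",
                         "FC6", "FT8")),
    C  = list(ends = c("T7", "T8"), mid = "Cz",
              labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
    CP = list(ends = c("TP7", "TP8"), mid = "CPz",
              labels = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4",
                         "CP6", "TP8")),
    P  = list(ends = c("P7", "P8"), mid = "Pz",
              labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
    PO = list(ends = c("PO7", "PO8"), mid = "POz",
              labels = c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8")),
    AF = list(ends = c("AF7", "AF8"), mid = "AFz",
              labels = c("AF7", "AF3", "AF4", "AF8"))
  )
  pos <- list(
    Fp1 = ring["Fp1", ], Fpz = ring["Fpz", ], Fp2 = ring["Fp2", ],
    O1 = ring["O1", ], Oz = ring["Oz", ], O2 = ring["O2", ]
  )
  for (rd in row_def) {
    k <- length(rd$labels)
    pts <- arc_points(
      ring[rd$ends[1], ], mid[rd$mid, ], ring[rd$ends[2], ],
      seq(0, 1, length.out = k)
    )
    for (j in seq_len(k)) pos[[rd$labels[j]]] <- pts[j, ]
  }
  order62 <- c(
    "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8", "O1", "Oz", "O2"
  )
  order19 <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz", "C4",
    "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2"
  )
  labels <- if (n_channels == "62") order62 else order19
  P <- t(vapply(labels, function(l) pos[[l]], numeric(3)))
  df <- tibble(label = labels, x = P[, 1], y = P[, 2], z = P[, 3])
  m <- new_montage(df, reference_label = NA_character_)
  if (add_reference) m <- add_reference_site(m) else m
}

#' Add the physical recording-reference site to a montage
#'
#' The reference electrode sits midway between two scalp sites (default CZ
#' and CPZ, as for a reference placed just behind the vertex), re-projected
#' to the unit sphere. Label matching is case-insensitive.
#'
#' @param m A montage.
#' @param label Label for the new entry (default `"REF"`).
#' @param between Two channel labels the site lies between.
#' @return The montage with the reference row appended and its
#'   `reference_label` attribute set.
#' @export
add_reference_site <- function(m, label = "REF", between = c("Cz", "CPz")) {
  stopifnot(inherits(m, "montage"))
  idx <- match(toupper(between), toupper(m$label))
  p <- if (anyNA(idx)) {
    # CPz may be absent from reduced montages; fall back to the idealised
    # midline geometry (CZ at the vertex, CPZ 18 degrees posterior).
    if (toupper(between[1]) == "CZ" && toupper(between[2]) == "CPZ") {
      sph_point(9, 180)
    } else {
      abort(sprintf("labels %s not all present", paste(between, collapse = ", ")))
    }
  } else {
    colMeans(montage_positions(m)[idx, , drop = FALSE])
  }
  if (toupper(label) %in% toupper(m$label)) {
    abort(sprintf("label %s already present", label))
  }
  df <- rbind(
    m[, c("label", "x", "y", "z")],
    tibble(label = label, x = p[1], y = p[2], z = p[3])
  )
  new_montage(as.data.frame(df), reference_label = label)
}

#' Read / write a montage file
#'
#' Plain-text, one channel per line, whitespace- or comma-separated. Two
#' dialects are auto-detected by column count: `label x y z` (Cartesian,
#' normalised to the unit sphere on read) and `label incl az` (spherical
#' angles in degrees: inclination from the vertex, azimuth clockwise from the
#' nasion towards the right ear).
#'
#' @param path File path.
#' @param add_reference If `TRUE`, append a synthetic `"REF"` entry midway
#'   between CZ and CPZ.
#' @return A montage tibble.
#' @export
read_montage <- function(path, add_reference = FALSE) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[,[:space:]]+")
  ncols <- unique(lengths(parts))
  if (length(ncols) != 1 || !(ncols %in% c(3L, 4L))) {
    abort("montage file must have 'label x y z' or 'label incl az' rows")
  }
  lab <- vapply(parts, `[[`, "", 1L)
  num <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(ncols - 1L)))
  if (anyNA(num)) abort("non-numeric coordinate in montage file")
  P <- if (ncols == 4L) {
    num
  } else {
    t(vapply(seq_len(nrow(num)), function(i) sph_point(num[i, 1], num[i, 2]),
             numeric(3)))
  }
  m <- new_montage(
    data.frame(label = lab, x = P[, 1], y = P[, 2], z = P[, 3]),
    reference_label = NA_character_
  )
  if (add_reference) add_reference_site(m) else m
}

#' @rdname read_montage
#' @param m A montage to write (Cartesian dialect).
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "montage"))
  write.table(
    as.data.frame(m[, c("label", "x", "y", "z")]),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
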