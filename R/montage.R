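#' Idealized 10-20 electrode montage on the unit sphere
#'
#' Constructs unit-sphere coordinates for the 16-channel motor-imagery montage
#' (F3, Fz, F4, FC1, FC5, FC2, FC6, C3, Cz, C4, CP1, CP5, CP2, CP6, T7, T8)
#' from the geometric definition of the 10-20 system: nasion, inion and the
#' preauricular points sit on the equator, named positions are placed at
#' fixed fractions along great-circle arcs, and 10-10 intermediate positions
#' (FC/CP rows, odd/even columns) are spherical midpoints of their
#' neighbouring 10-20 rows and columns.
#'
#' The head is modelled as a unit sphere with the vertex (Cz) at +z, the
#' nose at +y and the right ear at +x. These idealized positions feed the
#' spherical-spline surface Laplacian; no individual electrode digitization
#' is assumed.
#'
#' @param channels Optional character vector to subset/reorder the montage.
#' @return A data.frame with columns `channel`, `x`, `y`, `z` (unit norm).
#' @examples
#' m <- montage_1020()
#' stopifnot(all(abs(sqrt(m$x^2 + m$y^2 + m$z^2) - 1) < 1e-12))
#' @export
montage_1020 <- function(channels = NULL) {
  sph <- function(theta_deg, phi_deg) {
    th <- theta_deg * pi / 180
    ph <- phi_deg * pi / 180
    c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  # spherical midpoint along the great circle (slerp at t = 0.5)
  mid <- function(a, b) {
    v <- a + b
    v / sqrt(sum(v^2))
  }
  # 10-20 anchors: polar angle theta from vertex, azimuth phi from +x (right
  # ear) counterclockwise so the nose is at phi = 90.
  Cz <- c(0, 0, 1)
  Fz <- sph(36, 90);  Pz <- sph(36, 270)
  C3 <- sph(36, 180); C4 <- sph(36, 0)
  T7 <- sph(72, 180); T8 <- sph(72, 0)
  F7 <- sph(72, 126); F8 <- sph(72, 54)
  P7 <- sph(72, 234); P8 <- sph(72, 306)
  F3 <- mid(F7, Fz);  F4 <- mid(F8, Fz)
  P3 <- mid(P7, Pz);  P4 <- mid(P8, Pz)
  # 10-10 intermediates: row = midpoint between F and C (or C and P) rows,
  # column 1 = midpoint of midline and column 3, column 5 = midpoint of
  # columns 3 and 7.
  F1 <- mid(Fz, F3); C1 <- mid(Cz, C3); P1 <- mid(Pz, P3)
  F5 <- mid(F3, F7); C5 <- mid(C3, T7); P5 <- mid(P3, P7)
  F2 <- mid(Fz, F4); C2 <- mid(Cz, C4); P2 <- mid(Pz, P4)
  F6 <- mid(F4, F8); C6 <- mid(C4, T8); P6 <- mid(P4, P8)
  FC1 <- mid(F1, C1); FC5 <- mid(F5, C5)
  FC2 <- mid(F2, C2); FC6 <- mid(F6, C6)
  CP1 <- mid(C1, P1); CP5 <- mid(C5, P5)
  CP2 <- mid(C2, P2); CP6 <- mid(C6, P6)

  pos <- rbind(F3 = F3, Fz = Fz, F4 = F4,
               FC1 = FC1, FC5 = FC5, FC2 = FC2, FC6 = FC6,
               C3 = C3, Cz = Cz, C4 = C4,
               CP1 = CP1, CP5 = CP5, CP2 = CP2, CP6 = CP6,
               T7 = T7, T8 = T8)
  out <- data.frame(channel = rownames(pos),
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(channels)) {
    missing <- setdiff(channels, out$channel)
    if (length(missing) > 0L) {
      stop("unknown channel(s): ", paste(missing, collapse = ", "))
    }
    out <- out[match(channels, out$channel), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Default channel ordering of the 16-channel montage
#' @return Character vector of 16 channel names.
#' @export
montage_channels <- function() {
  c("F3", "Fz", "F4", "FC1", "FC5", "FC2", "FC6",
    "C3", "Cz", "C4", "CP1", "CP5", "CP2", "CP6", "T7", "T8")
}
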