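#' Standard 63-channel montage with FCz reference
#'
#' Returns the fixed 10-10 montage used throughout the package: 63 recorded
#' scalp electrodes (actiCAP-64 style layout) referenced online to FCz.
#' Positions are idealized unit-sphere coordinates computed geometrically from
#' the 10-10 nomenclature (great-circle interpolation between the midline and
#' the outer 10% ring), suitable for spherical-spline interpolation and
#' spatial-neighbor computations; they are not digitized cap coordinates.
#'
#' @return An object of class `montage`: a list with `channel_labels`
#'   (63 recorded labels), `reference_label` (`"FCz"`), and `positions`, a
#'   matrix of unit-norm x/y/z rows for every label including the reference.
#'   Orientation: +x right ear, +y nasion, +z vertex.
#' @export
standard_montage <- function() {
  pos <- montage_positions()
  labels <- rownames(pos)
  ref <- "FCz"
  structure(
    list(
      channel_labels = setdiff(labels, ref),
      reference_label = ref,
      positions = pos
    ),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$channel_labels), " recorded channels + reference ",
      x$reference_label, "\n", sep = "")
  invisible(x)
}

# unit vector at polar angle `polar` (radians from vertex) and azimuth `az`
# (radians, 0 = right ear, pi/2 = nasion), on the unit sphere
.sph_vec <- function(polar, az) {
  c(cos(az) * sin(polar), sin(az) * sin(polar), cos(polar))
}

# spherical linear interpolation between two unit vectors
.slerp <- function(a, b, f) {
  omega <- acos(max(-1, min(1, sum(a * b))))
  if (omega < 1e-12) return(a)
  (sin((1 - f) * omega) * a + sin(f * omega) * b) / sin(omega)
}

# Geometric 10-10 layout. Midline electrodes sit on the nasion-inion arc at
# 10% (18 deg) steps; the outer ring holds 20 electrodes at 18 deg azimuthal
# steps on the equator; intermediate electrodes divide the great-circle arc
# from the midline electrode of their row to the outer-ring electrode of the
# same row into equal parts. TP9/FT9 (and right homologues) lie 18 deg below
# the equator.
montage_positions <- function() {
  deg <- pi / 180
  pos <- list()
  put <- function(label, v) pos[[label]] <<- v / sqrt(sum(v^2))

  # midline: polar angle from vertex, front azimuth 90 deg, back 270 deg
  midline <- c(Fpz = NA, AFz = 54, Fz = 36, FCz = 18, Cz = 0,
               CPz = 18, Pz = 36, POz = 54, Oz = 72)
  put("AFz", .sph_vec(54 * deg, 90 * deg))
  put("Fz",  .sph_vec(36 * deg, 90 * deg))
  put("FCz", .sph_vec(18 * deg, 90 * deg))
  put("Cz",  .sph_vec(0, 0))
  put("CPz", .sph_vec(18 * deg, 270 * deg))
  put("Pz",  .sph_vec(36 * deg, 270 * deg))
  put("POz", .sph_vec(54 * deg, 270 * deg))
  put("Oz",  .sph_vec(72 * deg, 270 * deg))

  # outer ring (equator, 18 deg azimuth steps, left side azimuth 90->270)
  outer_left <- c(Fp1 = 108, AF7 = 126, F7 = 144, FT7 = 162, T7 = 180,
                  TP7 = 198, P7 = 216, PO7 = 234, O1 = 252)
  outer_right <- c(Fp2 = 72, AF8 = 54, F8 = 36, FT8 = 18, T8 = 0,
                   TP8 = -18, P8 = -36, PO8 = -54, O2 = -72)
  for (lab in names(outer_left)) put(lab, .sph_vec(90 * deg, outer_left[[lab]] * deg))
  for (lab in names(outer_right)) put(lab, .sph_vec(90 * deg, outer_right[[lab]] * deg))
  put("Fpz", .sph_vec(90 * deg, 90 * deg))

  # lower ring (18 deg below equator)
  put("FT9",  .sph_vec(108 * deg, 162 * deg))
  put("TP9",  .sph_vec(108 * deg, 198 * deg))
  put("FT10", .sph_vec(108 * deg, 18 * deg))
  put("TP10", .sph_vec(108 * deg, -18 * deg))

  # intermediate rows: interpolate midline -> outer along great circles
  rows <- list(
    AF = list(mid = "AFz", outer = c("AF7", "AF8"), inner = list(c("AF3", "AF4"))),
    F  = list(mid = "Fz",  outer = c("F7", "F8"),
              inner = list(c("F1", "F2"), c("F3", "F4"), c("F5", "F6"))),
    FC = list(mid = "FCz", outer = c("FT7", "FT8"),
              inner = list(c("FC1", "FC2"), c("FC3", "FC4"), c("FC5", "FC6"))),
    C  = list(mid = "Cz",  outer = c("T7", "T8"),
              inner = list(c("C1", "C2"), c("C3", "C4"), c("C5", "C6"))),
    CP = list(mid = "CPz", outer = c("TP7", "TP8"),
              inner = list(c("CP1", "CP2"), c("CP3", "CP4"), c("CP5", "CP6"))),
    P  = list(mid = "Pz",  outer = c("P7", "P8"),
              inner = list(c("P1", "P2"), c("P3", "P4"), c("P5", "P6"))),
    PO = list(mid = "POz", outer = c("PO7", "PO8"), inner = list(c("PO3", "PO4")))
  )
  for (row in rows) {
    n_in <- length(row$inner)
    denom <- n_in + 1
    # AF/PO rows: AF3 sits midway (1 inner of up to 3 slots); use fraction by
    # its 10-10 number: labels 1..6 map to fractions 1/4..3/4 on 4-slot rows,
    # 1/2 on 2-slot rows
    for (k in seq_len(n_in)) {
      f <- k / denom
      put(row$inner[[k]][1], .slerp(pos[[row$mid]], pos[[row$outer[1]]], f))
      put(row$inner[[k]][2], .slerp(pos[[row$mid]], pos[[row$outer[2]]], f))
    }
  }

  m <- do.call(rbind, pos)
  rownames(m) <- names(pos)
  colnames(m) <- c("x", "y", "z")
  # recorded set: 63 labels plus the FCz reference (Fpz is the ground site
  # in this cap layout and carries no data row)
  keep <- setdiff(rownames(m), "Fpz")
  m[keep, , drop = FALSE]
}

#' Great-circle (angular) distances between montage electrodes
#'
#' @param montage a `montage` object
#' @return symmetric matrix of angular distances in radians
#' @keywords internal
montage_distances <- function(montage) {
  p <- montage$positions
  cosang <- tcrossprod(p)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  acos(cosang)
}

#' Nearest spatial neighbors of each electrode
#'
#' @param montage a `montage` object
#' @param k number of neighbors
#' @return named list mapping each label to its `k` nearest labels
#' @keywords internal
montage_neighbors <- function(montage, k = 8) {
  d <- montage_distances(montage)
  labs <- rownames(d)
  out <- lapply(labs, function(l) {
    labs[order(d[l, ])][2:(k + 1)]
  })
  names(out) <- labs
  out
}
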