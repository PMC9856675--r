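#' Standard 64-channel 10-10 scalp montage
#'
#' Returns an idealized 64-channel sensor layout on the unit sphere, following
#' the extended 10-10 placement scheme used by 64-channel sintered Ag/AgCl
#' caps (including the inferior cerebellar-area sites CB1/CB2 and the full
#' left/right 5-per-side rows such as C5/C1 and FT7/FC5/FC3).
#'
#' Coordinates use a right-anterior-superior frame: +x toward the subject's
#' right ear, +y toward the nasion, +z toward the vertex, with Cz at
#' (0, 0, 1). Positions are generated by spherical interpolation along each
#' coronal row between its midline anchor and its 10 percent-ring endpoint on
#' the equator, which reproduces the proportional geometry of the 10-10
#' system; left/right pairs are exact mirror images in the sagittal plane.
#'
#' @return A `data.frame` of class `montage` with columns `channel`, `x`,
#'   `y`, `z`. All rows have unit norm.
#' @examples
#' m <- default_montage()
#' nrow(m)              # 64
#' "CB2" %in% m$channel # TRUE
#' @export
default_montage <- function() {
  deg <- pi / 180

  # point on the equator at angle `a` degrees from the nasion, on one side
  eq_pt <- function(a, side) c(side * sin(a * deg), cos(a * deg), 0)
  # midline point at inclination `b` degrees from the vertex (front > 0)
  mid_pt <- function(b) c(0, sin(b * deg), cos(b * deg))

  # spherical linear interpolation between unit vectors
  slerp <- function(p, q, t) {
    if (t <= 0) return(p)
    if (t >= 1) return(q)
    omega <- acos(max(-1, min(1, sum(p * q))))
    if (omega < 1e-12) return(p)
    (sin((1 - t) * omega) * p + sin(t * omega) * q) / sin(omega)
  }

  rows <- list()
  add <- function(name, v) rows[[length(rows) + 1L]] <<- c(list(name), as.list(v))

  # prefrontal ring (equator)
  add("FP1", eq_pt(18, -1)); add("FPZ", eq_pt(0, 1)); add("FP2", eq_pt(18, 1))

  # coronal rows: midline anchor inclination (signed, front positive) and the
  # equatorial endpoint angle of the 10 percent outer ring
  row_spec <- list(
    AF = list(mid = mid_pt(72),  eq = 36),
    F  = list(mid = mid_pt(54),  eq = 54),
    FC = list(mid = mid_pt(36),  eq = 72),
    C  = list(mid = c(0, 0, 1),  eq = 90),
    CP = list(mid = mid_pt(-36), eq = 108),
    P  = list(mid = mid_pt(-54), eq = 126)
  )

  # ante-frontal row: AF7 AF3 AF4 AF8 (no AFz electrode, anchor only)
  af <- row_spec$AF
  for (lab_t in list(c("AF7", 1), c("AF3", 0.5))) {
    add(lab_t[[1]], slerp(af$mid, eq_pt(af$eq, -1), as.numeric(lab_t[[2]])))
  }
  for (lab_t in list(c("AF4", 0.5), c("AF8", 1))) {
    add(lab_t[[1]], slerp(af$mid, eq_pt(af$eq, 1), as.numeric(lab_t[[2]])))
  }

  # full 9-electrode coronal rows
  full_rows <- list(
    list(pre = "F",  left = c("F7", "F5", "F3", "F1"),     mid = "FZ",
         right = c("F2", "F4", "F6", "F8"),     spec = row_spec$F),
    list(pre = "FC", left = c("FT7", "FC5", "FC3", "FC1"), mid = "FCZ",
         right = c("FC2", "FC4", "FC6", "FT8"), spec = row_spec$FC),
    list(pre = "C",  left = c("T7", "C5", "C3", "C1"),     mid = "CZ",
         right = c("C2", "C4", "C6", "T8"),     spec = row_spec$C),
    list(pre = "CP", left = c("TP7", "CP5", "CP3", "CP1"), mid = "CPZ",
         right = c("CP2", "CP4", "CP6", "TP8"), spec = row_spec$CP),
    list(pre = "P",  left = c("P7", "P5", "P3", "P1"),     mid = "PZ",
         right = c("P2", "P4", "P6", "P8"),     spec = row_spec$P)
  )
  fr <- c(1, 0.75, 0.5, 0.25)
  for (rw in full_rows) {
    for (i in 1:4) add(rw$left[i],  slerp(rw$spec$mid, eq_pt(rw$spec$eq, -1), fr[i]))
    add(rw$mid, rw$spec$mid)
    for (i in 1:4) add(rw$right[i], slerp(rw$spec$mid, eq_pt(rw$spec$eq, 1), fr[5 - i]))
  }

  # parieto-occipital row: PO7 PO5 PO3 POz PO4 PO6 PO8
  po_mid <- mid_pt(-72)
  for (lab_t in list(c("PO7", 1), c("PO5", 2 / 3), c("PO3", 1 / 3))) {
    add(lab_t[[1]], slerp(po_mid, eq_pt(144, -1), as.numeric(lab_t[[2]])))
  }
  add("POZ", po_mid)
  for (lab_t in list(c("PO4", 1 / 3), c("PO6", 2 / 3), c("PO8", 1))) {
    add(lab_t[[1]], slerp(po_mid, eq_pt(144, 1), as.numeric(lab_t[[2]])))
  }

  # occipital ring (equator) and inferior cerebellar-area sites below it
  add("O1", eq_pt(162, -1)); add("OZ", eq_pt(180, 1)); add("O2", eq_pt(162, 1))
  cb <- function(side) {
    incl <- 108 * deg # 18 degrees below the equator
    a <- 162 * deg
    c(side * sin(incl) * sin(a), sin(incl) * cos(a), cos(incl))
  }
  add("CB1", cb(-1)); add("CB2", cb(1))

  df <- data.frame(
    channel = vapply(rows, function(r) r[[1]], character(1)),
    x = vapply(rows, function(r) r[[2]], numeric(1)),
    y = vapply(rows, function(r) r[[3]], numeric(1)),
    z = vapply(rows, function(r) r[[4]], numeric(1)),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(df$channel), nrow(df) == 64L)
  class(df) <- c("montage", "data.frame")
  df
}

#' Project a montage to 2-D topographic coordinates
#'
#' Azimuthal equidistant projection about the vertex: a channel at angular
#' distance theta from Cz maps to a point at planar radius theta, preserving
#' its azimuth. The anterior direction (+y) maps to +v, the subject's right
#' (+x) to +u, so left/right mirror pairs get u-coordinates symmetric about
#' zero.
#'
#' @param montage A montage `data.frame` with unit-norm `x`, `y`, `z`.
#' @return A `data.frame` with columns `channel`, `u`, `v` (radians).
#' @export
project_montage <- function(montage) {
  stopifnot(all(c("channel", "x", "y", "z") %in% names(montage)))
  nrm <- sqrt(montage$x^2 + montage$y^2 + montage$z^2)
  if (any(abs(nrm - 1) > 0.01)) {
    stop("montage coordinates must lie on the unit sphere (norm within 1 +/- 0.01)")
  }
  theta <- acos(pmin(1, pmax(-1, montage$z / nrm)))
  h <- sqrt(montage$x^2 + montage$y^2)
  # at the pole the azimuth is undefined; the radius is 0 so any direction works
  hx <- ifelse(h < 1e-12, 0, montage$x / pmax(h, 1e-12))
  hy <- ifelse(h < 1e-12, 0, montage$y / pmax(h, 1e-12))
  data.frame(
    channel = montage$channel,
    u = theta * hx,
    v = theta * hy,
    stringsAsFactors = FALSE
  )
}

#' Map projected electrode coordinates to pixel positions
#'
#' Places projected 2-D coordinates into an `grid` x `grid` image frame.
#' Row 1 is anterior (nose), columns run from the subject's left to right.
#' The head disk radius is `radius_scale` times the largest projected
#' electrode radius, so all electrodes land strictly inside the disk.
#'
#' @param proj Output of [project_montage()].
#' @param grid Image side length in pixels.
#' @param radius_scale Head-disk radius as a multiple of the outermost
#'   electrode's projected radius.
#' @return A `data.frame` with `channel`, `row`, `col` (fractional pixel
#'   positions, 1-based) plus attributes `grid` and `head_radius_px`.
#' @export
electrode_pixels <- function(proj, grid = 32L, radius_scale = 1.06) {
  R <- radius_scale * max(sqrt(proj$u^2 + proj$v^2))
  ctr <- (grid + 1) / 2
  half <- (grid - 1) / 2
  out <- data.frame(
    channel = proj$channel,
    row = ctr - (proj$v / R) * half, # anterior (+v) -> small row index
    col = ctr + (proj$u / R) * half,
    stringsAsFactors = FALSE
  )
  attr(out, "grid") <- as.integer(grid)
  attr(out, "head_radius_px") <- half
  attr(out, "proj_radius") <- R
  out
}

#' Write a montage as tab-separated text
#'
#' @param montage A montage `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(montage, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a montage written by [write_montage()]
#'
#' @param path File path.
#' @return A montage `data.frame`.
#' @export
read_montage <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  class(df) <- c("montage", "data.frame")
  df
}
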