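# Thin-plate spline interpolation of scattered electrode values onto the
# pixel grid. The spline interpolates exactly at the electrodes (no
# smoothing), which is what the electrode-pixel consistency contract relies
# on; values between electrodes follow the minimum-bending-energy surface.

tps_kernel <- function(r) ifelse(r > 0, r^2 * log(r), 0)

# precompute everything that depends only on geometry: the factorized TPS
# system and the grid evaluation matrices
make_topomapper <- function(coords, grid = 32L, radius_scale = 1.06) {
  stopifnot(all(c("channel", "u", "v") %in% names(coords)))
  n <- nrow(coords)
  if (n < 4) stop("need at least 4 electrodes")
  R <- radius_scale * max(sqrt(coords$u^2 + coords$v^2))
  pts <- cbind(coords$u, coords$v)
  K <- tps_kernel(as.matrix(stats::dist(pts)))
  P <- cbind(1, pts)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Ainv <- solve(A)

  ctr <- (grid + 1) / 2
  half <- (grid - 1) / 2
  px_u <- ((seq_len(grid) - ctr) / half) * R        # column -> u
  px_v <- ((ctr - seq_len(grid)) / half) * R        # row -> v (row 1 anterior)
  # grid point (row i, col j) sits at index (j - 1) * grid + i (column-major)
  gx <- rep(px_u, each = grid); gy <- rep(px_v, times = grid)
  D <- sqrt(outer(gx, pts[, 1], `-`)^2 + outer(gy, pts[, 2], `-`)^2)
  E <- cbind(tps_kernel(D), 1, gx, gy)               # (grid^2) x (n + 3)
  mask <- matrix(gx^2 + gy^2 <= R^2, grid, grid)

  pixels <- electrode_pixels(data.frame(channel = coords$channel,
                                        u = coords$u, v = coords$v),
                             grid = grid, radius_scale = radius_scale)
  list(n = n, grid = as.integer(grid), R = R, Ainv = Ainv, E = E, mask = mask,
       channels = coords$channel, electrode_px = pixels)
}

tps_plane <- function(mapper, values) {
  coef <- mapper$Ainv %*% c(values, 0, 0, 0)
  matrix(mapper$E %*% coef, mapper$grid, mapper$grid)
}

#' Render a band-stacked scalp topomap image
#'
#' Per band, electrode powers are min-max normalized to `[0, 1]`,
#' interpolated over the head disk with an exact thin-plate spline, clipped
#' to `[0, 1]`, and zeroed outside the head mask. Bands are stacked as image
#' planes in band order; with the default alpha/beta/gamma bands this is the
#' Red = alpha, Green = beta, Blue = gamma convention.
#'
#' @param bp A `bandpower_matrix` (channels x bands) from
#'   [compute_bandpowers()].
#' @param coords Projected 2-D electrode coordinates from
#'   [project_montage()], rows matching `bp`.
#' @param grid Image side length in pixels (default 32).
#' @param mapper Optional precomputed geometry from repeated rendering; when
#'   supplied, `coords` and `grid` are ignored.
#' @return A `topomap_image`: list with `pixels` (grid x grid x bands, in
#'   `[0, 1]`), `mask`, `norm` (per-band min/max), `bands`,
#'   `electrode_px`.
#' @export
render_topomap <- function(bp, coords, grid = 32L, mapper = NULL) {
  if (is.null(mapper)) mapper <- make_topomapper(coords, grid)
  stopifnot(nrow(bp) == mapper$n)
  nb <- ncol(bp)
  px <- array(0, c(mapper$grid, mapper$grid, nb))
  norm <- matrix(NA_real_, 2, nb, dimnames = list(c("min", "max"), colnames(bp)))
  for (b in seq_len(nb)) {
    v <- bp[, b]
    rng <- range(v)
    norm[, b] <- rng
    if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2]))) {
      warning(sprintf("band %s has constant power; rendering uniform 0.5 plane",
                      colnames(bp)[b] %||% b))
      plane <- matrix(0.5, mapper$grid, mapper$grid)
    } else {
      vn <- (v - rng[1]) / diff(rng)
      plane <- pmin(1, pmax(0, tps_plane(mapper, vn)))
    }
    plane[!mapper$mask] <- 0
    px[, , b] <- plane
  }
  structure(
    list(pixels = px, mask = mapper$mask, norm = norm,
         bands = colnames(bp), electrode_px = mapper$electrode_px),
    class = "topomap_image"
  )
}

#' Topomap images for every ERP in an augmented set
#'
#' Convenience wrapper: computes band powers and renders the stacked topomap
#' for each sample, reusing the interpolation geometry.
#'
#' @param aug An [augmented_erp_set()].
#' @param montage Sensor montage matching the set's channel order.
#' @param bands Band definitions.
#' @param grid Image side length.
#' @return A list with `images` (samples x grid x grid x bands array),
#'   `category`, `subject_id`, `electrode_px`, `bands`.
#' @export
topomaps_from_erps <- function(aug, montage = default_montage(),
                               bands = band_defs(), grid = 32L) {
  stopifnot(inherits(aug, "augmented_erp_set"))
  proj <- project_montage(montage)
  mapper <- make_topomapper(proj, grid)
  ns <- dim(aug$erps)[1]
  out <- array(0, c(ns, grid, grid, nrow(bands)))
  for (i in seq_len(ns)) {
    bp <- compute_bandpowers(aug$erps[i, , ], aug$sfreq, bands,
                             channels = aug$channels)
    tm <- render_topomap(bp, mapper = mapper)
    out[i, , , ] <- tm$pixels
  }
  list(images = out, category = aug$category, subject_id = aug$subject_id,
       electrode_px = mapper$electrode_px, bands = bands$band)
}
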