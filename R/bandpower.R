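#' Welch power spectral density
#'
#' Averaged modified periodogram: the signal is cut into Hann-windowed
#' segments of `nperseg` samples with `overlap` fractional overlap, each
#' segment's periodogram is density-scaled (`1 / (fs * sum(w^2))`, one-sided
#' doubling for interior frequencies), and segments are averaged.
#'
#' @param x Numeric vector, or matrix with one column per channel (time in
#'   rows).
#' @param sfreq Sampling rate in Hz.
#' @param nperseg Segment length in samples; clipped to the signal length.
#' @param overlap Fractional segment overlap in `[0, 1)`.
#' @param demean Subtract each segment's mean before windowing.
#' @return A list with `freq` (Hz) and `psd` (power density, `freq` x
#'   channels, units^2/Hz).
#' @export
welch_psd <- function(x, sfreq, nperseg = 256, overlap = 0.5, demean = TRUE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  nper <- min(nperseg, n)
  step <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1)) # Hann
  scale <- 1 / (sfreq * sum(w^2))
  nf <- nper %/% 2 + 1L
  acc <- matrix(0, nf, ncol(x))
  for (s0 in starts) {
    seg <- x[s0:(s0 + nper - 1L), , drop = FALSE]
    if (demean) seg <- sweep(seg, 2, colMeans(seg))
    sp <- stats::mvfft(seg * w)
    p <- Mod(sp[seq_len(nf), , drop = FALSE])^2 * scale
    # one-sided: double everything except DC (and Nyquist when nper is even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nper %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nf) - 1L) * sfreq / nper, psd = acc / length(starts))
}

# trapezoidal integral of y(f) over [lo, hi], with linear interpolation at
# the band edges so edges falling between grid points are handled exactly
trapz_band <- function(freq, y, lo, hi) {
  inside <- freq > lo & freq < hi
  f <- c(lo, freq[inside], hi)
  v <- c(stats::approx(freq, y, lo, rule = 2)$y, y[inside],
         stats::approx(freq, y, hi, rule = 2)$y)
  sum(diff(f) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Per-channel band powers of a single ERP
#'
#' Computes the Welch power spectral density of each channel across the full
#' epoch and integrates it (trapezoid rule) over each analysis band.
#'
#' @param erp Matrix channels x time (microvolts), covering the full epoch.
#' @param sfreq Sampling rate in Hz.
#' @param bands Band definitions, see [band_defs()].
#' @param channels Optional channel names for the result rows.
#' @param nperseg,overlap Welch parameters; segment length defaults to
#'   `min(256, epoch length)` with 50 percent overlap.
#' @return A `bandpower_matrix`: numeric channels x bands (microvolt^2) with
#'   band names as columns and an attribute `channels`.
#' @export
compute_bandpowers <- function(erp, sfreq, bands = band_defs(), channels = NULL,
                               nperseg = 256, overlap = 0.5) {
  stopifnot(is.matrix(erp))
  if (any(bands$hi > sfreq / 2)) {
    stop(sprintf("band upper edge %g Hz exceeds the Nyquist frequency %g Hz",
                 max(bands$hi), sfreq / 2))
  }
  ps <- welch_psd(t(erp), sfreq, nperseg = nperseg, overlap = overlap)
  bp <- vapply(seq_len(nrow(bands)), function(b) {
    apply(ps$psd, 2, function(col) trapz_band(ps$freq, col, bands$lo[b], bands$hi[b]))
  }, numeric(nrow(erp)))
  if (nrow(erp) == 1) dim(bp) <- c(1L, nrow(bands))
  colnames(bp) <- bands$band
  attr(bp, "channels") <- channels
  class(bp) <- c("bandpower_matrix", class(bp))
  bp
}
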