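# bilinear upsampling with corner alignment
bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  ri <- if (H == 1) rep(1, H) else (seq_len(H) - 1) * (h - 1) / (H - 1) + 1
  ci <- if (W == 1) rep(1, W) else (seq_len(W) - 1) * (w - 1) / (W - 1) + 1
  r0 <- pmin(floor(ri), h - 1); r1 <- r0 + 1; fr <- ri - r0
  c0 <- pmin(floor(ci), w - 1); c1 <- c0 + 1; fc <- ci - c0
  if (h == 1) { r0 <- r1 <- rep(1, H); fr <- rep(0, H) }
  if (w == 1) { c0 <- c1 <- rep(1, W); fc <- rep(0, W) }
  m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
    m[r1, c1, drop = FALSE] * outer(fr, fc)
}

# index of the layer whose output is the last convolutional feature map
# (the final spatial tensor before flattening)
last_conv_layer <- function(layers) {
  fl <- which(vapply(layers, function(l) l$type == "flatten", logical(1)))[1]
  if (is.na(fl) || fl < 2) stop("decoder has no convolutional feature map")
  fl - 1L
}

#' GradCAM class-discriminative localization map
#'
#' The gradient of the target-class logit with respect to the chosen
#' convolutional feature map is spatially averaged into per-channel weights;
#' the rectified weighted sum of the feature channels is the coarse map,
#' bilinearly upsampled to the input resolution.
#'
#' @param decoder A trained [build_decoder()] network.
#' @param image Single image, array `(H, W, C)` or a `topomap_image`.
#' @param target Target class: integer index or label. Defaults to the
#'   predicted class.
#' @param layer Index of the layer whose output serves as the feature map;
#'   defaults to the last spatial layer before flattening.
#' @return List with `map` (H x W, non-negative), `coarse` (feature-map
#'   resolution), `target` (integer class index), `probs`.
#' @export
gradcam <- function(decoder, image, target = NULL, layer = NULL) {
  x <- as_input_array(decoder, image)
  layer <- layer %||% last_conv_layer(decoder$layers)
  fw <- nn_forward(decoder$layers, x, training = FALSE)
  probs <- softmax(fw$out)
  if (!is.null(decoder$label_order)) colnames(probs) <- decoder$label_order
  target <- resolve_target(decoder, target, probs)
  dy <- matrix(0, 1, ncol(fw$out)); dy[1, target] <- 1
  bw <- nn_backward(decoder$layers, fw$caches, dy, need_dw = FALSE)
  A <- fw$caches[[layer]]$out      # (H', W', K, 1)
  dA <- bw$douts[[layer]]
  if (is.null(dim(A)) || length(dim(A)) != 4) stop("chosen layer is not spatial")
  w <- apply(dA[, , , 1, drop = FALSE], 3, mean) # spatial mean per channel
  coarse <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(dim(A)[3])) coarse <- coarse + w[k] * A[, , k, 1]
  coarse <- pmax(coarse, 0)
  list(map = bilinear_upsample(coarse, dim(x)[1], dim(x)[2]),
       coarse = coarse, target = target, probs = probs[1, ])
}

#' Guided backpropagation pixel-space gradient map
#'
#' Input gradient of the target-class logit computed with the guided
#' rectifier rule at every activation: gradients pass only where the forward
#' activation is positive AND the incoming gradient is positive. With ELU
#' activations the rule masks the standard ELU gradient; for strictly
#' positive activations and positive upstream gradients it reduces to the
#' plain input gradient.
#'
#' @inheritParams gradcam
#' @return List with `map` (signed, H x W x C), `target`, `probs`.
#' @export
guided_backprop <- function(decoder, image, target = NULL) {
  x <- as_input_array(decoder, image)
  fw <- nn_forward(decoder$layers, x, training = FALSE)
  probs <- softmax(fw$out)
  if (!is.null(decoder$label_order)) colnames(probs) <- decoder$label_order
  target <- resolve_target(decoder, target, probs)
  dy <- matrix(0, 1, ncol(fw$out)); dy[1, target] <- 1
  bw <- nn_backward(decoder$layers, fw$caches, dy, guided = TRUE, need_dw = FALSE)
  list(map = bw$dx[, , , 1], target = target, probs = probs[1, ])
}

#' Guided-GradCAM saliency map
#'
#' Elementwise product of the upsampled GradCAM coarse map and the guided
#' backpropagation map, giving a high-resolution class-discriminative
#' saliency map with one plane per input band.
#'
#' @inheritParams gradcam
#' @return Object of class `saliency_map`: list with `gradcam` (H x W),
#'   `guided` (H x W x C, signed), `guided_gradcam` (H x W x C), `target`,
#'   `probs`.
#' @export
guided_gradcam <- function(decoder, image, target = NULL, layer = NULL) {
  x <- as_input_array(decoder, image)
  gc <- gradcam(decoder, image, target, layer)
  gb <- guided_backprop(decoder, image, gc$target)
  gg <- gb$map * array(gc$map, dim(gb$map))
  structure(
    list(gradcam = gc$map, guided = gb$map, guided_gradcam = gg,
         target = gc$target, probs = gc$probs),
    class = "saliency_map"
  )
}

as_input_array <- function(decoder, image) {
  if (inherits(image, "topomap_image")) image <- image$pixels
  d <- dim(image)
  if (length(d) == 3) dim(image) <- c(d, 1)
  else stop("image must be a single (H, W, C) array")
  image
}

resolve_target <- function(decoder, target, probs) {
  if (is.null(target)) return(which.max(probs[1, ]))
  if (is.character(target)) {
    idx <- match(target, decoder$label_order)
    if (is.na(idx)) stop(sprintf("unknown target class '%s'", target))
    return(idx)
  }
  target <- as.integer(target)
  if (target < 1 || target > ncol(probs)) stop("target class out of range")
  target
}

#' Per-electrode, per-band activation extraction
#'
#' For each saliency map, the activation of an electrode in a band is the
#' mean of `|guided_gradcam|` over the 3x3 pixel neighborhood centered on
#' the electrode's (rounded) pixel position, with zero padding at image
#' edges (i.e. the neighborhood sum divided by 9). One row is emitted per
#' (sample, electrode, band).
#'
#' @param maps List of `saliency_map` objects (one per sample).
#' @param electrode_px Electrode pixel table from the topomap stage
#'   ([electrode_pixels()] or `topomaps_from_erps()$electrode_px`).
#' @param bands Band names matching the map planes.
#' @param category Per-sample predicted category labels (optional).
#' @param subject_id Per-sample subject identifiers (optional).
#' @return `data.frame` (`activation_table`) with columns `sample`,
#'   `subject`, `category`, `electrode`, `band`, `activation`.
#' @export
extract_activations <- function(maps, electrode_px,
                                bands = c("alpha", "beta", "gamma"),
                                category = NULL, subject_id = NULL) {
  if (inherits(maps, "saliency_map")) maps <- list(maps)
  n <- length(maps)
  ne <- nrow(electrode_px)
  nb <- length(bands)
  category <- category %||% vapply(maps, function(m) {
    if (!is.null(names(m$probs))) names(m$probs)[m$target] else as.character(m$target)
  }, character(1))
  subject_id <- subject_id %||% rep(NA_character_, n)

  rows <- round(electrode_px$row); cols <- round(electrode_px$col)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- abs(maps[[i]]$guided_gradcam)
    H <- dim(g)[1]; W <- dim(g)[2]
    if (any(rows < 1 | rows > H | cols < 1 | cols > W)) {
      stop("electrode pixel outside the image")
    }
    act <- matrix(0, ne, nb)
    for (b in seq_len(nb)) {
      plane <- g[, , b]
      for (e in seq_len(ne)) {
        rr <- max(1, rows[e] - 1):min(H, rows[e] + 1)
        cc <- max(1, cols[e] - 1):min(W, cols[e] + 1)
        act[e, b] <- sum(plane[rr, cc]) / 9
      }
    }
    out[[i]] <- data.frame(
      sample = i, subject = subject_id[i], category = category[i],
      electrode = rep(electrode_px$channel, nb),
      band = rep(bands, each = ne),
      activation = as.vector(act),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  class(res) <- c("activation_table", "data.frame")
  res
}
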