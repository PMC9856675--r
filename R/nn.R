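# Compact CNN engine.
#
# Activations are 4-D arrays (H, W, C, N) for the convolutional part and
# (N, units) matrices after flattening. Convolutions and dense layers reduce
# to BLAS matrix products via im2col; all gradients are exact analytic
# backprop. The engine is deliberately small: just the layer types the
# decoder architecture needs (convolution, ELU, 3x3/stride-2 max-pool,
# inception-style reduction, flatten, dense, dropout) plus a softmax
# cross-entropy head, with SGD / Adagrad / Adam updates.

# ---- padding helpers ------------------------------------------------------

# TF-style 'same' padding amounts: output ceil(n / stride)
same_pad <- function(n, k, s) {
  out <- ceiling(n / s)
  total <- max(0L, (out - 1L) * s + k - n)
  c(floor(total / 2), total - floor(total / 2))
}

pad_hw <- function(x, pt, pb, pl, pr, value = 0) {
  if (pt + pb + pl + pr == 0) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + pt + pb, d[2] + pl + pr, d[3], d[4]))
  out[pt + seq_len(d[1]), pl + seq_len(d[2]), , ] <- x
  out
}

# im2col gather index for one sample volume (H2, W2, C): rows are output
# pixels (row index fastest), columns ordered (ki fastest, kj, channel)
im2col_idx <- function(H2, W2, C, k, s, Ho, Wo) {
  i <- rep(seq_len(Ho), times = Wo)
  j <- rep(seq_len(Wo), each = Ho)
  ki <- rep(seq_len(k), times = k)
  kj <- rep(seq_len(k), each = k)
  P <- Ho * Wo
  lin <- matrix(0L, P, k * k)
  for (q in seq_len(k * k)) {
    ri <- (i - 1L) * s + ki[q]
    cj <- (j - 1L) * s + kj[q]
    lin[, q] <- (cj - 1L) * H2 + ri
  }
  if (C == 1L) return(lin)
  do.call(cbind, lapply(seq_len(C), function(c) lin + (c - 1L) * H2 * W2))
}

batch_idx <- function(idx, vol, N) {
  P <- nrow(idx)
  idx[rep(seq_len(P), N), , drop = FALSE] +
    rep((seq_len(N) - 1L) * vol, each = P)
}

# ---- layer constructors ---------------------------------------------------

nn_conv <- function(filters, kernel = 3L, stride = 1L) {
  list(type = "conv", filters = as.integer(filters), kernel = as.integer(kernel),
       stride = as.integer(stride), W = NULL, b = NULL)
}
nn_elu <- function() list(type = "elu")
nn_maxpool <- function(kernel = 3L, stride = 2L) {
  list(type = "maxpool", kernel = as.integer(kernel), stride = as.integer(stride))
}
nn_flatten <- function() list(type = "flatten")
nn_dense <- function(units) list(type = "dense", units = as.integer(units),
                                 W = NULL, b = NULL)
nn_dropout <- function(rate) list(type = "dropout", rate = rate)
# inception-style grid reduction: three stride-2 branches concatenated on the
# channel axis (3x3 conv; 1x1 then 3x3 conv; 3x3 max-pool)
nn_inception_reduce <- function(filters) {
  fb <- as.integer(ceiling(filters / 3))
  list(type = "ireduce", filters = filters,
       branch1 = list(nn_conv(fb, 3L, 2L), nn_elu()),
       branch2 = list(nn_conv(fb, 1L, 1L), nn_elu(), nn_conv(fb, 3L, 2L), nn_elu()),
       branch3 = list(nn_maxpool(3L, 2L)))
}

# ---- initialization -------------------------------------------------------

# walks the layer list once with a dummy shape, allocating weights (He
# normal) and recording input/output shapes; errors if a reduction underflows
nn_init <- function(layers, input_shape) {
  shape <- input_shape # c(H, W, C) or scalar units
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    if (ly$type == "conv") {
      fan_in <- ly$kernel^2 * shape[3]
      layers[[l]]$W <- matrix(stats::rnorm(fan_in * ly$filters, 0, sqrt(2 / fan_in)),
                              fan_in, ly$filters)
      layers[[l]]$b <- numeric(ly$filters)
      shape <- c(ceiling(shape[1] / ly$stride), ceiling(shape[2] / ly$stride), ly$filters)
    } else if (ly$type == "maxpool") {
      shape <- c(ceiling(shape[1] / ly$stride), ceiling(shape[2] / ly$stride), shape[3])
    } else if (ly$type == "ireduce") {
      if (shape[1] < 2 || shape[2] < 2) {
        stop(sprintf("reduction block %d cannot halve a %dx%d input",
                     l, shape[1], shape[2]))
      }
      for (br in c("branch1", "branch2", "branch3")) {
        sub <- nn_init(layers[[l]][[br]], shape)
        layers[[l]][[br]] <- sub$layers
      }
      cin <- shape[3]
      fb <- as.integer(ceiling(layers[[l]]$filters / 3))
      shape <- c(ceiling(shape[1] / 2), ceiling(shape[2] / 2), 2L * fb + cin)
    } else if (ly$type == "flatten") {
      shape <- prod(shape)
    } else if (ly$type == "dense") {
      fan_in <- shape[1]
      layers[[l]]$W <- matrix(stats::rnorm(fan_in * ly$units, 0, sqrt(2 / fan_in)),
                              fan_in, ly$units)
      layers[[l]]$b <- numeric(ly$units)
      shape <- ly$units
    }
    # elu / dropout keep the shape
  }
  list(layers = layers, output_shape = shape)
}

# ---- forward --------------------------------------------------------------

elu_fwd <- function(x) { neg <- x < 0; x[neg] <- exp(x[neg]) - 1; x }

conv_fwd <- function(ly, x) {
  d <- dim(x); N <- d[4]
  k <- ly$kernel; s <- ly$stride
  ph <- same_pad(d[1], k, s); pw <- same_pad(d[2], k, s)
  xp <- pad_hw(x, ph[1], ph[2], pw[1], pw[2])
  dp <- dim(xp)
  Ho <- ceiling(d[1] / s); Wo <- ceiling(d[2] / s)
  idx <- im2col_idx(dp[1], dp[2], d[3], k, s, Ho, Wo)
  bi <- batch_idx(idx, prod(dp[1:3]), N)
  M <- matrix(xp[c(bi)], nrow(bi), ncol(bi)) # c(): plain vector indexing
  out <- M %*% ly$W
  out <- sweep(out, 2, ly$b, `+`)
  y <- aperm(array(out, c(Ho, Wo, N, ly$filters)), c(1, 2, 4, 3))
  list(y = y, cache = list(M = M, idx = idx, dims = d, pdims = dp,
                           Ho = Ho, Wo = Wo, ph = ph, pw = pw))
}

conv_bwd <- function(ly, dy, cache, need_dx = TRUE, need_dw = TRUE) {
  k <- ly$kernel; s <- ly$stride
  Ho <- cache$Ho; Wo <- cache$Wo
  d <- cache$dims; dp <- cache$pdims; N <- d[4]; C <- d[3]
  dy_mat <- matrix(aperm(dy, c(1, 2, 4, 3)), Ho * Wo * N, ly$filters)
  grads <- NULL
  if (need_dw) {
    grads <- list(W = crossprod(cache$M, dy_mat), b = colSums(dy_mat))
  }
  dx <- NULL
  if (need_dx) {
    dM <- tcrossprod(dy_mat, ly$W) # rows x (k^2 C)
    dxp <- array(0, dp)
    k2 <- k * k
    ki <- rep(seq_len(k), times = k); kj <- rep(seq_len(k), each = k)
    ri_base <- s * (seq_len(Ho) - 1L); cj_base <- s * (seq_len(Wo) - 1L)
    for (q in seq_len(k2)) {
      cols <- (seq_len(C) - 1L) * k2 + q
      sl <- aperm(array(dM[, cols], c(Ho, Wo, N, C)), c(1, 2, 4, 3))
      ri <- ri_base + ki[q]; cj <- cj_base + kj[q]
      dxp[ri, cj, , ] <- dxp[ri, cj, , , drop = FALSE] + sl
    }
    dx <- dxp[cache$ph[1] + seq_len(d[1]), cache$pw[1] + seq_len(d[2]), , ,
              drop = FALSE]
  }
  list(dx = dx, grads = grads)
}

pool_fwd <- function(ly, x) {
  d <- dim(x); N <- d[4]; C <- d[3]
  k <- ly$kernel; s <- ly$stride
  ph <- same_pad(d[1], k, s); pw <- same_pad(d[2], k, s)
  xp <- pad_hw(x, ph[1], ph[2], pw[1], pw[2], value = -Inf)
  dp <- dim(xp)
  Ho <- ceiling(d[1] / s); Wo <- ceiling(d[2] / s)
  idx <- im2col_idx(dp[1], dp[2], 1L, k, s, Ho, Wo) # per-plane window index
  bi <- batch_idx(idx, dp[1] * dp[2], C * N)
  M <- matrix(xp[c(bi)], nrow(bi), ncol(bi))
  amax <- max.col(M, ties.method = "first")
  win <- bi[cbind(seq_len(nrow(bi)), amax)]
  y <- array(M[cbind(seq_len(nrow(M)), amax)], c(Ho, Wo, C, N))
  list(y = y, cache = list(win = win, dims = d, pdims = dp, ph = ph, pw = pw))
}

pool_bwd <- function(ly, dy, cache) {
  dp <- cache$pdims; d <- cache$dims
  dxp <- numeric(prod(dp))
  rs <- rowsum(as.vector(dy), cache$win)
  dxp[as.integer(rownames(rs))] <- rs
  dim(dxp) <- dp
  dxp[cache$ph[1] + seq_len(d[1]), cache$pw[1] + seq_len(d[2]), , , drop = FALSE]
}

# forward through a layer list; `training` enables dropout; caches keep what
# backward needs plus each layer's output (for GradCAM and guided rules)
nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    if (ly$type == "conv") {
      cf <- conv_fwd(ly, x)
      caches[[l]] <- cf$cache
      x <- cf$y
    } else if (ly$type == "elu") {
      y <- elu_fwd(x)
      caches[[l]] <- list(x = x, y = y)
      x <- y
    } else if (ly$type == "maxpool") {
      pf <- pool_fwd(ly, x)
      caches[[l]] <- pf$cache
      x <- pf$y
    } else if (ly$type == "ireduce") {
      f1 <- nn_forward(ly$branch1, x, training)
      f2 <- nn_forward(ly$branch2, x, training)
      f3 <- nn_forward(ly$branch3, x, training)
      c1 <- dim(f1$out)[3]; c2 <- dim(f2$out)[3]; c3 <- dim(f3$out)[3]
      y <- array(0, c(dim(f1$out)[1:2], c1 + c2 + c3, dim(f1$out)[4]))
      y[, , seq_len(c1), ] <- f1$out
      y[, , c1 + seq_len(c2), ] <- f2$out
      y[, , c1 + c2 + seq_len(c3), ] <- f3$out
      caches[[l]] <- list(b1 = f1$caches, b2 = f2$caches, b3 = f3$caches,
                          splits = c(c1, c2, c3))
      x <- y
    } else if (ly$type == "flatten") {
      d <- dim(x)
      caches[[l]] <- list(dims = d)
      x <- t(matrix(x, prod(d[1:3]), d[4]))
    } else if (ly$type == "dense") {
      caches[[l]] <- list(x = x)
      x <- sweep(x %*% ly$W, 2, ly$b, `+`)
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- (matrix(stats::runif(length(x)), nrow(x)) >= ly$rate) / (1 - ly$rate)
        caches[[l]] <- list(mask = mask)
        x <- x * mask
      } else {
        caches[[l]] <- list(mask = NULL)
      }
    }
    caches[[l]]$out <- x
  }
  list(out = x, caches = caches)
}

# backward pass; `guided` switches ELU gradients to the guided rule (only
# positive upstream gradients pass through positively-activated units).
# Returns dx at the input, per-layer parameter gradients, and the gradient
# flowing into each layer's output (`dout`, used by GradCAM).
nn_backward <- function(layers, caches, dy, guided = FALSE, need_dw = TRUE) {
  grads <- vector("list", length(layers))
  douts <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    ly <- layers[[l]]
    douts[[l]] <- dy
    if (ly$type == "conv") {
      cb <- conv_bwd(ly, dy, caches[[l]], need_dx = TRUE, need_dw = need_dw)
      grads[[l]] <- cb$grads
      dy <- cb$dx
    } else if (ly$type == "elu") {
      x <- caches[[l]]$x
      if (guided) dy <- dy * (caches[[l]]$y > 0) * (dy > 0)
      deriv <- x
      pos <- x >= 0
      deriv[pos] <- 1
      deriv[!pos] <- exp(x[!pos])
      dy <- dy * deriv
    } else if (ly$type == "maxpool") {
      dy <- pool_bwd(ly, dy, caches[[l]])
    } else if (ly$type == "ireduce") {
      sp <- caches[[l]]$splits
      d1 <- dy[, , seq_len(sp[1]), , drop = FALSE]
      d2 <- dy[, , sp[1] + seq_len(sp[2]), , drop = FALSE]
      d3 <- dy[, , sp[1] + sp[2] + seq_len(sp[3]), , drop = FALSE]
      b1 <- nn_backward(ly$branch1, caches[[l]]$b1, d1, guided, need_dw)
      b2 <- nn_backward(ly$branch2, caches[[l]]$b2, d2, guided, need_dw)
      b3 <- nn_backward(ly$branch3, caches[[l]]$b3, d3, guided, need_dw)
      grads[[l]] <- list(b1 = b1$grads, b2 = b2$grads, b3 = b3$grads)
      dy <- b1$dx + b2$dx + b3$dx
    } else if (ly$type == "flatten") {
      d <- caches[[l]]$dims
      dy <- array(t(dy), d)
    } else if (ly$type == "dense") {
      x <- caches[[l]]$x
      if (need_dw) grads[[l]] <- list(W = crossprod(x, dy), b = colSums(dy))
      dy <- tcrossprod(dy, ly$W)
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[l]]$mask)) dy <- dy * caches[[l]]$mask
    }
  }
  list(dx = dy, grads = grads, douts = douts)
}

softmax <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# ---- parameter bookkeeping (flat views for the optimizers) ----------------

nn_collect_params <- function(layers, path = integer(0)) {
  out <- list()
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    if (ly$type %in% c("conv", "dense")) {
      out[[length(out) + 1]] <- list(path = c(path, l), field = "W")
      out[[length(out) + 1]] <- list(path = c(path, l), field = "b")
    } else if (ly$type == "ireduce") {
      for (br in c("branch1", "branch2", "branch3")) {
        for (s in nn_collect_params(ly[[br]])) {
          out[[length(out) + 1]] <- list(path = c(path, l), field = s$field,
                                         sub = list(branch = br, path = s$path))
        }
      }
    }
  }
  out
}

nn_get_param <- function(layers, ref) {
  l <- ref$path[length(ref$path)]
  if (is.null(ref$sub)) layers[[l]][[ref$field]]
  else layers[[l]][[ref$sub$branch]][[ref$sub$path]][[ref$field]]
}

nn_set_param <- function(layers, ref, value) {
  l <- ref$path[length(ref$path)]
  if (is.null(ref$sub)) layers[[l]][[ref$field]] <- value
  else layers[[l]][[ref$sub$branch]][[ref$sub$path]][[ref$field]] <- value
  layers
}

nn_get_grad <- function(grads, ref) {
  l <- ref$path[length(ref$path)]
  if (is.null(ref$sub)) grads[[l]][[ref$field]]
  else {
    bname <- c(branch1 = "b1", branch2 = "b2", branch3 = "b3")[[ref$sub$branch]]
    grads[[l]][[bname]][[ref$sub$path]][[ref$field]]
  }
}

nn_n_params <- function(layers) {
  tot <- 0
  for (ly in layers) {
    if (ly$type %in% c("conv", "dense")) tot <- tot + length(ly$W) + length(ly$b)
    if (ly$type == "ireduce") {
      for (br in c("branch1", "branch2", "branch3")) tot <- tot + nn_n_params(ly[[br]])
    }
  }
  tot
}

make_optimizer <- function(name, lr) {
  name <- tolower(name)
  state <- new.env(parent = emptyenv())
  state$lr <- lr
  step <- switch(
    name,
    sgd = function(ref_id, w, g) w - state$lr * g,
    adagrad = function(ref_id, w, g) {
      key <- paste0("G", ref_id)
      G <- (if (exists(key, state)) get(key, state) else 0) + g^2
      assign(key, G, state)
      w - state$lr * g / sqrt(G + 1e-10)
    },
    adam = function(ref_id, w, g) {
      tkey <- paste0("t", ref_id); mkey <- paste0("m", ref_id); vkey <- paste0("v", ref_id)
      t <- (if (exists(tkey, state)) get(tkey, state) else 0) + 1
      m <- 0.9 * (if (exists(mkey, state)) get(mkey, state) else 0) + 0.1 * g
      v <- 0.999 * (if (exists(vkey, state)) get(vkey, state) else 0) + 0.001 * g^2
      assign(tkey, t, state); assign(mkey, m, state); assign(vkey, v, state)
      mh <- m / (1 - 0.9^t); vh <- v / (1 - 0.999^t)
      w - state$lr * mh / (sqrt(vh) + 1e-8)
    },
    stop(sprintf("unknown optimizer '%s'", name))
  )
  list(step = step, state = state)
}
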