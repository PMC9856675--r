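# Shared fixtures, built in code at test time.

# tiny epoched trial set with a small montage: white noise plus an optional
# per-channel offset; channels default to a 4-sensor subset
tiny_trial_set <- function(n_trials = 20, n_ch = 4, n_t = 50, sfreq = 100,
                           seed = 1, rt = NULL, subject = NULL) {
  withr::with_seed(seed, {
    data <- array(rnorm(n_trials * n_ch * n_t), c(n_trials, n_ch, n_t))
    trial_set(
      data,
      rt_ms = rt %||% runif(n_trials, 200, 1200),
      subject_id = subject %||% rep("S01", n_trials),
      sfreq = sfreq, epoch_window = c(-100, 400),
      channels = paste0("CH", seq_len(n_ch))
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# discrete-event simulation of the bootstrap drop schedule; independent of
# the package implementation (counts only, no averaging)
simulate_drop_schedule <- function(pool_size, r, alpha, n, n_alpha) {
  if (pool_size == 0) return(0L)
  m <- max(1L, as.integer(round(r * alpha)))
  emitted <- 0L
  j <- 0L
  while (j < n) {
    j <- j + 1L
    if (pool_size <= r) {
      emitted <- emitted + 1L
      break
    }
    emitted <- emitted + 1L
    if (j %% n_alpha == 0L) {
      pool_size <- pool_size - min(m, pool_size)
      if (pool_size == 0L) break
    }
  }
  emitted
}

# i.i.d.-noise activation table on a reduced factorial grid (balanced)
null_activation_table <- function(n_per_cat = 5, n_electrodes = 6, seed = 1) {
  withr::with_seed(seed, {
    el <- sprintf("E%02d", seq_len(n_electrodes))
    bands <- c("alpha", "beta", "gamma")
    cats <- c("fast", "medium", "slow")
    samples <- seq_len(n_per_cat * 3)
    cat_of <- rep(cats, each = n_per_cat)
    df <- expand.grid(electrode = el, band = bands, sample = samples,
                      stringsAsFactors = FALSE)
    df$category <- cat_of[df$sample]
    df$subject <- "S01"
    df$activation <- rnorm(nrow(df), 3, 1)
    class(df) <- c("activation_table", "data.frame")
    df
  })
}

# three-class blob images: class-specific bright spot + uniform noise
blob_images <- function(n_per_class = 60, side = 16, seed = 1) {
  withr::with_seed(seed, {
    lab <- factor(rep(c("fast", "medium", "slow"), each = n_per_class))
    ctr <- list(fast = c(4, 4), medium = c(12, 4), slow = c(8, 12))
    imgs <- array(0, c(length(lab), side, side, 3))
    for (i in seq_along(lab)) {
      cc <- ctr[[as.character(lab[i])]]
      g <- outer(dnorm(seq_len(side), cc[1], 2), dnorm(seq_len(side), cc[2], 2))
      g <- g / max(g)
      for (b in 1:3) {
        imgs[i, , , b] <- g * 0.8 + matrix(runif(side^2, 0, 0.3), side)
      }
    }
    list(images = imgs, labels = lab)
  })
}

# minimal sequential network builders for saliency toys (internal API)
toy_linear_net <- function(Wconv, fc_weights, fc_bias = NULL) {
  # single 1x1 conv (linear, no activation) + flatten + dense logits
  conv <- rtdecoder:::nn_conv(ncol(Wconv), 1L, 1L)
  conv$W <- Wconv
  conv$b <- numeric(ncol(Wconv))
  dense <- rtdecoder:::nn_dense(ncol(fc_weights))
  dense$W <- fc_weights
  dense$b <- fc_bias %||% numeric(ncol(fc_weights))
  list(conv, rtdecoder:::nn_flatten(), dense)
}
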