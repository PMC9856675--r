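#' Bootstrap augmentation parameters
#'
#' @param r Number of trials averaged per bootstrap ERP.
#' @param alpha Named dropout rate per category (fraction of `r` dropped at
#'   each drop event); defaults to the study settings fast 0.3, medium 0.2,
#'   slow 0.1.
#' @param n Maximum bootstrap iterations per pool.
#' @param n_alpha Iteration interval between drop events.
#' @param seed Integer seed.
#' @return An object of class `bootstrap_params`.
#' @export
bootstrap_params <- function(r = 50,
                             alpha = c(fast = 0.3, medium = 0.2, slow = 0.1),
                             n = 1500, n_alpha = 10, seed = 1L) {
  stopifnot(r >= 1, n >= 1, n_alpha >= 1)
  if (is.null(names(alpha))) names(alpha) <- rt_categories
  if (!all(rt_categories %in% names(alpha))) {
    stop("alpha must name rates for fast, medium and slow")
  }
  if (any(alpha <= 0 | alpha >= 1)) stop("dropout rates must lie in (0, 1)")
  structure(list(r = as.integer(r), alpha = alpha, n = as.integer(n),
                 n_alpha = as.integer(n_alpha), seed = as.integer(seed)),
            class = "bootstrap_params")
}

#' Container for bootstrap-averaged ERPs
#'
#' @param erps Array samples x channels x time (microvolts).
#' @param category Per-sample RT category (fast/medium/slow).
#' @param subject_id Per-sample subject identifier.
#' @param provenance Number of raw trials averaged into each sample.
#' @param channels Optional channel names.
#' @param sfreq,epoch_window Carried over from the source trials.
#' @return An object of class `augmented_erp_set`.
#' @export
augmented_erp_set <- function(erps, category, subject_id, provenance,
                              channels = NULL, sfreq = NULL, epoch_window = NULL) {
  stopifnot(length(dim(erps)) == 3)
  n <- dim(erps)[1]
  stopifnot(length(category) == n, length(subject_id) == n, length(provenance) == n)
  if (!all(as.character(category) %in% rt_categories)) {
    stop("categories must be fast/medium/slow (outliers excluded upstream)")
  }
  structure(
    list(erps = erps, category = factor(as.character(category), levels = rt_categories),
         subject_id = subject_id, provenance = as.integer(provenance),
         channels = channels, sfreq = sfreq, epoch_window = epoch_window),
    class = "augmented_erp_set"
  )
}

#' @export
print.augmented_erp_set <- function(x, ...) {
  d <- dim(x$erps)
  cat(sprintf("<augmented_erp_set> %d ERPs x %d channels x %d samples\n", d[1], d[2], d[3]))
  print(table(x$category))
  invisible(x)
}

#' Bootstrap ERP generation with category-specific trial dropout
#'
#' Trials are pooled per (subject, category); outlier-labeled trials must be
#' excluded beforehand (they are dropped here with a message if present).
#' Within each pool, iterations `j = 1..n` draw `r` distinct trials uniformly
#' without replacement and emit their average as one ERP sample. Every
#' `n_alpha` iterations, `m = max(1, round(r * alpha[category]))` trials
#' chosen from the most recent draw are permanently removed from the pool.
#' When the pool size falls to `r` or below, the average of all remaining
#' trials is emitted once and the pool terminates (rather than emitting that
#' same average indefinitely, which would defeat the algorithm's anti-bias
#' purpose).
#'
#' @param trials A [trial_set()].
#' @param labels Per-trial category factor (from [assign_categories()]).
#' @param params A [bootstrap_params()].
#' @return An [augmented_erp_set()]. Deterministic given `params$seed`.
#' @export
bootstrap_erps <- function(trials, labels, params = bootstrap_params()) {
  stopifnot(inherits(trials, "trial_set"), inherits(params, "bootstrap_params"))
  labels <- factor(as.character(labels), levels = rt_categories_all)
  stopifnot(length(labels) == dim(trials$data)[1])
  keep <- !is.na(labels) & labels != "outlier"
  if (any(labels == "outlier", na.rm = TRUE)) {
    message(sprintf("excluding %d outlier trials before augmentation",
                    sum(labels == "outlier", na.rm = TRUE)))
  }
  d <- dim(trials$data)
  subjects <- unique(trials$subject_id)

  erps <- list(); cats <- character(0); subs <- character(0); prov <- integer(0)
  with_local_seed(params$seed, {
    for (s in subjects) {
      for (cat in rt_categories) {
        pool <- which(keep & trials$subject_id == s & labels == cat)
        if (!length(pool)) {
          warning(sprintf("empty pool for subject %s category %s: no samples", s, cat))
          next
        }
        m <- max(1L, as.integer(round(params$r * params$alpha[[cat]])))
        j <- 0L
        last_draw <- integer(0)
        while (j < params$n) {
          j <- j + 1L
          if (length(pool) <= params$r) {
            erps[[length(erps) + 1L]] <- pool_mean(trials$data, pool)
            cats <- c(cats, cat); subs <- c(subs, s); prov <- c(prov, length(pool))
            break
          }
          draw <- sample(pool, params$r)
          erps[[length(erps) + 1L]] <- pool_mean(trials$data, draw)
          cats <- c(cats, cat); subs <- c(subs, s); prov <- c(prov, params$r)
          if (j %% params$n_alpha == 0L) {
            drop_idx <- sample(draw, min(m, length(draw)))
            pool <- setdiff(pool, drop_idx)
            if (!length(pool)) break
          }
        }
      }
    }
  })
  if (!length(erps)) {
    return(augmented_erp_set(array(0, c(0, d[2], d[3])), character(0), character(0),
                             integer(0), trials$channels, trials$sfreq,
                             trials$epoch_window))
  }
  out <- array(0, c(length(erps), d[2], d[3]))
  for (i in seq_along(erps)) out[i, , ] <- erps[[i]]
  augmented_erp_set(out, cats, subs, prov, trials$channels, trials$sfreq,
                    trials$epoch_window)
}

pool_mean <- function(data, idx) {
  if (length(idx) == 1L) data[idx, , ] else colMeans(data[idx, , , drop = FALSE])
}

#' Closed-form bootstrap output size
#'
#' Predicts the number of ERP samples [bootstrap_erps()] emits for one pool:
#' 1 if the pool starts at or below `r`; otherwise the drop schedule removes
#' `m = max(1, round(r * alpha))` trials every `n_alpha` iterations, so the
#' terminal sample lands at iteration `ceil((pool - r) / m) * n_alpha + 1`,
#' capped at `n`.
#'
#' @param pool_size Number of trials in the pool (>= 0).
#' @param params A [bootstrap_params()].
#' @param category Category whose dropout rate applies.
#' @return Predicted sample count.
#' @export
expected_sample_count <- function(pool_size, params, category) {
  stopifnot(pool_size >= 0, inherits(params, "bootstrap_params"))
  if (pool_size == 0) return(0L)
  if (pool_size <= params$r) return(1L)
  m <- max(1L, as.integer(round(params$r * params$alpha[[category]])))
  drops_needed <- ceiling((pool_size - params$r) / m)
  as.integer(min(params$n, drops_needed * params$n_alpha + 1))
}

#' Category share bookkeeping
#'
#' Converts per-category sample counts into total and rounded percentage
#' shares, the arithmetic used when reporting how augmentation rebalances
#' the class distribution.
#'
#' @param counts Named numeric vector of per-category counts.
#' @return A list with `counts`, `total` and `share_pct` (rounded percent).
#' @export
category_share_table <- function(counts) {
  total <- sum(counts)
  list(counts = counts, total = total,
       share_pct = round(100 * counts / total))
}

#' Eigenspace reconstruction-error filtering
#'
#' Builds a PCA basis of the raw trials (flattened channels x time, centered
#' on the raw mean), computes each augmented sample's Euclidean residual from
#' its projection onto the top-`k` principal axes, and retains samples whose
#' residual lies within the central `[lo, hi]` percentile band (inclusive
#' bounds, stable input order). Samples in the low-error tail are
#' near-duplicates of raw-trial structure (biased); the high tail is
#' noise-dominated; both are discarded to control variance.
#'
#' @param raw A [trial_set()] (>= 2 trials) defining the eigenspace.
#' @param augmented An [augmented_erp_set()].
#' @param k Number of principal axes, or a variance fraction in (0, 1)
#'   selecting the smallest count explaining that fraction (default 0.95).
#'   Values exceeding the raw rank are clipped with a warning.
#' @param lo,hi Retention percentiles (default 25 and 75).
#' @param per_category If `TRUE`, percentile bounds are computed within each
#'   category instead of on the pooled residual distribution.
#' @return The filtered `augmented_erp_set`, with fields `residual` (per
#'   retained sample) and attributes `all_residuals` and `retained` (logical
#'   over the input order).
#' @export
eigenspace_filter <- function(raw, augmented, k = 0.95, lo = 25, hi = 75,
                              per_category = FALSE) {
  stopifnot(inherits(raw, "trial_set"), inherits(augmented, "augmented_erp_set"))
  n_raw <- dim(raw$data)[1]
  if (n_raw < 2) stop("need at least 2 raw trials")
  if (dim(augmented$erps)[1] < 1) stop("augmented set is empty")
  d <- prod(dim(raw$data)[2:3])
  stopifnot(prod(dim(augmented$erps)[2:3]) == d)

  X <- raw$data; dim(X) <- c(n_raw, d)
  mu <- colMeans(X)
  # Gram-matrix PCA: d >> n, so eigendecompose the centered Gram matrix and
  # map back; the centering is applied through inner-product identities to
  # avoid materializing centered copies of the large trial matrices
  G <- tcrossprod(X)
  a <- as.vector(X %*% mu)
  G <- G - outer(a, rep(1, n_raw)) - outer(rep(1, n_raw), a) + sum(mu^2)
  eg <- eigen(G, symmetric = TRUE)
  rm(G)
  tol <- max(eg$values) * 1e-10
  rank <- sum(eg$values > tol)
  if (k < 1) {
    vfrac <- cumsum(eg$values[seq_len(rank)]) / sum(eg$values[seq_len(rank)])
    k_use <- which(vfrac >= k)[1]
  } else {
    k_use <- as.integer(k)
    if (k_use > rank) {
      warning(sprintf("k = %d exceeds raw rank %d; clipped", k_use, rank))
      k_use <- rank
    }
  }
  U <- eg$vectors[, seq_len(k_use), drop = FALSE]
  # principal axes V = t(Xc) U S^-1, again via X and mu only
  V <- crossprod(X, U) - outer(mu, colSums(U))
  V <- sweep(V, 2, sqrt(eg$values[seq_len(k_use)]), `/`) # d x k, orthonormal
  rm(X)

  A <- augmented$erps; na <- dim(A)[1]; dim(A) <- c(na, d)
  # ||a - mu||^2 and the projection of (a - mu), without centering A
  P <- A %*% V - matrix(colSums(V * mu), na, k_use, byrow = TRUE)
  sq <- rowSums(A^2) - 2 * as.vector(A %*% mu) + sum(mu^2)
  rm(A)
  resid <- sqrt(pmax(sq - rowSums(P^2), 0))

  retained <- logical(na)
  if (per_category) {
    for (cat in levels(augmented$category)) {
      idx <- which(augmented$category == cat)
      if (!length(idx)) next
      q <- stats::quantile(resid[idx], c(lo, hi) / 100, type = 7, names = FALSE)
      retained[idx] <- resid[idx] >= q[1] & resid[idx] <= q[2]
    }
  } else {
    q <- stats::quantile(resid, c(lo, hi) / 100, type = 7, names = FALSE)
    retained <- resid >= q[1] & resid <= q[2]
  }

  out <- augmented_erp_set(
    augmented$erps[retained, , , drop = FALSE],
    augmented$category[retained], augmented$subject_id[retained],
    augmented$provenance[retained], augmented$channels, augmented$sfreq,
    augmented$epoch_window
  )
  out$residual <- resid[retained]
  attr(out, "all_residuals") <- resid
  attr(out, "retained") <- retained
  attr(out, "k_used") <- k_use
  out
}

#' Write augmentation provenance as CSV
#'
#' One row per sample: subject, category, trials averaged, and (when the set
#' went through [eigenspace_filter()]) the residual.
#'
#' @param aug An `augmented_erp_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_augmentation_provenance <- function(aug, path) {
  df <- data.frame(
    sample = seq_along(aug$category),
    subject = aug$subject_id,
    category = as.character(aug$category),
    trials_averaged = aug$provenance
  )
  if (!is.null(aug$residual)) df$residual <- aug$residual
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
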