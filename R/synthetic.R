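#' Frequency-band definitions
#'
#' Default analysis bands: alpha 9-13 Hz, beta 14-30 Hz, gamma 31-60 Hz.
#'
#' @param names Band names.
#' @param lo,hi Band edges in Hz, same length as `names`.
#' @return A `data.frame` with columns `band`, `lo`, `hi`.
#' @export
band_defs <- function(names = c("alpha", "beta", "gamma"),
                      lo = c(9, 14, 31),
                      hi = c(13, 30, 60)) {
  stopifnot(length(names) == length(lo), length(lo) == length(hi), all(hi > lo))
  if (any(diff(lo) <= 0) || any(utils::head(hi, -1) >= utils::tail(lo, -1) + 1e-9)) {
    stop("bands must be ordered and non-overlapping")
  }
  data.frame(band = names, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

#' Specification of planted spatial-spectral effects and the RT mixture
#'
#' An `effect_spec` encodes the ground truth the synthetic generator plants:
#' a multiplicative oscillation-amplitude factor per (channel, band, response
#' category), the band definitions, and the four-component response-time
#' mixture (fast/medium/slow/outlier) from which trial RTs are drawn.
#'
#' @param factors `data.frame` with columns `channel`, `band`, `category`,
#'   `factor` listing amplitude multipliers that differ from 1. All factors
#'   must be positive.
#' @param bands Band definitions, see [band_defs()].
#' @param mixture `data.frame` with columns `category`, `mean`, `sd`,
#'   `weight` (ms, ms, probability); weights must sum to 1.
#' @param rt_range Truncation range for sampled RTs, in ms.
#' @param base_amp Named vector of baseline oscillation amplitudes per band
#'   (microvolts).
#' @param noise_rms Per-channel RMS of the 1/f background noise (microvolts).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(factors,
                        bands = band_defs(),
                        mixture = default_rt_mixture(),
                        rt_range = c(100, 2500),
                        base_amp = c(alpha = 4, beta = 3, gamma = 2),
                        noise_rms = 10) {
  stopifnot(all(c("channel", "band", "category", "factor") %in% names(factors)))
  if (any(factors$factor <= 0)) stop("effect factors must be positive")
  if (!all(factors$band %in% bands$band)) stop("unknown band in factors")
  if (!all(factors$category %in% rt_categories_all)) stop("unknown category in factors")
  stopifnot(all(c("category", "mean", "sd", "weight") %in% names(mixture)))
  if (abs(sum(mixture$weight) - 1) > 1e-8) stop("mixture weights must sum to 1")
  structure(
    list(factors = factors, bands = bands, mixture = mixture,
         rt_range = rt_range, base_amp = base_amp, noise_rms = noise_rms),
    class = "effect_spec"
  )
}

#' Default response-time mixture
#'
#' Four truncated-normal components (ms): fast N(340, 70), medium
#' N(640, 65), slow N(1030, 140) and a low-probability outlier N(1800, 250),
#' with weights 0.55/0.27/0.12/0.06. Chosen so that the maximum-a-posteriori
#' cluster ranges approximate the study's printed fast/medium/slow spans
#' (roughly 100-504 / 506-770 / 772-1360 ms) and the fast-majority class
#' imbalance.
#'
#' @return A `data.frame` with columns `category`, `mean`, `sd`, `weight`.
#' @export
default_rt_mixture <- function() {
  data.frame(
    category = rt_categories_all,
    mean = c(340, 640, 1030, 1800),
    sd = c(70, 65, 140, 250),
    weight = c(0.55, 0.27, 0.12, 0.06),
    stringsAsFactors = FALSE
  )
}

#' Default planted effects
#'
#' Emulates the qualitative spatial-spectral structure the decoding chain is
#' built to recover: left-frontal alpha amplitude (FT7, FC5, FC3) decreasing
#' from fast to slow responses, right-cerebellar beta (CB2) elevated for
#' slow responses, and right-prefrontal beta (AF4, F2) elevated for medium
#' responses. In addition, every category carries one localized focus per
#' band of comparable strength (medium alpha at CP1, slow alpha over the
#' occiput, fast beta over left central sites), so that under per-image
#' band normalization the categories differ in where band power
#' concentrates rather than in overall plane brightness — the spatial
#' configuration, not a global intensity shortcut, is the decodable signal.
#'
#' @param ... Passed on to [effect_spec()].
#' @return An `effect_spec`.
#' @export
default_effect_spec <- function(...) {
  grid <- function(ch, band, cat) {
    expand.grid(channel = ch, band = band, category = cat,
                stringsAsFactors = FALSE)
  }
  f <- rbind(
    # left-frontal alpha gradient: fast > medium > slow
    cbind(grid(c("FT7", "FC5", "FC3"), "alpha", rt_categories),
          factor = rep(c(3.0, 1.5, 0.75), each = 3)),
    # medium: left centro-parietal alpha focus
    cbind(grid("CP1", "alpha", "medium"), factor = 3.0),
    # slow: occipital alpha focus
    cbind(grid(c("O1", "OZ", "O2"), "alpha", "slow"), factor = 2.5),
    # slow: right-cerebellar beta, with a mild gradient across categories
    cbind(grid("CB2", "beta", rt_categories), factor = c(0.8, 1.2, 3.0)),
    # medium: right-prefrontal beta focus
    cbind(grid(c("AF4", "F2"), "beta", "medium"), factor = 2.5),
    # fast: left central beta focus
    cbind(grid(c("C5", "C1"), "beta", "fast"), factor = 2.5)
  )
  effect_spec(f, ...)
}

#' Sample response times from a category mixture
#'
#' Draws component memberships by mixture weight, then RTs from each
#' component's normal distribution, rejection-truncated to `range`.
#'
#' @param n Number of RTs.
#' @param mixture Mixture table (see [default_rt_mixture()]).
#' @param range Truncation range in ms.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return List with `rt_ms` and `category` (the generating component).
#' @export
sample_rts <- function(n, mixture = default_rt_mixture(), range = c(100, 2500),
                       seed = NULL) {
  draw <- function() {
    comp <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
    rt <- mixture$mean[comp] + mixture$sd[comp] * stats::rnorm(n)
    bad <- which(rt < range[1] | rt > range[2])
    while (length(bad)) {
      rt[bad] <- mixture$mean[comp[bad]] +
        mixture$sd[comp[bad]] * stats::rnorm(length(bad))
      bad <- bad[rt[bad] < range[1] | rt[bad] > range[2]]
    }
    list(rt_ms = rt, category = mixture$category[comp])
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

amplitude_factor <- function(effect, channels, band, category) {
  out <- rep(1, length(channels))
  sel <- effect$factors$band == band & effect$factors$category == category
  if (any(sel)) {
    sub <- effect$factors[sel, ]
    idx <- match(sub$channel, channels)
    ok <- !is.na(idx)
    out[idx[ok]] <- sub$factor[ok]
  }
  out
}

#' Construct an epoched-trial container
#'
#' @param data Numeric array, trials x channels x time (microvolts).
#' @param rt_ms Per-trial response time in ms, positive.
#' @param subject_id Per-trial subject identifier.
#' @param sfreq Sampling rate in Hz.
#' @param epoch_window Epoch span `c(start, end)` in ms.
#' @param channels Channel names, length matching `dim(data)[2]`.
#' @param true_category Optional per-trial generating category (synthetic
#'   ground truth); kept for validation, never used by the analysis chain.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, rt_ms, subject_id, sfreq, epoch_window = c(-200, 800),
                      channels = NULL, true_category = NULL) {
  stopifnot(length(dim(data)) == 3)
  n <- dim(data)[1]
  if (length(rt_ms) != n || length(subject_id) != n) {
    stop("rt_ms and subject_id must match the number of trials")
  }
  if (any(rt_ms <= 0)) stop("rt_ms must be positive")
  if (!is.null(channels) && length(channels) != dim(data)[2]) {
    stop("channel names must match the channel dimension")
  }
  structure(
    list(data = data, rt_ms = as.numeric(rt_ms), subject_id = subject_id,
         sfreq = sfreq, epoch_window = epoch_window,
         channels = channels, true_category = true_category),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz, epoch [%g, %g] ms\n",
              d[1], d[2], d[3], x$sfreq, x$epoch_window[1], x$epoch_window[2]))
  cat(sprintf("  subjects: %d, RT range: %.0f-%.0f ms\n",
              length(unique(x$subject_id)), min(x$rt_ms), max(x$rt_ms)))
  invisible(x)
}

# 1/f-amplitude background noise, one column per (channel, trial) series
pink_noise <- function(n_t, n_series, rms) {
  w <- matrix(stats::rnorm(n_t * n_series), n_t, n_series)
  W <- stats::mvfft(w)
  f <- c(0, pmin(seq_len(n_t - 1), n_t - seq_len(n_t - 1))) # symmetric freq index
  g <- c(0, 1 / sqrt(f[-1]))
  x <- Re(stats::mvfft(W * g, inverse = TRUE)) / n_t
  sdv <- sqrt(colMeans(x^2))
  sweep(x, 2, rms / sdv, `*`)
}

#' Generate synthetic preprocessed epoched EEG trials
#'
#' Each trial is 1/f background noise plus stimulus-locked oscillatory bursts
#' at the centre frequency of each analysis band. The per-channel burst
#' amplitude is the band's baseline amplitude times the `effect_spec` factor
#' for the trial's response category, so the generator plants a known
#' spatial-spectral ground truth. RTs are drawn from the four-component
#' mixture, truncated to its configured range (default 100-2500 ms). Bursts are
#' gated to the post-stimulus interval with a Hann envelope and carry a small
#' trial-to-trial phase jitter (sd 0.5 rad) so that trial averaging behaves
#' like evoked-response averaging.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param trials_per_subject Trials per subject (>= 1).
#' @param effect An [effect_spec()]; defaults to [default_effect_spec()].
#' @param seed Integer seed; the output is a deterministic function of it.
#' @param sfreq Sampling rate in Hz (default 500).
#' @param epoch_window Epoch span in ms (default -200 to 800).
#' @param montage Sensor montage; defaults to [default_montage()].
#' @return A [trial_set()] with `true_category` ground-truth labels.
#' @export
generate_trials <- function(n_subjects, trials_per_subject,
                            effect = default_effect_spec(), seed = 1L,
                            sfreq = 500, epoch_window = c(-200, 800),
                            montage = default_montage()) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 1)
  if (!inherits(effect, "effect_spec")) stop("`effect` must be an effect_spec")
  n_ch <- nrow(montage)
  n_t <- round(diff(epoch_window) / 1000 * sfreq)
  t_s <- (seq_len(n_t) - 1) / sfreq + epoch_window[1] / 1000
  post <- t_s >= 0
  env <- numeric(n_t)
  np <- sum(post)
  env[post] <- 0.5 - 0.5 * cos(2 * pi * seq_len(np) / (np + 1)) # Hann gate
  centre <- (effect$bands$lo + effect$bands$hi) / 2

  with_local_seed(seed, {
    n_total <- n_subjects * trials_per_subject
    rts <- sample_rts(n_total, effect$mixture, effect$rt_range, seed = NULL)
    rt <- rts$rt_ms
    category <- rts$category

    data <- array(0, dim = c(n_total, n_ch, n_t))
    # per-band amplitude factor lookup per category, rows = channels
    fac <- lapply(rt_categories_all, function(cat) {
      vapply(seq_len(nrow(effect$bands)), function(b) {
        amplitude_factor(effect, montage$channel, effect$bands$band[b], cat)
      }, numeric(n_ch))
    })
    names(fac) <- rt_categories_all

    for (s in seq_len(n_subjects)) {
      idx <- ((s - 1) * trials_per_subject + 1):(s * trials_per_subject)
      noise <- pink_noise(n_t, n_ch * trials_per_subject, effect$noise_rms)
      dim(noise) <- c(n_t, n_ch, trials_per_subject)
      for (j in seq_along(idx)) {
        tr <- t(noise[, , j]) # channels x time
        fcat <- fac[[category[idx[j]]]]
        for (b in seq_len(nrow(effect$bands))) {
          phase <- stats::rnorm(1, 0, 0.5)
          wave <- env * sin(2 * pi * centre[b] * t_s + phase) *
            effect$base_amp[[effect$bands$band[b]]]
          tr <- tr + outer(fcat[, b], wave)
        }
        data[idx[j], , ] <- tr
      }
    }

    trial_set(
      data, rt_ms = rt,
      subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), each = trials_per_subject),
      sfreq = sfreq, epoch_window = epoch_window,
      channels = montage$channel,
      true_category = factor(category, levels = rt_categories_all)
    )
  })
}

#' Write a trial set as an array container plus JSON sidecar
#'
#' The data array is written as a compressed serialized array
#' (`<prefix>_data.rds`); all metadata (RTs, subject ids, sampling rate,
#' epoch window, channel names, any labels) goes to a plain-JSON sidecar
#' (`<prefix>_meta.json`).
#'
#' @param ts A `trial_set`.
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_trial_set <- function(ts, prefix) {
  data_path <- paste0(prefix, "_data.rds")
  meta_path <- paste0(prefix, "_meta.json")
  saveRDS(ts$data, data_path, compress = "gzip")
  meta <- list(
    rt_ms = ts$rt_ms, subject_id = ts$subject_id, sfreq = ts$sfreq,
    epoch_window = ts$epoch_window, channels = ts$channels,
    true_category = if (!is.null(ts$true_category)) as.character(ts$true_category)
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(data_path, meta_path))
}

#' Read a trial set written by [write_trial_set()]
#' @param prefix Path prefix used when writing.
#' @return A `trial_set`.
#' @export
read_trial_set <- function(prefix) {
  data <- readRDS(paste0(prefix, "_data.rds"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  trial_set(data, meta$rt_ms, meta$subject_id, meta$sfreq,
            as.numeric(meta$epoch_window), meta$channels,
            if (!is.null(meta$true_category)) {
              factor(meta$true_category, levels = rt_categories_all)
            })
}
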