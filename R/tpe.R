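#' Hyperparameter space constructors
#'
#' Building blocks for [tpe_search()] spaces: continuous uniform,
#' log-uniform, quantized (integer) variants, and categorical choices.
#'
#' @param lo,hi Range bounds (inclusive; on the original scale for the
#'   log-uniform variants).
#' @param q Quantization step for the `q*` variants.
#' @param values Candidate values for `sp_choice`.
#' @return A parameter-distribution object used by [tpe_search()].
#' @name tpe_space
NULL

#' @rdname tpe_space
#' @export
sp_uniform <- function(lo, hi) {
  structure(list(kind = "uniform", lo = lo, hi = hi, log = FALSE, q = NULL),
            class = "tpe_param")
}
#' @rdname tpe_space
#' @export
sp_loguniform <- function(lo, hi) {
  stopifnot(lo > 0)
  structure(list(kind = "uniform", lo = log(lo), hi = log(hi), log = TRUE, q = NULL),
            class = "tpe_param")
}
#' @rdname tpe_space
#' @export
sp_quniform <- function(lo, hi, q = 1) {
  structure(list(kind = "uniform", lo = lo, hi = hi, log = FALSE, q = q),
            class = "tpe_param")
}
#' @rdname tpe_space
#' @export
sp_qloguniform <- function(lo, hi, q = 1) {
  stopifnot(lo > 0)
  structure(list(kind = "uniform", lo = log(lo), hi = log(hi), log = TRUE, q = q),
            class = "tpe_param")
}
#' @rdname tpe_space
#' @export
sp_choice <- function(values) {
  structure(list(kind = "choice", values = values), class = "tpe_param")
}

tpe_sample_prior <- function(p) {
  if (p$kind == "choice") return(sample(seq_along(p$values), 1))
  tpe_finalize(p, stats::runif(1, p$lo, p$hi))
}

# map an internal-scale draw to the user scale (exp + quantization)
tpe_finalize <- function(p, x) {
  if (p$log) x <- exp(x)
  if (!is.null(p$q)) x <- round(x / p$q) * p$q
  x
}

# internal-scale representation of an observed value
tpe_internal <- function(p, v) {
  if (p$kind == "choice") return(v) # stored as index
  if (p$log) log(v) else v
}

# Parzen log-density of `x` under observations `obs` (internal scale) mixed
# with a uniform prior component over [lo, hi]
parzen_bw <- function(obs, span) {
  n <- length(obs)
  s <- if (n > 1) stats::sd(obs) else 0
  max(s * (4 / (3 * n))^(1 / 5), span / 20, 1e-12)
}

parzen_logdens <- function(x, obs, lo, hi) {
  n <- length(obs)
  span <- hi - lo
  if (n == 0) return(rep(-log(span), length(x)))
  bw <- parzen_bw(obs, span)
  comp <- vapply(obs, function(m) stats::dnorm(x, m, bw), numeric(length(x)))
  if (length(x) == 1) comp <- matrix(comp, 1)
  dens <- (rowSums(comp) + 1 / span) / (n + 1) # +1 pseudo-count of prior
  log(dens)
}

parzen_draw <- function(n_draw, obs, lo, hi) {
  n <- length(obs)
  span <- hi - lo
  bw <- if (n > 0) parzen_bw(obs, span) else span
  out <- numeric(n_draw)
  for (i in seq_len(n_draw)) {
    if (n == 0 || stats::runif(1) < 1 / (n + 1)) {
      out[i] <- stats::runif(1, lo, hi)
    } else {
      out[i] <- stats::rnorm(1, sample(obs, 1), bw)
      out[i] <- min(max(out[i], lo), hi)
    }
  }
  out
}

choice_logprob <- function(x, obs, k) {
  counts <- tabulate(obs, k) + 1 # Laplace prior
  log(counts[x] / sum(counts))
}

#' Tree-structured Parzen estimator hyperparameter search
#'
#' Sequential model-based optimization: past trials are split at the
#' `gamma` quantile of the objective into "good" and "bad" sets; per
#' parameter, Parzen density estimators `l(x)` (good) and `g(x)` (bad) are
#' built, `n_candidates` draws are taken from `l`, and the candidate
#' maximizing `log l(x) - log g(x)` (expected-improvement surrogate) is
#' evaluated next. The first `n_startup` trials are drawn from the prior.
#'
#' @param space Named list of [tpe_space] parameter distributions.
#' @param objective Function taking a named list of parameter values and
#'   returning a scalar score to MAXIMIZE (e.g. validation accuracy).
#'   Trials whose objective errors score `-Inf` and are logged.
#' @param budget Total number of trials; documented default 73, matching
#'   the scale of the original model search.
#' @param gamma Quantile defining the "good" split.
#' @param n_candidates Candidate draws per proposal.
#' @param n_startup Random-sampling warmup trials.
#' @param seed Integer seed.
#' @return A list with `best` (named parameter list), `best_score`, and
#'   `trials` (data frame of parameter values and scores, in order).
#' @export
tpe_search <- function(space, objective, budget = 73, gamma = 0.25,
                       n_candidates = 20, n_startup = 5, seed = 1L) {
  stopifnot(budget >= 1, length(space) >= 1, !is.null(names(space)))
  obs <- vector("list", budget)
  scores <- numeric(budget)

  with_local_seed(seed, {
    for (t in seq_len(budget)) {
      if (t <= n_startup || t <= 2) {
        prop <- lapply(space, tpe_sample_prior)
      } else {
        done <- seq_len(t - 1)
        ok <- done[is.finite(scores[done])]
        if (length(ok) < 2) {
          prop <- lapply(space, tpe_sample_prior)
        } else {
          n_good <- max(1L, ceiling(gamma * length(ok)))
          ord <- ok[order(scores[ok], decreasing = TRUE)]
          good <- ord[seq_len(n_good)]
          bad <- setdiff(ok, good)
          prop <- list()
          for (nm in names(space)) {
            p <- space[[nm]]
            vg <- vapply(good, function(i) tpe_internal(p, obs[[i]][[nm]]), numeric(1))
            vb <- vapply(bad, function(i) tpe_internal(p, obs[[i]][[nm]]), numeric(1))
            if (p$kind == "choice") {
              k <- length(p$values)
              cand <- sample.int(k, n_candidates, replace = TRUE,
                                 prob = (tabulate(vg, k) + 1) / (length(vg) + k))
              ei <- choice_logprob(cand, vg, k) - choice_logprob(cand, vb, k)
            } else {
              cand <- parzen_draw(n_candidates, vg, p$lo, p$hi)
              ei <- parzen_logdens(cand, vg, p$lo, p$hi) -
                parzen_logdens(cand, vb, p$lo, p$hi)
            }
            pick <- which.max(ei)
            if (!length(pick)) { # degenerate densities: fall back to the prior
              prop[[nm]] <- tpe_sample_prior(p)
            } else {
              prop[[nm]] <- if (p$kind == "choice") cand[pick]
                            else tpe_finalize(p, cand[pick])
            }
          }
        }
      }
      # choices are carried internally as indices; objective sees values
      vals <- prop
      for (nm in names(space)) {
        if (space[[nm]]$kind == "choice") vals[[nm]] <- space[[nm]]$values[[prop[[nm]]]]
      }
      sc <- tryCatch(objective(vals), error = function(e) {
        warning(sprintf("trial %d failed: %s", t, conditionMessage(e)))
        -Inf
      })
      obs[[t]] <- prop
      scores[t] <- sc
    }
  })
  if (all(!is.finite(scores))) stop("all TPE trials failed")

  tr <- do.call(rbind, lapply(seq_len(budget), function(t) {
    row <- obs[[t]]
    for (nm in names(space)) {
      if (space[[nm]]$kind == "choice") {
        v <- space[[nm]]$values[[row[[nm]]]]
        row[[nm]] <- if (is.numeric(v)) v else as.character(v)
      }
    }
    as.data.frame(c(list(trial = t), row, list(score = scores[t])))
  }))
  bi <- which.max(scores)
  best <- obs[[bi]]
  for (nm in names(space)) {
    if (space[[nm]]$kind == "choice") best[[nm]] <- space[[nm]]$values[[best[[nm]]]]
  }
  list(best = best, best_score = scores[bi], trials = tr)
}

#' Default decoder search space
#'
#' Depth 2-4 blocks, per-block filters 16-256 (log-uniform, quantized),
#' FC width 64-1024, dropout 0.2-0.6, learning rate 1e-4 to 1e-1
#' (log-uniform), optimizer among Adagrad/Adam/SGD.
#'
#' @return A named list of [tpe_space] distributions.
#' @export
decoder_search_space <- function() {
  list(
    n_blocks = sp_choice(2:4),
    filters1 = sp_qloguniform(16, 256),
    filters2 = sp_qloguniform(16, 256),
    filters3 = sp_qloguniform(16, 256),
    filters4 = sp_qloguniform(16, 256),
    fc1 = sp_quniform(64, 1024),
    dropout = sp_uniform(0.2, 0.6),
    learning_rate = sp_loguniform(1e-4, 1e-1),
    optimizer = sp_choice(c("adagrad", "adam", "sgd"))
  )
}

#' Translate a search-space sample into a decoder configuration
#'
#' @param params Named list as produced by [tpe_search()] over
#'   [decoder_search_space()].
#' @param ... Further arguments (epochs, seed, ...) passed to
#'   [decoder_config()].
#' @return A [decoder_config()].
#' @export
params_to_config <- function(params, ...) {
  nb <- as.integer(params$n_blocks)
  filt <- as.integer(unlist(params[paste0("filters", seq_len(nb))]))
  decoder_config(conv_filters = filt, fc_units = as.integer(params$fc1),
                 dropout = params$dropout, optimizer = params$optimizer,
                 learning_rate = params$learning_rate, ...)
}
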