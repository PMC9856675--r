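#' Cluster response times with BIC-selected Gaussian mixtures
#'
#' Fits Gaussian mixture models to the (one-dimensional) response-time
#' distribution for every combination of component count and covariance
#' parameterization, and returns the model with the lowest Bayesian
#' Information Criterion, `BIC = p * log(n) - 2 * logLik`. In one dimension
#' the spherical, diagonal and full parameterizations coincide (one variance
#' per component) while `tied` shares a single variance; all four labels are
#' scored so the selection grid mirrors the conventional multivariate sweep.
#' Ties are broken toward fewer components, then by covariance order
#' spherical < diagonal < tied < full.
#'
#' @param rt_ms Response times in ms (>= 10 values, not all identical).
#' @param component_range Candidate component counts, subset of 1..10.
#' @param covariance_types Candidate covariance labels.
#' @param restarts Random EM initializations per candidate; the best
#'   log-likelihood fit is kept.
#' @param seed Integer seed controlling the EM initializations.
#' @return An object of class `rt_cluster_model` with fields `n_components`,
#'   `covariance_type`, `means`, `variances`, `weights`, `bic`, `loglik`,
#'   `category_map`, `grand_median` and the full scored `grid`.
#' @export
fit_gmm_bic <- function(rt_ms, component_range = 1:8,
                        covariance_types = c("spherical", "diagonal", "tied", "full"),
                        restarts = 10, seed = 1L) {
  if (length(rt_ms) < 10) stop("need at least 10 response times")
  if (stats::var(rt_ms) == 0) stop("degenerate input: all response times identical")
  cov_order <- c("spherical", "diagonal", "tied", "full")
  covariance_types <- intersect(cov_order, covariance_types)
  if (!length(covariance_types)) stop("no valid covariance type")
  if (any(component_range < 1 | component_range > 10)) {
    stop("component_range must lie within 1..10")
  }
  n <- length(rt_ms)

  variant_of <- function(ct) if (ct == "tied") "tied" else "component"
  fits <- list()
  grid <- data.frame()
  with_local_seed(seed, {
    for (k in sort(component_range)) {
      for (variant in unique(vapply(covariance_types, variant_of, character(1)))) {
        fit <- gmm1d_fit(rt_ms, k, variant, restarts = restarts)
        fits[[paste(k, variant)]] <- fit
      }
      for (ct in covariance_types) {
        fit <- fits[[paste(k, variant_of(ct))]]
        grid <- rbind(grid, data.frame(
          n_components = k, covariance_type = ct,
          loglik = fit$loglik,
          n_params = gmm1d_n_params(k, variant_of(ct)),
          bic = gmm1d_bic(fit, n)
        ))
      }
    }
  })
  grid$cov_rank <- match(grid$covariance_type, cov_order)
  ord <- order(grid$bic, grid$n_components, grid$cov_rank)
  sel <- grid[ord[1], ]
  fit <- fits[[paste(sel$n_components, variant_of(sel$covariance_type))]]

  model <- structure(
    list(
      n_components = sel$n_components,
      covariance_type = sel$covariance_type,
      means = fit$means, variances = fit$variances, weights = fit$weights,
      loglik = fit$loglik, bic = sel$bic,
      grand_median = stats::median(rt_ms),
      grid = grid[order(grid$n_components, grid$cov_rank), setdiff(names(grid), "cov_rank")]
    ),
    class = "rt_cluster_model"
  )
  # a 1-component model has no category structure; the map stays NULL and
  # assign_categories() refuses it
  model$category_map <- tryCatch(map_components(model), error = function(e) NULL)
  model
}

# Component -> category map. With >= 4 components the outlier is the
# smallest-weight component among those whose mean exceeds the grand median
# of the fitting data (the low-probability slow tail); remaining components
# are ordered by mean into fast / medium(s) / slow.
map_components <- function(model) {
  k <- model$n_components
  outlier <- integer(0)
  if (k >= 4) {
    cand <- which(model$means > model$grand_median)
    if (!length(cand)) cand <- which.max(model$means)
    outlier <- cand[which.min(model$weights[cand])]
  }
  rest <- setdiff(seq_len(k), outlier)
  if (length(rest) < 2) stop("model has fewer than 2 non-outlier components")
  ord <- rest[order(model$means[rest])]
  lab <- rep("medium", length(ord))
  lab[1] <- "fast"
  lab[length(ord)] <- "slow"
  map <- character(k)
  map[ord] <- lab
  if (length(outlier)) map[outlier] <- "outlier"
  map
}

#' @export
print.rt_cluster_model <- function(x, ...) {
  cat(sprintf("<rt_cluster_model> %d components (%s), BIC = %.1f\n",
              x$n_components, x$covariance_type, x$bic))
  df <- data.frame(category = x$category_map %||% rep("?", x$n_components),
                   mean = round(x$means, 1),
                   sd = round(sqrt(x$variances), 1), weight = round(x$weights, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Hard category assignment of response times
#'
#' Maximum-a-posteriori assignment of each RT to a mixture component, then
#' mapping through the model's component-to-category map. Trials labeled
#' `outlier` are meant to be excluded before augmentation.
#'
#' @param model An [fit_gmm_bic()] model.
#' @param rt_ms Response times in ms.
#' @return A factor with levels fast/medium/slow/outlier.
#' @export
assign_categories <- function(model, rt_ms) {
  stopifnot(inherits(model, "rt_cluster_model"))
  map <- model$category_map %||% map_components(model)
  if (sum(map != "outlier") < 2) stop("model has fewer than 2 non-outlier components")
  resp <- gmm1d_responsibilities(model$means, model$variances, model$weights, rt_ms)
  comp <- max.col(resp, ties.method = "first")
  factor(map[comp], levels = rt_categories_all)
}

#' Serialize an RT cluster model to JSON
#' @param model An `rt_cluster_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rt_cluster_model <- function(model, path) {
  jsonlite::write_json(
    list(n_components = model$n_components, covariance_type = model$covariance_type,
         means = model$means, variances = model$variances, weights = model$weights,
         loglik = model$loglik, bic = model$bic, grand_median = model$grand_median,
         category_map = model$category_map),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
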