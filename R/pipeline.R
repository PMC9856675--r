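#' Pipeline configuration
#'
#' Bundles every stage's parameters with a single global seed. Stage seeds
#' are derived as `seed + stage index` so each stage is independently
#' reproducible.
#'
#' @param out_dir Run directory for artifacts and manifests.
#' @param seed Global integer seed.
#' @param n_subjects,trials_per_subject Synthetic cohort size.
#' @param effect Planted ground truth, an [effect_spec()].
#' @param sfreq Sampling rate (Hz).
#' @param grid Topomap side length in pixels.
#' @param component_range,gmm_restarts RT clustering grid.
#' @param bootstrap A [bootstrap_params()] (its `seed` is overridden by the
#'   derived stage seed).
#' @param filter_k,filter_lo,filter_hi Eigenspace filter settings.
#' @param decoder A [decoder_config()] (seed likewise overridden).
#' @param tpe Optional list with `space` and `budget` to run a
#'   hyperparameter search before the final fit; `NULL` skips the search.
#' @param test_fraction Held-out fraction for evaluation and saliency.
#' @param random_intercept Random-effects structure for the ANOVA stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_subjects = 4,
                            trials_per_subject = 120,
                            effect = default_effect_spec(), sfreq = 500,
                            grid = 32L, component_range = 1:8,
                            gmm_restarts = 10,
                            bootstrap = bootstrap_params(r = 15, n = 40),
                            filter_k = 150, filter_lo = 25, filter_hi = 75,
                            decoder = decoder_config(
                              conv_filters = c(8, 16), kernel = 5,
                              fc_units = 32, dropout = 0.3,
                              learning_rate = 0.02, epochs = 12),
                            tpe = NULL, test_fraction = 0.2,
                            random_intercept = "sample") {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), n_subjects = n_subjects,
         trials_per_subject = trials_per_subject, effect = effect,
         sfreq = sfreq, grid = as.integer(grid),
         component_range = component_range, gmm_restarts = gmm_restarts,
         bootstrap = bootstrap, filter_k = filter_k, filter_lo = filter_lo,
         filter_hi = filter_hi, decoder = decoder, tpe = tpe,
         test_fraction = test_fraction, random_intercept = random_intercept),
    class = "pipeline_config"
  )
}

pipeline_stages <- c("synth", "cluster", "augment", "filter", "topomap",
                     "train", "saliency", "stats")

write_manifest <- function(out_dir, stage, params, counts) {
  path <- file.path(out_dir, sprintf("manifest_%d_%s.json",
                                     match(stage, pipeline_stages), stage))
  jsonlite::write_json(list(stage = stage, params = params, counts = counts),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

pl_log <- function(...) message(sprintf(...))

#' Run the decoding pipeline end to end
#'
#' Executes synthesize -> cluster -> augment -> filter -> topomap -> train
#' (optionally preceded by a TPE search) -> saliency -> stats, persisting
#' each stage's artifact plus a JSON manifest (parameters, derived seed,
#' input/output counts) in the run directory. `stages` can name a
#' contiguous subset; stages whose inputs are not in memory reload them from
#' the persisted artifacts of an earlier run in the same directory.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run (default all, in order).
#' @return Invisibly, a list with the in-memory artifacts (`trials`,
#'   `labels`, `model`, `augmented`, `filtered`, `topomaps`, `decoder`,
#'   `metrics`, `activations`, `anova`, `ranking`) and `out_dir`.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  seed_of <- function(stage) config$seed + match(stage, pipeline_stages)
  need <- function(name, loader) {
    if (!exists(name, st)) {
      v <- tryCatch(loader(), error = function(e) {
        stop(sprintf("missing upstream artifact '%s': %s", name,
                     conditionMessage(e)))
      })
      assign(name, v, st)
    }
    get(name, st)
  }

  for (stage in pipeline_stages[pipeline_stages %in% stages]) {
    pl_log("[%s] starting", stage)
    switch(stage,
      synth = {
        trials <- generate_trials(config$n_subjects, config$trials_per_subject,
                                  config$effect, seed = seed_of("synth"),
                                  sfreq = config$sfreq)
        assign("trials", trials, st)
        write_trial_set(trials, file.path(config$out_dir, "trials"))
        write_montage(default_montage(), file.path(config$out_dir, "montage.tsv"))
        write_manifest(config$out_dir, "synth",
                       list(n_subjects = config$n_subjects,
                            trials_per_subject = config$trials_per_subject,
                            sfreq = config$sfreq, seed = seed_of("synth")),
                       list(trials = dim(trials$data)[1]))
      },
      cluster = {
        trials <- need("trials", function()
          read_trial_set(file.path(config$out_dir, "trials")))
        model <- fit_gmm_bic(trials$rt_ms, config$component_range,
                             restarts = config$gmm_restarts,
                             seed = seed_of("cluster"))
        labels <- assign_categories(model, trials$rt_ms)
        assign("model", model, st); assign("labels", labels, st)
        write_rt_cluster_model(model, file.path(config$out_dir, "rt_model.json"))
        jsonlite::write_json(as.character(labels),
                             file.path(config$out_dir, "labels.json"))
        write_manifest(config$out_dir, "cluster",
                       list(component_range = range(config$component_range),
                            seed = seed_of("cluster"),
                            n_components = model$n_components,
                            covariance_type = model$covariance_type),
                       as.list(table(labels)))
      },
      augment = {
        trials <- need("trials", function()
          read_trial_set(file.path(config$out_dir, "trials")))
        labels <- need("labels", function()
          factor(unlist(jsonlite::read_json(file.path(config$out_dir, "labels.json"))),
                 levels = rt_categories_all))
        bp <- config$bootstrap
        bp$seed <- seed_of("augment")
        augmented <- bootstrap_erps(trials, labels, bp)
        assign("augmented", augmented, st)
        saveRDS(augmented, file.path(config$out_dir, "augmented.rds"))
        write_manifest(config$out_dir, "augment",
                       list(r = bp$r, alpha = as.list(bp$alpha), n = bp$n,
                            n_alpha = bp$n_alpha, seed = bp$seed),
                       c(list(trials_in = sum(labels != "outlier")),
                         as.list(table(augmented$category))))
      },
      filter = {
        trials <- need("trials", function()
          read_trial_set(file.path(config$out_dir, "trials")))
        augmented <- need("augmented", function()
          readRDS(file.path(config$out_dir, "augmented.rds")))
        filtered <- eigenspace_filter(trials, augmented, k = config$filter_k,
                                      lo = config$filter_lo, hi = config$filter_hi)
        assign("filtered", filtered, st)
        saveRDS(filtered, file.path(config$out_dir, "filtered.rds"))
        write_augmentation_provenance(filtered,
                                      file.path(config$out_dir, "provenance.csv"))
        write_manifest(config$out_dir, "filter",
                       list(k = config$filter_k, lo = config$filter_lo,
                            hi = config$filter_hi,
                            k_used = attr(filtered, "k_used")),
                       list(augmented_in = dim(augmented$erps)[1],
                            retained = dim(filtered$erps)[1]))
      },
      topomap = {
        filtered <- need("filtered", function()
          readRDS(file.path(config$out_dir, "filtered.rds")))
        topomaps <- topomaps_from_erps(filtered, grid = config$grid)
        assign("topomaps", topomaps, st)
        saveRDS(topomaps, file.path(config$out_dir, "topomaps.rds"))
        utils::write.csv(data.frame(sample = seq_along(topomaps$category),
                                    category = as.character(topomaps$category),
                                    subject = topomaps$subject_id),
                         file.path(config$out_dir, "topomap_labels.csv"),
                         row.names = FALSE)
        write_manifest(config$out_dir, "topomap",
                       list(grid = config$grid),
                       list(filtered_in = dim(filtered$erps)[1],
                            images = dim(topomaps$images)[1]))
      },
      train = {
        topomaps <- need("topomaps", function()
          readRDS(file.path(config$out_dir, "topomaps.rds")))
        seed <- seed_of("train")
        n <- dim(topomaps$images)[1]
        split <- with_local_seed(seed, {
          te <- unlist(lapply(split(seq_len(n), topomaps$category), function(ix) {
            sample(ix, max(1L, round(length(ix) * config$test_fraction)))
          }), use.names = FALSE)
          list(test = sort(te), train = setdiff(seq_len(n), te))
        })
        cfg <- config$decoder
        cfg$seed <- seed
        xtr <- topomaps$images[split$train, , , , drop = FALSE]
        ytr <- droplevels(topomaps$category[split$train])
        if (!is.null(config$tpe)) {
          sp <- config$tpe$space %||% decoder_search_space()
          res <- tpe_search(sp, function(p) {
            c2 <- params_to_config(p, epochs = cfg$epochs, kernel = cfg$kernel,
                                   seed = seed)
            d <- build_decoder(c2, dim(xtr)[2:4])
            d <- train_decoder(d, xtr, ytr)
            max(d$history$val_acc)
          }, budget = config$tpe$budget %||% 73, seed = seed)
          utils::write.csv(res$trials, file.path(config$out_dir, "tpe_trials.csv"),
                           row.names = FALSE)
          cfg <- params_to_config(res$best, epochs = cfg$epochs,
                                  kernel = cfg$kernel, seed = seed)
        }
        decoder <- build_decoder(cfg, dim(xtr)[2:4])
        decoder <- train_decoder(decoder, xtr, ytr)
        metrics <- evaluate_decoder(decoder,
                                    topomaps$images[split$test, , , , drop = FALSE],
                                    topomaps$category[split$test])
        assign("decoder", decoder, st); assign("split", split, st)
        assign("metrics", metrics, st)
        saveRDS(decoder, file.path(config$out_dir, "decoder.rds"))
        saveRDS(split, file.path(config$out_dir, "split.rds"))
        jsonlite::write_json(
          list(accuracy = metrics$accuracy, macro = as.list(metrics$macro),
               weighted = as.list(metrics$weighted),
               average_precision = as.list(metrics$average_precision),
               per_class = metrics$per_class),
          file.path(config$out_dir, "metrics.json"),
          auto_unbox = TRUE, digits = NA, dataframe = "rows")
        write_manifest(config$out_dir, "train",
                       list(optimizer = cfg$optimizer, lr = cfg$learning_rate,
                            epochs = cfg$epochs, seed = seed,
                            tpe = !is.null(config$tpe)),
                       list(train = length(split$train), test = length(split$test),
                            accuracy = metrics$accuracy))
      },
      saliency = {
        topomaps <- need("topomaps", function()
          readRDS(file.path(config$out_dir, "topomaps.rds")))
        decoder <- need("decoder", function()
          readRDS(file.path(config$out_dir, "decoder.rds")))
        split <- need("split", function()
          readRDS(file.path(config$out_dir, "split.rds")))
        maps <- lapply(split$test, function(i) {
          guided_gradcam(decoder, topomaps$images[i, , , ])
        })
        acts <- extract_activations(maps, topomaps$electrode_px,
                                    bands = topomaps$bands,
                                    subject_id = topomaps$subject_id[split$test])
        assign("activations", acts, st)
        utils::write.csv(acts, file.path(config$out_dir, "activations.csv"),
                         row.names = FALSE)
        write_manifest(config$out_dir, "saliency",
                       list(target = "predicted"),
                       list(samples = length(maps), rows = nrow(acts)))
      },
      stats = {
        acts <- need("activations", function() {
          a <- utils::read.csv(file.path(config$out_dir, "activations.csv"),
                               stringsAsFactors = FALSE)
          class(a) <- c("activation_table", "data.frame"); a
        })
        anv <- factorial_anova(acts, config$random_intercept)
        rnk <- rank_activations(acts, seed = seed_of("stats"))
        assign("anova", anv, st); assign("ranking", rnk, st)
        write_report_csv(anv, file.path(config$out_dir, "anova.csv"))
        write_report_csv(rnk, file.path(config$out_dir, "ranking.csv"))
        jsonlite::write_json(list(anova = format_anova(anv)),
                             file.path(config$out_dir, "stats_summary.json"),
                             auto_unbox = TRUE)
        write_manifest(config$out_dir, "stats",
                       list(random_intercept = config$random_intercept,
                            seed = seed_of("stats")),
                       list(rows = nrow(acts),
                            three_way_p = anv$p[anv$effect == "electrode:band:category"]))
      }
    )
    pl_log("[%s] done", stage)
  }
  out <- as.list(st)
  out$out_dir <- config$out_dir
  invisible(out)
}
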