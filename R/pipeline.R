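#' Pipeline configuration
#'
#' Declarative configuration of the end-to-end workflow: which stages to
#' run (`simulate`, `preprocess`, `augment`, `extrapolate`, `classify`,
#' `evaluate`), their parameters, a global seed and an output directory.
#' A configuration can also be loaded from YAML or JSON with
#' [read_pipeline_config()].
#'
#' @param stages character vector of stage names, in order.
#' @param dataset_id protocol to simulate (see [sensing_protocol()]).
#' @param n_normal_per_class,n_anomaly simulation sizes.
#' @param target_length working segment length after standardization.
#' @param scheme labeling scheme, `"C1"` or `"C2"`.
#' @param input_mode classifier input representation.
#' @param arch classifier architecture.
#' @param total_per_class augmentation target per class.
#' @param gen_epochs,clf_epochs training epochs for the generative and
#'   classification stages.
#' @param extrap_variant forecaster variant for the extrapolation stage.
#' @param seed global seed.
#' @param out_dir output directory for artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(stages = c("simulate", "preprocess"),
                            dataset_id = "oestradiol31",
                            n_normal_per_class = 4L,
                            n_anomaly = 0L,
                            target_length = 300L,
                            scheme = "C1",
                            input_mode = "spectrogram",
                            arch = "ConvGRU",
                            total_per_class = 12L,
                            gen_epochs = 5L,
                            clf_epochs = 5L,
                            extrap_variant = "GRU",
                            seed = 1L,
                            out_dir = tempfile("apta_run_")) {
  known <- c("simulate", "preprocess", "augment", "extrapolate", "classify", "evaluate")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  structure(list(stages = stages, dataset_id = dataset_id,
                 n_normal_per_class = as.integer(n_normal_per_class),
                 n_anomaly = as.integer(n_anomaly),
                 target_length = as.integer(target_length),
                 scheme = scheme, input_mode = input_mode, arch = arch,
                 total_per_class = as.integer(total_per_class),
                 gen_epochs = as.integer(gen_epochs),
                 clf_epochs = as.integer(clf_epochs),
                 extrap_variant = extrap_variant,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path a YAML (`.yml`/`.yaml`) or JSON config file.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

stage_log <- function(dir, stage, seed, info = list()) {
  line <- jsonlite::toJSON(c(list(stage = stage, seed = seed,
                                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                             info), auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = file.path(dir, "pipeline.log.jsonl"), append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: simulation of sensor records,
#' preprocessing into labeled segments and spectrograms, CVAE
#' augmentation, optional recurrent extrapolation, classifier training and
#' evaluation. Every stage writes its artifacts (CSV/JSON) under
#' `config$out_dir`, appends a machine-readable provenance line
#' (stage, seed, sizes) to `pipeline.log.jsonl`, and later stages abort
#' with the name of the missing stage if a dependency has not run.
#'
#' @param config a [pipeline_config()].
#' @return the output directory path, invisibly; artifacts and a
#'   `metrics.json` (when `evaluate` ran) live inside it.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  for (stage in config$stages) {
    switch(stage,
      simulate = {
        state$dataset <- generate_dataset(
          sensing_protocol(config$dataset_id),
          n_normal_per_class = config$n_normal_per_class,
          n_anomaly = config$n_anomaly, seed = config$seed
        )
        write_signal_csv(state$dataset$signal[[1]],
                         file.path(config$out_dir, "example_signal.csv"))
        stage_log(config$out_dir, stage, config$seed,
                  list(n_signals = nrow(state$dataset)))
      },
      preprocess = {
        if (is.null(state$dataset)) abort("stage dependency unmet: simulate")
        segs <- segmentize_dataset(state$dataset)
        segs <- standardize_segments(segs, config$target_length)
        segs$label <- assign_labels(segs, config$scheme)
        segs <- add_spectrograms(segs)
        state$segments <- segs
        write_segments_csv(dplyr::select(segs, -"spectrogram"),
                           file.path(config$out_dir, "segments.csv"))
        stage_log(config$out_dir, stage, config$seed,
                  list(n_segments = nrow(segs),
                       spectrogram_dim = dim(segs$spectrogram[[1]])))
      },
      augment = {
        if (is.null(state$segments)) abort("stage dependency unmet: preprocess")
        norm <- state$segments[!state$segments$is_anomaly, ]
        gspec <- generative_model_spec("cvae_normal",
                                       input_length = config$target_length,
                                       n_classes = max(norm$label))
        gen <- train_generator(gspec, norm, labels = norm$label,
                               config = gen_train_config(epochs = config$gen_epochs),
                               seed = config$seed)
        aug <- augment_to_total(dplyr::select(norm, -"spectrogram"), norm$label,
                                gen, total_per_class = config$total_per_class,
                                seed = config$seed)
        aug <- add_spectrograms(aug)
        state$generator <- gen
        state$segments_augmented <- aug
        stage_log(config$out_dir, stage, config$seed,
                  list(n_after = nrow(aug),
                       val_recon = glance(gen)$final_val_recon))
      },
      extrapolate = {
        if (is.null(state$segments)) abort("stage dependency unmet: preprocess")
        segs <- state$segments_augmented %||% state$segments
        series <- do.call(rbind, segs$values)
        fc <- build_forecaster(forecast_net_spec(config$extrap_variant,
                                                 hidden_units = 32L),
                               seed = config$seed)
        ex <- extrapolate_segments(fc, series,
                                   extrap_config(L = 500L, epochs_first = 3L,
                                                 epochs_update = 1L),
                                   seed = config$seed)
        segs$values <- lapply(seq_len(nrow(ex$series)), function(i) ex$series[i, ])
        segs$n <- 500L
        segs$extrapolated <- TRUE
        segs <- add_spectrograms(segs)
        state$segments_augmented <- segs
        stage_log(config$out_dir, stage, config$seed,
                  list(n_iterations = ex$n_iterations))
      },
      classify = {
        segs <- state$segments_augmented %||% state$segments
        if (is.null(segs)) abort("stage dependency unmet: preprocess")
        ls <- length(segs$values[[1]])
        m <- max(segs$label)
        spec <- classifier_spec(config$arch, config$input_mode,
                                segment_length = ls, n_classes = m)
        x <- classifier_inputs(segs, config$input_mode)
        grp <- stratified_assign(segs$label, c(0.8, 0.2), config$seed)
        mod <- build_classifier(spec, seed = config$seed)
        mod <- fit_classifier(mod, subset_inputs(x, grp == 1L), segs$label[grp == 1L],
                              epochs = config$clf_epochs, seed = config$seed)
        state$classifier <- mod
        state$test <- list(x = subset_inputs(x, grp == 2L), y = segs$label[grp == 2L])
        stage_log(config$out_dir, stage, config$seed,
                  list(arch = config$arch, n_train = sum(grp == 1L)))
      },
      evaluate = {
        if (is.null(state$classifier)) abort("stage dependency unmet: classify")
        pr <- predict(state$classifier, state$test$x)
        rep <- confusion_and_metrics(state$test$y, pr$.pred_class,
                                     state$classifier$spec$n_classes)
        state$metrics <- rep
        jsonlite::write_json(
          list(accuracy = rep$accuracy, macro_f1 = rep$macro_f1,
               confusion = rep$confusion, seed = config$seed),
          file.path(config$out_dir, "metrics.json"),
          auto_unbox = TRUE, digits = NA
        )
        stage_log(config$out_dir, stage, config$seed,
                  list(accuracy = rep$accuracy))
      }
    )
  }
  attr(config$out_dir, "state") <- state
  invisible(config$out_dir)
}

subset_inputs <- function(x, keep) {
  if (is.matrix(x)) return(x[keep, , drop = FALSE])
  d <- dim(x)
  out <- x[keep, , , drop = FALSE]
  dim(out) <- c(sum(keep), d[2], d[3])
  out
}
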