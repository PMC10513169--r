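#' Configuration of the complete tracking pipeline
#'
#' One serialized configuration fully determines every stage: dataset
#' generation, network training, tracking options (region scoring and
#' connectivity) and evaluation options. A single global seed fans out to
#' per-stage seeds by fixed offsets ([derive_seed()]) so stages can be
#' re-run independently yet reproducibly.
#'
#' @param dataset A [dataset_config()].
#' @param training A [training_config()].
#' @param tracking List with `scoring` (`"mean"`/`"peak"`) and
#'   `connectivity` (4/8).
#' @param evaluation List with `n_subjects`, `dynamics_per_subject`,
#'   `negative_fraction`, `fn_if_missed`, `sd_type`.
#' @param global_seed Integer master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = dataset_config(),
                            training = training_config(),
                            tracking = list(scoring = "mean",
                                            connectivity = 8L),
                            evaluation = list(n_subjects = 4L,
                                              dynamics_per_subject = 15L,
                                              negative_fraction = 0.3,
                                              fn_if_missed = FALSE,
                                              sd_type = "population"),
                            global_seed = 1L) {
  dataset$rng_seed <- derive_seed(global_seed, 1L)
  training$rng_seed <- derive_seed(global_seed, 2L)
  structure(list(dataset = dataset, training = training,
                 tracking = tracking, evaluation = evaluation,
                 global_seed = as.integer(global_seed)),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_pipeline_config(write_pipeline_config(x))`
#' reconstructs an identical configuration.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (is.list(x)) unclass(x) else x
  }), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("dataset", "training", "tracking", "evaluation", "global_seed")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste("Malformed pipeline config; missing keys:",
                paste(missing, collapse = ", ")))
  }
  cfg <- pipeline_config(
    dataset = do.call(dataset_config, raw$dataset),
    training = do.call(training_config, raw$training),
    tracking = raw$tracking, evaluation = raw$evaluation,
    global_seed = raw$global_seed)
  # preserve explicit per-stage seeds from the file
  cfg$dataset$rng_seed <- as.integer(raw$dataset$rng_seed)
  cfg$training$rng_seed <- as.integer(raw$training$rng_seed)
  cfg
}

write_provenance <- function(dir, config, stage) {
  tmp <- tempfile(fileext = ".yaml")
  write_pipeline_config(config, tmp)
  jsonlite::write_json(
    list(stage = stage, global_seed = config$global_seed,
         config_md5 = unname(tools::md5sum(tmp)),
         package_version = as.character(utils::packageVersion("cathtrack")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, "provenance.json"), auto_unbox = TRUE)
  unlink(tmp)
}

#' Run the tracking pipeline end to end
#'
#' Executes the requested stages in order — `generate` (semi-artificial
#' dataset plus held-out dynamics), `train`, `track`, `evaluate` — writing
#' each stage's artifacts and a provenance record under `out_dir`. Re-running
#' with an identical configuration reproduces identical generated data and
#' evaluation outputs. A stage whose prerequisite artifacts are missing
#' fails with an error naming the stage to run first.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("generate", "train", "track", "evaluate")`.
#' @param out_dir Artifact directory.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with whichever of `dataset`, `dynamics`,
#'   `model`, `tips`, `report` the run produced or loaded.
#' @export
run_pipeline <- function(config, stages = c("generate", "train", "track",
                                            "evaluate"),
                         out_dir = "cathtrack_run", verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  res <- list()
  ddir <- file.path(out_dir, "data")
  mdir <- file.path(out_dir, "model")
  tips_path <- file.path(out_dir, "tips.csv")
  dyn_path <- file.path(out_dir, "dynamics.rds")

  if ("generate" %in% stages) {
    say("generate: building semi-artificial dataset")
    res$dataset <- build_dataset(config$dataset)
    write_dataset(res$dataset, ddir)
    ev <- config$evaluation
    res$dynamics <- build_dynamics(
      n_subjects = ev$n_subjects,
      dynamics_per_subject = ev$dynamics_per_subject,
      negative_fraction = ev$negative_fraction,
      image_shape = config$dataset$image_shape,
      rng_seed = derive_seed(config$global_seed, 3L))
    saveRDS(res$dynamics, dyn_path)
    write_provenance(ddir, config, "generate")
  }

  if ("train" %in% stages) {
    if (is.null(res$dataset)) {
      if (!file.exists(file.path(ddir, "manifest.csv"))) {
        abort("Training requires generated data; run the 'generate' stage first.")
      }
      res$dataset <- read_dataset(ddir)
    }
    say("train: %d frames, %d epochs", length(res$dataset$train),
        config$training$n_epochs)
    res$model <- train(res$dataset$train, res$dataset$val, config$training,
                       verbose = verbose)
    save_model(res$model, mdir)
    write_provenance(mdir, config, "train")
  }

  if ("track" %in% stages) {
    if (is.null(res$model)) {
      if (!file.exists(file.path(mdir, "model.rds"))) {
        abort("Tracking requires a trained model; run the 'train' stage first.")
      }
      res$model <- load_model(mdir)
    }
    if (is.null(res$dynamics)) {
      if (!file.exists(dyn_path)) {
        abort("Tracking requires dynamics; run the 'generate' stage first.")
      }
      res$dynamics <- readRDS(dyn_path)
    }
    say("track: %d dynamics", length(res$dynamics))
    res$tips <- track_sequence(res$dynamics, res$model,
                               connectivity = config$tracking$connectivity,
                               scoring = config$tracking$scoring)
    write.csv(res$tips, tips_path, row.names = FALSE)
    write_provenance(out_dir, config, "track")
  }

  if ("evaluate" %in% stages) {
    if (is.null(res$model)) {
      if (!file.exists(file.path(mdir, "model.rds"))) {
        abort("Evaluation requires a trained model; run the 'train' stage first.")
      }
      res$model <- load_model(mdir)
    }
    if (is.null(res$dynamics)) {
      if (!file.exists(dyn_path)) {
        abort("Evaluation requires dynamics; run the 'generate' stage first.")
      }
      res$dynamics <- readRDS(dyn_path)
    }
    say("evaluate: %d dynamics", length(res$dynamics))
    res$report <- evaluate_dynamics(res$dynamics, res$model,
                                    connectivity = config$tracking$connectivity,
                                    scoring = config$tracking$scoring)
    out <- list(per_patient = res$report$per_patient,
                summary = res$report$summary,
                counts = res$report$counts)
    jsonlite::write_json(out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write.csv(res$report$per_patient, file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
    write_provenance(out_dir, config, "evaluate")
  }
  invisible(res)
}
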