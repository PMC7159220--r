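# Orchestration: configuration, metadata IO, and the end-to-end pipeline
# (synthesize -> detect -> crop -> split -> train -> evaluate -> explain).

metadata_required_cols <- c("image_path", "animal_id", "sex", "treatment",
                            "time_label", "binary_label")

#' Read a metadata table
#'
#' Validates the declared column schema; unknown columns are preserved.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(metadata_required_cols, names(df))
  if (length(missing))
    stop("metadata missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Write a metadata table
#' @param table Data frame with the metadata schema.
#' @param path Output CSV path.
#' @export
write_metadata <- function(table, path) {
  missing <- setdiff(metadata_required_cols, names(table))
  if (length(missing))
    stop("metadata missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

pipeline_config_defaults <- function() {
  list(out_dir = "grimscan_run",
       seed = 1,
       stages = list(synthesize = TRUE, detect = TRUE, train = TRUE,
                     evaluate = TRUE, explain = FALSE),
       synth = list(animals = c(KXN = 8), images_per_group = 4,
                    times = list(KXN = c("baseline", "30min")),
                    margin = 1.0, image_size = c(96, 96)),
       detect = list(margin_frac = 0.1, n_train = 40),
       train = list(arch = "own_cnn", input_size = 64, epochs = 50,
                    batch_size = 100),
       evaluate = list(k = 4, average_by = c("animal_id", "time_label")),
       explain = list(n_images = 2, mode = "side_by_side"))
}

#' Load a pipeline configuration
#'
#' Reads a YAML file and merges it over the defaults; unknown top-level or
#' stage keys are rejected.
#'
#' @param path YAML config path, or `NULL` for pure defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- pipeline_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        badk <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(badk))
          stop("unknown config key(s) under '", k, "': ",
               paste(badk, collapse = ", "), call. = FALSE)
        cfg[[k]] <- modifyList(cfg[[k]], user[[k]])
      } else cfg[[k]] <- user[[k]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order on a synthetic dataset, writing
#' per-stage artifacts and a manifest (stage list, seeds, counts) to the
#' run directory. A failing stage aborts the run with the stage named.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run `manifest` and key results
#'   (`metrics`, `detection`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message("[", name, "] ", paste(names(list(...)), unlist(list(...)),
                                   sep = "=", collapse = " "))
  }
  results <- list()

  sy <- config$synth
  ds <- generate_dataset(
    synth_config(animals = unlist(sy$animals),
                 times = sy$times, images_per_group = sy$images_per_group,
                 margin = sy$margin,
                 scene = scene_params(image_size = sy$image_size)),
    seed = derive_seed(config$seed, "synth"))
  log_stage("synthesize", images = nrow(ds$metadata),
            animals = length(unique(ds$metadata$animal_id)))
  write_metadata(ds$metadata, file.path(config$out_dir, "metadata.csv"))

  images <- ds$images
  if (isTRUE(config$stages$detect)) {
    models <- train_face_detectors(ds, n_train = config$detect$n_train,
                                   seed = derive_seed(config$seed, "casc"))
    det <- detect_dataset(ds, models)
    rep <- detection_report(det)
    log_stage("detect", accepted = rep$accepted, total = rep$n,
              overall_rate = round(rep$overall, 3))
    write.csv(det, file.path(config$out_dir, "detections.csv"),
              row.names = FALSE)
    results$detection <- rep
    # crop accepted images for the classifier; rejected images drop out
    keep <- which(det$accepted)
    images <- lapply(keep, function(i) {
      hyp <- list(accepted = TRUE,
                  face_box = bbox(det$face_x0[i], det$face_y0[i],
                                  det$face_x1[i], det$face_y1[i]))
      crop_to_hypothesis(images[[basename(det$image_path[i])]], hyp,
                         config$detect$margin_frac)
    })
    names(images) <- basename(det$image_path[keep])
    ds$metadata <- ds$metadata[keep, , drop = FALSE]
  }

  if (isTRUE(config$stages$train) || isTRUE(config$stages$evaluate)) {
    tc <- train_config(input_size = config$train$input_size,
                       epochs = config$train$epochs,
                       batch_size = config$train$batch_size,
                       seed = derive_seed(config$seed, "train"))
    folds <- subject_kfold(ds$metadata, k = config$evaluate$k,
                           seed = derive_seed(config$seed, "split"))
    cv <- cross_validate(ds$metadata, folds, images,
                         arch = config$train$arch, config = tc,
                         average_by = config$evaluate$average_by,
                         balance_seed = derive_seed(config$seed, "bal"))
    log_stage("evaluate", folds = length(folds),
              mean_accuracy = round(cv$summary$accuracy[["mean"]], 3))
    jsonlite::write_json(cv, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    results$metrics <- cv

    if (isTRUE(config$stages$explain)) {
      tr <- balance_by_subsampling(ds$metadata,
                                   seed = derive_seed(config$seed, "xbal"))
      fit <- train_classifier(tr, images, config$train$arch, tc)
      n <- min(config$explain$n_images, nrow(ds$metadata))
      for (i in seq_len(n)) {
        img <- preprocess(images[[basename(ds$metadata$image_path[i])]], tc)
        map <- try(dtd_relevance(fit$model, img), silent = TRUE)
        if (!inherits(map, "try-error")) {
          hm <- render_heatmap(map, img, mode = config$explain$mode)
          png::writePNG(hm, file.path(config$out_dir,
                                      sprintf("heatmap_%02d.png", i)))
        }
      }
      log_stage("explain", images = n)
    }
  }

  manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(list(manifest = manifest), results))
}
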