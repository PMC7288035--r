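#' Pipeline configuration
#'
#' Collects every stage parameter (all package defaults) plus the global seed
#' into one serializable list. `write -> read` round-trips identically
#' through JSON.
#'
#' @param out_dir Output directory of the run.
#' @param in_dir Input directory with recordings + `manifest.json` when the
#'   generate stage is skipped.
#' @param stages Character vector of stages to run, in pipeline order:
#'   generate, preprocess, topomap, correlate, train, evaluate.
#' @param n_pairs,seed,preset,duration_s,rate_hz Generator settings.
#' @param hp,lp,bound Preprocessing settings.
#' @param window_s,image_size Segmentation window and rendered image side.
#' @param split Train/validation/test pair counts.
#' @param filters,dense,dropout,lr,batch_size,epochs,patience Classifier
#'   settings (see [classifier_spec()]).
#' @param run_id Free-form run identifier.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "eegsm_run", in_dir = NULL,
                            stages = c("generate", "preprocess", "topomap",
                                       "correlate", "train", "evaluate"),
                            n_pairs = 14, seed = 1, preset = "hypotheses",
                            duration_s = 60, rate_hz = 128,
                            hp = 0.2, lp = 50, bound = 10,
                            window_s = 0.5, image_size = 360,
                            split = c(10, 2, 2),
                            filters = c(16, 32, 64, 128), dense = 128,
                            dropout = 0.2, lr = 1e-3, batch_size = 32,
                            epochs = 30, patience = 5,
                            run_id = "run-1") {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path JSON file.
#' @return `read_config`: the configuration.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path)
  raw <- lapply(raw, function(v) if (is.list(v)) unlist(v) else v)
  cfg <- do.call(pipeline_config, raw[names(raw) != ""])
  cfg
}

#' @keywords internal
stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes generate -> preprocess -> topomap -> correlate -> train ->
#' evaluate (each stage only if listed in `config$stages`), writing every
#' stage's outputs under `config$out_dir` and a run manifest
#' (`manifest.json`) with the configuration snapshot, per-file MD5 checksums,
#' seeds and timestamps. Identical configuration and seed reproduce identical
#' checksums for the deterministic stages.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, the run manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  study <- NULL
  outputs <- character()

  if ("generate" %in% config$stages) {
    say("stage generate")
    study <- stage_wrap("generate", {
      profiles <- condition_profiles(config$preset)
      st <- generate_study(config$n_pairs, profiles, seed = config$seed,
                           duration_s = config$duration_s,
                           rate_hz = config$rate_hz)
      write_study(st, file.path(out, "recordings"))
      st
    })
    outputs <- c(outputs, list.files(file.path(out, "recordings"),
                                     full.names = TRUE))
  } else {
    src <- config$in_dir %||% file.path(out, "recordings")
    study <- stage_wrap("input", {
      if (!file.exists(file.path(src, "manifest.json")))
        stop("no input study at ", src)
      read_study(src)
    })
  }

  if ("preprocess" %in% config$stages) {
    say("stage preprocess")
    study <- stage_wrap("preprocess", {
      st <- preprocess_study(study, hp = config$hp, lp = config$lp,
                             bound = config$bound)
      write_study(st, file.path(out, "preprocessed"))
      st
    })
    outputs <- c(outputs, list.files(file.path(out, "preprocessed"),
                                     full.names = TRUE))
  }

  topo_dir <- file.path(out, "topomaps")
  if ("topomap" %in% config$stages) {
    say("stage topomap")
    stage_wrap("topomap", write_topomaps(study, topo_dir,
                                         grid_n = config$image_size,
                                         window_s = config$window_s))
    outputs <- c(outputs, file.path(topo_dir, "labels.csv"))
  }

  if ("correlate" %in% config$stages) {
    say("stage correlate")
    stage_wrap("correlate", {
      cdir <- file.path(out, "correlation")
      dir.create(cdir, showWarnings = FALSE)
      mats <- category_correlations(study)
      for (k in names(mats))
        utils::write.csv(round(mats[[k]], 6), file.path(cdir, paste0(k, ".csv")))
      for (pr in list(c("HKT_PO", "BSC_PO"), c("HKT_Leader", "BSC_Leader"),
                      c("HKT_Leader", "HKT_PO"), c("BSC_Leader", "BSC_PO"))) {
        d <- cor_difference(mats[[pr[1]]], mats[[pr[2]]])
        utils::write.csv(round(d, 6),
                         file.path(cdir, sprintf("diff_%s_minus_%s.csv",
                                                 pr[1], pr[2])))
      }
      rep <- evaluate_hypotheses(mats)
      jsonlite::write_json(rep, file.path(cdir, "hypotheses.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      outputs <<- c(outputs, list.files(cdir, full.names = TRUE))
    })
  }

  model <- NULL
  plan <- NULL
  imgset <- NULL
  if (any(c("train", "evaluate") %in% config$stages)) {
    say("reading topomaps")
    imgset <- stage_wrap("train", read_topomaps(topo_dir))
    plan <- plan_split(unique(imgset$meta$pair), config$split[1],
                       config$split[2], config$split[3], seed = config$seed)
  }

  if ("train" %in% config$stages) {
    say("stage train")
    model <- stage_wrap("train", {
      spec <- classifier_spec(
        input_shape = c(dim(imgset$images)[1:2], 3L),
        filters = config$filters, dense = config$dense,
        dropout = config$dropout, lr = config$lr,
        batch_size = config$batch_size, epochs = config$epochs,
        patience = config$patience)
      m <- build_classifier(spec, seed = config$seed)
      m <- train_classifier(m, imgset$images, imgset$meta, plan,
                            seed = config$seed, verbose = verbose)
      utils::write.csv(m$history, file.path(out, "history.csv"),
                       row.names = FALSE)
      saveRDS(m, file.path(out, "model.rds"))
      m
    })
    outputs <- c(outputs, file.path(out, "history.csv"))
  }

  metrics <- NULL
  if ("evaluate" %in% config$stages) {
    say("stage evaluate")
    metrics <- stage_wrap("evaluate", {
      if (is.null(model)) model <- readRDS(file.path(out, "model.rds"))
      test_pairs <- plan$pair[plan$split == "test"]
      keep <- imgset$meta$pair %in% test_pairs
      cm <- evaluate_classifier(model, imgset$images[, , , keep, drop = FALSE],
                                imgset$meta$category[keep])
      utils::write.csv(unclass(cm), file.path(out, "confusion.csv"))
      met <- list(accuracy = accuracy(cm), n_test_images = sum(keep),
                  test_pairs = test_pairs)
      jsonlite::write_json(met, file.path(out, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      met
    })
    outputs <- c(outputs, file.path(out, "confusion.csv"),
                 file.path(out, "metrics.json"))
  }

  manifest <- list(
    run_id = config$run_id,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("eegsm")),
    started = format(t0), finished = format(Sys.time()),
    outputs = lapply(outputs, function(f)
      list(file = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
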