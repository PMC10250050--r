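# End-to-end orchestration: simulate -> reconstruct -> extract ->
# select -> train/evaluate (classical models and, optionally, the
# CNN), with one master seed fanned out deterministically to every
# stage and a machine-readable report of all results.

#' Reconstruct every frame of a dataset
#'
#' Runs [reconstruct_qpm()] on each hologram of a [generate_dataset()]
#' result (in memory, or re-read from `ds$out_dir`), carrying the
#' manifest identifiers onto the crops. Frames that fail segmentation
#' ("empty frame") are skipped and logged, never silently dropped.
#'
#' @param ds a `holo_dataset`.
#' @param crop_size crop side in pixels.
#' @param z_search autofocus interval; defaults to the scene's defocus
#'   range widened by 5 um.
#' @param denoise run the denoising stage.
#' @param progress print a dot every 25 frames.
#' @return list with `crops` (list of `cell_crop`) and `log` (one row
#'   per frame: `frame_id`, `ok`, `z_um`, `tamura`,
#'   `residue_density`, `rmse_vs_truth` (when ground-truth phantoms
#'   are available), `flags`).
#' @export
reconstruct_dataset <- function(ds, crop_size = 384, z_search = NULL,
                                denoise = TRUE, progress = FALSE) {
  stopifnot(inherits(ds, "holo_dataset"))
  if (is.null(z_search)) {
    dr <- ds$scene$defocus_range_um
    z_search <- c(min(-dr[2], dr[1]) - 5, max(dr[2], -dr[1]) + 5)
  }
  n <- nrow(ds$manifest)
  reference <- ds$reference
  if (is.null(reference) && !is.null(ds$out_dir)) {
    sy <- yaml::read_yaml(file.path(ds$out_dir, "scene.yaml"))
    if (!is.null(sy$reference_file) && file.exists(sy$reference_file))
      reference <- read_hologram(sy$reference_file, sy$reference_offset,
                                 sy$reference_scale)
  }
  if (is.null(reference))
    stop("reference hologram missing: cannot compensate aberrations")
  crops <- list()
  logs <- vector("list", n)
  for (i in seq_len(n)) {
    holo <- if (!is.null(ds$holograms)) ds$holograms[[i]] else
      read_hologram(ds$manifest$file[i], ds$manifest$tiff_offset[i],
                    ds$manifest$tiff_scale[i])
    row <- ds$manifest[i, ]
    rec <- tryCatch(
      reconstruct_qpm(holo, reference, ds$optics, crop_size = crop_size,
                      z_search = z_search, denoise = denoise),
      error = function(e) e)
    if (inherits(rec, "error")) {
      logs[[i]] <- data.frame(frame_id = row$frame_id, ok = FALSE,
                              z_um = NA_real_, tamura = NA_real_,
                              residue_density = NA_real_,
                              rmse_vs_truth = NA_real_,
                              flags = conditionMessage(rec),
                              stringsAsFactors = FALSE)
      next
    }
    rmse <- NA_real_
    if (!is.null(ds$phantoms)) {
      ph <- ds$phantoms[[i]]
      sup <- attr(ph, "support")
      rmse <- sqrt(mean((rec$qpm - ph)[sup]^2))
    }
    cr <- rec$crop
    cr$cell_id <- row$cell_id
    cr$frame_id <- row$frame_id
    cr$label <- row$class_label
    crops[[length(crops) + 1L]] <- cr
    logs[[i]] <- data.frame(frame_id = row$frame_id, ok = TRUE,
                            z_um = rec$z_um, tamura = rec$tamura,
                            residue_density = rec$residue_density,
                            rmse_vs_truth = rmse,
                            flags = paste(rec$flags, collapse = "; "),
                            stringsAsFactors = FALSE)
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  list(crops = crops, log = do.call(rbind, logs))
}

#' Pipeline run configuration
#'
#' Bundles every stage configuration around one master seed, which is
#' fanned out deterministically to the scene, the splits, the
#' selection, and the network training.
#'
#' @param scene a [scene_config()] (its `seed` is overridden from
#'   `seed`).
#' @param optics an [optics_config()].
#' @param crop_size reconstruction crop side.
#' @param test_fraction holdout test fraction.
#' @param group_by_cell keep frames of one cell on one split side.
#' @param selection a [selection_config()].
#' @param models classical models to train.
#' @param cv_folds folds for the classical cross-validation.
#' @param dl train the CNN as well (default `TRUE`).
#' @param arch a [dl_arch_spec()].
#' @param dl_config a [train_config_dl()].
#' @param dl_max_crops cap on the number of crops used by the CNN
#'   stage (subsampled, stratified) to bound runtime; `Inf` uses all.
#' @param out_dir optional output directory for intermediates and the
#'   report.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(scene = scene_config(), optics = optics_config(),
                       crop_size = 384, test_fraction = 0.027,
                       group_by_cell = TRUE,
                       selection = selection_config(),
                       models = ml_model_names(), cv_folds = 10,
                       dl = TRUE, arch = arch_spec(),
                       dl_config = train_config_dl(),
                       dl_max_crops = Inf,
                       out_dir = NULL, seed = 1L) {
  scene$seed <- child_seed(seed, "scene")
  selection$seed <- child_seed(seed, "selection")
  dl_config$seed <- child_seed(seed, "dl")
  structure(list(scene = scene, optics = optics, crop_size = crop_size,
                 test_fraction = test_fraction,
                 group_by_cell = group_by_cell, selection = selection,
                 models = models, cv_folds = cv_folds, dl = dl,
                 arch = arch, dl_config = dl_config,
                 dl_max_crops = dl_max_crops, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' simulate -> reconstruct -> extract features -> feature selection ->
#' classical training with ablation -> (optionally) CNN training, then
#' assemble a run report. When `config$out_dir` is set, the feature
#' table, the reconstruction log and the report are written there
#' (`features/features.csv`, `qpms/reconstruction_log.csv`,
#' `report.json`, plus a `config.json` fingerprint). Re-running with an
#' unchanged configuration reuses the stored feature table and skips
#' the simulation and reconstruction stages (the learning stages are
#' deterministic given the seed, so the report is reproduced).
#' Note that the CNN stage needs the crops themselves, so `dl` runs
#' only when the imaging stages ran in this session.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: list with `dataset` (counts,
#'   ratio), `reconstruction` (QC summary), `features`
#'   (`feature_table`), `selection` (correlation report, pruning,
#'   relief ranking, PCA variance), `ml` (`ablation_grid` and the
#'   cubic-SVM confusion matrices), `dl` (fold accuracies, test
#'   confusion) when enabled, and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  cfg_print <- config; cfg_print$out_dir <- NULL
  strip_classes <- function(x)
    if (is.list(x)) lapply(unclass(x), strip_classes) else unname(x)
  fingerprint <- jsonlite::toJSON(strip_classes(cfg_print),
                                  auto_unbox = TRUE, digits = 12)
  resume <- FALSE
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    fp_file <- file.path(out, "config.json")
    ft_file <- file.path(out, "features", "features.csv")
    if (file.exists(fp_file) && file.exists(ft_file) &&
        identical(readLines(fp_file, warn = FALSE),
                  as.character(fingerprint)))
      resume <- TRUE
  }

  if (resume) {
    ft <- utils::read.csv(file.path(out, "features", "features.csv"),
                          stringsAsFactors = FALSE)
    class(ft) <- c("feature_table", "data.frame")
    rec <- list(crops = NULL,
                log = utils::read.csv(
                  file.path(out, "qpms", "reconstruction_log.csv"),
                  stringsAsFactors = FALSE))
    ds <- generate_dataset(config$scene, config$optics, render = FALSE)
  } else {
    ds <- generate_dataset(config$scene, config$optics,
                           out_dir = if (!is.null(out))
                             file.path(out, "holograms_raw") else NULL)
    rec <- reconstruct_dataset(ds, crop_size = config$crop_size)
    if (length(rec$crops) == 0) stop("reconstruction produced no crops")
    ft <- feature_table(rec$crops)
    if (!is.null(out)) {
      dir.create(file.path(out, "features"), showWarnings = FALSE)
      utils::write.csv(ft, file.path(out, "features", "features.csv"),
                       row.names = FALSE)
      dir.create(file.path(out, "qpms"), showWarnings = FALSE)
      utils::write.csv(rec$log,
                       file.path(out, "qpms", "reconstruction_log.csv"),
                       row.names = FALSE)
      writeLines(as.character(fingerprint), file.path(out, "config.json"))
    }
  }

  corr <- kendall_matrix(ft)
  pr <- prune_features(corr, config$selection)
  relief <- relief_rank(ft, config = config$selection)
  pca <- embed_pca(ft)

  split <- holdout_split(ft, test_fraction = config$test_fraction,
                         group_by_cell = config$group_by_cell,
                         seed = child_seed(config$seed, "split"))
  grid <- ablation_study(ft, split, models = config$models,
                         config = config$selection, k = config$cv_folds,
                         seed = child_seed(config$seed, "folds"))

  dl_res <- NULL
  if (isTRUE(config$dl) && !is.null(rec$crops)) {
    tr_idx <- split$train
    if (is.finite(config$dl_max_crops) &&
        length(tr_idx) > config$dl_max_crops) {
      set.seed(child_seed(config$seed, "dl-sub"))
      lab <- ft$class_label[tr_idx]
      keep <- unlist(lapply(split(tr_idx, lab), function(ii)
        sample(ii, round(length(ii) / length(tr_idx) *
                           config$dl_max_crops))))
      tr_idx <- sort(keep)
    }
    cv <- train_dl(rec$crops[tr_idx], ft$class_label[tr_idx],
                   arch = config$arch, config = config$dl_config)
    best <- which.max(cv$fold_val_accuracy)
    test_cm <- evaluate_dl(cv$fold_models[[best]],
                           rec$crops[split$test],
                           ft$class_label[split$test])
    dl_res <- list(cv = cv, test_confusion = test_cm,
                   best_fold = best)
  }

  tab <- table(ds$manifest$class_label[!duplicated(ds$manifest$cell_id)])
  report <- structure(list(
    dataset = list(
      n_frames = nrow(ds$manifest),
      n_cells = length(unique(ds$manifest$cell_id)),
      counts = c(OC = unname(tab[["OC"]]), MONO = unname(tab[["MONO"]])),
      class_ratio = unname(tab[["OC"]] / tab[["MONO"]])),
    reconstruction = list(
      n_ok = sum(rec$log$ok), n_skipped = sum(!rec$log$ok),
      rmse_vs_truth = rec$log$rmse_vs_truth,
      log = rec$log),
    features = ft,
    selection = list(correlation = corr, pruning = pr, relief = relief,
                     pca_explained_variance = pca$explained_variance),
    split = split,
    ml = list(grid = grid,
              cubic_svm_test =
                grid$confusions[["all.cubic_svm"]]),
    dl = dl_res,
    config = config
  ), class = "run_report")

  if (!is.null(out)) {
    js <- list(
      dataset = report$dataset,
      reconstruction = list(n_ok = report$reconstruction$n_ok,
                            n_skipped = report$reconstruction$n_skipped,
                            mean_rmse = mean(rec$log$rmse_vs_truth,
                                             na.rm = TRUE)),
      kept_features = grid$kept_features,
      relief_top = relief$feature[1:3],
      ml_validation = grid$validation,
      ml_test = grid$test,
      dl_val_accuracy = if (!is.null(dl_res))
        dl_res$cv$fold_val_accuracy else NULL,
      dl_test_accuracy = if (!is.null(dl_res))
        dl_res$test_confusion$accuracy else NULL)
    jsonlite::write_json(js, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d frames (%d cells), ratio %.2f\n",
              x$dataset$n_frames, x$dataset$n_cells,
              x$dataset$class_ratio))
  cat(sprintf("  reconstruction: %d ok, %d skipped\n",
              x$reconstruction$n_ok, x$reconstruction$n_skipped))
  cat(sprintf("  pruned: %s\n",
              paste(x$selection$pruning$dropped, collapse = ", ")))
  cat(sprintf("  cubic SVM (all features): val %.1f%%, test %.1f%%\n",
              x$ml$grid$validation["all", "cubic_svm"],
              x$ml$grid$test["all", "cubic_svm"]))
  if (!is.null(x$dl))
    cat(sprintf("  CNN: mean val %.1f%%, test %.1f%%\n",
                x$dl$cv$mean_val_accuracy, x$dl$test_confusion$accuracy))
  invisible(x)
}
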