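#' Experiment configuration
#'
#' Bundles every stage's settings into one serialisable object: synthetic
#' data generation, preprocessing, zone resize, attention variant(s) and
#' training. A locked copy is written into every run directory, and a run
#' is reproducible from the locked config alone.
#'
#' @param out_dir Run directory.
#' @param synthetic A [synth_config()].
#' @param train A [train_config()].
#' @param target_height Zone resize height (the desk-scale experiments use
#'   64; the full-scale protocol uses 256).
#' @param interpolation Resize interpolation.
#' @param histogram_match Harmonise image intensities against the pooled
#'   median histogram of each fold's training split before zone extraction.
#' @param variants Attention variants to run; more than one produces an
#'   ablation comparison in the report.
#' @param ratio Channel-attention compression ratio.
#' @param folds_to_run Which cross-validation folds to execute (default:
#'   fold 1 only, the desk-scale choice; use `seq_len(train$n_folds)` for
#'   the full protocol).
#' @return Object of class `dla_run_config`.
#' @export
run_config <- function(out_dir = tempfile("dla_run_"),
                       synthetic = synth_config(),
                       train = train_config(),
                       target_height = 64L,
                       interpolation = "bilinear",
                       histogram_match = TRUE,
                       variants = "sequential",
                       ratio = 16L,
                       folds_to_run = 1L) {
  variants <- vapply(variants, normalize_variant, "")
  structure(list(out_dir = out_dir, synthetic = synthetic, train = train,
                 target_height = as.integer(target_height),
                 interpolation = interpolation,
                 histogram_match = isTRUE(histogram_match),
                 variants = unname(variants), ratio = as.integer(ratio),
                 folds_to_run = as.integer(folds_to_run)),
            class = "dla_run_config")
}

#' Read and write experiment configurations as YAML
#'
#' The YAML round trip preserves every field, so a locked copy of the
#' config fully determines a run.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a `dla_run_config`.
#' @export
write_run_config <- function(config, path) {
  plain <- unclass(config)
  plain$synthetic <- unclass(plain$synthetic)
  plain$train <- unclass(plain$train)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synth_config, y$synthetic[setdiff(names(y$synthetic), character(0))])
  trc <- do.call(train_config, y$train)
  run_config(out_dir = y$out_dir, synthetic = syn, train = trc,
             target_height = y$target_height, interpolation = y$interpolation,
             histogram_match = y$histogram_match, variants = y$variants,
             ratio = y$ratio, folds_to_run = y$folds_to_run)
}

log_line <- function(con, verbose, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  if (!is.null(con)) writeLines(line, con)
  if (verbose) message(line)
}

#' Run a full experiment
#'
#' Orchestrates synthesis, zone extraction, preprocessing, per-zone
#' training and evaluation: generate the synthetic dataset; assign
#' stratified image-level folds; then, per attention variant and fold,
#' harmonise intensities against the training split's pooled histogram,
#' extract and resize the six zone crops under a training-split aspect
#' policy, train the six zone classifiers, predict the validation fold and
#' evaluate at zone and image level. All randomness derives from the seeds
#' in the config, and per-task seeds are independent of execution order, so
#' rerunning a config reproduces the run exactly.
#'
#' @param config A [run_config()] (or path to its YAML).
#' @param verbose Log progress to the console (always logged to `run.log`).
#' @return Object of class `dla_run`: per-variant, per-fold reports plus
#'   cross-fold summaries (mean and standard deviation in percent) and,
#'   with several variants, an ablation table. Artifacts (dataset,
#'   predictions, `report.json`, `config.lock.yaml`, `run.log`) are written
#'   under `config$out_dir`.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "dla_run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(con))
  stage <- "synthesis"
  result <- tryCatch({
    log_line(con, verbose, "stage %s: %d images", stage, config$synthetic$n_images)
    manifest <- generate_dataset(config$synthetic, file.path(out, "data"))
    images <- lapply(manifest$image_path, function(p) read_gray(file.path(out, "data", p)))
    masks <- lapply(manifest$mask_path, function(p) read_gray(file.path(out, "data", p)))
    stage <- "fold assignment"
    folds <- stratified_folds(manifest$image_label, config$train$n_folds,
                              config$train$seed)
    variants_out <- list()
    for (variant in config$variants) {
      fold_reports <- list()
      for (f in config$folds_to_run) {
        tr <- which(folds != f)
        va <- which(folds == f)
        stage <- sprintf("preprocessing (variant %s, fold %d)", variant, f)
        log_line(con, verbose, "stage %s", stage)
        imgs <- images
        if (config$histogram_match) {
          ref <- pooled_reference(images[tr])
          imgs <- lapply(images, match_histogram, reference = ref)
        }
        zonesets <- Map(extract_zones, imgs, lapply(masks, as_mask))
        policy <- compute_zone_aspects(zonesets[tr],
                                       target_height = config$target_height,
                                       interpolation = config$interpolation)
        preds <- list()
        for (z in ZONE_NAMES) {
          stage <- sprintf("training (variant %s, fold %d, zone %s)", variant, f, z)
          crops <- lapply(zonesets, function(zs) resize_zone(zs[[z]]$pixels, z, policy))
          seed_z <- derive_stream_seed(config$train$seed,
                                       match(variant, config$variants) * 100000 +
                                         f * 1000 + match(z, ZONE_NAMES))
          cfg_z <- config$train
          cfg_z$seed <- seed_z
          fit <- dla_fit(crops[tr], manifest[[z]][tr],
                         x_val = crops[va], y_val = manifest[[z]][va],
                         variant = variant, ratio = config$ratio, config = cfg_z)
          log_line(con, verbose, "  %s: best epoch %d, val acc %.3f", z,
                   fit$best_epoch, fit$history$val_acc[fit$best_epoch])
          pr <- predict(fit, crops[va])
          pr <- cbind(image_id = manifest$image_id[va], zone_name = z, pr)
          preds[[z]] <- pr
        }
        stage <- sprintf("evaluation (variant %s, fold %d)", variant, f)
        pdir <- file.path(out, "predictions", variant, sprintf("fold%d", f))
        dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
        for (z in ZONE_NAMES)
          write.csv(preds[[z]], file.path(pdir, paste0(z, ".csv")), row.names = FALSE)
        fold_reports[[sprintf("fold%d", f)]] <-
          evaluate_run(preds, manifest[manifest$image_id %in% manifest$image_id[va], ])
      }
      variants_out[[variant]] <- list(folds = fold_reports,
                                      summary = summarize_folds(fold_reports))
    }
    ablation <- do.call(rbind, lapply(names(variants_out), function(v) {
      s <- variants_out[[v]]$summary
      data.frame(variant = v, acc = s["image.acc", "mean"],
                 sen = s["image.sen", "mean"], spe = s["image.spe", "mean"],
                 f1 = s["image.f1", "mean"], auc = s["image.auc", "mean"])
    }))
    run <- structure(list(variants = variants_out, ablation = ablation,
                          manifest = manifest, folds = folds, config = config),
                     class = "dla_run")
    write_run_config(config, file.path(out, "config.lock.yaml"))
    jsonlite::write_json(report_json(run), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line(con, verbose, "run complete")
    run
  }, error = function(e) {
    log_line(con, verbose, "ABORT in stage %s: %s", stage, conditionMessage(e))
    stop(sprintf("pipeline error in stage [%s]: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}

# cross-fold mean and standard deviation (sd reported in percent, the
# convention used for the reference tables)
summarize_folds <- function(fold_reports) {
  rows <- lapply(fold_reports, function(r) {
    c(setNames(as.numeric(r$zone_avg), paste0("zone.", names(r$zone_avg))),
      image.acc = r$image$acc, image.sen = r$image$sen, image.spe = r$image$spe,
      image.f1 = r$image$f1, image.auc = r$image$auc,
      binary.acc = r$binary$acc, binary.sen = r$binary$sen,
      binary.spe = r$binary$spe, binary.f1 = r$binary$f1,
      binary.auc = r$binary$auc)
  })
  m <- do.call(rbind, rows)
  data.frame(mean = colMeans(m),
             sd_pct = if (nrow(m) > 1) apply(m, 2, sd) * 100 else rep(0, ncol(m)),
             row.names = colnames(m))
}

report_json <- function(run) {
  list(variants = lapply(run$variants, function(v) {
    list(summary = v$summary,
         folds = lapply(v$folds, function(r)
           list(zone = lapply(r$zone, function(m)
                  list(acc = m$acc, sen = m$sen, spe = m$spe, f1 = m$f1, auc = m$auc)),
                image = list(acc = r$image$acc, sen = r$image$sen,
                             spe = r$image$spe, f1 = r$image$f1, auc = r$image$auc),
                binary = list(acc = r$binary$acc, sen = r$binary$sen,
                              spe = r$binary$spe, f1 = r$binary$f1,
                              auc = r$binary$auc))))
  }), ablation = run$ablation)
}

#' @export
print.dla_run <- function(x, ...) {
  cat(sprintf("Experiment run: %d images, variants [%s], folds [%s]\n",
              nrow(x$manifest), paste(names(x$variants), collapse = ", "),
              paste(x$config$folds_to_run, collapse = ", ")))
  cat("\nImage-level summary (mean across folds, sd in %):\n")
  for (v in names(x$variants)) {
    s <- x$variants[[v]]$summary
    cat(sprintf("  %-10s ACC %.4f+/-%.2f  SEN %.4f  SPE %.4f  F1 %.4f  AUC %.4f\n",
                v, s["image.acc", "mean"], s["image.acc", "sd_pct"],
                s["image.sen", "mean"], s["image.spe", "mean"],
                s["image.f1", "mean"], s["image.auc", "mean"]))
  }
  invisible(x)
}
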