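#' Aggregate six zone categories into the image-level category
#'
#' The image-level ILO category is the maximum of the six zone categories:
#' e.g. zones (RUZ 1, RMZ 0, RLZ 0, LUZ 2, LMZ 1, LLZ 0) give image
#' category 2. All six zone names must be present.
#'
#' @param zone_labels Named vector or list of categories 0-3 with names
#'   RUZ, RMZ, RLZ, LUZ, LMZ, LLZ.
#' @return Integer image category.
#' @export
#' @examples
#' aggregate_image_label(c(RUZ = 1, RMZ = 0, RLZ = 0, LUZ = 2, LMZ = 1, LLZ = 0))
aggregate_image_label <- function(zone_labels) {
  zl <- unlist(zone_labels)
  missing <- setdiff(ZONE_NAMES, names(zl))
  if (length(missing) > 0)
    stop(sprintf("zone coverage error: missing zone(s) %s",
                 paste(missing, collapse = ", ")))
  as.integer(max(zl[ZONE_NAMES]))
}

#' Binary pneumoconiosis detection from the multiclass category
#'
#' Category 0 maps to `"negative"`, categories 1-3 to `"positive"`.
#' Vectorised.
#'
#' @param image_category Integer categories in 0..3.
#' @return Factor with levels `negative`, `positive`.
#' @export
binarize_detection <- function(image_category) {
  if (any(!image_category %in% 0:3))
    stop_param("image category must be in 0..3")
  factor(ifelse(image_category >= 1, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Confusion matrix
#'
#' @param y_true,y_pred Equal-length vectors of class labels in `0..K-1`.
#' @param num_classes K.
#' @return `K x K` integer matrix, rows = true class, columns = predicted.
#' @export
confusion <- function(y_true, y_pred, num_classes = 4L) {
  if (length(y_true) != length(y_pred))
    stop_param("y_true (%d) and y_pred (%d) differ in length",
               length(y_true), length(y_pred))
  if (any(!c(y_true, y_pred) %in% 0:(num_classes - 1)))
    stop_param("labels must lie in 0..%d", num_classes - 1)
  lv <- 0:(num_classes - 1)
  cm <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  m <- matrix(as.integer(cm), num_classes, num_classes,
              dimnames = list(true = lv, predicted = lv))
  m
}

# one-vs-rest AUC by the rank (Mann-Whitney) identity, equal to the area
# under the ROC curve swept over all distinct score thresholds
auc_ovr <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Support-weighted one-vs-rest classification metrics
#'
#' For every class `k` the one-vs-rest counts are read off the confusion
#' matrix (`TP = cm[k,k]`, `FN` = rest of row, `FP` = rest of column,
#' `TN` = remainder), giving per-class accuracy `(TP+TN)/N`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and `F1 = 2TP/(2TP+FP+FN)`.
#' Reported values are means over classes weighted by true class support
#' (the "weighted average" convention for imbalanced data). A useful
#' identity follows: the support-weighted sensitivity always equals the
#' plain multiclass accuracy, which is why accuracy and sensitivity
#' coincide for binary detection reports. Undefined 0/0 ratios are set to 0
#' with a warning; zero-support classes get weight 0.
#'
#' AUC, when probabilities are supplied, is the support-weighted mean of
#' one-vs-rest areas under the ROC curve.
#'
#' @param cm Confusion matrix from [confusion()].
#' @param probabilities Optional `N x K` matrix of class probabilities
#'   (rows aligned with `y_true`), required for AUC.
#' @param y_true True labels aligned with `probabilities`.
#' @return Object of class `dla_metrics`: list with `acc`, `sen`, `spe`,
#'   `f1`, `auc`, `per_class` (data frame of counts and per-class metrics),
#'   `averaging = "weighted"` and `n`.
#' @export
weighted_metrics <- function(cm, probabilities = NULL, y_true = NULL) {
  K <- nrow(cm)
  N <- sum(cm)
  support <- rowSums(cm)
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad & support > 0))
      warning(sprintf("undefined %s (0/0) for class(es) %s; set to 0", what,
                      paste(which(bad) - 1, collapse = ", ")))
    out <- ifelse(bad, 0, num / den)
    out
  }
  tp <- diag(cm)
  fn <- support - tp
  fp <- colSums(cm) - tp
  tn <- N - tp - fn - fp
  sen <- safe_div(tp, tp + fn, "sensitivity")
  spe <- safe_div(tn, tn + fp, "specificity")
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn, "F1")
  acc_k <- (tp + tn) / N
  w <- support / N
  auc_k <- rep(NA_real_, K)
  if (!is.null(probabilities)) {
    stopifnot(!is.null(y_true), nrow(probabilities) == length(y_true))
    for (k in seq_len(K))
      auc_k[k] <- auc_ovr(probabilities[, k], y_true == (k - 1))
  }
  wmean <- function(v) sum(w * ifelse(is.na(v), 0, v))
  structure(list(
    acc = wmean(acc_k), sen = wmean(sen), spe = wmean(spe), f1 = wmean(f1),
    auc = if (all(is.na(auc_k))) NA_real_ else wmean(auc_k),
    per_class = data.frame(class = 0:(K - 1), support = support,
                           TP = tp, TN = tn, FP = fp, FN = fn,
                           sen = sen, spe = spe, f1 = f1, acc = acc_k,
                           auc = auc_k, row.names = NULL),
    averaging = "weighted", n = N), class = "dla_metrics")
}

#' @export
print.dla_metrics <- function(x, ...) {
  cat(sprintf("Weighted one-vs-rest metrics (n = %d):\n", x$n))
  cat(sprintf("  ACC %.4f  SEN %.4f  SPE %.4f  F1 %.4f  AUC %s\n",
              x$acc, x$sen, x$spe, x$f1,
              if (is.na(x$auc)) "-" else sprintf("%.4f", x$auc)))
  invisible(x)
}

read_zone_predictions <- function(predictions) {
  if (is.character(predictions) && length(predictions) == 1) {
    files <- file.path(predictions, paste0(ZONE_NAMES, ".csv"))
    names(files) <- ZONE_NAMES
    predictions <- lapply(files, read.csv)
  }
  missing <- setdiff(ZONE_NAMES, names(predictions))
  if (length(missing) > 0)
    stop(sprintf("zone coverage error: missing prediction set(s) %s",
                 paste(missing, collapse = ", ")))
  predictions[ZONE_NAMES]
}

#' Evaluate a full prediction run at zone and image level
#'
#' Zone-level metrics compare each zone's predictions with the manifest's
#' zone labels. Image-level predictions aggregate the six predicted zone
#' categories with the max rule; image-level probabilities, needed for AUC,
#' take the per-class maximum over the six zone probability vectors and
#' renormalise to the simplex (the probabilistic mirror of the label rule).
#' A binary detection report (category >= 1 is positive) is derived from
#' the image-level result.
#'
#' @param predictions Named list (RUZ..LLZ) of data frames with columns
#'   `image_id, p0..p3, predicted`, or a directory containing
#'   `RUZ.csv .. LLZ.csv`.
#' @param manifest Manifest data frame with zone-label columns and
#'   `image_label` (as produced by [generate_dataset()]).
#' @return Object of class `dla_report`: list with `zone` (per-zone
#'   [weighted_metrics()] plus an `avg` row), `image` and `binary`.
#' @export
evaluate_run <- function(predictions, manifest) {
  predictions <- read_zone_predictions(predictions)
  ids <- sort(predictions[[1]]$image_id)
  for (z in ZONE_NAMES)
    if (!identical(sort(predictions[[z]]$image_id), ids))
      stop("zone coverage error: image_id sets differ across zone prediction files")
  manifest <- manifest[match(ids, manifest$image_id), ]
  if (any(is.na(manifest$image_id)))
    stop("zone coverage error: predictions contain image_ids absent from the manifest")
  K <- 4L
  pcols <- paste0("p", 0:(K - 1))
  zone_metrics <- list()
  for (z in ZONE_NAMES) {
    pz <- predictions[[z]][match(ids, predictions[[z]]$image_id), ]
    cm <- confusion(manifest[[z]], pz$predicted, K)
    zone_metrics[[z]] <- weighted_metrics(cm, as.matrix(pz[pcols]), manifest[[z]])
  }
  avg <- colMeans(do.call(rbind, lapply(zone_metrics, function(m)
    c(acc = m$acc, sen = m$sen, spe = m$spe, f1 = m$f1, auc = m$auc))))

  pred_mat <- vapply(ZONE_NAMES, function(z)
    predictions[[z]][match(ids, predictions[[z]]$image_id), "predicted"],
    numeric(length(ids)))
  img_pred <- apply(pred_mat, 1, max)
  prob_max <- Reduce(pmax, lapply(ZONE_NAMES, function(z)
    as.matrix(predictions[[z]][match(ids, predictions[[z]]$image_id), pcols])))
  img_prob <- prob_max / rowSums(prob_max)
  img_true <- manifest$image_label
  image_metrics <- weighted_metrics(confusion(img_true, img_pred, K),
                                    img_prob, img_true)

  bin_true <- as.integer(binarize_detection(img_true)) - 1L
  bin_pred <- as.integer(binarize_detection(img_pred)) - 1L
  bin_prob <- cbind(img_prob[, 1], rowSums(img_prob[, 2:K, drop = FALSE]))
  binary_metrics <- weighted_metrics(confusion(bin_true, bin_pred, 2L),
                                     bin_prob, bin_true)
  structure(list(zone = zone_metrics, zone_avg = avg,
                 image = image_metrics, binary = binary_metrics,
                 n = length(ids)),
            class = "dla_report")
}

#' @export
print.dla_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d images\n", x$n))
  cat("Zone level:\n")
  for (z in ZONE_NAMES) {
    m <- x$zone[[z]]
    cat(sprintf("  %s: ACC %.4f  F1 %.4f  AUC %s\n", z, m$acc, m$f1,
                if (is.na(m$auc)) "-" else sprintf("%.4f", m$auc)))
  }
  cat(sprintf("  avg: ACC %.4f  F1 %.4f  AUC %.4f\n",
              x$zone_avg["acc"], x$zone_avg["f1"], x$zone_avg["auc"]))
  cat("Image level (multiclass): ")
  print(x$image)
  cat("Image level (binary detection): ")
  print(x$binary)
  invisible(x)
}
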