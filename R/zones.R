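#' Split a lung-field mask into right and left lungs
#'
#' Labels the 4-connected foreground components of a binary mask and keeps
#' the two largest, discarding any smaller spurious components with a
#' warning. The component whose column centroid is smaller (on the image
#' left) is the patient's anatomical RIGHT lung, following standard PA
#' radiograph orientation; the other is the LEFT lung.
#'
#' @param mask Binary matrix (logical or 0/1) with at least two foreground
#'   components.
#' @return A list with logical full-size masks `right` and `left`.
#' @details If the column ranges of the two largest components overlap by
#'   more than 50% of the narrower range the lungs are considered fused and
#'   an error is raised: the zone geometry below is only meaningful for
#'   separated lung fields.
#' @export
split_lungs <- function(mask) {
  mask <- as_mask(mask)
  lab <- cc_label4(mask)
  n <- max(lab)
  if (n < 2)
    stop(sprintf("lung geometry error: expected at least 2 connected components, found %d", n))
  areas <- tabulate(lab[lab > 0], nbins = n)
  keep <- order(areas, decreasing = TRUE)[1:2]
  if (n > 2)
    warning(sprintf("discarding %d smaller component(s) (areas: %s)",
                    n - 2, paste(sort(areas[-keep]), collapse = ", ")))
  cols <- col(lab)
  rng <- lapply(keep, function(k) range(cols[lab == k]))
  ov <- min(rng[[1]][2], rng[[2]][2]) - max(rng[[1]][1], rng[[2]][1]) + 1
  minw <- min(rng[[1]][2] - rng[[1]][1], rng[[2]][2] - rng[[2]][1]) + 1
  if (ov > 0.5 * minw)
    stop("lung geometry error: the two largest components overlap in more than 50% of their column ranges (fused lungs?)")
  cent <- vapply(keep, function(k) mean(cols[lab == k]), numeric(1))
  right_k <- keep[which.min(cent)]
  left_k <- keep[which.max(cent)]
  list(right = lab == right_k, left = lab == left_k)
}

#' Compute the zone geometry of one lung
#'
#' Finds the lung apex (topmost foreground row) and the diaphragm dome
#' (bottommost foreground row) and divides the vertical span between them
#' into three equal parts, the boundaries falling at
#' `apex + floor(span/3)` and `apex + floor(2*span/3)` with
#' `span = dome - apex`. Rows and columns are 1-based (R convention); the
#' division arithmetic is identical in any index base.
#'
#' @param lung_mask Logical matrix covering a single lung.
#' @param side `"right"` or `"left"` (anatomical).
#' @return An object of class `dla_lung_geometry` with fields `side`,
#'   `apex_row`, `dome_row`, `boundary1_row`, `boundary2_row`, `col_min`,
#'   `col_max`.
#' @export
#' @examples
#' m <- matrix(FALSE, 300, 40); m[1:300, 10:30] <- TRUE
#' g <- compute_geometry(m, "right")
#' c(g$boundary1_row, g$boundary2_row)  # 100, 200
compute_geometry <- function(lung_mask, side = c("right", "left")) {
  side <- match.arg(side)
  lung_mask <- as_mask(lung_mask)
  fg_rows <- which(rowSums(lung_mask) > 0)
  if (length(fg_rows) == 0) stop("lung geometry error: empty mask")
  apex <- fg_rows[1]
  dome <- fg_rows[length(fg_rows)]
  span <- dome - apex
  if (span < 3)
    stop(sprintf("lung geometry error: degenerate lung spanning %d row(s), cannot form three zones", span + 1))
  fg_cols <- which(colSums(lung_mask) > 0)
  structure(list(side = side,
                 apex_row = apex,
                 dome_row = dome,
                 boundary1_row = apex + floor(span / 3),
                 boundary2_row = apex + floor(2 * span / 3),
                 col_min = fg_cols[1],
                 col_max = fg_cols[length(fg_cols)]),
            class = "dla_lung_geometry")
}

#' @export
print.dla_lung_geometry <- function(x, ...) {
  cat(sprintf("%s lung: apex row %d, dome row %d, boundaries %d / %d, cols %d..%d\n",
              x$side, x$apex_row, x$dome_row, x$boundary1_row, x$boundary2_row,
              x$col_min, x$col_max))
  invisible(x)
}

# Row/column windows and zone masks of the six zones of a full-image mask.
# Row intervals are [apex, b1), [b1, b2), [b2, dome]; the final interval is
# closed so the three intervals tile [apex, dome] exactly.
zone_layout <- function(mask, lungs = NULL) {
  if (is.null(lungs)) lungs <- split_lungs(mask)
  out <- list()
  for (side in c("right", "left")) {
    lm <- lungs[[side]]
    g <- compute_geometry(lm, side)
    ivals <- list(g$apex_row:(g$boundary1_row - 1),
                  g$boundary1_row:(g$boundary2_row - 1),
                  g$boundary2_row:g$dome_row)
    pos <- c("U", "M", "L")
    for (i in 1:3) {
      zn <- paste0(toupper(substr(side, 1, 1)), pos[i], "Z")
      rows <- ivals[[i]]
      cols <- g$col_min:g$col_max
      out[[zn]] <- list(rows = rows, cols = cols,
                        mask = lm[rows, cols, drop = FALSE],
                        geometry = g)
    }
  }
  out[ZONE_NAMES]
}

#' Extract the six labeled zone crops of a radiograph
#'
#' Splits the lung mask into the two lungs, computes each lung's apex-to-dome
#' thirds independently (apex and dome heights differ between lungs), and
#' crops each zone to the lung's column bounding box. Pixels outside the
#' lung field are zeroed inside every crop, so no extra-pulmonary signal
#' leaks into the classifier.
#'
#' @param image Grayscale numeric matrix.
#' @param mask Binary lung mask of identical dimensions.
#' @return An object of class `dla_zoneset`: a named list (RUZ, RMZ, RLZ,
#'   LUZ, LMZ, LLZ) of zone crops, each with `zone_name`, `pixels`,
#'   `origin` (row, col of the crop in the source image), `mask` (crop of
#'   the lung mask) and `mask_fraction`; the per-lung geometry is attached
#'   as attribute `"geometry"`.
#' @export
extract_zones <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    stop_param("image (%s) and mask (%s) dimensions differ",
               paste(dim(image), collapse = "x"), paste(dim(mask), collapse = "x"))
  mask <- as_mask(mask)
  lungs <- split_lungs(mask)
  layout <- zone_layout(mask, lungs)
  zones <- lapply(ZONE_NAMES, function(zn) {
    win <- layout[[zn]]
    px <- image[win$rows, win$cols, drop = FALSE]
    px[!win$mask] <- 0
    list(zone_name = zn,
         pixels = px,
         origin = c(row = win$rows[1], col = win$cols[1]),
         mask = win$mask,
         mask_fraction = mean(win$mask))
  })
  names(zones) <- ZONE_NAMES
  structure(zones,
            class = "dla_zoneset",
            geometry = list(right = layout$RUZ$geometry, left = layout$LUZ$geometry))
}

#' @export
print.dla_zoneset <- function(x, ...) {
  cat("Six-zone crop set:\n")
  for (z in ZONE_NAMES)
    cat(sprintf("  %s: %3d x %3d at (%d, %d), lung fraction %.2f\n",
                z, nrow(x[[z]]$pixels), ncol(x[[z]]$pixels),
                x[[z]]$origin["row"], x[[z]]$origin["col"], x[[z]]$mask_fraction))
  invisible(x)
}
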