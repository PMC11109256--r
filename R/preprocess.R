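#' Histogram matching by monotone quantile mapping
#'
#' Transforms `image` so that its empirical intensity distribution matches
#' that of `reference`, the usual harmonisation step when radiographs come
#' from heterogeneous sources. Each pixel value is mapped through the
#' inverse empirical CDF of the reference evaluated at the pixel's own
#' empirical quantile (a step function, so an image matched to a two-level
#' reference takes exactly the two reference levels).
#'
#' @param image Grayscale numeric matrix.
#' @param reference Either a grayscale matrix or a numeric vector of
#'   reference intensity values (e.g. from [pooled_reference()]).
#' @return Matrix of the same dimensions as `image`.
#' @export
#' @examples
#' img <- matrix(seq(0, 1, length.out = 16), 4)
#' ref <- matrix(rep(c(0.2, 0.8), each = 8), 4)
#' unique(as.vector(match_histogram(img, ref)))  # only 0.2 and 0.8
match_histogram <- function(image, reference) {
  rv <- as.numeric(reference)
  if (length(rv) == 0 || length(image) == 0)
    stop_param("image and reference must be nonempty")
  urv <- sort(unique(rv))
  if (length(urv) < 2)
    stop("degenerate reference: constant image has no invertible histogram")
  ref_cdf <- cumsum(tabulate(match(rv, urv), nbins = length(urv))) / length(rv)
  x <- as.numeric(image)
  ux <- sort(unique(x))
  x_cdf <- cumsum(tabulate(match(x, ux), nbins = length(ux))) / length(x)
  # inverse reference CDF, right-continuous step function
  mapped <- approx(x = ref_cdf, y = urv, xout = x_cdf,
                   method = "constant", f = 1, rule = 2,
                   ties = list("ordered", min))$y
  out <- mapped[match(x, ux)]
  matrix(out, nrow(image), ncol(image))
}

#' Pooled median reference histogram
#'
#' Builds a reference intensity distribution for [match_histogram()] as the
#' per-quantile median over a set of images (typically the training split),
#' so no single image dictates the target histogram.
#'
#' @param images List of grayscale matrices.
#' @param n_quantiles Number of quantile knots.
#' @return Sorted numeric vector of reference intensities.
#' @export
pooled_reference <- function(images, n_quantiles = 256) {
  stopifnot(length(images) >= 1)
  probs <- seq(0, 1, length.out = n_quantiles)
  qs <- vapply(images, function(im) quantile(as.numeric(im), probs, names = FALSE),
               numeric(n_quantiles))
  sort(apply(qs, 1, median))
}

#' Zone resize policy
#'
#' All crops of a zone must share output dimensions for batched training.
#' Following the protocol of fixing the output height and deriving the width
#' from the zone's average aspect ratio, the policy stores, per zone, the
#' width-per-unit-height ratio `ratio_w` (aspect `1 : ratio_w`); output
#' width is `round(target_height * ratio_w)` with round-half-away-from-zero.
#'
#' @param target_height Output height in pixels (the reference protocol
#'   uses 256; the desk-scale experiments in this package use 64).
#' @param aspect_by_zone Named numeric vector mapping each zone name to its
#'   `ratio_w`.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return Object of class `dla_resize_policy`.
#' @export
resize_policy <- function(target_height = 256L, aspect_by_zone,
                          interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (target_height <= 0) stop_param("target_height must be positive")
  if (any(aspect_by_zone <= 0)) stop_param("aspect ratios must be positive")
  structure(list(target_height = as.integer(target_height),
                 aspect_by_zone = aspect_by_zone,
                 interpolation = interpolation),
            class = "dla_resize_policy")
}

#' @export
print.dla_resize_policy <- function(x, ...) {
  cat(sprintf("Zone resize policy: height %d, %s interpolation\n",
              x$target_height, x$interpolation))
  for (z in names(x$aspect_by_zone))
    cat(sprintf("  %s: aspect 1:%.4g -> %d x %d\n", z, x$aspect_by_zone[[z]],
                x$target_height, round_half_up(x$target_height * x$aspect_by_zone[[z]])))
  invisible(x)
}

#' Measure average zone aspect ratios
#'
#' Computes, per zone, the mean height and mean width of the supplied crops
#' and expresses the zone aspect as `1 : mean(width)/mean(height)`. Run this
#' on the training split only and freeze the result into the policy, so the
#' test split cannot influence preprocessing.
#'
#' @param crops Either a list of [extract_zones()] zone sets, or a data
#'   frame with columns `zone_name`, `height`, `width`.
#' @param target_height,interpolation Passed to [resize_policy()].
#' @return A [resize_policy()] object.
#' @export
compute_zone_aspects <- function(crops, target_height = 256L,
                                 interpolation = "bilinear") {
  if (is.data.frame(crops)) {
    dims <- crops
  } else {
    dims <- do.call(rbind, lapply(crops, function(zs) {
      data.frame(zone_name = ZONE_NAMES,
                 height = vapply(ZONE_NAMES, function(z) nrow(zs[[z]]$pixels), 0L),
                 width = vapply(ZONE_NAMES, function(z) ncol(zs[[z]]$pixels), 0L))
    }))
  }
  missing <- setdiff(ZONE_NAMES, unique(dims$zone_name))
  if (length(missing) > 0)
    stop(sprintf("zone coverage error: no crops for zone(s) %s",
                 paste(missing, collapse = ", ")))
  aspect <- vapply(ZONE_NAMES, function(z) {
    d <- dims[dims$zone_name == z, ]
    mean(d$width) / mean(d$height)
  }, numeric(1))
  resize_policy(target_height, aspect, interpolation)
}

#' Resize a zone crop under a policy
#'
#' Output height is the policy's `target_height`; output width is
#' `round(target_height * ratio_w)` for the zone's aspect `1 : ratio_w`
#' (e.g. aspect 1:1.25 at height 256 gives width 320).
#'
#' @param crop Grayscale matrix.
#' @param zone_name One of the six zone names.
#' @param policy A [resize_policy()] object.
#' @return Matrix `target_height x width`.
#' @export
resize_zone <- function(crop, zone_name, policy) {
  if (!zone_name %in% names(policy$aspect_by_zone))
    stop_param("unknown zone name '%s'", zone_name)
  wd <- as.integer(round_half_up(policy$target_height * policy$aspect_by_zone[[zone_name]]))
  filt <- if (policy$interpolation == "bilinear") "bilinear" else "none"
  out <- EBImage::resize(crop, w = policy$target_height, h = wd, filter = filt)
  matrix(as.numeric(out), policy$target_height, wd)
}

#' Random small augmentation of a zone crop
#'
#' Config-gated augmentation used during training: rotation up to +/- 7
#' degrees, translation up to +/- 5% of each dimension, brightness jitter
#' up to +/- 10%. Horizontal flips are deliberately not offered: they swap
#' anatomical laterality.
#'
#' @param img Grayscale matrix.
#' @param seed Integer seed.
#' @param max_rotate Degrees.
#' @param max_translate Fraction of each dimension.
#' @param max_brightness Multiplicative jitter fraction.
#' @return Augmented matrix, same dimensions.
#' @export
augment_image <- function(img, seed, max_rotate = 7, max_translate = 0.05,
                          max_brightness = 0.1) {
  with_seed(seed, {
    ang <- runif(1, -max_rotate, max_rotate)
    out <- EBImage::rotate(img, ang, output.dim = dim(img), bg.col = 0)
    v <- round(runif(2, -max_translate, max_translate) * dim(img))
    out <- EBImage::translate(out, v, bg.col = 0)
    out <- out * (1 + runif(1, -max_brightness, max_brightness))
    clamp01(matrix(as.numeric(out), nrow(img), ncol(img)))
  })
}
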