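#' Channel attention (squeeze-and-excitation) parameters
#'
#' The channel gate is a two-layer perceptron over the globally
#' average-pooled channel descriptor: hidden size `max(1, floor(C/r))` for
#' compression ratio `r`, rectifier between the layers, sigmoid output.
#' Weights are initialised with fan-in scaled Gaussian noise (biases zero);
#' `init = "zero"` gives the all-0.5 neutral gate, handy for testing.
#'
#' @param channels Number of feature-map channels C.
#' @param ratio Compression ratio r (default 16, the value at which the
#'   reference experiments peaked).
#' @param seed Optional integer seed for reproducible initialisation.
#' @param init `"he"` (fan-in scaled) or `"zero"`.
#' @return Object of class `dla_ca_params` with `w0` ((C/r) x C), `b0`,
#'   `w1` (C x (C/r)), `b1`, `ratio`.
#' @export
ca_params <- function(channels, ratio = 16L, seed = NULL, init = c("he", "zero")) {
  init <- match.arg(init)
  if (ratio < 1) stop_param("ratio must be a positive integer")
  h <- max(1L, floor(channels / ratio))
  make <- function() {
    if (init == "zero") {
      list(w0 = matrix(0, h, channels), b0 = numeric(h),
           w1 = matrix(0, channels, h), b1 = numeric(channels))
    } else {
      list(w0 = matrix(rnorm(h * channels, 0, sqrt(2 / channels)), h, channels),
           b0 = numeric(h),
           w1 = matrix(rnorm(channels * h, 0, sqrt(2 / h)), channels, h),
           b1 = numeric(channels))
    }
  }
  p <- if (is.null(seed)) make() else with_seed(seed, make())
  structure(c(p, list(ratio = as.integer(ratio))), class = "dla_ca_params")
}

#' Spatial attention parameters
#'
#' A single `k x k` convolution (default 7x7) over the two channel-pooled
#' descriptor maps (average and maximum), plus a scalar bias, followed by a
#' sigmoid.
#'
#' @param seed Optional integer seed.
#' @param init `"he"` or `"zero"`.
#' @param kernel_size Odd kernel size; the reference design fixes 7.
#' @return Object of class `dla_sa_params` with `kernel`
#'   (`kernel_size x kernel_size x 2`) and scalar `bias`.
#' @export
sa_params <- function(seed = NULL, init = c("he", "zero"), kernel_size = 7L) {
  init <- match.arg(init)
  if (kernel_size %% 2 != 1) stop_param("kernel_size must be odd")
  make <- function() {
    k <- if (init == "zero") array(0, c(kernel_size, kernel_size, 2))
    else array(rnorm(kernel_size^2 * 2, 0, sqrt(2 / (kernel_size^2 * 2))),
               c(kernel_size, kernel_size, 2))
    list(kernel = k, bias = 0)
  }
  p <- if (is.null(seed)) make() else with_seed(seed, make())
  structure(p, class = "dla_sa_params")
}

check_feature_map <- function(f) {
  if (!(is.array(f) && length(dim(f)) == 3))
    stop_param("feature map must be a rank-3 array (H x W x C)")
  if (!all(is.finite(f))) stop_param("feature map contains non-finite values")
  invisible(dim(f))
}

#' Squeeze: global average pooling per channel
#'
#' @param f Feature map, `H x W x C` array.
#' @return Numeric length-C channel descriptor.
#' @export
channel_squeeze <- function(f) {
  d <- check_feature_map(f)
  colMeans(matrix(f, d[1] * d[2], d[3]))
}

#' Channel attention map
#'
#' Excitation: `sigmoid(w1 %*% relu(w0 %*% squeeze(f) + b0) + b1)`,
#' one multiplicative gate per channel, each strictly in (0, 1).
#'
#' @param f Feature map `H x W x C`.
#' @param params [ca_params()] consistent with C.
#' @return Numeric length-C vector of channel gates.
#' @export
channel_attention <- function(f, params) {
  d <- check_feature_map(f)
  if (ncol(params$w0) != d[3])
    stop_param("channel attention params expect %d channels, feature map has %d",
               ncol(params$w0), d[3])
  s <- channel_squeeze(f)
  r <- pmax(drop(params$w0 %*% s) + params$b0, 0)
  plogis(drop(params$w1 %*% r) + params$b1)
}

#' Apply a channel gate to a feature map
#'
#' `out[h, w, c] = a[c] * f[h, w, c]`, the gate broadcast over the spatial
#' dimensions.
#'
#' @param f Feature map `H x W x C`.
#' @param a Length-C gate vector.
#' @return Gated feature map, same shape.
#' @export
apply_channel <- function(f, a) {
  d <- check_feature_map(f)
  if (length(a) != d[3])
    stop_param("gate length %d does not match %d channels", length(a), d[3])
  f * rep(a, each = d[1] * d[2])
}

#' Channel-pooled spatial descriptors
#'
#' Per-position mean and maximum over the channel dimension, the two maps
#' that feed the spatial-attention convolution.
#'
#' @param f Feature map `H x W x C`.
#' @return List with `avg` and `max`, both `H x W` matrices.
#' @export
spatial_descriptors <- function(f) {
  d <- check_feature_map(f)
  m <- matrix(f, d[1] * d[2], d[3])
  mx <- do.call(pmax, lapply(seq_len(d[3]), function(c) m[, c]))
  list(avg = matrix(rowMeans(m), d[1], d[2]),
       max = matrix(mx, d[1], d[2]))
}

#' Spatial attention map
#'
#' `sigmoid(conv_kxk([avg, max]) + bias)` with zero ("same") padding, so the
#' attention map has the feature map's spatial dimensions; every entry is
#' strictly in (0, 1).
#'
#' @param f Feature map `H x W x C` (typically the channel-refined map).
#' @param params [sa_params()].
#' @return `H x W` matrix of spatial gates.
#' @export
spatial_attention <- function(f, params) {
  d <- check_feature_map(f)
  dsc <- spatial_descriptors(f)
  k <- dim(params$kernel)[1]
  x <- array(c(dsc$avg, dsc$max), c(d[1], d[2], 2, 1))
  kn <- array(params$kernel, c(k, k, 2, 1))
  u <- conv2d_fwd(x, kn, as.numeric(params$bias), 1L, as.integer((k - 1) / 2))
  plogis(matrix(u, d[1], d[2]))
}

#' Apply a spatial gate to a feature map
#'
#' `out[h, w, c] = a[h, w] * f[h, w, c]`, the gate broadcast over channels.
#'
#' @param f Feature map `H x W x C`.
#' @param a `H x W` gate matrix.
#' @return Gated feature map, same shape.
#' @export
apply_spatial <- function(f, a) {
  d <- check_feature_map(f)
  if (!identical(dim(a), d[1:2]))
    stop_param("spatial gate is %s, feature map is %dx%d",
               paste(dim(a), collapse = "x"), d[1], d[2])
  f * as.numeric(a)
}

normalize_variant <- function(variant) {
  v <- switch(variant, ca = "ca_only", sa = "sa_only", variant)
  if (!v %in% c("none", "ca_only", "sa_only", "sequential", "parallel"))
    stop_param("unknown attention variant '%s'", variant)
  v
}

#' Dual attention feature refinement
#'
#' Composes the channel and spatial attention gates over a feature map:
#' \describe{
#'   \item{none}{returns `f` unchanged (ablation baseline);}
#'   \item{ca_only / sa_only}{a single gate computed from `f`;}
#'   \item{sequential}{channel gate first, then the spatial gate computed
#'     from the channel-refined map (the configuration that performed best
#'     in ablation);}
#'   \item{parallel}{both gates computed from the raw `f` and applied as a
#'     joint broadcast product.}
#' }
#'
#' @param f Feature map `H x W x C`.
#' @param ca [ca_params()] (ignored for variants without a channel gate).
#' @param sa [sa_params()] (ignored for variants without a spatial gate).
#' @param variant One of `"none"`, `"ca_only"` (alias `"ca"`), `"sa_only"`
#'   (alias `"sa"`), `"sequential"`, `"parallel"`.
#' @return Refined feature map, same shape as `f`.
#' @export
dla_refine <- function(f, ca = NULL, sa = NULL, variant = "sequential") {
  variant <- normalize_variant(variant)
  switch(variant,
    none = f,
    ca_only = apply_channel(f, channel_attention(f, ca)),
    sa_only = apply_spatial(f, spatial_attention(f, sa)),
    sequential = {
      fc <- apply_channel(f, channel_attention(f, ca))
      apply_spatial(fc, spatial_attention(fc, sa))
    },
    parallel = {
      a_c <- channel_attention(f, ca)
      a_s <- spatial_attention(f, sa)
      apply_spatial(apply_channel(f, a_c), a_s)
    })
}
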