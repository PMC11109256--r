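# Independent reference implementations used as oracles. These are written
# with explicit scalar loops / base-R primitives only, deliberately sharing
# no code path with the package internals they check.

# Sequential dual-attention refinement, scalar loop reference.
ref_dla_sequential <- function(f, ca, sa) {
  H <- dim(f)[1]; W <- dim(f)[2]; C <- dim(f)[3]
  sig <- function(x) 1 / (1 + exp(-x))
  s <- numeric(C)
  for (c in 1:C) {
    acc <- 0
    for (h in 1:H) for (w in 1:W) acc <- acc + f[h, w, c]
    s[c] <- acc / (H * W)
  }
  nh <- nrow(ca$w0)
  q <- numeric(nh)
  for (i in 1:nh) {
    acc <- ca$b0[i]
    for (c in 1:C) acc <- acc + ca$w0[i, c] * s[c]
    q[i] <- max(acc, 0)
  }
  a <- numeric(C)
  for (c in 1:C) {
    acc <- ca$b1[c]
    for (i in 1:nh) acc <- acc + ca$w1[c, i] * q[i]
    a[c] <- sig(acc)
  }
  fc <- array(0, dim(f))
  for (h in 1:H) for (w in 1:W) for (c in 1:C) fc[h, w, c] <- a[c] * f[h, w, c]
  avg <- matrix(0, H, W); mx <- matrix(0, H, W)
  for (h in 1:H) for (w in 1:W) {
    tot <- 0; m <- -Inf
    for (c in 1:C) {
      tot <- tot + fc[h, w, c]
      if (fc[h, w, c] > m) m <- fc[h, w, c]
    }
    avg[h, w] <- tot / C; mx[h, w] <- m
  }
  k <- dim(sa$kernel)[1]; off <- (k - 1) / 2
  as_ <- matrix(0, H, W)
  for (h in 1:H) for (w in 1:W) {
    acc <- sa$bias
    for (kh in 1:k) for (kw in 1:k) {
      hh <- h + kh - 1 - off; ww <- w + kw - 1 - off
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
        acc <- acc + sa$kernel[kh, kw, 1] * avg[hh, ww] +
                     sa$kernel[kh, kw, 2] * mx[hh, ww]
    }
    as_[h, w] <- sig(acc)
  }
  out <- array(0, dim(f))
  for (h in 1:H) for (w in 1:W) for (c in 1:C) out[h, w, c] <- as_[h, w] * fc[h, w, c]
  out
}

# Count strict local maxima above a threshold (8-neighbourhood), used to
# count well-separated planted opacities.
count_peaks <- function(img, thr) {
  H <- nrow(img); W <- ncol(img)
  core <- img[2:(H - 1), 2:(W - 1)]
  is_peak <- core > thr
  for (dh in -1:1) for (dw in -1:1) {
    if (dh == 0 && dw == 0) next
    is_peak <- is_peak & (core > img[2:(H - 1) + dh, 2:(W - 1) + dw])
  }
  sum(is_peak)
}

# Two disjoint rectangles as a toy "lung" mask.
rect_mask <- function(H = 120, W = 260,
                      r1 = c(11, 100), c1 = c(31, 90),
                      r2 = c(16, 110), c2 = c(161, 230)) {
  m <- matrix(FALSE, H, W)
  m[r1[1]:r1[2], c1[1]:c1[2]] <- TRUE
  m[r2[1]:r2[2], c2[1]:c2[2]] <- TRUE
  m
}

# synthetic generator config kept small for fast tests
small_synth_config <- function(...) {
  synth_config(image_height = 128L, image_width = 128L, ...)
}
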