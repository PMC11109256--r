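# Internal compact CNN machinery: a three-block strided convolutional
# backbone, the dual attention refinement, a pooled softmax head, and
# reverse-mode gradients for all of it. Feature maps are dense arrays in
# (H, W, C, N) layout; convolutions run through the compiled kernels in
# src/. Everything here is deterministic given the RNG state.

nn_use_ca <- function(variant) variant %in% c("ca_only", "sequential", "parallel")
nn_use_sa <- function(variant) variant %in% c("sa_only", "sequential", "parallel")

nn_init_params <- function(variant, channels = c(8L, 16L, 32L), in_channels = 1L,
                           num_classes = 4L, ratio = 16L, sa_kernel = 7L) {
  conv_init <- function(kh, kw, ci, co)
    array(rnorm(kh * kw * ci * co, 0, sqrt(2 / (kh * kw * ci))), c(kh, kw, ci, co))
  C <- channels[3]
  p <- list(
    conv1_w = conv_init(3, 3, in_channels, channels[1]), conv1_b = numeric(channels[1]),
    conv2_w = conv_init(3, 3, channels[1], channels[2]), conv2_b = numeric(channels[2]),
    conv3_w = conv_init(3, 3, channels[2], channels[3]), conv3_b = numeric(channels[3]))
  if (nn_use_ca(variant)) {
    ca <- ca_params(C, ratio)
    p$ca_w0 <- ca$w0; p$ca_b0 <- ca$b0; p$ca_w1 <- ca$w1; p$ca_b1 <- ca$b1
  }
  if (nn_use_sa(variant)) {
    sa <- sa_params(kernel_size = sa_kernel)
    p$sa_w <- sa$kernel; p$sa_b <- sa$bias
  }
  p$fc_w <- matrix(rnorm(num_classes * C, 0, sqrt(2 / C)), num_classes, C)
  p$fc_b <- numeric(num_classes)
  p
}

# channel-block descriptor helpers on an (H, W, C, N) array
nn_channel_stats <- function(S, hw, C, N) {
  m <- matrix(S, hw)
  avgm <- matrix(0, hw, N); maxm <- matrix(0, hw, N); amax <- matrix(0L, hw, N)
  for (n in seq_len(N)) {
    blk <- m[, ((n - 1) * C + 1):(n * C), drop = FALSE]
    avgm[, n] <- rowMeans(blk)
    amax[, n] <- max.col(blk, ties.method = "first")
    maxm[, n] <- blk[cbind(seq_len(hw), amax[, n])]
  }
  list(avg = avgm, max = maxm, amax = amax)
}

nn_forward <- function(params, x, variant, keep = FALSE) {
  relu <- function(z) { z[z < 0] <- 0; z }
  z1 <- conv2d_fwd(x, params$conv1_w, params$conv1_b, 2L, 1L); a1 <- relu(z1)
  z2 <- conv2d_fwd(a1, params$conv2_w, params$conv2_b, 2L, 1L); a2 <- relu(z2)
  z3 <- conv2d_fwd(a2, params$conv3_w, params$conv3_b, 2L, 1L); F <- relu(z3)
  d <- dim(F); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; hw <- H * W
  use_ca <- nn_use_ca(variant); use_sa <- nn_use_sa(variant)
  cache <- if (keep) list(x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2, z3 = z3, F = F)
           else list()

  FC <- F; Ec <- NULL
  if (use_ca) {
    s <- matrix(colMeans(matrix(F, hw)), C, N)
    q <- params$ca_w0 %*% s + params$ca_b0
    r <- pmax(q, 0)
    a <- plogis(params$ca_w1 %*% r + params$ca_b1)
    Ec <- rep(as.numeric(a), each = hw)
    FC <- F * Ec; dim(FC) <- d
    if (keep) cache[c("s", "q", "r", "a", "Ec", "FC")] <- list(s, q, r, a, Ec, FC)
  }
  Fcs <- FC
  if (use_sa) {
    S <- if (variant == "sequential") FC else F
    st <- nn_channel_stats(S, hw, C, N)
    D <- array(0, c(H, W, 2, N))
    D[, , 1, ] <- st$avg; D[, , 2, ] <- st$max
    k <- dim(params$sa_w)[1]
    u <- conv2d_fwd(D, array(params$sa_w, c(k, k, 2, 1)), params$sa_b,
                    1L, as.integer((k - 1) / 2))
    As <- plogis(matrix(u, hw, N))
    Es <- As[, rep(seq_len(N), each = C), drop = FALSE]
    Fcs <- FC * as.numeric(Es); dim(Fcs) <- d
    if (keep) cache[c("D", "amax", "As", "Es")] <- list(D, st$amax, As, Es)
  }
  g <- matrix(colMeans(matrix(Fcs, hw)), C, N)
  logits <- params$fc_w %*% g + params$fc_b
  m0 <- apply(logits, 2, max)
  el <- exp(logits - rep(m0, each = nrow(logits)))
  probs <- el / rep(colSums(el), each = nrow(logits))
  if (keep) cache[c("Fcs", "g", "probs", "dims")] <- list(Fcs, g, probs, d)
  list(probs = probs, cache = cache)
}

# Cross-entropy loss and full parameter gradients for one batch.
# y: integer class indices 1..K; weights: optional per-class weights.
nn_loss_grad <- function(params, x, y, variant, class_weights = NULL) {
  fw <- nn_forward(params, x, variant, keep = TRUE)
  cc <- fw$cache
  d <- cc$dims; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; hw <- H * W
  K <- nrow(cc$probs)
  sw <- if (is.null(class_weights)) rep(1, N) else class_weights[y]
  py <- cc$probs[cbind(y, seq_len(N))]
  loss <- -sum(sw * log(pmax(py, 1e-12))) / sum(sw)
  Y <- matrix(0, K, N); Y[cbind(y, seq_len(N))] <- 1
  dlogits <- (cc$probs - Y) * rep(sw, each = K) / sum(sw)

  g <- cc$g
  grads <- list(fc_w = dlogits %*% t(g), fc_b = rowSums(dlogits))
  dg <- t(params$fc_w) %*% dlogits
  dFcs <- rep(as.numeric(dg), each = hw) / hw
  dim(dFcs) <- d

  use_ca <- nn_use_ca(variant); use_sa <- nn_use_sa(variant)
  FC <- if (use_ca) cc$FC else cc$F
  dF_extra <- NULL
  if (use_sa) {
    T1 <- matrix(dFcs * FC, hw)
    dAs <- matrix(0, hw, N)
    for (n in seq_len(N))
      dAs[, n] <- rowSums(T1[, ((n - 1) * C + 1):(n * C), drop = FALSE])
    dFC <- dFcs * as.numeric(cc$Es); dim(dFC) <- d
    du <- dAs * cc$As * (1 - cc$As)
    k <- dim(params$sa_w)[1]
    bw <- conv2d_bwd(cc$D, array(params$sa_w, c(k, k, 2, 1)),
                     array(du, c(H, W, 1, N)), 1L, as.integer((k - 1) / 2), TRUE)
    grads$sa_w <- array(bw$dw, c(k, k, 2))
    grads$sa_b <- bw$db
    davg <- matrix(bw$dx[, , 1, ], hw, N)
    dmax <- matrix(bw$dx[, , 2, ], hw, N)
    dSm <- matrix(0, hw, C * N)
    for (n in seq_len(N)) {
      cols <- ((n - 1) * C + 1):(n * C)
      dSm[, cols] <- davg[, n] / C
      idx <- cbind(seq_len(hw), (n - 1) * C + cc$amax[, n])
      dSm[idx] <- dSm[idx] + dmax[, n]
    }
    if (variant == "sequential") {
      dFC <- dFC + as.numeric(dSm); dim(dFC) <- d
    } else {
      dF_extra <- dSm
    }
  } else {
    dFC <- dFcs
  }

  if (use_ca) {
    T2 <- matrix(dFC * cc$F, hw)
    da <- matrix(colSums(T2), C, N)
    dF <- dFC * cc$Ec
    dv <- da * cc$a * (1 - cc$a)
    grads$ca_w1 <- dv %*% t(cc$r)
    grads$ca_b1 <- rowSums(dv)
    dq <- (t(params$ca_w1) %*% dv) * (cc$q > 0)
    grads$ca_w0 <- dq %*% t(cc$s)
    grads$ca_b0 <- rowSums(dq)
    ds <- t(params$ca_w0) %*% dq
    dF <- dF + rep(as.numeric(ds), each = hw) / hw
  } else {
    dF <- dFC
  }
  if (!is.null(dF_extra)) dF <- dF + as.numeric(dF_extra)
  dim(dF) <- d

  dz3 <- dF; dz3[cc$z3 <= 0] <- 0
  bw3 <- conv2d_bwd(cc$a2, params$conv3_w, dz3, 2L, 1L, TRUE)
  grads$conv3_w <- bw3$dw; grads$conv3_b <- bw3$db
  dz2 <- bw3$dx; dz2[cc$z2 <= 0] <- 0
  bw2 <- conv2d_bwd(cc$a1, params$conv2_w, dz2, 2L, 1L, TRUE)
  grads$conv2_w <- bw2$dw; grads$conv2_b <- bw2$db
  dz1 <- bw2$dx; dz1[cc$z1 <= 0] <- 0
  bw1 <- conv2d_bwd(cc$x, params$conv1_w, dz1, 2L, 1L, FALSE)
  grads$conv1_w <- bw1$dw; grads$conv1_b <- bw1$db

  list(loss = loss, grads = grads, probs = cc$probs)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# stack a list of equally sized matrices (or an H x W x N array) into the
# (H, W, 1, N) input layout
nn_stack_input <- function(x) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    arr <- array(unlist(x, use.names = FALSE), c(d[1], d[2], length(x)))
  } else if (is.matrix(x)) {
    arr <- array(x, c(dim(x), 1L))
  } else arr <- x
  d <- dim(arr)
  array(arr, c(d[1], d[2], 1L, d[3]))
}
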