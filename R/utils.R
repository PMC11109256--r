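# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stable per-item RNG stream derived from a master seed: a small
# multiplicative hash kept below 2^31 so subsets of a dataset are
# reproducible regardless of generation order. Exact in double precision.
derive_stream_seed <- function(master, index) {
  m <- as.numeric(master) %% 94906265
  as.integer((m * 22695477 + as.numeric(index) * 7919 + 1) %% 2147483647)
}

# round-half-away-from-zero (base round() is round-half-even)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_binary_mask <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

as_mask <- function(m) {
  if (!is_binary_mask(m)) stop("mask must be a binary (0/1 or logical) matrix")
  if (!is.logical(m)) m <- m > 0.5
  m
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)
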