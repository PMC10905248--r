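# internal helpers shared across modules

# Evaluate expr under a temporary RNG state so package functions that take a
# `seed` argument never disturb the caller's random stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 32-bit FNV-1a hash of a character string; used to fan a master seed out
# into per-stage sub-seeds and to fingerprint configs. Arithmetic is done in
# doubles (exact below 2^53) with explicit mod 2^32.
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # xor for doubles holding 32-bit unsigned values
  r <- 0; p <- 1
  for (i in 1:32) {
    ab <- a %% 2; bb <- b %% 2
    if (ab != bb) r <- r + p
    a <- (a - ab) / 2; b <- (b - bb) / 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Hashing the master seed together with a stage label gives every stochastic
#' stage its own reproducible stream without reusing the master seed.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return an integer in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stage) {
  as.integer(fnv1a(paste0(master, "/", stage)) %% 2147483647)
}

# truncated Gaussian convolution kernel (1-D weights), sd in cells
gauss_kernel <- function(sd_cells) {
  r <- max(1L, ceiling(3 * sd_cells))
  w <- exp(-(seq(-r, r))^2 / (2 * sd_cells^2))
  w / sum(w)
}

# separable 2-D Gaussian smoothing of a matrix with zero-padding at edges;
# if renormalize, per-cell division by the smoothed all-ones matrix removes
# the edge attenuation.
smooth_matrix <- function(m, sd_cells, renormalize = TRUE) {
  if (sd_cells <= 0) return(m)
  k <- gauss_kernel(sd_cells)
  sm <- conv_rows(conv_cols(m, k), k)
  if (renormalize) {
    ones <- matrix(1, nrow(m), ncol(m))
    norm <- conv_rows(conv_cols(ones, k), k)
    sm <- sm / norm
  }
  sm
}

conv_cols <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) {
    off <- i - r - 1L
    src <- seq_len(nrow(m)) + off
    ok <- src >= 1 & src <= nrow(m)
    out[ok, ] <- out[ok, ] + k[i] * m[src[ok], , drop = FALSE]
  }
  out
}

conv_rows <- function(m, k) t(conv_cols(t(m), k))
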