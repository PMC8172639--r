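# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic substream seeds: a stable string hash folded with the global
## seed, so each (method, sample, replicate) table gets its own reproducible
## stream and adding tables never perturbs existing ones.  All arithmetic
## stays below 2^53 so doubles are exact; results fit in a 32-bit seed.
.MOD31 <- 2147483647

.string_hash <- function(key) {
  h <- 5381
  for (c in utf8ToInt(key)) h <- (h * 33 + c) %% .MOD31
  h
}

substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- .string_hash(key)
  s <- (abs(seed) %% .MOD31) * 48271 %% .MOD31
  out <- (h + s) %% .MOD31
  as.integer(max(out, 1))
}

with_substream <- function(seed, key, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(substream_seed(seed, key))
  }
  force(expr)
}

## lognormal with unit mean and given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## finite-difference Hessian (central differences); avoids an extra dependency
num_hessian <- function(f, x, eps = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  h <- pmax(abs(x), 1) * eps
  for (i in seq_len(k)) {
    for (j in i:k) {
      xpp <- x; xpp[i] <- xpp[i] + h[i]; xpp[j] <- xpp[j] + h[j]
      xpm <- x; xpm[i] <- xpm[i] + h[i]; xpm[j] <- xpm[j] - h[j]
      xmp <- x; xmp[i] <- xmp[i] - h[i]; xmp[j] <- xmp[j] + h[j]
      xmm <- x; xmm[i] <- xmm[i] - h[i]; xmm[j] <- xmm[j] - h[j]
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}
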