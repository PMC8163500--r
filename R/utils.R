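#' @keywords internal
"_PACKAGE"

## Argument checking helpers -------------------------------------------------

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}

is_scalar_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

#' Derive a child seed from a master seed
#'
#' All stochastic operations in the package take an explicit integer seed.
#' Stages and per-participant streams derive their own seeds from a master
#' seed with this function, keeping every derived seed a valid 32-bit
#' integer. The derivation is a fixed affine map modulo the largest R
#' integer, so a run is fully reproducible from its master seed alone.
#'
#' @param seed master seed (integer).
#' @param k stream index (non-negative integer).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  stop_if_not(is_scalar_num(seed), "`seed` must be a single number")
  stop_if_not(is_scalar_num(k) && k >= 0, "`k` must be a non-negative number")
  m <- 2147483629 # largest prime below 2^31 - 1
  s0 <- abs(seed) %% m
  as.integer((s0 * 48271 + 75003 * (k + 1)) %% m) + 1L
}

## Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
## stream is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

## Paired / one-sample t statistic with degenerate-case conventions used
## throughout: an all-zero difference vector gives t = 0 (not NaN), so
## exchangeable-null permutation p-values stay well defined; a constant
## nonzero difference gives signed Inf.
t_stat <- function(d) {
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) return(if (m == 0) 0 else sign(m) * Inf)
  m / (s / sqrt(n))
}

cohens_d <- function(d) {
  s <- stats::sd(d)
  if (s == 0) return(0)
  mean(d) / s
}

## Moving average with reflect padding, centered window of `w` samples.
moving_average_reflect <- function(x, w) {
  n <- length(x)
  stop_if_not(w >= 2, "smoothing window must span at least 2 samples")
  stop_if_not(w <= n, "smoothing window longer than the signal")
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  xp <- c(rev(x[seq_len(left) + 1L]), x, rev(x[n - seq_len(right)]))
  cs <- c(0, cumsum(xp))
  (cs[(w + 1L):(n + w)] - cs[seq_len(n)]) / w
}
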