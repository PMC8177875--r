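# Internal helpers: condition classes, seeded evaluation, zero-phase filtering.

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("megalpha_invalid_argument", "megalpha_error")))
}

stop_insufficient <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("megalpha_insufficient_data", "megalpha_error")))
}

stop_undefined <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("megalpha_undefined_value", "megalpha_error")))
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
# Guarantees bit-identical output for identical (expr, seed) without
# perturbing the global random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_invalid("seed must be a single non-missing number, got %s",
                 deparse(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# Derive a stream of child seeds (< 2^31) from a master seed.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @importFrom signal butter filter
NULL

# Forward-backward (zero-phase) IIR filtering with odd reflection padding at
# both ends: avoids the startup transients of plain forward-backward
# filtering on finite records. npad must cover the filter's settling time
# (~3 time constants of its slowest pole), so callers with low-frequency
# edges pass a padding proportional to fs / f_edge.
filtfilt_pad <- function(filt, x, npad = NULL) {
  b <- filt$b
  a <- filt$a
  nfilt <- max(length(a), length(b))
  if (is.null(npad)) npad <- 3L * (nfilt - 1L)
  npad <- as.integer(npad)
  n <- length(x)
  if (npad >= n)
    stop_invalid("signal too short (%d samples) for zero-phase filtering (needs > %d)",
                 n, npad)
  # odd reflection: 2*x[1] - x[(npad+1):2], etc.
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  xp <- c(pre, x, post)
  y <- iir_filter_cpp(b, a, xp)
  y <- rev(iir_filter_cpp(b, a, rev(y)))
  y[seq(npad + 1L, npad + n)]
}

# Apply filtfilt_pad to every row of a channels x samples matrix.
filtfilt_rows <- function(filt, data, npad = NULL) {
  out <- t(apply(data, 1L, function(ch) filtfilt_pad(filt, ch, npad)))
  dimnames(out) <- dimnames(data)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
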