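# internal helpers shared across modules

# fail fast with a caller-facing message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, call = NULL)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

# deterministic child seeds derived from one base seed; kept < 2^31
derive_seed <- function(seed, ...) {
  key <- c(seed, ...)
  s <- 0
  for (k in key) s <- (s * 69069 + (as.numeric(k) %% 2147483647)) %% 2147483647
  as.integer(s %% 2147483629 + 1)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# raised-cosine ramp from 0 to 1 over [0, width]
cos_ramp <- function(t, width) {
  r <- (1 - cos(pi * pmin(pmax(t / width, 0), 1))) / 2
  r[width <= 0] <- as.numeric(t[width <= 0] >= 0)
  r
}

# 1/f-amplitude-weighted Gaussian noise, one column per series,
# standardized to unit SD per column
pink_noise <- function(n, n_series = 1, alpha = 1) {
  if (n < 4) return(matrix(rnorm(n * n_series), n))
  white <- matrix(rnorm(n * n_series), n)
  spec <- stats::mvfft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # two-sided frequency index
  w <- 1 / f^(alpha / 2)
  w[1] <- 0 # zero out DC so baselines stay centred
  y <- Re(stats::mvfft(spec * w, inverse = TRUE)) / n
  scale(y)[, , drop = FALSE]
}
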