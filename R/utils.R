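logistic <- function(x) 1 / (1 + exp(-x))

# Deterministic 32-bit seed derived from a master seed and a stage label, so
# per-stage streams are independent and adding a stage never perturbs others.
derive_seed <- function(master, ...) {
  h <- as.double(master) %% 2147483647
  for (tok in unlist(list(...))) {
    for (code in utf8ToInt(as.character(tok))) {
      h <- (h * 31 + code) %% 2147483647
    }
  }
  as.integer(h %% 2147483646) + 1L
}

# Separable Gaussian blur of a matrix, kernel sd `sigma` in cells, with
# edge renormalization (rows of the smoothing operator sum to 1).
smooth_matrix <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  op <- function(n) {
    s <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - half):min(n, i + half)
      w <- k[j - i + half + 1L]
      s[i, j] <- w / sum(w)
    }
    s
  }
  op(nrow(x)) %*% x %*% t(op(ncol(x)))
}

# Smoothed standard-normal random field (mean 0, sd 1 after rescaling).
gaussian_field <- function(n_rows, n_cols, autocorr_range_cells) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  f <- smooth_matrix(z, autocorr_range_cells / 2)
  (f - mean(f)) / stats::sd(f)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}
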