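# Shared fixtures and independent brute-force oracles.

# small phantom for fast tests
small_config <- function(...) {
  phantom_config(n_slices = 12, ...)
}

# tiny-FOV phantom (coarse pixels) for many-slice tests
coarse_config <- function(...) {
  phantom_config(slice_shape = c(32L, 32L), pixel_spacing = 500 / 32, ...)
}

# two-region vertical step image: left half `lo`, right half `hi`, plus
# i.i.d. Gaussian noise of SD `sigma`
step_image <- function(n = 96, lo = 0, hi = 200, sigma = 5, seed = 42) {
  set.seed(seed)
  px <- matrix(lo, n, n)
  px[, (n %/% 2 + 1):n] <- hi
  px + matrix(rnorm(n * n, sd = sigma), n, n)
  }

step_regions <- function(n = 96) {
  left <- matrix(FALSE, n, n); left[, 1:(n %/% 2)] <- TRUE
  list(left = left, right = !left)
}

# brute-force windowed same-region sample SD at pixel (i, j)
bf_window_sd <- function(px, region, i, j, hw = 5, min_support = 10) {
  rs <- max(1, i - hw):min(nrow(px), i + hw)
  cs <- max(1, j - hw):min(ncol(px), j + hw)
  vals <- px[rs, cs][region[rs, cs]]
  if (length(vals) < min_support) return(NA_real_)
  sd(vals)
}

# brute-force Otsu: exhaustive search over all bin boundaries
bf_otsu <- function(v, range = c(-1024, 1500), bins = 256L) {
  v <- pmin(pmax(as.numeric(v), range[1]), range[2])
  width <- diff(range) / bins
  idx <- pmin(floor((v - range[1]) / width) + 1, bins)
  mids <- range[1] + (idx - 0.5) * width   # bin-quantized values
  best <- -Inf; best_t <- NA
  for (t in seq_len(bins - 1)) {
    thr <- range[1] + t * width
    lo <- mids[mids < thr]; hi <- mids[mids >= thr]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(mids); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_t <- thr }
  }
  best_t
}

# integer-shift a matrix, filling vacated pixels with `fill`
shift_matrix <- function(m, dr, dc, fill = -1000) {
  out <- matrix(fill, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dr
  src_c <- seq_len(ncol(m)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

label_is_body <- function(lab) {
  b <- lab == "lung" | lab == "soft" | lab == "bone"
  dim(b) <- dim(lab)
  b
}

# erode a logical mask by k pixels (square structuring element)
erode_k <- function(mask, k) {
  m <- mask
  for (dr in -k:k) for (dc in -k:k) {
    m <- m & shift_matrix(mask * 1, dr, dc, fill = 0) > 0
  }
  m
}
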