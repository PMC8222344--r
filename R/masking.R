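#' Otsu threshold of an HU image
#'
#' Histogram-based Otsu threshold: values are clipped to `range`, binned
#' into `bins` equal-width bins, and the bin boundary maximizing the
#' between-class variance of the two resulting classes is returned, in HU.
#' The fixed default clip range covers the diagnostic HU scale so that the
#' binning (and hence the threshold) is reproducible across slices.
#'
#' @param pixels numeric matrix or vector of HU values.
#' @param range clip range used for binning.
#' @param bins number of histogram bins.
#' @return the threshold (a bin boundary, HU); pixels `>= threshold` form
#'   the upper (body) class.
#' @export
otsu_threshold <- function(pixels, range = c(-1024, 1500), bins = 256L) {
  v <- as.numeric(pixels)
  if (length(unique(v)) < 2)
    stop("image is constant; no separable classes for Otsu", call. = FALSE)
  v <- pmin(pmax(v, range[1]), range[2])
  width <- diff(range) / bins
  # bin index 1..bins; right edge closed into the last bin
  idx <- pmin(floor((v - range[1]) / width) + 1, bins)
  counts <- tabulate(idx, nbins = bins)
  mids <- range[1] + (seq_len(bins) - 0.5) * width

  w <- cumsum(counts)                      # pixels in bins 1..t (lower class)
  m <- cumsum(counts * mids)
  n <- w[bins]; mu_tot <- m[bins] / n
  # candidate thresholds are the boundaries after bin t, t = 1..bins-1
  t <- seq_len(bins - 1)
  w0 <- w[t]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[t] / w0
  mu1 <- (m[bins] - m[t]) / w1
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  best <- which.max(bcv)
  range[1] + best * width
}

#' Body contour mask of a slice
#'
#' Thresholds the slice at its Otsu threshold, closes the result
#' morphologically (disc), discards every connected component whose
#' bounding box touches the bottom image edge (which rejects the table,
#' rendered or real, hanging from the bottom of the field of view), keeps
#' the largest remaining component and fills its holes so that lungs count
#' as body. All downstream region analysis runs inside this mask only.
#'
#' @param slice a [ct_slice()] or a numeric HU matrix.
#' @param closing_radius disc radius (pixels) of the morphological closing;
#'   0 disables it.
#' @param exclude_bottom drop components touching the bottom edge (the
#'   table/mattress rejection rule); set `FALSE` for images known to hold
#'   the body only.
#' @param fill_holes fill interior holes of the retained component.
#' @return an object of class `body_mask`: list with the logical `mask`,
#'   `pixel_count` and `threshold_hu`.
#' @export
body_mask <- function(slice, closing_radius = 3, exclude_bottom = TRUE,
                      fill_holes = TRUE) {
  px <- if (inherits(slice, "ct_slice")) slice$pixels else slice
  thr <- otsu_threshold(px)
  bw <- (px >= thr) * 1
  # select the body component before closing, so the closing cannot
  # bridge the body to a nearby (already rejected) table slab
  lab <- EBImage::bwlabel(bw)
  ncomp <- max(lab)
  if (ncomp == 0)
    stop("no body component found (empty mask)", call. = FALSE)
  keep <- seq_len(ncomp)
  if (exclude_bottom) {
    bottom <- unique(lab[nrow(lab), ])
    keep <- setdiff(keep, bottom[bottom > 0])
  }
  if (!length(keep))
    stop("no body component found (empty mask)", call. = FALSE)
  sizes <- tabulate(lab[lab > 0], nbins = ncomp)
  largest <- keep[which.max(sizes[keep])]
  m <- (lab == largest) * 1
  if (closing_radius > 0) {
    kern <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    m <- EBImage::closing(m, kern)
  }
  if (fill_holes) m <- EBImage::fillHull(m)
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  structure(list(mask = m, pixel_count = sum(m), threshold_hu = thr),
            class = "body_mask")
}

#' @export
print.body_mask <- function(x, ...) {
  cat(sprintf("<body_mask> %d px at Otsu threshold %.1f HU\n",
              x$pixel_count, x$threshold_hu))
  invisible(x)
}

#' Export a mask as a PNG for visual inspection
#'
#' @param mask a `body_mask` or logical matrix.
#' @param path output PNG file.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "body_mask")) mask$mask else mask
  EBImage::writeImage(EBImage::Image(t(m) * 1), path)
  invisible(path)
}
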