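# Windowed sums over a (2*hw+1)^2 neighbourhood, truncated at the image
# borders, via a padded summed-area table. Exact up to floating rounding.
window_sums <- function(M, hw) {
  n <- nrow(M); m <- ncol(M)
  P <- matrix(0, n + 1, m + 1)
  P[-1, -1] <- apply(apply(M, 2, cumsum), 1, cumsum) |> t()
  rlo <- pmax(seq_len(n) - hw, 1); rhi <- pmin(seq_len(n) + hw, n)
  clo <- pmax(seq_len(m) - hw, 1); chi <- pmin(seq_len(m) + hw, m)
  P[rhi + 1, chi + 1, drop = FALSE] - P[rlo, chi + 1, drop = FALSE] -
    P[rhi + 1, clo, drop = FALSE] + P[rlo, clo, drop = FALSE]
}

# Local sample SD (denominator n-1) of `pixels` over the pixels selected by
# `support`, evaluated with a sliding square window; NA where the window
# holds fewer than `min_support` supported pixels. The image is centred on
# the support mean first: the SD is shift-invariant and the centring keeps
# the sum-of-squares cancellation benign.
windowed_sd <- function(pixels, support, half_width, min_support) {
  sup <- support * 1
  mu <- mean(pixels[support])
  x <- (pixels - mu) * sup
  n <- window_sums(sup, half_width)
  s1 <- window_sums(x, half_width)
  s2 <- window_sums(x * x, half_width)
  v <- (s2 - s1 * s1 / n) / (n - 1)
  out <- sqrt(pmax(v, 0))
  out[n < min_support] <- NA_real_
  out
}

#' Local noise map of one tissue region
#'
#' For every pixel of the region, the local noise is the sample standard
#' deviation (denominator n-1) of the HU values of *same-region* pixels
#' inside the square window `i-hw..i+hw`, `j-hw..j+hw` (truncated at the
#' image borders, no padding). Restricting the window to the region keeps
#' windows straddling a tissue boundary from reading the HU step between
#' materials as noise. Pixels whose window holds fewer than `min_support`
#' same-region pixels are left undefined rather than estimated from too
#' few samples.
#'
#' @param slice a [ct_slice()] or HU matrix.
#' @param region logical matrix selecting the region's pixels (e.g. one
#'   label of [segment_tissues()]).
#' @param half_width window half-width `hw` in pixels; the default 5 gives
#'   an 11 x 11 window.
#' @param min_support minimum same-region pixels per window.
#' @return an object of class `noise_map`: list with `values` (numeric
#'   matrix, `NA` where undefined), `region` (the input support) and the
#'   parameters.
#' @export
region_noise_map <- function(slice, region, half_width = 5,
                             min_support = 10) {
  px <- if (inherits(slice, "ct_slice")) slice$pixels else slice
  stopifnot(identical(dim(px), dim(region)), half_width >= 1,
            min_support >= 2)
  vals <- matrix(NA_real_, nrow(px), ncol(px))
  if (any(region)) {
    sd_all <- windowed_sd(px, region, half_width, min_support)
    vals[region] <- sd_all[region]
  }
  structure(list(values = vals, region = region, half_width = half_width,
                 min_support = min_support),
            class = "noise_map")
}

#' Naive whole-image local noise map
#'
#' The same sliding-window standard deviation, but computed over every
#' pixel of the support without tissue awareness. Windows straddling a
#' boundary between two materials then include the HU step and
#' over-estimate the noise there; this estimator exists as the comparison
#' baseline that motivates the region-restricted map.
#'
#' @inheritParams region_noise_map
#' @param support logical matrix of pixels to evaluate (default: all).
#' @export
naive_noise_map <- function(slice, support = NULL, half_width = 5,
                            min_support = 10) {
  px <- if (inherits(slice, "ct_slice")) slice$pixels else slice
  if (is.null(support)) support <- matrix(TRUE, nrow(px), ncol(px))
  region_noise_map(px, support, half_width, min_support)
}

#' Union of per-region noise maps
#'
#' Combines region maps from one slice into the global map: each defined
#' pixel carries exactly the value of its own region's map, with no
#' cross-region mixing. Overlapping defined sets violate the tissue
#' partition and are rejected.
#'
#' @param region_maps list of `noise_map` objects from the same slice.
#' @return a `noise_map` whose defined set is the disjoint union of the
#'   inputs'.
#' @export
global_noise_map <- function(region_maps) {
  stopifnot(length(region_maps) >= 1,
            all(vapply(region_maps, inherits, TRUE, "noise_map")))
  vals <- region_maps[[1]]$values
  region <- region_maps[[1]]$region
  if (length(region_maps) > 1) {
    for (k in 2:length(region_maps)) {
      nk <- region_maps[[k]]
      stopifnot(identical(dim(nk$values), dim(vals)))
      both <- !is.na(vals) & !is.na(nk$values)
      if (any(both))
        stop("region noise maps overlap; regions must partition the body",
             call. = FALSE)
      take <- !is.na(nk$values)
      vals[take] <- nk$values[take]
      region <- region | nk$region
    }
  }
  structure(list(values = vals, region = region,
                 half_width = region_maps[[1]]$half_width,
                 min_support = region_maps[[1]]$min_support),
            class = "noise_map")
}

#' Global noise level of a map
#'
#' The arithmetic mean of the map over its defined pixels.
#'
#' @param map a `noise_map`.
#' @return mean local noise, HU.
#' @export
global_noise_level <- function(map) {
  stopifnot(inherits(map, "noise_map"))
  v <- map$values[!is.na(map$values)]
  if (!length(v)) stop("noise map has no defined pixel", call. = FALSE)
  mean(v)
}

#' @export
print.noise_map <- function(x, ...) {
  nd <- sum(!is.na(x$values))
  cat(sprintf("<noise_map> %d defined px, window %dx%d, mean %.2f HU\n",
              nd, 2 * x$half_width + 1, 2 * x$half_width + 1,
              if (nd) mean(x$values, na.rm = TRUE) else NA))
  invisible(x)
}

#' Mean local noise of one tissue on one slice
#'
#' Builds the tissue's region noise map and averages it. Returns `NA`
#' (absent, not zero) when the tissue is missing from the slice or too
#' sparse to yield at least `min_support` defined pixels, so that profile
#' means are not dragged down by empty slices.
#'
#' @param slice a [ct_slice()] or HU matrix.
#' @param labels a `tissue_labels` matrix from [segment_tissues()].
#' @param tissue label name, e.g. `"lung"` or `"soft"`.
#' @inheritParams region_noise_map
#' @return mean noise in HU, or `NA_real_`.
#' @export
slice_tissue_noise <- function(slice, labels, tissue, half_width = 5,
                               min_support = 10) {
  region <- unclass(labels) == tissue
  if (!any(region)) return(NA_real_)
  nm <- region_noise_map(slice, region, half_width, min_support)
  v <- nm$values[!is.na(nm$values)]
  if (length(v) < min_support) return(NA_real_)
  mean(v)
}
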