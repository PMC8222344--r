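#' Tissue Hounsfield ranges
#'
#' Closed-open `[lo, hi)` HU intervals assigning body pixels to lung, soft
#' tissue or bone. The defaults leave a wide guard band between classes so
#' that realistic noise levels rarely flip an interior pixel; they are
#' fully configurable because reference cut-offs vary across sites.
#'
#' @param lung,soft,bone length-2 numeric `(lo, hi)` intervals.
#' @return a named list of class `hu_ranges`.
#' @export
hu_ranges <- function(lung = c(-950, -300), soft = c(-100, 200),
                      bone = c(200, 3000)) {
  r <- list(lung = as.numeric(lung), soft = as.numeric(soft),
            bone = as.numeric(bone))
  for (nm in names(r))
    if (length(r[[nm]]) != 2 || r[[nm]][1] >= r[[nm]][2])
      stop("range '", nm, "' must be (lo, hi) with lo < hi", call. = FALSE)
  nms <- names(r)
  for (i in seq_along(r)) for (j in seq_along(r)) {
    if (i >= j) next
    if (r[[i]][1] < r[[j]][2] && r[[j]][1] < r[[i]][2])
      stop("HU ranges '", nms[i], "' and '", nms[j], "' overlap",
           call. = FALSE)
  }
  structure(r, class = "hu_ranges")
}

#' Segment body pixels into tissue classes
#'
#' Assigns each pixel inside the body mask to the unique closed-open HU
#' interval containing it (`lo <= HU < hi`); body pixels in no interval
#' are `"unassigned"` and are excluded from all noise maps, since they sit
#' between classes (typically on material boundaries). Pixels outside the
#' mask are always `"outside"`.
#'
#' @param slice a [ct_slice()] or HU matrix.
#' @param mask a [body_mask()] (or logical matrix) for the same slice.
#' @param ranges a [hu_ranges()].
#' @return a character matrix of class `tissue_labels` with levels
#'   `outside`, `unassigned`, and the range names.
#' @export
segment_tissues <- function(slice, mask, ranges = hu_ranges()) {
  px <- if (inherits(slice, "ct_slice")) slice$pixels else slice
  m <- if (inherits(mask, "body_mask")) mask$mask else mask
  stopifnot(identical(dim(px), dim(m)))
  if (!any(m)) stop("body mask is empty", call. = FALSE)
  if (!inherits(ranges, "hu_ranges"))
    ranges <- do.call(hu_ranges, ranges)
  lab <- matrix("outside", nrow(px), ncol(px))
  lab[m] <- "unassigned"
  for (nm in names(ranges)) {
    hit <- m & px >= ranges[[nm]][1] & px < ranges[[nm]][2]
    lab[hit] <- nm
  }
  class(lab) <- c("tissue_labels", class(lab))
  lab
}

#' Count pixels per tissue label
#'
#' @param labels a `tissue_labels` matrix.
#' @return named integer vector over the labels present.
#' @export
tissue_counts <- function(labels) {
  tab <- table(unclass(labels))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
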