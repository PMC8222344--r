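#' Barycentre off-centering of one slice
#'
#' The body centre is the unweighted barycentre of the masked pixels
#' (pixel centres, converted to mm); the image centre is the pixel-centre
#' convention `((cols - 1)/2, (rows - 1)/2)` scaled by the spacing. The
#' deviation is barycentre minus image centre, with `x` increasing with
#' column index and `y` increasing downwards, so a body *above* the
#' isocentre has negative `dy`.
#'
#' @param slice a [ct_slice()] (used for pixel spacing) or an HU matrix
#'   with `pixel_spacing` supplied.
#' @param mask a [body_mask()] or logical matrix.
#' @param pixel_spacing `(row, col)` mm, required when `slice` is a bare
#'   matrix.
#' @param hu_weighted weight pixels by `HU + 1000` instead of uniformly;
#'   off by default (the barycentre of the *pixels*).
#' @return list of class `centering_result` with `barycentre_mm` (x, y),
#'   `deviation_mm` (dx, dy) and `magnitude_mm`; `NULL` for an empty mask.
#' @export
barycentre_deviation <- function(slice, mask, pixel_spacing = NULL,
                                 hu_weighted = FALSE) {
  if (inherits(slice, "ct_slice")) {
    px <- slice$pixels; sp <- slice$pixel_spacing
  } else {
    px <- slice; sp <- rep_len(as.numeric(pixel_spacing), 2)
  }
  m <- if (inherits(mask, "body_mask")) mask$mask else mask
  stopifnot(identical(dim(px), dim(m)))
  if (!any(m)) return(NULL)
  ix <- which(m, arr.ind = TRUE)
  w <- if (hu_weighted) pmax(px[m] + 1000, 0) else rep(1, nrow(ix))
  bary_px <- c(x = sum((ix[, 2] - 1) * w), y = sum((ix[, 1] - 1) * w)) / sum(w)
  centre_px <- c(x = (ncol(px) - 1) / 2, y = (nrow(px) - 1) / 2)
  bary_mm <- bary_px * c(sp[2], sp[1])
  dev_mm <- (bary_px - centre_px) * c(sp[2], sp[1])
  structure(list(barycentre_mm = bary_mm, deviation_mm = dev_mm,
                 magnitude_mm = sqrt(sum(dev_mm^2))),
            class = "centering_result")
}

#' @export
print.centering_result <- function(x, ...) {
  cat(sprintf("<centering_result> dx %+.1f mm, dy %+.1f mm (|d| %.1f mm)\n",
              x$deviation_mm["x"], x$deviation_mm["y"], x$magnitude_mm))
  invisible(x)
}

#' Series-level centering summary
#'
#' Mean and SD of the per-slice deviation magnitudes, the table height,
#' and its delta against a reference acquisition's table height. Table
#' heights are gantry readouts whose sign convention varies by vendor;
#' only the difference between acquisitions is meaningful.
#'
#' @param series a [ct_series()].
#' @param reference_table_height reference acquisition's table height, mm
#'   (`NA` to skip the delta).
#' @param config an [analysis_config()] controlling the per-slice masking.
#' @return list of class `centering_summary` with `mean_mm`, `sd_mm`,
#'   `n_slices`, `table_height_mm`, `table_height_delta_mm` and the
#'   per-slice deviation table.
#' @export
series_centering_summary <- function(series, reference_table_height = NA,
                                     config = analysis_config()) {
  stopifnot(inherits(series, "ct_series"))
  rows <- lapply(series$slices, function(s) {
    res <- tryCatch(
      barycentre_deviation(s, body_mask(
        s, closing_radius = config$closing_radius,
        exclude_bottom = config$exclude_bottom)),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(slice_index = s$slice_index, z_mm = s$z_position,
                        dx_mm = NA_real_, dy_mm = NA_real_,
                        magnitude_mm = NA_real_))
    data.frame(slice_index = s$slice_index, z_mm = s$z_position,
               dx_mm = res$deviation_mm["x"], dy_mm = res$deviation_mm["y"],
               magnitude_mm = res$magnitude_mm)
  })
  per_slice <- do.call(rbind, rows)
  rownames(per_slice) <- NULL
  mag <- per_slice$magnitude_mm[!is.na(per_slice$magnitude_mm)]
  if (!length(mag)) stop("no slice yielded a body mask", call. = FALSE)
  th <- series$slices[[1]]$table_height
  structure(list(mean_mm = mean(mag), sd_mm = stats::sd(mag),
                 n_slices = length(mag), table_height_mm = th,
                 table_height_delta_mm = th - reference_table_height,
                 per_slice = per_slice),
            class = "centering_summary")
}

#' @export
print.centering_summary <- function(x, ...) {
  cat(sprintf("<centering_summary> |deviation| %.1f +/- %.1f mm over %d slices\n",
              x$mean_mm, x$sd_mm, x$n_slices))
  if (!is.na(x$table_height_delta_mm))
    cat(sprintf("  table height %.1f mm (delta vs reference %+.1f mm)\n",
                x$table_height_mm, x$table_height_delta_mm))
  invisible(x)
}

#' Apparent body width on a topogram row
#'
#' Thresholds the topogram intensity image with Otsu (binned over the
#' image's own intensity range) and measures, on the requested row, the
#' lateral extent `(last - first body column + 1) * spacing`.
#'
#' @param topogram a `topogram` from [simulate_topogram()].
#' @param row slice/row index into the topogram.
#' @return width in mm (`NA` if the row holds no body columns).
#' @export
topogram_width <- function(topogram, row) {
  stopifnot(inherits(topogram, "topogram"),
            row >= 1, row <= nrow(topogram$intensity))
  thr <- otsu_threshold(topogram$intensity,
                        range = range(topogram$intensity), bins = 256L)
  on <- which(topogram$intensity[row, ] >= thr)
  if (!length(on)) return(NA_real_)
  dx <- diff(topogram$lateral_mm[1:2])
  (max(on) - min(on) + 1) * dx
}

#' Gap between the body's back and the table (or pad) top
#'
#' Measures `(table_row - lowest mask row) * row spacing`: the air-plus-
#' mattress space under the patient, the quantity that a depth camera
#' misjudges when an additional mattress is present.
#'
#' @param slice a [ct_slice()].
#' @param mask a [body_mask()] or logical matrix.
#' @param table_row row index of the support top (ground truth or
#'   configuration).
#' @return gap in mm; `NA` for an empty mask.
#' @export
back_to_table_gap <- function(slice, mask, table_row) {
  m <- if (inherits(mask, "body_mask")) mask$mask else mask
  if (!any(m)) return(NA_real_)
  lowest <- max(which(m, arr.ind = TRUE)[, 1])
  (table_row - lowest) * slice$pixel_spacing[1]
}
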