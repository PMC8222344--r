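#' A single axial CT slice
#'
#' Holds one image in Hounsfield units together with the per-slice
#' acquisition metadata the analysis consumes.
#'
#' @param pixels numeric matrix of HU values (rows x cols).
#' @param pixel_spacing `(row, col)` pixel size in mm.
#' @param z_position longitudinal position, mm.
#' @param table_height gantry table-height readout, mm (`NA` if absent).
#' @param mas effective tube current-time product delivered for this slice
#'   (mAs); `NA` when the acquisition metadata does not carry it.
#' @param slice_index ordinal position within the series.
#' @export
ct_slice <- function(pixels, pixel_spacing, z_position,
                     table_height = NA_real_, mas = NA_real_,
                     slice_index = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("`pixels` must be finite HU values", call. = FALSE)
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2)
  if (any(pixel_spacing <= 0))
    stop("`pixel_spacing` must be > 0", call. = FALSE)
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 z_position = as.numeric(z_position),
                 table_height = as.numeric(table_height),
                 mas = as.numeric(mas),
                 slice_index = as.integer(slice_index)),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice #%s> %dx%d px (%.3f mm), z = %.1f mm, mAs = %s\n",
              x$slice_index, nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing[1], x$z_position,
              if (is.na(x$mas)) "absent" else sprintf("%.1f", x$mas)))
  invisible(x)
}

#' An ordered CT series
#'
#' A list of [ct_slice()] objects sorted by z, with series-level
#' acquisition metadata.
#'
#' @param slices list of [ct_slice()]; reordered by `z_position`.
#' @param ctdi_vol volume CT dose index, mGy (32 cm reference phantom).
#' @param protocol free-text protocol label.
#' @param kvp tube potential.
#' @param quality_ref_mas quality reference mAs of the modulation system.
#' @export
ct_series <- function(slices, ctdi_vol = NA_real_, protocol = "",
                      kvp = NA_real_, quality_ref_mas = NA_real_) {
  stopifnot(length(slices) >= 1,
            all(vapply(slices, inherits, TRUE, "ct_slice")))
  z <- vapply(slices, function(s) s$z_position, numeric(1))
  if (anyDuplicated(z))
    stop("slice z positions must be strictly monotone", call. = FALSE)
  slices <- slices[order(z)]
  shp <- dim(slices[[1]]$pixels)
  sp <- slices[[1]]$pixel_spacing
  for (s in slices) {
    if (!identical(dim(s$pixels), shp) ||
        max(abs(s$pixel_spacing - sp)) > 1e-9)
      stop("all slices must share shape and pixel spacing", call. = FALSE)
  }
  structure(list(slices = slices, ctdi_vol = as.numeric(ctdi_vol),
                 protocol = protocol, kvp = as.numeric(kvp),
                 quality_ref_mas = as.numeric(quality_ref_mas)),
            class = "ct_series")
}

#' @export
print.ct_series <- function(x, ...) {
  z <- slice_z(x)
  cat(sprintf("<ct_series> %d slices, z %.1f..%.1f mm, CTDIvol %s mGy, %s\n",
              length(x$slices), min(z), max(z),
              if (is.na(x$ctdi_vol)) "?" else sprintf("%.2f", x$ctdi_vol),
              x$protocol))
  invisible(x)
}

#' @export
length.ct_series <- function(x) length(x$slices)

slice_z <- function(series)
  vapply(series$slices, function(s) s$z_position, numeric(1))

slice_mas <- function(series)
  vapply(series$slices, function(s) s$mas, numeric(1))
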