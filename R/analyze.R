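#' Analysis configuration
#'
#' Collects the tunable parameters of the slice-by-slice pipeline with the
#' package's documented defaults.
#'
#' @param ranges tissue [hu_ranges()].
#' @param half_width noise-window half-width, pixels.
#' @param min_support minimum same-region pixels per noise window.
#' @param closing_radius body-mask morphological closing radius, pixels.
#' @param exclude_bottom body-mask table rejection rule (see
#'   [body_mask()]).
#' @param lung_zone_fraction a slice counts as chest when its lung pixels
#'   are at least this fraction of its body pixels.
#' @param z_tolerance_mm pairing tolerance for [align_profiles()];
#'   `NULL` = half the median slice increment.
#' @export
analysis_config <- function(ranges = hu_ranges(), half_width = 5,
                            min_support = 10, closing_radius = 3,
                            exclude_bottom = TRUE,
                            lung_zone_fraction = 0.01,
                            z_tolerance_mm = NULL) {
  structure(list(ranges = ranges, half_width = half_width,
                 min_support = min_support, closing_radius = closing_radius,
                 exclude_bottom = exclude_bottom,
                 lung_zone_fraction = lung_zone_fraction,
                 z_tolerance_mm = z_tolerance_mm),
            class = "analysis_config")
}

#' Anatomical zone of a segmented slice
#'
#' A slice is `"chest"` when its lung-labelled pixels reach the configured
#' fraction of its body pixels, otherwise `"abdomen-pelvis"`. Lung noise
#' is reported for chest slices and soft-tissue noise for abdomen-pelvis
#' slices.
#'
#' @param labels a `tissue_labels` matrix from [segment_tissues()].
#' @param lung_zone_fraction the chest decision threshold.
#' @return `"chest"`, `"abdomen-pelvis"`, or `NA_character_` when the
#'   slice holds no body pixels.
#' @export
classify_zone <- function(labels, lung_zone_fraction = 0.01) {
  lab <- unclass(labels)
  body <- sum(lab != "outside")
  if (body == 0) return(NA_character_)
  lung <- sum(lab == "lung")
  if (lung >= lung_zone_fraction * body) "chest" else "abdomen-pelvis"
}

#' Slice-by-slice analysis of a CT series
#'
#' Runs, for every slice: Otsu body masking, tissue segmentation, zone
#' classification, barycentre off-centering, and the region-restricted
#' noise maps summarised as the global noise level plus the zone's tissue
#' noise (lung in the chest, soft tissue in the abdomen-pelvis). Slices
#' where no body is found yield `NA` rows rather than being dropped.
#'
#' @param series a [ct_series()].
#' @param config an [analysis_config()].
#' @return object of class `series_analysis`: list with `per_slice` (a
#'   data.frame with one row per slice), the `series` metadata
#'   (`ctdi_vol`, `quality_ref_mas`, table height) and the `config`.
#' @export
analyze_series <- function(series, config = analysis_config()) {
  stopifnot(inherits(series, "ct_series"))
  tissues <- names(config$ranges)
  rows <- lapply(series$slices, function(s) {
    out <- data.frame(
      slice_index = s$slice_index, z_mm = s$z_position, mas = s$mas,
      table_height_mm = s$table_height, body_pixels = NA_integer_,
      threshold_hu = NA_real_, zone = NA_character_,
      dx_mm = NA_real_, dy_mm = NA_real_, magnitude_mm = NA_real_,
      global_noise_hu = NA_real_, lung_noise_hu = NA_real_,
      soft_noise_hu = NA_real_
    )
    bm <- tryCatch(body_mask(s, closing_radius = config$closing_radius,
                             exclude_bottom = config$exclude_bottom),
                   error = function(e) NULL)
    if (is.null(bm)) return(out)
    out$body_pixels <- bm$pixel_count
    out$threshold_hu <- bm$threshold_hu
    labels <- segment_tissues(s, bm, config$ranges)
    out$zone <- classify_zone(labels, config$lung_zone_fraction)
    cen <- barycentre_deviation(s, bm)
    out$dx_mm <- cen$deviation_mm["x"]
    out$dy_mm <- cen$deviation_mm["y"]
    out$magnitude_mm <- cen$magnitude_mm
    maps <- list()
    for (t in tissues) {
      reg <- unclass(labels) == t
      if (any(reg))
        maps[[t]] <- region_noise_map(s, reg, config$half_width,
                                      config$min_support)
    }
    if (length(maps)) {
      gmap <- global_noise_map(maps)
      if (any(!is.na(gmap$values)))
        out$global_noise_hu <- global_noise_level(gmap)
    }
    if (identical(out$zone, "chest") && !is.null(maps$lung)) {
      v <- maps$lung$values[!is.na(maps$lung$values)]
      if (length(v) >= config$min_support) out$lung_noise_hu <- mean(v)
    }
    if (identical(out$zone, "abdomen-pelvis") && !is.null(maps$soft)) {
      v <- maps$soft$values[!is.na(maps$soft$values)]
      if (length(v) >= config$min_support) out$soft_noise_hu <- mean(v)
    }
    out
  })
  per_slice <- do.call(rbind, rows)
  rownames(per_slice) <- NULL
  structure(list(per_slice = per_slice, ctdi_vol = series$ctdi_vol,
                 quality_ref_mas = series$quality_ref_mas,
                 table_height_mm = series$slices[[1]]$table_height,
                 config = config),
            class = "series_analysis")
}

#' @export
print.series_analysis <- function(x, ...) {
  ps <- x$per_slice
  cat(sprintf("<series_analysis> %d slices (%d chest, %d abdomen-pelvis)\n",
              nrow(ps), sum(ps$zone == "chest", na.rm = TRUE),
              sum(ps$zone == "abdomen-pelvis", na.rm = TRUE)))
  cat(sprintf("  |off-centre| %.1f +/- %.1f mm; mean mAs %.1f; CTDIvol %s mGy\n",
              mean(ps$magnitude_mm, na.rm = TRUE),
              stats::sd(ps$magnitude_mm, na.rm = TRUE),
              mean(ps$mas, na.rm = TRUE),
              if (is.na(x$ctdi_vol)) "?" else sprintf("%.2f", x$ctdi_vol)))
  invisible(x)
}

#' Per-tissue noise z-profile of an analysed series
#'
#' @param analysis a `series_analysis`.
#' @param tissue `"lung"` (chest slices) or `"soft"` (abdomen-pelvis
#'   slices).
#' @return `data.frame(slice_index, z_mm, value)` restricted to the
#'   tissue's zone; `value` may be `NA` where the tissue was too sparse.
#' @export
noise_profile <- function(analysis, tissue = c("lung", "soft")) {
  stopifnot(inherits(analysis, "series_analysis"))
  tissue <- match.arg(tissue)
  ps <- analysis$per_slice
  zone <- if (tissue == "lung") "chest" else "abdomen-pelvis"
  sel <- !is.na(ps$zone) & ps$zone == zone
  col <- paste0(tissue, "_noise_hu")
  data.frame(slice_index = ps$slice_index[sel], z_mm = ps$z_mm[sel],
             value = ps[[col]][sel])
}

#' Write the per-slice analysis table to CSV
#'
#' @param analysis a `series_analysis`.
#' @param path output file.
#' @export
write_analysis_csv <- function(analysis, path) {
  data.table::fwrite(analysis$per_slice, path)
  invisible(path)
}
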