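#' Write a CT series as a portable archive
#'
#' The archive is a directory holding one plain-text pixel file per slice
#' (comma-separated integer HU, no header) and a `series.json` sidecar with
#' the series-level metadata and one record per slice (file name, z
#' position, table height, mAs). HU values are rounded to integers on
#' write, the storage precision of CT pixel data. An optional ground-truth
#' object is stored alongside as `ground_truth.json`.
#'
#' @param series a [ct_series()].
#' @param path directory to create (must not already contain an archive).
#' @param ground_truth optional ground-truth list from the simulator.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, ground_truth = NULL) {
  stopifnot(inherits(series, "ct_series"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "ctqc-archive", format_version = 1L,
    series_uid = sprintf("ctqc.%s", paste(sample_free_uid(series))),
    protocol = series$protocol, kvp = series$kvp,
    quality_ref_mas = series$quality_ref_mas, ctdi_vol = series$ctdi_vol,
    shape = dim(series$slices[[1]]$pixels),
    pixel_spacing = series$slices[[1]]$pixel_spacing,
    slices = lapply(seq_along(series$slices), function(i) {
      s <- series$slices[[i]]
      list(slice_index = i, file = sprintf("slice_%04d.csv", i),
           z_mm = s$z_position, table_height_mm = s$table_height,
           mas = s$mas)
    })
  )
  for (i in seq_along(series$slices)) {
    px <- round(series$slices[[i]]$pixels)
    data.table::fwrite(data.table::as.data.table(px),
                       file.path(path, sprintf("slice_%04d.csv", i)),
                       col.names = FALSE)
  }
  jsonlite::write_json(meta, file.path(path, "series.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  if (!is.null(ground_truth))
    jsonlite::write_json(ground_truth_portable(ground_truth),
                         file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

# deterministic content-derived uid so identical series archive identically
sample_free_uid <- function(series) {
  z <- slice_z(series)
  sprintf("%d.%0.0f.%0.0f", length(series$slices), sum(z),
          sum(series$slices[[1]]$pixels[1, ]))
}

ground_truth_portable <- function(gt) {
  gt$config <- unclass(gt$config)
  if (!is.null(gt$sigma_realized))
    gt$sigma_realized <- as.data.frame(gt$sigma_realized)
  gt
}

#' Read a CT series from a portable archive
#'
#' Restores slices sorted by z position (not by file or instance order)
#' with per-slice mAs and table height; metadata recorded as `null` in the
#' sidecar is flagged absent (`NA`), never silently zero.
#'
#' @param path archive directory written by [write_series()].
#' @return a [ct_series()].
#' @export
read_series <- function(path) {
  sidecar <- file.path(path, "series.json")
  if (!file.exists(sidecar))
    stop("no series.json found under '", path, "'", call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  if (!identical(meta$format, "ctqc-archive"))
    stop("'", path, "' is not a ctqc archive", call. = FALSE)
  if (!length(meta$slices))
    stop("archive lists no slices", call. = FALSE)
  shape <- as.integer(unlist(meta$shape))
  spacing <- as.numeric(unlist(meta$pixel_spacing))
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

  slices <- lapply(meta$slices, function(rec) {
    f <- file.path(path, rec$file)
    if (!file.exists(f))
      stop("pixel data file missing or unreadable: '", f, "'", call. = FALSE)
    px <- as.matrix(data.table::fread(f, header = FALSE))
    dimnames(px) <- NULL
    storage.mode(px) <- "double"
    if (!identical(dim(px), shape) || any(!is.finite(px)))
      stop("pixel data file malformed: '", f, "'", call. = FALSE)
    ct_slice(pixels = px, pixel_spacing = spacing,
             z_position = num_or_na(rec$z_mm),
             table_height = num_or_na(rec$table_height_mm),
             mas = num_or_na(rec$mas),
             slice_index = as.integer(rec$slice_index))
  })
  series <- ct_series(slices, ctdi_vol = num_or_na(meta$ctdi_vol),
                      protocol = if (is.null(meta$protocol)) "" else meta$protocol,
                      kvp = num_or_na(meta$kvp),
                      quality_ref_mas = num_or_na(meta$quality_ref_mas))
  for (i in seq_along(series$slices)) series$slices[[i]]$slice_index <- i
  series
}

#' Extract the modulated-mAs z-profile of a series
#'
#' One `(z, mAs)` pair per slice in z order; slices whose metadata lacks
#' the exposure are kept with `NA` so profile means stay honest.
#'
#' @param series a [ct_series()].
#' @return `data.frame(slice_index, z_mm, mas)`.
#' @export
extract_mas_profile <- function(series) {
  stopifnot(inherits(series, "ct_series"))
  mas <- slice_mas(series)
  if (all(is.na(mas)))
    stop("no slice in the series carries an mAs value", call. = FALSE)
  data.frame(slice_index = seq_along(series$slices),
             z_mm = slice_z(series), mas = mas)
}

#' Write a z-profile to CSV
#'
#' @param profile a profile `data.frame` (e.g. from
#'   [extract_mas_profile()]).
#' @param path output file.
#' @export
write_profile_csv <- function(profile, path) {
  data.table::fwrite(profile, path)
  invisible(path)
}
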