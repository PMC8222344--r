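#' Configuration for the synthetic anthropomorphic torso phantom
#'
#' Builds the parameter set that drives [generate_phantom_volume()] and the
#' full acquisition simulator [simulate_acquisition()]. Defaults emulate a
#' slim adult torso (BMI about 18 kg/m2) scanned head-to-pelvis over 600 mm
#' at a 500 mm field of view, resting on a thin fixed foam pad on the table,
#' optionally with an additional transfer mattress between back and pad.
#'
#' Geometry is expressed in image coordinates: `x` increases with column
#' index, `y` increases with row index (downwards). `vertical_offset` is the
#' height of the body centre *above* the isocentre (the image centre) in mm:
#' a positive offset raises the body, as happens when an automated centering
#' system fails to account for an additional mattress. The body barycentre
#' therefore sits at image-centre `y` minus `vertical_offset`.
#'
#' @param n_slices number of axial slices.
#' @param slice_shape integer `(rows, cols)` of each slice.
#' @param pixel_spacing in-plane pixel size, mm/pixel (isotropic).
#' @param slice_spacing longitudinal slice increment, mm.
#' @param torso_axes named list of `(semi_width, semi_height)` mm for the
#'   `shoulder`, `chest`, `abdomen` and `pelvis` zones.
#' @param zone_breaks cumulative fractions of the scan range at which the
#'   shoulder/chest/abdomen/pelvis zones end.
#' @param hu_values named numeric vector of Hounsfield units for the six
#'   materials `air`, `lung`, `soft`, `bone`, `foam`, `table`.
#' @param base_sigma named numeric vector, noise standard deviation (HU) per
#'   material at the quality reference mAs.
#' @param mattress_thickness additional mattress thickness, mm (0 = none;
#'   the study configurations are 0, 35, 100 and 135).
#' @param mattress_compression fraction of the additional mattress thickness
#'   lost to compression under the body; the rendered slab has thickness
#'   `mattress_thickness * (1 - mattress_compression)`.
#' @param mattress_gap air space between the additional mattress and the
#'   fixed pad, mm.
#' @param fixed_pad_thickness thickness of the fixed table-top pad, mm.
#' @param vertical_offset body centre height above isocentre, mm (signed).
#' @param table_height gantry table-height readout recorded in the slice
#'   metadata, mm.
#' @param kvp tube potential recorded in the metadata.
#' @param quality_ref_mas quality reference mAs of the modulation system.
#' @param ctdi_per_mas CTDIvol per unit mean mAs (mGy/mAs, 32 cm phantom).
#' @param seed integer seed for the noise generator.
#' @return an object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(n_slices = 120,
                           slice_shape = c(128L, 128L),
                           pixel_spacing = 500 / 128,
                           slice_spacing = 5,
                           torso_axes = list(
                             shoulder = c(190, 85),
                             chest    = c(150, 100),
                             abdomen  = c(135, 90),
                             pelvis   = c(155, 95)
                           ),
                           zone_breaks = c(shoulder = 0.10, chest = 0.45,
                                           abdomen = 0.75, pelvis = 1.00),
                           hu_values = c(air = -1000, lung = -750, soft = 40,
                                         bone = 700, foam = -850, table = 100),
                           base_sigma = c(air = 5, lung = 15, soft = 10,
                                          bone = 10, foam = 5, table = 5),
                           mattress_thickness = 0,
                           mattress_compression = 0.5,
                           mattress_gap = 0,
                           fixed_pad_thickness = 25,
                           vertical_offset = 0,
                           table_height = 120,
                           kvp = 120,
                           quality_ref_mas = 240,
                           ctdi_per_mas = 0.0579,
                           seed = 1L) {
  cfg <- list(
    n_slices = as.integer(n_slices), slice_shape = as.integer(slice_shape),
    pixel_spacing = pixel_spacing, slice_spacing = slice_spacing,
    torso_axes = torso_axes, zone_breaks = zone_breaks,
    hu_values = hu_values, base_sigma = base_sigma,
    mattress_thickness = mattress_thickness,
    mattress_compression = mattress_compression,
    mattress_gap = mattress_gap,
    fixed_pad_thickness = fixed_pad_thickness,
    vertical_offset = vertical_offset,
    table_height = table_height, kvp = kvp,
    quality_ref_mas = quality_ref_mas,
    ctdi_per_mas = ctdi_per_mas, seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(cfg$n_slices >= 1, length(cfg$slice_shape) == 2,
            all(cfg$slice_shape >= 16), cfg$pixel_spacing > 0,
            cfg$slice_spacing > 0)
  if (cfg$mattress_thickness < 0)
    stop("mattress_thickness must be >= 0", call. = FALSE)
  if (cfg$mattress_compression < 0 || cfg$mattress_compression > 1)
    stop("mattress_compression must lie in [0, 1]", call. = FALSE)
  need <- c("air", "lung", "soft", "bone", "foam", "table")
  if (!all(need %in% names(cfg$hu_values)))
    stop("hu_values must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cfg$hu_values[need]))
    stop("hu_values must be distinct per material", call. = FALSE)
  if (any(cfg$base_sigma[need] <= 0))
    stop("base_sigma must be > 0 for every material", call. = FALSE)
  zones <- c("shoulder", "chest", "abdomen", "pelvis")
  if (!all(zones %in% names(cfg$torso_axes)))
    stop("torso_axes must name shoulder, chest, abdomen and pelvis",
         call. = FALSE)
  # torso must fit the field of view on every slice, including the offset
  fov_x <- cfg$slice_shape[2] * cfg$pixel_spacing
  fov_y <- cfg$slice_shape[1] * cfg$pixel_spacing
  for (z in zones) {
    ax <- cfg$torso_axes[[z]]
    if (2 * ax[1] >= fov_x)
      stop("torso semi-width for zone '", z, "' exceeds the field of view",
           call. = FALSE)
    top <- -cfg$vertical_offset - ax[2]
    if (top <= -fov_y / 2 || -cfg$vertical_offset + ax[2] >= fov_y / 2)
      stop("torso for zone '", z,
           "' extends beyond the field of view at this vertical offset",
           call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  %d slices of %dx%d px, %.3f mm/px, %.1f mm increment (%.0f mm range)\n",
              x$n_slices, x$slice_shape[1], x$slice_shape[2],
              x$pixel_spacing, x$slice_spacing,
              x$n_slices * x$slice_spacing))
  cat(sprintf("  mattress %.0f mm (compression %.0f%%, air gap %.0f mm), vertical offset %+.1f mm\n",
              x$mattress_thickness, 100 * x$mattress_compression,
              x$mattress_gap, x$vertical_offset))
  cat(sprintf("  quality ref %.0f mAs at %.0f kVp, seed %d\n",
              x$quality_ref_mas, x$kvp, x$seed))
  invisible(x)
}

# zone label for slice s of n (zone_breaks are cumulative end fractions)
slice_zone <- function(s, n, zone_breaks) {
  f <- (s - 0.5) / n
  names(zone_breaks)[which(f <= zone_breaks + 1e-12)[1]]
}

# pixel-centre coordinate grids in mm, origin at the image centre
pixel_grid <- function(shape, spacing) {
  rows <- shape[1]; cols <- shape[2]
  y <- (seq_len(rows) - 1 - (rows - 1) / 2) * spacing
  x <- (seq_len(cols) - 1 - (cols - 1) / 2) * spacing
  list(x = matrix(x, rows, cols, byrow = TRUE),
       y = matrix(y, rows, cols), xv = x, yv = y)
}

in_ellipse <- function(gx, gy, cx, cy, a, b) {
  ((gx - cx) / a)^2 + ((gy - cy) / b)^2 <= 1
}

#' Generate a noise-free labelled phantom volume
#'
#' Renders, slice by slice, an elliptical soft-tissue torso whose axes vary
#' by longitudinal zone. Chest slices contain two lung ellipses and a
#' vertebral bone disc; abdomen and pelvis slices contain spine (and, in the
#' pelvis, lateral iliac) bone. Below the body the additional mattress (if
#' any), an optional air gap, the fixed table pad and the table top are
#' rendered; the table slab always reaches the bottom image edge.
#'
#' @param config a [phantom_config()].
#' @return a list with elements
#'   * `slices`: list of noise-free [ct_slice()] objects,
#'   * `labels`: list of character matrices over
#'     `air/lung/soft/bone/foam/table`,
#'   * `ground_truth`: per-slice truth (barycentre, body pixel count, zone,
#'     true body width, pad-top and table-top row indices) plus the config.
#' @export
generate_phantom_volume <- function(config) {
  validate_phantom_config(config)
  shape <- config$slice_shape
  g <- pixel_grid(shape, config$pixel_spacing)
  hu <- config$hu_values
  yc <- -config$vertical_offset            # body centre y in mm

  slices <- vector("list", config$n_slices)
  labels <- vector("list", config$n_slices)
  gt <- data.frame(
    slice_index = seq_len(config$n_slices),
    z_mm = (seq_len(config$n_slices) - 1) * config$slice_spacing,
    zone = NA_character_, bary_x_mm = NA_real_, bary_y_mm = NA_real_,
    body_pixels = NA_integer_, width_mm = NA_real_,
    pad_top_row = NA_integer_, table_top_row = NA_integer_
  )

  rendered_mattress <- config$mattress_thickness *
    (1 - config$mattress_compression)

  for (s in seq_len(config$n_slices)) {
    zone <- slice_zone(s, config$n_slices, config$zone_breaks)
    ax <- config$torso_axes[[zone]]
    a <- ax[1]; b <- ax[2]

    lab <- matrix("air", shape[1], shape[2])
    body <- in_ellipse(g$x, g$y, 0, yc, a, b)
    lab[body] <- "soft"

    if (zone == "chest") {
      lung_l <- in_ellipse(g$x, g$y, -0.45 * a, yc - 0.15 * b,
                           0.30 * a, 0.55 * b)
      lung_r <- in_ellipse(g$x, g$y, 0.45 * a, yc - 0.15 * b,
                           0.30 * a, 0.55 * b)
      lab[body & (lung_l | lung_r)] <- "lung"
    }
    # vertebral disc in every zone; iliac wings in the pelvis
    r_vert <- 0.12 * min(a, b)
    vert <- in_ellipse(g$x, g$y, 0, yc + 0.55 * b, r_vert, r_vert)
    lab[body & vert] <- "bone"
    if (zone == "pelvis") {
      r_il <- 0.15 * b
      il <- in_ellipse(g$x, g$y, -0.55 * a, yc + 0.30 * b, r_il, r_il) |
        in_ellipse(g$x, g$y, 0.55 * a, yc + 0.30 * b, r_il, r_il)
      lab[body & il] <- "bone"
    }

    # support stack below the body back (body bottom at yc + b)
    body_bottom <- yc + b
    pad_top <- body_bottom + rendered_mattress + config$mattress_gap
    table_top <- pad_top + config$fixed_pad_thickness
    half_support <- 0.75 * a + 40        # slabs a little wider than the body

    open_cols <- abs(g$x) <= half_support
    if (rendered_mattress > 0) {
      slab <- open_cols & g$y > body_bottom &
        g$y <= body_bottom + rendered_mattress & !body
      lab[slab] <- "foam"
    }
    pad <- open_cols & g$y > pad_top & g$y <= table_top & !body
    lab[pad] <- "foam"
    tbl <- g$y > table_top & !body       # full-width, down to the image edge
    lab[tbl] <- "table"

    px <- matrix(hu["air"], shape[1], shape[2])
    for (m in c("lung", "soft", "bone", "foam", "table"))
      px[lab == m] <- hu[[m]]

    body_lab <- lab == "lung" | lab == "soft" | lab == "bone"
    body_ix <- which(body_lab, arr.ind = TRUE)
    gt$zone[s] <- zone
    gt$bary_x_mm[s] <- mean(g$xv[body_ix[, 2]])
    gt$bary_y_mm[s] <- mean(g$yv[body_ix[, 1]])
    gt$body_pixels[s] <- nrow(body_ix)
    gt$width_mm[s] <- diff(range(body_ix[, 2]) + c(0, 1)) *
      config$pixel_spacing
    gt$pad_top_row[s] <- which(g$yv > pad_top)[1]
    gt$table_top_row[s] <- which(g$yv > table_top)[1]

    slices[[s]] <- ct_slice(
      pixels = px, pixel_spacing = rep(config$pixel_spacing, 2),
      z_position = gt$z_mm[s], table_height = config$table_height,
      mas = NA_real_, slice_index = s
    )
    labels[[s]] <- lab
  }

  list(slices = slices, labels = labels,
       ground_truth = list(per_slice = gt, config = config))
}

#' Topogram acquisition geometry
#'
#' Geometry of the anteroposterior scout projection. With the X-ray source
#' above the patient, a body raised by `offset` mm above the isocentre is
#' laterally magnified on the detector-plane image by
#' `m = 1 / (1 - offset / source_to_isocentre)`.
#'
#' @param source_to_isocentre focal-spot-to-isocentre distance, mm.
#' @param projection projection direction; only `"AP"` is modelled.
#' @param response_tau_mm saturation length of the displayed scout
#'   intensity: a ray crossing `L` mm of body renders as
#'   `1 - exp(-L / response_tau_mm)`, emulating the high-contrast display
#'   processing of scout images so the body edge is sharp.
#' @export
topogram_geometry <- function(source_to_isocentre = 595, projection = "AP",
                              response_tau_mm = 10) {
  stopifnot(source_to_isocentre > 0, identical(projection, "AP"),
            response_tau_mm > 0)
  structure(list(source_to_isocentre = source_to_isocentre,
                 projection = projection,
                 response_tau_mm = response_tau_mm),
            class = "topogram_geometry")
}

#' Simulate an AP topogram from a labelled volume
#'
#' Projects the body (lung/soft/bone labels) of each slice onto a lateral
#' mm axis: a vertical ray at isocentre-plane position `u / m` crosses `L`
#' mm of body and renders as intensity `1 - exp(-L / tau)` (the geometry's
#' saturating scout response), where `m` is the height-dependent lateral
#' magnification. The mattress, pad and table are not projected; scout
#' processing on scanners suppresses the table, and the foam is nearly
#' radiolucent.
#'
#' @param volume output of [generate_phantom_volume()].
#' @param geometry a [topogram_geometry()].
#' @param vertical_offset body height above isocentre, mm; must satisfy
#'   `abs(vertical_offset) < source_to_isocentre`.
#' @return a `topogram`: list with `intensity` (n_slices x n_lateral,
#'   path length in mm), `lateral_mm`, `z_mm`, `magnification`.
#' @export
simulate_topogram <- function(volume, geometry = topogram_geometry(),
                              vertical_offset = volume$ground_truth$config$vertical_offset) {
  sid <- geometry$source_to_isocentre
  if (abs(vertical_offset) >= sid)
    stop("`vertical_offset` must be smaller in magnitude than the ",
         "source-to-isocentre distance", call. = FALSE)
  m <- 1 / (1 - vertical_offset / sid)

  cfg <- volume$ground_truth$config
  g <- pixel_grid(cfg$slice_shape, cfg$pixel_spacing)
  lat <- g$xv                              # lateral sampling grid, mm
  n <- length(volume$labels)
  intensity <- matrix(0, n, length(lat))
  for (s in seq_len(n)) {
    body <- volume$labels[[s]] %in% c("lung", "soft", "bone")
    dim(body) <- dim(volume$labels[[s]])
    path <- colSums(body) * cfg$pixel_spacing
    display <- 1 - exp(-path / geometry$response_tau_mm)
    # magnification stretches the lateral axis by m about the midline
    intensity[s, ] <- stats::approx(x = g$xv * m, y = display, xout = lat,
                                    rule = 1)$y
  }
  intensity[is.na(intensity)] <- 0
  structure(list(intensity = intensity, lateral_mm = lat,
                 z_mm = volume$ground_truth$per_slice$z_mm,
                 magnification = m),
            class = "topogram")
}

#' Phenomenological longitudinal tube-current modulation
#'
#' Emulates a longitudinal modulation system planning from the topogram:
#' the modulated mAs for the slice at row `z` is
#' `quality_ref_mas * (W(z) / reference_width)^strength_exponent`, where
#' `W(z)` is the apparent body width on the topogram. A body magnified by
#' vertical off-centering appears wider and so draws more mAs, which is the
#' mechanism by which off-centering inflates dose.
#'
#' @param topogram a `topogram` from [simulate_topogram()].
#' @param quality_ref_mas quality reference mAs.
#' @param strength_exponent modulation strength `alpha > 0`; 1 makes mAs
#'   proportional to apparent width.
#' @param reference_width_mm the calibration width at which the system
#'   delivers exactly the quality reference mAs.
#' @return a z-profile `data.frame(slice_index, z_mm, mas)`.
#' @export
simulate_tcm_profile <- function(topogram, quality_ref_mas = 240,
                                 strength_exponent = 1,
                                 reference_width_mm = 300) {
  stopifnot(inherits(topogram, "topogram"), strength_exponent >= 0,
            reference_width_mm > 0)
  dx <- diff(topogram$lateral_mm[1:2])
  widths <- apply(topogram$intensity, 1, function(row) {
    on <- which(row > 1e-9)
    if (!length(on)) return(NA_real_)
    (max(on) - min(on) + 1) * dx
  })
  if (anyNA(widths) || any(widths <= 0))
    stop("topogram has rows with no body projection", call. = FALSE)
  data.frame(
    slice_index = seq_along(widths),
    z_mm = topogram$z_mm,
    mas = quality_ref_mas * (widths / reference_width_mm)^strength_exponent
  )
}

#' Add region-wise Gaussian noise and acquisition metadata to a volume
#'
#' Draws one standard normal deviate per pixel (column-major, slice by
#' slice, from a single generator seeded once) and scales it by the
#' per-pixel standard deviation `base_sigma[material] *
#' sqrt(quality_ref_mas / mas(z))`, so halving the delivered mAs inflates
#' the noise by sqrt(2). Writes per-slice mAs, table height and z into the
#' slice metadata and a CTDIvol proportional to the mean modulated mAs into
#' the series.
#'
#' @param volume output of [generate_phantom_volume()].
#' @param mas_profile z-profile with a `mas` column, one row per slice
#'   (e.g. from [simulate_tcm_profile()]); `NULL` gives a flat profile at
#'   the quality reference mAs.
#' @param base_sigma per-material noise SD (HU) at the reference mAs;
#'   defaults to the config's.
#' @param seed integer seed; defaults to the config's.
#' @return a list with `series` (a [ct_series()]) and `ground_truth` (the
#'   volume's truth extended with the realized mAs profile and the
#'   per-material sigma actually injected into each slice).
#' @export
render_noisy_series <- function(volume, mas_profile = NULL,
                                base_sigma = NULL, seed = NULL) {
  cfg <- volume$ground_truth$config
  if (is.null(base_sigma)) base_sigma <- cfg$base_sigma
  if (is.null(seed)) seed <- cfg$seed
  n <- length(volume$slices)
  if (is.null(mas_profile)) {
    mas <- rep(cfg$quality_ref_mas, n)
  } else {
    stopifnot(nrow(mas_profile) == n)
    mas <- mas_profile$mas
  }
  stopifnot(all(mas > 0), all(base_sigma > 0))

  materials <- c("air", "lung", "soft", "bone", "foam", "table")
  sigma_real <- matrix(NA_real_, n, length(materials),
                       dimnames = list(NULL, materials))
  slices <- vector("list", n)
  set.seed(as.integer(seed))
  for (s in seq_len(n)) {
    lab <- volume$labels[[s]]
    scale_s <- sqrt(cfg$quality_ref_mas / mas[s])
    sig <- base_sigma[materials] * scale_s
    sigma_real[s, ] <- sig
    sigma_map <- matrix(sig[match(lab, materials)], nrow(lab), ncol(lab))
    noisy <- volume$slices[[s]]$pixels +
      matrix(stats::rnorm(length(lab)), nrow(lab), ncol(lab)) * sigma_map
    slices[[s]] <- ct_slice(
      pixels = noisy, pixel_spacing = volume$slices[[s]]$pixel_spacing,
      z_position = volume$slices[[s]]$z_position,
      table_height = cfg$table_height, mas = mas[s], slice_index = s
    )
  }
  gt <- volume$ground_truth
  gt$mas_profile <- data.frame(slice_index = seq_len(n),
                               z_mm = gt$per_slice$z_mm, mas = mas)
  gt$sigma_realized <- sigma_real
  gt$base_sigma <- base_sigma
  series <- ct_series(
    slices = slices, ctdi_vol = cfg$ctdi_per_mas * mean(mas),
    protocol = "synthetic torso", kvp = cfg$kvp,
    quality_ref_mas = cfg$quality_ref_mas
  )
  list(series = series, ground_truth = gt)
}

#' Simulate a complete acquisition (volume, topogram, TCM, noise)
#'
#' Convenience wrapper chaining [generate_phantom_volume()],
#' [simulate_topogram()], [simulate_tcm_profile()] and
#' [render_noisy_series()].
#'
#' @inheritParams generate_phantom_volume
#' @param geometry a [topogram_geometry()].
#' @param strength_exponent,reference_width_mm passed to
#'   [simulate_tcm_profile()].
#' @return list with `series`, `ground_truth`, `topogram`, `labels`.
#' @export
simulate_acquisition <- function(config, geometry = topogram_geometry(),
                                 strength_exponent = 1,
                                 reference_width_mm = 300) {
  vol <- generate_phantom_volume(config)
  topo <- simulate_topogram(vol, geometry, config$vertical_offset)
  tcm <- simulate_tcm_profile(topo, config$quality_ref_mas,
                              strength_exponent, reference_width_mm)
  out <- render_noisy_series(vol, tcm)
  out$ground_truth$topogram_width_mm <-
    vol$ground_truth$per_slice$width_mm * topo$magnification
  out$topogram <- topo
  out$labels <- vol$labels
  out
}

#' Study configurations: mattresses and centering modes
#'
#' Returns the [phantom_config()] for one of the acquisition conditions of
#' the mattress experiment: no additional mattress, or a 3.5 cm ("grey"),
#' 10 cm ("orange") or 13.5 cm ("double", grey plus orange) transfer
#' mattress, each with either automatic camera centering or manual
#' centering at the isocentre.
#'
#' The emulated camera measures the top of the body but cannot see the
#' mattress below it, so it lowers the table by only half the mattress
#' thickness; the body it was asked to centre ends up above the isocentre
#' by the remaining `thickness / 2 + air gap`. Manual centering lowers the
#' table by the full mattress stack height, putting the body back at the
#' isocentre. The table-height readout grows as the table is lowered, from
#' a reference of 120 mm without an additional mattress. The mattress is
#' rendered uncompressed here; compression is a separate, configurable
#' knob of [phantom_config()].
#'
#' @param mattress one of `"none"`, `"grey"`, `"orange"`, `"double"`.
#' @param centering `"automatic"` or `"manual"`.
#' @param ... overrides forwarded to [phantom_config()].
#' @export
study_config <- function(mattress = c("none", "grey", "orange", "double"),
                         centering = c("automatic", "manual"), ...) {
  mattress <- match.arg(mattress)
  centering <- match.arg(centering)
  thick <- c(none = 0, grey = 35, orange = 100, double = 135)[[mattress]]
  gap <- c(none = 0, grey = 0, orange = 5, double = 30)[[mattress]]
  stack <- thick + gap                  # uncompressed mattress + air space
  reference_height <- 120
  if (centering == "automatic") {
    offset <- thick / 2 + gap           # residual height above isocentre
    height <- reference_height + thick / 2
  } else {
    offset <- 0
    height <- reference_height + stack
  }
  phantom_config(
    mattress_thickness = thick, mattress_gap = gap,
    mattress_compression = 0,
    vertical_offset = offset, table_height = height,
    ...
  )
}
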