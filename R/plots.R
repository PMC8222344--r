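#' Plot one or more z-profiles
#'
#' Line plot of per-slice values (mAs or noise) along the z-axis, one
#' line per acquisition.
#'
#' @param profiles named list of profile `data.frame`s with `z_mm` and a
#'   value column (last column).
#' @param ylab y-axis label.
#' @return a ggplot object.
#' @export
plot_profiles <- function(profiles, ylab = "value") {
  stopifnot(length(profiles) >= 1)
  if (is.null(names(profiles)))
    names(profiles) <- paste("series", seq_along(profiles))
  df <- do.call(rbind, lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    data.frame(z_mm = p$z_mm, value = p[[ncol(p)]], acquisition = nm)
  }))
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = z_mm, y = value,
                                   colour = acquisition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (mm)", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}
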