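#' Align two z-profiles by nearest z
#'
#' Pairs each reference slice with the nearest test slice within the
#' tolerance; a test slice is used at most once (ties go to the closer
#' reference). Unmatched slices on either side are dropped and counted,
#' never interpolated.
#'
#' @param ref,test profile `data.frame`s with `z_mm` and a value column
#'   (the last column is taken as the value).
#' @param tolerance_mm maximum |z_ref - z_test| for a pair; default half
#'   the reference's median slice increment.
#' @return object of class `paired_profiles`: `data.frame(z_mm, ref,
#'   test)` plus attributes `n_dropped_ref`, `n_dropped_test`.
#' @export
align_profiles <- function(ref, test, tolerance_mm = NULL) {
  stopifnot(nrow(ref) >= 1, nrow(test) >= 1)
  if (is.null(tolerance_mm)) {
    inc <- stats::median(diff(sort(ref$z_mm)))
    tolerance_mm <- if (is.na(inc) || inc <= 0) 1e-6 else inc / 2
  }
  rv <- ref[[ncol(ref)]]; tv <- test[[ncol(test)]]
  # nearest test index per reference slice
  near <- vapply(ref$z_mm, function(z) which.min(abs(test$z_mm - z)),
                 integer(1))
  dist <- abs(test$z_mm[near] - ref$z_mm)
  ok <- dist <= tolerance_mm & !is.na(rv) & !is.na(tv[near])
  # enforce one-to-one use of test slices, keeping the closest reference
  ord <- order(dist)
  used <- logical(nrow(test))
  keep <- logical(nrow(ref))
  for (i in ord) {
    if (!ok[i] || used[near[i]]) next
    used[near[i]] <- TRUE
    keep[i] <- TRUE
  }
  if (!any(keep))
    stop("no slice pairs within the z tolerance", call. = FALSE)
  out <- data.frame(z_mm = ref$z_mm[keep], ref = rv[keep],
                    test = tv[near[keep]])
  out <- out[order(out$z_mm), ]
  rownames(out) <- NULL
  structure(out, class = c("paired_profiles", "data.frame"),
            n_dropped_ref = sum(!keep), n_dropped_test = sum(!used))
}

#' Percent difference of a test value against a reference
#'
#' `100 * (test - ref) / ref`; the reference must be non-zero.
#'
#' @param test_value,ref_value numeric (vectorised).
#' @return percent difference.
#' @export
percent_difference <- function(test_value, ref_value) {
  if (any(ref_value == 0))
    stop("reference value must be non-zero", call. = FALSE)
  100 * (test_value - ref_value) / ref_value
}

#' Mean and SD of per-slice percent differences
#'
#' @param pairs a `paired_profiles` object (or data.frame with `ref` and
#'   `test` columns).
#' @return list with `mean_pct`, `sd_pct` (denominator n-1), `n`.
#' @export
mean_percent_difference <- function(pairs) {
  stopifnot(nrow(pairs) >= 2)
  d <- percent_difference(pairs$test, pairs$ref)
  list(mean_pct = mean(d), sd_pct = stats::sd(d), n = length(d))
}

#' Paired Student's t-test on aligned profiles
#'
#' Two-sided paired t-test on the per-slice differences `test - ref`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, with the p-value from the t
#' distribution on `n - 1` degrees of freedom. Degenerate zero-variance
#' differences are resolved by convention: all-zero differences give
#' `t = 0, p = 1`; identical non-zero differences give `p = 0` and are
#' flagged.
#'
#' @param pairs a `paired_profiles` (or data.frame with `ref`/`test`).
#' @return list with `t`, `p`, `df`, `mean_diff`, `significant`
#'   (p < 0.05) and `degenerate`.
#' @export
paired_t_test <- function(pairs) {
  stopifnot(nrow(pairs) >= 2)
  d <- pairs$test - pairs$ref
  n <- length(d)
  s <- stats::sd(d)
  md <- mean(d)
  if (s == 0) {
    if (md == 0)
      return(list(t = 0, p = 1, df = n - 1, mean_diff = 0,
                  significant = FALSE, degenerate = TRUE))
    return(list(t = sign(md) * Inf, p = 0, df = n - 1, mean_diff = md,
                significant = TRUE, degenerate = TRUE))
  }
  t <- md / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, p = p, df = n - 1, mean_diff = md,
       significant = p < 0.05, degenerate = FALSE)
}

#' Compare a test acquisition against a reference
#'
#' Runs (or reuses) the slice-by-slice analysis of both series, aligns the
#' modulated-mAs profiles and the zone-restricted noise profiles (lung in
#' the chest, soft tissue in the abdomen-pelvis) by nearest z, and reports
#' mean +/- SD percent differences with paired t-tests, the CTDIvol
#' percent difference (metadata only, independent of pixel data), and the
#' table-height delta.
#'
#' @param ref,test [ct_series()] objects, or precomputed
#'   `series_analysis` objects.
#' @param config an [analysis_config()].
#' @return object of class `comparison_report`.
#' @export
compare_acquisitions <- function(ref, test, config = analysis_config()) {
  aref <- if (inherits(ref, "series_analysis")) ref
          else analyze_series(ref, config)
  atest <- if (inherits(test, "series_analysis")) test
           else analyze_series(test, config)

  tol <- config$z_tolerance_mm
  mas_ref <- aref$per_slice[, c("z_mm", "mas")]
  mas_test <- atest$per_slice[, c("z_mm", "mas")]
  mas_pairs <- align_profiles(mas_ref, mas_test, tol)
  mas_diff <- mean_percent_difference(mas_pairs)
  mas_t <- paired_t_test(mas_pairs)

  tissue_block <- function(tissue) {
    pr <- noise_profile(aref, tissue); pt <- noise_profile(atest, tissue)
    pr <- pr[!is.na(pr$value), ]; pt <- pt[!is.na(pt$value), ]
    if (nrow(pr) < 2 || nrow(pt) < 2) return(NULL)
    pairs <- tryCatch(align_profiles(pr, pt, tol), error = function(e) NULL)
    if (is.null(pairs) || nrow(pairs) < 2) return(NULL)
    list(pairs = pairs, diff = mean_percent_difference(pairs),
         t = paired_t_test(pairs))
  }

  ctdi_pct <- if (!is.na(aref$ctdi_vol) && !is.na(atest$ctdi_vol))
    percent_difference(atest$ctdi_vol, aref$ctdi_vol) else NA_real_

  structure(list(
    mas = c(mas_diff, mas_t[c("t", "p", "significant", "degenerate")],
            list(pairs = mas_pairs)),
    lung_noise = tissue_block("lung"),
    soft_noise = tissue_block("soft"),
    ctdi_vol = list(ref = aref$ctdi_vol, test = atest$ctdi_vol,
                    pct = ctdi_pct, pct_printed = round(ctdi_pct)),
    table_height_delta_mm = atest$table_height_mm - aref$table_height_mm,
    zone_counts = list(
      ref = table(aref$per_slice$zone, useNA = "no"),
      test = table(atest$per_slice$zone, useNA = "no")),
    ref_analysis = aref, test_analysis = atest
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> test vs reference\n")
  cat(sprintf("  mAs:  %+.0f%% +/- %.0f%% over %d pairs (t = %.2f, p = %.3g%s)\n",
              x$mas$mean_pct, x$mas$sd_pct, x$mas$n, x$mas$t, x$mas$p,
              if (x$mas$significant) ", significant" else ""))
  for (nm in c("lung_noise", "soft_noise")) {
    b <- x[[nm]]
    if (is.null(b)) next
    cat(sprintf("  %s: %+.0f%% +/- %.0f%% over %d pairs (p = %.3g%s)\n",
                sub("_", " ", nm), b$diff$mean_pct, b$diff$sd_pct,
                b$diff$n, b$t$p,
                if (b$t$significant) ", significant" else ""))
  }
  if (!is.na(x$ctdi_vol$pct))
    cat(sprintf("  CTDIvol: %.2f vs %.2f mGy (%+d%%)\n",
                x$ctdi_vol$test, x$ctdi_vol$ref, x$ctdi_vol$pct_printed))
  if (!is.na(x$table_height_delta_mm))
    cat(sprintf("  table height delta: %+.1f mm\n", x$table_height_delta_mm))
  invisible(x)
}

#' Deltas of acquisition summaries against their reference row
#'
#' Reporting helper for summary measurement tables with one row per
#' acquisition: columns `mattress`, `centering`, and any of
#' `table_height_mm`, `width_mm`, `ctdi_vol_mgy`. The row with
#' `mattress == "none"` is the reference; every other row gets its
#' table-height delta (mm), topogram width delta (mm) and CTDIvol percent
#' difference, the latter both exact and rounded to the integer percent
#' used in printed reports.
#'
#' @param measurements a data.frame as above.
#' @return the non-reference rows with `table_height_delta_mm`,
#'   `width_delta_mm`, `ctdi_pct` and `ctdi_pct_printed` columns added.
#' @export
compare_to_reference <- function(measurements) {
  stopifnot(all(c("mattress", "centering") %in% names(measurements)))
  ref <- measurements[measurements$mattress == "none", ]
  if (nrow(ref) != 1)
    stop("measurements must hold exactly one reference row ",
         "(mattress == 'none')", call. = FALSE)
  out <- measurements[measurements$mattress != "none", ]
  if ("table_height_mm" %in% names(out))
    out$table_height_delta_mm <- out$table_height_mm - ref$table_height_mm
  if ("width_mm" %in% names(out))
    out$width_delta_mm <- out$width_mm - ref$width_mm
  if ("ctdi_vol_mgy" %in% names(out)) {
    out$ctdi_pct <- percent_difference(out$ctdi_vol_mgy, ref$ctdi_vol_mgy)
    out$ctdi_pct_printed <- round(out$ctdi_pct)
  }
  rownames(out) <- NULL
  out
}
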