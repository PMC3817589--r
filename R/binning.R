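#' Percentage of available substrate used by corals
#'
#' `% used = 100 * patch size / available substrate`, the fraction of
#' settleable (non-sediment) rock actually colonised. When patch area and
#' available substrate come from the same frames the result is bounded by
#' \[0, 100\].
#'
#' @param patch_size_m2 Coral patch area(s), square metres.
#' @param available_substrate_m2 Available substrate area(s), square metres.
#' @return Percentages; `NA` where both areas are zero (undefined).
#' @export
percent_used <- function(patch_size_m2, available_substrate_m2) {
  if (any(available_substrate_m2 < 0) || any(patch_size_m2 < 0)) {
    abort("Areas must be >= 0.")
  }
  bad <- available_substrate_m2 == 0 & patch_size_m2 > 0
  if (any(bad)) {
    abort("Coral cover reported on zero available substrate (data inconsistency).")
  }
  ifelse(available_substrate_m2 == 0, NA_real_,
         100 * patch_size_m2 / available_substrate_m2)
}

#' Aggregate frames and CTD data into per-site depth bins
#'
#' Implements the survey's aggregation rule: within half-open
#' `[k*w, (k+1)*w)` depth intervals per site, surfaces are summed (surface
#' analysed, available substrate, coral cover) and the remaining quantities
#' averaged (patch size, abundance, coral shape, CTD parameters). Each
#' retained frame is assigned to a bin by its CTD depth; bins with no
#' frames are omitted, and every bin is labelled by its centre (data in a
#' partially sampled interval still plot at the interval centre).
#'
#' CTD parameters are first attached to each frame by nearest-depth record
#' within the same site and then averaged per bin.
#'
#' @param annotations Annotation tibble (see [collect_patches()]).
#' @param geoframes Geoframe tibble with `retained` flags; only retained
#'   frames enter the bins.
#' @param ctd Optional CTD record tibble for per-bin environmental means.
#' @param measurements Optional per-coral measurement tibble for the mean
#'   shape per bin.
#' @param bin_width_m Interval width in metres, default 10.
#' @param abundance Denominator convention for per-bin coral abundance:
#'   `"per_frame"` (mean count over all retained frames in the bin, zeros
#'   included; the default) or `"per_patch_frame"` (mean over patch-bearing
#'   frames only).
#' @return A tibble of class `rov_bins`: `site`, `bin_lower_m`,
#'   `bin_upper_m`, `bin_centre_m`, `n_frames`, `n_patches`,
#'   `surface_analysed_m2`, `available_substrate_m2`, `coral_cover_m2`,
#'   `patch_size_m2` (mean), `abundance`, `shape_mean`, `pct_used`, and the
#'   CTD means when `ctd` is supplied.
#' @export
bin_frames <- function(annotations, geoframes, ctd = NULL,
                       measurements = NULL, bin_width_m = 10,
                       abundance = c("per_frame", "per_patch_frame")) {
  abundance <- match.arg(abundance)
  stop_not_df(annotations, "annotations")
  stop_not_df(geoframes, "geoframes")
  if (!is.numeric(bin_width_m) || bin_width_m <= 0) {
    abort("`bin_width_m` must be positive.")
  }
  require_cols(geoframes, c("frame_id", "site", "y_m", "retained"),
               "geoframes")
  ret <- geoframes[geoframes$retained %in% TRUE, , drop = FALSE]
  if (any(ret$y_m < 0)) abort("Frame depths must be >= 0.")
  df <- dplyr::inner_join(
    tibble::as_tibble(ret)[, c("frame_id", "site", "y_m")],
    tibble::as_tibble(annotations), by = "frame_id")
  df$bin_lower_m <- floor(df$y_m / bin_width_m) * bin_width_m

  if (!is.null(ctd)) {
    env <- nearest_ctd(df$site, df$y_m, ctd)
    df <- dplyr::bind_cols(df, env)
  }
  env_params <- if (is.null(ctd)) character(0) else
    intersect(c("salinity", "temperature_C", "pH", "oxygen_umol_l",
                "fluorescence"), names(df))

  out <- df |>
    dplyr::group_by(.data$site, .data$bin_lower_m) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      n_patches = sum(.data$coral_covered_m2 > 0),
      surface_analysed_m2 = sum(.data$analysed_area_m2),
      available_substrate_m2 = sum(.data$available_substrate_m2),
      coral_cover_m2 = sum(.data$coral_covered_m2),
      patch_size_m2 = mean(.data$coral_covered_m2[.data$coral_covered_m2 > 0]),
      abundance = if (abundance == "per_frame") mean(.data$coral_count) else
        mean(.data$coral_count[.data$coral_covered_m2 > 0]),
      dplyr::across(dplyr::all_of(env_params),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop") |>
    dplyr::mutate(
      patch_size_m2 = ifelse(is.nan(.data$patch_size_m2), NA_real_,
                             .data$patch_size_m2),
      abundance = ifelse(is.nan(.data$abundance), NA_real_, .data$abundance),
      dplyr::across(dplyr::all_of(env_params),
                    ~ ifelse(is.nan(.x), NA_real_, .x)),
      bin_upper_m = .data$bin_lower_m + bin_width_m,
      bin_centre_m = .data$bin_lower_m + bin_width_m / 2,
      pct_used = percent_used(.data$coral_cover_m2,
                              .data$available_substrate_m2))

  if (!is.null(measurements) && nrow(measurements) > 0) {
    sh <- shape_metrics(measurements)
    sh <- dplyr::inner_join(
      sh, tibble::as_tibble(ret)[, c("frame_id", "site", "y_m")],
      by = "frame_id")
    sh$bin_lower_m <- floor(sh$y_m / bin_width_m) * bin_width_m
    sh_bin <- sh |>
      dplyr::group_by(.data$site, .data$bin_lower_m) |>
      dplyr::summarise(shape_mean = mean(.data$shape), .groups = "drop")
    out <- dplyr::left_join(out, sh_bin, by = c("site", "bin_lower_m"))
  } else {
    out$shape_mean <- NA_real_
  }

  out <- out |>
    dplyr::relocate("site", "bin_lower_m", "bin_upper_m", "bin_centre_m",
                    "n_frames", "n_patches", "surface_analysed_m2",
                    "available_substrate_m2", "coral_cover_m2",
                    "patch_size_m2", "abundance", "shape_mean", "pct_used") |>
    dplyr::arrange(.data$site, .data$bin_lower_m)
  class(out) <- c("rov_bins", class(out))
  attr(out, "bin_width_m") <- bin_width_m
  attr(out, "abundance") <- abundance
  out
}
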