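#' Run the full survey pipeline on a synthetic configuration
#'
#' Orchestrates simulate, georeference, overlap-exclude, quantify, bin and
#' test/regress as one seeded, reproducible run: identical configuration
#' and seed give identical results (and identical files when `out_dir` is
#' set).
#'
#' Stages, in order:
#' 1. [generate_survey()] builds frames, annotations, measurements and CTD
#'    casts with known ground truth;
#' 2. [place_frames()] + [exclude_overlaps()] place frames in lanes and
#'    drop overlapping ones;
#' 3. [collect_patches()], [detect_banks()], [shape_metrics()] extract the
#'    coral quantities;
#' 4. [bin_frames()] aggregates into 10-m depth bins with CTD means;
#' 5. [test_break()] and [regress_bins()] run the statistical layer.
#'
#' @param config A [fjord_config()].
#' @param presets Water-mass presets.
#' @param out_dir Optional run directory; when given, all stage outputs,
#'   a `stats.json`, a plain-text `report.txt` and the logged configuration
#'   are written there.
#' @param bin_width_m Depth-bin width, metres.
#' @param break_depth_m Break depth tested; defaults to the configured one.
#' @param B Permutation count for the break test.
#' @param exclude_surface Exclude surface-layer bins from the regressions.
#' @param abundance Abundance denominator, see [bin_frames()].
#' @param overlap_tolerance Tolerated overlap area, see [exclude_overlaps()].
#' @return An object of class `rov_run`: list with `survey`, `geoframes`,
#'   `patches`, `banks`, `shapes`, `bins`, `break_test`, `regressions`
#'   (abundance and substrate-usage responses, whole column and surface
#'   excluded), and `config`.
#' @examples
#' cfg <- fjord_config(n_sites = 2, max_depths_m = c(320, 340),
#'                     frames_per_metre = 0.5, seed = 11)
#' run <- run_pipeline(cfg, B = 500)
#' run$break_test
#' @export
run_pipeline <- function(config = fjord_config(),
                         presets = water_mass_presets(),
                         out_dir = NULL, bin_width_m = 10,
                         break_depth_m = config$break_depth_m, B = 10000,
                         exclude_surface = FALSE,
                         abundance = "per_frame",
                         overlap_tolerance = 0) {
  validate_fjord_config(config)
  survey <- generate_survey(config, presets)

  geo <- place_frames(survey$frames, config$camera,
                      site_order = config$sites)
  geo <- exclude_overlaps(geo, tolerance = overlap_tolerance)

  retained_ann <- survey$annotations[
    survey$annotations$frame_id %in% geo$frame_id[geo$retained], ,
    drop = FALSE]
  patches <- collect_patches(retained_ann, geo)
  banks <- detect_banks(patches, geo)
  retained_meas <- survey$measurements[
    survey$measurements$frame_id %in% geo$frame_id[geo$retained], ,
    drop = FALSE]
  shapes <- shape_metrics(retained_meas)

  bins <- bin_frames(retained_ann, geo, ctd = survey$ctd,
                     measurements = retained_meas,
                     bin_width_m = bin_width_m, abundance = abundance)

  bt <- test_break(bins, response = "abundance",
                   break_depth_m = break_depth_m, B = B,
                   seed = config$seed)

  env <- c("temperature_C", "salinity", "pH", "oxygen_umol_l",
           "available_substrate_m2")
  regressions <- dplyr::bind_rows(lapply(
    c("abundance", "pct_used"), function(resp) {
      dplyr::bind_rows(
        regress_bins(bins, resp, env, exclude_surface = FALSE),
        regress_bins(bins, resp, env, exclude_surface = TRUE,
                     halocline_depth_m = config$halocline_depth_m + 3))
    }))

  run <- structure(
    list(survey = survey, geoframes = geo, patches = patches, banks = banks,
         shapes = shapes, bins = bins, break_test = bt,
         regressions = regressions, config = config,
         bin_width_m = bin_width_m, B = as.integer(B)),
    class = "rov_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.rov_run <- function(x, ...) {
  cat(sprintf(
    "<rov_run> %d sites | %d frames (%d retained) | %d patches | %d banks | %d bins\n",
    x$config$n_sites, nrow(x$geoframes), sum(x$geoframes$retained),
    nrow(x$patches), nrow(x$banks), nrow(x$bins)))
  print(x$break_test)
  invisible(x)
}

#' Write all pipeline outputs to a run directory
#'
#' Emits the synthetic input tables, `geoframes.csv`, `patches.csv`,
#' `banks.csv`, `shapes.csv`, `bins.csv`, the test/regression results as
#' `stats.json`, and a human-readable `report.txt`. All content is a pure
#' function of the run's configuration and seed.
#'
#' @param run An `rov_run` from [run_pipeline()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  if (!inherits(run, "rov_run")) abort("`run` must be an rov_run.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_survey(run$survey, dir)
  readr::write_csv(run$geoframes, file.path(dir, "geoframes.csv"))
  readr::write_csv(run$patches, file.path(dir, "patches.csv"))
  banks_flat <- run$banks
  banks_flat$member_frame_ids <- vapply(
    banks_flat$member_frame_ids, paste, character(1), collapse = ";")
  readr::write_csv(banks_flat, file.path(dir, "banks.csv"))
  readr::write_csv(run$shapes, file.path(dir, "shapes.csv"))
  readr::write_csv(run$bins, file.path(dir, "bins.csv"))
  stats <- list(
    break_test = glance(run$break_test),
    regressions = tidy(run$regressions),
    config = run$config[setdiff(names(run$config), "camera")],
    camera = unclass(run$config$camera),
    bin_width_m = run$bin_width_m, B = run$B)
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  writeLines(run_report(run), file.path(dir, "report.txt"))
  invisible(dir)
}

# Plain-text run summary.
run_report <- function(run) {
  g <- glance(run$break_test)
  c(sprintf("Survey of %d sites, seed %d", run$config$n_sites,
            run$config$seed),
    sprintf("Frames: %d placed, %d retained after overlap exclusion",
            nrow(run$geoframes), sum(run$geoframes$retained)),
    sprintf("Patches: %d; banks (>= 3 consecutive frames): %d",
            nrow(run$patches), nrow(run$banks)),
    sprintf("Depth bins (%g m): %d", run$bin_width_m, nrow(run$bins)),
    sprintf(
      "Break test at %g m: diff = %.4g, Wilcoxon p = %.4g, permutation p = %.4g (B = %d)",
      g$break_depth_m, g$observed_diff, g$wilcoxon_p, g$perm_p, g$B),
    "Regressions (adjusted r-squared):",
    sprintf("  %s ~ %s%s: %.3f", run$regressions$response,
            run$regressions$predictor,
            ifelse(run$regressions$surface_excluded,
                   " (surface excluded)", ""),
            run$regressions$adj_r_squared))
}
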