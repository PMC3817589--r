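#' Generate synthetic CTD down-casts for every site
#'
#' One down-cast per site at 1-m vertical resolution. Each observation is
#' the noise-free water-mass profile value plus Gaussian sensor noise with
#' the per-channel SDs in `config$noise_sd`. Depths within a cast are
#' strictly increasing. Sites listed in `config$salinity_na_sites` get a
#' missing salinity channel.
#'
#' @param config A [fjord_config()].
#' @param presets Water-mass preset tibble; see [water_mass_presets()].
#' @return A tibble of CTD records: `site`, `cast`, `depth_m`, `salinity`,
#'   `temperature_C`, `pH`, `oxygen_umol_l`, `fluorescence`.
#' @export
generate_ctd_casts <- function(config, presets = water_mass_presets()) {
  validate_fjord_config(config)
  presets <- validate_presets(presets, max(config$max_depths_m))
  withr::local_seed(config$seed)
  gen_ctd_(config, presets)
}

gen_ctd_ <- function(config, presets) {
  params <- c("salinity", "temperature_C", "pH", "oxygen_umol_l",
              "fluorescence")
  casts <- purrr::map2(config$sites, config$max_depths_m, function(s, dmax) {
    depth <- seq(1, dmax, by = 1)
    prof <- water_mass_profile(presets, depth)
    rec <- tibble::tibble(site = s, cast = "down", depth_m = depth)
    for (p in params) {
      rec[[p]] <- prof[[p]] + stats::rnorm(length(depth), 0,
                                           config$noise_sd[[p]])
    }
    rec$oxygen_umol_l <- pmax(rec$oxygen_umol_l, 0)
    if (s %in% config$salinity_na_sites) rec$salinity <- NA_real_
    rec
  })
  dplyr::bind_rows(casts)
}

#' Generate a complete synthetic fjord survey with known ground truth
#'
#' Produces, for each site, a down and an up vertical transect of frames on
#' a regular depth grid, per-frame echo-sounder ranges (truncated normal),
#' per-frame substrate/coral annotations, a CTD down-cast, and a ground-truth
#' record of the expectations every downstream stage should recover.
#'
#' The coral model: expected coral count per frame is
#' `density(depth) * available substrate`, with `density` equal to
#' `coral_density_m2` between the halocline and the break depth, and
#' `coral_density_m2 / abundance_drop_factor` below the break (zero in the
#' brackish surface layer, where the coral does not occur). Counts are drawn
#' from a negative binomial (overdispersed, patchy aggregation); frames with
#' a zero count carry zero coral cover. The substrate model: a rock fraction
#' is drawn once per site and `substrate_stratum_m` depth stratum (outcrop
#' scale patchiness, shared by both transects of a site), and the available
#' substrate in a frame is that fraction times the nominal frame area,
#' capped by the frame's actual footprint. Availability is thus governed by
#' geology, not by sampling effort, mirroring the representativeness
#' property of the original survey (available substrate unrelated to
#' surface analysed).
#'
#' @param config A [fjord_config()].
#' @param presets Water-mass presets; see [water_mass_presets()].
#' @return An object of class `rov_survey`: a list with tibbles `frames`,
#'   `annotations`, `measurements`, `ctd`, a `ground_truth` list, and the
#'   `config`.
#' @examples
#' cfg <- fjord_config(n_sites = 2, max_depths_m = c(60, 80), seed = 7)
#' sv <- generate_survey(cfg)
#' sv$frames
#' @export
generate_survey <- function(config, presets = water_mass_presets()) {
  validate_fjord_config(config)
  presets <- validate_presets(presets, max(config$max_depths_m))
  withr::local_seed(config$seed)

  ctd <- gen_ctd_(config, presets)

  # Substrate fraction per site x depth stratum (shared by down/up lanes).
  strata <- purrr::map2(config$sites, config$max_depths_m, function(s, dmax) {
    k <- seq(0, floor(dmax / config$substrate_stratum_m))
    tibble::tibble(site = s, stratum = k,
                   substrate_fraction = rbeta_mc(
                     length(k), config$substrate_fraction_mean,
                     config$substrate_fraction_conc))
  })
  strata <- dplyr::bind_rows(strata)

  frames <- purrr::map2(config$sites, config$max_depths_m, function(s, dmax) {
    depth_down <- seq(1, dmax, by = 1 / config$frames_per_metre)
    depth <- c(depth_down, rev(depth_down))
    dir <- rep(c("down", "up"), each = length(depth_down))
    n <- length(depth)
    tibble::tibble(
      frame_id = sprintf("%s_%s_%05d", s, dir,
                         c(seq_along(depth_down), seq_along(depth_down))),
      site = s, transect = dir,
      timestamp_s = (seq_len(n) - 1) * config$frame_interval_s,
      echo_distance_m = rnorm_pos(n, config$echo_distance_mean_m,
                                  config$echo_distance_sd_m),
      ctd_depth_m = depth
    )
  })
  frames <- dplyr::bind_rows(frames)

  ext <- frame_extent(frames$echo_distance_m, config$camera)
  analysed <- ext$width_m * ext$height_m
  stratum <- floor(frames$ctd_depth_m / config$substrate_stratum_m)
  f_sub <- strata$substrate_fraction[
    match(paste(frames$site, stratum), paste(strata$site, strata$stratum))]
  # Rock area in view is set by the outcrop (stratum fraction x nominal
  # frame area), not by this frame's footprint; the footprint only caps it.
  # Sampling effort therefore does not predict substrate availability.
  available <- pmin(analysed, f_sub * nominal_frame_area(config))

  dens <- coral_density_at(frames$ctd_depth_m, config)
  n_fr <- nrow(frames)
  if (config$occupancy_mean == 0 || config$coral_density_m2 == 0) {
    count <- integer(n_fr)
    covered <- numeric(n_fr)
  } else {
    count <- stats::rnbinom(n_fr, size = config$count_dispersion,
                            mu = dens * available)
    frac <- if (config$occupancy_mean >= 1) rep(1, n_fr) else
      rbeta_mc(n_fr, config$occupancy_mean, config$occupancy_conc)
    covered <- ifelse(count > 0, available * frac, 0)
  }

  annotations <- tibble::tibble(
    frame_id = frames$frame_id,
    analysed_area_m2 = analysed,
    available_substrate_m2 = available,
    coral_covered_m2 = covered,
    coral_count = as.integer(count)
  )

  n_meas <- stats::rbinom(n_fr, count, config$measurable_fraction)
  total <- sum(n_meas)
  if (total > 0) {
    len <- stats::rlnorm(total, log(0.05), 0.35)
    ratio <- stats::rlnorm(total, log(3), 0.45)
    measurements <- tibble::tibble(
      frame_id = rep(frames$frame_id, n_meas),
      coral_id = unlist(lapply(n_meas[n_meas > 0], seq_len)),
      length_m = len, width_m = len / ratio
    )
  } else {
    measurements <- tibble::tibble(frame_id = character(),
                                   coral_id = integer(),
                                   length_m = numeric(), width_m = numeric())
  }

  structure(
    list(frames = frames, annotations = annotations,
         measurements = measurements, ctd = ctd,
         ground_truth = ground_truth_(config), config = config),
    class = "rov_survey"
  )
}

# Expected coral density (counts per m^2 of available substrate) at depth.
coral_density_at <- function(depth_m, config) {
  ifelse(depth_m < config$halocline_depth_m, 0,
         ifelse(depth_m < config$break_depth_m, config$coral_density_m2,
                config$coral_density_m2 / config$abundance_drop_factor))
}

# Expected frame footprint area, ignoring the truncation of the
# echo-distance normal at zero (negligible for mean/sd ratios of 5+).
nominal_frame_area <- function(config) {
  cam <- config$camera
  (config$echo_distance_mean_m^2 + config$echo_distance_sd_m^2) *
    4 * tan(cam$hfov_deg * pi / 360) * tan(cam$vfov_deg * pi / 360)
}

# Expected available substrate per frame: E[min(analysed, f * nominal)]
# by deterministic quadrature over the echo-distance normal and the
# substrate-fraction beta.
expected_available_ <- function(config) {
  a0 <- nominal_frame_area(config)
  s <- config$substrate_fraction_mean
  if (s <= 0) return(0)
  k <- a0 / (config$echo_distance_mean_m^2 + config$echo_distance_sd_m^2)
  if (config$echo_distance_sd_m == 0) {
    areas <- k * config$echo_distance_mean_m^2
    wd <- 1
  } else {
    d <- seq(max(1e-6, config$echo_distance_mean_m -
                   6 * config$echo_distance_sd_m),
             config$echo_distance_mean_m + 6 * config$echo_distance_sd_m,
             length.out = 801)
    wd <- stats::dnorm(d, config$echo_distance_mean_m,
                       config$echo_distance_sd_m)
    wd <- wd / sum(wd)
    areas <- k * d^2
  }
  if (s >= 1) {
    return(sum(wd * pmin(areas, a0)))
  }
  f <- seq(1e-6, 1 - 1e-6, length.out = 801)
  wf <- stats::dbeta(f, s * config$substrate_fraction_conc,
                     (1 - s) * config$substrate_fraction_conc)
  wf <- wf / sum(wf)
  sum(wf * vapply(f, function(fi) sum(wd * pmin(areas, fi * a0)),
                  numeric(1)))
}

# Analytic expectations recorded next to the draws.
ground_truth_ <- function(config, bin_width_m = 10) {
  e_area <- nominal_frame_area(config)
  e_avail <- expected_available_(config)
  above <- config$coral_density_m2 * e_avail
  below <- above / config$abundance_drop_factor

  bins <- purrr::map2(config$sites, config$max_depths_m, function(s, dmax) {
    depth <- seq(1, dmax, by = 1 / config$frames_per_metre)
    dens <- coral_density_at(depth, config)
    lower <- floor(depth / bin_width_m) * bin_width_m
    tibble::tibble(site = s, bin_lower_m = lower, dens = dens) |>
      dplyr::group_by(.data$site, .data$bin_lower_m) |>
      dplyr::summarise(expected_abundance = mean(.data$dens) * e_avail,
                       .groups = "drop") |>
      dplyr::mutate(bin_centre_m = .data$bin_lower_m + bin_width_m / 2)
  })

  list(
    break_depth_m = config$break_depth_m,
    abundance_drop_factor = config$abundance_drop_factor,
    halocline_depth_m = config$halocline_depth_m,
    seed = config$seed,
    expected_frame_area_m2 = e_area,
    expected_available_m2 = e_avail,
    expected_abundance_above = above,
    expected_abundance_below = below,
    bin_width_m = bin_width_m,
    expected_bins = dplyr::bind_rows(bins)
  )
}

#' @export
print.rov_survey <- function(x, ...) {
  cat(sprintf(
    "<rov_survey> %d sites, %d frames, %d CTD records, %d measured corals\n",
    length(unique(x$frames$site)), nrow(x$frames), nrow(x$ctd),
    nrow(x$measurements)))
  cat(sprintf("  break %g m, drop factor %g, seed %d\n",
              x$ground_truth$break_depth_m,
              x$ground_truth$abundance_drop_factor, x$config$seed))
  invisible(x)
}

#' Write a synthetic survey to a directory of delimited text tables
#'
#' Writes `ctd.csv`, `frames.csv`, `annotations.csv`, `measured.csv`
#' (UTF-8, one header line each) and a `ground_truth.json` sidecar.
#'
#' @param survey An `rov_survey` from [generate_survey()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  if (!inherits(survey, "rov_survey")) abort("`survey` must be an rov_survey.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(survey$ctd, file.path(dir, "ctd.csv"))
  readr::write_csv(survey$frames, file.path(dir, "frames.csv"))
  readr::write_csv(survey$annotations, file.path(dir, "annotations.csv"))
  readr::write_csv(survey$measurements, file.path(dir, "measured.csv"))
  jsonlite::write_json(survey$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
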