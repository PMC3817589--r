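#' Configure a synthetic fjord survey
#'
#' Bundles every knob of the synthetic-survey generator. The defaults emulate
#' the design of the ROV campaign the package is built around: seven dive
#' sites along the fjord axis (codes `LL`, `CL`, `NT`, `SW`, `CH`, `PG`, `RB`
#' with their maximum dive depths), a brackish surface layer above ~7 m, a
#' coral abundance break at 275 m (the midpoint of the 270--280 m band), and
#' down+up vertical transects of frames per site.
#'
#' @param n_sites Number of dive sites along the fjord axis.
#' @param sites Character site codes; defaults to the canonical seven.
#' @param site_spacing_km Along-fjord spacing between sites (bookkeeping only).
#' @param max_depths_m Per-site maximum dive depth, metres.
#' @param halocline_depth_m Bottom of the low-salinity surface layer, metres.
#' @param break_depth_m Depth of the abundance break, metres. Must exceed
#'   `halocline_depth_m`.
#' @param abundance_drop_factor Ratio (>= 1) of expected per-area coral
#'   abundance above the break to below it. 1 means no break.
#' @param coral_density_m2 Expected coral count per square metre of available
#'   substrate above the break.
#' @param count_dispersion Negative-binomial size parameter for per-frame
#'   coral counts; smaller values give patchier aggregation.
#' @param frames_per_metre Frame extraction rate mapped onto the depth axis.
#'   The 10-s video extraction cadence corresponds to a depth grid through an
#'   assumed constant vertical speed.
#' @param frame_interval_s Nominal seconds between extracted frames.
#' @param echo_distance_mean_m,echo_distance_sd_m Mean and SD of the
#'   camera-to-substrate echo-sounder range (truncated > 0).
#' @param substrate_fraction_mean Mean fraction of the analysed area that is
#'   non-sediment rock (available substrate), in \[0, 1\].
#' @param substrate_fraction_conc Beta concentration of the substrate
#'   fraction; low values emulate geologically patchy rock/sediment cover.
#' @param substrate_stratum_m Vertical scale (m) over which the substrate
#'   fraction is constant at a site; rock/sediment patchiness has outcrop
#'   scale structure, not frame-to-frame independence.
#' @param occupancy_mean Expected fraction of available substrate covered by
#'   coral, above the break, in \[0, 1\].
#' @param occupancy_conc Beta concentration of per-frame coral cover.
#' @param measurable_fraction Probability that an individual coral is
#'   adequately oriented for length/width measurement.
#' @param salinity_na_sites Site codes whose salinity record is withheld
#'   (emulates a failed conductivity channel at one station).
#' @param noise_sd Named numeric vector of Gaussian sensor noise SDs for the
#'   CTD channels `salinity`, `temperature_C`, `pH`, `oxygen_umol_l`,
#'   `fluorescence`.
#' @param camera A [camera_model()] used to scale frames.
#' @param seed Integer RNG seed; identical configurations reproduce
#'   identical datasets byte for byte.
#'
#' @return A validated list of class `fjord_config`.
#' @seealso [generate_survey()], [water_mass_presets()]
#' @export
fjord_config <- function(n_sites = 7,
                         sites = NULL,
                         site_spacing_km = 6.5,
                         max_depths_m = NULL,
                         halocline_depth_m = 7,
                         break_depth_m = 275,
                         abundance_drop_factor = 5,
                         coral_density_m2 = 100,
                         count_dispersion = 1.5,
                         frames_per_metre = 2,
                         frame_interval_s = 10,
                         echo_distance_mean_m = 1,
                         echo_distance_sd_m = 0.2,
                         substrate_fraction_mean = 0.5,
                         substrate_fraction_conc = 1.5,
                         substrate_stratum_m = 10,
                         occupancy_mean = 0.3,
                         occupancy_conc = 5,
                         measurable_fraction = 0.3,
                         salinity_na_sites = character(),
                         noise_sd = c(salinity = 0.15, temperature_C = 0.15,
                                      pH = 0.03, oxygen_umol_l = 5,
                                      fluorescence = 0.1),
                         camera = camera_model(),
                         seed = 1L) {
  canonical <- c(LL = 198, CL = 115, NT = 422, SW = 209,
                 CH = 282, PG = 355, RB = 216)
  if (is.null(sites)) {
    sites <- if (n_sites <= length(canonical)) {
      names(canonical)[seq_len(n_sites)]
    } else {
      c(names(canonical), sprintf("S%d", seq(length(canonical) + 1, n_sites)))
    }
  }
  if (length(sites) != n_sites) abort("`sites` must have length `n_sites`.")
  if (is.null(max_depths_m)) {
    max_depths_m <- unname(ifelse(sites %in% names(canonical),
                                  canonical[sites], 300))
  }
  max_depths_m <- rep_len(max_depths_m, n_sites)

  cfg <- structure(
    list(n_sites = as.integer(n_sites), sites = sites,
         site_spacing_km = site_spacing_km, max_depths_m = max_depths_m,
         halocline_depth_m = halocline_depth_m, break_depth_m = break_depth_m,
         abundance_drop_factor = abundance_drop_factor,
         coral_density_m2 = coral_density_m2,
         count_dispersion = count_dispersion,
         frames_per_metre = frames_per_metre,
         frame_interval_s = frame_interval_s,
         echo_distance_mean_m = echo_distance_mean_m,
         echo_distance_sd_m = echo_distance_sd_m,
         substrate_fraction_mean = substrate_fraction_mean,
         substrate_fraction_conc = substrate_fraction_conc,
         substrate_stratum_m = substrate_stratum_m,
         occupancy_mean = occupancy_mean, occupancy_conc = occupancy_conc,
         measurable_fraction = measurable_fraction,
         salinity_na_sites = salinity_na_sites,
         noise_sd = noise_sd, camera = camera, seed = as.integer(seed)),
    class = "fjord_config"
  )
  validate_fjord_config(cfg)
  cfg
}

#' Validate a fjord survey configuration
#'
#' Checks the structural invariants of a [fjord_config()]: the abundance
#' break must lie below the halocline, the drop factor cannot be < 1, all
#' fraction parameters must lie in \[0, 1\], and rates/ranges must be
#' positive. Called automatically by the constructor.
#'
#' @param config A `fjord_config`.
#' @return `config`, invisibly, if valid; otherwise an error.
#' @export
validate_fjord_config <- function(config) {
  if (!inherits(config, "fjord_config")) abort("Not a `fjord_config` object.")
  with(config, {
    if (break_depth_m <= halocline_depth_m) {
      abort("`break_depth_m` must exceed `halocline_depth_m`.")
    }
    if (abundance_drop_factor < 1) {
      abort("`abundance_drop_factor` must be >= 1.")
    }
    for (f in c(substrate_fraction_mean, occupancy_mean, measurable_fraction)) {
      if (f < 0 || f > 1) abort("Fraction parameters must lie in [0, 1].")
    }
    if (echo_distance_mean_m <= 0) {
      abort("`echo_distance_mean_m` must be positive.")
    }
    if (echo_distance_sd_m < 0) abort("`echo_distance_sd_m` must be >= 0.")
    if (frames_per_metre <= 0) abort("`frames_per_metre` must be positive.")
    if (coral_density_m2 < 0) abort("`coral_density_m2` must be >= 0.")
    if (any(max_depths_m <= halocline_depth_m)) {
      abort("Every site's `max_depths_m` must exceed the halocline depth.")
    }
    if (any(!c("salinity", "temperature_C", "pH", "oxygen_umol_l",
               "fluorescence") %in% names(noise_sd))) {
      abort("`noise_sd` must name all five CTD channels.")
    }
    if (any(noise_sd < 0)) abort("`noise_sd` entries must be >= 0.")
  })
  invisible(config)
}

#' @export
print.fjord_config <- function(x, ...) {
  cat(sprintf(
    "<fjord_config> %d sites (%s)\n  break %g m (drop x%g), halocline %g m, %g frames/m, seed %d\n",
    x$n_sites, paste(x$sites, collapse = ", "),
    x$break_depth_m, x$abundance_drop_factor, x$halocline_depth_m,
    x$frames_per_metre, x$seed))
  invisible(x)
}
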