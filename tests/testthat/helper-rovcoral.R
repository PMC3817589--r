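# Shared fixtures and independent oracles for the test suite.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_sites = 2, max_depths_m = c(40, 60),
                   frames_per_metre = 1, measurable_fraction = 0.2,
                   seed = 42)
  do.call(fjord_config, utils::modifyList(defaults, args))
}

# Independent trigonometric oracle for frame footprints.
oracle_extent <- function(distance, fov_deg) {
  2 * distance * tan(fov_deg / 2 * pi / 180)
}

# Brute-force 1-D interval-union retention: a frame is kept iff its depth
# interval has zero-length intersection with the union of previously kept
# intervals. Valid reference for same-lane frames (which always overlap in
# x) at zero tolerance.
oracle_retain_1d <- function(lo, hi) {
  keep <- logical(length(lo))
  seg_lo <- seg_hi <- numeric(0)
  for (i in seq_along(lo)) {
    ov <- sum(pmax(0, pmin(seg_hi, hi[i]) - pmax(seg_lo, lo[i])))
    if (ov <= 1e-12) {
      keep[i] <- TRUE
      seg_lo <- c(seg_lo, lo[i])
      seg_hi <- c(seg_hi, hi[i])
    }
  }
  keep
}

# Exhaustive two-sided rank-sum p-value by enumerating every assignment of
# the pooled values to groups and counting pairwise wins (Mann-Whitney U),
# independent of the implementation's rank-sum path.
oracle_wilcoxon_p <- function(a, b) {
  vals <- c(a, b)
  n_a <- length(a)
  ustat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- ustat(a, b)
  mu <- n_a * length(b) / 2
  splits <- utils::combn(length(vals), n_a)
  us <- apply(splits, 2, function(ix) ustat(vals[ix], vals[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Minimal hand-built geoframe/annotation pair for binning tests: one lane,
# all frames retained.
manual_frames <- function(depths, analysed, available, covered, counts,
                          site = "S1") {
  n <- length(depths)
  geo <- tibble::tibble(
    frame_id = sprintf("F%03d", seq_len(n)), site = site,
    transect = "down", timestamp_s = 10 * (seq_len(n) - 1),
    echo_distance_m = 1, ctd_depth_m = depths,
    width_m = 1, height_m = 1, pixel_size_x_m = 1 / 1920,
    pixel_size_y_m = 1 / 1080, lane = 1L, x_m = 0, y_m = depths,
    retained = TRUE)
  ann <- tibble::tibble(
    frame_id = geo$frame_id, analysed_area_m2 = analysed,
    available_substrate_m2 = available, coral_covered_m2 = covered,
    coral_count = as.integer(counts))
  list(geo = geo, ann = ann)
}

# Constant-profile single-layer presets for zero-noise identity checks.
flat_presets <- function(pH = 8, salinity = 30, temperature_C = 11,
                         oxygen_umol_l = 200, fluorescence = 0.5,
                         max_depth_m = 500) {
  tibble::tibble(
    layer_id = 1L, depth_min_m = 0, depth_max_m = max_depth_m,
    salinity = salinity, salinity_grad = 0,
    temperature_C = temperature_C, temperature_C_grad = 0,
    pH = pH, pH_grad = 0,
    oxygen_umol_l = oxygen_umol_l, oxygen_umol_l_grad = 0,
    fluorescence = fluorescence, fluorescence_grad = 0)
}

zero_noise <- c(salinity = 0, temperature_C = 0, pH = 0,
                oxygen_umol_l = 0, fluorescence = 0)
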