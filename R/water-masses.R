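#' Default water-mass presets for the synthetic water column
#'
#' The synthetic CTD generator draws noisy observations around a piecewise
#' linear vertical profile made of stacked water-mass layers. The default
#' four-layer stack emulates a stratified Patagonian fjord in austral summer:
#'
#' 1. a thin brackish surface layer (low salinity, warm, high pH/oxygen,
#'    high fluorescence) above the halocline,
#' 2. a subsurface transition with a local pH/oxygen minimum below the
#'    halocline (layer id 4, kept at its depth position),
#' 3. an intermediate layer of oceanic origin occupying most of the column,
#' 4. a deep basin layer with the overall lowest pH and oxygen (layer id 3),
#'    reflecting long residence time and decomposition at depth.
#'
#' Each layer row gives the value of every parameter at the top of the layer
#' plus a per-metre linear gradient within the layer. Layers are half-open
#' `[depth_min_m, depth_max_m)` and must tile the column without gaps.
#'
#' @param max_depth_m Bottom of the modelled water column, metres.
#' @return A tibble with one row per layer: `layer_id`, `depth_min_m`,
#'   `depth_max_m`, and `<param>` / `<param>_grad` pairs for `salinity`,
#'   `temperature_C`, `pH`, `oxygen_umol_l`, `fluorescence`.
#' @seealso [water_mass_profile()], [generate_ctd_casts()]
#' @export
water_mass_presets <- function(max_depth_m = 480) {
  tibble::tribble(
    ~layer_id, ~depth_min_m, ~depth_max_m,
    ~salinity, ~salinity_grad,
    ~temperature_C, ~temperature_C_grad,
    ~pH, ~pH_grad,
    ~oxygen_umol_l, ~oxygen_umol_l_grad,
    ~fluorescence, ~fluorescence_grad,
    1L,   0,   7, 15.0,  0.9, 16.5, -0.25, 8.30,  0.000, 265,  2.0, 3.0,  0.00,
    4L,   7,  22, 31.2,  0.03, 12.5, -0.10, 8.05, -0.012, 245, -5.5, 1.8, -0.10,
    2L,  22, 300, 31.9,  0.003, 10.9,  0.001, 7.84,  0.0002, 150,  0.03, 0.3, -0.001,
    3L, 300, max_depth_m, 32.8, 0.001, 10.5, 0.002, 7.79, -0.0005, 125, -0.18, 0.05, 0
  )
}

#' Validate that water-mass presets tile the water column
#'
#' @param presets Preset tibble as from [water_mass_presets()].
#' @param max_depth_m Depth the presets must cover, metres.
#' @return `presets` (sorted by `depth_min_m`), invisibly-checked.
#' @export
validate_presets <- function(presets, max_depth_m) {
  stop_not_df(presets, "presets")
  require_cols(presets, c("layer_id", "depth_min_m", "depth_max_m"), "presets")
  presets <- dplyr::arrange(presets, .data$depth_min_m)
  if (presets$depth_min_m[1] > 0) {
    abort("Water-mass presets must start at the surface (depth 0).")
  }
  if (nrow(presets) > 1) {
    lo <- presets$depth_min_m[-1]
    hi <- presets$depth_max_m[-nrow(presets)]
    if (any(lo > hi)) abort("Water-mass presets leave a gap in the column.")
    if (any(lo < hi)) abort("Water-mass presets overlap in depth.")
  }
  if (max(presets$depth_max_m) < max_depth_m) {
    abort(sprintf("Presets cover only to %g m but %g m is required.",
                  max(presets$depth_max_m), max_depth_m))
  }
  presets
}

#' Evaluate the noise-free water-mass profile at given depths
#'
#' Looks up the layer containing each depth (half-open intervals; a depth on
#' a boundary belongs to the deeper layer, and the bottom of the deepest
#' layer is included) and evaluates the linear within-layer profile.
#'
#' @param presets Preset tibble, see [water_mass_presets()].
#' @param depth_m Numeric depths, metres, >= 0.
#' @return A tibble with `depth_m`, `layer_id` and the five parameters.
#' @export
water_mass_profile <- function(presets, depth_m) {
  presets <- validate_presets(presets, max(depth_m))
  if (any(depth_m < 0)) abort("Depths must be >= 0.")
  idx <- findInterval(depth_m, presets$depth_min_m)
  idx[depth_m >= max(presets$depth_max_m)] <- nrow(presets)
  params <- c("salinity", "temperature_C", "pH", "oxygen_umol_l",
              "fluorescence")
  dz <- depth_m - presets$depth_min_m[idx]
  out <- tibble::tibble(depth_m = depth_m, layer_id = presets$layer_id[idx])
  for (p in params) {
    out[[p]] <- presets[[p]][idx] + presets[[paste0(p, "_grad")]][idx] * dz
  }
  out
}
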