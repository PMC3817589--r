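#' Read a delimited CTD cast table
#'
#' Reads a comma- or tab-separated table of depth-stamped physico-chemical
#' records. Columns can be renamed via `col_map` so field exports with other
#' headers slot into the standard names used throughout the package. Cells
#' that do not parse as numbers (including `"NA"`) become missing values;
#' the row count of the file is preserved.
#'
#' @param path Path to the table. The delimiter is sniffed from the header
#'   line (tab wins over comma) unless `delim` is given.
#' @param col_map Optional named character vector mapping standard names
#'   (`site`, `depth_m`, `salinity`, `temperature_C`, `pH`,
#'   `oxygen_umol_l`, `fluorescence`, `cast`) to the file's column names.
#' @param delim Field delimiter; `NULL` to sniff.
#' @return A tibble of CTD records with at least `site` and `depth_m`.
#' @export
read_ctd_table <- function(path, col_map = NULL, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("CTD file not found: %s", path))
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[std]]] <- std
      }
    }
  }
  for (mandatory in c("site", "depth_m")) {
    if (!mandatory %in% names(raw)) {
      abort(sprintf("CTD table %s lacks mandatory column '%s'.",
                    path, mandatory))
    }
  }
  num_cols <- setdiff(names(raw), c("site", "cast"))
  for (p in num_cols) raw[[p]] <- suppressWarnings(as.numeric(raw[[p]]))
  if (any(!is.na(raw$depth_m) & raw$depth_m < 0)) {
    abort("CTD table contains negative depths.")
  }
  raw
}

#' Read a CTD table in the PANGAEA tab-separated dialect
#'
#' Data repository exports wrap a tab-separated table in a `/* ... */`
#' comment header and use descriptive column labels. This reader strips the
#' header block and maps the usual labels (`Depth water [m]`, `Sal`,
#' `Temp [deg C]`, `pH`, `O2 [µmol/l]`, `Fluorometer [arbitrary units]`,
#' `Event`) onto the package's standard names.
#'
#' @param path Path to the `.tab` file.
#' @return A tibble of CTD records.
#' @export
read_pangaea_ctd <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  start <- 1L
  if (length(lines) > 0 && startsWith(lines[1], "/*")) {
    end <- grep("^\\*/", lines)[1]
    if (is.na(end)) abort("Unterminated /* ... */ header block.")
    start <- end + 1L
  }
  tmp <- tempfile(fileext = ".tab")
  on.exit(unlink(tmp))
  writeLines(lines[start:length(lines)], tmp)
  raw <- readr::read_tsv(tmp, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  label_map <- c(
    "^Event" = "site", "^Depth" = "depth_m", "^Sal" = "salinity",
    "^Temp" = "temperature_C", "^pH" = "pH", "^O2|^Oxygen" = "oxygen_umol_l",
    "^Fluoro|^Chl" = "fluorescence"
  )
  for (pat in names(label_map)) {
    hit <- grep(pat, names(raw))
    if (length(hit) > 0) names(raw)[hit[1]] <- label_map[[pat]]
  }
  for (mandatory in c("site", "depth_m")) {
    if (!mandatory %in% names(raw)) {
      abort(sprintf("PANGAEA table lacks a recognisable '%s' column.",
                    mandatory))
    }
  }
  num_cols <- setdiff(names(raw), c("site", "cast"))
  for (p in num_cols) raw[[p]] <- suppressWarnings(as.numeric(raw[[p]]))
  raw
}

ctd_params <- function(records) {
  intersect(c("salinity", "temperature_C", "pH", "oxygen_umol_l",
              "fluorescence"), names(records))
}

#' Per-site summary statistics of CTD parameters
#'
#' Computes, for each site and parameter, the range (`min`, `max`), `mean`
#' and sample (`n - 1`) standard deviation over non-missing values, the way
#' site-statistics tables report "Range" and "Mean +/- SD". Parameters with
#' no valid values at a site (e.g. a dead salinity channel) are reported as
#' absent rather than as zeros.
#'
#' @param records CTD record tibble (see [read_ctd_table()]).
#' @param sites Optional site codes to keep (default: all).
#' @param depth_range Optional length-2 numeric `c(min, max)` depth filter,
#'   inclusive.
#' @param cast Optional cast direction filter (`"down"` / `"up"`) applied
#'   when the records carry a `cast` column; default uses all records.
#' @return A tibble: `site`, `depth_min_m`, `depth_max_m`, `parameter`,
#'   `n`, `min`, `max`, `mean`, `sd`.
#' @export
site_summary <- function(records, sites = NULL, depth_range = NULL,
                         cast = NULL) {
  stop_not_df(records, "records")
  require_cols(records, c("site", "depth_m"), "records")
  if (!is.null(cast) && "cast" %in% names(records)) {
    records <- records[records$cast %in% cast, , drop = FALSE]
  }
  if (!is.null(depth_range)) {
    records <- records[records$depth_m >= depth_range[1] &
                         records$depth_m <= depth_range[2], , drop = FALSE]
  }
  if (!is.null(sites)) {
    absent <- setdiff(sites, unique(records$site))
    if (length(absent) > 0) {
      abort(sprintf("No CTD records for site(s): %s.",
                    paste(absent, collapse = ", ")))
    }
    records <- records[records$site %in% sites, , drop = FALSE]
  }
  if (nrow(records) == 0) abort("No CTD records left after filtering.")
  params <- ctd_params(records)
  long <- tidyr::pivot_longer(
    records[, c("site", "depth_m", params)],
    dplyr::all_of(params), names_to = "parameter", values_to = "value")
  long |>
    dplyr::group_by(.data$site, .data$parameter) |>
    dplyr::summarise(
      depth_min_m = min(.data$depth_m), depth_max_m = max(.data$depth_m),
      n = sum(!is.na(.data$value)),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::filter(.data$n > 0) |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = params)) |>
    dplyr::arrange(.data$parameter, .data$site) |>
    dplyr::relocate("site", "depth_min_m", "depth_max_m", "parameter")
}

#' Grid CTD records into a site-by-depth-bin section
#'
#' Bin-average gridding of cast records into half-open 10-m (by default)
#' depth intervals per site, the tabular counterpart of a contoured
#' along-fjord section. Cells with no records, or only missing values, are
#' flagged missing (`NA` value, `n = 0`); the full site x bin x parameter
#' grid is returned so missing cells are explicit.
#'
#' @param records CTD record tibble.
#' @param depth_bin_m Bin width in metres, > 0.
#' @param site_order Optional character vector giving the along-fjord order
#'   of sites (e.g. mouth to head); defaults to order of appearance.
#' @param cast Optional cast filter, as in [site_summary()]; sections are
#'   conventionally drawn from down-casts.
#' @return A tibble: `site` (factor in section order), `bin_lower_m`,
#'   `bin_centre_m`, `parameter`, `value`, `n`.
#' @export
grid_section <- function(records, depth_bin_m = 10, site_order = NULL,
                         cast = NULL) {
  stop_not_df(records, "records")
  require_cols(records, c("site", "depth_m"), "records")
  if (!is.numeric(depth_bin_m) || depth_bin_m <= 0) {
    abort("`depth_bin_m` must be positive.")
  }
  if (!is.null(cast) && "cast" %in% names(records)) {
    records <- records[records$cast %in% cast, , drop = FALSE]
  }
  if (nrow(records) == 0) abort("No CTD records to grid.")
  site_order <- site_order %||% unique(records$site)
  unknown <- setdiff(unique(records$site), site_order)
  if (length(unknown) > 0) {
    abort(sprintf("Site(s) not in `site_order`: %s.",
                  paste(unknown, collapse = ", ")))
  }
  params <- ctd_params(records)
  long <- tidyr::pivot_longer(
    records[, c("site", "depth_m", params)],
    dplyr::all_of(params), names_to = "parameter", values_to = "value")
  cells <- long |>
    dplyr::mutate(bin_lower_m = floor(.data$depth_m / depth_bin_m) *
                    depth_bin_m) |>
    dplyr::group_by(.data$site, .data$bin_lower_m, .data$parameter) |>
    dplyr::summarise(n = sum(!is.na(.data$value)),
                     value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value))
  grid <- tidyr::complete(
    cells,
    site = site_order,
    bin_lower_m = seq(min(cells$bin_lower_m), max(cells$bin_lower_m),
                      by = depth_bin_m),
    parameter = params,
    fill = list(value = NA_real_, n = 0L))
  grid |>
    dplyr::mutate(site = factor(.data$site, levels = site_order),
                  bin_centre_m = .data$bin_lower_m + depth_bin_m / 2,
                  parameter = factor(.data$parameter, levels = params)) |>
    dplyr::arrange(.data$parameter, .data$site, .data$bin_lower_m) |>
    dplyr::relocate("site", "bin_lower_m", "bin_centre_m", "parameter",
                    "value", "n")
}
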