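#' Place frames in the fjord coordinate system
#'
#' Every frame is scaled from its echo-sounder range via [frame_extent()]
#' and placed with the CTD depth on the y axis (positive down) and an
#' arbitrary x coordinate that respects the along-fjord sequence of sites:
#' each (site, transect) pair gets its own vertical lane, lanes ordered by
#' `site_order` with the down transect before the up transect, and lane
#' spacing of `lane_spacing_factor` times the widest frame so lanes can
#' never overlap ("next to each other but not overlapping").
#'
#' @param frames Frame-metadata tibble with columns `frame_id`, `site`,
#'   `transect` (`"down"`/`"up"`), `timestamp_s`, `echo_distance_m`,
#'   `ctd_depth_m`.
#' @param camera A [camera_model()].
#' @param site_order Character vector of site codes in along-fjord order;
#'   defaults to order of first appearance. Frames at sites not listed are
#'   an error.
#' @param lane_spacing_factor Lane pitch as a multiple of the maximum frame
#'   width; must be >= 1.
#' @return A geoframe tibble: the input keys plus `width_m`, `height_m`,
#'   `pixel_size_x_m`, `pixel_size_y_m`, `lane`, `x_m`, `y_m`, and a
#'   `retained` flag initialised to `NA` (set by [exclude_overlaps()]).
#' @export
place_frames <- function(frames, camera = camera_model(), site_order = NULL,
                         lane_spacing_factor = 1.5) {
  stop_not_df(frames, "frames")
  require_cols(frames, c("frame_id", "site", "transect", "echo_distance_m",
                         "ctd_depth_m"), "frames")
  if (lane_spacing_factor < 1) abort("`lane_spacing_factor` must be >= 1.")
  site_order <- site_order %||% unique(frames$site)
  if (nrow(frames) == 0) {
    return(tibble::tibble(
      frame_id = character(), site = character(), transect = character(),
      timestamp_s = numeric(), echo_distance_m = numeric(),
      ctd_depth_m = numeric(), width_m = numeric(), height_m = numeric(),
      pixel_size_x_m = numeric(), pixel_size_y_m = numeric(),
      lane = integer(), x_m = numeric(), y_m = numeric(),
      retained = logical()))
  }
  unknown <- setdiff(unique(frames$site), site_order)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown site code(s): %s.", paste(unknown, collapse = ", ")))
  }
  if (any(!frames$transect %in% c("down", "up"))) {
    abort("`transect` must be 'down' or 'up'.")
  }
  if (any(frames$ctd_depth_m < 0)) abort("Frame depths must be >= 0.")

  ext <- frame_extent(frames$echo_distance_m, camera)
  lane_width <- max(ext$width_m) * lane_spacing_factor
  site_rank <- match(frames$site, site_order)
  lane <- (site_rank - 1L) * 2L + (frames$transect == "up") + 1L

  out <- dplyr::mutate(
    tibble::as_tibble(frames),
    width_m = ext$width_m,
    height_m = ext$height_m,
    pixel_size_x_m = ext$width_m / camera$pixel_width,
    pixel_size_y_m = ext$height_m / camera$pixel_height,
    lane = as.integer(lane),
    x_m = (lane - 0.5) * lane_width,
    y_m = .data$ctd_depth_m,
    retained = NA
  )
  if (!"timestamp_s" %in% names(out)) out$timestamp_s <- seq_len(nrow(out))
  out
}

# Area of the union of axis-aligned rectangles, by y-slab sweep with
# x-interval merging inside each slab.
rect_union_area <- function(xlo, xhi, ylo, yhi) {
  if (length(xlo) == 0) return(0)
  ys <- sort(unique(c(ylo, yhi)))
  area <- 0
  for (i in seq_len(length(ys) - 1L)) {
    y0 <- ys[i]; y1 <- ys[i + 1L]
    sel <- ylo < y1 & yhi > y0
    if (!any(sel)) next
    o <- order(xlo[sel])
    xl <- xlo[sel][o]; xh <- xhi[sel][o]
    tot <- 0; cur_lo <- xl[1]; cur_hi <- xh[1]
    if (length(xl) > 1) {
      for (j in 2:length(xl)) {
        if (xl[j] > cur_hi) {
          tot <- tot + cur_hi - cur_lo
          cur_lo <- xl[j]; cur_hi <- xh[j]
        } else if (xh[j] > cur_hi) cur_hi <- xh[j]
      }
    }
    tot <- tot + cur_hi - cur_lo
    area <- area + tot * (y1 - y0)
  }
  area
}

# Greedy retention within one lane, frames already in acquisition order.
exclude_lane_ <- function(xlo, xhi, ylo, yhi, tolerance) {
  n <- length(xlo)
  keep <- logical(n)
  kx0 <- kx1 <- ky0 <- ky1 <- numeric(0)
  eps <- 1e-12
  for (i in seq_len(n)) {
    ov <- which(kx0 < xhi[i] & kx1 > xlo[i] & ky0 < yhi[i] & ky1 > ylo[i])
    if (length(ov) == 0) {
      inter <- 0
    } else {
      inter <- rect_union_area(pmax(kx0[ov], xlo[i]), pmin(kx1[ov], xhi[i]),
                               pmax(ky0[ov], ylo[i]), pmin(ky1[ov], yhi[i]))
    }
    if (inter <= tolerance + eps) {
      keep[i] <- TRUE
      kx0 <- c(kx0, xlo[i]); kx1 <- c(kx1, xhi[i])
      ky0 <- c(ky0, ylo[i]); ky1 <- c(ky1, yhi[i])
    }
  }
  keep
}

#' Exclude overlapping frames within each lane
#'
#' Frames are processed in acquisition order (by `timestamp_s` within each
#' lane). A frame is retained if and only if the area of intersection
#' between its rectangle and the union of the previously retained
#' rectangles in the same lane is at most `tolerance` (default 0, i.e. any
#' positive overlap excludes). The greedy in-order rule is deterministic and
#' respects the transect sequence; lanes never interact because their
#' rectangles are disjoint by construction.
#'
#' @param geos Geoframe tibble from [place_frames()].
#' @param tolerance Maximum tolerated intersection area in square metres.
#' @return `geos` with the `retained` logical filled in, original row order
#'   preserved.
#' @export
exclude_overlaps <- function(geos, tolerance = 0) {
  stop_not_df(geos, "geos")
  require_cols(geos, c("lane", "x_m", "y_m", "width_m", "height_m"), "geos")
  if (tolerance < 0) abort("`tolerance` must be >= 0.")
  if (nrow(geos) == 0) return(geos)
  geos <- tibble::as_tibble(geos)
  geos$retained <- NA
  ord_key <- if ("timestamp_s" %in% names(geos)) geos$timestamp_s else
    seq_len(nrow(geos))
  for (ln in unique(geos$lane)) {
    rows <- which(geos$lane == ln)
    rows <- rows[order(ord_key[rows])]
    keep <- exclude_lane_(
      geos$x_m[rows] - geos$width_m[rows] / 2,
      geos$x_m[rows] + geos$width_m[rows] / 2,
      geos$y_m[rows] - geos$height_m[rows] / 2,
      geos$y_m[rows] + geos$height_m[rows] / 2,
      tolerance)
    geos$retained[rows] <- keep
  }
  geos
}

# Fixed-decimal formatting with ~12 significant digits; worldfile lines are
# plain decimal notation, never scientific.
fmt_worldfile_num <- function(v) {
  vapply(v, function(x) {
    if (x == 0) return("0.0")
    decs <- max(1L, 12L - max(0L, floor(log10(abs(x))) + 1L))
    formatC(x, format = "f", digits = decs)
  }, character(1))
}

#' Worldfile parameters and text for a placed frame
#'
#' An ESRI worldfile is a six-line text sidecar giving the affine placement
#' of an image in map coordinates: pixel x-size `A`, rotations `D` and `B`
#' (zero here, axis-aligned), negative pixel y-size `E`, and the map
#' coordinates `C`, `F` of the centre of the upper-left pixel. Map space is
#' y-up, so depth enters negated and `E < 0`; the analytic pipeline keeps
#' depth positive-down throughout.
#'
#' @param geo A one-row geoframe (from [place_frames()]).
#' @return Named list with elements `A`, `D`, `B`, `E`, `C`, `F`.
#' @export
worldfile_params <- function(geo) {
  stop_not_df(geo, "geo")
  require_cols(geo, c("x_m", "y_m", "width_m", "height_m",
                      "pixel_size_x_m", "pixel_size_y_m"), "geo")
  if (nrow(geo) != 1) abort("`geo` must be a single geoframe row.")
  if (geo$pixel_size_x_m <= 0 || geo$pixel_size_y_m <= 0) {
    abort("Pixel sizes must be positive (zero pixel counts?).")
  }
  A <- geo$pixel_size_x_m
  E <- -geo$pixel_size_y_m
  C <- geo$x_m - geo$width_m / 2 + A / 2
  F <- -geo$y_m + geo$height_m / 2 + E / 2
  list(A = A, D = 0, B = 0, E = E, C = C, F = F)
}

#' @rdname worldfile_params
#' @param path Optional file path; when given the text is also written
#'   (conventionally `<frame_id>.pgw` next to `<frame_id>.png`).
#' @return `worldfile_text()`: the six-line text, invisibly when written.
#' @export
worldfile_text <- function(geo, path = NULL) {
  p <- worldfile_params(geo)
  txt <- fmt_worldfile_num(c(p$A, p$D, p$B, p$E, p$C, p$F))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write worldfiles for all retained frames
#'
#' @param geos Geoframe tibble with `retained` flags.
#' @param dir Output directory for the `.pgw` sidecars.
#' @param retained_only Write only retained frames (default) or all.
#' @return Invisible character vector of file paths written.
#' @export
write_worldfiles <- function(geos, dir, retained_only = TRUE) {
  stop_not_df(geos, "geos")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- if (retained_only && "retained" %in% names(geos)) {
    which(geos$retained %in% TRUE)
  } else {
    seq_len(nrow(geos))
  }
  paths <- character(0)
  for (i in rows) {
    p <- file.path(dir, paste0(geos$frame_id[i], ".pgw"))
    worldfile_text(geos[i, ], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Parse a six-line worldfile
#'
#' @param path Path to a `.pgw` file.
#' @return Named list `A`, `D`, `B`, `E`, `C`, `F`.
#' @export
read_worldfile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) != 6) abort("A worldfile must have exactly six lines.")
  vals <- as.numeric(lines)
  if (any(is.na(vals))) abort("Worldfile lines must each hold one number.")
  setNames(as.list(vals), c("A", "D", "B", "E", "C", "F"))
}
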