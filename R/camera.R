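#' Define a pinhole camera model for frame scaling
#'
#' The physical footprint of a video frame on the substrate is computed from
#' the echo-sounder range and the camera's horizontal and vertical angles of
#' view, assuming the optical axis is perpendicular to a planar substrate
#' (the ROV pitch is adjusted during the dive to keep it so).
#'
#' @param hfov_deg Horizontal angle of view in degrees, in (0, 180).
#' @param vfov_deg Vertical angle of view in degrees, in (0, 180).
#' @param pixel_width,pixel_height Frame size in pixels (positive integers).
#'
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(60, 40, 1920, 1080)
#' frame_extent(1.0, cam)
#' @export
camera_model <- function(hfov_deg = 60, vfov_deg = 40,
                         pixel_width = 1920, pixel_height = 1080) {
  if (!is.numeric(hfov_deg) || hfov_deg <= 0 || hfov_deg >= 180) {
    abort("`hfov_deg` must lie strictly between 0 and 180 degrees.")
  }
  if (!is.numeric(vfov_deg) || vfov_deg <= 0 || vfov_deg >= 180) {
    abort("`vfov_deg` must lie strictly between 0 and 180 degrees.")
  }
  if (pixel_width <= 0 || pixel_height <= 0) {
    abort("Pixel counts must be positive.")
  }
  structure(
    list(hfov_deg = hfov_deg, vfov_deg = vfov_deg,
         pixel_width = as.integer(pixel_width),
         pixel_height = as.integer(pixel_height)),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %g x %g deg FOV, %d x %d px\n",
              x$hfov_deg, x$vfov_deg, x$pixel_width, x$pixel_height))
  invisible(x)
}

#' Physical extent of a frame from its echo-sounder range
#'
#' Under the pinhole model with the substrate plane perpendicular to the
#' optical axis, a frame at range \eqn{d} covers
#' \eqn{w = 2 d \tan(\theta_h / 2)} by \eqn{h = 2 d \tan(\theta_v / 2)}
#' metres, where \eqn{\theta_h, \theta_v} are the angles of view.
#'
#' @param distance_m Echo-sounder range(s) camera-to-substrate, metres, > 0.
#' @param camera A [camera_model()].
#'
#' @return A tibble with columns `distance_m`, `width_m`, `height_m`.
#' @export
frame_extent <- function(distance_m, camera = camera_model()) {
  if (!inherits(camera, "camera_model")) abort("`camera` must be a camera_model.")
  if (!is.numeric(distance_m) || any(!is.finite(distance_m)) ||
      any(distance_m <= 0)) {
    abort("`distance_m` must be finite and strictly positive.")
  }
  w <- 2 * distance_m * tan(camera$hfov_deg * pi / 360)
  h <- 2 * distance_m * tan(camera$vfov_deg * pi / 360)
  tibble::tibble(distance_m = distance_m, width_m = w, height_m = h)
}
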