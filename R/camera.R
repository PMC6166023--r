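#' Camera model
#'
#' Geometry and timing of the downward-facing camera that images the
#' tabletop workspace. The physical scale \code{mm_per_px} is derived from
#' the horizontal field of view: \code{fov_width_mm / image_width_px}.
#'
#' Defaults correspond to the reference acquisition setup: a 183-mm
#' horizontal field of view imaged at 752 x 480 and 30 frames per second.
#'
#' @param image_width_px,image_height_px sensor size in pixels.
#' @param fov_width_mm horizontal field of view on the tabletop, in mm.
#' @param fps frame rate, frames per second.
#' @return An object of class \code{camera_model} with fields
#'   \code{image_width_px}, \code{image_height_px}, \code{fov_width_mm},
#'   \code{fps} and the derived \code{mm_per_px}.
#' @examples
#' cam <- camera_model()
#' cam$mm_per_px # 183/752
#' @export
camera_model <- function(image_width_px = 752L, image_height_px = 480L,
                         fov_width_mm = 183, fps = 30) {
  stopifnot(image_width_px > 0, image_height_px > 0,
            fov_width_mm > 0, fps > 0)
  structure(list(
    image_width_px  = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    fov_width_mm    = fov_width_mm,
    fps             = fps,
    mm_per_px       = fov_width_mm / image_width_px
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %d x %d px, FOV %.0f mm (%.4f mm/px), %g fps\n",
              x$image_width_px, x$image_height_px, x$fov_width_mm,
              x$mm_per_px, x$fps))
  invisible(x)
}

#' Fiducial marker specification
#'
#' The hand-worn fiducial is an 18 x 18 mm dark adhesive square carrying a
#' bright 12-mm contrast circle; detection keys on the bright circle.
#' Intensities are gray levels on a 0-255 scale.
#'
#' @param square_side_mm side of the dark square, mm.
#' @param circle_diameter_mm diameter of the bright circle, mm.
#' @param square_intensity,circle_intensity,background_intensity gray levels.
#' @return An object of class \code{marker_spec}.
#' @export
marker_spec <- function(square_side_mm = 18, circle_diameter_mm = 12,
                        square_intensity = 0, circle_intensity = 230,
                        background_intensity = 20) {
  stopifnot(circle_diameter_mm < square_side_mm,
            circle_intensity > square_intensity,
            circle_intensity > background_intensity)
  structure(list(
    square_side_mm       = square_side_mm,
    circle_diameter_mm   = circle_diameter_mm,
    square_intensity     = square_intensity,
    circle_intensity     = circle_intensity,
    background_intensity = background_intensity
  ), class = "marker_spec")
}

#' Expected circle radius in pixels
#'
#' @param marker a \code{\link{marker_spec}}.
#' @param camera a \code{\link{camera_model}}.
#' @return radius of the bright circle in pixels.
#' @export
expected_radius_px <- function(marker, camera) {
  (marker$circle_diameter_mm / 2) / camera$mm_per_px
}
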