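#' Stimulus specification
#'
#' Describes a projected visual pattern (square-wave grating or random
#' dot-field) shown behind the feeder, together with the screen geometry and
#' the motion imposed on the pattern.
#'
#' @param pattern `"grating"` or `"dotfield"`.
#' @param n_cycles Number of full grating cycles across the screen (gratings
#'   only).
#' @param n_dots Number of dots in the field (dot-fields only).
#' @param dot_diameter_px Dot diameter in pixels.
#' @param screen_width_m Physical width of the projection surface (m).
#' @param screen_px Screen resolution along the motion axis (pixels).
#' @param viewing_distance_m Distance from the bird's head to the surface (m).
#' @param motion_direction One of `"left"`, `"right"`, `"up"`, `"down"`,
#'   `"none"`.
#' @param motion_speed_deg_s Pattern speed in degrees of visual angle per
#'   second (>= 0).
#'
#' @return An object of class `stimulus_spec`.
#' @examples
#' stimulus_spec("dotfield", n_dots = 250, motion_direction = "left",
#'               motion_speed_deg_s = 12)
#' @export
stimulus_spec <- function(pattern = c("grating", "dotfield"),
                          n_cycles = 4L,
                          n_dots = 250L,
                          dot_diameter_px = 40,
                          screen_width_m = 0.5,
                          screen_px = 1050L,
                          viewing_distance_m = 0.25,
                          motion_direction = c("none", "left", "right", "up", "down"),
                          motion_speed_deg_s = 0) {
  pattern <- match.arg(pattern)
  motion_direction <- match.arg(motion_direction)
  if (screen_px <= 0) stopf("screen_px must be positive")
  if (viewing_distance_m <= 0) stopf("viewing_distance_m must be positive")
  if (motion_speed_deg_s < 0) stopf("motion_speed_deg_s must be >= 0")
  structure(
    list(pattern = pattern, n_cycles = as.integer(n_cycles),
         n_dots = as.integer(n_dots), dot_diameter_px = dot_diameter_px,
         screen_width_m = screen_width_m, screen_px = as.integer(screen_px),
         viewing_distance_m = viewing_distance_m,
         motion_direction = motion_direction,
         motion_speed_deg_s = motion_speed_deg_s),
    class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  ext <- angular_extent(x$screen_width_m, x$viewing_distance_m)
  cat(sprintf("<stimulus_spec> %s, %.1f deg field, motion %s at %g deg/s\n",
              x$pattern, ext, x$motion_direction, x$motion_speed_deg_s))
  invisible(x)
}

#' Angular extent of a flat surface
#'
#' Visual angle subtended by a flat surface of width `width_m` centred on the
#' viewing axis at distance `distance_m`: `2 * atan(width / (2 * distance))`.
#'
#' @param width_m Surface width (m), > 0.
#' @param distance_m Viewing distance (m), > 0.
#' @return Angular extent in degrees.
#' @examples
#' angular_extent(0.5, 0.25)  # 90 degrees
#' @export
angular_extent <- function(width_m, distance_m) {
  if (any(width_m <= 0) || any(distance_m <= 0)) {
    stopf("width_m and distance_m must be positive")
  }
  2 * rad2deg(atan(width_m / (2 * distance_m)))
}

#' Grating spatial frequency
#'
#' @param n_cycles Number of full cycles across the surface (>= 1).
#' @param extent_deg Angular extent of the surface (degrees), > 0.
#' @return Spatial frequency in cycles per degree.
#' @examples
#' grating_spatial_frequency(4, 90)  # 0.044 cycles/deg
#' @export
grating_spatial_frequency <- function(n_cycles, extent_deg) {
  if (any(n_cycles < 1)) stopf("n_cycles must be >= 1")
  if (any(extent_deg <= 0)) stopf("extent_deg must be positive")
  n_cycles / extent_deg
}

#' Convert an on-screen extent from pixels to degrees
#'
#' Linear small-angle mapping used for on-screen feature sizes (dot
#' diameters, displacement per frame). The exact arctangent form is reserved
#' for whole-surface extents ([angular_extent()]).
#'
#' @param extent_px Extent in pixels.
#' @param screen_px Screen resolution along the same axis (pixels), > 0.
#' @param screen_extent_deg Angular extent of the whole screen (degrees).
#' @return Extent in degrees.
#' @examples
#' pixels_to_degrees(40, 1050, 90)  # ~3.4 deg
#' @export
pixels_to_degrees <- function(extent_px, screen_px, screen_extent_deg) {
  if (any(screen_px <= 0)) stopf("screen_px must be positive")
  extent_px * screen_extent_deg / screen_px
}

#' Angular speed of a laterally translating feeder
#'
#' Instantaneous angular speed, as seen by a stationary observer at
#' `distance_m`, of a target translating at `speed_m_s` perpendicular to the
#' line of sight: `v / d` rad/s converted to degrees per second.
#'
#' @param speed_m_s Translation speed (m/s), >= 0.
#' @param distance_m Viewing distance (m), > 0.
#' @return Angular speed in degrees per second.
#' @examples
#' translation_angular_speed(0.15, 0.25)  # ~34.4 deg/s
#' @export
translation_angular_speed <- function(speed_m_s, distance_m) {
  if (any(distance_m <= 0)) stopf("distance_m must be positive")
  rad2deg(speed_m_s / distance_m)
}

#' Render a random dot-field stimulus
#'
#' Dots are placed uniformly at random, move rigidly at the specified speed,
#' have infinite lifetimes, and regenerate at the upstream (origin-of-motion)
#' edge with a uniformly random transverse coordinate when they leave the
#' field. The field is a square of `screen_px` x `screen_px` pixels.
#'
#' @param spec A [stimulus_spec()] with `pattern = "dotfield"`.
#' @param duration_s Duration to render (s).
#' @param fps Frame rate (frames per second), default 60.
#' @param seed Integer seed; the same seed yields an identical sequence.
#' @return A data frame with columns `frame`, `dot_id`, `x_px`, `y_px`.
#' @export
render_dotfield <- function(spec, duration_s, fps = 60, seed = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$pattern != "dotfield") stopf("spec$pattern must be 'dotfield'")
  n_frames <- max(1L, as.integer(round(duration_s * fps)))
  n <- spec$n_dots
  px <- spec$screen_px
  extent_deg <- angular_extent(spec$screen_width_m, spec$viewing_distance_m)
  px_per_deg <- px / extent_deg
  step_px <- spec$motion_speed_deg_s * px_per_deg / fps
  dir <- switch(spec$motion_direction,
                none = c(0, 0), left = c(-1, 0), right = c(1, 0),
                up = c(0, 1), down = c(0, -1))
  with_seed(seed, {
    x <- stats::runif(n, 0, px)
    y <- stats::runif(n, 0, px)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      frames[[f]] <- data.frame(frame = f, dot_id = seq_len(n),
                                x_px = x, y_px = y)
      x <- x + dir[1L] * step_px
      y <- y + dir[2L] * step_px
      # regenerate exited dots at the upstream edge, uniform transverse coord
      out <- x < 0 | x > px | y < 0 | y > px
      if (any(out)) {
        k <- sum(out)
        if (dir[1L] != 0) {
          x[out] <- if (dir[1L] < 0) px else 0
          y[out] <- stats::runif(k, 0, px)
        } else if (dir[2L] != 0) {
          y[out] <- if (dir[2L] < 0) px else 0
          x[out] <- stats::runif(k, 0, px)
        }
      }
    }
    do.call(rbind, frames)
  })
}
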