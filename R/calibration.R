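#' Microscope calibration
#'
#' Bundles the optical parameters needed to convert camera pixels to
#' physical micrometres and frame indices to hours.
#'
#' @param pixel_pitch Physical sensor pixel size in micrometres.
#' @param binning Camera binning factor (integer >= 1); binned pixels are
#'   \code{binning} times larger on the sensor.
#' @param objective_mag Objective magnification (e.g. 10 for a 10x objective).
#' @param intermediate_mag Intermediate (tube-lens) magnification factor.
#' @param frame_interval Time between consecutive frames, in minutes.
#' @return An object of class \code{etx_calibration}.
#' @examples
#' cal <- calibration(pixel_pitch = 6.5, binning = 2,
#'                    objective_mag = 10, intermediate_mag = 1.5,
#'                    frame_interval = 10)
#' effective_pixel_size(cal)  # ~0.87 um/pixel
#' @export
calibration <- function(pixel_pitch, binning = 1L, objective_mag = 1,
                        intermediate_mag = 1, frame_interval = 10) {
  vals <- c(pixel_pitch = pixel_pitch, binning = binning,
            objective_mag = objective_mag, intermediate_mag = intermediate_mag,
            frame_interval = frame_interval)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid calibration: all fields must be finite and strictly positive",
         call. = FALSE)
  if (binning != round(binning))
    stop("invalid calibration: binning must be an integer", call. = FALSE)
  structure(list(pixel_pitch = pixel_pitch, binning = as.integer(binning),
                 objective_mag = objective_mag,
                 intermediate_mag = intermediate_mag,
                 frame_interval = frame_interval),
            class = "etx_calibration")
}

#' Effective pixel size at the sample plane
#'
#' The size, in micrometres, that one (possibly binned) camera pixel covers
#' at the sample: \code{pixel_pitch * binning / (objective_mag *
#' intermediate_mag)}.
#'
#' @param cal An \code{etx_calibration}.
#' @return Effective pixel size in um/pixel.
#' @export
effective_pixel_size <- function(cal) {
  stopifnot(inherits(cal, "etx_calibration"))
  cal$pixel_pitch * cal$binning / (cal$objective_mag * cal$intermediate_mag)
}

#' @export
print.etx_calibration <- function(x, ...) {
  cat(sprintf(
    "Calibration: %.3g um pitch, %dx binning, %gx obj, %gx intermediate\n",
    x$pixel_pitch, x$binning, x$objective_mag, x$intermediate_mag))
  cat(sprintf("  effective pixel size: %.4f um/px, frame interval %g min\n",
              effective_pixel_size(x), x$frame_interval))
  invisible(x)
}
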