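#' Viewing geometry of the stimulation display
#'
#' Bundles the physical description of the display used to convert between
#' pixels and degrees of visual angle. Defaults reproduce the study setup:
#' an 800x600 px panel at 60 Hz, mean luminance mapping to 45 cd/m^2
#' (normalized 0.5), viewed from 70 cm. The physical panel size defaults to a
#' 32-inch 16:9 screen (69.8 x 39.3 cm); the display model fixes only the
#' diagonal, so the physical size is exposed as a parameter.
#'
#' @param screen_width_px,screen_height_px display resolution in pixels.
#' @param screen_width_cm,screen_height_cm physical panel size in cm.
#' @param viewing_distance_cm eye-to-screen distance in cm.
#' @param refresh_hz frame rate in Hz.
#' @param mean_luminance_norm normalized mean luminance in \[0, 1\].
#' @return An object of class `viewing_geometry`.
#' @examples
#' geom <- viewing_geometry()
#' pixels_per_degree(geom)
#' @export
viewing_geometry <- function(screen_width_px = 800, screen_height_px = 600,
                             screen_width_cm = 69.8, screen_height_cm = 39.3,
                             viewing_distance_cm = 70, refresh_hz = 60,
                             mean_luminance_norm = 0.5) {
  vals <- c(screen_width_px, screen_height_px, screen_width_cm,
            screen_height_cm, viewing_distance_cm, refresh_hz)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry fields must be positive and finite", call. = FALSE)
  if (mean_luminance_norm < 0 || mean_luminance_norm > 1)
    stop("mean_luminance_norm must lie in [0, 1]", call. = FALSE)
  structure(
    list(screen_width_px = screen_width_px, screen_height_px = screen_height_px,
         screen_width_cm = screen_width_cm, screen_height_cm = screen_height_cm,
         viewing_distance_cm = viewing_distance_cm, refresh_hz = refresh_hz,
         mean_luminance_norm = mean_luminance_norm),
    class = "viewing_geometry")
}

#' Pixels per degree of visual angle at screen centre
#'
#' @param geom a [viewing_geometry()].
#' @return Pixels per degree (scalar).
#' @export
pixels_per_degree <- function(geom) {
  stopifnot(inherits(geom, "viewing_geometry"))
  half_angle_deg <- atan2(geom$screen_width_cm / 2, geom$viewing_distance_cm) *
    180 / pi
  ppd <- geom$screen_width_px / (2 * half_angle_deg)
  if (!is.finite(ppd) || ppd <= 0)
    stop("degenerate geometry: non-positive pixels-per-degree", call. = FALSE)
  ppd
}

#' Checkerboard stimulus parameters
#'
#' Parameters of the full-field reversing radial checkerboard: spatial
#' frequency 0.33 cycles/degree and a 4 Hz pattern-reversal rate (four abrupt
#' phase inversions per second), 90% Michelson contrast for the stimulus
#' condition and 0% for the mock condition.
#'
#' @param spatial_freq_cpd spatial frequency in cycles per degree (> 0).
#' @param reversal_rate_hz phase inversions per second (>= 0; 0 = static).
#' @param contrast Michelson contrast in \[0, 1\].
#' @param phase checkerboard polarity, 0 or 1.
#' @return An object of class `checkerboard_spec`.
#' @export
checkerboard_spec <- function(spatial_freq_cpd = 0.33, reversal_rate_hz = 4,
                              contrast = 0.9, phase = 0) {
  if (!is.finite(spatial_freq_cpd) || spatial_freq_cpd <= 0)
    stop("spatial_freq_cpd must be positive", call. = FALSE)
  if (reversal_rate_hz < 0) stop("reversal_rate_hz must be >= 0", call. = FALSE)
  if (contrast < 0 || contrast > 1)
    stop("contrast must lie in [0, 1]", call. = FALSE)
  if (!phase %in% c(0, 1)) stop("phase must be 0 or 1", call. = FALSE)
  structure(
    list(spatial_freq_cpd = spatial_freq_cpd,
         reversal_rate_hz = reversal_rate_hz,
         contrast = contrast, phase = phase),
    class = "checkerboard_spec")
}
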