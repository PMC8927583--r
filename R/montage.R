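# Idealized 10-10 electrode positions for the 32-channel cap, as spherical
# angles: inclination (degrees from the vertex) and azimuth (degrees from
# the nasion, negative = left hemisphere). The outer ring sits at 92
# degrees, just below the ear plane, following common cap geometry.

montage_angles <- function() {
  tibble::tribble(
    ~channel, ~inclination, ~azimuth,
    "FP1", 92, -18, "FP2", 92, 18,
    "AF3", 74, -25, "AF4", 74, 25,
    "F7", 92, -54, "F3", 60, -39, "FZ", 46, 0, "F4", 60, 39, "F8", 92, 54,
    "FC5", 72, -69, "FC1", 32, -45, "FC2", 32, 45, "FC6", 72, 69,
    "T7", 92, -90, "C3", 46, -90, "CZ", 0, 0, "C4", 46, 90, "T8", 92, 90,
    "CP5", 72, -111, "CP1", 32, -135, "CP2", 32, 135, "CP6", 72, 111,
    "P7", 92, -126, "P3", 60, -141, "PZ", 46, 180, "P4", 60, 141, "P8", 92, 126,
    "PO7", 92, -144, "PO3", 74, -155, "PO4", 74, 155, "PO8", 92, 144,
    "OZ", 92, 180
  )
}

#' Standard montage with 3D electrode coordinates
#'
#' Unit-sphere positions of the 32 electrodes (x toward the right ear,
#' y toward the nasion, z up, head centre at the origin).
#'
#' @return A tibble with columns `channel`, `x3`, `y3`, `z3`.
#' @export
standard_montage <- function() {
  ang <- montage_angles()
  inc <- ang$inclination * pi / 180
  az <- ang$azimuth * pi / 180
  tibble(channel = ang$channel,
         x3 = sin(inc) * sin(az),
         y3 = sin(inc) * cos(az),
         z3 = cos(inc))
}

#' Project 3D electrode positions onto the 2D head disk
#'
#' Azimuthal equidistant projection from the vertex: the planar radius is
#' proportional to the arc angle from the vertex, scaled so the outermost
#' ring lies on the unit head circle. The vertex electrode CZ maps to the
#' centre (0, 0) and left/right pairs mirror in x. Deterministic.
#'
#' @param montage A tibble with `channel`, `x3`, `y3`, `z3` unit-sphere
#'   coordinates (default [standard_montage()]).
#' @return The montage tibble with projected `x`, `y` columns appended.
#' @export
project_montage <- function(montage = standard_montage()) {
  required <- c("channel", "x3", "y3", "z3")
  if (!all(required %in% names(montage))) {
    abort("montage must have channel, x3, y3, z3 columns.")
  }
  unknown <- setdiff(montage$channel, cap32_channels())
  if (length(unknown)) {
    abort(sprintf("unknown electrode name(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  arc <- acos(pmin(pmax(montage$z3, -1), 1))       # angle from vertex
  r <- arc / max(arc)                              # outer ring -> radius 1
  az <- atan2(montage$x3, montage$y3)
  out <- montage
  out$x <- r * sin(az)
  out$y <- r * cos(az)
  out
}
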