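# Arena geometry and the radial light-intensity profile.

#' Radially symmetric arena light model
#'
#' The behavioral arena is a circular dish (radius `arena_radius_cm`, 4 cm by
#' default) with a central circular light zone (radius `light_zone_radius_cm`,
#' 1.25 cm by default).  The optogenetic light intensity is modeled as a
#' plateau inside the zone falling off smoothly to zero at the border via a
#' logistic profile; the measured profile of a focused LED is qualitatively
#' of this shape.  At the nominal border the intensity is exactly half the
#' plateau value.
#'
#' @param arena_radius_cm arena radius, cm
#' @param light_zone_radius_cm light-zone radius, cm; must be smaller than
#'   the arena radius
#' @param plateau_intensity intensity on the plateau, uW/mm^2
#' @param falloff_width width of the border falloff, normalized units; the
#'   profile is within ~0.3% of its asymptotes beyond this distance from the
#'   border
#' @return an object of class `arena_model` with an `intensity(r)` function
#'   of normalized radial distance
#' @export
make_arena_model <- function(arena_radius_cm = 4, light_zone_radius_cm = 1.25,
                             plateau_intensity = 20, falloff_width = 0.05) {
  if (!is.finite(arena_radius_cm) || arena_radius_cm <= 0 ||
      !is.finite(light_zone_radius_cm) || light_zone_radius_cm <= 0)
    stop("invalid geometry: radii must be positive")
  if (light_zone_radius_cm >= arena_radius_cm)
    stop("invalid geometry: light zone must be smaller than the arena")
  if (plateau_intensity < 0) stop("plateau_intensity must be >= 0")
  border <- light_zone_radius_cm / arena_radius_cm
  scale <- falloff_width / 6   # logistic reaches ~99.75% within falloff_width
  intensity <- function(r) {
    plateau_intensity * stats::plogis(-(r - border) / scale)
  }
  structure(
    list(arena_radius_cm = arena_radius_cm,
         light_zone_radius_cm = light_zone_radius_cm,
         light_zone_radius_norm = border,
         plateau_intensity = plateau_intensity,
         falloff_width = falloff_width,
         intensity = intensity),
    class = "arena_model")
}

#' @export
print.arena_model <- function(x, ...) {
  cat(sprintf(
    "<arena_model> radius %.3g cm, light zone %.3g cm (%.4g normalized),\n",
    x$arena_radius_cm, x$light_zone_radius_cm, x$light_zone_radius_norm))
  cat(sprintf("  plateau %.3g uW/mm^2, falloff width %.3g normalized\n",
              x$plateau_intensity, x$falloff_width))
  invisible(x)
}
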