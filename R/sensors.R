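#' Sensor models
#'
#' Deterministic boolean detection models for the trap's two sensors. The PIR
#' (passive infrared) sensor requires a moving warm body: a detection needs
#' the target inside the PIR angular zone and range, moving at least
#' `min_speed`, and presenting an effective thermal contrast (the animal's
#' heat signature scaled by any rain attenuation) of at least
#' `contrast_threshold`. The radar model is range-gated between `min_range`
#' and `max_range` and needs a radar cross-section of at least
#' `min_cross_section`; it has no angular restriction.
#'
#' These thresholds encode the classic miss mechanisms: birds feeding on the
#' ground move too slowly for the PIR; rain masks thermal signatures;
#' small-bodied birds present too little radar cross-section; and targets
#' beyond range are invisible to either sensor. Detection is deterministic
#' given a track sample, which keeps every mechanism exactly testable.
#'
#' @param fov_halfangle PIR half-angle, degrees.
#' @param max_range PIR range, metres.
#' @param min_speed Minimum detectable speed, m/s.
#' @param contrast_threshold Minimum effective thermal contrast.
#' @return `pir_model`, `radar_model` and `env_conditions` return parameter
#'   objects of the matching class.
#' @export
pir_model <- function(fov_halfangle = 45, max_range = 9, min_speed = 0.05,
                      contrast_threshold = 10) {
  stopifnot(fov_halfangle >= 0, max_range >= 0, min_speed >= 0,
            contrast_threshold >= 0)
  structure(list(fov_halfangle = fov_halfangle, max_range = max_range,
                 min_speed = min_speed,
                 contrast_threshold = contrast_threshold),
            class = "pir_model")
}

#' @rdname pir_model
#' @param min_range,max_range Radar range gate, metres (defaults 2.4-9, a
#'   10.5 GHz module's adjustable detection range).
#' @param min_cross_section Minimum detectable radar cross-section.
#' @export
radar_model <- function(min_range = 2.4, max_range = 9, min_cross_section = 1) {
  stopifnot(min_range >= 0, min_range < max_range, min_cross_section >= 0)
  structure(list(min_range = min_range, max_range = max_range,
                 min_cross_section = min_cross_section),
            class = "radar_model")
}

#' @rdname pir_model
#' @param rain_attenuation Multiplicative factor in \[0, 1\] applied to
#'   thermal contrast (1 = dry conditions).
#' @export
env_conditions <- function(rain_attenuation = 1) {
  stopifnot(rain_attenuation >= 0, rain_attenuation <= 1)
  structure(list(rain_attenuation = rain_attenuation),
            class = "env_conditions")
}

#' PIR detection of a track sample
#'
#' @param sample One-row data.frame or list with `x`, `y` (metres) and
#'   `speed` (m/s).
#' @param animal The [animal_track()] the sample belongs to (supplies
#'   `thermal_contrast`).
#' @param model A [pir_model()].
#' @param env An [env_conditions()].
#' @param geometry A [trap_geometry()] giving the trap position and heading.
#' @return `TRUE` iff the sample is detected.
#' @export
pir_detect <- function(sample, animal, model = pir_model(),
                       env = env_conditions(), geometry = trap_geometry()) {
  inside <- in_sector(sample$x, sample$y, geometry,
                      model$fov_halfangle, model$max_range)
  inside & sample$speed >= model$min_speed &
    animal$thermal_contrast * env$rain_attenuation >= model$contrast_threshold
}

#' Radar detection of a track sample
#'
#' @inheritParams pir_detect
#' @param model A [radar_model()].
#' @return `TRUE` iff the sample is detected.
#' @export
radar_detect <- function(sample, animal, model = radar_model(),
                         geometry = trap_geometry()) {
  r <- trap_polar(sample$x, sample$y, geometry)$range
  r >= model$min_range & r <= model$max_range &
    animal$radar_cross_section >= model$min_cross_section
}
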