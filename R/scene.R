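#' Scene configuration
#'
#' Describes the synthetic arena and the virtual camera sensor that frames it:
#' a flat study area of `arena_width` x `arena_depth` metres (marked
#' conceptually with a grid of `grid_spacing` metre squares), imaged top-down
#' onto a `frame_width` x `frame_height` pixel grayscale frame. The rendered
#' background is `background_mean` plus a deterministic illumination drift of
#' `illumination_drift_amplitude` intensity units per hour and zero-mean
#' Gaussian pixel noise with standard deviation `noise_sigma`. Identical
#' `rng_seed` values reproduce identical scenes bit-for-bit.
#'
#' Defaults mirror a roof-top trial arena: a 6 m x 8 m flat area with a 1 m
#' grid, viewed by a trap mounted 0.8 m above the surface.
#'
#' @param arena_width,arena_depth Arena dimensions in metres (> 0).
#' @param grid_spacing Grid square side in metres (> 0).
#' @param background_mean Mean background intensity, 0-255.
#' @param noise_sigma Pixel noise standard deviation, intensity units (>= 0).
#' @param illumination_drift_amplitude Linear illumination drift, intensity
#'   units per hour of simulated time.
#' @param frame_width,frame_height Frame dimensions in pixels (> 0).
#' @param rng_seed Integer seed controlling all per-frame noise.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(arena_width = 6, arena_depth = 8, grid_spacing = 1,
                         background_mean = 120, noise_sigma = 2,
                         illumination_drift_amplitude = 10,
                         frame_width = 320, frame_height = 240,
                         rng_seed = 1L) {
  stopifnot(arena_width > 0, arena_depth > 0, grid_spacing > 0,
            noise_sigma >= 0, frame_width > 0, frame_height > 0,
            background_mean >= 0, background_mean <= 255)
  structure(list(
    arena_width = arena_width, arena_depth = arena_depth,
    grid_spacing = grid_spacing, background_mean = background_mean,
    noise_sigma = noise_sigma,
    illumination_drift_amplitude = illumination_drift_amplitude,
    frame_width = as.integer(frame_width),
    frame_height = as.integer(frame_height),
    rng_seed = as.integer(rng_seed)
  ), class = "scene_config")
}

#' Trap geometry
#'
#' Placement and angular coverage of the trap. The camera field of view (FOV)
#' and the PIR detection zone are both symmetric angular sectors centred on
#' `heading`, measured in degrees counter-clockwise from the +x axis of the
#' arena. By construction the PIR zone is at least as wide and as deep as the
#' camera FOV: this is the configuration in which a target can sit inside the
#' detection zone yet outside the picture, producing a false-positive image.
#'
#' @param trap_position Numeric length-2, trap (x, y) in arena metres.
#' @param mount_height Mount height in metres (default 0.8; informational --
#'   the projection is planar).
#' @param heading Viewing direction, degrees CCW from +x.
#' @param camera_fov_halfangle Camera half-angle, degrees.
#' @param camera_max_range Camera range, metres.
#' @param pir_fov_halfangle PIR half-angle, degrees; must be >=
#'   `camera_fov_halfangle`.
#' @param pir_max_range PIR range, metres; must be >= `camera_max_range`.
#' @return An object of class `trap_geometry`.
#' @export
trap_geometry <- function(trap_position = c(3, 0), mount_height = 0.8,
                          heading = 90, camera_fov_halfangle = 27,
                          camera_max_range = 8, pir_fov_halfangle = 45,
                          pir_max_range = 9) {
  stopifnot(length(trap_position) == 2, camera_max_range > 0,
            pir_max_range > 0, camera_fov_halfangle > 0,
            pir_fov_halfangle >= camera_fov_halfangle,
            pir_max_range >= camera_max_range)
  structure(list(
    trap_position = as.numeric(trap_position), mount_height = mount_height,
    heading = heading, camera_fov_halfangle = camera_fov_halfangle,
    camera_max_range = camera_max_range,
    pir_fov_halfangle = pir_fov_halfangle, pir_max_range = pir_max_range
  ), class = "trap_geometry")
}

## signed angular offset (degrees, in (-180, 180]) of point (x, y) from the
## trap heading; range in metres. Vectorised over x, y.
trap_polar <- function(x, y, geometry) {
  dx <- x - geometry$trap_position[1]
  dy <- y - geometry$trap_position[2]
  r <- sqrt(dx^2 + dy^2)
  bearing <- atan2(dy, dx) * 180 / pi
  off <- ((bearing - geometry$heading + 180) %% 360) - 180
  list(range = r, offset = off)
}

in_sector <- function(x, y, geometry, halfangle, max_range) {
  p <- trap_polar(x, y, geometry)
  # a point at the trap itself has no defined bearing; count it as inside
  (p$range <= max_range) & (abs(p$offset) <= halfangle | p$range < 1e-9)
}

#' Zone membership tests
#'
#' Whether arena points lie inside the camera field of view or the PIR
#' detection zone of a trap. Vectorised over `x` and `y`.
#'
#' @param x,y Arena coordinates in metres.
#' @param geometry A [trap_geometry()].
#' @return Logical vector.
#' @export
in_camera_fov <- function(x, y, geometry) {
  in_sector(x, y, geometry, geometry$camera_fov_halfangle,
            geometry$camera_max_range)
}

#' @rdname in_camera_fov
#' @export
in_pir_zone <- function(x, y, geometry) {
  in_sector(x, y, geometry, geometry$pir_fov_halfangle, geometry$pir_max_range)
}

#' Animal track
#'
#' An ordered series of timestamped positions with instantaneous speeds, plus
#' the target's rendering and sensing properties: `body_radius_px` (the radius
#' of the disc composited into frames), `thermal_contrast` (the heat signature
#' seen by the PIR sensor, in intensity-equivalent arbitrary units; it doubles
#' as the blob intensity contrast in the infrared-like render) and
#' `radar_cross_section` (arbitrary units, small for small-bodied birds).
#'
#' @param samples data.frame with columns `t` (seconds, strictly increasing),
#'   `x`, `y` (metres) and `speed` (m/s, >= 0).
#' @param body_radius_px Blob radius in pixels (>= 1).
#' @param thermal_contrast Heat-signature amplitude (intensity units).
#' @param radar_cross_section Radar cross-section, arbitrary units.
#' @param id Track identifier.
#' @return An object of class `animal_track`.
#' @export
animal_track <- function(samples, body_radius_px = 6, thermal_contrast = 80,
                         radar_cross_section = 0.5, id = 1L) {
  stopifnot(is.data.frame(samples),
            all(c("t", "x", "y", "speed") %in% names(samples)),
            body_radius_px >= 1)
  if (nrow(samples) > 1 && any(diff(samples$t) <= 0))
    stop("track sample timestamps must be strictly increasing")
  if (any(samples$speed < 0)) stop("speeds must be non-negative")
  structure(list(samples = samples, body_radius_px = body_radius_px,
                 thermal_contrast = thermal_contrast,
                 radar_cross_section = radar_cross_section, id = id),
            class = "animal_track")
}

## evaluate RNG-consuming code under a given seed, restoring global RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Generate seeded animal tracks
#'
#' Each track is a bounded correlated random walk inside the arena, sampled on
#' a regular clock from `t = 0` to `t = duration` inclusive. Per-sample speeds
#' are drawn from a two-component mixture: with probability `dwell_prob` the
#' animal is in a "dwell" mode of near-zero speed (a bird feeding on the
#' ground -- the slow movers a PIR sensor fails to detect), otherwise the speed
#' is gamma-distributed around `speed_mean`. Headings perform a random walk
#' and reflect off the arena walls. Output is deterministic for a fixed seed.
#'
#' @param scene A [scene_config()].
#' @param geometry A [trap_geometry()] (used only to seed starting positions
#'   towards the instrumented part of the arena).
#' @param n_animals Number of tracks (>= 0).
#' @param duration Trial length in seconds (> 0).
#' @param sample_interval Sampling interval in seconds (> 0).
#' @param seed Integer seed.
#' @param speed_mean Mean moving speed, m/s.
#' @param dwell_prob Probability of the dwell (feeding) mode per sample.
#' @param dwell_speed Upper speed of the dwell mode, m/s.
#' @param body_radius_px,thermal_contrast,radar_cross_section Passed to
#'   [animal_track()].
#' @return List of [animal_track()] objects.
#' @export
generate_tracks <- function(scene, geometry, n_animals, duration,
                            sample_interval = 1, seed = scene$rng_seed,
                            speed_mean = 0.5, dwell_prob = 0.3,
                            dwell_speed = 0.02, body_radius_px = 6,
                            thermal_contrast = 80, radar_cross_section = 0.5) {
  if (duration <= 0) stop("duration must be positive")
  if (sample_interval <= 0) stop("sample_interval must be positive")
  if (n_animals == 0) return(list())
  times <- seq(0, duration, by = sample_interval)
  with_seed(seed, {
    lapply(seq_len(n_animals), function(i) {
      n <- length(times)
      x <- numeric(n); y <- numeric(n); speed <- numeric(n)
      x[1] <- stats::runif(1, 0, scene$arena_width)
      y[1] <- stats::runif(1, 0, scene$arena_depth)
      theta <- stats::runif(1, 0, 2 * pi)
      speed[1] <- if (stats::runif(1) < dwell_prob)
        stats::runif(1, 0, dwell_speed) else
        stats::rgamma(1, shape = 4, scale = speed_mean / 4)
      for (k in seq_len(n)[-1]) {
        dt <- times[k] - times[k - 1]
        speed[k] <- if (stats::runif(1) < dwell_prob)
          stats::runif(1, 0, dwell_speed) else
          stats::rgamma(1, shape = 4, scale = speed_mean / 4)
        theta <- theta + stats::rnorm(1, 0, 40 * pi / 180)
        nx <- x[k - 1] + speed[k] * dt * cos(theta)
        ny <- y[k - 1] + speed[k] * dt * sin(theta)
        # reflect off arena walls
        if (nx < 0) { nx <- -nx; theta <- pi - theta }
        if (nx > scene$arena_width) {
          nx <- 2 * scene$arena_width - nx; theta <- pi - theta
        }
        if (ny < 0) { ny <- -ny; theta <- -theta }
        if (ny > scene$arena_depth) {
          ny <- 2 * scene$arena_depth - ny; theta <- -theta
        }
        x[k] <- min(max(nx, 0), scene$arena_width)
        y[k] <- min(max(ny, 0), scene$arena_depth)
      }
      animal_track(data.frame(t = times, x = x, y = y, speed = speed),
                   body_radius_px = body_radius_px,
                   thermal_contrast = thermal_contrast,
                   radar_cross_section = radar_cross_section, id = i)
    })
  })
}

#' Straight constant-speed track
#'
#' A scripted track moving in a straight line from `from` to `to` at constant
#' `speed`, sampled every `sample_interval` seconds starting at `start_time`.
#' Useful for exercising specific geometry: a path through the camera field
#' of view yields capturable visits, while a path kept between the camera and
#' PIR half-angles crosses the detection zone without ever entering the
#' picture -- the out-of-view false-positive mechanism.
#'
#' @param from,to Numeric length-2 arena points (x, y), metres.
#' @param speed Speed in m/s (> 0).
#' @param sample_interval Sampling interval, seconds.
#' @param start_time Time of the first sample, seconds.
#' @param ... Passed to [animal_track()].
#' @return An [animal_track()].
#' @export
crossing_track <- function(from, to, speed = 0.5, sample_interval = 1,
                           start_time = 0, ...) {
  stopifnot(speed > 0, sample_interval > 0)
  d <- sqrt(sum((to - from)^2))
  times <- seq(0, d / speed, by = sample_interval)
  frac <- if (d > 0) times * speed / d else rep(0, length(times))
  animal_track(data.frame(t = start_time + times,
                          x = from[1] + frac * (to[1] - from[1]),
                          y = from[2] + frac * (to[2] - from[2]),
                          speed = speed), ...)
}

#' Interpolate a track position
#'
#' Linear interpolation of position and speed at time `t`; clamped to the
#' track's first/last sample outside its time span.
#'
#' @param track An [animal_track()].
#' @param t Time in seconds.
#' @return List with `x`, `y`, `speed`.
#' @export
track_position <- function(track, t) {
  s <- track$samples
  if (nrow(s) == 1 || t <= s$t[1])
    return(list(x = s$x[1], y = s$y[1], speed = s$speed[1]))
  n <- nrow(s)
  if (t >= s$t[n]) return(list(x = s$x[n], y = s$y[n], speed = s$speed[n]))
  list(x = stats::approx(s$t, s$x, t)$y,
       y = stats::approx(s$t, s$y, t)$y,
       speed = stats::approx(s$t, s$speed, t)$y)
}

## per-frame noise seed: a fixed arithmetic mix of the scene seed and the
## frame timestamp (ms), so the same instant re-renders identically
frame_noise_seed <- function(scene, t) {
  (scene$rng_seed * 1000003 + round(t * 1000)) %% 2147483647
}

## arena (x, y) metres -> 0-based pixel (col, row), top-down orthographic map;
## y = 0 (the trap side) maps to the bottom image row
arena_to_pixel <- function(scene, x, y) {
  col <- floor(x / scene$arena_width * scene$frame_width)
  row <- floor((scene$arena_depth - y) / scene$arena_depth * scene$frame_height)
  list(col = pmin(pmax(col, 0), scene$frame_width - 1L),
       row = pmin(pmax(row, 0), scene$frame_height - 1L))
}

#' Render a frame
#'
#' Produces the grayscale image the trap would record at time `t`: the
#' background (mean intensity + deterministic illumination drift + seeded
#' per-frame Gaussian noise) with a bright disc of each track's
#' `body_radius_px` composited, additively at `thermal_contrast`, for every
#' track currently inside the camera field of view. A target inside the PIR
#' detection zone but outside the camera FOV leaves no pixel trace, so such a
#' frame is bit-identical to the empty-scene render at the same instant --
#' the mechanism by which out-of-view triggers yield blank (false-positive)
#' images.
#'
#' @param scene A [scene_config()].
#' @param geometry A [trap_geometry()].
#' @param tracks List of [animal_track()] (may be empty).
#' @param t Capture time, seconds.
#' @param kind `"timelapse"` or `"motion"`.
#' @return A [trap_frame()].
#' @export
render_frame <- function(scene, geometry, tracks, t,
                         kind = c("timelapse", "motion")) {
  kind <- match.arg(kind)
  h <- scene$frame_height; w <- scene$frame_width
  drift <- scene$illumination_drift_amplitude * (t / 3600)
  noise <- with_seed(frame_noise_seed(scene, t),
                     matrix(stats::rnorm(h * w, 0, scene$noise_sigma), h, w))
  px <- scene$background_mean + drift + noise
  for (tr in tracks) {
    pos <- track_position(tr, t)
    if (!in_camera_fov(pos$x, pos$y, geometry)) next
    ctr <- arena_to_pixel(scene, pos$x, pos$y)
    r <- tr$body_radius_px
    rows <- max(0L, ctr$row - r):min(h - 1L, ctr$row + r)
    cols <- max(0L, ctr$col - r):min(w - 1L, ctr$col + r)
    disc <- outer((rows - ctr$row)^2, (cols - ctr$col)^2, `+`) <= r^2
    sub <- px[rows + 1L, cols + 1L, drop = FALSE]
    sub[disc] <- sub[disc] + tr$thermal_contrast
    px[rows + 1L, cols + 1L] <- sub
  }
  trap_frame(round(pmin(pmax(px, 0), 255)), t = t, kind = kind)
}

#' Ground-truth detection events
#'
#' Converts tracks into the log an observer watching reference video would
#' produce: each contiguous run of samples inside the PIR detection zone
#' becomes one event, flagged `in_camera_fov = TRUE` if any sample of the run
#' also lies inside the camera field of view. Under the default geometry the
#' camera FOV is a subset of the PIR zone, so every in-FOV event is also
#' in-zone.
#'
#' @param tracks List of [animal_track()].
#' @param geometry A [trap_geometry()].
#' @return A data.frame of class `ground_truth_log` with columns `t_start`,
#'   `t_end`, `track_id`, `in_pir_zone`, `in_camera_fov`.
#' @export
make_ground_truth <- function(tracks, geometry) {
  rows <- list()
  for (tr in tracks) {
    s <- tr$samples
    zone <- in_pir_zone(s$x, s$y, geometry)
    if (!any(zone)) next
    r <- rle(zone)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      rows[[length(rows) + 1L]] <- data.frame(
        t_start = s$t[starts[j]], t_end = s$t[ends[j]], track_id = tr$id,
        in_pir_zone = TRUE,
        in_camera_fov = any(in_camera_fov(s$x[idx], s$y[idx], geometry)))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t_start = numeric(), t_end = numeric(), track_id = integer(),
               in_pir_zone = logical(), in_camera_fov = logical())
  out <- out[order(out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ground_truth_log", "data.frame")
  out
}

#' Read a scene/geometry configuration file
#'
#' YAML mapping with two optional top-level blocks, `scene` and `geometry`,
#' whose keys are the arguments of [scene_config()] and [trap_geometry()].
#' Missing keys take the documented defaults.
#'
#' @param path Path to a YAML file.
#' @return List with elements `scene` and `geometry`.
#' @export
read_scene_config <- function(path) {
  doc <- yaml::read_yaml(path)
  sc <- do.call(scene_config, doc$scene %||% list())
  gargs <- doc$geometry %||% list()
  if (!is.null(gargs$trap_position)) gargs$trap_position <- unlist(gargs$trap_position)
  list(scene = sc, geometry = do.call(trap_geometry, gargs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
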