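#' Arc track skirting the camera field of view
#'
#' A scripted track moving at constant speed along a circular arc of radius
#' `radius` around the trap, sweeping its angular offset from the trap
#' heading from `offset_from` down to `offset_to` and back out. With the
#' offsets chosen between the camera and PIR half-angles the target dips into
#' the PIR detection zone without ever entering the picture: the trap
#' triggers, and the captured frame is blank -- the out-of-view
#' false-positive mechanism.
#'
#' @param geometry A [trap_geometry()] (supplies trap position and heading).
#' @param radius Arc radius, metres.
#' @param offset_from Starting/ending angular offset from the heading,
#'   degrees (use a value beyond the PIR half-angle so the track starts and
#'   ends outside the zone).
#' @param offset_to Deepest offset reached, degrees (keep it above the camera
#'   half-angle to stay out of view).
#' @param side `+1` (counter-clockwise of the heading) or `-1`.
#' @param speed Linear speed, m/s.
#' @param sample_interval Sampling interval, seconds.
#' @param start_time Time of the first sample, seconds.
#' @param ... Passed to [animal_track()].
#' @return An [animal_track()].
#' @export
arc_track <- function(geometry, radius = 3, offset_from = 55, offset_to = 30,
                      side = 1, speed = 0.5, sample_interval = 1,
                      start_time = 0, ...) {
  stopifnot(radius > 0, speed > 0, offset_from > offset_to)
  ang_speed <- speed / radius * 180 / pi  # degrees per second
  half <- (offset_from - offset_to) / ang_speed
  times <- seq(0, 2 * half, by = sample_interval)
  offset <- offset_from - ang_speed * times
  back <- times > half
  offset[back] <- offset_to + ang_speed * (times[back] - half)
  bearing <- (geometry$heading + side * offset) * pi / 180
  animal_track(data.frame(
    t = start_time + times,
    x = geometry$trap_position[1] + radius * cos(bearing),
    y = geometry$trap_position[2] + radius * sin(bearing),
    speed = speed), ...)
}

#' Tracks crossing the detection zone inside and outside the field of view
#'
#' Builds the scripted visit schedule used for triage-completeness
#' campaigns: `n_in` straight crossings that pass through the camera field of
#' view (capturable visits) interleaved with `n_out` arc passes through the
#' PIR-only flank of the detection zone (triggers whose frames are blank).
#' Visits are spread over `[first_start, duration - 60]` on an evenly spaced
#' slot grid with seeded jitter, so consecutive visits are well separated and
#' every capture can be allocated to its visit unambiguously. All start and
#' end points lie outside the PIR detection zone.
#'
#' @param geometry A [trap_geometry()].
#' @param duration Trial length, seconds.
#' @param seed Integer seed for the jitter.
#' @param n_in,n_out Numbers of in-view and out-of-view visits.
#' @param speed Visit speed, m/s.
#' @param first_start Earliest visit start, seconds (default 150, after the
#'   first scheduled time-lapse background exists).
#' @param sample_interval Track sampling interval, seconds.
#' @param ... Passed to [animal_track()] via the track constructors.
#' @return List of [animal_track()] objects.
#' @export
zone_crossing_tracks <- function(geometry, duration, seed, n_in = 4,
                                 n_out = 4, speed = 0.5, first_start = 150,
                                 sample_interval = 1, ...) {
  n <- n_in + n_out
  stopifnot(n > 0, duration > first_start + 120)
  slots <- seq(first_start, duration - 60, length.out = n)
  with_seed(seed, {
    starts <- slots + stats::runif(n, 0, 20)
    kinds <- rep(c("in", "out"), length.out = n)
    tracks <- vector("list", n)
    for (i in seq_len(n)) {
      if (kinds[i] == "in") {
        y <- stats::runif(1, 1.5, 2.5)
        ends <- list(c(0.5, y), c(5.5, y))
        if (i %% 4 == 1) ends <- rev(ends)  # alternate crossing direction
        tracks[[i]] <- crossing_track(ends[[1]], ends[[2]], speed = speed,
                                      sample_interval = sample_interval,
                                      start_time = starts[i], id = i, ...)
      } else {
        tracks[[i]] <- arc_track(geometry,
                                 radius = stats::runif(1, 2.8, 3.4),
                                 offset_from = 55, offset_to = 30,
                                 side = if (i %% 4 == 2) 1 else -1,
                                 speed = speed,
                                 sample_interval = sample_interval,
                                 start_time = starts[i], id = i, ...)
      }
    }
    tracks
  })
}

#' Simulate one complete trial end-to-end
#'
#' Convenience wrapper wiring the whole pipeline together: generates seeded
#' animal tracks in the arena, derives the ground-truth event log, runs the
#' virtual trap (scheduling, triggering, triage), and scores the resulting
#' captures against the ground truth. This is the synthetic analogue of one
#' day of a field trial in which the trap is watched by a reference video
#' camera.
#'
#' @param seed Integer seed; drives track generation and, via the scene seed,
#'   per-frame noise.
#' @param duration Trial length in seconds.
#' @param n_animals Number of simulated animals.
#' @param scene A [scene_config()]; its `rng_seed` defaults to `seed`.
#' @param geometry A [trap_geometry()].
#' @param config A [trap_config()].
#' @param sample_interval Track sampling interval, seconds.
#' @param env An [env_conditions()].
#' @param window Matching window for [match_captures()].
#' @param ... Passed to [generate_tracks()] (speeds, dwell mode, blob size...).
#' @return List with `tracks`, `truth`, `run` (a `trap_run`) and `counts`
#'   (a [confusion_counts()] row).
#' @export
simulate_trial <- function(seed, duration = 1800, n_animals = 3,
                           scene = scene_config(rng_seed = seed),
                           geometry = trap_geometry(),
                           config = trap_config(), sample_interval = 1,
                           env = env_conditions(), window = 5, ...) {
  tracks <- generate_tracks(scene, geometry, n_animals, duration,
                            sample_interval, seed = seed, ...)
  truth <- make_ground_truth(tracks, geometry)
  run <- run_trap(config, scene, geometry, tracks, duration, env = env)
  counts <- match_captures(run$captures, truth, window = window,
                           trial_id = paste0("seed-", seed))
  list(tracks = tracks, truth = truth, run = run, counts = counts)
}
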