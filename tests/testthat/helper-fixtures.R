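# Shared fixtures. Small frames keep renders and brute-force oracles fast.

tiny_scene <- function(seed = 1L, noise_sigma = 2) {
  scene_config(frame_width = 64, frame_height = 48, noise_sigma = noise_sigma,
               rng_seed = seed)
}

default_geom <- function() trap_geometry()

# a stationary track parked at (x, y) with a given per-sample speed
parked_track <- function(x, y, speed = 0.5, times = 0:60, ...) {
  animal_track(data.frame(t = times, x = x, y = y, speed = speed), ...)
}

random_pixels <- function(h, w) matrix(sample(0:255, h * w, replace = TRUE), h, w)

# independent double-loop difference-count oracle (0-based half-open ROI)
brute_force_diff_count <- function(a, b, roi, delta) {
  count <- 0L
  for (y in roi$y0:(roi$y1 - 1L)) {
    for (x in roi$x0:(roi$x1 - 1L)) {
      if (abs(a[y + 1L, x + 1L] - b[y + 1L, x + 1L]) > delta)
        count <- count + 1L
    }
  }
  count
}

# capture record rows for evaluate tests (handles zero-length t)
capture_row <- function(t, source = "motion", triage = "pending") {
  data.frame(filename = sprintf("f%.2f.jpg", t), t = t,
             source = rep_len(source, length(t)),
             triage = rep_len(triage, length(t)))
}

truth_row <- function(t_start, t_end, in_fov, track_id = 1L) {
  data.frame(t_start = t_start, t_end = t_end,
             track_id = rep_len(track_id, length(t_start)),
             in_pir_zone = rep_len(TRUE, length(t_start)),
             in_camera_fov = in_fov)
}

write_test_jpeg <- function(path, seed = 42L, h = 24, w = 32) {
  set.seed(seed)
  jpeg::writeJPEG(matrix(runif(h * w), h, w), path, quality = 0.95)
  path
}
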