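test_that("track generation honours counts, the sampling clock and bounds", {
  sc <- tiny_scene(); geom <- default_geom()

  expect_identical(generate_tracks(sc, geom, 0, 60), list())
  expect_error(generate_tracks(sc, geom, 2, -1), "duration")
  expect_error(generate_tracks(sc, geom, 2, 60, sample_interval = 0),
               "sample_interval")

  # expected number of samples from an independent loop over the clock
  expected_n <- 0L; t <- 0
  while (t <= 60) { expected_n <- expected_n + 1L; t <- t + 1 }
  tracks <- generate_tracks(sc, geom, 3, 60, sample_interval = 1, seed = 7)
  for (tr in tracks) {
    expect_equal(nrow(tr$samples), expected_n)
    expect_equal(tr$samples$t, 0:60)
    expect_true(all(tr$samples$x >= 0 & tr$samples$x <= sc$arena_width))
    expect_true(all(tr$samples$y >= 0 & tr$samples$y <= sc$arena_depth))
    expect_true(all(tr$samples$speed >= 0))
  }
})

test_that("identical seeds reproduce identical tracks, different seeds differ", {
  sc <- tiny_scene(); geom <- default_geom()
  a <- generate_tracks(sc, geom, 2, 120, seed = 11)
  b <- generate_tracks(sc, geom, 2, 120, seed = 11)
  c <- generate_tracks(sc, geom, 2, 120, seed = 12)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  expect_false(identical(a[[1]]$samples, c[[1]]$samples))
})

test_that("the dwell mode produces slow samples when enabled", {
  sc <- tiny_scene(); geom <- default_geom()
  tr <- generate_tracks(sc, geom, 1, 300, seed = 5, dwell_prob = 0.5,
                        dwell_speed = 0.02)[[1]]
  expect_gt(sum(tr$samples$speed < 0.02), 0)
  tr2 <- generate_tracks(sc, geom, 1, 300, seed = 5, dwell_prob = 0)[[1]]
  expect_equal(sum(tr2$samples$speed < 0.02), 0)
})

test_that("frames are bit-reproducible and background noise stays in bound", {
  # (deterministic per-frame seeding: same instant re-renders identically)
  sc <- tiny_scene(seed = 3); geom <- default_geom()
  f1 <- render_frame(sc, geom, list(), 42, "timelapse")
  f2 <- render_frame(sc, geom, list(), 42, "timelapse")
  expect_identical(f1$pixels, f2$pixels)

  # against a noiseless render (same scene, sigma = 0) the only difference is
  # the seeded noise, bounded well within 5 sigma
  sc0 <- tiny_scene(seed = 3, noise_sigma = 0)
  f0 <- render_frame(sc0, geom, list(), 42, "timelapse")
  expect_lte(max(abs(f1$pixels - f0$pixels)), 5 * sc$noise_sigma)

  # an out-of-FOV animal in the PIR zone leaves no pixel trace: bit-identical
  flank <- parked_track(1.85, 1.64)  # offset ~35 deg: inside PIR, outside camera
  expect_true(in_pir_zone(1.85, 1.64, geom))
  expect_false(in_camera_fov(1.85, 1.64, geom))
  f3 <- render_frame(sc, geom, list(flank), 42, "timelapse")
  expect_identical(f3$pixels, f1$pixels)
})

test_that("an in-view animal renders as a compact high-contrast blob", {
  sc <- scene_config(rng_seed = 9)  # full 320x240 frame for a radius-10 blob
  geom <- default_geom()
  tr <- parked_track(3, 4, body_radius_px = 10, thermal_contrast = 80)
  expect_true(in_camera_fov(3, 4, geom))
  with_animal <- render_frame(sc, geom, list(tr), 30, "motion")
  background <- render_frame(sc, geom, list(), 30, "motion")
  n_diff <- sum(abs(with_animal$pixels - background$pixels) > 40)
  expect_gte(n_diff, 150)
})

test_that("ground truth turns in-zone runs into events with correct FOV flags", {
  geom <- default_geom()

  # never enters the PIR zone -> no events
  far <- parked_track(0.1, 0.1)
  expect_false(any(in_pir_zone(0.1, 0.1, geom)))
  expect_equal(nrow(make_ground_truth(list(far), geom)), 0)

  # crossing the zone along a diameter at constant speed v:
  # event duration = 2 * pir_max_range / v, within one sample interval
  g <- trap_geometry(trap_position = c(10, 10), heading = 0,
                     camera_fov_halfangle = 27, camera_max_range = 8,
                     pir_fov_halfangle = 180, pir_max_range = 9)
  v <- 0.5
  tr <- crossing_track(c(0, 10), c(20, 10), speed = v, sample_interval = 1)
  ev <- make_ground_truth(list(tr), g)
  expect_equal(nrow(ev), 1)
  expect_lte(abs((ev$t_end - ev$t_start) - 2 * g$pir_max_range / v), 1)

  # FOV flag: flank arc never enters the camera FOV, a centre crossing does
  geom2 <- default_geom()
  arc <- arc_track(geom2, radius = 3, offset_from = 55, offset_to = 30,
                   id = 1L)
  centre <- crossing_track(c(0.5, 2), c(5.5, 2), id = 2L)
  ev2 <- make_ground_truth(list(arc, centre), geom2)
  expect_equal(nrow(ev2), 2)
  expect_false(ev2$in_camera_fov[ev2$track_id == 1])
  expect_true(ev2$in_camera_fov[ev2$track_id == 2])
  expect_true(all(ev2$in_pir_zone))
  expect_true(all(ev2$t_start < ev2$t_end))
})

test_that("the camera FOV is contained in the PIR zone (brute-force check)", {
  geom <- default_geom()
  set.seed(101)
  x <- runif(500, 0, 6); y <- runif(500, 0, 8)
  fov <- in_camera_fov(x, y, geom)
  zone <- in_pir_zone(x, y, geom)
  # independent per-point angle/range computation
  for (i in seq_along(x)) {
    dx <- x[i] - 3; dy <- y[i] - 0
    r <- sqrt(dx^2 + dy^2)
    off <- abs(((atan2(dy, dx) * 180 / pi - 90 + 180) %% 360) - 180)
    expect_equal(fov[i], r <= 8 && (off <= 27 || r < 1e-9))
    expect_equal(zone[i], r <= 9 && (off <= 45 || r < 1e-9))
  }
  expect_true(all(zone[fov]))  # containment
})

test_that("a frame differs from the empty render iff an in-FOV event spans it", {
  sc <- tiny_scene(seed = 21); geom <- default_geom()
  tracks <- list(crossing_track(c(0.5, 2), c(5.5, 2), speed = 0.5,
                                start_time = 10, id = 1L))
  truth <- make_ground_truth(tracks, geom)
  fov_events <- truth[truth$in_camera_fov, ]
  for (t in seq(0, 40, by = 4)) {
    f <- render_frame(sc, geom, tracks, t, "motion")
    bg <- render_frame(sc, geom, list(), t, "motion")
    differs <- max(abs(f$pixels - bg$pixels)) > 5 * sc$noise_sigma
    pos <- track_position(tracks[[1]], t)
    expect_equal(differs, in_camera_fov(pos$x, pos$y, geom))
    if (differs)
      expect_true(any(t >= fov_events$t_start & t <= fov_events$t_end))
  }
})

test_that("scene/geometry YAML configs round defaults and overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scene:", "  arena_width: 10", "  rng_seed: 7",
               "geometry:", "  trap_position: [5, 0]",
               "  pir_fov_halfangle: 60"), path)
  cfg <- read_scene_config(path)
  expect_equal(cfg$scene$arena_width, 10)
  expect_equal(cfg$scene$arena_depth, 8)  # default retained
  expect_equal(cfg$geometry$trap_position, c(5, 0))
  expect_equal(cfg$geometry$pir_fov_halfangle, 60)
})
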