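test_that("configuration parsing: defaults, overrides, rejections", {
  cfg <- parse_trap_config("")
  expect_equal(cfg$min_motion_interval, 5)
  expect_equal(cfg$timelapse_interval, 120)
  expect_equal(cfg$trigger_latency, 0.44)
  expect_false(cfg$keep_background)
  expect_equal(cfg$fp_policy, "flag")

  cfg2 <- parse_trap_config(c("timelapse_interval: 120",
                              "min_motion_interval = 5",
                              "keep_background: true",
                              "fp_policy: delete",
                              "custom_label: SITE1",
                              "roi: 10,20,100,80",
                              "active_windows: 06:00-09:00, 17:00-20:00",
                              "pir_min_speed: 0.1",
                              "radar_min_cross_section: 2",
                              "# a comment", ""))
  expect_equal(cfg2$timelapse_interval, 120)
  expect_true(cfg2$keep_background)
  expect_equal(cfg2$fp_policy, "delete")
  expect_equal(cfg2$custom_label, "SITE1")
  expect_equal(unclass(cfg2$roi)[c("x0", "y0", "x1", "y1")],
               list(x0 = 10L, y0 = 20L, x1 = 100L, y1 = 80L))
  expect_equal(cfg2$active_windows,
               list(c(6 * 3600, 9 * 3600), c(17 * 3600, 20 * 3600)))
  expect_equal(cfg2$pir$min_speed, 0.1)
  expect_equal(cfg2$radar$min_cross_section, 2)

  expect_error(parse_trap_config("min_motion_interval: -1"),
               "min_motion_interval")
  expect_error(parse_trap_config("pir_sensitivity: 3"), "pir_sensitivity")
  expect_error(parse_trap_config("timelapse_interval: fast"),
               "timelapse_interval")
  expect_error(parse_trap_config("active_windows: 06:00-09:00, 08:00-10:00"),
               "overlap")
})

test_that("time-lapse schedule: floor(duration/interval) captures, none at t=0", {
  sc <- tiny_scene(); geom <- default_geom()
  run <- run_trap(trap_config(timelapse_interval = 120, keep_background = TRUE),
                  sc, geom, list(), 600)
  tl <- run$captures[run$captures$source == "timelapse", ]
  expect_equal(nrow(run$captures), 5)       # schedule oracle: floor(600/120)
  expect_equal(tl$t, (1:5) * 120)
  expect_true(all(tl$triage == "not-applicable"))
  expect_error(run_trap(trap_config(), sc, geom, list(), 0), "duration")
})

test_that("minimum motion interval: triggers 3 s apart yield one capture", {
  sc <- tiny_scene(); geom <- default_geom()
  # PIR fires exactly at the two sample instants (in zone, moving, warm)
  tr <- animal_track(data.frame(t = c(10, 13), x = 3, y = 4, speed = 0.5))
  run <- run_trap(trap_config(), sc, geom, list(tr), 60)
  motion <- run$captures[run$captures$source == "motion", ]
  expect_equal(nrow(motion), 1)
  expect_equal(motion$t, 10.44)  # capture trails the trigger by the latency
  expect_true(any(grepl("suppressed", run$log)))
})

test_that("radar activity is cross-referenced to motion captures", {
  sc <- tiny_scene(); geom <- default_geom()
  big <- animal_track(data.frame(t = c(10, 11), x = 3, y = 4, speed = 0.5),
                      radar_cross_section = 2)
  run <- run_trap(trap_config(), sc, geom, list(big), 60)
  motion <- run$captures[run$captures$source == "motion", ]
  expect_true(all(motion$radar_confirmed))
  expect_true(any(grepl("radar detection", run$log)))

  gull <- animal_track(data.frame(t = c(10, 11), x = 3, y = 4, speed = 0.5),
                       radar_cross_section = 0.5)
  run2 <- run_trap(trap_config(), sc, geom, list(gull), 60)
  expect_true(all(!run2$captures$radar_confirmed[run2$captures$source == "motion"]))
})

test_that("spacing, conservation and reproducibility hold on a full simulation", {
  sc <- tiny_scene(seed = 8); geom <- default_geom()
  tracks <- generate_tracks(sc, geom, 3, 900, seed = 8)
  cfg <- trap_config()
  run <- run_trap(cfg, sc, geom, tracks, 900)
  motion <- run$captures[run$captures$source == "motion", ]

  # consecutive motion captures separated by at least the minimum interval
  if (nrow(motion) > 1)
    expect_true(all(diff(motion$t) >= cfg$min_motion_interval - 1e-9))

  # count conservation: captures = triggers - suppressed
  n_triggers <- sum(grepl("] pir trigger$", run$log))
  n_suppressed <- sum(grepl("pir trigger suppressed", run$log))
  expect_equal(nrow(motion), n_triggers - n_suppressed)

  # identical inputs reproduce the identical capture list and frames
  run2 <- run_trap(cfg, sc, geom, tracks, 900)
  expect_identical(run$captures, run2$captures)
  expect_identical(lapply(run$frames, `[[`, "pixels"),
                   lapply(run2$frames, `[[`, "pixels"))
})

test_that("no capture of any kind happens outside the active windows", {
  sc <- tiny_scene(); geom <- default_geom()
  # trial starts 06:30; active 06:00-07:00 -> only the first 1800 s are live
  cfg <- trap_config(active_windows = "06:00-07:00")
  tracks <- list(animal_track(
    data.frame(t = c(600, 2000, 2400), x = 3, y = 4, speed = c(0.5, 0.5, 0.5))))
  run <- run_trap(cfg, sc, geom, tracks, 3600,
                  trial_start = as.POSIXct("2016-03-01 06:30:00", tz = "UTC"))
  expect_true(all(run$captures$t <= 1800))
  motion <- run$captures[run$captures$source == "motion", ]
  expect_equal(nrow(motion), 1)  # the 600 s trigger; later ones suppressed
  expect_true(any(grepl("outside active window", run$log)))
})

test_that("a coincident time-lapse is captured first and used as background", {
  sc <- tiny_scene(seed = 6); geom <- default_geom()
  tr <- animal_track(data.frame(t = 120, x = 3, y = 4, speed = 0.5))
  run <- run_trap(trap_config(), sc, geom, list(tr), 240)
  motion <- run$captures[run$captures$source == "motion", ]
  expect_equal(nrow(motion), 1)
  # the coincident time-lapse was captured first, so triage is not pending;
  # the bird sits in that fresh background too, so the frames barely differ
  expect_false(motion$triage == "pending")
  expect_lt(motion$diff_count, 50)

  # a motion capture before any time-lapse exists stays pending, never deleted
  tr2 <- animal_track(data.frame(t = 30, x = 3, y = 4, speed = 0.5))
  run2 <- run_trap(trap_config(fp_policy = "delete"), sc, geom, list(tr2), 240)
  m2 <- run2$captures[run2$captures$source == "motion", ]
  expect_equal(m2$triage, "pending")
  expect_true(m2$file_kept)
})

test_that("superseded backgrounds are deleted unless keep_background is set", {
  sc <- tiny_scene(); geom <- default_geom()
  run <- run_trap(trap_config(keep_background = FALSE), sc, geom, list(), 600)
  tl <- run$captures[run$captures$source == "timelapse", ]
  expect_equal(sum(tl$file_kept), 1)  # only the latest retained
  expect_equal(length(run$frames), 1)
  expect_true(any(grepl("background time-lapse deleted", run$log)))

  run2 <- run_trap(trap_config(keep_background = TRUE), sc, geom, list(), 600)
  expect_equal(sum(run2$captures$file_kept), 5)
})
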