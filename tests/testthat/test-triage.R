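mk_frame <- function(pixels, t = 0, kind = "motion") trap_frame(pixels, t, kind)

test_that("background selection returns the latest time-lapse at or before t", {
  hist <- list(mk_frame(matrix(1, 2, 2), t = 120, kind = "timelapse"),
               mk_frame(matrix(2, 2, 2), t = 240, kind = "timelapse"),
               mk_frame(matrix(3, 2, 2), t = 230, kind = "motion"))
  expect_equal(select_background(hist, 250)$t, 240)
  expect_equal(select_background(hist, 240)$t, 240)  # ties resolve to <=
  expect_equal(select_background(hist, 125)$t, 120)
  expect_null(select_background(hist, 119))          # cold start: no background
  expect_null(select_background(list(), 500))
})

test_that("background subtraction counts only ROI pixels beyond the delta", {
  base <- random_pixels(20, 30)
  bg <- mk_frame(base, kind = "timelapse")

  expect_equal(background_subtract(mk_frame(base), bg, NULL, 10)$diff_count, 0)

  # exactly one ROI pixel altered by delta + 1 -> count 1; by delta -> 0
  px <- base
  px[5, 5] <- max(0, min(255, base[5, 5] + ifelse(base[5, 5] < 128, 11, -11)))
  roi <- region_of_interest(0, 0, 15, 15)
  expect_equal(background_subtract(mk_frame(px), bg, roi, 10)$diff_count, 1)
  expect_equal(background_subtract(mk_frame(px), bg, roi, 11)$diff_count, 0)

  # alterations wholly outside the ROI are invisible to it
  px2 <- base
  px2[18:20, 25:30] <- 255 - px2[18:20, 25:30]
  expect_equal(background_subtract(mk_frame(px2), bg, roi, 10)$diff_count, 0)

  # contract violations
  expect_error(background_subtract(mk_frame(random_pixels(10, 10)), bg, NULL, 5),
               "dimensions")
  expect_error(background_subtract(mk_frame(base), bg,
                                   region_of_interest(0, 0, 40, 10), 5),
               "region of interest")
  expect_error(region_of_interest(5, 0, 5, 10))
})

test_that("diff_count equals the brute-force oracle on random frame pairs", {
  set.seed(1234)
  for (i in 1:200) {
    h <- sample(4:64, 1); w <- sample(4:64, 1)
    a <- random_pixels(h, w)
    b <- if (i %% 3 == 0) a + sample(-20:20, h * w, replace = TRUE) else
      random_pixels(h, w)
    b <- pmin(pmax(b, 0), 255)
    roi <- if (i %% 2 == 0) {
      x0 <- sample(0:(w - 2), 1); y0 <- sample(0:(h - 2), 1)
      region_of_interest(x0, y0, sample((x0 + 1):w, 1), sample((y0 + 1):h, 1))
    } else region_of_interest(0, 0, w, h)
    delta <- sample(0:40, 1)
    res <- background_subtract(mk_frame(a), mk_frame(b, kind = "timelapse"),
                               roi, delta)
    expect_identical(res$diff_count, brute_force_diff_count(a, b, roi, delta))
    expect_identical(res$diff_count, sum(res$diff_mask))
    expect_lte(res$diff_count, (roi$x1 - roi$x0) * (roi$y1 - roi$y0))
  }
})

test_that("diff_count is monotone under ROI nesting; verdicts under thresholds", {
  set.seed(99)
  a <- random_pixels(40, 40); b <- random_pixels(40, 40)
  fa <- mk_frame(a); fb <- mk_frame(b, kind = "timelapse")
  for (i in 1:25) {
    x0 <- sample(0:30, 1); y0 <- sample(0:30, 1)
    x1 <- sample((x0 + 2):40, 1); y1 <- sample((y0 + 2):40, 1)
    outer_roi <- region_of_interest(x0, y0, x1, y1)
    inner_roi <- region_of_interest(x0 + 1, y0 + 1, x1, y1)
    delta <- sample(0:30, 1)
    big <- background_subtract(fa, fb, outer_roi, delta)
    small <- background_subtract(fa, fb, inner_roi, delta)
    expect_lte(small$diff_count, big$diff_count)
    # raising the count threshold never converts false-positive to true-capture
    th <- sample(0:100, 1)
    if (classify_capture(big, th) == "false-positive")
      expect_equal(classify_capture(big, th + sample(1:50, 1)),
                   "false-positive")
  }
})

test_that("classification applies the strictly-below rule", {
  res0 <- list(diff_count = 0); res50 <- list(diff_count = 50)
  expect_equal(classify_capture(res0, 50), "false-positive")
  expect_equal(classify_capture(res50, 50), "true-capture")  # boundary
  expect_equal(classify_capture(res0, 0), "true-capture")    # nothing < 0
})

test_that("the false-positive policy deletes or flags files as configured", {
  dir <- withr::local_tempdir()
  p1 <- write_test_jpeg(file.path(dir, "a.jpg"), seed = 1)
  p2 <- write_test_jpeg(file.path(dir, "b.jpg"), seed = 2)
  rec <- function(p) data.frame(filename = basename(p), path = p,
                                triage = NA, file_kept = NA)

  out <- apply_policy(rec(p1), "false-positive", "flag", diff_count = 3)
  expect_true(file.exists(p1))
  expect_true(out$file_kept)
  expect_equal(extract_metadata(p1)$triage_verdict, "false-positive")

  out2 <- apply_policy(rec(p1), "true-capture", "delete", diff_count = 500)
  expect_true(file.exists(p1))  # true captures survive either policy
  expect_equal(extract_metadata(p1)$triage_verdict, "true-capture")

  out3 <- apply_policy(rec(p2), "false-positive", "delete")
  expect_false(file.exists(p2))
  expect_false(out3$file_kept)
})

test_that("stand-alone folder triage reproduces the in-controller verdicts", {
  dir <- withr::local_tempdir()
  mdir <- file.path(dir, "motion"); tdir <- file.path(dir, "timelapse")
  dir.create(mdir); dir.create(tdir)
  sc <- tiny_scene(seed = 31); geom <- default_geom()
  bird <- parked_track(3, 3, times = 0:400)
  t0 <- as.POSIXct("2016-03-01 08:00:00", tz = "UTC")

  bg <- render_frame(sc, geom, list(), 120, "timelapse")
  write_frame(bg, file.path(tdir, compose_filename(t0 + 120, "", "timelapse",
                                                   ext = "png")))
  blank <- render_frame(sc, geom, list(), 200, "motion")     # out-of-view trigger
  with_bird <- render_frame(sc, geom, list(bird), 300, "motion")
  f_blank <- compose_filename(t0 + 200, "", "motion", ext = "png")
  f_bird <- compose_filename(t0 + 300, "", "motion", ext = "png")
  write_frame(blank, file.path(mdir, f_blank))
  write_frame(with_bird, file.path(mdir, f_bird))
  # a motion image predating every time-lapse stays pending
  early <- render_frame(sc, geom, list(), 60, "motion")
  f_early <- compose_filename(t0 + 60, "", "motion", ext = "png")
  write_frame(early, file.path(mdir, f_early))

  rep <- triage_folder(mdir, tdir, pixel_delta = 12, count_threshold = 20,
                       policy = "flag")
  rep <- rep[order(rep$filename), ]
  expect_equal(rep$classification[rep$filename == f_early], "pending")
  expect_equal(rep$classification[rep$filename == f_blank], "false-positive")
  expect_equal(rep$classification[rep$filename == f_bird], "true-capture")
  expect_true(all(file.exists(file.path(mdir, rep$filename))))
})
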