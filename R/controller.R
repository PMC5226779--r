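#' Trap configuration
#'
#' Every user-definable setting of the trap in one object: trigger timing
#' (`trigger_latency`, the delay between sensor activation and image capture;
#' `min_motion_interval`, the enforced minimum spacing between two
#' motion-activated images; `timelapse_interval`, the scheduled background
#' capture period), triage settings (`roi`, `diff_pixel_delta`,
#' `diff_count_threshold`, `fp_policy`), background retention
#' (`keep_background`; the default deletes superseded time-lapse backgrounds
#' to save storage, retaining only the latest), duty cycling
#' (`active_windows`, times of day when the trap operates; empty = always
#' active), a `custom_label` added to filenames and metadata, and the two
#' sensor models.
#'
#' @param trigger_latency Seconds from PIR activation to image capture
#'   (default 0.44, a measured prototype latency).
#' @param min_motion_interval Minimum seconds between two motion-activated
#'   captures, capture-to-capture (default 5).
#' @param timelapse_interval Seconds between scheduled time-lapse captures
#'   (default 120).
#' @param keep_background Keep every time-lapse image (`TRUE`) or delete each
#'   one once superseded, retaining only the latest (`FALSE`, default).
#' @param roi A [region_of_interest()] or `NULL` for the whole frame.
#' @param diff_pixel_delta Per-pixel intensity delta for background
#'   subtraction.
#' @param diff_count_threshold Difference-pixel count below which a motion
#'   capture is classified a false positive.
#' @param fp_policy `"flag"` (keep and mark) or `"delete"` false positives.
#' @param active_windows List of `c(start, end)` seconds-of-day pairs, or
#'   character vector `"HH:MM-HH:MM"`; must not overlap or wrap midnight.
#' @param custom_label Label added to filenames/metadata (letters, digits,
#'   hyphens).
#' @param pir A [pir_model()].
#' @param radar A [radar_model()].
#' @param seed Integer seed for any stochastic extension.
#' @return An object of class `trap_config`.
#' @export
trap_config <- function(trigger_latency = 0.44, min_motion_interval = 5,
                        timelapse_interval = 120, keep_background = FALSE,
                        roi = NULL, diff_pixel_delta = 12,
                        diff_count_threshold = 50,
                        fp_policy = c("flag", "delete"),
                        active_windows = list(), custom_label = "",
                        pir = pir_model(), radar = radar_model(), seed = 1L) {
  fp_policy <- match.arg(fp_policy)
  if (min_motion_interval <= 0) stop("min_motion_interval must be positive")
  if (timelapse_interval <= 0) stop("timelapse_interval must be positive")
  if (trigger_latency < 0) stop("trigger_latency must be non-negative")
  if (diff_pixel_delta < 0) stop("diff_pixel_delta must be non-negative")
  if (diff_count_threshold < 0) stop("diff_count_threshold must be non-negative")
  if (!grepl("^[A-Za-z0-9-]*$", custom_label))
    stop("custom_label may contain only letters, digits and hyphens")
  active_windows <- normalise_windows(active_windows)
  structure(list(
    trigger_latency = trigger_latency,
    min_motion_interval = min_motion_interval,
    timelapse_interval = timelapse_interval,
    keep_background = keep_background, roi = roi,
    diff_pixel_delta = diff_pixel_delta,
    diff_count_threshold = diff_count_threshold, fp_policy = fp_policy,
    active_windows = active_windows, custom_label = custom_label,
    pir = pir, radar = radar, seed = as.integer(seed)
  ), class = "trap_config")
}

## windows -> list of c(start, end) seconds-of-day; validates non-overlap
normalise_windows <- function(w) {
  if (is.character(w)) w <- lapply(w, parse_window)
  if (!is.list(w)) stop("active_windows must be a list or character vector")
  w <- lapply(w, function(x) {
    x <- as.numeric(x)
    if (length(x) != 2 || x[1] < 0 || x[2] > 86400 || x[1] >= x[2])
      stop("active window must satisfy 0 <= start < end <= 86400 seconds")
    x
  })
  if (length(w) > 1) {
    ord <- order(vapply(w, `[`, numeric(1), 1))
    w <- w[ord]
    starts <- vapply(w, `[`, numeric(1), 1)
    ends <- vapply(w, `[`, numeric(1), 2)
    if (any(starts[-1] < ends[-length(ends)]))
      stop("active windows must not overlap")
  }
  w
}

parse_window <- function(s) {
  m <- regmatches(s, regexec("^(\\d{1,2}):(\\d{2})-(\\d{1,2}):(\\d{2})$", s))[[1]]
  if (!length(m)) stop("active window must look like HH:MM-HH:MM: ", s)
  v <- as.numeric(m[-1])
  c(v[1] * 3600 + v[2] * 60, v[3] * 3600 + v[4] * 60)
}

is_active <- function(config, tod) {
  if (!length(config$active_windows)) return(TRUE)
  any(vapply(config$active_windows,
             function(w) tod >= w[1] && tod < w[2], logical(1)))
}

## key registry for the flat key: value configuration format
config_keys <- function() {
  c("trigger_latency", "min_motion_interval", "timelapse_interval",
    "keep_background", "roi", "diff_pixel_delta", "diff_count_threshold",
    "fp_policy", "active_windows", "custom_label", "seed",
    "pir_fov_halfangle", "pir_max_range", "pir_min_speed",
    "pir_contrast_threshold",
    "radar_min_range", "radar_max_range", "radar_min_cross_section")
}

#' Parse a trap configuration document
#'
#' The trap is configured from a flat plain-text document, one `key: value`
#' per line (`key = value` also accepted; blank lines and `#` comments
#' ignored). Unknown keys are rejected; missing keys take the documented
#' defaults of [trap_config()], so an empty document yields a configuration
#' of pure defaults. Sensor parameters use `pir_` / `radar_` prefixes, the
#' ROI is `x0,y0,x1,y1`, and active windows a comma-separated list of
#' `HH:MM-HH:MM` ranges.
#'
#' @param text A file path, or the document itself as a character vector.
#' @return A [trap_config()].
#' @export
parse_trap_config <- function(text) {
  lines <- if (length(text) == 1 && file.exists(text)) readLines(text)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (!length(m)) stop("malformed configuration line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% config_keys()) stop("unknown configuration key: ", key)
    kv[[key]] <- val
  }
  num <- function(key) {
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop("configuration value for '", key, "' is not a number")
    v
  }
  args <- list()
  for (key in c("trigger_latency", "min_motion_interval", "timelapse_interval",
                "diff_pixel_delta", "diff_count_threshold", "seed"))
    if (!is.null(kv[[key]])) args[[key]] <- num(key)
  if (!is.null(kv$keep_background)) {
    v <- tolower(kv$keep_background)
    if (!v %in% c("true", "false", "yes", "no", "1", "0"))
      stop("configuration value for 'keep_background' must be true/false")
    args$keep_background <- v %in% c("true", "yes", "1")
  }
  if (!is.null(kv$fp_policy)) {
    if (!kv$fp_policy %in% c("flag", "delete"))
      stop("configuration value for 'fp_policy' must be flag or delete")
    args$fp_policy <- kv$fp_policy
  }
  if (!is.null(kv$custom_label)) args$custom_label <- kv$custom_label
  if (!is.null(kv$roi)) {
    v <- suppressWarnings(as.numeric(strsplit(kv$roi, ",")[[1]]))
    if (length(v) != 4 || anyNA(v))
      stop("configuration value for 'roi' must be x0,y0,x1,y1")
    args$roi <- region_of_interest(v[1], v[2], v[3], v[4])
  }
  if (!is.null(kv$active_windows))
    args$active_windows <- trimws(strsplit(kv$active_windows, ",")[[1]])
  pir_args <- list(); radar_args <- list()
  for (key in names(kv)) {
    if (startsWith(key, "pir_")) pir_args[[sub("^pir_", "", key)]] <- num(key)
    if (startsWith(key, "radar_")) radar_args[[sub("^radar_", "", key)]] <- num(key)
  }
  if (length(pir_args)) args$pir <- do.call(pir_model, pir_args)
  if (length(radar_args)) args$radar <- do.call(radar_model, radar_args)
  res <- try(do.call(trap_config, args), silent = TRUE)
  if (inherits(res, "try-error"))
    stop("configuration error: ", attr(res, "condition")$message)
  res
}

#' Run the virtual trap over a simulated trial
#'
#' The event-driven capture loop. Time-lapse frames are captured at
#' `t = k * timelapse_interval` for `k = 1, 2, ...` (none at `t = 0`); the
#' latest one serves as the triage background. A PIR detection at a track
#' sample time `t` triggers a motion capture at `t + trigger_latency` --
#' evaluating the scene at the capture instant, so a fast target may have
#' left the field of view by the time the shutter fires -- provided the trap
#' is inside an active window and at least `min_motion_interval` seconds have
#' passed since the previous motion capture (capture-to-capture). When a
#' trigger and a time-lapse instant coincide, the time-lapse frame is
#' captured first and becomes the background for the motion frame. Radar
#' detections are logged throughout and each motion capture records whether
#' radar confirmed a target at the capture instant. Every motion capture is
#' triaged against the most recent time-lapse frame (pending if none exists
#' yet, e.g. before the first time-lapse), honouring `fp_policy`. Suppressed
#' triggers, radar activity and triage results all go to the system log.
#'
#' @param config A [trap_config()].
#' @param scene A [scene_config()].
#' @param geometry A [trap_geometry()].
#' @param tracks List of [animal_track()].
#' @param duration Trial length in seconds (> 0).
#' @param env An [env_conditions()].
#' @param out_dir If given, kept images are written there (with embedded
#'   metadata) along with `captures.csv` and `system.log`.
#' @param trial_start Absolute start time (`POSIXct`) used for filenames,
#'   catalog timestamps and active-window times of day.
#' @param image_format `"jpg"` (EXIF metadata) or `"png"` (JSON sidecar).
#' @return An object of class `trap_run`: list with `captures` (data.frame:
#'   `filename`, `t`, `timestamp`, `source`, `radar_confirmed`, `triage`,
#'   `diff_count`, `file_kept`), `frames` (named list of kept
#'   [trap_frame()]s), `log` (character vector) and the inputs.
#' @export
run_trap <- function(config, scene, geometry, tracks, duration,
                     env = env_conditions(), out_dir = NULL,
                     trial_start = as.POSIXct("2016-03-01 06:00:00",
                                              tz = "UTC"),
                     image_format = c("jpg", "png")) {
  if (duration <= 0) stop("duration must be positive")
  image_format <- match.arg(image_format)
  start_tod <- as.numeric(trial_start) %% 86400
  tod <- function(t) (start_tod + t) %% 86400
  log <- character()
  put <- function(t, msg) log[[length(log) + 1L]] <<-
    sprintf("[%10.2f] %s", t, msg)

  # PIR trigger times: track sample instants where any animal is detected;
  # radar activity is evaluated on the same clock and logged
  trigger_times <- numeric()
  for (tr in tracks) {
    s <- tr$samples[tr$samples$t <= duration, , drop = FALSE]
    if (!nrow(s)) next
    hit <- pir_detect(s, tr, config$pir, env, geometry)
    trigger_times <- c(trigger_times, s$t[hit])
    rhit <- radar_detect(s, tr, config$radar, geometry)
    for (t in s$t[rhit]) put(t, sprintf("radar detection (track %s)", tr$id))
  }
  trigger_times <- sort(unique(trigger_times))

  tl_times <- seq_len(floor(duration / config$timelapse_interval)) *
    config$timelapse_interval
  events <- rbind(
    data.frame(t = tl_times, type = rep("timelapse", length(tl_times))),
    data.frame(t = trigger_times, type = rep("trigger", length(trigger_times))))
  events <- events[order(events$t, events$type), , drop = FALSE]

  radar_at <- function(t) {
    any(vapply(tracks, function(tr)
      radar_detect(track_position(tr, t), tr, config$radar, geometry),
      logical(1)))
  }

  records <- list()
  frames <- list()
  background <- NULL
  last_motion <- -Inf
  existing <- character()

  add_record <- function(rec) records[[length(records) + 1L]] <<- rec

  for (i in seq_len(nrow(events))) {
    t <- events$t[i]
    if (events$type[i] == "timelapse") {
      if (!is_active(config, tod(t))) {
        put(t, "timelapse suppressed (outside active window)")
        next
      }
      frame <- render_frame(scene, geometry, tracks, t, "timelapse")
      fn <- compose_filename(trial_start + t, config$custom_label,
                             "timelapse", existing, ext = image_format)
      existing <- c(existing, fn)
      if (!config$keep_background && !is.null(background)) {
        # superseded background deleted to save storage; only latest retained
        old_fn <- attr(background, "filename")
        frames[[old_fn]] <- NULL
        for (k in seq_along(records))
          if (records[[k]]$filename == old_fn) records[[k]]$file_kept <- FALSE
        put(t, sprintf("background time-lapse deleted: %s", old_fn))
      }
      attr(frame, "filename") <- fn
      background <- frame
      frames[[fn]] <- frame
      put(t, sprintf("timelapse captured: %s", fn))
      add_record(list(filename = fn, t = t, source = "timelapse",
                      radar_confirmed = NA, triage = "not-applicable",
                      diff_count = NA_integer_, file_kept = TRUE))
    } else {
      put(t, "pir trigger")
      if (!is_active(config, tod(t))) {
        put(t, "pir trigger suppressed (outside active window)")
        next
      }
      t_cap <- t + config$trigger_latency
      if (t_cap - last_motion < config$min_motion_interval) {
        put(t, sprintf("pir trigger suppressed (within %gs of previous capture)",
                       config$min_motion_interval))
        next
      }
      frame <- render_frame(scene, geometry, tracks, min(t_cap, duration),
                            "motion")
      frame$t <- t_cap
      fn <- compose_filename(trial_start + t_cap, config$custom_label,
                             "motion", existing, ext = image_format)
      existing <- c(existing, fn)
      rc <- radar_at(t_cap)
      if (rc) put(t_cap, sprintf("radar confirmed capture %s", fn))
      triage <- "pending"; dc <- NA_integer_; kept <- TRUE
      if (!is.null(background)) {
        res <- background_subtract(frame, background, config$roi,
                                   config$diff_pixel_delta)
        triage <- classify_capture(res, config$diff_count_threshold)
        dc <- res$diff_count
        put(t_cap, sprintf("triage %s vs %s: diff_count=%d -> %s", fn,
                           attr(background, "filename"), dc, triage))
        if (triage == "false-positive" && config$fp_policy == "delete") {
          kept <- FALSE
          put(t_cap, sprintf("false positive deleted: %s", fn))
        }
      } else {
        put(t_cap, sprintf("triage pending (no background yet): %s", fn))
      }
      if (kept) frames[[fn]] <- frame
      put(t_cap, sprintf("motion captured: %s", fn))
      add_record(list(filename = fn, t = t_cap, source = "motion",
                      radar_confirmed = rc, triage = triage, diff_count = dc,
                      file_kept = kept))
      last_motion <- t_cap
    }
  }

  captures <- if (length(records)) do.call(rbind, lapply(records, function(r) {
    data.frame(filename = r$filename, t = r$t,
               timestamp = format(trial_start + r$t, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               source = r$source, radar_confirmed = r$radar_confirmed,
               triage = r$triage, diff_count = r$diff_count,
               file_kept = r$file_kept, stringsAsFactors = FALSE)
  })) else data.frame(filename = character(), t = numeric(),
                      timestamp = character(), source = character(),
                      radar_confirmed = logical(), triage = character(),
                      diff_count = integer(), file_kept = logical())
  rownames(captures) <- NULL
  run <- structure(list(captures = captures, frames = frames, log = log,
                        config = config, scene = scene, geometry = geometry,
                        duration = duration, trial_start = trial_start),
                   class = "trap_run")
  if (!is.null(out_dir)) write_trap_run(run, out_dir)
  run
}

#' @export
print.trap_run <- function(x, ...) {
  n_m <- sum(x$captures$source == "motion")
  n_t <- sum(x$captures$source == "timelapse")
  cat(sprintf("<trap_run: %g s, %d motion + %d timelapse captures, %d log lines>\n",
              x$duration, n_m, n_t, length(x$log)))
  if (n_m) {
    tab <- table(x$captures$triage[x$captures$source == "motion"])
    cat("  motion triage:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a trap run to disk
#'
#' Writes every kept image (with its metadata embedded), the `captures.csv`
#' catalog (one row per capture, including deleted ones) and the timestamped
#' `system.log`.
#'
#' @param run A [run_trap()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_trap_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (fn in names(run$frames)) {
    path <- file.path(out_dir, fn)
    write_frame(run$frames[[fn]], path)
    rec <- run$captures[run$captures$filename == fn, ]
    tags <- list(trigger_source = rec$source,
                 triage_verdict = rec$triage,
                 timestamp = rec$timestamp)
    if (!is.na(rec$radar_confirmed)) tags$radar_confirmed <- rec$radar_confirmed
    if (!is.na(rec$diff_count)) tags$diff_count <- rec$diff_count
    if (nzchar(run$config$custom_label))
      tags$custom_label <- run$config$custom_label
    embed_metadata(path, tags)
  }
  catalog <- file.path(out_dir, "captures.csv")
  if (file.exists(catalog)) file.remove(catalog)
  for (i in seq_len(nrow(run$captures))) {
    rec <- run$captures[i, ]
    append_summary(list(filename = rec$filename, timestamp = rec$timestamp,
                        source = rec$source,
                        radar_confirmed = rec$radar_confirmed,
                        diff_count = rec$diff_count,
                        classification = rec$triage,
                        custom_label = run$config$custom_label), catalog)
  }
  writeLines(run$log, file.path(out_dir, "system.log"))
  invisible(out_dir)
}
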