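#' Confusion counts for one trial
#'
#' Per-trial tallies of the trap's detection performance: images containing a
#' target (`true_positive`), images containing none (`false_positive`),
#' in-view visits that produced no image (`false_negative`, a count of missed
#' potential detections, not of images), and `fp_after_triage`, the false
#' positives that background-subtraction triage failed to flag.
#'
#' @param trial_id Trial identifier.
#' @param true_positive,false_positive,false_negative Non-negative counts.
#' @param fp_after_triage Count `<= false_positive` (`NA` when triage was not
#'   available, e.g. for a unit without on-board image processing).
#' @return One-row data.frame of class `confusion_counts`.
#' @export
confusion_counts <- function(trial_id = "trial", true_positive = 0,
                             false_positive = 0, false_negative = 0,
                             fp_after_triage = NA_integer_) {
  stopifnot(true_positive >= 0, false_positive >= 0, false_negative >= 0)
  if (!is.na(fp_after_triage) &&
      (fp_after_triage < 0 || fp_after_triage > false_positive))
    stop("fp_after_triage must lie in [0, false_positive]")
  structure(data.frame(trial_id = trial_id,
                       true_positive = true_positive,
                       false_positive = false_positive,
                       false_negative = false_negative,
                       fp_after_triage = fp_after_triage),
            class = c("confusion_counts", "data.frame"))
}

#' Match capture records against ground truth
#'
#' Scores a trial the way reference video review would: a motion capture is a
#' true positive when its timestamp falls within `window` seconds of a
#' ground-truth event during which the target was inside the camera field of
#' view, i.e. the capture time overlaps `[t_start - window, t_end + window]`
#' of an in-FOV event; otherwise it is a false positive (typically a target
#' inside the PIR detection zone but outside the camera field of view, or no
#' target near at all). A false negative is an in-FOV event overlapped by no
#' motion capture. Counting is per image for TP/FP (several closely spaced
#' captures of one long visit are all true positives) and per event for FN.
#' `fp_after_triage` counts the false positives whose triage verdict is
#' `"true-capture"`, i.e. the blanks that background subtraction failed to
#' flag. For reporting, each true-positive capture is also allocated to the
#' earliest overlapping in-FOV event (attribute `"matching"`).
#'
#' @param captures data.frame of capture records (needs `t`, `source` and,
#'   for `fp_after_triage`, `triage`), e.g. `run_trap(...)$captures`.
#' @param truth A [make_ground_truth()] log (or data.frame with `t_start`,
#'   `t_end`, `in_camera_fov`).
#' @param window Matching half-window in seconds (> 0); the default equals
#'   the enforced 5 s capture spacing, which gives a clear separation of
#'   images for unambiguous allocation to events.
#' @param trial_id Identifier for the returned counts.
#' @return A [confusion_counts()] row, with a `"matching"` attribute
#'   (data.frame: capture `t`, allocated event index or `NA`).
#' @export
match_captures <- function(captures, truth, window = 5, trial_id = "trial") {
  if (window <= 0) stop("window must be positive")
  motion <- captures[captures$source == "motion", , drop = FALSE]
  fov <- truth[truth$in_camera_fov, , drop = FALSE]
  alloc <- rep(NA_integer_, nrow(motion))
  for (i in seq_len(nrow(motion))) {
    t <- motion$t[i]
    hit <- which(t >= fov$t_start - window & t <= fov$t_end + window)
    if (length(hit)) alloc[i] <- hit[1]  # earliest-starting overlapping event
  }
  tp <- sum(!is.na(alloc))
  fp <- sum(is.na(alloc))
  covered <- logical(nrow(fov))
  for (j in seq_len(nrow(fov)))
    covered[j] <- any(motion$t >= fov$t_start[j] - window &
                      motion$t <= fov$t_end[j] + window)
  fn <- sum(!covered)
  fp_at <- if ("triage" %in% names(motion))
    sum(is.na(alloc) & motion$triage == "true-capture") else NA_integer_
  out <- confusion_counts(trial_id, tp, fp, fn, fp_at)
  attr(out, "matching") <- data.frame(t = motion$t, event = alloc)
  out
}

#' Aggregate confusion counts across trials
#'
#' Field-wise sums, the totals row of a multi-day trial table. Accepts a list
#' of [confusion_counts()] rows or a data.frame with the count columns (extra
#' columns such as a day number are ignored). `fp_after_triage` sums over
#' trials where it applies and stays `NA` when it applied to none.
#'
#' @param per_trial List of [confusion_counts()] or a data.frame.
#' @param trial_id Identifier for the totals row.
#' @return A [confusion_counts()] row of totals.
#' @export
aggregate_counts <- function(per_trial, trial_id = "total") {
  df <- if (is.data.frame(per_trial)) per_trial else do.call(rbind, per_trial)
  if (is.null(df) || !nrow(df))
    return(confusion_counts(trial_id, 0, 0, 0, NA_integer_))
  if (!"fp_after_triage" %in% names(df)) df$fp_after_triage <- NA_integer_
  s <- function(x) if (all(is.na(x))) NA_integer_ else sum(x, na.rm = TRUE)
  confusion_counts(trial_id,
                   sum(df$true_positive), sum(df$false_positive),
                   sum(df$false_negative), s(df$fp_after_triage))
}

#' Read and write ground-truth logs as CSV
#'
#' Columns: `t_start`, `t_end`, `track_id`, `in_pir_zone`, `in_camera_fov`.
#'
#' @param truth A [make_ground_truth()] log.
#' @param path CSV path.
#' @return `write_truth_csv` returns `path` invisibly; `read_truth_csv` a
#'   `ground_truth_log` data.frame.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("ground_truth_log", "data.frame")
  df
}

#' Read a captures catalog CSV
#'
#' Reads a `captures.csv` written by [run_trap()] / [append_summary()] back
#' into a capture-record data.frame usable by [match_captures()]; the `t`
#' column (seconds) is reconstructed from the ISO timestamps relative to the
#' earliest row when absent.
#'
#' @param path CSV path.
#' @param trial_start Optional `POSIXct`; defaults to the earliest timestamp.
#' @return data.frame of capture records.
#' @export
read_captures_csv <- function(path, trial_start = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"t" %in% names(df) && "timestamp" %in% names(df)) {
    ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    t0 <- if (is.null(trial_start)) min(ts) else trial_start
    df$t <- as.numeric(ts) - as.numeric(t0)
  }
  if ("classification" %in% names(df) && !"triage" %in% names(df))
    df$triage <- df$classification
  df
}

#' Per-day trial counts from a three-day roof-top field trial
#'
#' Loads the bundled per-day detection counts recorded when a prototype
#' dual-sensor trap and a commercial reference unit were deployed side by
#' side for three days over a baited 6 m x 8 m roof-top arena visited by
#' gulls and pigeons, with simultaneous video as ground truth. Columns:
#' `unit` (`"prototype"` / `"commercial"`), `day`, `true_positive`,
#' `false_positive`, `false_negative` and `fp_after_triage` (false positives
#' remaining after on-board background subtraction; `NA` for the commercial
#' unit, which has no such processing).
#'
#' @return data.frame of per-unit, per-day counts.
#' @export
rooftop_trial_counts <- function() {
  utils::read.csv(system.file("extdata", "rooftop_trial_daily_counts.csv",
                              package = "trapsim"))
}
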