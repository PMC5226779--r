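#' Region of interest
#'
#' A sub-rectangle of the frame to which difference analysis is restricted,
#' e.g. a nest or burrow entrance, or to exclude moving vegetation elsewhere
#' in the scene. Coordinates are 0-based pixel indices and the rectangle is
#' half-open: a pixel (x, y) is inside iff `x0 <= x < x1` and `y0 <= y < y1`.
#' `NULL` in place of an ROI means the whole frame.
#'
#' @param x0,y0 Top-left corner (inclusive).
#' @param x1,y1 Bottom-right corner (exclusive).
#' @return An object of class `region_of_interest`.
#' @export
region_of_interest <- function(x0, y0, x1, y1) {
  stopifnot(x0 >= 0, y0 >= 0, x0 < x1, y0 < y1)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "region_of_interest")
}

validate_roi <- function(roi, frame) {
  if (is.null(roi))
    roi <- region_of_interest(0, 0, frame_width(frame), frame_height(frame))
  if (roi$x1 > frame_width(frame) || roi$y1 > frame_height(frame))
    stop("region of interest exceeds frame dimensions")
  roi
}

roi_area <- function(roi) (roi$x1 - roi$x0) * (roi$y1 - roi$y0)

#' Select the triage background frame
#'
#' The background for triaging a motion-activated capture is the most recent
#' time-lapse frame: the time-lapse frame with the greatest timestamp `<= t`
#' (a frame taken exactly at `t` qualifies). With no prior time-lapse frame
#' there is no background and the caller must mark triage as pending.
#'
#' @param history List of [trap_frame()] objects of any kind.
#' @param t Query time, seconds.
#' @return A [trap_frame()], or `NULL` when no time-lapse frame precedes `t`.
#' @export
select_background <- function(history, t) {
  best <- NULL
  for (f in history) {
    if (f$kind != "timelapse" || f$t > t) next
    if (is.null(best) || f$t > best$t) best <- f
  }
  best
}

#' Background subtraction within a region of interest
#'
#' Compares a motion-activated frame against a time-lapse background frame:
#' pixels inside the ROI whose absolute intensity difference exceeds
#' `pixel_delta` form the binary difference mask, and their count is the
#' difference count on which classification is based. Animals present in the
#' motion frame but not the background appear as clusters of set
#' ("difference") pixels.
#'
#' @param motion Motion-activated [trap_frame()].
#' @param background Time-lapse [trap_frame()] of identical dimensions.
#' @param roi A [region_of_interest()] or `NULL` for the whole frame.
#' @param pixel_delta Per-pixel intensity delta (difference must strictly
#'   exceed it).
#' @return An object of class `difference_result`: `diff_count`, `diff_mask`
#'   (logical matrix over the ROI, rows = y), `pixel_delta`, `roi`.
#' @export
background_subtract <- function(motion, background, roi = NULL, pixel_delta) {
  if (frame_width(motion) != frame_width(background) ||
      frame_height(motion) != frame_height(background))
    stop("motion and background frames must share dimensions")
  stopifnot(pixel_delta >= 0)
  roi <- validate_roi(roi, motion)
  rows <- (roi$y0 + 1L):roi$y1
  cols <- (roi$x0 + 1L):roi$x1
  mask <- abs(motion$pixels[rows, cols, drop = FALSE] -
              background$pixels[rows, cols, drop = FALSE]) > pixel_delta
  structure(list(diff_count = sum(mask), diff_mask = mask,
                 pixel_delta = pixel_delta, roi = roi),
            class = "difference_result")
}

#' Classify a capture from its difference count
#'
#' A motion-activated image whose difference count falls strictly below the
#' user-specified threshold is similar to the recent background and therefore
#' classified as a false positive; otherwise it is a true capture. A threshold
#' of 0 accepts everything.
#'
#' @param result A [background_subtract()] result.
#' @param count_threshold Difference-pixel count threshold (>= 0).
#' @return `"false-positive"` or `"true-capture"`.
#' @export
classify_capture <- function(result, count_threshold) {
  stopifnot(count_threshold >= 0)
  if (result$diff_count < count_threshold) "false-positive" else "true-capture"
}

#' Apply the false-positive policy to a capture on disk
#'
#' Images identified as false positives can be deleted to save storage, or
#' kept and marked for further analysis. Under `policy = "delete"` a
#' false-positive image file is removed (the log line survives); under
#' `policy = "flag"` the file is kept and the verdict written into its
#' metadata. True captures are kept under either policy, their metadata
#' updated with the verdict and difference count.
#'
#' @param record One-row data.frame with at least `filename` and `path`
#'   columns (as produced by [triage_folder()] / [run_trap()] output).
#' @param classification `"false-positive"` or `"true-capture"`.
#' @param policy `"delete"` or `"flag"`.
#' @param diff_count Difference count to record in the metadata.
#' @return The updated record row, with `triage` and `file_kept` set; the
#'   file is removed from disk when deleted.
#' @export
apply_policy <- function(record, classification, policy = c("flag", "delete"),
                         diff_count = NA) {
  policy <- match.arg(policy)
  record$triage <- classification
  if (policy == "delete" && classification == "false-positive") {
    if (!is.na(record$path) && file.exists(record$path))
      file.remove(record$path)
    record$file_kept <- FALSE
  } else {
    record$file_kept <- TRUE
    if (!is.na(record$path) && file.exists(record$path)) {
      tags <- list(triage_verdict = classification)
      if (!is.na(diff_count)) tags$diff_count <- diff_count
      embed_metadata(record$path, tags, merge = TRUE)
    }
  }
  record
}

#' Stand-alone triage of image folders
#'
#' Runs the confirmatory-sensing triage over folders of already-collected
#' images: every motion-activated image is compared (within the ROI) against
#' the most recent time-lapse image, the difference count thresholded, and the
#' false-positive policy applied. Capture timestamps are parsed from the
#' [compose_filename()] pattern, falling back to file modification times.
#'
#' @param motion_dir Folder of motion-activated images (JPEG/PNG).
#' @param timelapse_dir Folder of time-lapse images.
#' @param roi A [region_of_interest()] or `NULL`.
#' @param pixel_delta Per-pixel intensity delta.
#' @param count_threshold Difference-count threshold.
#' @param policy `"flag"` or `"delete"`.
#' @param save_masks If `TRUE`, the binary difference mask of each comparison
#'   is written next to the report as `<image>_mask.png`.
#' @param mask_dir Folder for masks (defaults to `motion_dir`).
#' @return data.frame report: `filename`, `background_filename`, `diff_count`,
#'   `classification` (with `"pending"` for motion images that precede every
#'   time-lapse image).
#' @export
triage_folder <- function(motion_dir, timelapse_dir, roi = NULL,
                          pixel_delta = 12, count_threshold = 50,
                          policy = c("flag", "delete"), save_masks = FALSE,
                          mask_dir = motion_dir) {
  policy <- match.arg(policy)
  list_imgs <- function(d) list.files(d, "\\.(jpg|jpeg|png)$",
                                      ignore.case = TRUE, full.names = TRUE)
  file_time <- function(p, kind) {
    parsed <- parse_filename(basename(p))
    parsed$t %||% as.numeric(file.mtime(p))
  }
  tl_paths <- list_imgs(timelapse_dir)
  history <- lapply(tl_paths, function(p)
    read_frame(p, t = file_time(p), kind = "timelapse"))
  rows <- list()
  for (p in list_imgs(motion_dir)) {
    t <- file_time(p)
    motion <- read_frame(p, t = t, kind = "motion")
    bg <- select_background(history, t)
    if (is.null(bg)) {
      rows[[length(rows) + 1L]] <- data.frame(
        filename = basename(p), background_filename = NA_character_,
        diff_count = NA_integer_, classification = "pending")
      next
    }
    res <- background_subtract(motion, bg, roi, pixel_delta)
    cls <- classify_capture(res, count_threshold)
    rec <- data.frame(filename = basename(p), path = p, triage = NA,
                      file_kept = NA)
    apply_policy(rec, cls, policy, diff_count = res$diff_count)
    if (save_masks && cls == "true-capture") {
      mp <- file.path(mask_dir, paste0(tools::file_path_sans_ext(basename(p)),
                                       "_mask.png"))
      png::writePNG(res$diff_mask * 1, mp)
    }
    bg_name <- tl_paths[vapply(history, function(f) identical(f$t, bg$t),
                               logical(1))][1]
    rows[[length(rows) + 1L]] <- data.frame(
      filename = basename(p), background_filename = basename(bg_name),
      diff_count = res$diff_count, classification = cls)
  }
  if (!length(rows))
    return(data.frame(filename = character(), background_filename = character(),
                      diff_count = integer(), classification = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
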