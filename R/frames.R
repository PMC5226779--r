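#' Frame objects
#'
#' A frame is a grayscale pixel grid (integer intensities 0-255, stored as a
#' `height` x `width` matrix, row-major, 0-based pixel coordinates in the
#' API), timestamped and tagged as either a scheduled time-lapse capture or a
#' motion-activated capture.
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\].
#' @param t Capture time, seconds since trial start.
#' @param kind `"timelapse"` or `"motion"`.
#' @return An object of class `trap_frame`.
#' @export
trap_frame <- function(pixels, t, kind = c("timelapse", "motion")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(pixels), nrow(pixels) > 0, ncol(pixels) > 0)
  if (any(pixels < 0 | pixels > 255)) stop("intensities must lie in [0, 255]")
  structure(list(pixels = pixels, t = t, kind = kind), class = "trap_frame")
}

#' @export
print.trap_frame <- function(x, ...) {
  cat(sprintf("<trap_frame %dx%d px, t = %.2f s, kind = %s>\n",
              ncol(x$pixels), nrow(x$pixels), x$t, x$kind))
  invisible(x)
}

frame_width <- function(frame) ncol(frame$pixels)
frame_height <- function(frame) nrow(frame$pixels)

#' Write and read frames as image files
#'
#' PNG is lossless (frames round-trip exactly); JPEG uses quality 0.95 and is
#' the format that carries embedded EXIF metadata. `read_frame` infers the
#' capture kind and timestamp from a filename following the
#' [compose_filename()] pattern when possible; otherwise they must be given.
#'
#' @param frame A [trap_frame()].
#' @param path Output path; format chosen by extension (`.png`, `.jpg`,
#'   `.jpeg`).
#' @return `write_frame` returns `path` invisibly; `read_frame` a
#'   [trap_frame()].
#' @export
write_frame <- function(frame, path) {
  img <- frame$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("jpg", "jpeg")) {
    jpeg::writeJPEG(img, path, quality = 0.95)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' @rdname write_frame
#' @param t,kind Overrides when the filename does not encode them.
#' @export
read_frame <- function(path, t = NULL, kind = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("jpg", "jpeg")) jpeg::readJPEG(path)
         else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]  # take one channel of RGB
  parsed <- parse_filename(basename(path))
  if (is.null(kind)) kind <- parsed$source %||% "motion"
  if (is.null(t)) t <- parsed$t %||% 0
  trap_frame(round(img * 255), t = t, kind = kind)
}

## parse the compose_filename() pattern; returns NULL fields when it does not
## match
parse_filename <- function(name) {
  m <- regmatches(name, regexec(
    "^(\\d{8}T\\d{6})(?:_([A-Za-z0-9-]+))?_(M|T)(?:_(\\d+))?\\.(jpg|jpeg|png)$",
    name))[[1]]
  if (!length(m)) return(list(t = NULL, source = NULL, label = NULL))
  ts <- as.POSIXct(m[2], format = "%Y%m%dT%H%M%S", tz = "UTC")
  list(t = as.numeric(ts), source = if (m[4] == "M") "motion" else "timelapse",
       label = if (nzchar(m[3])) m[3] else "")
}
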