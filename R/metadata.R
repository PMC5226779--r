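#' Metadata tag registry
#'
#' The documented set of per-image metadata keys. Any key in this registry,
#' plus arbitrary auxiliary sensor readings under an `aux_` prefix (e.g.
#' `aux_temperature`), may be embedded in an image and recovered losslessly.
#'
#' @return Character vector of registry keys.
#' @export
metadata_registry <- function() {
  c("site_label", "trap_id", "custom_label", "trigger_source",
    "radar_confirmed", "triage_verdict", "diff_count", "timestamp",
    "latitude", "longitude")
}

validate_tags <- function(tags) {
  if (!length(tags)) return(invisible(tags))
  keys <- names(tags)
  if (is.null(keys) || any(!nzchar(keys)))
    stop("metadata tags must be a named list")
  bad <- keys[!(keys %in% metadata_registry() | startsWith(keys, "aux_"))]
  if (length(bad))
    stop("unknown metadata tag(s): ", paste(bad, collapse = ", "))
  ok <- vapply(tags, function(v)
    length(v) == 1 && (is.character(v) || is.numeric(v) || is.logical(v)),
    logical(1))
  if (!all(ok))
    stop("tag values must be scalar text, number or flag: ",
         paste(keys[!ok], collapse = ", "))
  invisible(tags)
}

#' Compose a capture filename
#'
#' Filenames are self-describing: an ISO-style compact timestamp, an optional
#' custom label (e.g. a study-site code), a trigger-source letter (`M` for
#' motion-activated, `T` for time-lapse) and, when several captures share the
#' same second, a collision counter. Pattern:
#' `YYYYMMDDThhmmss[_LABEL]_{M|T}[_k].jpg`.
#'
#' @param time Capture time, a `POSIXct` (or seconds since epoch, UTC).
#' @param custom_label Optional label; letters, digits and hyphens only.
#' @param source `"motion"` or `"timelapse"`.
#' @param existing Character vector of filenames already taken (collision
#'   counter is chosen against these).
#' @param ext File extension without the dot.
#' @return A filename string.
#' @export
compose_filename <- function(time, custom_label = "",
                             source = c("motion", "timelapse"),
                             existing = character(), ext = "jpg") {
  source <- match.arg(source)
  if (!grepl("^[A-Za-z0-9-]*$", custom_label))
    stop("custom_label may contain only letters, digits and hyphens")
  if (is.numeric(time))
    time <- as.POSIXct(time, origin = "1970-01-01", tz = "UTC")
  stamp <- format(time, "%Y%m%dT%H%M%S", tz = "UTC")
  base <- paste0(stamp,
                 if (nzchar(custom_label)) paste0("_", custom_label) else "",
                 "_", if (source == "motion") "M" else "T")
  name <- paste0(base, ".", ext)
  k <- 0L
  while (name %in% existing) {
    k <- k + 1L
    name <- paste0(base, "_", k, ".", ext)
  }
  name
}

#' Embed metadata tags in an image file
#'
#' For JPEG files the tags are written as EXIF: the mapping is serialised to
#' JSON in the ImageDescription slot (so numbers and flags survive as such)
#' and any `timestamp` tag is mirrored to the standard DateTime slot, making
#' every image self-describing to ordinary image-management software. Pixel
#' content is unchanged. PNG has no EXIF container, so tags go to a JSON
#' sidecar file `<image>.json` next to the image (documented fallback).
#'
#' @param path Image path (`.jpg`/`.jpeg`/`.png`).
#' @param tags Named list of registry tags (see [metadata_registry()]).
#' @param merge If `TRUE`, tags already present in the file are kept and the
#'   new ones merged over them.
#' @return `path`, invisibly.
#' @export
embed_metadata <- function(path, tags, merge = FALSE) {
  validate_tags(tags)
  if (!file.exists(path)) stop("no such file: ", path)
  if (merge) {
    old <- extract_metadata(path)
    tags <- utils::modifyList(old, tags)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    dt <- NULL
    if (!is.null(tags$timestamp)) {
      ts <- tags$timestamp
      if (is.numeric(ts)) ts <- as.POSIXct(ts, origin = "1970-01-01", tz = "UTC")
      if (inherits(ts, "POSIXct")) {
        dt <- format(ts, "%Y:%m:%d %H:%M:%S", tz = "UTC")
        tags$timestamp <- format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      } else {
        dt <- gsub("-", ":", sub("[TZ]", " ", as.character(ts)))
        dt <- trimws(gsub("Z", "", dt, fixed = TRUE))
      }
    }
    write_jpeg_exif(path,
                    description = jsonlite::toJSON(tags, auto_unbox = TRUE),
                    datetime = dt)
  } else if (ext == "png") {
    jsonlite::write_json(tags, sidecar_path(path), auto_unbox = TRUE)
  } else stop("unsupported format for metadata embedding: ", ext)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Extract metadata tags from an image file
#'
#' Returns every registry tag present in the image (JPEG EXIF or PNG sidecar);
#' missing tags are omitted, never defaulted. A file carrying no tags yields
#' an empty list.
#'
#' @param path Image path.
#' @return Named list of tags.
#' @export
extract_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    ex <- read_jpeg_exif(path)
    tags <- if (is.null(ex$description)) list() else
      jsonlite::fromJSON(ex$description, simplifyVector = TRUE)
    if (is.null(tags$timestamp) && !is.null(ex$datetime)) {
      tags$timestamp <- format(
        as.POSIXct(ex$datetime, format = "%Y:%m:%d %H:%M:%S", tz = "UTC"),
        "%Y-%m-%dT%H:%M:%SZ")
    }
    tags
  } else if (ext == "png") {
    sp <- sidecar_path(path)
    if (!file.exists(sp)) return(list())
    jsonlite::fromJSON(sp, simplifyVector = TRUE)
  } else stop("unsupported format for metadata extraction: ", ext)
}

#' Append a capture record to a CSV catalog
#'
#' The per-capture summary that spares a return visit to every image: one row
#' per capture with its filename, ISO-8601 timestamp, trigger source, radar
#' cross-reference, triage outcome and the deployment's custom label. The
#' header is written once; rows are append-only, in call order.
#'
#' @param record Named list or one-row data.frame with any of the catalog
#'   fields (`filename`, `timestamp`, `source`, `radar_confirmed`,
#'   `diff_count`, `classification`, `custom_label`); missing fields become
#'   `NA`.
#' @param catalog Path of the CSV catalog file.
#' @return `catalog`, invisibly.
#' @export
append_summary <- function(record, catalog) {
  cols <- c("filename", "timestamp", "source", "radar_confirmed",
            "diff_count", "classification", "custom_label")
  record <- as.list(record)
  row <- as.data.frame(lapply(cols, function(c) {
    v <- record[[c]]
    if (is.null(v) || length(v) != 1) NA else v
  }), col.names = cols)
  new <- !file.exists(catalog) || file.size(catalog) == 0
  utils::write.table(row, catalog, sep = ",", row.names = FALSE,
                     col.names = new, append = !new, qmethod = "double")
  invisible(catalog)
}

#' Catalog a folder of images from their embedded metadata
#'
#' Reads the metadata of every image in a folder into one data.frame, one row
#' per image, optionally filtered on a tag value (for example
#' `trigger_source=timelapse` to separate scheduled from motion-activated
#' captures).
#'
#' @param dir Folder of images.
#' @param filter Optional `"key=value"` string; only images whose tag `key`
#'   equals `value` (as text) are returned.
#' @return data.frame with a `filename` column plus one column per tag seen.
#' @export
catalog_images <- function(dir, filter = NULL) {
  paths <- list.files(dir, "\\.(jpg|jpeg|png)$", ignore.case = TRUE,
                      full.names = TRUE)
  rows <- lapply(paths, function(p) {
    tags <- extract_metadata(p)
    c(list(filename = basename(p)), tags)
  })
  keys <- unique(unlist(lapply(rows, names)))
  df <- as.data.frame(lapply(keys, function(k)
    sapply(rows, function(r) if (is.null(r[[k]])) NA else r[[k]])),
    col.names = keys, stringsAsFactors = FALSE)
  if (!is.null(filter)) {
    kv <- strsplit(filter, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("filter must be key=value")
    if (!kv[1] %in% names(df)) return(df[0, , drop = FALSE])
    df <- df[!is.na(df[[kv[1]]]) & as.character(df[[kv[1]]]) == kv[2], ,
             drop = FALSE]
  }
  rownames(df) <- NULL
  df
}
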