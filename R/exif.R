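## Minimal EXIF APP1 reader/writer.
##
## Tags are carried in two IFD0 slots of a little-endian TIFF structure:
## ImageDescription (0x010E) holds the full tag mapping serialised as JSON,
## and DateTime (0x0132) holds the capture timestamp in the standard
## "YYYY:MM:DD HH:MM:SS" form. Both slots are plain ASCII, so the tags are
## readable by ordinary image-management software. Writing only inserts or
## replaces the APP1 segment; the entropy-coded image data is untouched, so
## pixel content is bit-identical before and after embedding.

TAG_IMAGE_DESCRIPTION <- 0x010EL
TAG_DATETIME <- 0x0132L

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

## one ASCII IFD entry; value longer than 4 bytes goes to the data area
ifd_ascii_entry <- function(tag, value, data_offset) {
  bytes <- c(charToRaw(value), as.raw(0))
  n <- length(bytes)
  if (n <= 4) {
    entry <- c(u16le(tag), u16le(2), u32le(n), bytes, rep(as.raw(0), 4 - n))
    list(entry = entry, data = raw(0), advance = 0L)
  } else {
    entry <- c(u16le(tag), u16le(2), u32le(n), u32le(data_offset))
    list(entry = entry, data = bytes, advance = n)
  }
}

## build the APP1 payload ("Exif\0\0" + TIFF) for the given ASCII slots
exif_payload <- function(description = NULL, datetime = NULL) {
  slots <- list()
  if (!is.null(description))
    slots[[length(slots) + 1L]] <- list(tag = TAG_IMAGE_DESCRIPTION,
                                        value = description)
  if (!is.null(datetime))
    slots[[length(slots) + 1L]] <- list(tag = TAG_DATETIME, value = datetime)
  slots <- slots[order(vapply(slots, `[[`, integer(1), "tag"))]
  n <- length(slots)
  data_offset <- 8L + 2L + 12L * n + 4L  # first free byte after IFD0
  entries <- raw(0); data <- raw(0)
  for (s in slots) {
    e <- ifd_ascii_entry(s$tag, s$value, data_offset)
    entries <- c(entries, e$entry)
    data <- c(data, e$data)
    data_offset <- data_offset + e$advance
  }
  tiff <- c(charToRaw("II"), u16le(42), u32le(8),  # header, IFD0 at offset 8
            u16le(n), entries, u32le(0), data)
  c(charToRaw("Exif"), as.raw(c(0, 0)), tiff)
}

## walk JPEG marker segments up to SOS; returns data.frame(marker, start, end)
## with 1-based byte positions spanning each segment including its marker
jpeg_segments <- function(bytes) {
  if (length(bytes) < 4 || bytes[1] != as.raw(0xFF) || bytes[2] != as.raw(0xD8))
    stop("not a JPEG file")
  segs <- list(); pos <- 3L
  while (pos + 3L <= length(bytes)) {
    if (bytes[pos] != as.raw(0xFF)) stop("corrupt JPEG segment structure")
    marker <- as.integer(bytes[pos + 1L])
    if (marker == 0xDA) break  # start of scan: entropy-coded data follows
    len <- as.integer(bytes[pos + 2L]) * 256L + as.integer(bytes[pos + 3L])
    segs[[length(segs) + 1L]] <- data.frame(marker = marker, start = pos,
                                            end = pos + 1L + len)
    pos <- pos + 2L + len
  }
  if (length(segs)) do.call(rbind, segs) else
    data.frame(marker = integer(), start = integer(), end = integer())
}

is_exif_app1 <- function(bytes, seg) {
  seg$marker == 0xE1 && seg$end - seg$start >= 9 &&
    identical(bytes[(seg$start + 4L):(seg$start + 9L)],
              c(charToRaw("Exif"), as.raw(c(0, 0))))
}

## insert (or replace) the Exif APP1 segment in a JPEG file
write_jpeg_exif <- function(path, description = NULL, datetime = NULL) {
  bytes <- readBin(path, "raw", file.size(path))
  segs <- jpeg_segments(bytes)
  payload <- exif_payload(description, datetime)
  app1 <- c(as.raw(c(0xFF, 0xE1)), as.raw(c((length(payload) + 2) %/% 256,
                                            (length(payload) + 2) %% 256)),
            payload)
  drop <- rep(FALSE, length(bytes))
  for (i in seq_len(nrow(segs)))
    if (is_exif_app1(bytes, segs[i, ])) drop[segs$start[i]:segs$end[i]] <- TRUE
  bytes <- bytes[!drop]
  # place APP1 after an initial APP0 (JFIF) segment if one exists
  segs <- jpeg_segments(bytes)
  at <- if (nrow(segs) && segs$marker[1] == 0xE0) segs$end[1] else 2L
  writeBin(c(bytes[1:at], app1, bytes[(at + 1L):length(bytes)]), path)
  invisible(path)
}

read_uint <- function(bytes, pos, n, little) {
  v <- as.integer(bytes[pos:(pos + n - 1L)])
  if (little) sum(v * 256^(seq_len(n) - 1L)) else sum(v * 256^(rev(seq_len(n)) - 1L))
}

## read the two ASCII slots back from a JPEG's Exif APP1 (if any)
read_jpeg_exif <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  segs <- jpeg_segments(bytes)
  out <- list(description = NULL, datetime = NULL)
  for (i in seq_len(nrow(segs))) {
    if (!is_exif_app1(bytes, segs[i, ])) next
    tiff0 <- segs$start[i] + 10L  # first byte of the TIFF header
    little <- identical(bytes[tiff0:(tiff0 + 1L)], charToRaw("II"))
    ifd <- tiff0 + read_uint(bytes, tiff0 + 4L, 4L, little)
    count <- read_uint(bytes, ifd, 2L, little)
    for (k in seq_len(count)) {
      e <- ifd + 2L + (k - 1L) * 12L
      tag <- read_uint(bytes, e, 2L, little)
      type <- read_uint(bytes, e + 2L, 2L, little)
      n <- read_uint(bytes, e + 4L, 4L, little)
      if (type != 2L || !(tag %in% c(TAG_IMAGE_DESCRIPTION, TAG_DATETIME)))
        next
      at <- if (n <= 4L) e + 8L else tiff0 + read_uint(bytes, e + 8L, 4L, little)
      val <- rawToChar(bytes[at:(at + n - 2L)])  # strip trailing NUL
      if (tag == TAG_IMAGE_DESCRIPTION) out$description <- val
      if (tag == TAG_DATETIME) out$datetime <- val
    }
    break
  }
  out
}
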