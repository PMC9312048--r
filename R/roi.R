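# ImageJ ROI interoperability. The .roi format is a big-endian binary
# record starting with the magic bytes "Iout": a 64-byte header (version,
# type, integer pixel bounds, coordinate count) followed, for polygon-family
# ROIs, by n 16-bit x offsets then n 16-bit y offsets relative to the
# bounding box; straight-line ROIs store their endpoints as floats in the
# header. RoiSet.zip is an ordinary ZIP archive of .roi members. Only the
# ROI types the measurement workflow needs (polygon, freehand, line) are
# supported. Because no zip binary can be assumed, set writing uses a
# minimal store-only (uncompressed) ZIP encoder.

ROI_TYPES <- c(polygon = 0L, line = 3L, freehand = 7L)
ROI_VERSION <- 227L

#' Read an ImageJ .roi file
#'
#' @param path path to a .roi file.
#' @return List (class `imagej_roi`) with `name`, `type` (`"polygon"`,
#'   `"freehand"` or `"line"`), and `coords` (n x 2 integer matrix of pixel
#'   x, y; two rows for a line).
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) tdm_data_error(paste("file not found:", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  parse_roi(raw, name = sub("\\.roi$", "", basename(path), ignore.case = TRUE))
}

parse_roi <- function(raw, name = "roi") {
  if (length(raw) < 64L) tdm_data_error("truncated ROI: shorter than the 64-byte header")
  if (rawToChar(raw[1:4]) != "Iout") tdm_data_error("not an ImageJ ROI: bad magic bytes")
  be_short <- function(off, n = 1L) {
    readBin(raw[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L,
            endian = "big", signed = TRUE)
  }
  type_byte <- as.integer(raw[7L])
  type <- names(ROI_TYPES)[match(type_byte, ROI_TYPES)]
  if (is.na(type)) {
    tdm_data_error(sprintf("unsupported ROI type byte %d (need polygon=0, line=3 or freehand=7)",
                           type_byte))
  }
  top <- be_short(8L); left <- be_short(10L)
  if (type == "line") {
    xy <- readBin(raw[19:34], "numeric", n = 4L, size = 4L, endian = "big")
    coords <- matrix(round(xy), 2L, 2L, byrow = TRUE)
  } else {
    n <- be_short(16L)
    if (n < 1L) tdm_data_error("polygon ROI with no coordinates")
    if (length(raw) < 64L + 4L * n) tdm_data_error("truncated ROI coordinate block")
    xs <- be_short(64L, n); ys <- be_short(64L + 2L * n, n)
    coords <- cbind(xs + left, ys + top)
  }
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(list(name = name, type = type, coords = coords),
            class = "imagej_roi")
}

#' Write an ImageJ .roi file
#'
#' @param roi an `imagej_roi` (see [read_roi()]) or a list with `type` and
#'   integer `coords`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path) {
  writeBin(encode_roi(roi), path)
  invisible(path)
}

encode_roi <- function(roi) {
  if (is.null(roi$type) || !roi$type %in% names(ROI_TYPES)) {
    tdm_config_error("roi$type must be one of polygon, freehand, line")
  }
  coords <- round(roi$coords)
  if (!is.matrix(coords) || ncol(coords) != 2L) {
    tdm_config_error("roi$coords must be an n x 2 matrix")
  }
  if (roi$type == "line" && nrow(coords) != 2L) {
    tdm_config_error("a line ROI needs exactly 2 points")
  }
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  wshort <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "big")
  writeChar("Iout", con, eos = NULL)
  wshort(ROI_VERSION)
  writeBin(as.raw(c(ROI_TYPES[[roi$type]], 0L)), con)
  top <- min(coords[, 2]); left <- min(coords[, 1])
  bottom <- max(coords[, 2]); right <- max(coords[, 1])
  wshort(c(top, left, bottom, right))
  n <- if (roi$type == "line") 0L else nrow(coords)
  wshort(n)
  if (roi$type == "line") {
    writeBin(as.numeric(t(coords)), con, size = 4L, endian = "big")
  } else {
    writeBin(numeric(4L), con, size = 4L, endian = "big")  # x1..y2 unused
  }
  writeBin(raw(64L - 34L), con)  # stroke/fill/options/header2: zeroed
  if (n > 0L) wshort(c(coords[, 1] - left, coords[, 2] - top))
  rawConnectionValue(con)
}

#' Read every ROI in an ImageJ RoiSet.zip
#'
#' @param path path to a RoiSet.zip archive.
#' @return Named list of `imagej_roi` objects.
#' @export
read_roi_zip <- function(path) {
  if (!file.exists(path)) tdm_data_error(paste("file not found:", path))
  exdir <- tempfile("roiset")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  files <- files[grepl("\\.roi$", files, ignore.case = TRUE)]
  if (!length(files)) tdm_data_error("archive contains no .roi members")
  rois <- lapply(files, read_roi)
  stats::setNames(rois, vapply(rois, `[[`, "", "name"))
}

#' Write ROIs as an ImageJ RoiSet.zip
#'
#' Encodes each ROI and stores it (uncompressed) in a ZIP archive that
#' ImageJ's ROI Manager can open.
#'
#' @param rois list of `imagej_roi` objects (named, or with `name` fields).
#' @param path output .zip path.
#' @return `path`, invisibly.
#' @export
write_roi_zip <- function(rois, path) {
  if (!is.list(rois) || !length(rois)) tdm_config_error("rois must be a nonempty list")
  names(rois) <- vapply(seq_along(rois), function(i) {
    nm <- if (!is.null(rois[[i]]$name)) rois[[i]]$name
          else if (!is.null(names(rois)) && nzchar(names(rois)[i])) names(rois)[i]
          else sprintf("roi_%03d", i)
    nm
  }, "")
  entries <- lapply(rois, encode_roi)
  zip_store(stats::setNames(entries, paste0(names(rois), ".roi")), path)
  invisible(path)
}

# ---- minimal store-only ZIP encoder ---------------------------------------

# 32-bit values are held as doubles (R integers are signed 32-bit); XOR is
# applied to 16-bit halves
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256L)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (c %% 2) xor32(0xEDB88320, c %/% 2) else c %/% 2
        }
        t[i + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- xor32(tab[[bitwXor(as.integer(crc %% 256), b) + 1L]], crc %/% 256)
  }
  0xFFFFFFFF - crc  # final complement
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, floor(x / 256) %% 256, floor(x / 65536) %% 256,
           floor(x / 16777216) %% 256))
}

zip_store <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  pos <- 0
  centrals <- list()
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crc <- crc32(data)
    local_hdr <- c(u32(0x04034b50), u16(20L), u16(0L), u16(0L), u16(0L),
                   u16(0L), u32(crc), u32(length(data)), u32(length(data)),
                   u16(length(name)), u16(0L))
    writeBin(c(local_hdr, name, data), con)
    offsets[i] <- pos
    pos <- pos + length(local_hdr) + length(name) + length(data)
    centrals[[i]] <- c(u32(0x02014b50), u16(20L), u16(20L), u16(0L), u16(0L),
                       u16(0L), u16(0L), u32(crc), u32(length(data)),
                       u32(length(data)), u16(length(name)), u16(0L), u16(0L),
                       u16(0L), u16(0L), u32(0L), u32(offsets[i]), name)
  }
  central <- do.call(c, centrals)
  writeBin(central, con)
  writeBin(c(u32(0x06054b50), u16(0L), u16(0L), u16(length(entries)),
             u16(length(entries)), u32(length(central)), u32(pos), u16(0L)),
           con)
  invisible(path)
}
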