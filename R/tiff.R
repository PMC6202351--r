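# Minimal baseline TIFF I/O for monochrome microscopy images.
#
# Scope: grayscale (one sample per pixel), 8/16-bit unsigned or 32-bit float,
# single- or multi-page, uncompressed, single or multiple strips, II or MM
# byte order on read (II on write). RGB/CMYK and compressed files are
# rejected with informative errors; pixel values pass through bit-exactly.

TIFF_TAGS <- c(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, Photometric = 262L, StripOffsets = 273L,
  SamplesPerPixel = 277L, RowsPerStrip = 278L, StripByteCounts = 279L,
  PlanarConfig = 284L, SampleFormat = 339L
)

.u16 <- function(raw, off, endian) {
  readBin(raw[(off + 1L):(off + 2L)], "integer", size = 2L,
          signed = FALSE, endian = endian)
}

.u32 <- function(raw, off, endian) {
  v <- readBin(raw[(off + 1L):(off + 4L)], "integer", size = 4L,
               endian = endian)
  if (v < 0) v <- v + 2^32
  v
}

# Read one IFD entry value (SHORT/LONG scalars and arrays).
.tiff_entry_values <- function(raw, entry_off, endian) {
  type <- .u16(raw, entry_off + 2L, endian)
  count <- .u32(raw, entry_off + 4L, endian)
  width <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
  if (is.na(width)) return(NULL)
  total <- width * count
  src <- if (total <= 4L) entry_off + 8L else .u32(raw, entry_off + 8L, endian)
  vapply(seq_len(count) - 1L, function(i) {
    if (width == 1L) as.numeric(as.integer(raw[src + i + 1L]))
    else if (width == 2L) as.numeric(.u16(raw, src + i * 2L, endian))
    else .u32(raw, src + i * 4L, endian)
  }, numeric(1))
}

.compression_name <- function(code) {
  switch(as.character(code),
         "5" = "LZW", "8" = "Deflate/ZIP", "32773" = "PackBits",
         "7" = "JPEG", "6" = "JPEG (old)",
         paste0("code ", code))
}

#' Read a grayscale TIFF file
#'
#' Reads a single- or multi-page uncompressed grayscale TIFF (8- or 16-bit
#' unsigned integer, or 32-bit IEEE float) and returns its pages as numeric
#' matrices with pixel values passed through unchanged. RGB/CMYK and
#' compressed files are rejected, mirroring the input contract of the
#' analysis pipeline (monochromatic images that retain original intensities).
#'
#' @param path Path to a TIFF file.
#' @return A list with elements `images` (list of numeric matrices, page
#'   order preserved), `bit_depth` (8, 16 or 32), and `sample_format`
#'   (`"uint"` or `"float"`).
#' @seealso [write_tiff()]
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (too short): ", path)
  order_mark <- rawToChar(raw[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  if (.u16(raw, 2L, endian) != 42L) stop("not a TIFF file (bad magic): ", path)

  images <- list()
  bit_depth <- NULL
  sample_format <- NULL
  ifd_off <- .u32(raw, 4L, endian)
  while (ifd_off != 0) {
    n_entries <- .u16(raw, ifd_off, endian)
    tags <- new.env(parent = emptyenv())
    for (i in seq_len(n_entries)) {
      entry_off <- ifd_off + 2L + (i - 1L) * 12L
      tag <- .u16(raw, entry_off, endian)
      vals <- .tiff_entry_values(raw, entry_off, endian)
      if (!is.null(vals)) assign(as.character(tag), vals, envir = tags)
    }
    g <- function(tag, default = NULL) {
      key <- as.character(TIFF_TAGS[[tag]])
      if (exists(key, envir = tags)) get(key, envir = tags) else default
    }
    spp <- g("SamplesPerPixel", 1)
    photometric <- g("Photometric", 1)
    if (spp != 1 || photometric %in% c(2, 5, 6, 8)) {
      stop("monochromatic input required: ", path,
           " has ", spp, " samples/pixel (photometric ", photometric, ")")
    }
    compression <- g("Compression", 1)
    if (compression != 1) {
      stop("unsupported TIFF compression (", .compression_name(compression),
           ") in ", path, "; only uncompressed grayscale TIFF is supported")
    }
    w <- g("ImageWidth"); h <- g("ImageLength")
    if (is.null(w) || is.null(h)) stop("TIFF missing dimensions: ", path)
    bits <- g("BitsPerSample", 1)
    if (!bits %in% c(8, 16, 32)) {
      stop("unsupported bit depth ", bits, " in ", path, " (need 8, 16 or 32)")
    }
    fmt <- g("SampleFormat", if (bits == 32) 3 else 1)
    offsets <- g("StripOffsets"); counts <- g("StripByteCounts")
    if (is.null(offsets)) stop("TIFF missing strip offsets: ", path)
    if (is.null(counts)) counts <- w * h * bits / 8
    data <- raw(0)
    for (s in seq_along(offsets)) {
      data <- c(data, raw[(offsets[s] + 1L):(offsets[s] + counts[s])])
    }
    n_px <- w * h
    vals <- if (bits == 8) {
      as.numeric(as.integer(data[seq_len(n_px)]))
    } else if (bits == 16) {
      as.numeric(readBin(data, "integer", n = n_px, size = 2L,
                         signed = FALSE, endian = endian))
    } else if (fmt == 3) {
      readBin(data, "double", n = n_px, size = 4L, endian = endian)
    } else {
      v <- readBin(data, "integer", n = n_px, size = 4L, endian = endian)
      ifelse(v < 0, v + 2^32, as.numeric(v))
    }
    images[[length(images) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                            byrow = TRUE)
    bit_depth <- bits
    sample_format <- if (bits == 32 && fmt == 3) "float" else "uint"
    ifd_off <- .u32(raw, ifd_off + 2L + n_entries * 12L, endian)
  }
  if (!length(images)) stop("TIFF contains no images: ", path)
  list(images = images, bit_depth = as.integer(bit_depth),
       sample_format = sample_format)
}

.le16 <- function(v) {
  v <- as.integer(round(v))
  as.raw(c(rbind(v %% 256L, v %/% 256L)))
}

.le32 <- function(v) {
  v <- round(v)
  b0 <- v %% 256; v <- v %/% 256
  b1 <- v %% 256; v <- v %/% 256
  b2 <- v %% 256; b3 <- v %/% 256
  as.raw(c(rbind(b0, b1, b2, b3)))
}

.encode_pixels <- function(m, bit_depth) {
  v <- as.vector(t(m))
  if (bit_depth == 8) {
    as.raw(as.integer(round(v)))
  } else if (bit_depth == 16) {
    .le16(v)
  } else {
    writeBin(as.numeric(v), raw(), size = 4L, endian = "little")
  }
}

.ifd_entry <- function(tag, type, count, value) {
  c(.le16(tag), .le16(type), .le32(count), .le32(value))
}

#' Write matrices as a grayscale TIFF
#'
#' Writes one or more numeric matrices as an uncompressed little-endian
#' grayscale TIFF (multi-page when more than one matrix is given). Integer
#' depths are written as unsigned values; 32-bit output is IEEE float, so
#' arbitrary intensities survive a round trip bit-exactly.
#'
#' @param images A numeric matrix or list of matrices sharing dimensions.
#' @param path Output file path.
#' @param bit_depth 8, 16 or 32. Default picks the smallest depth that
#'   represents the data exactly (32-bit float for non-integer values).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(images, path, bit_depth = NULL) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1L)
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1L) stop("all pages must share dimensions")
  vals <- unlist(lapply(images, range))
  if (is.null(bit_depth)) {
    all_int <- all(vapply(images, function(m) all(m == round(m)), logical(1)))
    bit_depth <- if (!all_int || min(vals) < 0) 32L
    else if (max(vals) <= 255) 8L
    else if (max(vals) <= 65535) 16L
    else 32L
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L, 32L)) stop("bit_depth must be 8, 16 or 32")
  if (bit_depth %in% c(8L, 16L)) {
    lim <- if (bit_depth == 8L) 255 else 65535
    if (min(vals) < 0 || max(vals) > lim) {
      stop("pixel values out of range for ", bit_depth, "-bit output")
    }
  }
  h <- nrow(images[[1L]]); w <- ncol(images[[1L]])
  bytes_px <- bit_depth / 8L
  strip_len <- w * h * bytes_px
  n <- length(images)
  sample_fmt <- if (bit_depth == 32L) 3L else 1L

  n_entries <- 11L
  ifd_size <- 2L + n_entries * 12L + 4L
  # layout: 8-byte header | n strips | n IFDs
  strip_off <- 8L + (seq_len(n) - 1L) * strip_len
  ifd_off <- 8L + n * strip_len + (seq_len(n) - 1L) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(.le16(42L), .le32(ifd_off[1L])), con)
  for (m in images) writeBin(.encode_pixels(m, bit_depth), con)
  for (i in seq_len(n)) {
    next_off <- if (i < n) ifd_off[i + 1L] else 0L
    ifd <- c(
      .le16(n_entries),
      .ifd_entry(TIFF_TAGS[["ImageWidth"]], 4L, 1L, w),
      .ifd_entry(TIFF_TAGS[["ImageLength"]], 4L, 1L, h),
      .ifd_entry(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, bit_depth),
      .ifd_entry(TIFF_TAGS[["Compression"]], 3L, 1L, 1L),
      .ifd_entry(TIFF_TAGS[["Photometric"]], 3L, 1L, 1L),
      .ifd_entry(TIFF_TAGS[["StripOffsets"]], 4L, 1L, strip_off[i]),
      .ifd_entry(TIFF_TAGS[["SamplesPerPixel"]], 3L, 1L, 1L),
      .ifd_entry(TIFF_TAGS[["RowsPerStrip"]], 4L, 1L, h),
      .ifd_entry(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, strip_len),
      .ifd_entry(TIFF_TAGS[["PlanarConfig"]], 3L, 1L, 1L),
      .ifd_entry(TIFF_TAGS[["SampleFormat"]], 3L, 1L, sample_fmt),
      .le32(next_off)
    )
    writeBin(ifd, con)
  }
  invisible(path)
}
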