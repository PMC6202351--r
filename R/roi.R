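# ImageJ ROI file format (.roi and RoiSet.zip).
#
# Implements the subset of the ImageJ ROI binary format needed for cell
# outlines: rectangle, oval, polygon, freehand and traced types. All
# multi-byte fields are big-endian. Vertices use ImageJ's corner coordinate
# system (integer coordinates sit at pixel corners; the pixel at column c,
# row r spans [c, c+1] x [r, r+1]).

ROI_TYPES <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L, freeline = 4L,
               polyline = 5L, noroi = 6L, freehand = 7L, traced = 8L,
               angle = 9L, point = 10L)

.be16 <- function(raw, off, signed = FALSE) {
  readBin(raw[(off + 1L):(off + 2L)], "integer", size = 2L,
          signed = signed, endian = "big")
}

#' Read a single ImageJ .roi file
#'
#' Decodes one ROI into a closed polygon in ImageJ corner coordinates.
#' Rectangles become their 4 corners; ovals are approximated by a 72-gon
#' inscribed in their bounding box; polygon/freehand/traced types return
#' their stored vertices.
#'
#' @param path Path to a `.roi` file, or a raw vector with its contents.
#' @return A list with `x`, `y` (numeric vertex vectors, corner coordinates),
#'   `type` (ROI type name) and `name`.
#' @export
read_imagej_roi <- function(path) {
  raw <- if (is.raw(path)) path else readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout") {
    stop("not an ImageJ ROI file")
  }
  type_code <- as.integer(raw[7L])
  type <- names(ROI_TYPES)[match(type_code, ROI_TYPES)]
  if (is.na(type)) stop("unsupported ROI type code ", type_code)
  top <- .be16(raw, 8L, signed = TRUE)
  left <- .be16(raw, 10L, signed = TRUE)
  bottom <- .be16(raw, 12L, signed = TRUE)
  right <- .be16(raw, 14L, signed = TRUE)
  n <- .be16(raw, 16L)
  if (type == "rect") {
    x <- c(left, right, right, left)
    y <- c(top, top, bottom, bottom)
  } else if (type == "oval") {
    t <- seq(0, 2 * pi, length.out = 73L)[-73L]
    x <- (left + right) / 2 + (right - left) / 2 * cos(t)
    y <- (top + bottom) / 2 + (bottom - top) / 2 * sin(t)
  } else if (type %in% c("polygon", "freehand", "traced")) {
    if (n < 1L) stop("ROI has no coordinates")
    xs <- vapply(seq_len(n) - 1L, function(i)
      .be16(raw, 64L + i * 2L, signed = TRUE), integer(1))
    ys <- vapply(seq_len(n) - 1L, function(i)
      .be16(raw, 64L + (n + i) * 2L, signed = TRUE), integer(1))
    x <- left + xs
    y <- top + ys
  } else {
    stop("ROI type '", type, "' is not a closed region")
  }
  list(x = as.numeric(x), y = as.numeric(y), type = type,
       name = if (!is.raw(path))
         sub("\\.roi$", "", basename(path), ignore.case = TRUE) else "")
}

.wbe16 <- function(v) {
  v <- as.integer(round(v))
  v <- ifelse(v < 0, v + 65536L, v)
  as.raw(c(rbind(v %/% 256L, v %% 256L)))
}

#' Write a polygon as an ImageJ .roi file
#'
#' Encodes a closed polygon (ImageJ corner coordinates) in the ImageJ ROI
#' binary format, readable by ImageJ's ROI Manager and by
#' [read_imagej_roi()].
#'
#' @param x,y Numeric vertex coordinates (rounded to integers on write).
#' @param path Output path, or `NULL` to return the encoded raw vector.
#' @param type `"polygon"`, `"freehand"` or `"traced"`.
#' @return `path` (or the raw vector when `path` is `NULL`), invisibly.
#' @export
write_imagej_roi <- function(x, y, path = NULL, type = "polygon") {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            type %in% c("polygon", "freehand", "traced"))
  x <- as.integer(round(x)); y <- as.integer(round(y))
  left <- min(x); top <- min(y)
  header <- raw(64L)
  header[1:4] <- charToRaw("Iout")
  header[5:6] <- .wbe16(227L)                       # version
  header[7L] <- as.raw(ROI_TYPES[[type]])
  header[9:10] <- .wbe16(top)
  header[11:12] <- .wbe16(left)
  header[13:14] <- .wbe16(max(y))
  header[15:16] <- .wbe16(max(x))
  header[17:18] <- .wbe16(length(x))
  body <- c(.wbe16(x - left), .wbe16(y - top))
  out <- c(header, body)
  if (is.null(path)) return(invisible(out))
  writeBin(out, path)
  invisible(path)
}

#' Load an ROI set (.roi file or RoiSet.zip)
#'
#' Reads either a single `.roi` file or an ImageJ `RoiSet.zip` archive and
#' converts every ROI to a closed polygon in the package's internal pixel
#' coordinates (0-based row/column, pixel centers at integers). ROI order is
#' preserved: it defines cell numbering downstream.
#'
#' @param path Path to a `.roi` file or a zip archive of `.roi` files.
#' @param image_shape Integer `(height, width)` of the target image, used to
#'   sanity-check that outlines overlap the frame.
#' @return An object of class `roi_set`: list with `outlines` (each a list
#'   with `row`, `col` vertex vectors), `names`, and `image_shape`.
#' @export
load_roi_set <- function(path, image_shape) {
  stopifnot(length(image_shape) == 2L)
  if (!file.exists(path)) stop("ROI file not found: ", path)
  is_zip <- grepl("\\.zip$", path, ignore.case = TRUE) ||
    identical(as.integer(readBin(path, "raw", n = 2L)), c(80L, 75L))
  rois <- if (is_zip) {
    entries <- tryCatch(zip::zip_list(path)$filename, error = function(e) {
      stop("unreadable ROI archive: ", path, " (", conditionMessage(e), ")")
    })
    entries <- entries[grepl("\\.roi$", entries, ignore.case = TRUE)]
    if (!length(entries)) stop("no ROIs found in ", path)
    exdir <- tempfile("roiset")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE))
    zip::unzip(path, files = entries, exdir = exdir)
    lapply(entries, function(e) read_imagej_roi(file.path(exdir, e)))
  } else {
    list(read_imagej_roi(path))
  }
  outlines <- lapply(rois, function(r) {
    # corner coords -> internal pixel-center coords
    list(row = r$y - 0.5, col = r$x - 0.5)
  })
  structure(list(outlines = outlines,
                 names = vapply(rois, `[[`, character(1), "name"),
                 image_shape = as.integer(image_shape)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set> ", length(x$outlines), " ROI(s) for a ",
      x$image_shape[1], "x", x$image_shape[2], " image\n", sep = "")
  invisible(x)
}

#' Write an ROI set as an ImageJ-compatible RoiSet.zip
#'
#' @param outlines List of polygons; each element has `row`, `col` numeric
#'   vectors in internal pixel-center coordinates (converted to ImageJ
#'   corner coordinates on write) or `x`, `y` already in corner coordinates.
#' @param path Output zip path.
#' @param names Optional entry names (without extension); defaults to
#'   zero-padded indices, mirroring ImageJ's ROI manager numbering.
#' @return `path`, invisibly. An empty outline list writes a valid empty
#'   zip archive with a warning.
#' @export
write_roi_set <- function(outlines, path, names = NULL) {
  if (!length(outlines)) {
    warning("writing empty ROI set: ", path)
    # minimal end-of-central-directory record
    writeBin(c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), raw(18L)), path)
    return(invisible(path))
  }
  if (is.null(names)) names <- sprintf("%04d", seq_along(outlines))
  tmp <- tempfile("roiwrite")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- character(length(outlines))
  for (i in seq_along(outlines)) {
    o <- outlines[[i]]
    if (!is.null(o$row)) {
      x <- o$col + 0.5
      y <- o$row + 0.5
    } else {
      x <- o$x; y <- o$y
    }
    files[i] <- file.path(tmp, paste0(names[i], ".roi"))
    write_imagej_roi(x, y, files[i], type = "traced")
  }
  zip::zip(normalizePath(path, mustWork = FALSE), files, mode = "cherry-pick")
  invisible(path)
}
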