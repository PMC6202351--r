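# Channel stacks and label maps: the input contract of the pipeline.
#
# Internal coordinate convention: 0-based (row, col) = (y, x), pixel centers
# at integer coordinates. ImageJ corner-coordinate polygons are converted at
# the I/O boundary (see roi.R).

CHANNEL_ROLES <- c("cell_id", "reporter1", "reporter2", "reporter3")

#' Construct a channel stack
#'
#' A channel stack is an ordered list of 2-D intensity matrices for one
#' channel (different fields of view or a time series) sharing identical
#' dimensions; the unit consumed by alignment, segmentation and metrics.
#'
#' @param images A numeric matrix or list of matrices (equal dimensions).
#' @param role One of `"cell_id"`, `"reporter1"`, `"reporter2"`,
#'   `"reporter3"`.
#' @param bit_depth 8, 16 or 32; recorded, not enforced on values.
#' @param name Optional display name (defaults to the role).
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(images, role, bit_depth = 16L, name = role) {
  if (is.matrix(images)) images <- list(images)
  role <- match.arg(role, CHANNEL_ROLES)
  stopifnot(length(images) >= 1L, all(vapply(images, is.matrix, logical(1))))
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1L) {
    stop("all images in a channel stack must share dimensions; got ",
         paste(vapply(dims, paste, character(1), collapse = "x"),
               collapse = ", "))
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L, 32L)) stop("bit_depth must be 8, 16 or 32")
  structure(list(images = lapply(images, function(m) {
    storage.mode(m) <- "double"; m
  }), bit_depth = bit_depth, name = name, role = role),
  class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$images[[1L]])
  cat("<channel_stack> role=", x$role, " name=", x$name, ": ",
      length(x$images), " image(s) of ", d[1], "x", d[2], ", ",
      x$bit_depth, "-bit\n", sep = "")
  invisible(x)
}

#' @export
length.channel_stack <- function(x) length(x$images)

#' Load a channel stack from TIFF files
#'
#' Loads one or more single- or multi-page grayscale TIFFs into a channel
#' stack; multi-page files are unrolled in page order. Pixel values pass
#' through bit-exactly. RGB/CMYK input is rejected (monochromatic images are
#' required) and all images must share dimensions.
#'
#' @param paths Character vector of TIFF paths, in stack order.
#' @param role Channel role (see [channel_stack()]).
#' @param name Optional display name.
#' @return A `channel_stack`.
#' @export
load_channel_stack <- function(paths, role, name = role) {
  stopifnot(length(paths) >= 1L)
  images <- list()
  bit_depth <- 0L
  for (p in paths) {
    tf <- read_tiff(p)
    images <- c(images, tf$images)
    bit_depth <- max(bit_depth, tf$bit_depth)
  }
  channel_stack(images, role = role, bit_depth = bit_depth, name = name)
}

#' Construct a label map
#'
#' @param labels Integer matrix; 0 = background, k > 0 = pixels of cell k.
#'   Labels must be contiguous `1..K`.
#' @param source_image_index Index of the stack image the labels refer to.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, source_image_index = 1L) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) && !identical(u, seq_len(length(u)))) {
    stop("labels must be contiguous positive integers starting at 1")
  }
  structure(list(labels = labels, n = length(u),
                 source_image_index = as.integer(source_image_index)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", x$n, " object(s), ",
      nrow(x$labels), "x", ncol(x$labels),
      " (image ", x$source_image_index, ")\n", sep = "")
  invisible(x)
}

# Even-odd point-in-polygon, boundary-inclusive, vectorized over points.
.points_in_polygon <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- rep(FALSE, length(py))
  on_edge <- rep(FALSE, length(py))
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    y1 <- vy[j]; x1 <- vx[j]; y2 <- vy[i]; x2 <- vx[i]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xi))
      on_edge <- on_edge | (crosses & abs(px - xi) <= eps)
    }
    # point exactly on the segment (covers horizontal edges too)
    dx <- x2 - x1; dy <- y2 - y1
    cross <- dx * (py - y1) - dy * (px - x1)
    within <- (px >= pmin(x1, x2) - eps) & (px <= pmax(x1, x2) + eps) &
      (py >= pmin(y1, y2) - eps) & (py <= pmax(y1, y2) + eps)
    on_edge <- on_edge | (abs(cross) <= eps * (abs(dx) + abs(dy) + 1) & within)
    j <- i
  }
  inside | on_edge
}

#' Rasterize an ROI set into a label map
#'
#' A pixel belongs to ROI k when its center lies inside or on the boundary
#' of polygon k (even-odd rule). Where polygons overlap, the later ROI wins.
#' Polygons that are entirely outside the frame are dropped with a warning;
#' remaining ROIs keep their original order for numbering (labels are
#' renumbered contiguously after drops).
#'
#' @param rois A `roi_set` from [load_roi_set()], or a bare list of outlines
#'   (each with `row`, `col` vertex vectors).
#' @param shape Integer `(height, width)`.
#' @return A `label_map`.
#' @export
rois_to_labelmap <- function(rois, shape = NULL) {
  outlines <- if (inherits(rois, "roi_set")) rois$outlines else rois
  if (is.null(shape)) shape <- rois$image_shape
  h <- shape[1]; w <- shape[2]
  labels <- matrix(0L, h, w)
  kept <- 0L
  for (k in seq_along(outlines)) {
    o <- outlines[[k]]
    r0 <- max(0L, floor(min(o$row))); r1 <- min(h - 1L, ceiling(max(o$row)))
    c0 <- max(0L, floor(min(o$col))); c1 <- min(w - 1L, ceiling(max(o$col)))
    if (r0 > r1 || c0 > c1) {
      warning("ROI ", k, " lies outside the image; dropped")
      next
    }
    rr <- rep(r0:r1, times = c1 - c0 + 1L)
    cc <- rep(c0:c1, each = r1 - r0 + 1L)
    inside <- .points_in_polygon(rr, cc, o$row, o$col)
    if (!any(inside)) {
      warning("ROI ", k, " covers no pixel centers; dropped")
      next
    }
    kept <- kept + 1L
    labels[cbind(rr[inside] + 1L, cc[inside] + 1L)] <- kept
  }
  # later-ROI-wins overwrites can empty an earlier label: renumber
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) && !identical(u, seq_len(length(u)))) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  label_map(labels)
}
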