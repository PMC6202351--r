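# Cell identification: connected components, Euclidean distance transform,
# marker-based watershed, border-object removal, boundary tracing.
#
# Conventions (ImageJ particle-analysis style): foreground is 8-connected;
# components are labeled 1..K in raster-scan order (topmost, then leftmost
# pixel); watershed lines become background so objects stay separated.

# row-major scan key for 1-based (r, c): smaller = earlier in raster order
.raster_key <- function(r, c, w) (r - 1) * w + c

.NEIGH8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                 dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Label connected components of a binary mask
#'
#' 8-connected (default) flood labeling; labels are assigned 1..K in
#' raster-scan order of each component's topmost-leftmost pixel, so labeling
#' is fully deterministic.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  offs <- if (connectivity == 8L) .NEIGH8 else
    .NEIGH8[.NEIGH8[, 1] == 0L | .NEIGH8[, 2] == 0L, , drop = FALSE]
  lab <- matrix(0L, h, w)
  fg <- which(mask)                       # column-major linear indices
  if (!length(fg)) return(lab)
  r <- (fg - 1L) %% h + 1L
  c <- (fg - 1L) %/% h + 1L
  fg <- fg[order(.raster_key(r, c, w))]
  cur <- 0L
  for (seed in fg) {
    if (lab[seed] > 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      fr <- (frontier - 1L) %% h + 1L
      fc <- (frontier - 1L) %/% h + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        nr <- fr + offs[k, 1L]; nc <- fc + offs[k, 2L]
        ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
        if (!any(ok)) next
        np <- (nc[ok] - 1L) * h + nr[ok]
        np <- np[mask[np] & lab[np] == 0L]
        if (length(np)) {
          lab[np] <- cur
          nxt <- c(nxt, np)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

# Renumber positive labels 1..K in raster-scan order of their
# topmost-leftmost pixel; drops gaps.
.renumber_raster <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  pos <- which(lab > 0L)
  if (!length(pos)) return(lab)
  r <- (pos - 1L) %% h + 1L
  c <- (pos - 1L) %/% h + 1L
  key <- .raster_key(r, c, w)
  first_key <- tapply(key, lab[pos], min)
  old <- as.integer(names(first_key))
  remap <- integer(max(old))
  remap[old[order(first_key)]] <- seq_along(old)
  lab[pos] <- remap[lab[pos]]
  lab
}

# Felzenszwalb & Huttenlocher 1-D squared distance transform.
# Callers encode "no site" as a large finite value, never Inf.
.dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance transform of a binary mask
#'
#' Exact Euclidean distance from each foreground pixel to the nearest
#' background pixel. Pixels outside the frame count as background (an object
#' touching the border has distance 1 at the border), matching ImageJ's
#' distance map.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Numeric matrix of distances (0 on background).
#' @export
distance_transform <- function(mask) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  big <- 4 * (h + w + 4)^2            # larger than any attainable distance^2
  # pad with a background ring so the frame edge acts as background
  f <- matrix(0, h + 2L, w + 2L)
  f[2:(h + 1L), 2:(w + 1L)] <- ifelse(mask, big, 0)
  for (j in seq_len(ncol(f))) f[, j] <- .dt1d(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- .dt1d(f[i, ])
  sqrt(f[2:(h + 1L), 2:(w + 1L)])
}

# shift a matrix, filling with `fill`
.shiftm <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  sr <- intersect(seq_len(h) - dy, seq_len(h))
  sc <- intersect(seq_len(w) - dx, seq_len(w))
  if (length(sr) && length(sc)) out[sr + dy, sc + dx] <- m[sr, sc]
  out
}

# Markers for watershed: plateau-merged local maxima of the EDT.
.watershed_markers <- function(edt, mask) {
  is_max <- mask
  for (k in seq_len(nrow(.NEIGH8))) {
    nb <- .shiftm(edt, .NEIGH8[k, 1L], .NEIGH8[k, 2L], -Inf)
    is_max <- is_max & (edt >= nb)
  }
  label_components(is_max, 8L)
}

# Synchronous priority flood from markers; returns labels with watershed
# line pixels marked -1.
.watershed_flood <- function(edt, mask, markers) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- markers
  lab[!mask] <- 0L
  levels <- sort(unique(edt[mask & lab == 0L]), decreasing = TRUE)
  pending <- integer(0)
  for (lev in levels) {
    active <- union(pending, which(mask & lab == 0L & edt == lev))
    repeat {
      if (!length(active)) break
      r <- (active - 1L) %% h + 1L
      c <- (active - 1L) %/% h + 1L
      nmin <- rep(Inf, length(active))
      nmax <- rep(0, length(active))
      for (k in seq_len(nrow(.NEIGH8))) {
        nr <- r + .NEIGH8[k, 1L]; nc <- c + .NEIGH8[k, 2L]
        ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
        v <- rep(0L, length(active))
        v[ok] <- lab[(nc[ok] - 1L) * h + nr[ok]]
        v[v < 0L] <- 0L
        pos <- v > 0L
        nmax <- pmax(nmax, v)
        nmin[pos] <- pmin(nmin[pos], v[pos])
      }
      assign_one <- nmax > 0 & nmin == nmax
      assign_line <- nmax > 0 & nmin < nmax
      if (!any(assign_one) && !any(assign_line)) break
      lab[active[assign_one]] <- as.integer(nmin[assign_one])
      lab[active[assign_line]] <- -1L
      active <- active[!(assign_one | assign_line)]
    }
    pending <- active
  }
  lab
}

#' Segment cells from a thresholded image
#'
#' Binarizes the cell-identification image at `cutoff`, optionally removes
#' very large objects before watershed (the pre-watershed area filter, meant
#' for aggregates that watershed would otherwise shatter into cell-sized
#' fragments), optionally splits touching objects by marker-based watershed
#' on the Euclidean distance transform, and labels the result 1..K in
#' raster-scan order.
#'
#' @param image Numeric matrix (cell-identification channel).
#' @param cutoff Intensity cutoff (from [auto_threshold()] or manual).
#' @param polarity Background polarity (see [threshold_mask()]).
#' @param use_watershed Split touching objects?
#' @param prewatershed_max_area Remove objects with area strictly greater
#'   than this many pixels before watershed (`NULL` = off).
#' @param source_image_index Stored in the returned label map.
#' @return A [label_map()].
#' @export
segment_cells <- function(image, cutoff, polarity = "dark_background",
                          use_watershed = FALSE,
                          prewatershed_max_area = NULL,
                          source_image_index = 1L) {
  mask <- threshold_mask(image, cutoff, polarity)
  if (!is.null(prewatershed_max_area)) {
    lab0 <- label_components(mask, 8L)
    if (max(lab0) > 0L) {
      areas <- tabulate(lab0[lab0 > 0L], nbins = max(lab0))
      big <- which(areas > prewatershed_max_area)
      if (length(big)) mask[lab0 %in% big] <- FALSE
    }
  }
  lab <- if (use_watershed && any(mask)) {
    edt <- distance_transform(mask)
    markers <- .watershed_markers(edt, mask)
    flooded <- .watershed_flood(edt, mask, markers)
    flooded[flooded < 0L] <- 0L       # watershed lines -> background
    .renumber_raster(flooded)
  } else {
    label_components(mask, 8L)
  }
  label_map(lab, source_image_index = source_image_index)
}

#' Remove objects touching the image border
#'
#' Cells only partly within the frame would yield misleading measurements;
#' any object with at least one pixel on the first/last row or column is
#' removed and the remaining labels are renumbered contiguously in
#' raster-scan order.
#'
#' @param lm A [label_map()].
#' @return A `label_map` without border-touching objects (a warning is
#'   raised when nothing remains).
#' @export
remove_border_objects <- function(lm) {
  lab <- lm$labels
  h <- nrow(lab); w <- ncol(lab)
  border <- unique(c(lab[1L, ], lab[h, ], lab[, 1L], lab[, w]))
  border <- border[border > 0L]
  if (length(border)) lab[lab %in% border] <- 0L
  if (!any(lab > 0L) && lm$n > 0L) {
    warning("all objects touched the border; label map is empty")
  }
  label_map(.renumber_raster(lab), source_image_index = lm$source_image_index)
}

# Crack-boundary trace of one label: closed polygon along pixel edges in
# ImageJ corner coordinates (pixel r,c 1-based spans [c-1,c] x [r-1,r]).
# Outer boundary only; holes are not traced.
.trace_boundary <- function(labels, k) {
  member <- labels == k
  h <- nrow(member); w <- ncol(member)
  px <- which(member)
  if (!length(px)) stop("label ", k, " not present")
  pr <- (px - 1L) %% h + 1L
  pc <- (px - 1L) %/% h + 1L
  has <- function(r, c) {
    ok <- r >= 1L & r <= h & c >= 1L & c <= w
    res <- logical(length(r))
    res[ok] <- member[(c[ok] - 1L) * h + r[ok]]
    res
  }
  # directed edges, interior on the left: keyed by start corner
  # corner key for (x, y) with x in 0..w, y in 0..h
  ckey <- function(x, y) y * (w + 1L) + x + 1L
  # direction codes: 1=R(+x), 2=D(+y), 3=L(-x), 4=U(-y)
  starts <- integer(0); dirs <- integer(0)
  top <- !has(pr - 1L, pc)
  right <- !has(pr, pc + 1L)
  bottom <- !has(pr + 1L, pc)
  left <- !has(pr, pc - 1L)
  # top edge: (c-1, r-1) -> (c, r-1), heading R
  starts <- c(starts, ckey(pc[top] - 1L, pr[top] - 1L))
  dirs <- c(dirs, rep(1L, sum(top)))
  # right edge: (c, r-1) -> (c, r), heading D
  starts <- c(starts, ckey(pc[right], pr[right] - 1L))
  dirs <- c(dirs, rep(2L, sum(right)))
  # bottom edge: (c, r) -> (c-1, r), heading L
  starts <- c(starts, ckey(pc[bottom], pr[bottom]))
  dirs <- c(dirs, rep(3L, sum(bottom)))
  # left edge: (c-1, r) -> (c-1, r-1), heading U
  starts <- c(starts, ckey(pc[left] - 1L, pr[left]))
  dirs <- c(dirs, rep(4L, sum(left)))

  edge_env <- split(dirs, starts)
  dxy <- rbind(c(1L, 0L), c(0L, 1L), c(-1L, 0L), c(0L, -1L))  # by dir code

  # start at topmost-leftmost pixel's top edge
  start_px <- which.min(.raster_key(pr, pc, w))
  x <- pc[start_px] - 1L; y <- pr[start_px] - 1L
  dir <- 1L
  start_key <- ckey(x, y); start_dir <- dir
  used <- new.env(parent = emptyenv())
  xs <- x; ys <- y
  repeat {
    x <- x + dxy[dir, 1L]; y <- y + dxy[dir, 2L]
    key <- ckey(x, y)
    if (key == start_key) break
    cand <- edge_env[[as.character(key)]]
    if (is.null(cand)) stop("boundary tracing failed for label ", k)
    if (length(cand) > 1L) {
      # pinch corner (diagonal touch): prefer the left turn relative to
      # travel direction so the trace continues around the 8-connected set
      left_of <- c(4L, 1L, 2L, 3L)
      pref <- c(left_of[dir], dir, (dir %% 4L) + 1L)
      cand <- pref[pref %in% cand]
    }
    chosen <- NA_integer_
    for (d in cand) {
      uk <- paste0(key, ":", d)
      if (is.null(used[[uk]])) { chosen <- d; break }
    }
    if (is.na(chosen)) stop("boundary tracing stuck for label ", k)
    used[[paste0(key, ":", chosen)]] <- TRUE
    if (chosen != dir) { xs <- c(xs, x); ys <- c(ys, y) }
    dir <- chosen
  }
  list(x = xs, y = ys)
}

#' Trace cell outlines as polygons
#'
#' Traces the outer crack boundary (along pixel edges) of each label as a
#' closed polygon in ImageJ corner coordinates, suitable for ROI export.
#' Rasterizing the polygon back (pixel-center rule) reproduces the exact
#' pixel set for objects without holes.
#'
#' @param lm A [label_map()].
#' @return List of polygons (elements `x`, `y`), one per label in order.
#' @export
trace_outlines <- function(lm) {
  lapply(seq_len(lm$n), function(k) .trace_boundary(lm$labels, k))
}
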