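# Background polarity detection and thresholded-mask image alignment.
#
# Channels acquired separately can be offset by a few pixels (stage drift,
# chromatic shift). Alignment thresholds each channel, then finds the integer
# translation of the reporter mask that maximizes foreground overlap with the
# cell-identification mask. Pixels shifted out of frame are discarded and
# vacated pixels are filled with exact zeros, so all channels keep one common
# aligned region of identical dimensions.

#' Detect dark vs light background from intensity skewness
#'
#' Assuming background pixels outnumber cell pixels, a positively skewed
#' intensity distribution indicates bright objects on a dark background and
#' a negatively skewed one the reverse. The skewness is the sample third
#' standardized moment with `n` normalization; exactly zero skew falls back
#' to `dark_background` with a warning.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @return List with `value` (`"dark_background"` or `"light_background"`)
#'   and `skewness`.
#' @export
detect_background_polarity <- function(image) {
  v <- as.numeric(image)
  m <- mean(v)
  s2 <- mean((v - m)^2)
  if (s2 == 0) stop("polarity undeterminable: image is constant")
  skew <- mean((v - m)^3) / s2^1.5
  value <- if (skew > 0) {
    "dark_background"
  } else if (skew < 0) {
    "light_background"
  } else {
    warning("zero skewness; defaulting to dark_background")
    "dark_background"
  }
  list(value = value, skewness = skew)
}

#' Translate an image by integer pixels with zero fill
#'
#' Content moves by `(dy, dx)` (positive = down/right); pixels shifted out of
#' frame are discarded and vacated pixels are set to `fill` (exactly 0 by
#' default). Dimensions are preserved.
#'
#' @param image Numeric or integer matrix.
#' @param dy,dx Integer shifts in pixels.
#' @param fill Fill value for vacated pixels.
#' @return Matrix of the same dimensions and storage mode.
#' @export
translate_image <- function(image, dy, dx, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  out <- matrix(fill, h, w)
  storage.mode(out) <- storage.mode(image)
  src_r <- intersect(seq_len(h) - dy, seq_len(h))
  src_c <- intersect(seq_len(w) - dx, seq_len(w))
  if (length(src_r) && length(src_c)) {
    out[src_r + dy, src_c + dx] <- image[src_r, src_c]
  }
  out
}

#' Estimate the integer shift aligning one binary mask to another
#'
#' Exhaustively searches translations `(dy, dx)` in the square window
#' `[-max_shift, max_shift]^2` for the one maximizing the count of
#' overlapping foreground pixels between the translated moving mask and the
#' reference mask. Ties are broken by smallest `|dy| + |dx|`, then smallest
#' `dy`, then smallest `dx`. If no translation yields any overlap the shift
#' is `(0, 0)` with a warning.
#'
#' @param ref_mask,mov_mask Logical (or 0/1) matrices of equal shape, each
#'   with at least one foreground pixel.
#' @param max_shift Half-width of the search window in pixels.
#' @return List with `dy`, `dx` (integers) and `overlap` (pixel count).
#' @export
estimate_shift <- function(ref_mask, mov_mask, max_shift = 20L) {
  ref <- ref_mask != 0; mov <- mov_mask != 0
  stopifnot(identical(dim(ref), dim(mov)))
  if (!any(ref) || !any(mov)) {
    stop("empty mask: thresholding must select cell areas before alignment")
  }
  s <- as.integer(max_shift)
  cand <- expand.grid(dy = -s:s, dx = -s:s)
  overlap <- integer(nrow(cand))
  h <- nrow(ref); w <- ncol(ref)
  for (i in seq_len(nrow(cand))) {
    dy <- cand$dy[i]; dx <- cand$dx[i]
    r1 <- max(1L, 1L + dy); r2 <- min(h, h + dy)
    c1 <- max(1L, 1L + dx); c2 <- min(w, w + dx)
    if (r1 > r2 || c1 > c2) next
    overlap[i] <- sum(ref[r1:r2, c1:c2] & mov[(r1:r2) - dy, (c1:c2) - dx])
  }
  if (max(overlap) == 0L) {
    warning("alignment not found: no overlap within the search window")
    return(list(dy = 0L, dx = 0L, overlap = 0L))
  }
  ord <- order(-overlap, abs(cand$dy) + abs(cand$dx), cand$dy, cand$dx)
  best <- ord[1L]
  list(dy = cand$dy[best], dx = cand$dx[best], overlap = overlap[best])
}

#' Align reporter stacks to the cell-identification stack
#'
#' Each reporter image is thresholded (same auto-threshold registry as
#' segmentation), registered to the corresponding cell-identification image
#' by [estimate_shift()], and translated with zero fill. Alignment is
#' per-slice: each stack position is registered independently. Failures
#' (e.g. an empty threshold mask) skip alignment for that image with a
#' warning, leaving it untranslated.
#'
#' @param cell_stack `channel_stack` with role `cell_id`.
#' @param reporter_stacks List of reporter `channel_stack`s (equal length).
#' @param threshold_method Auto-threshold method name (see
#'   [auto_threshold()]).
#' @param max_shift Search half-width in pixels.
#' @param background `"auto"`, `"dark"` or `"light"`.
#' @return List with `cell` (unchanged stack), `reporters` (aligned stacks)
#'   and `shifts` (per reporter, per image `dy`/`dx` table).
#' @export
align_stacks <- function(cell_stack, reporter_stacks,
                         threshold_method = "Default", max_shift = 20L,
                         background = "auto") {
  stopifnot(inherits(cell_stack, "channel_stack"))
  if (inherits(reporter_stacks, "channel_stack")) {
    reporter_stacks <- list(reporter_stacks)
  }
  n <- length(cell_stack$images)
  for (rs in reporter_stacks) {
    if (length(rs$images) != n) {
      stop("all channel stacks must have equal length")
    }
  }
  fg_mask <- function(img) {
    pol <- if (background == "auto") {
      detect_background_polarity(img)$value
    } else {
      paste0(background, "_background")
    }
    cut <- auto_threshold(img, method = threshold_method, polarity = pol)
    if (pol == "dark_background") img > cut else img < cut
  }
  shifts <- vector("list", length(reporter_stacks))
  aligned <- reporter_stacks
  for (j in seq_along(reporter_stacks)) {
    tab <- data.frame(image = seq_len(n), dy = 0L, dx = 0L)
    for (i in seq_len(n)) {
      sh <- tryCatch({
        ref <- fg_mask(cell_stack$images[[i]])
        mov <- fg_mask(reporter_stacks[[j]]$images[[i]])
        estimate_shift(ref, mov, max_shift)
      }, error = function(e) {
        warning("alignment skipped for reporter ", j, " image ", i, ": ",
                conditionMessage(e))
        NULL
      })
      if (is.null(sh)) next
      tab$dy[i] <- sh$dy; tab$dx[i] <- sh$dx
      if (sh$dy != 0L || sh$dx != 0L) {
        aligned[[j]]$images[[i]] <-
          translate_image(reporter_stacks[[j]]$images[[i]], sh$dy, sh$dx)
      }
    }
    shifts[[j]] <- tab
  }
  list(cell = cell_stack, reporters = aligned, shifts = shifts)
}
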