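# Colocalization metrics on per-cell pixel vectors.
#
# All metrics operate on a cell_pixels object: equal-length intensity vectors
# (one per reporter channel) over the same in-cell pixels in a fixed order.
# Thresholds are top-percentile selections: F_T = 0.1 selects the 10% of
# pixels with the highest intensity in that channel. For metrics that do not
# intrinsically need a threshold (PCC, SRCC, ICQ) a supplied threshold
# restricts the computation to pixels selected in all channels, as if only
# those pixels existed. Failure to compute a value yields NaN, never an
# error, so per-cell tables can record it.

#' Construct a per-cell pixel container
#'
#' @param ... Numeric vectors of in-cell pixel intensities, one per channel
#'   (2 or 3 for the standard metrics), all the same length and pixel order.
#'   A single list argument is also accepted.
#' @param names Optional channel names.
#' @return An object of class `cell_pixels` (a named list of vectors with
#'   attribute `N`).
#' @export
cell_pixels <- function(..., names = NULL) {
  chans <- list(...)
  if (length(chans) == 1L && is.list(chans[[1L]]) &&
      !is.numeric(chans[[1L]])) {
    chans <- chans[[1L]]
  }
  stopifnot(length(chans) >= 1L)
  lens <- vapply(chans, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all channel vectors must have the same length")
  }
  if (lens[1L] < 1L) stop("a cell must contain at least one pixel")
  chans <- lapply(chans, as.numeric)
  if (!is.null(names)) base::names(chans) <- names
  else if (is.null(base::names(chans))) {
    base::names(chans) <- paste0("ch", seq_along(chans))
  }
  structure(chans, N = lens[1L], class = "cell_pixels")
}

#' @export
print.cell_pixels <- function(x, ...) {
  cat("<cell_pixels> ", length(x), " channel(s) x ", attr(x, "N"),
      " pixel(s): ", paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract per-cell pixel vectors from reporter images
#'
#' @param lm A [label_map()].
#' @param reporter_stacks List of reporter `channel_stack`s (2 or 3).
#' @param labels Which labels to extract (default all).
#' @return Named list of `cell_pixels`, one per requested label, pixel order
#'   fixed by column-major position within the label map.
#' @export
extract_cell_pixels <- function(lm, reporter_stacks, labels = NULL) {
  if (inherits(reporter_stacks, "channel_stack")) {
    reporter_stacks <- list(reporter_stacks)
  }
  if (is.null(labels)) labels <- seq_len(lm$n)
  idx <- lm$source_image_index
  imgs <- lapply(reporter_stacks, function(rs) {
    img <- rs$images[[min(idx, length(rs$images))]]
    stopifnot(identical(dim(img), dim(lm$labels)))
    img
  })
  roles <- vapply(reporter_stacks, `[[`, character(1), "role")
  out <- lapply(labels, function(k) {
    px <- which(lm$labels == k)
    cell_pixels(lapply(imgs, function(img) img[px]), names = roles)
  })
  names(out) <- as.character(labels)
  out
}

#' Select the top-F_T fraction of pixels by intensity
#'
#' Exactly `max(1, round(fT * N))` pixel indices are returned: pixels ranked
#' by descending intensity, ties broken by ascending pixel index, so the
#' selection is deterministic under ties. `fT = 1` selects every pixel.
#'
#' @param values Numeric intensity vector (length `N >= 1`).
#' @param fT Fraction in `(0, 1]`.
#' @return Integer vector of selected (1-based) indices.
#' @export
select_top_fraction <- function(values, fT) {
  if (!is.numeric(fT) || length(fT) != 1L || is.na(fT) ||
      fT <= 0 || fT > 1) {
    stop("fT must be a fraction in (0, 1]")
  }
  n <- length(values)
  stopifnot(n >= 1L)
  n_sel <- max(1L, as.integer(round(fT * n)))
  if (n_sel >= n) return(seq_len(n))
  ord <- order(-values, seq_len(n))
  sort(ord[seq_len(n_sel)])
}

# selections for every channel; spec is a numeric vector of fT, one per
# channel (recycled if length 1)
.selections <- function(cell, spec) {
  k <- length(cell)
  fts <- rep_len(as.numeric(spec), k)
  lapply(seq_len(k), function(i) select_top_fraction(cell[[i]], fts[i]))
}

# pixels selected in ALL channels (the restriction set for PCC/SRCC/ICQ)
.restrict_idx <- function(cell, spec, restrict = "intersection") {
  if (is.null(spec)) return(seq_len(attr(cell, "N")))
  sels <- .selections(cell, spec)
  if (restrict == "union") sort(unique(unlist(sels)))
  else Reduce(intersect, sels)
}

#' Threshold overlap score (TOS)
#'
#' Measures how much the top-`fT` pixel sets of 2 or 3 channels overlap,
#' rescaled so +1 is the maximal possible overlap, 0 the overlap expected
#' under independence, and -1 the minimal possible overlap. With actual
#' selected fractions \eqn{f_i = n_i/N}: the observed overlap is
#' \eqn{A_O = |\cap_i S_i|/N}, the expected \eqn{A_E = \prod_i f_i}, the
#' maximum \eqn{A_{max} = \min_i f_i} and the minimum
#' \eqn{A_{min} = \max(0, \sum_i f_i - (k-1))}. Linear scaling rescales the
#' two branches linearly; logarithmic scaling uses
#' \eqn{\ln(A_O/A_E)/\ln(A_{max}/A_E)} above expectation and
#' \eqn{-\ln(A_O/A_E)/\ln(A_{min}/A_E)} below (falling back to the linear
#' branch value when \eqn{A_{min} = 0}, where the log form diverges).
#' The score is NaN when the applicable denominator vanishes — notably
#' whenever any channel's `fT` is 1, since then overlap is forced (the
#' blacked-out row/column of a TOS metric matrix).
#'
#' @param cell A [cell_pixels()] with 2 or 3 channels.
#' @param spec Numeric `fT` per channel in `(0, 1]` (recycled).
#' @param scaling `"linear"` or `"log"`.
#' @return Score in `[-1, 1]`, or NaN.
#' @export
tos <- function(cell, spec, scaling = c("linear", "log")) {
  scaling <- match.arg(scaling)
  k <- length(cell)
  stopifnot(k %in% c(2L, 3L))
  n <- attr(cell, "N")
  sels <- .selections(cell, spec)
  f <- vapply(sels, length, integer(1)) / n
  # a full selection forces overlap: the score is uninformative (matrix
  # blackout row/column). For 2 channels this also falls out of the
  # denominators; for 3 it must be imposed.
  if (any(f == 1)) return(NaN)
  a_o <- length(Reduce(intersect, sels)) / n
  a_e <- prod(f)
  a_max <- min(f)
  a_min <- max(0, sum(f) - (k - 1))
  lin <- function() {
    if (a_o >= a_e) {
      den <- a_max - a_e
      if (den == 0) NaN else (a_o - a_e) / den
    } else {
      den <- a_e - a_min
      if (den == 0) NaN else (a_o - a_e) / den
    }
  }
  if (scaling == "linear") return(lin())
  if (a_o >= a_e) {
    den <- log(a_max / a_e)
    if (den == 0) NaN else log(a_o / a_e) / den
  } else {
    if (a_min == 0) lin() else -log(a_o / a_e) / log(a_min / a_e)
  }
}

.pearson <- function(a, b) {
  if (length(a) < 2L) return(NaN)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(NaN)
  sum((a - mean(a)) * (b - mean(b))) / ((length(a) - 1) * sa * sb)
}

#' Pearson correlation coefficient of two channels
#'
#' Optionally restricted to the pixels selected in both channels' top-`fT`
#' sets (computed as if only those pixels existed). NaN when fewer than two
#' pixels remain or a restricted channel is constant.
#'
#' @param cell A 2-channel [cell_pixels()].
#' @param spec Optional `fT` per channel (`NULL` = no threshold).
#' @param restrict `"intersection"` (default) or `"union"` of the
#'   per-channel selections.
#' @return `r` in `[-1, 1]`, or NaN.
#' @export
pcc <- function(cell, spec = NULL, restrict = c("intersection", "union")) {
  restrict <- match.arg(restrict)
  stopifnot(length(cell) == 2L)
  idx <- .restrict_idx(cell, spec, restrict)
  .pearson(cell[[1L]][idx], cell[[2L]][idx])
}

#' Spearman rank correlation coefficient of two channels
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with the same
#' restriction and NaN rules as [pcc()].
#'
#' @inheritParams pcc
#' @return `rho` in `[-1, 1]`, or NaN.
#' @export
srcc <- function(cell, spec = NULL, restrict = c("intersection", "union")) {
  restrict <- match.arg(restrict)
  stopifnot(length(cell) == 2L)
  idx <- .restrict_idx(cell, spec, restrict)
  a <- cell[[1L]][idx]; b <- cell[[2L]][idx]
  if (length(a) < 2L) return(NaN)
  .pearson(rank(a), rank(b))
}

#' Intensity correlation quotient (ICQ)
#'
#' For two channels: the fraction of pixels whose demeaned intensities agree
#' in sign minus 1/2 (the independence expectation), over pixels with a
#' nonzero demeaned product; range `[-0.5, 0.5]`. For three channels: the
#' fraction of pixels where all three demeaned intensities share one sign
#' minus 1/4; range `[-0.25, 0.75]`. Means are taken on the restricted set
#' when a threshold is supplied. NaN when no valid pixel remains (e.g. no
#' pixel above all three thresholds).
#'
#' @param cell A 2- or 3-channel [cell_pixels()].
#' @inheritParams pcc
#' @return The quotient, or NaN.
#' @export
icq <- function(cell, spec = NULL, restrict = c("intersection", "union")) {
  restrict <- match.arg(restrict)
  k <- length(cell)
  stopifnot(k %in% c(2L, 3L))
  idx <- .restrict_idx(cell, spec, restrict)
  if (!length(idx)) return(NaN)
  dm <- lapply(cell, function(v) v[idx] - mean(v[idx]))
  if (k == 2L) {
    prod_sign <- dm[[1L]] * dm[[2L]]
    valid <- prod_sign != 0
    if (!any(valid)) return(NaN)
    sum(prod_sign[valid] > 0) / sum(valid) - 0.5
  } else {
    s1 <- sign(dm[[1L]]); s2 <- sign(dm[[2L]]); s3 <- sign(dm[[3L]])
    valid <- s1 != 0 & s2 != 0 & s3 != 0
    if (!any(valid)) return(NaN)
    same <- s1 == s2 & s2 == s3
    sum(same & valid) / sum(valid) - 0.25
  }
}

#' Manders' colocalization coefficients
#'
#' For two channels, `M1` is the fraction of channel 1's total intensity in
#' pixels selected by channel 2's threshold (and `M2` symmetrically). For
#' three channels, `M1` uses pixels selected by both channels 2 and 3, with
#' `M2`, `M3` cyclic. A zero channel total gives NaN for that coefficient.
#' Thresholds are required (the coefficients are undefined without one).
#'
#' @param cell A 2- or 3-channel [cell_pixels()].
#' @param spec Numeric `fT` per channel in `(0, 1]` (recycled).
#' @return Named numeric vector `M1..Mk`, each in `[0, 1]` or NaN.
#' @export
manders <- function(cell, spec) {
  if (is.null(spec)) stop("Manders' coefficients require a threshold")
  k <- length(cell)
  stopifnot(k %in% c(2L, 3L))
  sels <- .selections(cell, spec)
  m <- numeric(k)
  for (i in seq_len(k)) {
    others <- setdiff(seq_len(k), i)
    sel <- Reduce(intersect, sels[others])
    tot <- sum(cell[[i]])
    m[i] <- if (tot == 0) NaN else sum(cell[[i]][sel]) / tot
  }
  names(m) <- paste0("M", seq_len(k))
  m
}

#' Costes' automatic thresholds for two channels
#'
#' Fits the least-squares line `B = a + b*A` over all in-cell pixels, then
#' scans candidate thresholds `T_A` downward from the highest intensity
#' (sorted unique values of A, or 512 evenly spaced quantiles when there are
#' more), with `T_B = a + b*T_A`. The selected thresholds are the first
#' (highest) pair for which the Pearson correlation of the pixels below both
#' thresholds is <= 0. If the below-threshold correlation never drops to 0
#' (e.g. perfectly correlated channels) the scan descends to the minimum of
#' A and a warning is issued.
#'
#' @param cell A 2-channel [cell_pixels()] with at least 8 pixels and
#'   non-constant channels.
#' @return List with `t1`, `t2` (thresholds for channels 1 and 2),
#'   `converged` (did the below-threshold correlation reach <= 0?), and the
#'   regression `slope`/`intercept`.
#' @export
costes_thresholds <- function(cell) {
  stopifnot(length(cell) == 2L)
  a <- cell[[1L]]; b <- cell[[2L]]
  if (length(a) < 8L) stop("Costes' method needs at least 8 pixels")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("degenerate regression: a channel is constant")
  }
  slope <- stats::cov(a, b) / stats::var(a)
  intercept <- mean(b) - slope * mean(a)
  cand <- sort(unique(a), decreasing = TRUE)
  if (length(cand) > 512L) {
    cand <- sort(unique(stats::quantile(a, probs = seq(1, 0, length.out = 512L),
                                        names = FALSE, type = 7)),
                 decreasing = TRUE)
  }
  for (t_a in cand) {
    t_b <- intercept + slope * t_a
    below <- a < t_a & b < t_b
    if (sum(below) < 2L) next
    r <- .pearson(a[below], b[below])
    if (!is.nan(r) && r <= 0) {
      return(list(t1 = t_a, t2 = t_b, converged = TRUE,
                  slope = slope, intercept = intercept))
    }
  }
  warning("Costes scan reached the minimum intensity without the ",
          "below-threshold correlation dropping to zero")
  t_a <- min(a)
  list(t1 = t_a, t2 = intercept + slope * t_a, converged = FALSE,
       slope = slope, intercept = intercept)
}
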