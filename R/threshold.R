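# Automatic intensity thresholding on a 256-bin histogram.
#
# All methods follow the ImageJ convention: intensities are min-max scaled
# onto 256 bins, the method picks a bin index t (bins <= t are background for
# a dark-background image), and the cutoff is mapped back to raw units as the
# upper edge of bin t. Foreground is strictly above the cutoff on a dark
# background and strictly below it on a light background.

.hist256 <- function(image) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("cannot threshold a constant image")
  idx <- pmin(255L, as.integer(floor((v - lo) / (hi - lo) * 256)))
  counts <- tabulate(idx + 1L, nbins = 256L)
  list(counts = counts, lo = lo, hi = hi)
}

.bin_to_cutoff <- function(t, lo, hi) lo + (t + 1) * (hi - lo) / 256

# Iterative intermeans (IsoData variant; ImageJ's "Default").
.th_default <- function(h) {
  i <- 0:255
  nz <- which(h > 0) - 1L
  t <- floor((min(nz) + max(nz)) / 2)
  repeat {
    lo_i <- i <= t
    w1 <- sum(h[lo_i]); w2 <- sum(h[!lo_i])
    if (w1 == 0) { t <- t + 1L; next }
    if (w2 == 0) { t <- t - 1L; next }
    m1 <- sum(i[lo_i] * h[lo_i]) / w1
    m2 <- sum(i[!lo_i] * h[!lo_i]) / w2
    t_new <- floor((m1 + m2) / 2)
    if (t_new == t) return(t)
    t <- t_new
  }
}

# Otsu: maximize between-class variance; first maximum wins.
.th_otsu <- function(h) {
  i <- 0:255
  total <- sum(h)
  best_t <- -1L; best_v <- -1
  for (t in 0:254) {
    w1 <- sum(h[i <= t]); w2 <- total - w1
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(i[i <= t] * h[i <= t]) / w1
    m2 <- sum(i[i > t] * h[i > t]) / w2
    v <- w1 * w2 * (m1 - m2)^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  if (best_t < 0) stop("cannot threshold a constant image")
  best_t
}

.th_mean <- function(h) {
  i <- 0:255
  as.integer(floor(sum(i * h) / sum(h)))
}

# Kittler & Illingworth minimum-error iterative method.
.th_minerror <- function(h) {
  i <- 0:255
  t <- .th_mean(h)
  A <- function(tt) sum(h[i <= tt])
  B <- function(tt) sum(i[i <= tt] * h[i <= tt])
  C <- function(tt) sum(i[i <= tt]^2 * h[i <= tt])
  total_A <- sum(h); total_B <- sum(i * h); total_C <- sum(i^2 * h)
  for (iter in 1:200) {
    a1 <- A(t); b1 <- B(t); c1 <- C(t)
    a2 <- total_A - a1; b2 <- total_B - b1; c2 <- total_C - c1
    if (a1 == 0 || a2 == 0) break
    mu <- b1 / a1; nu <- b2 / a2
    p <- a1 / total_A; q <- a2 / total_A
    sigma2 <- pmax(c1 / a1 - mu^2, 1e-8)
    tau2 <- pmax(c2 / a2 - nu^2, 1e-8)
    w0 <- 1 / sigma2 - 1 / tau2
    w1 <- mu / sigma2 - nu / tau2
    w2 <- mu^2 / sigma2 - nu^2 / tau2 +
      log((sigma2 * q^2) / (tau2 * p^2))
    disc <- w1^2 - w0 * w2
    if (disc < 0 || w0 == 0) break
    t_new <- as.integer(floor((w1 + sqrt(disc)) / w0))
    if (is.na(t_new) || t_new < 0 || t_new > 255 || t_new == t) break
    t <- t_new
  }
  t
}

# Triangle method (Zack): maximize distance from the peak-to-tail line.
.th_triangle <- function(h) {
  peak <- which.max(h) - 1L
  nz <- which(h > 0) - 1L
  lo <- min(nz); hi <- max(nz)
  # use the longer tail
  if ((peak - lo) >= (hi - peak)) { a <- lo; b <- peak; flip <- TRUE }
  else { a <- peak; b <- hi; flip <- FALSE }
  if (a == b) return(a)
  xs <- a:b
  ha <- h[a + 1L]; hb <- h[b + 1L]
  # distance of (x, h(x)) from the line through (a, h(a))-(b, h(b))
  num <- abs((hb - ha) * (xs - a) - (b - a) * (h[xs + 1L] - ha))
  t <- xs[which.max(num)]
  t
}

.THRESHOLD_REGISTRY <- list(
  Default = .th_default,
  Otsu = .th_otsu,
  Mean = .th_mean,
  MinError = .th_minerror,
  Triangle = .th_triangle
)

#' List available auto-threshold methods
#' @return Character vector of method names accepted by [auto_threshold()].
#' @export
threshold_methods <- function() names(.THRESHOLD_REGISTRY)

#' Compute an automatic intensity threshold
#'
#' Builds a 256-bin histogram of min-max scaled intensities, applies the
#' selected algorithm, and maps the chosen bin back to raw intensity units.
#' Foreground pixels are those strictly above the cutoff on a dark
#' background, strictly below on a light background.
#'
#' @param image Non-constant numeric matrix.
#' @param method One of [threshold_methods()] (`"Default"` is the iterative
#'   intermeans/IsoData variant).
#' @param polarity `"dark_background"`, `"light_background"`, or the list
#'   returned by [detect_background_polarity()].
#' @return Cutoff intensity in raw units (attribute `bin` keeps the 0-255
#'   bin index).
#' @export
auto_threshold <- function(image, method = "Default",
                           polarity = "dark_background") {
  if (is.list(polarity)) polarity <- polarity$value
  polarity <- match.arg(polarity, c("dark_background", "light_background"))
  fn <- .THRESHOLD_REGISTRY[[method]]
  if (is.null(fn)) {
    stop("unknown threshold method '", method, "'; available: ",
         paste(threshold_methods(), collapse = ", "))
  }
  hh <- .hist256(image)
  if (polarity == "dark_background") {
    t <- fn(hh$counts)
    # foreground strictly above the upper edge of bin t
    cutoff <- .bin_to_cutoff(t, hh$lo, hh$hi)
  } else {
    # mirror the histogram so every method sees a dark background, then map
    # the split back; foreground is strictly below the lower edge of the
    # lowest background bin
    t <- 255L - fn(rev(hh$counts))
    cutoff <- hh$lo + t * (hh$hi - hh$lo) / 256
  }
  structure(cutoff, bin = as.integer(t))
}

#' Binarize an image at a cutoff
#'
#' @param image Numeric matrix.
#' @param cutoff Intensity cutoff (e.g. from [auto_threshold()]).
#' @param polarity Background polarity; foreground is above the cutoff on a
#'   dark background, below it on a light background.
#' @return Logical matrix (TRUE = foreground).
#' @export
threshold_mask <- function(image, cutoff, polarity = "dark_background") {
  if (is.list(polarity)) polarity <- polarity$value
  polarity <- match.arg(polarity, c("dark_background", "light_background"))
  if (polarity == "dark_background") image > as.numeric(cutoff)
  else image < as.numeric(cutoff)
}
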