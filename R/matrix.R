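# Metric matrices over the F_T threshold grid, cross-cell aggregation,
# heat maps, and scatterplot data.

#' The F_T threshold grid
#'
#' The step `fT` defines the grid `{fT, 2*fT, ...}` capped at 1; when `fT`
#' does not divide 1 evenly, the remainder becomes the last step so the grid
#' always ends exactly at 1 (e.g. step 0.3 gives 0.3, 0.6, 0.9, 1.0).
#'
#' @param step_fT Fraction in `(0, 1]`.
#' @return Numeric vector of `ceiling(1/step_fT)` thresholds, last = 1.
#' @export
ft_grid <- function(step_fT) {
  if (!is.numeric(step_fT) || length(step_fT) != 1L || is.na(step_fT) ||
      step_fT <= 0 || step_fT > 1) {
    stop("step_fT must be a fraction in (0, 1]")
  }
  k <- floor(1 / step_fT + 1e-9)
  g <- round(step_fT * seq_len(k), 12)
  if (1 - g[k] > 1e-9) g <- c(g, 1) else g[k] <- 1
  g
}

.MATRIX_METRICS <- c("TOS", "PCC", "SRCC", "ICQ", "M1", "M2", "M3")

# evaluate one metric at one threshold combination
.metric_at <- function(cell, metric, fts, scaling, restrict) {
  switch(metric,
         TOS = tos(cell, fts, scaling = scaling),
         PCC = pcc(cell, fts, restrict = restrict),
         SRCC = srcc(cell, fts, restrict = restrict),
         ICQ = icq(cell, fts, restrict = restrict),
         M1 = unname(manders(cell, fts)[1L]),
         M2 = unname(manders(cell, fts)[2L]),
         M3 = unname(manders(cell, fts)[3L]))
}

#' Metric matrix over all threshold combinations
#'
#' Evaluates a colocalization metric at every combination of per-channel
#' `F_T` thresholds on the grid defined by `step_fT` (axis 1 = reporter 1,
#' axis 2 = reporter 2, axis 3 = reporter 3 for three channels). Entries are
#' NaN wherever the metric's contract yields NaN — for TOS that is the whole
#' `fT = 1` row/column, rendered black in the plugin's matrix display.
#'
#' @param cell A [cell_pixels()] with 2 or 3 channels.
#' @param metric One of `"TOS"`, `"PCC"`, `"SRCC"`, `"ICQ"`, `"M1"`, `"M2"`,
#'   `"M3"` (M3 needs 3 channels), or a function
#'   `f(cell, fts)` for a custom metric.
#' @param step_fT Grid step (see [ft_grid()]).
#' @param scaling TOS scaling, `"linear"` or `"log"`.
#' @param restrict Restriction rule for PCC/SRCC/ICQ (see [pcc()]).
#' @return An object of class `metric_matrix`: list with `grid`, `values`
#'   (matrix or 3-D array), `metric`, `scaling`.
#' @export
metric_matrix <- function(cell, metric, step_fT, scaling = "linear",
                          restrict = "intersection") {
  k <- length(cell)
  stopifnot(k %in% c(2L, 3L))
  custom <- is.function(metric)
  metric_name <- if (custom) "custom" else as.character(metric)
  if (!custom && !metric_name %in% .MATRIX_METRICS) {
    stop("unknown metric '", metric_name, "'; available: ",
         paste(.MATRIX_METRICS, collapse = ", "))
  }
  if (!custom && metric_name == "M3" && k != 3L) {
    stop("M3 requires three channels")
  }
  g <- ft_grid(step_fT)
  m <- length(g)
  eval_at <- function(fts) {
    if (custom) metric(cell, fts)
    else .metric_at(cell, metric_name, fts, scaling, restrict)
  }
  if (k == 2L) {
    values <- matrix(NA_real_, m, m, dimnames = list(format(g), format(g)))
    for (i in seq_len(m)) for (j in seq_len(m)) {
      values[i, j] <- eval_at(c(g[i], g[j]))
    }
  } else {
    values <- array(NA_real_, c(m, m, m),
                    dimnames = list(format(g), format(g), format(g)))
    for (i in seq_len(m)) for (j in seq_len(m)) for (l in seq_len(m)) {
      values[i, j, l] <- eval_at(c(g[i], g[j], g[l]))
    }
  }
  structure(list(grid = g, values = values, metric = metric_name,
                 scaling = if (metric_name == "TOS") scaling else "none"),
            class = "metric_matrix")
}

#' @export
print.metric_matrix <- function(x, ...) {
  cat("<metric_matrix> ", x$metric,
      if (x$scaling != "none") paste0(" (", x$scaling, ")"),
      ": ", paste(dim(x$values), collapse = "x"),
      " over F_T grid {", paste(format(x$grid), collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

# mode of values binned to width 0.01 over [-1, 1]; ties -> lower bin;
# reported as the midpoint of the winning bin
.binned_mode <- function(v) {
  idx <- pmin(pmax(floor((v + 1) / 0.01) + 1L, 1L), 200L)
  counts <- tabulate(idx, nbins = 200L)
  win <- which.max(counts)            # which.max takes the first (lower) tie
  -1 + (win - 0.5) * 0.01
}

#' Aggregate per-cell metric matrices
#'
#' Element-wise mean, median or mode across cells; NaN entries are excluded
#' per element, and an element is NaN only when it is NaN in every input.
#' The mode is computed on values binned to width 0.01 over `[-1, 1]`
#' (midpoint of the most populated bin, ties to the lower bin).
#'
#' @param matrices List of `metric_matrix` sharing grid and metric.
#' @param stat `"mean"`, `"median"` or `"mode"`.
#' @return A `metric_matrix` of the aggregated values.
#' @export
aggregate_matrices <- function(matrices, stat = c("mean", "median", "mode")) {
  stat <- match.arg(stat)
  stopifnot(length(matrices) >= 1L)
  first <- matrices[[1L]]
  for (m in matrices) {
    if (!isTRUE(all.equal(m$grid, first$grid)) ||
        !identical(m$metric, first$metric) ||
        !identical(dim(m$values), dim(first$values))) {
      stop("matrices must share grid and metric to be aggregated")
    }
  }
  stacked <- vapply(matrices, function(m) as.numeric(m$values),
                    numeric(length(first$values)))
  if (is.null(dim(stacked))) stacked <- matrix(stacked, nrow = 1L)
  fn <- switch(stat,
               mean = function(v) mean(v),
               median = function(v) stats::median(v),
               mode = .binned_mode)
  agg <- apply(stacked, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NaN else fn(v)
  })
  out <- first
  out$values[] <- agg
  out
}

#' Heat maps of reporter signal with cell/image/stack scaling
#'
#' Rescales in-cell intensities linearly to 0-255 so localization patterns
#' are comparable: `scope = "cell"` rescales each labeled object
#' independently (min of the scope maps to 0, max to 255), `"image"` over
#' all in-cell pixels of one image, `"stack"` over all in-cell pixels of the
#' whole stack. Background pixels are 0; a constant scope maps all its
#' member pixels to 0. Output values are integers, so re-scaling a
#' cell-scoped heat map is the identity.
#'
#' @param stack A reporter `channel_stack`.
#' @param label_maps A `label_map` or list of them, one per stack image.
#' @param scope `"cell"`, `"image"` or `"stack"`.
#' @return List of integer matrices (0-255), one per image.
#' @export
heatmap_rescale <- function(stack, label_maps, scope = c("cell", "image",
                                                         "stack")) {
  scope <- match.arg(scope)
  if (inherits(label_maps, "label_map")) label_maps <- list(label_maps)
  stopifnot(length(label_maps) == length(stack$images))
  rescale <- function(v, lo, hi) {
    if (hi > lo) as.integer(round((v - lo) * 255 / (hi - lo))) else 0L
  }
  out <- vector("list", length(stack$images))
  if (scope == "stack") {
    all_in <- unlist(lapply(seq_along(out), function(i) {
      stack$images[[i]][label_maps[[i]]$labels > 0L]
    }))
    lo <- if (length(all_in)) min(all_in) else 0
    hi <- if (length(all_in)) max(all_in) else 0
  }
  for (i in seq_along(out)) {
    img <- stack$images[[i]]
    lab <- label_maps[[i]]$labels
    stopifnot(identical(dim(img), dim(lab)))
    hm <- matrix(0L, nrow(img), ncol(img))
    if (scope == "cell") {
      for (k in seq_len(label_maps[[i]]$n)) {
        px <- lab == k
        v <- img[px]
        hm[px] <- rescale(v, min(v), max(v))
      }
    } else {
      px <- lab > 0L
      if (any(px)) {
        v <- img[px]
        if (scope == "image") { lo <- min(v); hi <- max(v) }
        hm[px] <- rescale(v, lo, hi)
      }
    }
    out[[i]] <- hm
  }
  out
}

#' Per-pixel intensity tuples for scatterplots
#'
#' One row per in-cell pixel with its intensity in each reporter channel,
#' plus the pixel index — the 2-D or 3-D scatter view of a cell. Costes
#' threshold lines can be attached for plotting.
#'
#' @param cell A [cell_pixels()].
#' @param costes Optional result of [costes_thresholds()]; attached as the
#'   `"costes"` attribute.
#' @return A data frame with column `pixel` then one column per channel.
#' @export
scatterplot_data <- function(cell, costes = NULL) {
  out <- data.frame(pixel = seq_len(attr(cell, "N")))
  for (nm in names(cell)) out[[nm]] <- cell[[nm]]
  if (!is.null(costes)) attr(out, "costes") <- costes
  out
}
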