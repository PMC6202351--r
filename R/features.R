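# Per-object physical and intensity features, and the cell filters.
#
# Physical features come from the cell-identification label map; intensity
# features are computed per reporter channel. The background-ratio filters
# (MeanBgndRatio/MedianBgndRatio) divide an object's mean/median intensity by
# the mean/median of extracellular pixels (label 0) in the same image — the
# tool's own criterion for cells with genuine signal above background.

# polygon area by the shoelace formula (corner coordinates)
.poly_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# crack perimeter: count of exposed 4-neighbor pixel sides (includes holes)
.crack_perimeter <- function(member) {
  h <- nrow(member); w <- ncol(member)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- member
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  sum(core & !pad[1:h, 2:(w + 1L)]) +
    sum(core & !pad[3:(h + 2L), 2:(w + 1L)]) +
    sum(core & !pad[2:(h + 1L), 1:w]) +
    sum(core & !pad[2:(h + 1L), 3:(w + 2L)])
}

# second-moment ellipse fit (ImageJ-style, with the 1/12 pixel-extent term)
.fit_ellipse <- function(rr, cc) {
  a <- length(rr)
  u20 <- sum((cc - mean(cc))^2) / a + 1 / 12
  u02 <- sum((rr - mean(rr))^2) / a + 1 / 12
  u11 <- sum((cc - mean(cc)) * (rr - mean(rr))) / a
  common <- sqrt((u20 - u02)^2 + 4 * u11^2)
  major <- 4 * sqrt((u20 + u02 + common) / 2)
  minor <- 4 * sqrt((u20 + u02 - common) / 2)
  c(major = major, minor = max(minor, 1e-9))
}

#' Compute per-object features
#'
#' One row per labeled object: physical parameters measured on the label map
#' (area, centroid, crack perimeter, circularity `4*pi*A/P^2` clamped to
#' `[0, 1]`, fitted-ellipse aspect ratio and roundness, convex-hull solidity,
#' Feret diameter) and, per reporter channel, mean/median intensity plus the
#' mean/median background ratios. Centroids are 0-based pixel coordinates
#' (`centroid_x` = mean column index). A zero background mean or median
#' makes the corresponding ratio `NaN`.
#'
#' @param lm A [label_map()].
#' @param reporter_stacks List of reporter `channel_stack`s (may be empty);
#'   the image at the label map's `source_image_index` is measured.
#' @return A data frame of class `feature_table`.
#' @export
compute_features <- function(lm, reporter_stacks = list()) {
  if (inherits(reporter_stacks, "channel_stack")) {
    reporter_stacks <- list(reporter_stacks)
  }
  lab <- lm$labels
  h <- nrow(lab); w <- ncol(lab)
  n <- lm$n
  idx <- lm$source_image_index
  out <- data.frame(label = seq_len(n))
  phys <- c("area", "centroid_x", "centroid_y", "perimeter", "circularity",
            "aspect_ratio", "roundness", "solidity", "feret")
  for (f in phys) out[[f]] <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    px <- which(lab == k)
    rr <- (px - 1L) %% h      # 0-based rows
    cc <- (px - 1L) %/% h     # 0-based cols
    a <- length(px)
    out$area[k] <- a
    out$centroid_x[k] <- mean(cc)
    out$centroid_y[k] <- mean(rr)
    member <- lab == k
    p <- .crack_perimeter(member)
    out$perimeter[k] <- p
    out$circularity[k] <- min(1, 4 * pi * a / p^2)
    ell <- .fit_ellipse(rr, cc)
    out$aspect_ratio[k] <- ell[["major"]] / ell[["minor"]]
    out$roundness[k] <- min(1, 4 * a / (pi * ell[["major"]]^2))
    # hull over the 4 corners of each pixel (corner coordinates)
    hx <- c(cc, cc + 1, cc, cc + 1)
    hy <- c(rr, rr, rr + 1, rr + 1)
    hull <- grDevices::chull(hx, hy)
    hull_area <- .poly_area(hx[hull], hy[hull])
    out$solidity[k] <- min(1, a / hull_area)
    d2 <- outer(hx[hull], hx[hull], "-")^2 + outer(hy[hull], hy[hull], "-")^2
    out$feret[k] <- sqrt(max(d2))
  }
  for (rs in reporter_stacks) {
    img <- rs$images[[min(idx, length(rs$images))]]
    stopifnot(identical(dim(img), dim(lab)))
    bg <- img[lab == 0L]
    bg_mean <- if (length(bg)) mean(bg) else 0
    bg_median <- if (length(bg)) stats::median(bg) else 0
    mi <- md <- mr <- dr <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      v <- img[lab == k]
      mi[k] <- mean(v)
      md[k] <- stats::median(v)
      mr[k] <- if (bg_mean == 0) NaN else mi[k] / bg_mean
      dr[k] <- if (bg_median == 0) NaN else md[k] / bg_median
    }
    out[[paste0("mean_intensity.", rs$role)]] <- mi
    out[[paste0("median_intensity.", rs$role)]] <- md
    out[[paste0("mean_bgnd_ratio.", rs$role)]] <- mr
    out[[paste0("median_bgnd_ratio.", rs$role)]] <- dr
  }
  class(out) <- c("feature_table", "data.frame")
  out
}

# filter name -> (column stem, whether a reporter channel is required)
.FILTER_REGISTRY <- list(
  Area = list(column = "area", intensity = FALSE),
  Perimeter = list(column = "perimeter", intensity = FALSE),
  Circularity = list(column = "circularity", intensity = FALSE),
  AspectRatio = list(column = "aspect_ratio", intensity = FALSE),
  Roundness = list(column = "roundness", intensity = FALSE),
  Solidity = list(column = "solidity", intensity = FALSE),
  Feret = list(column = "feret", intensity = FALSE),
  MeanIntensity = list(column = "mean_intensity", intensity = TRUE),
  MedianIntensity = list(column = "median_intensity", intensity = TRUE),
  MeanBgndRatio = list(column = "mean_bgnd_ratio", intensity = TRUE),
  MedianBgndRatio = list(column = "median_bgnd_ratio", intensity = TRUE)
)

#' List available cell-filter parameters
#' @return Character vector of filter names accepted by [filter_spec()].
#' @export
filter_parameters <- function() names(.FILTER_REGISTRY)

#' Define a cell filter
#'
#' A filter retains objects whose feature value lies in `[min, max]`
#' (inclusive both ends). Physical parameters apply to the cell
#' identification channel and carry no reporter channel; signal-intensity
#' parameters apply only to the reporter channel they name.
#'
#' @param parameter One of [filter_parameters()].
#' @param min,max Inclusive bounds (defaults unbounded).
#' @param channel Reporter role (`"reporter1"` ...), required for intensity
#'   parameters and forbidden for physical ones.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(parameter, min = -Inf, max = Inf, channel = NULL) {
  entry <- .FILTER_REGISTRY[[parameter]]
  if (is.null(entry)) {
    stop("unknown filter parameter '", parameter, "'; available: ",
         paste(filter_parameters(), collapse = ", "))
  }
  if (entry$intensity && is.null(channel)) {
    stop("intensity filter '", parameter, "' requires a reporter channel")
  }
  if (!entry$intensity && !is.null(channel)) {
    stop("physical filter '", parameter, "' must not name a channel")
  }
  stopifnot(min <= max)
  structure(list(parameter = parameter, min = min, max = max,
                 channel = channel, column = if (entry$intensity)
                   paste0(entry$column, ".", channel) else entry$column),
            class = "filter_spec")
}

#' Apply cell filters to a feature table
#'
#' An object is retained iff every filter's interval test passes
#' (conjunction; order-independent). `NaN` feature values fail the test for
#' that filter. With no filters, every object is retained.
#'
#' @param features A `feature_table` from [compute_features()].
#' @param specs A `filter_spec` or list of them.
#' @return Integer vector of retained labels.
#' @export
apply_filters <- function(features, specs = list()) {
  if (inherits(specs, "filter_spec")) specs <- list(specs)
  keep <- rep(TRUE, nrow(features))
  for (s in specs) {
    if (!s$column %in% names(features)) {
      stop("filter references feature '", s$column,
           "' absent from the feature table")
    }
    v <- features[[s$column]]
    ok <- !is.na(v) & v >= s$min & v <= s$max
    keep <- keep & ok
  }
  features$label[keep]
}
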