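# Seeded synthetic microscopy fixtures with known colocalization structure.
#
# Generates non-overlapping elliptical "cells" on a noisy background, paints
# 2-3 reporter channels per a chosen localization pattern, and records the
# ground truth — so segmentation, filtering, metrics and the full pipeline
# are testable without real image downloads. All randomness is driven by the
# seed in the config (R's default Mersenne-Twister RNG); rasters are written
# as 16-bit integers, the common acquisition depth.

#' Configuration for the synthetic-image generator
#'
#' Defaults describe a realistic desk-scale field: a 256x256 frame, cells of
#' roughly 200 px (semi-axes 7-9 px), background level 100 with Gaussian
#' noise (sd 10), in-cell base signal well above background, bright/dim
#' structure depending on the pattern.
#'
#' @param size Frame `(height, width)` in pixels.
#' @param n_cells Number of cells to place.
#' @param axes_range Semi-axis range (pixels) of the random ellipses.
#' @param background Extracellular background level (a.u.).
#' @param noise_sd Gaussian noise sd added everywhere (a.u.).
#' @param pattern One of `"correlated"`, `"colocalized_foci"`,
#'   `"anticolocalized_foci"`, `"independent"`, `"nested_organelles"`.
#' @param rho Target per-cell pixel correlation for `"correlated"`.
#' @param channels 2 or 3 reporter channels.
#' @param foci_fraction Fraction of cell pixels forming a focus.
#' @param border_cells Also place one cell touching the frame border?
#' @param seed Integer RNG seed; the generator is deterministic per seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(size = c(256L, 256L), n_cells = 10L,
                         axes_range = c(7, 9), background = 100,
                         noise_sd = 10,
                         pattern = c("correlated", "colocalized_foci",
                                     "anticolocalized_foci", "independent",
                                     "nested_organelles"),
                         rho = 0.8, channels = 2L, foci_fraction = 0.1,
                         border_cells = FALSE, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(length(size) == 2L, n_cells >= 1L, channels %in% c(2L, 3L),
            rho > -1, rho < 1, foci_fraction > 0, foci_fraction <= 0.5)
  max_area <- pi * axes_range[2]^2
  if (n_cells * max_area >= 0.5 * prod(size)) {
    stop("infeasible packing: n_cells x max cell area exceeds half the frame")
  }
  structure(list(size = as.integer(size), n_cells = as.integer(n_cells),
                 axes_range = axes_range, background = background,
                 noise_sd = noise_sd, pattern = pattern, rho = rho,
                 channels = as.integer(channels),
                 foci_fraction = foci_fraction,
                 border_cells = isTRUE(border_cells),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# rasterize one ellipse; returns column-major linear indices
.ellipse_pixels <- function(cy, cx, a, b, theta, h, w) {
  r0 <- max(1L, floor(cy - max(a, b))); r1 <- min(h, ceiling(cy + max(a, b)))
  c0 <- max(1L, floor(cx - max(a, b))); c1 <- min(w, ceiling(cx + max(a, b)))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  u <- (cc - cx) * cos(theta) + (rr - cy) * sin(theta)
  v <- -(cc - cx) * sin(theta) + (rr - cy) * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  (cc[inside] - 1L) * h + rr[inside]
}

#' Generate non-overlapping elliptical cells
#'
#' Seeded rejection placement of random ellipses: none overlap (a 1-pixel
#' moat keeps them from touching) and none touch the border unless
#' `border_cells` is set, in which case one extra border-touching object is
#' added (for border-removal tests). Deterministic per seed.
#'
#' @param cfg A [synth_config()].
#' @return A [label_map()] with `n_cells` labels (plus one border object
#'   when requested).
#' @export
generate_cells <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  h <- cfg$size[1]; w <- cfg$size[2]
  occupied <- matrix(FALSE, h, w)   # cells plus their 1-px moat
  lab <- matrix(0L, h, w)
  placed <- 0L
  margin <- ceiling(cfg$axes_range[2]) + 2L
  attempts <- 0L
  max_attempts <- 400L * cfg$n_cells
  while (placed < cfg$n_cells) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("cell packing failed after ", max_attempts, " attempts")
    }
    cy <- stats::runif(1, margin, h - margin)
    cx <- stats::runif(1, margin, w - margin)
    a <- stats::runif(1, cfg$axes_range[1], cfg$axes_range[2])
    b <- stats::runif(1, cfg$axes_range[1], cfg$axes_range[2])
    theta <- stats::runif(1, 0, pi)
    px <- .ellipse_pixels(cy, cx, a, b, theta, h, w)
    if (length(px) < 4L) next
    moat <- .ellipse_pixels(cy, cx, a + 1.5, b + 1.5, theta, h, w)
    if (any(occupied[moat])) next
    placed <- placed + 1L
    lab[px] <- placed
    occupied[moat] <- TRUE
  }
  if (cfg$border_cells) {
    a <- mean(cfg$axes_range)
    px <- .ellipse_pixels(1, round(w / 2), a, a, 0, h, w)
    px <- px[!occupied[px]]
    if (length(px)) lab[px] <- placed + 1L
  }
  label_map(.renumber_raster(lab))
}

# disjoint focus pixel sets: the n_f pixels nearest each anchor, in order
.focus_sets <- function(rr, cc, n_f, anchors, exclude = integer(0)) {
  sets <- list()
  taken <- exclude
  for (i in seq_len(nrow(anchors))) {
    d <- (rr - anchors[i, 1])^2 + (cc - anchors[i, 2])^2
    ord <- order(d, seq_along(d))
    ord <- ord[!ord %in% taken]
    sel <- ord[seq_len(min(n_f, length(ord)))]
    sets[[i]] <- sel
    taken <- c(taken, sel)
  }
  sets
}

#' Paint reporter channels over a label map
#'
#' Fills the background with `background + N(0, noise_sd)` everywhere, then
#' paints each cell according to the configured pattern:
#' \describe{
#'   \item{correlated}{per-cell pixel pairs (triples) from a multivariate
#'     normal with correlation `rho`, shifted positive and clipped at 0 —
#'     per-cell PCC recovers `rho` up to sampling error.}
#'   \item{colocalized_foci}{one bright focus, identical pixel set in all
#'     channels and strictly brighter than the rest of the cell, sized so
#'     the top-`foci_fraction` selection is exactly the focus: TOS at that
#'     `fT` is +1 by construction.}
#'   \item{anticolocalized_foci}{disjoint foci per channel: TOS at
#'     `fT = foci_fraction` is -1 by construction.}
#'   \item{independent}{channels drawn independently.}
#'   \item{nested_organelles}{channel 2 bright in a ring around channel 1's
#'     focus (channel 3, if present, bright in an outer ring) — overlap at
#'     cell edges only, so the TOS sign flips as `fT` grows.}
#' }
#' Intensities are rounded and clipped to the 16-bit range.
#'
#' @param lm A [label_map()] from [generate_cells()].
#' @param cfg The same [synth_config()].
#' @return List with `stacks` (list of reporter `channel_stack`s), `cell_id`
#'   (a cell-identification `channel_stack`, cells bright on dark), and
#'   `truth` (data frame of per-cell ground truth).
#' @export
paint_reporters <- function(lm, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  h <- nrow(lm$labels); w <- ncol(lm$labels)
  k <- cfg$channels
  base_lvl <- 600; focus_lvl <- 4000; mu <- 3000; sigma <- 500
  chans <- lapply(seq_len(k), function(j) {
    matrix(pmax(0, stats::rnorm(h * w, cfg$background, cfg$noise_sd)), h, w)
  })
  cell_id <- matrix(pmax(0, stats::rnorm(h * w, 50, cfg$noise_sd)), h, w)
  truth <- data.frame(label = integer(0), pattern = character(0),
                      target = numeric(0), area = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0))
  for (ci in seq_len(lm$n)) {
    px <- which(lm$labels == ci)
    n <- length(px)
    rr <- (px - 1L) %% h + 1L
    cc <- (px - 1L) %/% h + 1L
    cell_id[px] <- pmax(0, stats::rnorm(n, 200, cfg$noise_sd))
    n_f <- max(1L, as.integer(round(cfg$foci_fraction * n)))
    target <- NA_real_
    if (cfg$pattern == "correlated") {
      z0 <- stats::rnorm(n)
      vals <- lapply(seq_len(k), function(j) {
        # equicorrelated factor construction: pairwise correlation = rho
        z <- sqrt(abs(cfg$rho)) * z0 +
          sqrt(1 - abs(cfg$rho)) * stats::rnorm(n)
        if (cfg$rho < 0 && j == 2L) z <- -z
        pmax(0, mu + sigma * z)
      })
      for (j in seq_len(k)) chans[[j]][px] <- vals[[j]]
      target <- cfg$rho
    } else if (cfg$pattern == "independent") {
      for (j in seq_len(k)) {
        chans[[j]][px] <- pmax(0, stats::rnorm(n, mu, sigma))
      }
      target <- 0
    } else if (cfg$pattern == "colocalized_foci") {
      anchor <- cbind(rr[which.min((rr - mean(rr))^2 + (cc - mean(cc))^2)],
                      cc[which.min((rr - mean(rr))^2 + (cc - mean(cc))^2)])
      f <- .focus_sets(rr, cc, n_f, anchor)[[1L]]
      for (j in seq_len(k)) {
        v <- base_lvl + stats::runif(n, -100, 100)
        v[f] <- focus_lvl + stats::runif(length(f), -100, 100)
        chans[[j]][px] <- v
      }
      target <- 1
    } else if (cfg$pattern == "anticolocalized_foci") {
      # anchors at opposite ends of the cell
      i1 <- which.min(rr * w + cc); i2 <- which.max(rr * w + cc)
      sets <- .focus_sets(rr, cc, n_f,
                          rbind(c(rr[i1], cc[i1]), c(rr[i2], cc[i2]),
                                c(rr[which.min(cc)], cc[which.min(cc)])))
      for (j in seq_len(k)) {
        v <- base_lvl + stats::runif(n, -100, 100)
        f <- sets[[j]]
        v[f] <- focus_lvl + stats::runif(length(f), -100, 100)
        chans[[j]][px] <- v
      }
      target <- -1
    } else if (cfg$pattern == "nested_organelles") {
      # concentric structures: channel 1 bright at the center, channel 2 in
      # a ring around it (channel 3 in the next ring); every channel is
      # dimmest in the same outer zone, as reporter signal drops toward the
      # cell periphery. Tight thresholds select disjoint structures
      # (anticolocalization); loose thresholds exclude the shared outer
      # zone, so the selections overlap (colocalization) - the sign of TOS
      # flips with F_T.
      d <- (rr - mean(rr))^2 + (cc - mean(cc))^2
      ord <- order(d, seq_along(d))
      f1 <- ord[seq_len(min(n_f, n))]
      f2 <- setdiff(ord[seq_len(min(2L * n_f, n))], f1)
      f3 <- setdiff(ord[seq_len(min(3L * n_f, n))], c(f1, f2))
      outer_zone <- ord[seq.int(max(1L, n - n_f + 1L), n)]
      sets <- list(f1, f2, if (length(f3)) f3 else f2)
      for (j in seq_len(k)) {
        v <- base_lvl + stats::runif(n, -50, 50)
        f <- sets[[j]]
        if (length(f)) v[f] <- focus_lvl + stats::runif(length(f), -50, 50)
        v[outer_zone] <- 300 + stats::runif(length(outer_zone), -50, 50)
        chans[[j]][px] <- v
      }
      target <- 0
    }
    truth <- rbind(truth, data.frame(
      label = ci, pattern = cfg$pattern, target = target, area = n,
      centroid_x = mean(cc - 1L), centroid_y = mean(rr - 1L)))
  }
  clip16 <- function(m) matrix(pmin(65535, pmax(0, round(m))), nrow(m))
  stacks <- lapply(seq_len(k), function(j) {
    channel_stack(clip16(chans[[j]]), role = paste0("reporter", j),
                  bit_depth = 16L)
  })
  list(stacks = stacks,
       cell_id = channel_stack(clip16(cell_id), role = "cell_id",
                               bit_depth = 16L),
       truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' TIFF per channel (cell identification + reporters), a 16-bit label TIFF,
#' an ImageJ `RoiSet.zip` of the true outlines, and the ground-truth CSV —
#' directly consumable by [run_analysis()].
#'
#' @param painted Result of [paint_reporters()].
#' @param lm The [label_map()] the reporters were painted on.
#' @param out_dir Output directory.
#' @return Invisible named list of file paths.
#' @export
write_dataset <- function(painted, lm, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  p <- file.path(out_dir, "cellid.tif")
  write_tiff(painted$cell_id$images[[1L]], p, bit_depth = 16L)
  files$cell_id <- p
  for (j in seq_along(painted$stacks)) {
    p <- file.path(out_dir, sprintf("reporter%d.tif", j))
    write_tiff(painted$stacks[[j]]$images[[1L]], p, bit_depth = 16L)
    files[[paste0("reporter", j)]] <- p
  }
  p <- file.path(out_dir, "labels.tif")
  write_tiff(lm$labels, p, bit_depth = 16L)
  files$labels <- p
  p <- file.path(out_dir, "RoiSet.zip")
  write_roi_set(trace_outlines(lm), p)
  files$rois <- p
  p <- file.path(out_dir, "truth.csv")
  utils::write.csv(painted$truth, p, row.names = FALSE)
  files$truth <- p
  invisible(files)
}
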