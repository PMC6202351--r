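# Per-cell data table, summary, histogram, mask/ROI export, and the
# full analysis pipeline driver.

#' Build the per-cell data table
#'
#' One record per retained cell: the label text `"image:cellnumber"`, the
#' physical features, per-channel mean intensities, and the metric values.
#' A metric missing for a cell is recorded as NaN (the table convention for
#' a value that could not be calculated).
#'
#' @param features A `feature_table` (or list of them, one per image).
#' @param metrics Named list: metric name -> numeric vector with one value
#'   per feature row (or list of such lists, parallel to `features`).
#' @param image_names Image name(s) used in the label text.
#' @param retained Optional list of retained label vectors per image
#'   (default: all rows).
#' @return A data frame of class `cell_table`.
#' @export
build_cell_table <- function(features, metrics = list(),
                             image_names = NULL, retained = NULL) {
  if (inherits(features, "data.frame")) {
    features <- list(features)
    metrics <- list(metrics)
    if (!is.null(retained)) retained <- list(retained)
  }
  n_img <- length(features)
  if (is.null(image_names)) image_names <- as.character(seq_len(n_img))
  rows <- list()
  for (i in seq_len(n_img)) {
    ft <- features[[i]]
    keep <- if (is.null(retained)) ft$label else
      ft$label[ft$label %in% retained[[i]]]
    if (!length(keep)) next
    sub <- ft[match(keep, ft$label), , drop = FALSE]
    rec <- data.frame(label = paste0(image_names[i], ":", sub$label),
                      stringsAsFactors = FALSE)
    for (col in setdiff(names(sub), "label")) rec[[col]] <- sub[[col]]
    mt <- if (length(metrics) >= i) metrics[[i]] else list()
    for (mn in names(mt)) {
      v <- mt[[mn]]
      rec[[mn]] <- if (is.null(v)) NaN else {
        vv <- v[match(keep, ft$label)]
        ifelse(is.na(vv), NaN, vv)
      }
    }
    rows[[length(rows) + 1L]] <- rec
  }
  if (!length(rows)) {
    out <- data.frame(label = character(0))
  } else {
    cols <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) {
      for (m in setdiff(cols, names(r))) r[[m]] <- NaN
      r[cols]
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Write a cell table (or any data frame) as CSV with literal NaN
#'
#' The data-table convention: a value that could not be calculated is
#' serialized as the string `NaN`, never as an empty field or `NA`.
#'
#' @param tab Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, na = "NaN")
  invisible(path)
}

#' Summary statistics for one metric
#'
#' Count, mean, median and sample standard deviation (n-1 denominator; NaN
#' for a single value) over the finite values of the selected metric; the
#' count is the number of cells with a finite value.
#'
#' @param records A `cell_table` or numeric vector.
#' @param metric Column name when `records` is a table.
#' @return List with `count`, `mean`, `median`, `stddev`.
#' @export
summarize_metric <- function(records, metric = NULL) {
  v <- if (is.data.frame(records)) {
    if (is.null(metric) || !metric %in% names(records)) {
      stop("metric column '", metric, "' not found")
    }
    records[[metric]]
  } else {
    as.numeric(records)
  }
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite values to summarize")
  sdv <- if (length(v) > 1L) stats::sd(v) else NaN
  list(count = length(v), mean = mean(v), median = stats::median(v),
       stddev = sdv)
}

#' Histogram of metric values
#'
#' Equal-width bins spanning `[min, max]` of the finite values. Bins are
#' left-open/right-closed with the first bin closed at the minimum, so the
#' maximum falls in the last bin. The mode is the midpoint of the most
#' populated bin (ties to the lower bin). Constant input degenerates to a
#' single occupied bin of width 0.
#'
#' @param values Numeric vector (NaN/NA excluded).
#' @param bins Number of bins (>= 1); default 50.
#' @return List with `counts`, `count`, `mean`, `stddev`, `bins`, `min`,
#'   `max`, `mode`, `bin_width`.
#' @export
metric_histogram <- function(values, bins = 50L) {
  stopifnot(bins >= 1L)
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values to histogram")
  lo <- min(v); hi <- max(v)
  width <- (hi - lo) / bins
  if (width == 0) {
    counts <- c(length(v), rep(0L, bins - 1L))
    mode <- lo
  } else {
    idx <- ceiling((v - lo) / width)
    idx[idx < 1L] <- 1L               # the minimum belongs to the first bin
    idx[idx > bins] <- bins
    counts <- tabulate(idx, nbins = bins)
    mode <- lo + (which.max(counts) - 0.5) * width
  }
  list(counts = counts, count = length(v), mean = mean(v),
       stddev = if (length(v) > 1L) stats::sd(v) else NaN,
       bins = as.integer(bins), min = lo, max = hi, mode = mode,
       bin_width = width)
}

#' Export binary masks and ImageJ ROI sets for re-analysis
#'
#' For each label map, writes an 8-bit binary mask TIFF (255 = in-cell) and
#' an ImageJ-compatible `RoiSet.zip` of traced cell outlines. Re-importing
#' the ROI set with [load_roi_set()] + [rois_to_labelmap()] reproduces the
#' identical per-cell pixel sets (objects without holes), so the same cells
#' can be re-analyzed later.
#'
#' @param label_maps A `label_map` or list of them.
#' @param out_dir Output directory (created if needed).
#' @param basenames File name stems, one per label map.
#' @return Invisible character vector of files written.
#' @export
export_masks_and_rois <- function(label_maps, out_dir,
                                  basenames = NULL) {
  if (inherits(label_maps, "label_map")) label_maps <- list(label_maps)
  if (is.null(basenames)) {
    basenames <- sprintf("image%03d", seq_along(label_maps))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (i in seq_along(label_maps)) {
    lm <- label_maps[[i]]
    mask_path <- file.path(out_dir, paste0(basenames[i], "_mask.tif"))
    mask <- matrix(0, nrow(lm$labels), ncol(lm$labels))
    mask[lm$labels > 0L] <- 255
    write_tiff(mask, mask_path, bit_depth = 8L)
    roi_path <- file.path(out_dir, paste0(basenames[i], "_RoiSet.zip"))
    if (lm$n == 0L) {
      warning("label map ", i, " is empty; writing empty ROI set")
      write_roi_set(list(), roi_path)
    } else {
      write_roi_set(trace_outlines(lm), roi_path,
                    names = sprintf("%04d", seq_len(lm$n)))
    }
    files <- c(files, mask_path, roi_path)
  }
  invisible(files)
}

#' Read a flat key=value config file
#'
#' Lines of `key = value`; `#` starts a comment; values holding several
#' items are comma-separated. Returns a named list of character values that
#' [run_analysis()] coerces as needed.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", ln)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (grepl(",", val, fixed = TRUE)) val <- trimws(strsplit(val, ",")[[1L]])
    out[[key]] <- val
  }
  out
}

.as_flag <- function(x, default = FALSE) {
  if (is.null(x)) return(default)
  if (is.logical(x)) return(isTRUE(x))
  tolower(as.character(x)) %in% c("true", "yes", "1", "on")
}

# parse "Name[:channel]=min,max" filter strings from config/CLI
.parse_filter_string <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z]+)(:([A-Za-z0-9]+))?=([^,]+),(.+)$",
                             s))[[1L]]
  if (!length(m)) stop("malformed filter '", s,
                       "'; expected Name[:channel]=min,max")
  ch <- if (nzchar(m[4L])) m[4L] else NULL
  filter_spec(m[2L], min = as.numeric(m[5L]), max = as.numeric(m[6L]),
              channel = ch)
}

#' Run the full colocalization analysis pipeline
#'
#' Drives the four-stage workflow — inputs, cell identification and filters,
#' visualization, analysis — over image stacks: optional alignment,
#' thresholding/segmentation (or ROI-based cell identification), border
#' removal, feature computation, cell filters, per-cell metrics, and the
#' requested outputs (cell table CSV, summary, histogram, aggregated metric
#' matrix, heat maps, masks/ROI sets, decision log). Deterministic given the
#' same config.
#'
#' @param config Named list or path to a key=value config file. Recognized
#'   keys: `cell_images`, `reporter1_images`, `reporter2_images`,
#'   `reporter3_images` (TIFF paths, comma-separated); or in-memory stacks
#'   via `cell_stack`, `reporter_stacks`; `roi_set` (path, optional);
#'   `align` (flag), `max_shift`, `background` (auto/dark/light),
#'   `threshold_method`, `manual_threshold`, `watershed` (flag),
#'   `prewatershed_max_area`, `filters` (strings `Name[:channel]=min,max`
#'   or `filter_spec` list), `metrics` (default `pcc,srcc,icq,tos,manders`;
#'   3 reporters restrict to `icq,tos,manders`), `ft` (default 0.1),
#'   `scaling` (TOS), `costes` (flag: Costes thresholds per cell),
#'   `matrix_metric`, `matrix_stat` (mean/median/mode), `step_ft`,
#'   `heatmap_scope`, `bins`, `out_dir`, `custom_metric` (function
#'   `f(cell, fts)`, in-memory configs only).
#' @return Invisibly, a list with `cell_table`, `summary`, `histogram`,
#'   `matrix`, `heatmaps`, `label_maps`, `features`, `log`, and `files`
#'   (paths written when `out_dir` is set).
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  cfg <- config
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  # ---- inputs -------------------------------------------------------------
  cell_stack <- if (!is.null(cfg$cell_stack)) cfg$cell_stack else
    load_channel_stack(cfg$cell_images, role = "cell_id")
  reporters <- if (!is.null(cfg$reporter_stacks)) cfg$reporter_stacks else {
    rs <- list()
    for (r in c("reporter1", "reporter2", "reporter3")) {
      key <- paste0(r, "_images")
      if (!is.null(cfg[[key]])) {
        rs[[length(rs) + 1L]] <- load_channel_stack(cfg[[key]], role = r)
      }
    }
    rs
  }
  k <- length(reporters)
  if (k < 1L) stop("at least one reporter channel is required")
  n_img <- length(cell_stack$images)
  note("inputs: ", n_img, " image(s), ", k, " reporter channel(s)")

  background <- if (is.null(cfg$background)) "auto" else cfg$background
  threshold_method <- if (is.null(cfg$threshold_method)) "Default" else
    cfg$threshold_method

  # ---- alignment ----------------------------------------------------------
  if (.as_flag(cfg$align)) {
    max_shift <- if (is.null(cfg$max_shift)) 20L else
      as.integer(cfg$max_shift)
    al <- align_stacks(cell_stack, reporters,
                       threshold_method = threshold_method,
                       max_shift = max_shift, background = background)
    reporters <- al$reporters
    for (j in seq_along(al$shifts)) {
      sh <- al$shifts[[j]]
      note("alignment reporter ", j, ": ",
           paste(sprintf("image %d -> (dy=%d, dx=%d)", sh$image, sh$dy,
                         sh$dx), collapse = "; "))
    }
  }

  # ---- cell identification + filters --------------------------------------
  specs <- cfg$filters
  if (is.character(specs)) {
    # a config file splits values on commas, severing "Area=10,500";
    # re-join and extract each Name[:channel]=min,max unit
    collapsed <- paste(specs, collapse = ",")
    units <- regmatches(collapsed,
                        gregexpr("[A-Za-z]+(:[A-Za-z0-9]+)?=[-+0-9.eEInf]+,[-+0-9.eEInf]+",
                                 collapsed))[[1L]]
    if (!length(units)) stop("no parseable filters in '", collapsed, "'")
    specs <- lapply(units, .parse_filter_string)
  }
  if (inherits(specs, "filter_spec")) specs <- list(specs)
  if (is.null(specs)) specs <- list()

  label_maps <- vector("list", n_img)
  features <- vector("list", n_img)
  retained <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    img <- cell_stack$images[[i]]
    pol <- if (background == "auto") {
      detect_background_polarity(img)$value
    } else paste0(background, "_background")
    lm <- if (!is.null(cfg$roi_set)) {
      rois <- if (inherits(cfg$roi_set, "roi_set")) cfg$roi_set else
        load_roi_set(cfg$roi_set, dim(img))
      lm0 <- rois_to_labelmap(rois, dim(img))
      lm0$source_image_index <- i
      note("image ", i, ": ", lm0$n, " cell(s) from ROI set")
      lm0
    } else {
      cutoff <- if (!is.null(cfg$manual_threshold)) {
        as.numeric(cfg$manual_threshold)
      } else {
        auto_threshold(img, method = threshold_method, polarity = pol)
      }
      note("image ", i, ": threshold ", format(as.numeric(cutoff)),
           " (", if (!is.null(cfg$manual_threshold)) "manual" else
             threshold_method, ", ", pol, ")")
      segment_cells(img, cutoff, polarity = pol,
                    use_watershed = .as_flag(cfg$watershed),
                    prewatershed_max_area =
                      if (is.null(cfg$prewatershed_max_area)) NULL else
                        as.numeric(cfg$prewatershed_max_area),
                    source_image_index = i)
    }
    n_before <- lm$n
    lm <- remove_border_objects(lm)
    if (lm$n < n_before) {
      note("image ", i, ": removed ", n_before - lm$n,
           " border-touching object(s)")
    }
    ft <- compute_features(lm, reporters)
    kept <- apply_filters(ft, specs)
    for (dropped in setdiff(ft$label, kept)) {
      fails <- vapply(specs, function(s) {
        v <- ft[[s$column]][ft$label == dropped]
        is.na(v) || v < s$min || v > s$max
      }, logical(1))
      note("image ", i, ": cell ", dropped, " dropped by filter ",
           paste(vapply(specs[fails], function(s) s$parameter, character(1)),
                 collapse = "+"))
    }
    label_maps[[i]] <- lm
    features[[i]] <- ft
    retained[[i]] <- kept
  }

  # ---- metrics ------------------------------------------------------------
  default_metrics <- if (k == 3L) c("icq", "tos", "manders") else
    c("pcc", "srcc", "icq", "tos", "manders")
  wanted <- if (is.null(cfg$metrics)) default_metrics else
    tolower(cfg$metrics)
  if (k == 3L) {
    bad <- setdiff(wanted, c("icq", "tos", "manders", "custom"))
    if (length(bad)) {
      note("metrics ", paste(bad, collapse = ","),
           " unavailable for 3 reporters; dropped")
      wanted <- setdiff(wanted, bad)
    }
  }
  ft_val <- if (is.null(cfg$ft)) 0.1 else as.numeric(cfg$ft)
  scaling <- if (is.null(cfg$scaling)) "linear" else cfg$scaling
  use_costes <- .as_flag(cfg$costes)

  metric_values <- vector("list", n_img)
  cells_by_image <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    lm <- label_maps[[i]]
    cells <- extract_cell_pixels(lm, reporters)
    cells_by_image[[i]] <- cells
    vals <- list()
    nlab <- lm$n
    spec_for <- function(cell) {
      if (use_costes && k == 2L) {
        ct <- suppressWarnings(
          tryCatch(costes_thresholds(cell), error = function(e) NULL))
        if (is.null(ct)) return(rep(ft_val, k))
        # convert intensity thresholds to the fractions above them
        n <- attr(cell, "N")
        pmin(1, pmax(1 / n, c(mean(cell[[1L]] >= ct$t1),
                              mean(cell[[2L]] >= ct$t2))))
      } else rep(ft_val, k)
    }
    get_metric <- function(fn) {
      vapply(seq_len(nlab), function(ci) {
        cell <- cells[[ci]]
        tryCatch(fn(cell), error = function(e) NaN)
      }, numeric(1))
    }
    # PCC/SRCC/ICQ take a threshold only on request (or with Costes);
    # TOS and Manders always need one
    corr_spec <- if (use_costes || .as_flag(cfg$threshold_correlation)) {
      spec_for
    } else {
      function(cell) NULL
    }
    for (m in wanted) {
      if (m == "pcc") vals$pcc <- get_metric(function(cl)
        pcc(cl, spec = corr_spec(cl)))
      if (m == "srcc") vals$srcc <- get_metric(function(cl)
        srcc(cl, spec = corr_spec(cl)))
      if (m == "icq") vals$icq <- get_metric(function(cl)
        icq(cl, spec = corr_spec(cl)))
      if (m == "tos") vals$tos <- get_metric(function(cl)
        tos(cl, spec_for(cl), scaling = scaling))
      if (m == "manders") {
        mm <- lapply(seq_len(nlab), function(ci) {
          tryCatch(manders(cells[[ci]], spec_for(cells[[ci]])),
                   error = function(e) rep(NaN, k))
        })
        for (j in seq_len(k)) {
          vals[[paste0("m", j)]] <- vapply(mm, `[[`, numeric(1), j)
        }
      }
    }
    if (!is.null(cfg$custom_metric) && is.function(cfg$custom_metric)) {
      vals$custom <- get_metric(function(cl)
        cfg$custom_metric(cl, spec_for(cl)))
    }
    metric_values[[i]] <- vals
  }

  image_names <- if (!is.null(cfg$image_names)) cfg$image_names else
    paste0("image", seq_len(n_img))
  cell_table <- build_cell_table(features, metric_values,
                                 image_names = image_names,
                                 retained = retained)

  # ---- summary / histogram ------------------------------------------------
  summary_metric <- if (!is.null(cfg$summary_metric)) {
    tolower(cfg$summary_metric)
  } else {
    cand <- intersect(c("tos", "pcc", "icq", "m1"), names(cell_table))
    if (length(cand)) cand[1L] else NULL
  }
  summary_report <- NULL
  histogram_report <- NULL
  if (!is.null(summary_metric) && summary_metric %in% names(cell_table) &&
      any(is.finite(cell_table[[summary_metric]]))) {
    summary_report <- summarize_metric(cell_table, summary_metric)
    bins <- if (is.null(cfg$bins)) 50L else as.integer(cfg$bins)
    histogram_report <- metric_histogram(cell_table[[summary_metric]], bins)
  }

  # ---- metric matrix ------------------------------------------------------
  matrix_report <- NULL
  if (!is.null(cfg$matrix_metric)) {
    step <- if (is.null(cfg$step_ft)) ft_val else as.numeric(cfg$step_ft)
    stat <- if (is.null(cfg$matrix_stat)) "median" else cfg$matrix_stat
    per_cell <- list()
    for (i in seq_len(n_img)) {
      for (ci in which(features[[i]]$label %in% retained[[i]])) {
        per_cell[[length(per_cell) + 1L]] <-
          metric_matrix(cells_by_image[[i]][[ci]],
                        toupper(cfg$matrix_metric), step, scaling = scaling)
      }
    }
    if (length(per_cell)) {
      matrix_report <- aggregate_matrices(per_cell, stat = stat)
    }
  }

  # ---- heat maps ----------------------------------------------------------
  heatmaps <- NULL
  if (!is.null(cfg$heatmap_scope)) {
    heatmaps <- lapply(reporters, heatmap_rescale, label_maps = label_maps,
                       scope = cfg$heatmap_scope)
    names(heatmaps) <- vapply(reporters, `[[`, character(1), "role")
  }

  # ---- outputs ------------------------------------------------------------
  files <- character(0)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, "cells.csv")
    write_cell_table(cell_table, p)
    files <- c(files, p)
    if (!is.null(summary_report)) {
      p <- file.path(out_dir, "summary.txt")
      writeLines(c(paste0("metric: ", summary_metric),
                   paste0("count: ", summary_report$count),
                   paste0("mean: ", format(summary_report$mean)),
                   paste0("median: ", format(summary_report$median)),
                   paste0("stddev: ", format(summary_report$stddev))), p)
      files <- c(files, p)
    }
    if (!is.null(matrix_report)) {
      p <- file.path(out_dir, "matrix.csv")
      if (length(dim(matrix_report$values)) == 2L) {
        utils::write.csv(matrix_report$values, p, row.names = TRUE,
                         na = "NaN")
      } else {
        long <- expand.grid(fT1 = matrix_report$grid,
                            fT2 = matrix_report$grid,
                            fT3 = matrix_report$grid)
        long$value <- as.numeric(matrix_report$values[
          cbind(match(long$fT1, matrix_report$grid),
                match(long$fT2, matrix_report$grid),
                match(long$fT3, matrix_report$grid))])
        utils::write.csv(long, p, row.names = FALSE, na = "NaN")
      }
      files <- c(files, p)
    }
    if (!is.null(heatmaps)) {
      for (nm in names(heatmaps)) {
        p <- file.path(out_dir, paste0("heatmap_", nm, ".tif"))
        write_tiff(heatmaps[[nm]], p, bit_depth = 8L)
        files <- c(files, p)
      }
    }
    files <- c(files, export_masks_and_rois(label_maps, out_dir,
                                            basenames = image_names))
    p <- file.path(out_dir, "analysis.log")
    writeLines(log_lines, p)
    files <- c(files, p)
  }

  invisible(list(cell_table = cell_table, summary = summary_report,
                 histogram = histogram_report, matrix = matrix_report,
                 heatmaps = heatmaps, label_maps = label_maps,
                 features = features, retained = retained,
                 log = log_lines, files = files))
}
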