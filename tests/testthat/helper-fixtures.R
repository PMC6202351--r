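# Shared fixture builders. Everything is generated in code: no binary files.

# filled disc mask
disc_mask <- function(h, w, cy, cx, r) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - cy)^2 + (cc - cx)^2 <= r^2
}

# two touching discs of radius 10 with centers 15 px apart
touching_discs <- function() {
  disc_mask(40, 60, 20, 20, 10) | disc_mask(40, 60, 20, 35, 10)
}

# bimodal test image: n_lo pixels at lo, n_hi at hi
bimodal_image <- function(n_lo = 100, n_hi = 100, lo = 10, hi = 200) {
  v <- c(rep(lo, n_lo), rep(hi, n_hi))
  n <- length(v)
  h <- floor(sqrt(n))
  while (n %% h != 0) h <- h - 1
  matrix(v, h, n / h)
}

# hand-built RGB TIFF (SamplesPerPixel 3, Photometric 2) for rejection tests
write_rgb_tiff <- function(path, w = 2L, h = 2L) {
  le16 <- function(v) as.raw(c(v %% 256L, v %/% 256L))
  le32 <- function(v) {
    b0 <- v %% 256; v <- v %/% 256; b1 <- v %% 256; v <- v %/% 256
    as.raw(c(b0, b1, v %% 256, v %/% 256))
  }
  entry <- function(tag, type, count, value) {
    c(le16(tag), le16(type), le32(count), le32(value))
  }
  px <- as.raw(rep(c(255L, 0L, 0L), w * h))   # solid red
  n_entries <- 8L
  ifd_off <- 8L + length(px)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(le16(42L), le32(ifd_off)), con)
  writeBin(px, con)
  writeBin(c(le16(n_entries),
             entry(256L, 4L, 1L, w), entry(257L, 4L, 1L, h),
             entry(258L, 3L, 1L, 8L), entry(259L, 3L, 1L, 1L),
             entry(262L, 3L, 1L, 2L), entry(273L, 4L, 1L, 8L),
             entry(277L, 3L, 1L, 3L), entry(279L, 4L, 1L, length(px)),
             le32(0L)), con)
  invisible(path)
}

# brute-force TOS oracle: explicit top-n selection by sorting index pairs,
# explicit set intersection, and the branch formulas applied to counted sets
tos_oracle <- function(a, b, ft1, ft2) {
  n <- length(a)
  top_n <- function(v, ft) {
    ns <- max(1L, round(ft * n))
    ranked <- order(v, -seq_along(v), decreasing = TRUE)
    ranked[seq_len(ns)]
  }
  s1 <- top_n(a, ft1); s2 <- top_n(b, ft2)
  a_o <- sum(s1 %in% s2) / n
  f1 <- length(s1) / n; f2 <- length(s2) / n
  a_e <- f1 * f2; a_max <- min(f1, f2); a_min <- max(0, f1 + f2 - 1)
  if (a_o >= a_e) {
    if (a_max == a_e) NaN else (a_o - a_e) / (a_max - a_e)
  } else {
    if (a_e == a_min) NaN else (a_o - a_e) / (a_e - a_min)
  }
}

# small seeded synthetic dataset on disk, returning the config for analyze
make_synth_dataset <- function(dir, pattern = "correlated", n_cells = 6L,
                               seed = 11L, channels = 2L, rho = 0.8) {
  cfg <- synth_config(size = c(192L, 192L), n_cells = n_cells,
                      pattern = pattern, rho = rho, channels = channels,
                      seed = seed)
  lm <- generate_cells(cfg)
  pr <- paint_reporters(lm, cfg)
  write_dataset(pr, lm, dir)
  list(cfg = cfg, lm = lm, painted = pr, dir = dir)
}
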