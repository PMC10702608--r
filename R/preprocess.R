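# Fundus preprocessing: NTSC grayscale conversion, gamma correction, and
# contrast-limited adaptive histogram equalisation (CLAHE), with an optional
# crop to the field-of-view bounding box. Intensities are real in [0, 1]
# internally; 8-bit quantisation happens only at file I/O and inside CLAHE.

#' Preprocessing configuration
#'
#' @param gamma Gamma value; the correction applied is `out = in^(1/gamma)`,
#'   so gamma > 1 brightens dark regions (default 1.2).
#' @param clahe_clip_limit CLAHE clip limit (default 2).
#' @param clahe_tile_grid Integer pair: CLAHE tile grid (default 8 x 8).
#' @param crop_to_fov Crop to the field-of-view bounding box first?
#' @param apply_clahe Apply the CLAHE stage? (disable to bypass).
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(gamma = 1.2, clahe_clip_limit = 2,
                              clahe_tile_grid = c(8L, 8L),
                              crop_to_fov = TRUE, apply_clahe = TRUE) {
  if (gamma <= 0) stop("gamma must be positive")
  if (any(clahe_tile_grid < 1)) stop("tile grid dims must be >= 1")
  structure(list(gamma = gamma, clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 crop_to_fov = isTRUE(crop_to_fov),
                 apply_clahe = isTRUE(apply_clahe)),
            class = "preprocess_config")
}

#' NTSC grayscale conversion
#'
#' `Gray = 0.299 R + 0.587 G + 0.114 B`, rescaled to `[0, 1]`. The heavy
#' green weight matches the fact that retinal vessels carry most contrast in
#' the green channel.
#'
#' @param img Integer/numeric array `(H, W, 3)` with values in `[0, 255]`,
#'   channel order R, G, B.
#' @return Numeric matrix `(H, W)` in `[0, 1]`.
#' @examples
#' rgb_to_gray(array(c(200, 100, 50), c(1, 1, 3))) # 124.2 / 255
#' @export
rgb_to_gray <- function(img) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected an (H, W, 3) RGB array")
  g <- (0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]) / 255
  g <- pmin(pmax(g, 0), 1)
  dim(g) <- d[1:2] # keep matrix shape even for 1-pixel images
  g
}

#' Gamma correction
#'
#' Power-law remap `out = in^(1/gamma)`; gamma > 1 lifts dark intensities,
#' making dark retinal structure more visible.
#'
#' @param img Numeric raster in `[0, 1]`.
#' @param cfg A [preprocess_config()] (only `gamma` is used), or a number.
#' @return Raster of the same shape in `[0, 1]`.
#' @export
gamma_correct <- function(img, cfg = preprocess_config()) {
  gamma <- if (is.numeric(cfg)) cfg else cfg$gamma
  if (gamma <= 0) stop("gamma must be positive")
  img^(1 / gamma)
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Applies CLAHE (through EBImage) on the 8-bit quantisation of the input and
#' rescales back to `[0, 1]`. A constant image is returned unchanged (flat
#' histogram). Tile counts are reduced automatically on images too small for
#' the requested grid (tiles are kept at least 8 pixels wide).
#'
#' @param img Numeric matrix `(H, W)` in `[0, 1]`.
#' @param cfg A [preprocess_config()].
#' @return Matrix of the same shape in `[0, 1]`.
#' @export
clahe_enhance <- function(img, cfg = preprocess_config()) {
  rng <- range(img)
  if (diff(rng) == 0) return(img)
  q <- round(img * 255) / 255
  if (diff(range(q)) == 0) return(img)
  nx <- max(1L, min(cfg$clahe_tile_grid[2], floor(ncol(img) / 8)))
  ny <- max(1L, min(cfg$clahe_tile_grid[1], floor(nrow(img) / 8)))
  # the equaliser needs dimensions divisible by the tile counts:
  # reflect-pad to the next multiple, equalise, crop back
  H <- nrow(q); W <- ncol(q)
  H2 <- as.integer(ceiling(H / ny) * ny)
  W2 <- as.integer(ceiling(W / nx) * nx)
  if (H2 != H || W2 != W) {
    q <- q[rep(c(seq_len(H), rev(seq_len(H))), length.out = H2),
           rep(c(seq_len(W), rev(seq_len(W))), length.out = W2),
           drop = FALSE]
  }
  out <- EBImage::clahe(t(q), nx = nx, ny = ny, bins = 256L,
                        limit = cfg$clahe_clip_limit)
  out <- t(out)[seq_len(H), seq_len(W), drop = FALSE]
  pmin(pmax(out, 0), 1)
}

#' Estimate the field of view from a raw fundus photograph
#'
#' Thresholds the red channel at 20/255 and keeps the largest connected
#' component; fundus photographs have a near-black border outside the
#' circular field of view.
#'
#' @param img `(H, W, 3)` RGB array in `[0, 255]`.
#' @return Logical matrix `(H, W)`, `TRUE` inside the field of view.
#' @export
fov_from_image <- function(img) {
  red <- img[, , 1] > 20
  if (!any(red)) return(matrix(TRUE, dim(img)[1], dim(img)[2]))
  lab <- EBImage::bwlabel(t(red))
  tab <- tabulate(as.integer(lab))
  keep <- which.max(tab)
  t(lab == keep)
}

fov_bbox <- function(fov) {
  rows <- which(rowSums(fov) > 0)
  cols <- which(colSums(fov) > 0)
  if (length(rows) == 0) stop("empty field-of-view mask")
  c(r0 = min(rows), r1 = max(rows), c0 = min(cols), c1 = max(cols))
}

#' Full preprocessing pipeline
#'
#' Optional crop to the field-of-view bounding box, then grayscale
#' conversion, gamma correction, and CLAHE, in that order.
#'
#' @param img `(H, W, 3)` RGB array in `[0, 255]`.
#' @param cfg A [preprocess_config()].
#' @param fov Optional logical field-of-view mask of the same height/width;
#'   when absent and cropping is requested, the mask is estimated with
#'   [fov_from_image()].
#' @return Numeric matrix in `[0, 1]` with attributes `offset` (0-based
#'   row/col of the crop origin) and `fov` (the cropped mask, if any).
#' @export
preprocess_fundus <- function(img, cfg = preprocess_config(), fov = NULL) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("expected an (H, W, 3) RGB array")
  if (!is.null(fov) && !identical(dim(fov), d[1:2]))
    stop("fov dimensions differ from the image")
  offset <- c(0L, 0L)
  if (cfg$crop_to_fov) {
    if (is.null(fov)) fov <- fov_from_image(img)
    bb <- fov_bbox(fov)
    img <- img[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], , drop = FALSE]
    fov <- fov[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"]]
    offset <- c(bb[["r0"]] - 1L, bb[["c0"]] - 1L)
  }
  g <- rgb_to_gray(img)
  g <- gamma_correct(g, cfg)
  if (cfg$apply_clahe) g <- clahe_enhance(g, cfg)
  attr(g, "offset") <- offset
  attr(g, "fov") <- fov
  g
}

## ---- raster I/O ------------------------------------------------------------

#' Read a fundus photograph
#'
#' Reads PNG/JPEG/TIFF rasters (through EBImage) into the `(H, W, 3)` RGB
#' integer convention used by this package.
#'
#' @param path File path.
#' @return `(H, W, 3)` array in `[0, 255]`; grayscale files are replicated
#'   across channels.
#' @export
read_fundus <- function(path) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  a <- aperm(a, c(2, 1, 3)) # EBImage is (x, y, c)
  if (dim(a)[3] == 1L) a <- a[, , c(1, 1, 1), drop = FALSE]
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Read a binary mask image
#'
#' @param path File path.
#' @return Integer matrix `(H, W)` in `{0, 1}` (threshold at half intensity).
#' @export
read_mask <- function(path) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- t(a)
  array(as.integer(m > 0.5), dim = dim(m))
}

#' Write a grayscale raster as an 8-bit PNG
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output path (`.png`).
#' @export
write_gray_png <- function(img, path) {
  EBImage::writeImage(t(pmin(pmax(img, 0), 1)), path, type = "png",
                      bits.per.sample = 8L)
  invisible(path)
}

#' Write an RGB raster as an 8-bit PNG
#'
#' @param img `(H, W, 3)` array in `[0, 255]`.
#' @param path Output path (`.png`).
#' @export
write_rgb_png <- function(img, path) {
  im <- EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(im, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}
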