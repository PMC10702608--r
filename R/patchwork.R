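# Overlapping-patch machinery: planning a sliding-window grid, extracting
# aligned image/mask patches, augmenting them, and stitching per-patch
# probability maps back into a full-image prediction by overlap averaging.
# Coordinates are 0-based, row-major; windows are half-open.

#' Plan a sliding-window patch grid
#'
#' Origins run `0, stride, 2*stride, ...` per axis with the last origin at
#' most `dim - window`; with `edge_complete = TRUE` the origin `dim - window`
#' is appended per axis when missing, so the union of windows covers every
#' pixel.
#'
#' @param height,width Image dimensions.
#' @param window Square window size (default 128).
#' @param stride Step between origins (default 15).
#' @param edge_complete Guarantee full coverage?
#' @return Object of class `patch_grid`: window, stride, 0-based `origins`
#'   matrix (row, col; row-major order), `image_dims`, `edge_complete`.
#' @examples
#' nrow(plan_grid(584, 565)$origins) # 930 on DRIVE-sized images
#' @export
plan_grid <- function(height, width, window = 128L, stride = 15L,
                      edge_complete = FALSE) {
  if (window > height || window > width)
    stop("window (", window, ") larger than image (", height, "x", width,
         ")")
  if (stride < 1) stop("stride must be >= 1")
  axis_origins <- function(n) {
    o <- as.integer(seq(0L, n - window, by = stride))
    if (edge_complete && o[length(o)] != n - window)
      o <- c(o, as.integer(n - window))
    o
  }
  rows <- axis_origins(height)
  cols <- axis_origins(width)
  origins <- cbind(row = rep(rows, each = length(cols)),
                   col = rep(cols, times = length(rows)))
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 origins = origins,
                 image_dims = c(as.integer(height), as.integer(width)),
                 edge_complete = isTRUE(edge_complete)),
            class = "patch_grid")
}

#' Linear overlap between adjacent windows
#'
#' `100 * (window - stride) / window`; 0 when the stride is at least the
#' window (abutting or disjoint windows).
#'
#' @param window,stride Window size and step.
#' @return Overlap percentage.
#' @examples
#' overlap_percent(128, 16) # 87.5
#' @export
overlap_percent <- function(window, stride) {
  if (stride >= window) return(0)
  100 * (window - stride) / window
}

#' Extract patches on a grid
#'
#' @param img Numeric matrix `(H, W)`.
#' @param mask Optional aligned mask, cut identically.
#' @param grid A [plan_grid()] result planned for this image's dimensions.
#' @return Object of class `patch_set`: the grid plus `images` (and `masks`)
#'   arrays of shape `(window, window, n_patches)`.
#' @export
extract_patches <- function(img, mask = NULL, grid) {
  if (!identical(as.integer(dim(img)), grid$image_dims))
    stop("grid was planned for different image dimensions")
  w <- grid$window
  n <- nrow(grid$origins)
  cut <- function(src) {
    out <- array(0, c(w, w, n))
    for (i in seq_len(n)) {
      r <- grid$origins[i, 1]
      cc <- grid$origins[i, 2]
      out[, , i] <- src[(r + 1):(r + w), (cc + 1):(cc + w)]
    }
    out
  }
  ps <- list(grid = grid, images = cut(img),
             masks = if (!is.null(mask)) cut(mask))
  class(ps) <- "patch_set"
  ps
}

#' Stitch per-patch predictions into a full probability map
#'
#' Each output pixel is the mean of all patch predictions covering it
#' (sum and count accumulators). Requires full coverage, which an
#' edge-complete grid guarantees.
#'
#' @param prob_patches `(window, window, n)` array of patch predictions, or a
#'   `patch_set` whose `images` hold predictions.
#' @param grid The [plan_grid()] the patches were cut on.
#' @return Numeric matrix `(H, W)`.
#' @export
stitch <- function(prob_patches, grid) {
  if (inherits(prob_patches, "patch_set")) {
    grid <- prob_patches$grid
    prob_patches <- prob_patches$images
  }
  H <- grid$image_dims[1]
  W <- grid$image_dims[2]
  w <- grid$window
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_len(nrow(grid$origins))) {
    r <- grid$origins[i, 1]
    cc <- grid$origins[i, 2]
    ri <- (r + 1):(r + w)
    ci <- (cc + 1):(cc + w)
    acc[ri, ci] <- acc[ri, ci] + prob_patches[, , i]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  if (any(cnt == 0))
    stop("grid does not cover every pixel; plan with edge_complete = TRUE")
  acc / cnt
}

## ---- augmentation ----------------------------------------------------------

#' Draw a random augmentation parameter set
#'
#' Horizontal and vertical flips (probability 1/2 each), a rotation angle
#' uniform on `[-180, 180)` degrees, and a random crop-and-resize with scale
#' uniform on `[0.75, 1]`. Fully determined by the seed.
#'
#' @param seed Integer seed.
#' @return List of augmentation parameters, usable with [apply_augment()].
#' @export
draw_augment <- function(seed) {
  r <- with_seed(seed, stats::runif(6))
  list(hflip = r[1] < 0.5, vflip = r[2] < 0.5,
       angle = -180 + 360 * r[3],
       scale = 0.75 + 0.25 * r[4],
       off = r[5:6])
}

augment_identity <- function() {
  list(hflip = FALSE, vflip = FALSE, angle = 0, scale = 1, off = c(0, 0))
}

# Rotate a square patch about its centre by `angle` degrees (inverse
# mapping); bilinear for intensities, nearest for masks; zero fill outside.
warp_rotate <- function(img, angle, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (angle == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- rep(seq_len(H), times = W) - cy
  c <- rep(seq_len(W), each = H) - cx
  sr <- cos(th) * r - sin(th) * c + cy
  sc <- sin(th) * r + cos(th) * c + cx
  out <- numeric(H * W)
  if (method == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    for (dr in 0:1) for (dc in 0:1) {
      ri <- r0 + dr; ci <- c0 + dc
      wgt <- (if (dr == 1) fr else 1 - fr) * (if (dc == 1) fc else 1 - fc)
      ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W & wgt > 0
      out[ok] <- out[ok] + wgt[ok] * img[cbind(ri[ok], ci[ok])]
    }
  }
  matrix(out, H, W)
}

# Crop a sub-window (scale + fractional offset) and resize back to the
# original size; bilinear for intensities, nearest for masks.
crop_resize <- function(img, scale, off, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (scale >= 1) return(img)
  H <- nrow(img); W <- ncol(img)
  h <- max(2L, round(H * scale)); w <- max(2L, round(W * scale))
  r0 <- 1L + floor(off[1] * (H - h))
  c0 <- 1L + floor(off[2] * (W - w))
  sub <- img[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
  if (method == "nearest") {
    ri <- pmin(h, pmax(1L, round(seq(0.5, h - 0.5, length.out = H) + 0.5)))
    ci <- pmin(w, pmax(1L, round(seq(0.5, w - 0.5, length.out = W) + 0.5)))
    sub[ri, ci, drop = FALSE]
  } else {
    apply_resize(array(sub, c(h, w, 1, 1)),
                 resize_matrix(h, H), resize_matrix(w, W))[, , 1, 1]
  }
}

#' Apply an augmentation to an aligned image/mask patch pair
#'
#' The same geometric transform is applied to both members; the mask is
#' resampled nearest-neighbour so it stays binary.
#'
#' @param image,mask Square patches (mask may be `NULL`).
#' @param params From [draw_augment()].
#' @return List with transformed `image` and `mask`.
#' @export
apply_augment <- function(image, mask = NULL, params) {
  tf <- function(x, method) {
    if (params$hflip) x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
    if (params$vflip) x <- x[rev(seq_len(nrow(x))), , drop = FALSE]
    x <- warp_rotate(x, params$angle, method)
    crop_resize(x, params$scale, params$off, method)
  }
  list(image = tf(image, "bilinear"),
       mask = if (!is.null(mask)) {
         m <- tf(mask, "nearest")
         array(as.integer(m > 0.5), dim = dim(m))
       })
}

#' Randomly augment an aligned image/mask patch pair
#'
#' @param image,mask Square patches.
#' @param seed Integer seed; the transform is fully determined by it.
#' @return List with augmented `image` and `mask`.
#' @export
augment_patch <- function(image, mask = NULL, seed) {
  apply_augment(image, mask, draw_augment(seed))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}
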