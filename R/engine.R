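# Training and inference engine: seeded patch sampling with an image-level
# train/validation split, Adam optimisation of the deep-supervision loss with
# step learning-rate decay, best-checkpoint selection by validation AUC,
# patchwise inference with overlap-average stitching, and dataset-level
# evaluation (including cross-dataset evaluation of a frozen model).

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with `beta1 = 0.9`,
#' `beta2 = 0.99`, initial learning rate `5e-4` decayed by `0.1` every 50
#' epochs, batch size 32, 10% of the source images held out for validation,
#' and the checkpoint with the highest validation AUC kept.
#'
#' @param epochs Number of epochs.
#' @param batch_size Patches per optimisation step.
#' @param lr Initial learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param lr_decay,lr_decay_every Step decay factor and period (epochs).
#' @param val_fraction Fraction of source images held out for validation
#'   (the split is by image, never by patch, so overlapping patches cannot
#'   leak across the split).
#' @param val_images Optional explicit number of validation images
#'   (overrides `val_fraction`).
#' @param n_patches_per_image Random patches sampled per source image.
#' @param window Patch side in pixels.
#' @param augment Apply random flip/rotation/crop augmentation to training
#'   patches?
#' @param loss_weights Length-3 weights of the deep-supervision terms.
#' @param seed Seed controlling the split, patch sampling, augmentation and
#'   weight initialisation (combined with the model config seed).
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 32L, lr = 5e-4,
                         beta1 = 0.9, beta2 = 0.99, lr_decay = 0.1,
                         lr_decay_every = 50L, val_fraction = 0.10,
                         val_images = NULL, n_patches_per_image = 20L,
                         window = 64L, augment = TRUE,
                         loss_weights = c(1, 1, 1), seed = 7L) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  if (lr <= 0) stop("lr must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 val_fraction = val_fraction,
                 val_images = if (!is.null(val_images))
                   as.integer(val_images),
                 n_patches_per_image = as.integer(n_patches_per_image),
                 window = as.integer(window), augment = isTRUE(augment),
                 loss_weights = loss_weights, seed = as.integer(seed)),
            class = "train_config")
}

## ---- dataset loading -------------------------------------------------------

# Accepts a directory (images/, masks/, optional fov/) or an in-memory list
# with elements images, masks, fovs.
load_dataset <- function(data) {
  if (is.list(data) && !is.null(data$images)) {
    if (is.null(data$fovs)) data$fovs <- vector("list", length(data$images))
    return(data)
  }
  if (!is.character(data) || !dir.exists(data))
    stop("dataset must be a directory or a list with images/masks")
  imgs <- sort(list.files(file.path(data, "images"), full.names = TRUE))
  if (length(imgs) == 0) stop("no images found under ", data)
  base <- tools::file_path_sans_ext(basename(imgs))
  find_match <- function(dir) {
    if (!dir.exists(file.path(data, dir))) return(rep(NA_character_,
                                                      length(base)))
    cand <- list.files(file.path(data, dir), full.names = TRUE)
    cand[match(base, tools::file_path_sans_ext(basename(cand)))]
  }
  masks <- find_match("masks")
  fovs <- find_match("fov")
  list(images = lapply(imgs, read_fundus),
       masks = lapply(masks, function(f) if (!is.na(f)) read_mask(f)),
       fovs = lapply(fovs, function(f) if (!is.na(f)) read_mask(f) > 0),
       ids = base)
}

# Preprocess every image and align its mask/fov with the crop.
prepare_pairs <- function(ds, pp) {
  n <- length(ds$images)
  grays <- masks <- fovs <- vector("list", n)
  for (i in seq_len(n)) {
    g <- preprocess_fundus(ds$images[[i]], pp, fov = ds$fovs[[i]])
    off <- attr(g, "offset")
    m <- ds$masks[[i]]
    f <- ds$fovs[[i]]
    if (!is.null(m) && any(off > 0 | !identical(dim(m), dim(g)))) {
      m <- m[(off[1] + 1):(off[1] + nrow(g)),
             (off[2] + 1):(off[2] + ncol(g)), drop = FALSE]
    }
    if (!is.null(f) && !identical(dim(f), dim(g))) {
      f <- f[(off[1] + 1):(off[1] + nrow(g)),
             (off[2] + 1):(off[2] + ncol(g)), drop = FALSE]
    }
    grays[[i]] <- g
    masks[[i]] <- m
    fovs[[i]] <- if (is.null(f)) attr(g, "fov") else f
  }
  list(grays = grays, masks = masks, fovs = fovs,
       ids = ds$ids %||% sprintf("img_%03d", seq_len(n)))
}

# Sample n random window origins per image and cut aligned patch stacks.
sample_patches <- function(grays, masks, idx, n_per, w) {
  xs <- ys <- list()
  for (i in idx) {
    g <- grays[[i]]
    m <- masks[[i]]
    H <- nrow(g); W <- ncol(g)
    if (H < w || W < w) stop("image ", i, " smaller than the patch window")
    r0 <- sample.int(H - w + 1L, n_per, replace = TRUE) - 1L
    c0 <- sample.int(W - w + 1L, n_per, replace = TRUE) - 1L
    for (j in seq_len(n_per)) {
      xs[[length(xs) + 1L]] <- g[(r0[j] + 1):(r0[j] + w),
                                 (c0[j] + 1):(c0[j] + w)]
      ys[[length(ys) + 1L]] <- m[(r0[j] + 1):(r0[j] + w),
                                 (c0[j] + 1):(c0[j] + w)]
    }
  }
  list(x = xs, y = ys)
}

as_batch <- function(lst, sel) {
  w <- nrow(lst[[1]])
  out <- array(0, c(w, w, 1L, length(sel)))
  for (k in seq_along(sel)) out[, , 1, k] <- lst[[sel[k]]]
  out
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim(p$value) %||%
                                             length(p$value)))
  st$v <- st$m
  st$t <- 0L
  st
}

adam_step <- function(params, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    p$value <- p$value - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
    p$grad <- NULL
  }
  invisible()
}

## ---- training --------------------------------------------------------------

#' Train an MFA-UNet on a patch dataset
#'
#' Preprocesses the dataset, splits the source images into training and
#' validation sets (split by image so overlapping patches never leak),
#' samples random patches, and optimises the deep-supervision loss with
#' Adam. After every epoch the validation loss, accuracy, soft Dice and AUC
#' are recorded; the parameters achieving the highest validation AUC are
#' restored into the returned model.
#'
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param data Dataset directory (`images/`, `masks/`, optional `fov/`) or an
#'   in-memory list with `images`, `masks`, `fovs`.
#' @param pp A [preprocess_config()]; cropping is disabled by default for
#'   training since synthetic and patch data are already tight.
#' @param quiet Suppress per-epoch progress lines?
#' @return Object of class `mfa_fit`: the trained model, a per-epoch
#'   `history` data frame, the best epoch, and the configurations used.
#' @export
mfa_train <- function(model_cfg, train_cfg, data,
                      pp = preprocess_config(crop_to_fov = FALSE),
                      quiet = TRUE) {
  stopifnot(inherits(model_cfg, "mfa_model_config"),
            inherits(train_cfg, "train_config"))
  set.seed(train_cfg$seed)
  ds <- load_dataset(data)
  n_img <- length(ds$images)
  if (n_img == 0) stop("empty dataset")
  if (any(vapply(ds$masks, is.null, TRUE)))
    stop("every training image needs a mask")
  pairs <- prepare_pairs(ds, pp)
  nv <- train_cfg$val_images %||%
    max(1L, round(train_cfg$val_fraction * n_img))
  if (nv >= n_img) stop("validation split leaves no training images")
  vidx <- sort(sample.int(n_img, nv))
  tidx <- setdiff(seq_len(n_img), vidx)
  w <- train_cfg$window
  tr <- sample_patches(pairs$grays, pairs$masks, tidx,
                       train_cfg$n_patches_per_image, w)
  va <- sample_patches(pairs$grays, pairs$masks, vidx,
                       train_cfg$n_patches_per_image, w)
  n_tr <- length(tr$x)
  model <- mfa_unet(model_cfg)
  st <- adam_init(model$params)
  history <- NULL
  best <- list(auc = -Inf, epoch = 0L, params = NULL)
  for (epoch in seq_len(train_cfg$epochs)) {
    lr <- train_cfg$lr *
      train_cfg$lr_decay^((epoch - 1) %/% train_cfg$lr_decay_every)
    ord <- sample.int(n_tr)
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      xb <- as_batch(tr$x, b)
      yb <- as_batch(tr$y, b)
      if (train_cfg$augment) {
        seeds <- sample.int(.Machine$integer.max, length(b))
        for (k in seq_along(b)) {
          au <- augment_patch(xb[, , 1, k], yb[, , 1, k], seeds[k])
          xb[, , 1, k] <- au$image
          yb[, , 1, k] <- au$mask
        }
      }
      ad_tape_begin()
      outs <- nn_forward(model, ad_const(xb))
      loss <- deep_supervision_loss(outs, yb,
                                    weights = train_cfg$loss_weights)
      if (!is.finite(loss$value))
        stop("non-finite training loss at epoch ", epoch,
             " (lr = ", lr, "); inspect the data scaling")
      ad_backward(loss)
      ad_tape_end()
      adam_step(model$params, st, lr, train_cfg$beta1, train_cfg$beta2)
      ep_loss <- ep_loss + loss$value * length(b)
    }
    ep_loss <- ep_loss / n_tr
    vm <- validate_patches(model, va, train_cfg$loss_weights)
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                train_loss = ep_loss,
                                val_loss = vm$loss, val_acc = vm$acc,
                                val_dsc = vm$dsc, val_auc = vm$auc))
    if (!quiet)
      message(sprintf(
        "epoch %3d  train %.4f  val %.4f  acc %.4f  dice %.4f  auc %.4f",
        epoch, ep_loss, vm$loss, vm$acc, vm$dsc, vm$auc))
    if (is.finite(vm$auc) && vm$auc > best$auc) {
      best <- list(auc = vm$auc, epoch = epoch,
                   params = lapply(model$params, function(p) p$value))
    }
  }
  if (!is.null(best$params)) set_params(model, best$params)
  fit <- list(model = model, history = history, best_epoch = best$epoch,
              best_auc = best$auc, model_cfg = model_cfg,
              train_cfg = train_cfg,
              split = list(train_images = tidx, val_images = vidx))
  class(fit) <- "mfa_fit"
  fit
}

# Forward the validation patches (no tape) and score them.
validate_patches <- function(model, va, weights) {
  n <- length(va$x)
  probs <- numeric(0)
  truth <- numeric(0)
  loss <- 0
  chunk <- 32L
  for (b in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    xb <- as_batch(va$x, b)
    yb <- as_batch(va$y, b)
    outs <- nn_forward(model, ad_const(xb))
    l <- deep_supervision_loss(lapply(outs, function(o) o$value), yb,
                               weights = weights)
    loss <- loss + l * length(b)
    p <- 1 / (1 + exp(-outs$fusion$value))
    probs <- c(probs, as.vector(p))
    truth <- c(truth, as.vector(yb))
  }
  list(loss = loss / n,
       acc = mean((probs > 0.5) == (truth > 0.5)),
       dsc = 1 - dice_loss(probs, truth),
       auc = suppressWarnings(roc_auc(probs, truth)))
}

## ---- inference -------------------------------------------------------------

pad_reflect <- function(img, H2, W2) {
  H <- nrow(img); W <- ncol(img)
  ri <- rep(c(seq_len(H), rev(seq_len(H))), length.out = H2)
  ci <- rep(c(seq_len(W), rev(seq_len(W))), length.out = W2)
  img[ri, ci, drop = FALSE]
}

#' Segment a full image by patchwise prediction and stitching
#'
#' Preprocesses the image (if given as RGB), plans an edge-complete grid,
#' runs the network on every patch (fusion-branch sigmoid), and averages the
#' overlapping patch predictions. Images smaller than the window are
#' reflect-padded, predicted, and cropped back.
#'
#' @param model An `mfa_unet` model (or an `mfa_fit`).
#' @param img `(H, W, 3)` RGB array in `[0, 255]`, or an already
#'   preprocessed `(H, W)` gray matrix in `[0, 1]`.
#' @param pp A [preprocess_config()] used when `img` is RGB.
#' @param window,stride Patch grid geometry.
#' @param fov Optional field-of-view mask passed to preprocessing.
#' @param batch_size Patches per forward pass.
#' @return Probability matrix with the dimensions of the preprocessed image.
#' @export
predict_image <- function(model, img, pp = preprocess_config(),
                          window = 64L, stride = max(1L, window %/% 2L),
                          fov = NULL, batch_size = 32L) {
  if (inherits(model, "mfa_fit")) model <- model$model
  g <- if (length(dim(img)) == 3L) preprocess_fundus(img, pp, fov) else img
  H <- nrow(g); W <- ncol(g)
  padded <- H < window || W < window
  gp <- if (padded) pad_reflect(g, max(H, window), max(W, window)) else g
  grid <- plan_grid(nrow(gp), ncol(gp), window, stride,
                    edge_complete = TRUE)
  ps <- extract_patches(gp, grid = grid)
  n <- nrow(grid$origins)
  preds <- array(0, dim(ps$images))
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    xb <- array(ps$images[, , b], c(window, window, 1L, length(b)))
    preds[, , b] <- nn_predict(model, xb)[, , 1, ]
  }
  out <- stitch(preds, grid)
  if (padded) out <- out[seq_len(H), seq_len(W), drop = FALSE]
  attr(out, "offset") <- attr(g, "offset")
  out
}

#' Evaluate a model over a dataset
#'
#' Predicts every image, scores it against its mask, and pools the confusion
#' counts. `msen` and `msp` are the per-image means of sensitivity and
#' specificity; `acc` and `dsc` come from the pooled counts; `auc` pools all
#' pixels.
#'
#' @param model An `mfa_unet` model or `mfa_fit`.
#' @param data Dataset directory or in-memory list (see [mfa_train()]).
#' @param threshold Binarisation threshold.
#' @param pp Preprocessing configuration.
#' @param window,stride Patch grid geometry.
#' @param restrict_fov Score only pixels inside the field of view?
#' @return List with `per_image` (data frame) and `pooled` metrics.
#' @export
evaluate_dataset <- function(model, data, threshold = 0.5,
                             pp = preprocess_config(crop_to_fov = FALSE),
                             window = 64L,
                             stride = max(1L, window %/% 2L),
                             restrict_fov = FALSE) {
  if (inherits(model, "mfa_fit")) model <- model$model
  ds <- load_dataset(data)
  pairs <- prepare_pairs(ds, pp)
  per <- NULL
  tot <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  all_p <- all_y <- list()
  for (i in seq_along(pairs$grays)) {
    if (is.null(pairs$masks[[i]])) {
      warning("no mask for image ", pairs$ids[i], "; skipped")
      next
    }
    prob <- predict_image(model, pairs$grays[[i]], pp, window, stride)
    dom <- if (restrict_fov) pairs$fovs[[i]]
    m <- segmentation_metrics(prob, pairs$masks[[i]], threshold, dom)
    per <- rbind(per, data.frame(id = pairs$ids[i], acc = m$acc,
                                 dsc = m$dsc, se = m$se, sp = m$sp,
                                 auc = m$auc))
    for (f in names(tot)) tot[[f]] <- tot[[f]] + m$counts[[f]]
    keep <- if (is.null(dom)) TRUE else as.vector(dom) > 0
    all_p[[length(all_p) + 1L]] <- as.vector(prob)[keep]
    all_y[[length(all_y) + 1L]] <- as.vector(pairs$masks[[i]])[keep]
  }
  if (is.null(per)) stop("no scorable images in the dataset")
  cc <- structure(c(tot, list(n = tot$tp + tot$fp + tot$tn + tot$fn)),
                  class = "confusion_counts")
  pm <- compute_metrics(cc)
  pooled <- list(msen = mean(per$se), msp = mean(per$sp), acc = pm$acc,
                 auc = suppressWarnings(roc_auc(unlist(all_p),
                                                unlist(all_y))),
                 dsc = pm$dsc)
  list(per_image = per, pooled = pooled, counts = cc,
       threshold = threshold)
}

#' Cross-dataset evaluation of a frozen model
#'
#' Evaluates a model trained on one dataset against another without any
#' retraining; identical to [evaluate_dataset()] and provided for the
#' cross-training protocol.
#'
#' @inheritParams evaluate_dataset
#' @export
cross_evaluate <- function(model, data, threshold = 0.5,
                           pp = preprocess_config(crop_to_fov = FALSE),
                           window = 64L,
                           stride = max(1L, window %/% 2L),
                           restrict_fov = FALSE) {
  evaluate_dataset(model, data, threshold, pp, window, stride,
                   restrict_fov)
}

## ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints store a format version, the full model configuration and the
#' parameter values; loading rebuilds the architecture and restores the
#' weights exactly.
#'
#' @param model An `mfa_unet` model or `mfa_fit`.
#' @param path Checkpoint file path.
#' @return `save_model` returns the path invisibly; `load_model` returns the
#'   restored `mfa_unet`.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "mfa_fit")) model <- model$model
  saveRDS(list(format = "mfaunet-checkpoint-1", config = model$config,
               params = lapply(model$params, function(p) p$value)),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "mfaunet-checkpoint-1"))
    stop("not an mfaunet checkpoint")
  model <- mfa_unet(ck$config)
  set_params(model, ck$params)
  model
}

## ---- mfa_fit methods -------------------------------------------------------

#' @export
print.mfa_fit <- function(x, ...) {
  cat("MFA-UNet fit:", nrow(x$history), "epochs\n")
  cat(sprintf("  best validation AUC %.4f at epoch %d\n", x$best_auc,
              x$best_epoch))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final: train loss %.4f | val loss %.4f | val dice %.4f\n",
              last$train_loss, last$val_loss, last$val_dsc))
  invisible(x)
}

#' @export
summary.mfa_fit <- function(object, ...) {
  out <- list(history = object$history, best_epoch = object$best_epoch,
              best_auc = object$best_auc,
              n_params = count_parameters(object$model),
              split = object$split)
  class(out) <- "summary.mfa_fit"
  out
}

#' @export
print.summary.mfa_fit <- function(x, ...) {
  cat("Training history:\n")
  print(x$history, row.names = FALSE, digits = 4)
  cat(sprintf("Best epoch %d (val AUC %.4f); %s parameters\n",
              x$best_epoch, x$best_auc,
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' @export
plot.mfa_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "loss",
                 ylim = range(c(h$train_loss, h$val_loss)))
  graphics::lines(h$epoch, h$val_loss, col = "tomato")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "tomato"), bty = "n")
  graphics::plot(h$epoch, h$val_dsc, type = "l", col = "seagreen",
                 xlab = "epoch", ylab = "validation Dice / AUC",
                 ylim = range(c(h$val_dsc, h$val_auc)))
  graphics::lines(h$epoch, h$val_auc, col = "orchid")
  graphics::legend("bottomright", c("Dice", "AUC"), lty = 1,
                   col = c("seagreen", "orchid"), bty = "n")
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}

#' @export
predict.mfa_fit <- function(object, newdata, ...) {
  predict_image(object$model, newdata, ...)
}

#' @export
predict.mfa_unet <- function(object, newdata, ...) {
  predict_image(object, newdata, ...)
}

#' @export
coef.mfa_fit <- function(object, ...) coef(object$model)
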