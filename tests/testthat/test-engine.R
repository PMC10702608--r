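# Engine tests run miniature configurations: a few synthetic images, a very
# slim network, and one or two epochs - enough to exercise the contracts
# without long runtimes.

slim_cfg <- function(seed = 5) {
  model_config(encoder_channels = c(2L, 4L, 8L, 16L),
               msam_align_groups = c(1, 1, 1), msam_out_groups = 1,
               msam_token_groups = 1, pam_reduction = 2,
               mbdm_branch_channels = 2L, seed = seed)
}

smoke_train <- function(epochs = 2L, seed = 5L, ...) {
  ds <- small_synth_dataset(n = 4L, size = 96L)
  mfa_train(slim_cfg(), train_config(epochs = epochs, batch_size = 16L,
                                     val_images = 1L,
                                     n_patches_per_image = 6L,
                                     window = 64L, seed = seed, ...), ds)
}

test_that("a short training run completes and records its history", {
  fit <- smoke_train()
  expect_s3_class(fit, "mfa_fit")
  expect_identical(nrow(fit$history), 2L)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(is.finite(fit$history$val_auc)))
  expect_true(fit$best_epoch %in% 1:2)
  # split is disjoint at the source-image level
  expect_length(intersect(fit$split$train_images, fit$split$val_images), 0L)
  expect_length(fit$split$val_images, 1L)
  # print/summary/plot methods work
  expect_output(print(fit), "best validation AUC")
  expect_output(print(summary(fit)), "Training history")
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})

test_that("training is reproducible under a fixed seed", {
  f1 <- smoke_train(epochs = 1L)
  f2 <- smoke_train(epochs = 1L)
  expect_equal(f1$history$train_loss, f2$history$train_loss,
               tolerance = 1e-6)
  expect_identical(coef(f1), coef(f2))
})

test_that("training rejects empty or mask-less datasets", {
  expect_error(mfa_train(slim_cfg(), train_config(), list(images = list())),
               "empty|directory")
  ds <- small_synth_dataset(n = 2L, size = 96L)
  ds$masks[2] <- list(NULL)
  expect_error(mfa_train(slim_cfg(),
                         train_config(val_images = 1L, window = 64L),
                         ds), "mask")
})

test_that("patchwise prediction stitches a constant stub to a constant map", {
  cfg <- slim_cfg()
  cfg$use_mbdm <- FALSE
  m <- mfa_unet(cfg)
  m$params[["head.w"]]$value[] <- 0
  m$params[["head.b"]]$value[] <- log(0.7 / 0.3)
  g <- matrix(runif(100 * 90), 100, 90)
  p <- predict_image(m, g, window = 64L, stride = 32L)
  expect_identical(dim(p), c(100L, 90L))
  expect_equal(as.vector(p), rep(0.7, length(p)), tolerance = 1e-12)
})

test_that("prediction output is a probability map of the input size", {
  m <- mfa_unet(slim_cfg())
  g <- matrix(runif(80 * 70), 80, 70)
  p <- predict_image(m, g, window = 64L, stride = 48L)
  expect_identical(dim(p), c(80L, 70L))
  expect_true(all(p > 0 & p < 1))
  # images smaller than the window are reflect-padded and cropped back
  sm <- matrix(runif(40 * 30), 40, 30)
  ps <- predict_image(m, sm, window = 64L, stride = 64L)
  expect_identical(dim(ps), c(40L, 30L))
  # RGB input goes through preprocessing first
  ds <- small_synth_dataset(n = 1L, size = 96L)
  pr <- predict_image(m, ds$images[[1]],
                      pp = preprocess_config(crop_to_fov = FALSE),
                      window = 64L, stride = 32L)
  expect_identical(dim(pr), c(96L, 96L))
})

test_that("dataset evaluation pools confusion counts additively", {
  cfg <- slim_cfg()
  cfg$use_mbdm <- FALSE
  m <- mfa_unet(cfg)
  ds <- small_synth_dataset(n = 3L, size = 96L)
  rep <- evaluate_dataset(m, ds, threshold = 0.5, window = 64L,
                          stride = 48L)
  expect_identical(nrow(rep$per_image), 3L)
  expect_true(all(c("msen", "msp", "acc", "auc", "dsc") %in%
                    names(rep$pooled)))
  expect_equal(rep$pooled$msen, mean(rep$per_image$se))
  expect_equal(rep$pooled$msp, mean(rep$per_image$sp))
  # pooled accuracy equals (sum TP + sum TN) / sum N over images
  expect_equal(rep$pooled$acc,
               (rep$counts$tp + rep$counts$tn) / rep$counts$n)
  expect_equal(rep$counts$n, 3 * 96 * 96)
})

test_that("a perfect-oracle stub yields perfect pooled metrics", {
  ds <- small_synth_dataset(n = 2L, size = 96L)
  ns <- asNamespace("mfaunet")
  pairs <- ns$prepare_pairs(ns$load_dataset(ds),
                            preprocess_config(crop_to_fov = FALSE))
  tot <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in 1:2) {
    m <- segmentation_metrics(pairs$masks[[i]] * 1.0, pairs$masks[[i]])
    for (f in names(tot)) tot[[f]] <- tot[[f]] + m$counts[[f]]
  }
  expect_equal(tot$fp + tot$fn, 0)
  expect_equal((tot$tp + tot$tn) / (2 * 96 * 96), 1)
})

test_that("checkpoints round-trip and cross-evaluation reuses the frozen model", {
  m <- mfa_unet(slim_cfg(seed = 17))
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tmp)
  m2 <- load_model(tmp)
  expect_identical(coef(m), coef(m2))
  g <- matrix(runif(70 * 70), 70, 70)
  expect_identical(predict_image(m, g, window = 64L, stride = 64L),
                   predict_image(m2, g, window = 64L, stride = 64L))
  # cross-evaluation is evaluate_dataset without retraining
  ds <- small_synth_dataset(n = 2L, size = 96L)
  before <- coef(m)
  r1 <- cross_evaluate(m, ds, window = 64L, stride = 48L)
  expect_identical(coef(m), before)
  r2 <- evaluate_dataset(m, ds, window = 64L, stride = 48L)
  expect_equal(r1$pooled, r2$pooled)
})

test_that("datasets on disk load through the directory layout", {
  skip_if_not_installed("EBImage")
  tmp <- withr::local_tempdir()
  make_synth_dataset(synth_config(image_size = 96L, seed = 70), 2L, tmp)
  ns <- asNamespace("mfaunet")
  ds <- ns$load_dataset(tmp)
  expect_length(ds$images, 2L)
  expect_identical(dim(ds$images[[1]]), c(96L, 96L, 3L))
  expect_true(all(ds$masks[[1]] %in% 0:1))
  expect_identical(dim(ds$fovs[[1]]), c(96L, 96L))
  expect_identical(ds$ids, c("synth_001", "synth_002"))
})
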