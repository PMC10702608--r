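test_that("grid planning matches the closed form and edge completion", {
  # exact fit: one origin
  g <- plan_grid(128, 128, 128, 15)
  expect_identical(nrow(g$origins), 1L)
  expect_identical(g$origins[1, ], c(row = 0L, col = 0L))
  # fundus-photograph-sized image, window 128, stride 15
  g <- plan_grid(584, 565, 128, 15)
  expect_identical(nrow(g$origins), 930L)
  expect_identical(nrow(g$origins),
                   as.integer((floor((584 - 128) / 15) + 1) *
                                (floor((565 - 128) / 15) + 1)))
  # edge completion appends the flush-right/bottom origin when missing
  g <- plan_grid(130, 128, 128, 15, edge_complete = TRUE)
  expect_identical(nrow(g$origins), 2L)
  expect_setequal(unique(g$origins[, "row"]), c(0L, 2L))
  expect_identical(unique(g$origins[, "col"]), 0L)
  expect_error(plan_grid(100, 100, 128, 15), "larger")
})

test_that("grid counts equal the closed form over random geometries", {
  set.seed(10)
  for (i in 1:20) {
    H <- sample(64:300, 1); W <- sample(64:300, 1)
    w <- sample(16:min(H, W), 1); s <- sample(1:40, 1)
    g <- plan_grid(H, W, w, s)
    expect_identical(nrow(g$origins),
                     as.integer((floor((H - w) / s) + 1) *
                                  (floor((W - w) / s) + 1)))
  }
})

test_that("overlap percentage follows 100 (window - stride) / window", {
  expect_identical(overlap_percent(128, 128), 0)
  expect_identical(overlap_percent(128, 16), 87.5)
  expect_equal(overlap_percent(128, 15), 100 * (128 - 15) / 128)
  expect_equal(overlap_percent(128, 15), 88.28125)
  expect_identical(overlap_percent(128, 200), 0)
})

test_that("patch extraction respects half-open window coordinates", {
  H <- 40L; W <- 50L
  coded <- matrix(seq_len(H * W) - 1, H, W, byrow = TRUE) # r*W + c
  g <- plan_grid(H, W, 16, 10)
  ps <- extract_patches(coded, grid = g)
  for (i in seq_len(nrow(g$origins))) {
    r <- g$origins[i, 1]; cc <- g$origins[i, 2]
    expect_equal(ps$images[, , i],
                 outer(r + 0:15, cc + 0:15, function(a, b) a * W + b))
  }
  # constant image and identity crop
  const <- matrix(0.3, 32, 32)
  ps <- extract_patches(const, grid = plan_grid(32, 32, 32, 1))
  expect_equal(ps$images[, , 1], const)
  expect_error(extract_patches(matrix(0, 10, 10), grid = g), "dimensions")
})

test_that("mask patches are cut identically to image patches", {
  set.seed(11)
  img <- matrix(runif(60 * 60), 60)
  msk <- matrix(rbinom(3600, 1, 0.2), 60)
  g <- plan_grid(60, 60, 20, 13, edge_complete = TRUE)
  ps <- extract_patches(img, msk, g)
  i <- nrow(g$origins)
  r <- g$origins[i, 1]; cc <- g$origins[i, 2]
  expect_equal(ps$masks[, , i], msk[r + 1:20, cc + 1:20])
})

test_that("stitching averages overlapping predictions", {
  # constant predictions stitch to the same constant
  g <- plan_grid(40, 40, 16, 8, edge_complete = TRUE)
  n <- nrow(g$origins)
  ps <- array(0.7, c(16, 16, n))
  expect_equal(stitch(ps, g), matrix(0.7, 40, 40))
  # two overlapping patches disagreeing on a shared pixel average to 0.5
  g2 <- plan_grid(16, 24, 16, 8, edge_complete = TRUE)
  ps2 <- array(0, c(16, 16, nrow(g2$origins)))
  ps2[, , 1] <- 0.2
  ps2[, , 2] <- 0.8
  out <- stitch(ps2, g2)
  expect_equal(out[1, 12], 0.5) # covered by both windows
  expect_equal(out[1, 1], 0.2)  # first window only
  # zero coverage is an error
  g3 <- plan_grid(40, 40, 16, 20, edge_complete = FALSE)
  expect_error(stitch(array(0, c(16, 16, nrow(g3$origins))), g3), "cover")
})

test_that("stitch after extract is the identity for edge-complete grids", {
  set.seed(12)
  for (geom in list(c(40, 40, 16, 8), c(37, 53, 16, 11), c(64, 64, 32, 5))) {
    prob <- matrix(runif(geom[1] * geom[2]), geom[1], geom[2])
    g <- plan_grid(geom[1], geom[2], geom[3], geom[4], edge_complete = TRUE)
    ps <- extract_patches(prob, grid = g)
    expect_equal(stitch(ps$images, g), prob, tolerance = 1e-12)
  }
})

test_that("augmentation transforms image and mask jointly and keeps masks binary", {
  pair <- toy_pair()
  for (seed in 1:40) {
    au <- augment_patch(pair$image, pair$mask, seed)
    expect_true(all(au$mask %in% c(0L, 1L)))
    expect_identical(dim(au$image), dim(pair$image))
    expect_identical(dim(au$mask), dim(pair$mask))
  }
})

test_that("augmentation is seed-deterministic and no-op parameters are identity", {
  pair <- toy_pair()
  a1 <- augment_patch(pair$image, pair$mask, 99)
  a2 <- augment_patch(pair$image, pair$mask, 99)
  expect_identical(a1, a2)
  id <- list(hflip = FALSE, vflip = FALSE, angle = 0, scale = 1,
             off = c(0, 0))
  au <- apply_augment(pair$image, pair$mask, id)
  expect_equal(au$image, pair$image)
  expect_equal(au$mask, pair$mask, ignore_attr = TRUE)
  # double horizontal flip is an involution
  fl <- list(hflip = TRUE, vflip = FALSE, angle = 0, scale = 1,
             off = c(0, 0))
  twice <- apply_augment(apply_augment(pair$image, pair$mask, fl)$image,
                         NULL, fl)
  expect_equal(twice$image, pair$image)
})
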