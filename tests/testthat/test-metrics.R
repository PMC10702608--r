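test_that("binarisation uses a strict threshold and is idempotent", {
  p <- matrix(c(0, 0.5, 0.51, 1), 2, 2)
  b <- binarize(p, 0.5)
  expect_identical(as.vector(b), c(0L, 0L, 1L, 1L)) # 0.5 itself maps to 0
  expect_identical(binarize(b, 0.5), b)
  expect_identical(binarize(matrix(0, 3, 3)), matrix(0L, 3, 3))
})

test_that("confusion counts match a hand-counted example and partition pixels", {
  pred <- matrix(c(1, 1, 0, 1), 2, 2)  # [[1,0],[1,1]] row-wise
  truth <- matrix(c(1, 0, 1, 1), 2, 2) # [[1,1],[0,1]] row-wise
  cc <- confusion_counts(pred, truth)
  expect_identical(cc$tp, 2L)
  expect_identical(cc$fp, 1L)
  expect_identical(cc$fn, 1L)
  expect_identical(cc$tn, 0L)
  expect_identical(cc$n, 4L)
  # perfect prediction
  cc2 <- confusion_counts(truth, truth)
  expect_identical(cc2$fp + cc2$fn, 0L)
  set.seed(30)
  a <- matrix(rbinom(100, 1, 0.4), 10)
  b <- matrix(rbinom(100, 1, 0.4), 10)
  cc3 <- confusion_counts(a, b)
  expect_identical(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 100L)
  expect_error(confusion_counts(a, b[1:5, ]), "differ")
})

test_that("metrics follow the confusion-count formulas", {
  sym <- structure(list(tp = 25L, fp = 25L, tn = 25L, fn = 25L, n = 100L),
                   class = "confusion_counts")
  m <- compute_metrics(sym)
  expect_equal(unlist(m[c("acc", "dsc", "se", "sp")]),
               c(acc = 0.5, dsc = 0.5, se = 0.5, sp = 0.5))
  hand <- confusion_counts(matrix(c(1, 1, 0, 1), 2),
                           matrix(c(1, 0, 1, 1), 2))
  mh <- compute_metrics(hand)
  expect_equal(mh$acc, 0.5)
  expect_equal(mh$dsc, 2 / 3)
  expect_equal(mh$se, 2 / 3)
  expect_equal(mh$sp, 0)
  expect_false(mh$degenerate) # sp = 0/1 is defined, just zero
  degen <- structure(list(tp = 0L, fp = 0L, tn = 4L, fn = 0L, n = 4L),
                     class = "confusion_counts")
  expect_true(compute_metrics(degen)$degenerate) # no positives at all
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  mp <- compute_metrics(perfect)
  expect_equal(unlist(mp[c("acc", "dsc", "se", "sp")]),
               c(acc = 1, dsc = 1, se = 1, sp = 1))
})

test_that("AUC equals the all-pairs rank oracle and handles ties", {
  # perfectly separated scores
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  # constant scores are chance level
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  # random example vs O(n^2) pair counting, ties counted one half
  set.seed(31)
  s <- round(runif(20), 1) # coarse grid forces ties
  y <- rbinom(20, 1, 0.5)
  pos <- s[y == 1]; neg <- s[y == 0]
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  expect_equal(roc_auc(s, y), wins / (length(pos) * length(neg)),
               tolerance = 1e-9)
  expect_warning(out <- roc_auc(runif(5), rep(1, 5)), "single class")
  expect_true(is.na(out))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(32)
  s <- runif(50)
  y <- rbinom(50, 1, 0.3)
  a0 <- roc_auc(s, y)
  expect_equal(roc_auc(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), y), a0)
  expect_equal(roc_auc(s^3, y), a0)
  expect_equal(roc_auc(100 * s + 7, y), a0)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  s <- runif(200)
  y <- rbinom(200, 1, 0.25)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-9)
})

test_that("hard-mask Dice from counts equals 1 - dice_loss in the smooth->0 limit", {
  set.seed(34)
  pred <- matrix(rbinom(64, 1, 0.4), 8)
  truth <- matrix(rbinom(64, 1, 0.4), 8)
  dsc <- compute_metrics(confusion_counts(pred, truth))$dsc
  expect_equal(dsc, 1 - dice_loss(pred, truth, smooth = 1e-12),
               tolerance = 1e-6)
})

test_that("metrics pool additively across images", {
  set.seed(35)
  p1 <- matrix(rbinom(36, 1, 0.5), 6); t1 <- matrix(rbinom(36, 1, 0.5), 6)
  p2 <- matrix(rbinom(36, 1, 0.5), 6); t2 <- matrix(rbinom(36, 1, 0.5), 6)
  cc <- confusion_counts(c(p1, p2), c(t1, t2))
  c1 <- confusion_counts(p1, t1)
  c2 <- confusion_counts(p2, t2)
  expect_identical(cc$tp, c1$tp + c2$tp)
  expect_identical(cc$n, c1$n + c2$n)
  expect_equal(compute_metrics(cc)$acc,
               (c1$tp + c1$tn + c2$tp + c2$tn) / (c1$n + c2$n))
})

test_that("the evaluation domain mask restricts scoring", {
  pred <- matrix(c(1, 1, 0, 0), 2)
  truth <- matrix(c(1, 0, 0, 1), 2)
  dom <- matrix(c(1, 1, 0, 0), 2)
  cc <- confusion_counts(pred, truth, dom)
  expect_identical(cc$n, 2L)
  expect_identical(cc$tp, 1L)
  expect_identical(cc$fp, 1L)
  r <- segmentation_metrics(matrix(runif(4), 2), truth, domain = dom)
  expect_identical(r$domain, "restricted")
})
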