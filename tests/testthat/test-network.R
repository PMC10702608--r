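test_that("the built model honours shape and determinism contracts", {
  cfg <- desk_model_config(seed = 7)
  m1 <- mfa_unet(cfg)
  m2 <- mfa_unet(cfg)
  expect_identical(coef(m1), coef(m2)) # bit-identical builds
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  outs <- nn_predict(m1, x, what = "logits")
  expect_named(outs, c("branch1", "branch2", "fusion"))
  for (o in outs) expect_identical(dim(o), c(64L, 64L, 1L, 1L))
  p1 <- nn_predict(m1, x)
  expect_identical(p1, nn_predict(m1, x)) # deterministic forward
  expect_true(all(p1 > 0 & p1 < 1))
  expect_error(model_config(encoder_channels = c(64, 32, 128, 256)),
               "increasing")
})

test_that("module toggles change the parameter count in the expected order", {
  n <- sapply(list(c(FALSE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                   c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE)),
              function(tg) {
    count_parameters(mfa_unet(desk_model_config(
      use_msam = tg[1], use_pam = tg[2], use_mbdm = tg[3])))
  })
  # baseline < +PAM < +MSAM < +MBDM, strictly
  expect_true(all(diff(n) > 0))
  # a lone 3x3 conv, 4 -> 8 channels with bias: 4*8*9 + 8
  ns <- asNamespace("mfaunet")
  expect_identical(sum(lengths(lapply(
    ns$collect_params(ns$mod_conv(4L, 8L, 3L)), function(p) p$value))),
    296L)
})

test_that("channel and spatial self-attention match a double-loop oracle", {
  set.seed(40)
  D <- 8L
  msam <- new_msam(c(4L, 4L, 8L), D = D, align_groups = c(1, 1, 1),
                   out_groups = 1, token_groups = 1)
  z <- matrix(rnorm(16 * D), 16, D) # 4x4 spatial grid of tokens
  got <- msam_refine_tokens(msam, z, internals = TRUE)
  # --- naive oracle, everything by explicit loops ---
  ch <- msam$ch$value
  Wq <- msam$Wq$value; Wk <- msam$Wk$value; Wv <- msam$Wv$value
  mmul <- function(A, B) {
    out <- matrix(0, nrow(A), ncol(B))
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(B))) {
      out[i, j] <- sum(A[i, ] * B[, j])
    }
    out
  }
  softmax_rows <- function(A) {
    t(apply(A, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  }
  K <- mmul(z, Wk); V <- mmul(z, Wv); Q <- mmul(ch, Wq)
  att <- softmax_rows(mmul(Q, t(K)) / sqrt(D))
  Fch <- ch + mmul(att, V)
  gate <- 1 / (1 + exp(-(Fch %*% msam$wg$value + msam$bg$value[1])))
  Sch <- sweep(z, 2, as.vector(gate), `*`)
  Qs <- mmul(Sch, Wq); Ks <- mmul(Sch, Wk); Vs <- mmul(Sch, Wv)
  atts <- softmax_rows(mmul(Qs, t(Ks)) / sqrt(D))
  Ssp <- Sch + mmul(atts, Vs)
  h <- Ssp %*% msam$W1$value
  h <- sweep(h, 2, msam$b1$value, `+`)
  h <- h * pnorm(h)
  S <- Ssp + sweep(h %*% msam$W2$value, 2, msam$b2$value, `+`)
  expect_equal(got$Fch, Fch, tolerance = 1e-5)
  expect_equal(got$Ssp, Ssp, tolerance = 1e-5)
  expect_equal(got$S, S, tolerance = 1e-5)
  # attention rows are probability distributions
  expect_equal(rowSums(got$att_ch), rep(1, D), tolerance = 1e-6)
  expect_equal(rowSums(got$att_sp), rep(1, 16), tolerance = 1e-6)
  expect_true(all(got$gate > 0 & got$gate < 1))
})

test_that("a single spatial token reduces channel attention to ch + V", {
  set.seed(41)
  D <- 8L
  msam <- new_msam(c(4L, 4L, 8L), D = D, align_groups = c(1, 1, 1),
                   out_groups = 1, token_groups = 1)
  z <- matrix(rnorm(D), 1, D) # one token: softmax over one key is 1
  got <- msam_refine_tokens(msam, z, internals = TRUE)
  V1 <- as.vector(z %*% msam$Wv$value)
  expect_equal(got$Fch,
               msam$ch$value + matrix(V1, D, D, byrow = TRUE),
               tolerance = 1e-10)
})

test_that("the fusion module replaces skips with matching shapes", {
  set.seed(42)
  msam <- new_msam(c(8L, 16L, 32L), D = 16L, align_groups = c(1, 1, 1),
                   out_groups = 1, token_groups = 1)
  F1 <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  F2 <- array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2))
  F3 <- array(rnorm(4 * 4 * 32 * 2), c(4, 4, 32, 2))
  s <- msam_forward(msam, F1, F2, F3)
  expect_identical(dim(s$S1), dim(F1))
  expect_identical(dim(s$S2), dim(F2))
  expect_identical(dim(s$S3), dim(F3))
  # token-count overflow guard
  msam2 <- new_msam(c(8L, 16L, 32L), D = 16L, align_groups = c(1, 1, 1),
                    out_groups = 1, token_groups = 1, max_tokens = 16L)
  expect_error(msam_forward(msam2, F1, F2, F3), "cap")
})

test_that("parallel attention matches a scalar pooling + MLP oracle", {
  set.seed(43)
  pam <- new_pam(2L, reduction = 1L)
  # give the zero-initialised layers random values so the oracle is sharp
  pam$W1$value[] <- rnorm(length(pam$W1$value), sd = 0.5)
  pam$b1$value[] <- rnorm(length(pam$b1$value), sd = 0.2)
  pam$sp$w$value[] <- rnorm(length(pam$sp$w$value), sd = 0.2)
  pam$sp$b$value[] <- rnorm(1, sd = 0.2)
  F <- array(rnorm(2 * 2 * 2 * 1), c(2, 2, 2, 1))
  got <- pam_forward(pam, F)
  # oracle: explicit pooling, MLP, 7x7 conv on the 2x2 grid
  avg <- sapply(1:2, function(c) mean(F[, , c, 1]))
  mx <- sapply(1:2, function(c) max(F[, , c, 1]))
  mlp <- function(v) {
    h <- pmax(as.vector(v %*% pam$W0$value) + pam$b0$value, 0)
    as.vector(h %*% pam$W1$value) + pam$b1$value
  }
  Mc <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  cm <- apply(F[, , , 1], c(1, 2), mean)
  cx <- apply(F[, , , 1], c(1, 2), max)
  sp <- array(0, c(2, 2, 2)); sp[, , 1] <- cm; sp[, , 2] <- cx
  k <- pam$sp$w$value # (7, 7, 2, 1)
  conv_at <- function(i, j) {
    s <- pam$sp$b$value[1]
    for (di in -3:3) for (dj in -3:3) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 2 && jj >= 1 && jj <= 2) {
        s <- s + sum(sp[ii, jj, ] * k[di + 4, dj + 4, , 1])
      }
    }
    s
  }
  Ms <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) Ms[i, j] <- 1 / (1 + exp(-conv_at(i, j)))
  ref <- array(0, dim(F))
  for (c in 1:2) ref[, , c, 1] <- F[, , c, 1] * Mc[c] + F[, , c, 1] * Ms
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("zero-initialised parallel attention is the identity", {
  pam <- new_pam(4L, reduction = 2L)
  for (p in c("W0", "b0", "W1", "b1")) pam[[p]]$value[] <- 0
  pam$sp$w$value[] <- 0
  pam$sp$b$value[] <- 0
  F <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  # Mc = Ms = sigmoid(0) = 0.5, so 0.5 F + 0.5 F = F
  expect_equal(pam_forward(pam, F), F, tolerance = 1e-12)
  # constant channels pool to the constant
  Fc <- array(rep(c(1.5, -2), each = 36), c(6, 6, 2, 1))
  ns <- asNamespace("mfaunet")
  expect_equal(ns$ad_global_avgpool(ns$ad_const(Fc))$value,
               matrix(c(1.5, -2), 2, 1))
  expect_equal(ns$ad_global_maxpool(ns$ad_const(Fc))$value,
               matrix(c(1.5, -2), 2, 1))
})

test_that("the multi-branch head keeps resolution and trains all branches", {
  set.seed(44)
  mbdm <- new_mbdm(4L, branch_channels = 2L)
  F <- array(rnorm(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  outs <- mbdm_forward(mbdm, F)
  expect_named(outs, c("branch1", "branch2", "fusion"))
  for (o in outs) expect_identical(dim(o), c(16L, 16L, 1L, 2L))
  # gradient flows into every branch's parameters under the total loss
  ns <- asNamespace("mfaunet")
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  ns$ad_tape_begin()
  node_outs <- mbdm$fwd(ns$ad_const(F))
  loss <- deep_supervision_loss(node_outs, y)
  ns$ad_backward(loss)
  ns$ad_tape_end()
  for (mod in c("c7", "p1", "c9", "p2", "cf", "pf")) {
    expect_gt(max(abs(mbdm[[mod]]$w$grad)), 0)
  }
})

test_that("autodiff gradients of a small network match finite differences", {
  set.seed(45)
  ns <- asNamespace("mfaunet")
  cfg <- model_config(encoder_channels = c(2L, 4L, 8L, 16L),
                      msam_align_groups = c(1, 1, 1), msam_out_groups = 1,
                      msam_token_groups = 1, pam_reduction = 2,
                      mbdm_branch_channels = 2L, seed = 9)
  m <- mfa_unet(cfg)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  y <- array(rbinom(256, 1, 0.2), c(16, 16, 1, 1))
  fwd <- function() {
    deep_supervision_loss(ns$nn_forward(m, ns$ad_const(x)), y)
  }
  ns$ad_tape_begin()
  loss <- fwd()
  ns$ad_backward(loss)
  ns$ad_tape_end()
  # a small step keeps the central difference on one side of the ReLU /
  # max-pool kinks a deep network is full of
  eps <- 1e-6
  picks <- c("stem.conv.w", "msam.Wq", "msam.ch", "pam1.W0",
             "head.c9.w", "dec2.fuse.conv.w", "enc4.c2.conv.w")
  for (nm in picks) {
    p <- m$params[[nm]]
    g <- p$grad
    i <- which.max(abs(g))
    v0 <- p$value[i]
    p$value[i] <- v0 + eps
    ns$ad_tape_begin(); l1 <- fwd()$value; ns$ad_tape_end()
    p$value[i] <- v0 - eps
    ns$ad_tape_begin(); l2 <- fwd()$value; ns$ad_tape_end()
    p$value[i] <- v0
    expect_equal(g[i], (l1 - l2) / (2 * eps), tolerance = 1e-2,
                 label = paste("gradient of", nm))
  }
  for (p in m$params) p$grad <- NULL
})
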