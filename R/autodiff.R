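# Reverse-mode automatic differentiation on dense arrays.
#
# A minimal tape machine sized for this package's networks: values are plain
# R arrays (feature maps use the column-major layout (H, W, C, N); token
# matrices are (tokens x dim)). Every op records a closure that propagates the
# output gradient to its parents; backward() replays the tape in reverse
# creation order, which is a valid topological order for a define-by-run
# graph. Heavy kernels (grouped convolution) live in src/ and are called
# through .cpp_conv2d_fw / .cpp_conv2d_bw.
#
# Nodes are environments with fields:
#   value  array / matrix / scalar
#   grad   accumulated gradient (NULL until backward reaches the node)
#   rg     TRUE if the node depends on a parameter (requires grad)
#   bw     closure(g) pushing g to the parents, or NULL for leaves

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_begin <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  .ad$tape <- t
  invisible(t)
}

ad_tape_end <- function() {
  .ad$tape <- NULL
  invisible()
}

ad_leaf <- function(value, rg = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$rg <- rg
  nd$bw <- NULL
  class(nd) <- "ad_node"
  nd
}

#' @noRd
ad_param <- function(value) ad_leaf(value, rg = TRUE)

ad_const <- function(value) ad_leaf(value, rg = FALSE)

# Record a computed node on the active tape. When no tape is active (pure
# inference) or the node does not require gradients, the backward closure is
# dropped so intermediate caches can be collected.
ad_record <- function(value, rg, bw) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$rg <- rg
  t <- .ad$tape
  if (rg && !is.null(t)) {
    nd$bw <- bw
    t$n <- t$n + 1L
    if (t$n > length(t$nodes)) length(t$nodes) <- 2L * length(t$nodes)
    t$nodes[[t$n]] <- nd
  } else {
    nd$bw <- NULL
  }
  class(nd) <- "ad_node"
  nd
}

ad_acc <- function(node, g) {
  if (isTRUE(node$rg)) {
    node$grad <- if (is.null(node$grad)) g else node$grad + g
  }
  invisible()
}

# Backpropagate from a scalar loss node through the active tape.
ad_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  t <- .ad$tape
  if (is.null(t)) stop("no active tape; wrap the forward pass in ad_tape_begin()")
  loss$grad <- 1
  for (i in rev(seq_len(t$n))) {
    nd <- t$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
    t$nodes[i] <- list(NULL) # release caches as we go
  }
  t$n <- 0L
  invisible()
}

## ---- elementwise -----------------------------------------------------------

ad_add <- function(a, b) {
  v <- a$value + b$value
  ad_record(v, a$rg || b$rg, function(g) {
    ad_acc(a, g)
    ad_acc(b, g)
  })
}

ad_sub <- function(a, b) {
  v <- a$value - b$value
  ad_record(v, a$rg || b$rg, function(g) {
    ad_acc(a, g)
    ad_acc(b, -g)
  })
}

ad_mul <- function(a, b) {
  v <- a$value * b$value
  ad_record(v, a$rg || b$rg, function(g) {
    ad_acc(a, g * b$value)
    ad_acc(b, g * a$value)
  })
}

ad_smul <- function(a, s) {
  ad_record(a$value * s, a$rg, function(g) ad_acc(a, g * s))
}

ad_relu <- function(a) {
  v <- a$value
  neg <- which(v < 0)
  v[neg] <- 0
  ad_record(v, a$rg, function(g) {
    g[neg] <- 0
    ad_acc(a, g)
  })
}

ad_leakyrelu <- function(a, slope = 0.1) {
  v <- a$value
  neg <- which(v < 0)
  v[neg] <- v[neg] * slope
  ad_record(v, a$rg, function(g) {
    g[neg] <- g[neg] * slope
    ad_acc(a, g)
  })
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_record(s, a$rg, function(g) ad_acc(a, g * s * (1 - s)))
}

# Exact (erf-based) GELU: x * Phi(x); d/dx = Phi(x) + x phi(x).
ad_gelu <- function(a) {
  ph <- stats::pnorm(a$value)
  ad_record(a$value * ph, a$rg, function(g) {
    ad_acc(a, g * (ph + a$value * stats::dnorm(a$value)))
  })
}

## ---- convolution and bias --------------------------------------------------

ad_conv2d <- function(x, w, b, stride = 1L, pad = NULL, groups = 1L) {
  if (is.null(pad)) pad <- (dim(w$value)[1] - 1L) %/% 2L
  v <- .cpp_conv2d_fw(x$value, w$value, b$value, as.integer(stride),
                      as.integer(pad), as.integer(groups))
  rg <- x$rg || w$rg || b$rg
  ad_record(v, rg, function(g) {
    r <- .cpp_conv2d_bw(x$value, w$value, g, as.integer(stride),
                        as.integer(pad), as.integer(groups),
                        isTRUE(x$rg))
    ad_acc(x, r$gx)
    ad_acc(w, r$gw)
    ad_acc(b, r$gb)
  })
}

## ---- normalisation ---------------------------------------------------------

# Group normalisation over (H, W, C/groups) per sample, with per-channel
# affine parameters. Fused compiled forward/backward using the standard
# closed form dx = (1/sigma)(dyhat - mean(dyhat) - xhat * mean(dyhat*xhat)).
ad_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  f <- .cpp_groupnorm_fw(x$value, gamma$value, beta$value,
                         as.integer(groups), eps)
  rg <- x$rg || gamma$rg || beta$rg
  ad_record(f$y, rg, function(g) {
    r <- .cpp_groupnorm_bw(g, f$xhat, f$inv, gamma$value,
                           as.integer(groups))
    ad_acc(x, r$gx)
    ad_acc(gamma, r$ggamma)
    ad_acc(beta, r$gbeta)
  })
}

## ---- resampling ------------------------------------------------------------

# Separable resize operator matrix: box-average rows for downsampling,
# bilinear (half-pixel centres) rows for upsampling. Backward is the
# transposed operator.
resize_matrix <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_in))
  A <- matrix(0, n_out, n_in)
  if (n_out < n_in) {
    r <- n_in / n_out
    for (i in seq_len(n_out)) {
      lo <- floor((i - 1) * r) + 1
      hi <- ceiling(i * r)
      idx <- lo:hi
      wts <- rep(1, length(idx))
      wts[1] <- lo - (i - 1) * r
      wts[length(idx)] <- i * r - (hi - 1)
      A[i, idx] <- wts / sum(wts)
    }
  } else {
    scale <- n_in / n_out
    for (i in seq_len(n_out)) {
      src <- (i - 0.5) * scale - 0.5
      lo <- floor(src)
      f <- src - lo
      i0 <- min(max(lo + 1, 1), n_in)
      i1 <- min(max(lo + 2, 1), n_in)
      A[i, i0] <- A[i, i0] + (1 - f)
      A[i, i1] <- A[i, i1] + f
    }
  }
  A
}

# Apply y[h2, w2, c, n] = sum_{h, w} Ah[h2, h] Aw[w2, w] x[h, w, c, n].
apply_resize <- function(x, Ah, Aw) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  H2 <- nrow(Ah); W2 <- nrow(Aw)
  y <- Ah %*% matrix(x, H, W * C * N)              # (H2, W*C*N)
  y <- array(y, c(H2, W, C, N))
  y <- aperm(y, c(2, 1, 3, 4))                     # (W, H2, C, N)
  y <- Aw %*% matrix(y, W, H2 * C * N)             # (W2, H2*C*N)
  y <- array(y, c(W2, H2, C, N))
  aperm(y, c(2, 1, 3, 4))
}

ad_resize <- function(x, H2, W2) {
  d <- dim(x$value)
  if (d[1] == H2 && d[2] == W2) return(x)
  Ah <- resize_matrix(d[1], H2)
  Aw <- resize_matrix(d[2], W2)
  v <- apply_resize(x$value, Ah, Aw)
  ad_record(v, x$rg, function(g) ad_acc(x, apply_resize(g, t(Ah), t(Aw))))
}

## ---- pooling ---------------------------------------------------------------

ad_global_avgpool <- function(x) {
  d <- dim(x$value)
  HW <- d[1] * d[2]
  v <- matrix(colMeans(matrix(x$value, HW, d[3] * d[4])), d[3], d[4])
  ad_record(v, x$rg, function(g) {
    ad_acc(x, array(rep(as.vector(g) / HW, each = HW), dim = d))
  })
}

ad_global_maxpool <- function(x) {
  d <- dim(x$value)
  HW <- d[1] * d[2]
  m <- matrix(x$value, HW, d[3] * d[4])
  idx <- max.col(t(m), ties.method = "first")
  v <- matrix(m[cbind(idx, seq_along(idx))], d[3], d[4])
  ad_record(v, x$rg, function(g) {
    gm <- matrix(0, HW, d[3] * d[4])
    gm[cbind(idx, seq_along(idx))] <- as.vector(g)
    ad_acc(x, array(gm, dim = d))
  })
}

# Mean and max over the channel dimension, returned as (H, W, 1, N) maps.
ad_channel_mean <- function(x) {
  d <- dim(x$value)
  v <- x$value[, , 1, , drop = FALSE]
  if (d[3] > 1) for (c in 2:d[3]) v <- v + x$value[, , c, , drop = FALSE]
  v <- v / d[3]
  ad_record(v, x$rg, function(g) {
    ad_acc(x, g[, , rep(1L, d[3]), , drop = FALSE] / d[3])
  })
}

ad_channel_max <- function(x) {
  d <- dim(x$value)
  v <- x$value[, , 1, , drop = FALSE]
  arg <- array(1L, dim(v))
  if (d[3] > 1) {
    for (c in 2:d[3]) {
      xc <- x$value[, , c, , drop = FALSE]
      gt <- xc > v
      v[gt] <- xc[gt]
      arg[gt] <- c
    }
  }
  ad_record(v, x$rg, function(g) {
    gx <- array(0, d)
    for (c in seq_len(d[3])) {
      sel <- arg == c
      slice <- array(0, dim(v))
      slice[sel] <- g[sel]
      gx[, , c, ] <- slice
    }
    ad_acc(x, gx)
  })
}

## ---- channel plumbing ------------------------------------------------------

ad_concat_c <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  v <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$value
  v[, , da[3] + seq_len(db[3]), ] <- b$value
  ad_record(v, a$rg || b$rg, function(g) {
    ad_acc(a, g[, , seq_len(da[3]), , drop = FALSE])
    ad_acc(b, g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# Per-channel, per-sample scaling: x is (H, W, C, N), s is (C, N).
ad_scale_channels <- function(x, s) {
  d <- dim(x$value)
  HW <- d[1] * d[2]
  sf <- array(rep(as.vector(s$value), each = HW), dim = d)
  v <- x$value * sf
  ad_record(v, x$rg || s$rg, function(g) {
    ad_acc(x, g * sf)
    if (isTRUE(s$rg)) {
      ad_acc(s, matrix(colSums(matrix(g * x$value, HW, d[3] * d[4])),
                       d[3], d[4]))
    }
  })
}

# Per-pixel, per-sample scaling: s is (H, W, 1, N), broadcast over channels.
ad_scale_spatial <- function(x, s) {
  d <- dim(x$value)
  sf <- s$value[, , rep(1L, d[3]), , drop = FALSE]
  v <- x$value * sf
  ad_record(v, x$rg || s$rg, function(g) {
    ad_acc(x, g * sf)
    if (isTRUE(s$rg)) {
      gs <- matrix(aperm(g * x$value, c(1, 2, 4, 3)),
                   d[1] * d[2] * d[4], d[3])
      ad_acc(s, array(aperm(array(rowSums(gs), c(d[1], d[2], d[4], 1)),
                            c(1, 2, 4, 3)), c(d[1], d[2], 1, d[4])))
    }
  })
}

## ---- token / matrix ops ----------------------------------------------------

ad_matmul <- function(a, b) {
  v <- a$value %*% b$value
  ad_record(v, a$rg || b$rg, function(g) {
    ad_acc(a, g %*% t(b$value))
    ad_acc(b, crossprod(a$value, g))
  })
}

# x (n x d) %*% W (d x k) + bias (k), bias broadcast across rows.
ad_linear <- function(x, W, b) {
  v <- x$value %*% W$value
  v <- v + rep(b$value, each = nrow(v))
  ad_record(v, x$rg || W$rg || b$rg, function(g) {
    ad_acc(x, g %*% t(W$value))
    ad_acc(W, crossprod(x$value, g))
    ad_acc(b, colSums(g))
  })
}

ad_t <- function(a) {
  ad_record(t(a$value), a$rg, function(g) ad_acc(a, t(g)))
}

ad_softmax_rows <- function(a) {
  rmax <- a$value[cbind(seq_len(nrow(a$value)),
                        max.col(a$value, ties.method = "first"))]
  v <- exp(a$value - rmax)
  v <- v / rowSums(v)
  ad_record(v, a$rg, function(g) {
    ad_acc(a, v * (g - rowSums(g * v)))
  })
}

# Column-wise scaling of a token matrix (tokens x D) by a length-D gate.
ad_scale_cols <- function(z, gate) {
  n <- nrow(z$value)
  gf <- rep(as.vector(gate$value), each = n)
  v <- z$value * gf
  ad_record(v, z$rg || gate$rg, function(g) {
    ad_acc(z, g * gf)
    if (isTRUE(gate$rg)) ad_acc(gate, matrix(colSums(g * z$value), ncol = 1))
  })
}

# Extract sample n of a feature map as a (H*W x C) token matrix.
ad_tokens_from <- function(x, n) {
  d <- dim(x$value)
  v <- matrix(x$value[, , , n], d[1] * d[2], d[3])
  ad_record(v, x$rg, function(g) {
    if (isTRUE(x$rg)) {
      if (is.null(x$grad)) x$grad <- array(0, d)
      x$grad[, , , n] <- x$grad[, , , n] + array(as.vector(g),
                                                 c(d[1], d[2], d[3]))
    }
  })
}

# Reassemble per-sample token matrices into a (H, W, C, N) feature map.
ad_tokens_to <- function(tokens, H, W) {
  N <- length(tokens)
  C <- ncol(tokens[[1]]$value)
  v <- array(0, c(H, W, C, N))
  for (n in seq_len(N)) v[, , , n] <- array(tokens[[n]]$value, c(H, W, C))
  rg <- any(vapply(tokens, function(t) isTRUE(t$rg), TRUE))
  ad_record(v, rg, function(g) {
    for (n in seq_len(N)) {
      ad_acc(tokens[[n]], matrix(g[, , , n], H * W, C))
    }
  })
}

## ---- reductions and losses -------------------------------------------------

ad_mean_all <- function(x) {
  n <- length(x$value)
  ad_record(mean(x$value), x$rg, function(g) {
    ad_acc(x, array(g / n, dim = dim(x$value) %||% n))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Binary cross-entropy on probabilities, clipped to [eps, 1-eps]; the clip
# has zero gradient outside the open interval so gradients stay finite at
# p in {0, 1}.
ad_bce <- function(p, y, eps = 1e-7) {
  yv <- if (inherits(y, "ad_node")) y$value else y
  pc <- pmin(pmax(p$value, eps), 1 - eps)
  n <- length(pc)
  v <- -sum(yv * log(pc) + (1 - yv) * log(1 - pc)) / n
  ad_record(v, p$rg, function(g) {
    inside <- (p$value > eps) & (p$value < 1 - eps)
    dp <- (-(yv / pc) + (1 - yv) / (1 - pc)) / n
    ad_acc(p, array(as.vector(g * dp * inside), dim = dim(p$value) %||% n))
  })
}

# Soft Dice loss on probabilities (foreground channel), smoothed.
ad_dice <- function(p, y, smooth = 1) {
  yv <- if (inherits(y, "ad_node")) y$value else y
  num <- 2 * sum(yv * p$value) + smooth
  den <- sum(yv * yv + p$value * p$value) + smooth
  v <- 1 - num / den
  ad_record(v, p$rg, function(g) {
    dp <- -(2 * yv * den - num * 2 * p$value) / (den * den)
    ad_acc(p, array(as.vector(g * dp), dim = dim(p$value)))
  })
}
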