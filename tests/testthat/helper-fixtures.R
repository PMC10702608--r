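# Shared fixtures: all synthetic, generated in code at test time.

# Desk-scale model configuration used by the miniature training studies.
desk_model_config <- function(...) model_config_small(...)

# A tiny aligned image/mask pair with a dark bar on a bright background.
toy_pair <- function(H = 32L, W = 32L) {
  img <- matrix(0.7, H, W)
  msk <- matrix(0L, H, W)
  msk[, (W %/% 2 - 1):(W %/% 2 + 1)] <- 1L
  img[msk == 1] <- 0.3
  list(image = img, mask = msk)
}

# In-memory synthetic dataset shared across engine tests.
small_synth_dataset <- function(n = 4L, size = 96L, seed = 300L) {
  synth_dataset(synth_config(image_size = as.integer(size), seed = seed), n)
}

# Naive scalar-loop 2-D convolution oracle (dense, stride 1, same padding).
naive_conv2d <- function(x, w, b) {
  kh <- dim(w)[1]; kw <- dim(w)[2]
  cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  xp <- array(0, c(H + 2 * ph, W + 2 * pw, cin))
  xp[ph + seq_len(H), pw + seq_len(W), ] <- x
  out <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(H)) for (j in seq_len(W)) {
      s <- b[co]
      for (ci in seq_len(cin)) {
        s <- s + sum(xp[i:(i + kh - 1), j:(j + kw - 1), ci] * w[, , ci, co])
      }
      out[i, j, co] <- s
    }
  }
  out
}
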