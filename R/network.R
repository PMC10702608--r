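# The MFA-UNet architecture: a compact residual encoder-decoder for retinal
# vessel segmentation with three optional modules:
#   * MSAM - multi-scale fusion self-attention on the skip paths: the three
#     deepest encoder features are resampled to the middle scale, summed,
#     tokenised, passed through channel self-attention (a learned channel
#     embedding queries the spatial tokens), spatial self-attention, and a
#     token MLP, then resampled back to replace the skip features.
#   * PAM - parallel channel + spatial attention (CBAM-style, applied in
#     parallel and summed) after each decoder block.
#   * MBDM - deep-supervised multi-branch head: a 7x7 branch trained with BCE
#     (macrovessels), a 9x9 branch trained with Dice (microvessels), and a
#     3x3/1x1 fusion branch combining their probability maps.
#
# Parameter budget: the reference configuration is deliberately lean (about
# 2.4 M trainable parameters, under 70% of a plain U-Net) via bottleneck
# residual blocks at the wide stages, depthwise large-kernel downsampling,
# and grouped convolutions for the MSAM channel-alignment layers.

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Largest group count <= g that divides both channel counts.
eff_groups <- function(g, cin, cout) {
  d <- gcd2(cin, cout)
  divs <- which(d %% seq_len(d) == 0)
  max(divs[divs <= max(1, g)])
}

norm_groups <- function(C, g = 8) eff_groups(g, C, C)

#' Model configuration for MFA-UNet
#'
#' Collects every architectural hyperparameter. The defaults are the
#' reference configuration whose trainable-parameter count is about 2.4
#' million with all modules enabled and about 1.9 million with all modules
#' disabled.
#'
#' @param encoder_channels Integer vector of four strictly increasing stage
#'   widths; skips at the first three widths, bottom feature at the fourth.
#' @param msam_token_dim Token dimension `D` of the fusion self-attention;
#'   defaults to the third encoder width (the fused channel count).
#' @param msam_mlp_ratio Expansion ratio of the token MLP.
#' @param msam_align_groups Convolution groups for the three MSAM
#'   channel-alignment 3x3 convolutions (clamped to divide the channels).
#' @param msam_out_groups,msam_token_groups Groups for the MSAM output and
#'   token 1x1 convolutions.
#' @param msam_max_tokens Guard on the spatial token count at the fusion
#'   scale; exceeding it is an error.
#' @param pam_reduction Channel-MLP reduction ratio of the parallel attention.
#' @param mbdm_branch_channels Hidden width of the two MBDM branches.
#' @param downsample_kernel Odd kernel size of the large-kernel strided
#'   downsampling convolutions.
#' @param dense_down_stages Number of leading downsampling stages using a
#'   dense (rather than depthwise + pointwise) strided convolution.
#' @param enc_block_ratio,dec_block_ratio Bottleneck reduction ratio per
#'   encoder/decoder residual block (1 = plain double 3x3 convolution).
#' @param use_msam,use_pam,use_mbdm Module toggles for ablations.
#' @param seed Integer seed fixing the weight initialisation.
#' @return An object of class `mfa_model_config`.
#' @export
model_config <- function(encoder_channels = c(64L, 128L, 256L, 512L),
                         msam_token_dim = NULL,
                         msam_mlp_ratio = 0.125,
                         msam_align_groups = c(8L, 16L, 64L),
                         msam_out_groups = 16L,
                         msam_token_groups = 16L,
                         msam_max_tokens = 4096L,
                         pam_reduction = 8L,
                         mbdm_branch_channels = 8L,
                         downsample_kernel = 5L,
                         dense_down_stages = 1L,
                         enc_block_ratio = c(1L, 1L, 2L, 4L),
                         dec_block_ratio = c(2L, 2L, 1L),
                         use_msam = TRUE,
                         use_pam = TRUE,
                         use_mbdm = TRUE,
                         seed = 42L) {
  ec <- as.integer(encoder_channels)
  if (length(ec) != 4L || any(diff(ec) <= 0))
    stop("encoder_channels must be four strictly increasing integers")
  if (downsample_kernel %% 2L != 1L) stop("downsample_kernel must be odd")
  if (msam_mlp_ratio <= 0) stop("msam_mlp_ratio must be positive")
  cfg <- list(
    encoder_channels = ec,
    msam_token_dim = as.integer(msam_token_dim %||% ec[3]),
    msam_mlp_ratio = msam_mlp_ratio,
    msam_align_groups = as.integer(msam_align_groups),
    msam_out_groups = as.integer(msam_out_groups),
    msam_token_groups = as.integer(msam_token_groups),
    msam_max_tokens = as.integer(msam_max_tokens),
    pam_reduction = as.integer(pam_reduction),
    mbdm_branch_channels = as.integer(mbdm_branch_channels),
    downsample_kernel = as.integer(downsample_kernel),
    dense_down_stages = as.integer(dense_down_stages),
    enc_block_ratio = as.integer(enc_block_ratio),
    dec_block_ratio = as.integer(dec_block_ratio),
    use_msam = isTRUE(use_msam),
    use_pam = isTRUE(use_pam),
    use_mbdm = isTRUE(use_mbdm),
    seed = as.integer(seed)
  )
  class(cfg) <- "mfa_model_config"
  cfg
}

#' A slimmed configuration for desk-scale experiments
#'
#' Same topology as the reference configuration at one-sixteenth of the
#' channel widths (~16k parameters); used for the miniature CPU training
#' studies in the tests and the vignette.
#' @param ... Overrides passed on to [model_config()].
#' @export
model_config_small <- function(...) {
  model_config(encoder_channels = c(4L, 8L, 16L, 32L),
               msam_align_groups = c(1L, 2L, 4L),
               msam_out_groups = 1L, msam_token_groups = 1L,
               pam_reduction = 4L, mbdm_branch_channels = 2L, ...)
}

## ---- module constructors ---------------------------------------------------

mod_conv <- function(cin, cout, k, stride = 1L, groups = 1L) {
  g <- eff_groups(groups, cin, cout)
  fan_in <- k * k * cin / g
  w <- ad_param(array(stats::rnorm(k * k * (cin / g) * cout,
                                   sd = sqrt(2 / fan_in)),
                      c(k, k, cin / g, cout)))
  b <- ad_param(numeric(cout))
  pad <- (k - 1L) %/% 2L
  list(kind = "conv", w = w, b = b,
       fwd = function(x) ad_conv2d(x, w, b, stride, pad, g))
}

mod_norm <- function(C) {
  gamma <- ad_param(rep(1, C))
  beta <- ad_param(numeric(C))
  g <- norm_groups(C)
  list(kind = "norm", gamma = gamma, beta = beta,
       fwd = function(x) ad_groupnorm(x, gamma, beta, g))
}

# conv -> groupnorm -> optional ReLU
mod_cnr <- function(cin, cout, k, stride = 1L, groups = 1L, act = TRUE) {
  cv <- mod_conv(cin, cout, k, stride, groups)
  nm <- mod_norm(cout)
  list(kind = "cnr", conv = cv, norm = nm,
       fwd = function(x) {
         h <- nm$fwd(cv$fwd(x))
         if (act) ad_relu(h) else h
       })
}

# Residual block: plain double 3x3 when ratio <= 1, bottleneck otherwise.
mod_block <- function(C, ratio = 1L) {
  if (ratio <= 1L) {
    c1 <- mod_cnr(C, C, 3L)
    c2 <- mod_cnr(C, C, 3L, act = FALSE)
    list(kind = "block", c1 = c1, c2 = c2,
         fwd = function(x) ad_relu(ad_add(c2$fwd(c1$fwd(x)), x)))
  } else {
    Cm <- max(1L, C %/% ratio)
    c1 <- mod_cnr(C, Cm, 1L)
    c2 <- mod_cnr(Cm, Cm, 3L)
    c3 <- mod_cnr(Cm, C, 1L, act = FALSE)
    list(kind = "block", c1 = c1, c2 = c2, c3 = c3,
         fwd = function(x) ad_relu(ad_add(c3$fwd(c2$fwd(c1$fwd(x))), x)))
  }
}

# Large-kernel strided downsampling. The first (narrow) stage can afford a
# dense strided convolution; deeper stages use a depthwise strided kernel
# followed by a pointwise channel expansion to keep the parameter budget.
mod_down <- function(cin, cout, k, dense = FALSE) {
  if (dense) {
    cv <- mod_cnr(cin, cout, k, stride = 2L)
    return(list(kind = "down", cv = cv, fwd = function(x) cv$fwd(x)))
  }
  dw <- mod_conv(cin, cin, k, stride = 2L, groups = cin)
  pw <- mod_cnr(cin, cout, 1L)
  list(kind = "down", dw = dw, pw = pw,
       fwd = function(x) pw$fwd(dw$fwd(x)))
}

# Decoder stage: bilinear 2x upsample + pointwise reduce, concatenate the
# skip feature, pointwise fuse, residual block.
mod_up <- function(cin, cout, ratio) {
  red <- mod_cnr(cin, cout, 1L)
  fuse <- mod_cnr(2L * cout, cout, 1L)
  blk <- mod_block(cout, ratio)
  list(kind = "up", red = red, fuse = fuse, blk = blk,
       fwd = function(x, skip) {
         d <- dim(skip$value)
         h <- red$fwd(ad_resize(x, d[1], d[2]))
         blk$fwd(fuse$fwd(ad_concat_c(h, skip)))
       })
}

#' Parallel attention module (channel + spatial attention in parallel)
#'
#' Channel weights come from a shared two-layer MLP applied to global average
#' and max pooled descriptors; spatial weights from a 7x7 convolution over the
#' channel-pooled mean/max maps. Both pass through a logistic sigmoid and the
#' two reweighted feature maps are summed.
#'
#' @param C Number of input channels.
#' @param reduction Channel-MLP reduction ratio.
#' @return A PAM module (list with a `fwd` closure and parameter nodes).
#' @export
new_pam <- function(C, reduction = 8L) {
  Cr <- max(1L, C %/% reduction)
  W0 <- ad_param(matrix(stats::rnorm(C * Cr, sd = sqrt(1 / C)), C, Cr))
  b0 <- ad_param(numeric(Cr))
  # second MLP layer and spatial kernel start at zero: sigma(0) = 1/2 on
  # both attention maps makes the module the exact identity at build time
  W1 <- ad_param(matrix(0, Cr, C))
  b1 <- ad_param(numeric(C))
  sp <- mod_conv(2L, 1L, 7L)
  sp$w$value[] <- 0
  sp$b$value[] <- 0
  mlp <- function(d) ad_linear(ad_relu(ad_linear(ad_t(d), W0, b0)), W1, b1)
  list(kind = "pam", W0 = W0, b0 = b0, W1 = W1, b1 = b1, sp = sp,
       fwd = function(F) {
         Mc <- ad_t(ad_sigmoid(ad_add(mlp(ad_global_avgpool(F)),
                                      mlp(ad_global_maxpool(F)))))
         Ms <- ad_sigmoid(sp$fwd(ad_concat_c(ad_channel_mean(F),
                                             ad_channel_max(F))))
         ad_add(ad_scale_channels(F, Mc), ad_scale_spatial(F, Ms))
       })
}

#' Multi-branch deep-supervision head
#'
#' Branch 1 (7x7 then 1x1, BCE-supervised) targets macrovessels; branch 2
#' (9x9 then 1x1, Dice-supervised) targets microvessels; the fusion branch
#' concatenates the two branch probability maps and refines them with 3x3 and
#' 1x1 convolutions. All three logits maps are returned.
#'
#' @param cin Input channel count (full-resolution decoder features).
#' @param branch_channels Hidden width of the branches.
#' @return An MBDM module (list with a `fwd` closure and parameter nodes).
#' @export
new_mbdm <- function(cin, branch_channels = 8L, prior_logit = -2) {
  bc <- branch_channels
  c7 <- mod_conv(cin, bc, 7L)
  p1 <- mod_conv(bc, 1L, 1L)
  c9 <- mod_conv(cin, bc, 9L)
  p2 <- mod_conv(bc, 1L, 1L)
  cf <- mod_conv(2L, bc, 3L)
  pf <- mod_conv(bc, 1L, 1L)
  # start the logits at the foreground prior so early training is spent on
  # discrimination rather than on matching the class marginal
  p1$b$value[] <- prior_logit
  p2$b$value[] <- prior_logit
  pf$b$value[] <- prior_logit
  list(kind = "mbdm", c7 = c7, p1 = p1, c9 = c9, p2 = p2, cf = cf, pf = pf,
       fwd = function(F) {
         # leaky activations: the thin branch convolutions must not die when
         # early training pulls every logit toward the class prior
         l1 <- p1$fwd(ad_leakyrelu(c7$fwd(F)))
         l2 <- p2$fwd(ad_leakyrelu(c9$fwd(F)))
         pr <- ad_concat_c(ad_sigmoid(l1), ad_sigmoid(l2))
         lf <- pf$fwd(ad_leakyrelu(cf$fwd(pr)))
         list(branch1 = l1, branch2 = l2, fusion = lf)
       })
}

#' Multi-scale fusion self-attention module
#'
#' Resamples the three deepest encoder features to the middle scale, aligns
#' them to `D` channels with grouped 3x3 convolutions and sums them into the
#' fusion feature. A 1x1 convolution tokenises the fusion feature; channel
#' self-attention (learned channel embeddings as queries, residual form
#' `ch + softmax(QK'/sqrt(D)) V`, followed by a sigmoid channel gate applied
#' to the tokens), spatial self-attention (tied projections, residual), and a
#' residual token MLP refine the tokens, which are reshaped and resampled
#' back to the three input shapes.
#'
#' @param channels Integer vector of the three skip channel counts.
#' @param D Token dimension (equals the fused channel count).
#' @param mlp_ratio Token MLP expansion ratio.
#' @param align_groups,out_groups,token_groups Convolution group counts.
#' @param max_tokens Guard on the spatial token count.
#' @return An MSAM module (list with a `fwd` closure and parameter nodes).
#' @export
new_msam <- function(channels, D, mlp_ratio = 0.25,
                     align_groups = c(8L, 16L, 32L), out_groups = 8L,
                     token_groups = 8L, max_tokens = 4096L) {
  stopifnot(length(channels) == 3L)
  a1 <- mod_conv(channels[1], D, 3L, groups = align_groups[1])
  a2 <- mod_conv(channels[2], D, 3L, groups = align_groups[2])
  a3 <- mod_conv(channels[3], D, 3L, groups = align_groups[3])
  tok <- mod_conv(D, D, 1L, groups = token_groups)
  ch <- ad_param(matrix(stats::rnorm(D * D, sd = 0.02), D, D))
  Wq <- ad_param(matrix(stats::rnorm(D * D, sd = sqrt(1 / D)), D, D))
  Wk <- ad_param(matrix(stats::rnorm(D * D, sd = sqrt(1 / D)), D, D))
  Wv <- ad_param(matrix(stats::rnorm(D * D, sd = sqrt(1 / D)), D, D))
  wg <- ad_param(matrix(stats::rnorm(D, sd = sqrt(1 / D)), D, 1))
  bg <- ad_param(numeric(1))
  dm <- max(1L, as.integer(round(D * mlp_ratio)))
  W1 <- ad_param(matrix(stats::rnorm(D * dm, sd = sqrt(1 / D)), D, dm))
  b1 <- ad_param(numeric(dm))
  W2 <- ad_param(matrix(stats::rnorm(dm * D, sd = sqrt(1 / dm)), dm, D))
  b2 <- ad_param(numeric(D))
  o1 <- mod_conv(D, channels[1], 1L, groups = out_groups)
  o2 <- mod_conv(D, channels[2], 1L, groups = out_groups)
  o3 <- mod_conv(D, channels[3], 1L, groups = out_groups)
  # zero-initialised output projections: the module starts as the identity
  # on the skip paths and learns a refinement, avoiding the early-training
  # transient of overwriting skips with an untrained attention transform
  for (o in list(o1, o2, o3)) {
    o$w$value[] <- 0
    o$b$value[] <- 0
  }
  refine <- function(z, internals = FALSE) {
    # channel self-attention: channel embedding queries the spatial tokens
    K <- ad_matmul(z, Wk)
    V <- ad_matmul(z, Wv)
    Q <- ad_matmul(ch, Wq)
    att <- ad_softmax_rows(ad_smul(ad_matmul(Q, ad_t(K)), 1 / sqrt(D)))
    Fch <- ad_add(ch, ad_matmul(att, V))
    gate <- ad_sigmoid(ad_linear(Fch, wg, bg))
    Sch <- ad_scale_cols(z, gate)
    # spatial self-attention over tokens (projections tied to the CSA)
    Qs <- ad_matmul(Sch, Wq)
    Ks <- ad_matmul(Sch, Wk)
    Vs <- ad_matmul(Sch, Wv)
    atts <- ad_softmax_rows(ad_smul(ad_matmul(Qs, ad_t(Ks)), 1 / sqrt(D)))
    Ssp <- ad_add(Sch, ad_matmul(atts, Vs))
    # token MLP with residual
    S <- ad_add(Ssp, ad_linear(ad_gelu(ad_linear(Ssp, W1, b1)), W2, b2))
    if (internals) {
      list(S = S, Fch = Fch, gate = gate, Sch = Sch, Ssp = Ssp,
           att_ch = att, att_sp = atts)
    } else S
  }
  list(kind = "msam", a1 = a1, a2 = a2, a3 = a3, tok = tok, ch = ch,
       Wq = Wq, Wk = Wk, Wv = Wv, wg = wg, bg = bg,
       W1 = W1, b1 = b1, W2 = W2, b2 = b2, o1 = o1, o2 = o2, o3 = o3,
       refine = refine,
       fwd = function(F1, F2, F3) {
         d1 <- dim(F1$value); d2 <- dim(F2$value); d3 <- dim(F3$value)
         if (d2[1] * d2[2] > max_tokens)
           stop("MSAM token count ", d2[1] * d2[2], " exceeds the cap ",
                max_tokens)
         Fa <- ad_add(ad_add(a1$fwd(ad_resize(F1, d2[1], d2[2])),
                             a2$fwd(F2)),
                      a3$fwd(ad_resize(F3, d2[1], d2[2])))
         Tm <- tok$fwd(Fa)
         N <- d2[4]
         S <- ad_tokens_to(lapply(seq_len(N), function(n) {
           refine(ad_tokens_from(Tm, n))
         }), d2[1], d2[2])
         # refined features enter the skip paths as residual corrections
         list(S1 = ad_add(F1, o1$fwd(ad_resize(S, d1[1], d1[2]))),
              S2 = ad_add(F2, o2$fwd(S)),
              S3 = ad_add(F3, o3$fwd(ad_resize(S, d3[1], d3[2]))))
       })
}

## ---- the full model --------------------------------------------------------

#' Build an MFA-UNet model
#'
#' Constructs the network with freshly initialised weights. Initialisation is
#' fully determined by `config$seed`; two builds with the same configuration
#' are bit-identical.
#'
#' @param config A [model_config()] object.
#' @return An object of class `mfa_unet`.
#' @examples
#' m <- mfa_unet(model_config_small())
#' m
#' @export
mfa_unet <- function(config = model_config()) {
  stopifnot(inherits(config, "mfa_model_config"))
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(config$seed)
  ec <- config$encoder_channels
  k <- config$downsample_kernel
  er <- config$enc_block_ratio
  dr <- config$dec_block_ratio
  mods <- list(
    stem = mod_cnr(1L, ec[1], 3L),
    enc1 = mod_block(ec[1], er[1]),
    down1 = mod_down(ec[1], ec[2], k, dense = config$dense_down_stages >= 1L),
    enc2 = mod_block(ec[2], er[2]),
    down2 = mod_down(ec[2], ec[3], k, dense = config$dense_down_stages >= 2L),
    enc3 = mod_block(ec[3], er[3]),
    down3 = mod_down(ec[3], ec[4], k, dense = config$dense_down_stages >= 3L),
    enc4 = mod_block(ec[4], er[4])
  )
  if (config$use_msam) {
    mods$msam <- new_msam(ec[2:4], config$msam_token_dim,
                          config$msam_mlp_ratio, config$msam_align_groups,
                          config$msam_out_groups, config$msam_token_groups,
                          config$msam_max_tokens)
  }
  mods$dec3 <- mod_up(ec[4], ec[3], dr[1])
  mods$dec2 <- mod_up(ec[3], ec[2], dr[2])
  mods$dec1 <- mod_up(ec[2], ec[1], dr[3])
  if (config$use_pam) {
    mods$pam3 <- new_pam(ec[3], config$pam_reduction)
    mods$pam2 <- new_pam(ec[2], config$pam_reduction)
    mods$pam1 <- new_pam(ec[1], config$pam_reduction)
  }
  if (config$use_mbdm) {
    mods$head <- new_mbdm(ec[1], config$mbdm_branch_channels)
  } else {
    mods$head <- mod_conv(ec[1], 1L, 1L)
    mods$head$b$value[] <- -2
  }
  model <- list(config = config, modules = mods,
                params = collect_params(mods))
  class(model) <- "mfa_unet"
  model
}

# Recursively collect every parameter node of a module tree.
collect_params <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "ad_node")) {
    if (isTRUE(x$rg)) out[[prefix]] <- x
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x)) {
      if (is.function(x[[i]]) || is.character(x[[i]])) next
      out <- c(out, collect_params(x[[i]],
                                   if (prefix == "") nms[i]
                                   else paste0(prefix, ".", nms[i])))
    }
  }
  out
}

#' Count trainable parameters
#'
#' @param model An `mfa_unet` model.
#' @return Integer number of trainable scalar parameters.
#' @examples
#' count_parameters(mfa_unet(model_config_small()))
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), 0))
}

# Full forward pass on a (H, W, 1, N) input node. Returns a named list of
# logits nodes: branch1/branch2/fusion with MBDM, fusion only without.
nn_forward <- function(model, x) {
  m <- model$modules
  # standardise [0, 1] intensities to [-1, 1] for better conditioning
  x <- ad_smul(ad_add(x, ad_const(-0.5)), 2)
  e1 <- m$enc1$fwd(m$stem$fwd(x))
  e2 <- m$enc2$fwd(m$down1$fwd(e1))
  e3 <- m$enc3$fwd(m$down2$fwd(e2))
  e4 <- m$enc4$fwd(m$down3$fwd(e3))
  if (!is.null(m$msam)) {
    s <- m$msam$fwd(e2, e3, e4)
    s1 <- s$S1; s2 <- s$S2; s3 <- s$S3
  } else {
    s1 <- e2; s2 <- e3; s3 <- e4
  }
  d3 <- m$dec3$fwd(s3, s2)
  if (!is.null(m$pam3)) d3 <- m$pam3$fwd(d3)
  d2 <- m$dec2$fwd(d3, s1)
  if (!is.null(m$pam2)) d2 <- m$pam2$fwd(d2)
  d1 <- m$dec1$fwd(d2, e1)
  if (!is.null(m$pam1)) d1 <- m$pam1$fwd(d1)
  if (model$config$use_mbdm) {
    m$head$fwd(d1)
  } else {
    list(fusion = m$head$fwd(d1))
  }
}

#' Forward pass on a batch of patches
#'
#' @param model An `mfa_unet` model.
#' @param x Numeric array `(H, W, 1, N)` (or `(H, W)` for a single patch) of
#'   preprocessed intensities in `[0, 1]`.
#' @param what `"probs"` for the sigmoid of the fusion logits, `"logits"` for
#'   all branch logits arrays.
#' @return `(H, W, 1, N)` array of fusion probabilities, or a list of logits
#'   arrays when `what = "logits"`.
#' @export
nn_predict <- function(model, x, what = c("probs", "logits")) {
  what <- match.arg(what)
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L, 1L))
  outs <- nn_forward(model, ad_const(x))
  if (what == "probs") {
    1 / (1 + exp(-outs$fusion$value))
  } else {
    lapply(outs, function(o) o$value)
  }
}

#' Token refinement of the fusion self-attention module
#'
#' Applies the channel self-attention, spatial self-attention and token MLP
#' of an MSAM to a bare token matrix. Exposed for inspection and for oracle
#' tests against naive loop implementations of scaled-dot-product attention.
#'
#' @param msam A module from [new_msam()].
#' @param z Token matrix (tokens x D).
#' @param internals Also return the attention maps, channel feature and gate?
#' @return Refined token matrix, or (with `internals`) a list of arrays:
#'   `S`, `Fch`, `gate`, `Sch`, `Ssp`, `att_ch`, `att_sp`.
#' @export
msam_refine_tokens <- function(msam, z, internals = FALSE) {
  out <- msam$refine(ad_const(z), internals = internals)
  if (internals) lapply(out, function(x) x$value) else out$value
}

#' Forward pass through the multi-scale fusion self-attention module
#'
#' Exposes the MSAM in isolation, operating on plain arrays; used for oracle
#' tests and inspection.
#'
#' @param msam A module from [new_msam()] (or the `msam` entry of a model).
#' @param F1,F2,F3 Skip feature arrays `(H, W, C, N)` at 1/2, 1/4, 1/8 scale.
#' @return List of arrays `S1`, `S2`, `S3` matching the input shapes.
#' @export
msam_forward <- function(msam, F1, F2, F3) {
  s <- msam$fwd(ad_const(F1), ad_const(F2), ad_const(F3))
  lapply(s, function(x) x$value)
}

#' Forward pass through the parallel attention module
#'
#' @param pam A module from [new_pam()].
#' @param F Feature array `(H, W, C, N)`.
#' @return Array of the same shape.
#' @export
pam_forward <- function(pam, F) {
  pam$fwd(ad_const(F))$value
}

#' Forward pass through the multi-branch decoder head
#'
#' @param mbdm A module from [new_mbdm()].
#' @param F Full-resolution feature array `(H, W, C, N)`.
#' @return List of logits arrays `branch1`, `branch2`, `fusion`.
#' @export
mbdm_forward <- function(mbdm, F) {
  lapply(mbdm$fwd(ad_const(F)), function(x) x$value)
}

## ---- S3 methods ------------------------------------------------------------

#' @export
print.mfa_unet <- function(x, ...) {
  cfg <- x$config
  cat("MFA-UNet segmentation network\n")
  cat("  encoder channels:", paste(cfg$encoder_channels, collapse = "/"),
      "\n")
  cat("  modules: MSAM", if (cfg$use_msam) "on" else "off",
      "| PAM", if (cfg$use_pam) "on" else "off",
      "| MBDM", if (cfg$use_mbdm) "on" else "off", "\n")
  cat(sprintf("  trainable parameters: %s (%.2f M)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

#' @export
summary.mfa_unet <- function(object, ...) {
  p <- vapply(object$params, function(q) length(q$value), 0)
  top <- vapply(strsplit(names(p), ".", fixed = TRUE), `[`, "", 1L)
  tab <- sort(tapply(p, top, sum), decreasing = TRUE)
  out <- list(by_module = tab, total = sum(p), config = object$config)
  class(out) <- "summary.mfa_unet"
  out
}

#' @export
print.summary.mfa_unet <- function(x, ...) {
  cat("Trainable parameters by module:\n")
  for (nm in names(x$by_module))
    cat(sprintf("  %-8s %10s\n", nm, format(x$by_module[[nm]],
                                            big.mark = ",")))
  cat(sprintf("  %-8s %10s\n", "total", format(x$total, big.mark = ",")))
  invisible(x)
}

#' @export
coef.mfa_unet <- function(object, ...) {
  lapply(object$params, function(p) p$value)
}

# Load a flat list of parameter values (as from coef) back into a model.
set_params <- function(model, values) {
  stopifnot(identical(names(model$params), names(values)))
  for (nm in names(values)) model$params[[nm]]$value <- values[[nm]]
  invisible(model)
}
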