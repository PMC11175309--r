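# The five sub-networks of the coupled fusion model and their dataflows.
#
# Parallel decomposition encoder (PDE): a stem of large-kernel convolution
# plus pooling feeds two parallel branches. The ViT branch (8x8 patches,
# 4 heads, depth 6, 10% dropout) produces base (low-frequency) features;
# the CNN branch produces detail (high-frequency) features. From the second
# of the two interaction stacks, each branch receives a transformed summary
# of the other. Transposed convolutions restore both outputs to the input
# resolution at 64 channels.
#
# Shapes follow the package convention [H, W, C, N]; the canonical NCHW
# tensor [N,1,H,W] of the model description corresponds to an R array
# [H, W, 1, N].

#' Model architecture configuration
#'
#' @param image_size training image side in pixels (divisible by 32)
#' @param patch_size ViT patch side on the post-stem feature map
#' @param n_heads self-attention heads
#' @param vit_depth total transformer blocks, split across the interaction stacks
#' @param drop_rate dropout rate in transformer blocks
#' @param n_stacks interaction stacks (interaction active from the second)
#' @param stem_kernel stem convolution kernel size
#' @param channels encoder output channels per branch
#' @param decoder_dim channel width inside the fusion/reconstruction decoders
#' @return list of class `cirf_model_config`
#' @export
model_config <- function(image_size = 256L, patch_size = 8L, n_heads = 4L,
                         vit_depth = 6L, drop_rate = 0.1, n_stacks = 2L,
                         stem_kernel = 7L, channels = 64L, decoder_dim = 32L) {
  stopifnot(vit_depth %% n_stacks == 0, n_stacks >= 1)
  structure(list(image_size = as.integer(image_size), patch_size = as.integer(patch_size),
                 n_heads = as.integer(n_heads), vit_depth = as.integer(vit_depth),
                 drop_rate = drop_rate, n_stacks = as.integer(n_stacks),
                 stem_kernel = as.integer(stem_kernel), channels = as.integer(channels),
                 decoder_dim = as.integer(decoder_dim)),
            class = "cirf_model_config")
}

check_hw <- function(h, w) {
  if (h %% 32L != 0L || w %% 32L != 0L)
    stop("input height and width must be divisible by 32 (stem pooling x patching); got ",
         h, "x", w)
}

as_batch <- function(x) {
  # accept a matrix, [H,W,1] or [H,W,1,N]
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

## ---- PDE: parallel decomposition encoder ------------------------------------

build_pde <- function(cfg) {
  ch <- cfg$channels
  d <- ch  # token embedding dimension
  per_stack <- cfg$vit_depth %/% cfg$n_stacks
  grid <- cfg$image_size %/% (2L * cfg$patch_size)
  m <- nn_module("pde")
  m$cfg <- cfg
  m$grid0 <- grid
  m$children$stem1 <- layer_conv(1L, 32L, cfg$stem_kernel)
  m$children$stem2 <- layer_conv(32L, 32L, 3L)
  m$children$vit_pre <- layer_conv(32L, ch, 3L)
  m$children$patch <- layer_conv(ch, d, cfg$patch_size, stride = cfg$patch_size, pad = 0L)
  m$params$pos <- tg_param(init_trunc_normal(c(grid * grid, d)))
  for (s in seq_len(cfg$n_stacks)) {
    for (b in seq_len(per_stack)) {
      m$children[[sprintf("vit_s%d_b%d", s, b)]] <-
        layer_vit_block(d, cfg$n_heads, cfg$drop_rate)
    }
  }
  m$children$cnn_pre <- layer_conv(32L, ch, 3L)
  for (s in seq_len(cfg$n_stacks)) {
    m$children[[sprintf("cnn_s%d_c1", s)]] <- layer_conv(ch, ch, 3L)
    m$children[[sprintf("cnn_s%d_bn1", s)]] <- layer_batchnorm(ch)
  }
  # detail -> base interaction: pool, flatten, layer-norm
  m$children$d2b_ln <- layer_layernorm(d)
  # base -> detail interaction: reshape, interpolate, batch-norm
  m$children$b2d_bn <- layer_batchnorm(ch)
  m$children$base_up1 <- layer_convt(d, ch, cfg$patch_size, stride = cfg$patch_size, pad = 0L)
  m$children$base_up2 <- layer_convt(ch, ch, 2L, stride = 2L, pad = 0L)
  m$children$detail_up <- layer_convt(ch, ch, 2L, stride = 2L, pad = 0L)
  m$per_stack <- per_stack
  m$forward <- function(x) {
    m$n_calls <- m$n_calls + 1L
    x <- as_tg(x)
    dd <- dim(val(x))
    check_hw(dd[1], dd[2])
    n <- dd[4]
    # stem: coarse features at half resolution
    h <- tg_relu(m$children$stem1$forward(x))
    h <- tg_relu(m$children$stem2$forward(h))
    h <- tg_avgpool(h, 2L)
    hs <- dim(val(h))[1]; ws <- dim(val(h))[2]
    gh <- hs %/% m$cfg$patch_size; gw <- ws %/% m$cfg$patch_size
    # ViT branch: pre-conv, patchify, positional embedding
    vb <- tg_relu(m$children$vit_pre$forward(h))
    pg <- m$children$patch$forward(vb)       # [gh,gw,d,N]
    tok <- tokens_from_grid(pg)              # [N*T, d]
    pos <- m$params$pos
    if (gh != m$grid0 || gw != m$grid0) {
      pos4 <- tg_reshape(pos, c(m$grid0, m$grid0, ncol(val(pos)), 1L))
      pos4 <- tg_interp_to(pos4, gh, gw)
      pos <- tg_reshape(pos4, c(gh * gw, ncol(val(m$params$pos))))
    }
    tok <- tg_add_tile_rows(tok, pos, n)
    # CNN branch
    cb <- tg_relu(m$children$cnn_pre$forward(h))
    for (s in seq_len(m$cfg$n_stacks)) {
      if (s >= 2L) {
        # cross-branch interaction
        pooled <- tg_avgpool(cb, hs %/% gh)              # detail -> patch grid
        tok <- tg_add(tok, m$children$d2b_ln$forward(tokens_from_grid(pooled)))
        bgrid <- grid_from_tokens(tok, gh, gw, n)        # base -> detail
        bup <- tg_interp_to(bgrid, hs, ws)
        cb <- tg_add(cb, m$children$b2d_bn$forward(bup))
      }
      for (b in seq_len(m$per_stack)) {
        tok <- m$children[[sprintf("vit_s%d_b%d", s, b)]]$forward(tok, n)
      }
      cb <- tg_relu(m$children[[sprintf("cnn_s%d_bn1", s)]]$forward(
        m$children[[sprintf("cnn_s%d_c1", s)]]$forward(cb)))
    }
    # restore both branches to input resolution
    base <- m$children$base_up2$forward(
      tg_relu(m$children$base_up1$forward(grid_from_tokens(tok, gh, gw, n))))
    detail <- m$children$detail_up$forward(cb)
    list(base = base, detail = detail)
  }
  m
}

## ---- BFB: base fusion block (lite-transformer style) ------------------------

build_bfb <- function(cfg) {
  ch <- cfg$channels
  half <- ch %/% 2L
  m <- nn_module("bfb")
  m$children$loc1 <- layer_conv(half, half, 3L)
  m$children$loc2 <- layer_conv(half, half, 3L)
  m$children$attn <- layer_mha(half, 2L)
  m$children$glu <- layer_linear(half, ch)
  m$children$proj <- layer_conv(ch, ch, 1L, pad = 0L)
  m$half <- half
  m$forward <- function(x) {
    m$n_calls <- m$n_calls + 1L
    x <- as_tg(x)
    d <- dim(val(x))
    n <- d[4]
    # one head-group models local context by convolution ...
    lo <- tg_slice_c(x, 1L, m$half)
    lo <- m$children$loc2$forward(tg_gelu(m$children$loc1$forward(lo)))
    # ... the other models long-range structure by attention on a pooled grid
    gl <- tg_slice_c(x, m$half + 1L, 2L * m$half)
    f <- 2L^max(0, floor(log2(min(d[1], d[2]) / 16)))
    while (f > 1L && (d[1] %% f != 0L || d[2] %% f != 0L)) f <- f %/% 2L
    glp <- if (f > 1L) tg_avgpool(gl, f) else gl
    gh <- dim(val(glp))[1]; gw <- dim(val(glp))[2]
    tok <- tokens_from_grid(glp)
    tok <- m$children$attn$forward(tok, n)
    g2 <- m$children$glu$forward(tok)  # gated linear unit
    ga <- tg_slice_cols(g2, 1L, m$half)
    gb <- tg_slice_cols(g2, m$half + 1L, 2L * m$half)
    tok <- tg_mul(ga, tg_sigmoid(gb))
    glf <- grid_from_tokens(tok, gh, gw, n)
    if (f > 1L) glf <- tg_interp_to(glf, d[1], d[2])
    y <- m$children$proj$forward(tg_cat_c(lo, glf))
    tg_add(y, x)
  }
  m
}

## ---- DFB: detail fusion block (residual fusion CNN) -------------------------

build_dfb <- function(cfg) {
  ch <- cfg$channels
  m <- nn_module("dfb")
  m$children$c1a <- layer_conv(ch, ch, 3L)
  m$children$bn1a <- layer_batchnorm(ch)
  m$children$c1b <- layer_conv(ch, ch, 3L)
  m$children$bn1b <- layer_batchnorm(ch)
  m$children$c2a <- layer_conv(ch, ch, 3L)
  m$children$bn2a <- layer_batchnorm(ch)
  m$children$c2b <- layer_conv(ch, ch, 3L)
  m$children$bn2b <- layer_batchnorm(ch)
  m$children$res <- layer_conv(ch, ch, 3L)
  m$children$res_bn <- layer_batchnorm(ch)
  m$forward <- function(x) {
    m$n_calls <- m$n_calls + 1L
    x <- as_tg(x)
    cell1 <- m$children$bn1b$forward(m$children$c1b$forward(
      m$children$bn1a$forward(m$children$c1a$forward(x))))
    mid <- tg_elu(cell1)
    cell2 <- m$children$bn2b$forward(m$children$c2b$forward(
      m$children$bn2a$forward(m$children$c2a$forward(mid))))
    res <- m$children$res_bn$forward(m$children$res$forward(x))
    # ReLU6 caps the fused detail response at 6
    tg_relu6(tg_add(cell2, res))
  }
  m
}

## ---- DFD / DRD: transformer decoders ----------------------------------------

build_restormer_block <- function(dim, heads) {
  dh <- dim %/% heads
  hidden <- 2L * dim
  m <- nn_module(sprintf("restormer_%d", dim))
  m$children$ln1 <- layer_channel_ln(dim)
  m$children$qkv <- layer_conv(dim, 3L * dim, 1L, pad = 0L)
  m$children$qkv_dw <- layer_dwconv(3L * dim)
  m$children$attn_out <- layer_conv(dim, dim, 1L, pad = 0L)
  m$params$tau <- tg_param(rep(1, heads))
  m$children$ln2 <- layer_channel_ln(dim)
  m$children$ff_in <- layer_conv(dim, 2L * hidden, 1L, pad = 0L)
  m$children$ff_dw <- layer_dwconv(2L * hidden)
  m$children$ff_out <- layer_conv(hidden, dim, 1L, pad = 0L)
  m$dim <- dim; m$heads <- heads; m$dh <- dh; m$hidden <- hidden
  m$forward <- function(x) {
    m$n_calls <- m$n_calls + 1L
    # transposed (channel) attention, fused into one core op
    h <- m$children$ln1$forward(x)
    qkv <- m$children$qkv_dw$forward(m$children$qkv$forward(h))
    att4 <- tg_chattn_core(qkv, m$params$tau, m$heads)
    x <- tg_add(x, m$children$attn_out$forward(att4))
    # gated-dconv feed-forward
    h <- m$children$ln2$forward(x)
    f <- m$children$ff_dw$forward(m$children$ff_in$forward(h))
    fa <- tg_slice_c(f, 1L, m$hidden)
    fb <- tg_slice_c(f, m$hidden + 1L, 2L * m$hidden)
    tg_add(x, m$children$ff_out$forward(tg_mul(tg_gelu(fa), fb)))
  }
  m
}

build_decoder <- function(cfg, kind) {
  ch <- cfg$channels
  dim <- cfg$decoder_dim
  m <- nn_module(kind)
  # transformer blocks run at half resolution; a transposed convolution
  # restores full resolution before the sigmoid head
  m$children$embed <- layer_conv(2L * ch, dim, 3L, stride = 2L, pad = 1L)
  m$children$blk1 <- build_restormer_block(dim, cfg$n_heads)
  m$children$blk2 <- build_restormer_block(dim, cfg$n_heads)
  m$children$up <- layer_convt(dim, dim, 2L, stride = 2L, pad = 0L)
  m$children$out <- layer_conv(dim, 1L, 3L)
  # start the sigmoid head near 0.5 rather than saturated
  m$children$out$params$w$value <- init_trunc_normal(c(3L, 3L, dim, 1L))
  m$forward <- function(x) {
    m$n_calls <- m$n_calls + 1L
    d <- dim(val(x))
    if (d[3] != 2L * ch) stop(m$kind, " expects ", 2L * ch, " input channels, got ", d[3])
    h <- m$children$embed$forward(x)
    h <- m$children$blk1$forward(h)
    h <- m$children$blk2$forward(h)
    h <- tg_gelu(m$children$up$forward(h))
    tg_sigmoid(m$children$out$forward(h))
  }
  m
}

## ---- the assembled model ----------------------------------------------------

#' Build a coupled fusion/reconstruction model
#'
#' Constructs the five sub-networks: the shared parallel decomposition
#' encoder, the base and detail fusion blocks, and the fusion and
#' reconstruction decoders. The encoder instance is shared by both
#' branches (weight sharing, not copies).
#'
#' @param cfg a [model_config()]
#' @param seed integer seed for weight initialization
#' @return object of class `cirf_model`
#' @export
cirf_model <- function(cfg = model_config(), seed = 0L) {
  local_seed(seed, {
    m <- nn_module("cirf")
    m$cfg <- cfg
    m$children$encoder <- build_pde(cfg)
    m$children$bfb <- build_bfb(cfg)
    m$children$dfb <- build_dfb(cfg)
    m$children$dfd <- build_decoder(cfg, "dfd")
    m$children$drd <- build_decoder(cfg, "drd")
    class(m) <- c("cirf_model", class(m))
    m
  })
}

#' Encoder forward pass
#'
#' Decomposes a batch of single-channel images into base and detail
#' feature stacks, each with `cfg$channels` channels at input resolution.
#'
#' @param x matrix or `[H,W,1,N]` array in `[0,1]`
#' @param model a [cirf_model()]
#' @return list with `base` and `detail` arrays `[H,W,C,N]`
#' @export
pde_forward <- function(x, model) {
  set_training(model, FALSE)
  out <- with_no_grad(model$children$encoder$forward(as_batch(x)))
  list(base = val(out$base), detail = val(out$detail))
}

#' Base fusion block forward pass
#' @param base_sum `[H,W,C,N]` array: the element-wise sum of the two
#'   sources' base features
#' @inheritParams pde_forward
#' @return fused base features, same shape
#' @export
bfb_forward <- function(base_sum, model) {
  set_training(model, FALSE)
  val(with_no_grad(model$children$bfb$forward(base_sum)))
}

#' Detail fusion block forward pass
#'
#' Residual fusion CNN with ELU between cells, a convolutional residual
#' line, and a final ReLU6 capping outputs to `[0, 6]`.
#'
#' @param detail_sum `[H,W,C,N]` array: sum of the two sources' detail features
#' @inheritParams pde_forward
#' @return fused detail features in `[0,6]`, same shape
#' @export
dfb_forward <- function(detail_sum, model) {
  set_training(model, FALSE)
  val(with_no_grad(model$children$dfb$forward(detail_sum)))
}

#' Fusion decoder forward pass
#' @param features `[H,W,2C,N]` concatenation of fused base and detail features
#' @inheritParams pde_forward
#' @return fused image batch `[H,W,1,N]` in `[0,1]`
#' @export
dfd_forward <- function(features, model) {
  set_training(model, FALSE)
  val(with_no_grad(model$children$dfd$forward(features)))
}

#' Reconstruction decoder forward pass
#' @param features `[H,W,2C,N]` concatenation of one modality's base and
#'   detail features
#' @inheritParams pde_forward
#' @return reconstructed image batch `[H,W,1,N]` in `[0,1]`
#' @export
drd_forward <- function(features, model) {
  set_training(model, FALSE)
  val(with_no_grad(model$children$drd$forward(features)))
}

# fusion-branch forward on the tape (training path)
fuse_tg <- function(t1, t2, model) {
  e1 <- model$children$encoder$forward(as_batch(t1))
  e2 <- model$children$encoder$forward(as_batch(t2))
  psi_b <- model$children$bfb$forward(tg_add(e1$base, e2$base))
  psi_d <- model$children$dfb$forward(tg_add(e1$detail, e2$detail))
  model$children$dfd$forward(tg_cat_c(psi_b, psi_d))
}

#' Fuse two co-registered images
#'
#' Full fusion-branch forward in evaluation mode: shared encoder, base and
#' detail fusion blocks, fusion decoder. The reconstruction branch is not
#' executed.
#'
#' @param t1,t2 `[0,1]` matrices (or `[H,W,1,N]` batches) of equal shape
#' @param model a [cirf_model()]
#' @return fused image, same shape class as the input
#' @export
fuse <- function(t1, t2, model) {
  was_mat <- is.matrix(t1)
  stopifnot(all(dim(as_batch(t1)) == dim(as_batch(t2))))
  set_training(model, FALSE)
  y <- val(with_no_grad(fuse_tg(as_batch(t1), as_batch(t2), model)))
  if (was_mat) matrix(y[, , 1L, 1L], dim(y)[1], dim(y)[2]) else y
}

# reconstruction-branch forward on the tape (training path)
reconstruct_tg <- function(tk, model, mask_ratio = 0, seed = 0L) {
  x <- as_batch(val(tk))
  if (mask_ratio > 0) {
    for (n in seq_len(dim(x)[4])) {
      x[, , 1L, n] <- random_mask(x[, , 1L, n, drop = TRUE], mask_ratio, seed = seed + n)
    }
  }
  e <- model$children$encoder$forward(x)
  model$children$drd$forward(tg_cat_c(e$base, e$detail))
}

#' Reconstruct a (possibly masked) image through the shared encoder
#'
#' Training-path operation: the input is patch-masked at `mask_ratio`,
#' encoded by the same encoder instance the fusion branch uses, and
#' decoded by the reconstruction decoder.
#'
#' @param tk `[0,1]` matrix or `[H,W,1,N]` batch
#' @param model a [cirf_model()]
#' @param mask_ratio fraction of 16x16 patches to mask (0 disables masking)
#' @param seed mask seed
#' @return reconstructed batch `[H,W,1,N]`
#' @export
reconstruct <- function(tk, model, mask_ratio = 0, seed = 0L) {
  set_training(model, FALSE)
  val(with_no_grad(reconstruct_tg(as_batch(tk), model, mask_ratio, seed)))
}
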