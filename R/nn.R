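# Minimal neural-network layer library on top of the autograd engine.
# A module is an environment carrying parameters (tg leaves), child modules,
# optional buffers (batch-norm running statistics), a training flag and a
# forward-call counter used by tests to verify which branches executed.

nn_module <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- list()
  e$children <- list()
  e$training <- TRUE
  e$n_calls <- 0L
  e$mid <- tg_next_id()  # identity key for shared-module deduplication
  class(e) <- "cirf_module"
  e
}

#' @export
print.cirf_module <- function(x, ...) {
  cat("<module", x$kind, ":", length(module_parameters(x)), "parameter tensors >\n")
  invisible(x)
}

#' Collect all parameter tensors of a module tree
#'
#' Shared submodules are visited once, so a weight-sharing encoder
#' contributes each tensor exactly once.
#'
#' @param mod a network module
#' @return named list of parameter tensors
#' @export
module_parameters <- function(mod) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  walk <- function(m, prefix) {
    key <- as.character(m$mid)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    for (nm in names(m$params)) out[[paste0(prefix, nm)]] <<- m$params[[nm]]
    for (nm in names(m$children)) walk(m$children[[nm]], paste0(prefix, nm, "."))
  }
  walk(mod, "")
  out
}

set_training <- function(mod, flag) {
  seen <- new.env(parent = emptyenv())
  walk <- function(m) {
    key <- as.character(m$mid)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    m$training <- flag
    for (ch in m$children) walk(ch)
  }
  walk(mod)
  invisible(mod)
}

## ---- initializers -----------------------------------------------------------

init_kaiming <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

init_trunc_normal <- function(dims, sd = 0.02) {
  x <- stats::rnorm(prod(dims), 0, sd)
  x <- pmin(pmax(x, -2 * sd), 2 * sd)
  array(x, dims)
}

## ---- layers -----------------------------------------------------------------

layer_conv <- function(ci, co, k, stride = 1L, pad = (k - 1L) %/% 2L, bias = TRUE) {
  m <- nn_module(sprintf("conv%dx%d_%d.%d", k, k, ci, co))
  m$params$w <- tg_param(init_kaiming(c(k, k, ci, co), fan_in = k * k * ci))
  if (bias) m$params$b <- tg_param(numeric(co))
  m$stride <- stride; m$pad <- pad
  m$forward <- function(x) {
    m$n_calls <- m$n_calls + 1L
    tg_conv2d(x, m$params$w, m$params$b, stride = m$stride, pad = m$pad)
  }
  m
}

layer_convt <- function(ci, co, k, stride = 2L, pad = (k - stride) %/% 2L) {
  m <- nn_module(sprintf("convT%dx%d_%d.%d", k, k, ci, co))
  m$params$w <- tg_param(init_kaiming(c(k, k, co, ci), fan_in = k * k * ci / (stride^2)))
  m$params$b <- tg_param(numeric(co))
  m$co <- co; m$stride <- stride; m$pad <- pad
  m$forward <- function(x) {
    m$n_calls <- m$n_calls + 1L
    tg_convt2d(x, m$params$w, m$params$b, stride = m$stride, pad = m$pad)
  }
  m
}

layer_dwconv <- function(c, k = 3L) {
  m <- nn_module(sprintf("dwconv%d_%d", k, c))
  m$params$w <- tg_param(init_kaiming(c(k, k, c), fan_in = k * k))
  m$forward <- function(x) {
    m$n_calls <- m$n_calls + 1L
    tg_dwconv2d(x, m$params$w, pad = (k - 1L) %/% 2L)
  }
  m
}

layer_linear <- function(din, dout, init = "trunc") {
  m <- nn_module(sprintf("linear_%d.%d", din, dout))
  w0 <- if (init == "trunc") init_trunc_normal(c(din, dout)) else init_kaiming(c(din, dout), din)
  m$params$w <- tg_param(w0)
  m$params$b <- tg_param(numeric(dout))
  m$forward <- function(x) {
    m$n_calls <- m$n_calls + 1L
    tg_add_bias_cols(tg_matmul(x, m$params$w), m$params$b)
  }
  m
}

layer_layernorm <- function(d) {
  m <- nn_module(sprintf("layernorm_%d", d))
  m$params$gamma <- tg_param(rep(1, d))
  m$params$beta <- tg_param(numeric(d))
  m$forward <- function(x) {
    m$n_calls <- m$n_calls + 1L
    tg_layernorm_rows(x, m$params$gamma, m$params$beta)
  }
  m
}

layer_batchnorm <- function(c) {
  m <- nn_module(sprintf("batchnorm_%d", c))
  m$params$gamma <- tg_param(rep(1, c))
  m$params$beta <- tg_param(numeric(c))
  m$running_mean <- numeric(c)
  m$running_var <- rep(1, c)
  m$forward <- function(x) {
    m$n_calls <- m$n_calls + 1L
    tg_batchnorm(x, m$params$gamma, m$params$beta, m, training = m$training)
  }
  m
}

# multi-head self-attention over an [N*T, D] token matrix
layer_mha <- function(d, heads, drop = 0) {
  stopifnot(d %% heads == 0)
  dh <- d %/% heads
  m <- nn_module(sprintf("mha_%dh%d", d, heads))
  m$children$wq <- layer_linear(d, d)
  m$children$wk <- layer_linear(d, d)
  m$children$wv <- layer_linear(d, d)
  m$children$wo <- layer_linear(d, d)
  m$heads <- heads; m$dh <- dh; m$drop <- drop
  m$forward <- function(x, n_batch) {
    m$n_calls <- m$n_calls + 1L
    q <- m$children$wq$forward(x)
    k <- m$children$wk$forward(x)
    v <- m$children$wv$forward(x)
    o <- tg_mha_core(q, k, v, m$heads, n_batch, 1 / sqrt(dh))
    y <- m$children$wo$forward(o)
    tg_dropout(y, m$drop, m$training)
  }
  m
}

# pre-norm ViT transformer block: MHA + MLP with residuals
layer_vit_block <- function(d, heads, drop = 0.1) {
  m <- nn_module(sprintf("vit_block_%d", d))
  m$children$ln1 <- layer_layernorm(d)
  m$children$attn <- layer_mha(d, heads, drop)
  m$children$ln2 <- layer_layernorm(d)
  m$children$fc1 <- layer_linear(d, 2L * d)
  m$children$fc2 <- layer_linear(2L * d, d)
  m$drop <- drop
  m$forward <- function(x, n_batch) {
    m$n_calls <- m$n_calls + 1L
    x <- tg_add(x, m$children$attn$forward(m$children$ln1$forward(x), n_batch))
    h <- m$children$fc2$forward(tg_gelu(m$children$fc1$forward(m$children$ln2$forward(x))))
    tg_add(x, tg_dropout(h, m$drop, m$training))
  }
  m
}

# channel-wise layer norm of [H,W,C,N] (normalizes across C at each pixel)
layer_channel_ln <- function(c) {
  m <- nn_module(sprintf("channel_ln_%d", c))
  m$params$gamma <- tg_param(rep(1, c))
  m$params$beta <- tg_param(numeric(c))
  m$forward <- function(x) {
    m$n_calls <- m$n_calls + 1L
    d <- dim(val(x))
    xm <- tg_reshape(tg_aperm(x, c(1, 2, 4, 3)), c(d[1] * d[2] * d[4], d[3]))
    ym <- tg_layernorm_rows(xm, m$params$gamma, m$params$beta)
    tg_aperm(tg_reshape(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  }
  m
}

# tokens [N*T,D] <-> feature grid [gh,gw,D,N]
tokens_from_grid <- function(x) {
  d <- dim(val(x))
  tg_reshape(tg_aperm(x, c(1, 2, 4, 3)), c(d[1] * d[2] * d[4], d[3]))
}

grid_from_tokens <- function(x, gh, gw, n) {
  d <- ncol(val(x))
  tg_aperm(tg_reshape(x, c(gh, gw, n, d)), c(1, 2, 4, 3))
}
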