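# Coupled multi-task training: every step runs BOTH branches through the
# shared encoder — fusion on the original pair, reconstruction on the
# (optionally masked) sources — combines the losses with the sigma weight
# and takes one Adam step over all parameters.

#' Training configuration
#'
#' @param weights a [loss_weights()]
#' @param model a [model_config()]
#' @param batch_size images per step (default 4)
#' @param learning_rate Adam step size
#' @param n_epochs passes over the training pairs
#' @param seed master seed controlling initialization, data order, masking
#'   and dropout
#' @param image_size training image side in pixels
#' @return list of class `cirf_train_config`
#' @export
train_config <- function(weights = loss_weights(), model = NULL,
                         batch_size = 4L, learning_rate = 1e-4,
                         n_epochs = 1L, seed = 0L, image_size = 256L) {
  if (is.null(model)) model <- model_config(image_size = image_size)
  stopifnot(batch_size >= 1, learning_rate > 0)
  structure(list(weights = weights, model = model,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
                 seed = as.integer(seed), image_size = as.integer(image_size)),
            class = "cirf_train_config")
}

## ---- Adam -------------------------------------------------------------------

adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim(p$value) %||% length(p$value)))
  st$v <- lapply(params, function(p) array(0, dim(p$value) %||% length(p$value)))
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g^2
    p$value <- p$value - st$lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + st$eps)
  }
  invisible(st)
}

## ---- one coupled step -------------------------------------------------------

check_finite_terms <- function(terms) {
  for (nm in names(terms)) {
    if (!is.finite(terms[[nm]]))
      stop("non-finite loss term '", nm, "' (", terms[[nm]], "); aborting training")
  }
}

#' One coupled training step
#'
#' Runs the fusion branch on the original pair and the reconstruction
#' branch on the masked (or original) sources through the shared encoder,
#' forms the weighted total loss, backpropagates and applies one Adam
#' update. With `sigma = 0` the fusion-only modules receive zero gradient;
#' with `sigma = 1` the reconstruction decoder does.
#'
#' @param t1,t2 `[H,W,1,N]` batches of co-registered sources
#' @param model a [cirf_model()] in training mode
#' @param opt optimizer state from `adam_new()`
#' @param w a [loss_weights()]
#' @param step_seed seed for this step's masking
#' @return list of class `cirf_loss_breakdown`: `rec_1`, `rec_2`, `loss1`,
#'   fusion terms, `loss2`, `total`
#' @export
train_step <- function(t1, t2, model, opt, w = loss_weights(), step_seed = 0L) {
  t1 <- as_batch(t1); t2 <- as_batch(t2)
  # fusion branch on originals
  tf <- fuse_tg(t1, t2, model)
  fl <- fusion_loss(t1, t2, tf, w)
  # reconstruction branch on masked-or-original inputs
  r1 <- reconstruct_tg(t1, model, w$mask_ratio, seed = step_seed * 2L + 1L)
  r2 <- reconstruct_tg(t2, model, w$mask_ratio, seed = step_seed * 2L + 2L)
  rl1 <- rec_loss(r1, t1, w)
  rl2 <- rec_loss(r2, t2, w)
  loss1 <- total_rec_loss(rl1, rl2, w)
  total <- total_loss(loss1, fl$loss2, w)
  breakdown <- list(
    rec_1 = val(rl1), rec_2 = val(rl2), loss1 = val(loss1),
    l_mi = fl$terms[["l_mi"]], l_scd = fl$terms[["l_scd"]],
    l_ssim = fl$terms[["l_ssim"]], l_qabf = fl$terms[["l_qabf"]],
    loss2 = val(fl$loss2), total = val(total)
  )
  check_finite_terms(breakdown)
  tg_backward(total)
  adam_step(opt)
  tg_zero_grad(opt$params)
  class(breakdown) <- "cirf_loss_breakdown"
  breakdown
}

## ---- the training loop ------------------------------------------------------

#' Train a coupled fusion model
#'
#' Deterministic given `cfg$seed`: weight initialization, data order,
#' masking and dropout all derive from it. Both branches are updated
#' simultaneously by one optimizer.
#'
#' @param pairs list of image pairs, each a list with `[0,1]` matrices
#'   `a` and `b` of equal size (sides divisible by 32)
#' @param cfg a [train_config()]
#' @param model optional pre-built [cirf_model()] to continue training
#' @return list with `model` and `log` (one row per step with the loss
#'   breakdown, plus per-epoch means in `attr(log, "epoch_means")`)
#' @export
train <- function(pairs, cfg = train_config(), model = NULL) {
  if (length(pairs) == 0L) stop("empty training dataset")
  if (is.null(model)) model <- cirf_model(cfg$model, seed = cfg$seed)
  set_training(model, TRUE)
  params <- module_parameters(model)
  opt <- adam_new(params, lr = cfg$learning_rate)
  logs <- list()
  step <- 0L
  local_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$n_epochs)) {
      ord <- sample.int(length(pairs))
      nb <- ceiling(length(ord) / cfg$batch_size)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, length(ord))]
        h <- nrow(pairs[[idx[1]]]$a); wd <- ncol(pairs[[idx[1]]]$a)
        t1 <- array(0, c(h, wd, 1L, length(idx)))
        t2 <- array(0, c(h, wd, 1L, length(idx)))
        for (k in seq_along(idx)) {
          t1[, , 1L, k] <- pairs[[idx[k]]]$a
          t2[, , 1L, k] <- pairs[[idx[k]]]$b
        }
        step <- step + 1L
        br <- train_step(t1, t2, model, opt, cfg$weights, step_seed = step)
        logs[[step]] <- c(epoch = ep, step = step, unlist(unclass(br)))
      }
    }
  })
  log <- as.data.frame(do.call(rbind, logs))
  em <- stats::aggregate(log[setdiff(names(log), c("epoch", "step"))],
                         by = list(epoch = log$epoch), FUN = mean)
  attr(log, "epoch_means") <- em
  list(model = model, log = log)
}

#' Fuse a list of image pairs (inference)
#'
#' Evaluation-mode fusion-branch forwards only; the reconstruction branch
#' is never executed. Pairs carrying a pseudo-color `color_b` are fused on
#' the luma channel and re-colored from the stored U/V chroma.
#'
#' @param pairs list of pairs as in [train()], optionally with `color_b`
#' @param model a trained [cirf_model()]
#' @return list of fused images: matrices, or RGB arrays for pseudo-color
#'   inputs
#' @export
infer <- function(pairs, model) {
  set_training(model, FALSE)
  lapply(pairs, function(p) {
    if (!is.null(p$color_b)) {
      yuv <- rgb_to_yuv(p$color_b)
      fy <- fuse(p$a, yuv$y, model)
      yuv_to_rgb(fy, yuv$u, yuv$v)
    } else {
      fuse(p$a, p$b, model)
    }
  })
}

#' @export
print.cirf_loss_breakdown <- function(x, ...) {
  cat(sprintf("total %.5f | loss1 %.5f (rec %.4f/%.4f) | loss2 %.5f (mi %.3f scd %.3f ssim %.3f qabf %.3f)\n",
              x$total, x$loss1, x$rec_1, x$rec_2, x$loss2,
              x$l_mi, x$l_scd, x$l_ssim, x$l_qabf))
  invisible(x)
}
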