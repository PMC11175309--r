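# Training losses.
#
# Reconstruction branch (supervised): per source k,
#   Lrec_k = L_MSE + alpha * (1 - SSIM) + beta * L_SG,
# with L_SG the mean absolute difference of Sobel gradient magnitudes, and
#   Loss1 = mu * (Lrec_1 + Lrec_2).
# Fusion branch (unsupervised): each term is one minus a normalized average
# of a quality metric of (A, B, F), using differentiable surrogates where
# the exact metric is not smooth (soft-histogram mutual information, smooth
# edge-preservation), and
#   Loss2 = lambda * (L_MI + L_SCD) + (1 - lambda) * (L_SSIM + L_QABF).
# Total: Loss_total = (1 - sigma) * Loss1 + sigma * Loss2.

#' Loss hyper-parameters
#'
#' @param alpha SSIM weight in the reconstruction loss (>= 0)
#' @param beta gradient-loss weight in the reconstruction loss (>= 0)
#' @param mu scale balance of the total reconstruction loss (> 0)
#' @param lambda fusion-loss mix between information terms (MI, SCD) and
#'   structure terms (SSIM, QAB/F), in `[0,1]`; 0.3 is the recommended value
#' @param sigma branch balance: 0 trains reconstruction only, 1 fusion only
#' @param mask_ratio fraction of patches masked before the reconstruction
#'   encoder pass, in `[0,1]`
#' @return list of class `cirf_loss_weights`
#' @export
loss_weights <- function(alpha = 1, beta = 1, mu = 1, lambda = 0.3,
                         sigma = 0.2, mask_ratio = 0.1) {
  stopifnot(alpha >= 0, beta >= 0, mu > 0,
            lambda >= 0, lambda <= 1, sigma >= 0, sigma <= 1,
            mask_ratio >= 0, mask_ratio <= 1)
  structure(list(alpha = alpha, beta = beta, mu = mu, lambda = lambda,
                 sigma = sigma, mask_ratio = mask_ratio),
            class = "cirf_loss_weights")
}

.sobel_x4 <- array(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), c(3, 3, 1, 1))
.sobel_y4 <- array(t(matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)), c(3, 3, 1, 1))

# smooth Sobel gradient magnitude of an [H,W,1,N] batch, valid interior
# (no padding, so constant offsets cancel exactly)
sobel_mag_tg <- function(x, eps = 1e-6) {
  gx <- tg_conv2d(x, tg_const(.sobel_x4), stride = 1L, pad = 0L)
  gy <- tg_conv2d(x, tg_const(.sobel_y4), stride = 1L, pad = 0L)
  tg_sqrt(tg_add(tg_add(tg_square(gx), tg_square(gy)), eps^2))
}

#' Spatial gradient loss
#'
#' Mean absolute difference between the Sobel gradient magnitudes of a
#' reconstruction and its target, `mean(||grad(recon)| - |grad(target)||)`,
#' taken over the valid (unpadded) interior and the batch. Insensitive to
#' constant intensity offsets.
#'
#' @param recon,target `[0,1]` matrices or `[H,W,1,N]` batches of equal shape
#' @return differentiable scalar (a `tg` node; use `val()` for the number)
#' @export
loss_sg <- function(recon, target) {
  r <- if (is_tg(recon)) recon else as_tg(as_batch(recon))
  t <- if (is_tg(target)) target else as_tg(as_batch(target))
  if (!all(dim(val(r)) == dim(val(t)))) stop("recon and target shapes differ")
  tg_mean(tg_abs_smooth(tg_sub(sobel_mag_tg(r), sobel_mag_tg(t))))
}

# differentiable SSIM (Gaussian 11x11 window, sigma 1.5, data range 1)
.ssim_win <- local({
  k <- NULL
  function() {
    if (is.null(k)) k <<- array(gauss_kernel(1.5, 11L), c(11L, 11L, 1L, 1L))
    k
  }
})

ssim_tg <- function(x, y, k1 = 0.01, k2 = 0.03) {
  w <- tg_const(.ssim_win())
  c1 <- k1^2; c2 <- k2^2
  mx <- tg_conv2d(x, w); my <- tg_conv2d(y, w)
  sxx <- tg_sub(tg_conv2d(tg_square(x), w), tg_square(mx))
  syy <- tg_sub(tg_conv2d(tg_square(y), w), tg_square(my))
  sxy <- tg_sub(tg_conv2d(tg_mul(x, y), w), tg_mul(mx, my))
  num <- tg_mul(tg_add(tg_mul(tg_mul(mx, my), 2), c1), tg_add(tg_mul(sxy, 2), c2))
  den <- tg_mul(tg_add(tg_add(tg_square(mx), tg_square(my)), c1),
                tg_add(tg_add(sxx, syy), c2))
  tg_mean(tg_div(num, den))
}

#' Per-source reconstruction loss
#'
#' `L_MSE + alpha * (1 - SSIM) + beta * L_SG`, each term differentiable.
#' The returned scalar carries the individual terms in `$components`.
#'
#' @inheritParams loss_sg
#' @param w a [loss_weights()]
#' @return differentiable scalar with `components` field
#' @export
rec_loss <- function(recon, target, w = loss_weights()) {
  r <- if (is_tg(recon)) recon else as_tg(as_batch(recon))
  t <- if (is_tg(target)) target else as_tg(as_batch(target))
  if (!all(dim(val(r)) == dim(val(t)))) stop("recon and target shapes differ")
  mse <- tg_mean(tg_square(tg_sub(r, t)))
  ssim_term <- tg_sub(1, ssim_tg(r, t))
  sg_term <- loss_sg(r, t)
  total <- tg_add(mse, tg_add(tg_mul(ssim_term, w$alpha), tg_mul(sg_term, w$beta)))
  total$components <- list(mse = val(mse), ssim_term = val(ssim_term), sg_term = val(sg_term))
  total
}

#' Total reconstruction loss
#'
#' `mu * (Lrec_1 + Lrec_2)`: the scale-balancing weight applies to the
#' whole reconstruction term.
#'
#' @param rec_1,rec_2 per-source reconstruction losses (scalar or `tg`)
#' @param w a [loss_weights()]
#' @return scalar of the same kind as the inputs
#' @export
total_rec_loss <- function(rec_1, rec_2, w = loss_weights()) {
  if (is_tg(rec_1) || is_tg(rec_2)) {
    tg_mul(tg_add(rec_1, rec_2), w$mu)
  } else {
    w$mu * (rec_1 + rec_2)
  }
}

## ---- differentiable fusion-metric surrogates --------------------------------

# Pearson correlation of two tg vectors/arrays, smooth guard on variances
pearson_tg <- function(x, y, eps = 1e-8) {
  xc <- tg_sub(x, tg_mean(x))
  yc <- tg_sub(y, tg_mean(y))
  num <- tg_mean(tg_mul(xc, yc))
  den <- tg_sqrt(tg_add(tg_mul(tg_mean(tg_square(xc)), tg_mean(tg_square(yc))), eps))
  tg_div(num, den)
}

# soft-histogram mutual information, normalized by symmetric uncertainty;
# 32 Gaussian-kernel bins of bandwidth 1/32 on [0,1]
soft_nmi_tg <- function(x, y, bins = 32L, bw = 1 / 32, eps = 1e-10) {
  p <- length(val(x))
  centers <- matrix((seq_len(bins) - 0.5) / bins, 1L, bins)
  onesb <- matrix(1, 1L, bins)
  soft_hist <- function(v) {
    vm <- tg_reshape(v, c(p, 1L))
    diff <- tg_sub(tg_matmul(vm, onesb), tg_const(matrix(centers, p, bins, byrow = TRUE)))
    wgt <- tg_exp(tg_mul(tg_square(diff), -0.5 / bw^2))
    s <- tg_matmul(wgt, matrix(1, bins, 1L))
    tg_div_rowvec(wgt, tg_reshape(s, NULL))
  }
  wx <- soft_hist(x); wy <- soft_hist(y)
  joint <- tg_mul(tg_matmul(tg_t(wx), wy), 1 / p)          # [bins,bins]
  px <- tg_mul(tg_matmul(tg_t(wx), matrix(1 / p, p, 1L)), 1)  # [bins,1]
  py <- tg_mul(tg_matmul(tg_t(wy), matrix(1 / p, p, 1L)), 1)
  outer_xy <- tg_matmul(px, tg_t(py))
  mi <- tg_div(tg_sum(tg_mul(joint, tg_sub(tg_log(tg_add(joint, eps)),
                                           tg_log(tg_add(outer_xy, eps))))), log(2))
  hx <- tg_div(tg_neg(tg_sum(tg_mul(px, tg_log(tg_add(px, eps))))), log(2))
  hy <- tg_div(tg_neg(tg_sum(tg_mul(py, tg_log(tg_add(py, eps))))), log(2))
  tg_div(tg_mul(mi, 2), tg_add(tg_add(hx, hy), eps))
}

# smooth edge-preservation score (differentiable QAB/F surrogate):
# Sobel convolutions, smooth absolute values, atan2 orientations
qabf_tg <- function(a, b, f, eps = 1e-6) {
  edge <- function(x) {
    gx <- tg_conv2d(x, tg_const(.sobel_x4), stride = 1L, pad = 1L)
    gy <- tg_conv2d(x, tg_const(.sobel_y4), stride = 1L, pad = 1L)
    g <- tg_sqrt(tg_add(tg_add(tg_square(gx), tg_square(gy)), eps^2))
    al <- tg_fold_halfpi(tg_atan2(gy, gx))
    list(g = g, a = al)
  }
  cc <- .qabf_const
  pres <- function(es, ef) {
    # smooth min/max ratio of edge strengths
    mn <- tg_mul(tg_sub(tg_add(es$g, ef$g), tg_abs_smooth(tg_sub(es$g, ef$g), eps)), 0.5)
    mx <- tg_mul(tg_add(tg_add(es$g, ef$g), tg_abs_smooth(tg_sub(es$g, ef$g), eps)), 0.5)
    gaf <- tg_div(tg_add(mn, eps), tg_add(mx, eps))
    aaf <- tg_mul(tg_abs_smooth(tg_sub(tg_abs_smooth(tg_sub(es$a, ef$a), eps), pi / 2), eps), 2 / pi)
    qg <- tg_div(cc$Gg, tg_add(tg_exp(tg_mul(tg_sub(gaf, cc$dg), cc$kg)), 1))
    qa <- tg_div(cc$Ga, tg_add(tg_exp(tg_mul(tg_sub(aaf, cc$da), cc$ka)), 1))
    qg1 <- cc$Gg / (1 + exp(cc$kg * (1 - cc$dg)))
    qa1 <- cc$Ga / (1 + exp(cc$ka * (1 - cc$da)))
    tg_mul(tg_mul(qg, qa), 1 / (qg1 * qa1))
  }
  ea <- edge(a); eb <- edge(b); ef <- edge(f)
  qa <- pres(ea, ef); qb <- pres(eb, ef)
  num <- tg_add(tg_sum(tg_mul(qa, ea$g)), tg_sum(tg_mul(qb, eb$g)))
  den <- tg_add(tg_add(tg_sum(ea$g), tg_sum(eb$g)), eps)
  tg_div(num, den)
}

#' Unsupervised fusion loss
#'
#' Four terms, each one minus a normalized average quality score of
#' (A, B, F): soft-histogram mutual information normalized by symmetric
#' uncertainty; SCD and SSIM mapped from `[-1,1]` to `[0,1]`; smooth
#' edge preservation already in `[0,1]`. Combined as
#' `lambda * (L_MI + L_SCD) + (1 - lambda) * (L_SSIM + L_QABF)`.
#'
#' @param a,b source batches, `[0,1]` matrices or `[H,W,1,N]` arrays
#' @param f fused batch (typically a `tg` node from the fusion forward)
#' @param w a [loss_weights()]
#' @return list: `loss2` (differentiable scalar), `terms` (numeric l_mi,
#'   l_scd, l_ssim, l_qabf)
#' @export
fusion_loss <- function(a, b, f, w = loss_weights()) {
  a <- if (is_tg(a)) a else as_tg(as_batch(a))
  b <- if (is_tg(b)) b else as_tg(as_batch(b))
  f <- if (is_tg(f)) f else as_tg(as_batch(f))
  stopifnot(all(dim(val(a)) == dim(val(f))), all(dim(val(b)) == dim(val(f))))
  n <- dim(val(a))[4]
  # per-image information terms, averaged over batch and sources
  mi_acc <- NULL; scd_acc <- NULL
  for (i in seq_len(n)) {
    ai <- tg_slice_n(a, i); bi <- tg_slice_n(b, i); fi <- tg_slice_n(f, i)
    nmi <- tg_mul(tg_add(soft_nmi_tg(ai, fi), soft_nmi_tg(bi, fi)), 0.5)
    mi_acc <- if (is.null(mi_acc)) nmi else tg_add(mi_acc, nmi)
    r1 <- pearson_tg(tg_sub(fi, bi), ai)
    r2 <- pearson_tg(tg_sub(fi, ai), bi)
    scd01 <- tg_mul(tg_add(tg_mul(tg_add(r1, 1), 0.5), tg_mul(tg_add(r2, 1), 0.5)), 0.5)
    scd_acc <- if (is.null(scd_acc)) scd01 else tg_add(scd_acc, scd01)
  }
  l_mi <- tg_sub(1, tg_mul(mi_acc, 1 / n))
  l_scd <- tg_sub(1, tg_mul(scd_acc, 1 / n))
  ssim01 <- tg_mul(tg_add(tg_mul(tg_add(ssim_tg(a, f), 1), 0.5),
                          tg_mul(tg_add(ssim_tg(b, f), 1), 0.5)), 0.5)
  l_ssim <- tg_sub(1, ssim01)
  l_qabf <- tg_sub(1, qabf_tg(a, b, f))
  loss2 <- tg_add(tg_mul(tg_add(l_mi, l_scd), w$lambda),
                  tg_mul(tg_add(l_ssim, l_qabf), 1 - w$lambda))
  list(loss2 = loss2,
       terms = c(l_mi = val(l_mi), l_scd = val(l_scd),
                 l_ssim = val(l_ssim), l_qabf = val(l_qabf)))
}

#' Total coupled loss
#'
#' `(1 - sigma) * Loss1 + sigma * Loss2`.
#'
#' @param loss1 total reconstruction loss (scalar or `tg`)
#' @param loss2 fusion loss (scalar or `tg`)
#' @param w a [loss_weights()]
#' @return scalar of the same kind as the inputs
#' @export
total_loss <- function(loss1, loss2, w = loss_weights()) {
  if (is_tg(loss1) || is_tg(loss2)) {
    tg_add(tg_mul(loss1, 1 - w$sigma), tg_mul(loss2, w$sigma))
  } else {
    (1 - w$sigma) * loss1 + w$sigma * loss2
  }
}

#' Check that a loss is differentiable at a random point
#'
#' Evaluates a loss on a small random batch with gradient tracking and
#' verifies that the gradient with respect to the first argument is
#' finite, non-NaN and (for non-degenerate inputs) not identically zero.
#'
#' @param loss_fn one of [rec_loss()], [loss_sg()], or a closure taking
#'   `(x, target)` and returning a `tg` scalar
#' @param h,w,n batch dimensions
#' @param seed RNG seed
#' @return `TRUE` if the gradient is finite and live, else `FALSE`
#' @export
differentiability_check <- function(loss_fn, h = 16L, w = 16L, n = 2L, seed = 0L) {
  local_seed(seed, {
    x <- tg_param(array(stats::runif(h * w * n), c(h, w, 1L, n)))
    tgt <- array(stats::runif(h * w * n), c(h, w, 1L, n))
    out <- loss_fn(x, tgt)
    if (!is_tg(out)) return(FALSE)
    tg_backward(out)
    g <- x$grad
    !is.null(g) && all(is.finite(g)) && any(g != 0)
  })
}
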