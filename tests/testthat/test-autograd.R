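# The autograd engine underpins every network and loss; these checks compare
# analytic gradients with central differences on random small inputs.

fd_grad <- function(fn, x, idx, eps = 1e-6) {
  sapply(idx, function(i) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    (fn(x1) - fn(x2)) / (2 * eps)
  })
}

expect_grad_matches <- function(make_loss, x, idx, tol = 1e-6) {
  p <- cirf:::tg_param(x)
  loss <- make_loss(p)
  cirf:::tg_backward(loss)
  ana <- p$grad[idx]
  num <- fd_grad(function(xx) cirf:::val(make_loss(cirf:::as_tg(xx))), x, idx)
  expect_equal(ana, num, tolerance = tol)
}

test_that("elementwise and reduction ops backpropagate correctly", {
  withr::with_seed(1, x <- array(runif(60, 0.1, 0.9), c(5, 3, 2, 2)))
  idx <- c(1, 17, 42, 60)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_square(cirf:::tg_sub(p, 0.3))), x, idx)
  expect_grad_matches(function(p) cirf:::tg_sum(cirf:::tg_sqrt(cirf:::tg_add(p, 0.5))), x, idx)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_exp(cirf:::tg_neg(p))), x, idx)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_abs_smooth(cirf:::tg_sub(p, 0.5))), x, idx, tol = 1e-4)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_sigmoid(p)), x, idx)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_gelu(p)), x, idx)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_elu(cirf:::tg_sub(p, 0.5))), x, idx, tol = 1e-4)
})

test_that("matrix, softmax and normalization ops backpropagate correctly", {
  withr::with_seed(2, {
    m <- matrix(rnorm(20), 4, 5)
    w <- matrix(rnorm(15), 5, 3)
  })
  idx <- c(1, 7, 20)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_square(cirf:::tg_matmul(p, w))), m, idx)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_square(cirf:::tg_softmax_rows(p))), m, idx)
  g <- runif(5); b <- rnorm(5)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_square(
    cirf:::tg_layernorm_rows(p, g, b))), m, idx, tol = 1e-5)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_square(cirf:::tg_l2norm_rows(p))), m, idx, tol = 1e-5)
})

test_that("structured ops (resample, slicing, concatenation) backpropagate correctly", {
  withr::with_seed(3, x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2)))
  idx <- c(2, 30, 90)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_square(cirf:::tg_avgpool(p, 2L))), x, idx)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_square(cirf:::tg_interp_to(p, 8L, 8L))), x, idx)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_square(
    cirf:::tg_cat_c(cirf:::tg_slice_c(p, 1L, 2L), cirf:::tg_slice_c(p, 2L, 3L)))), x, idx)
  expect_grad_matches(function(p) cirf:::tg_mean(cirf:::tg_square(cirf:::tg_slice_n(p, 2L))), x, idx)
})

test_that("a conv-BN-attention composite matches finite differences end to end", {
  withr::with_seed(4, x <- array(runif(8 * 8 * 2 * 2), c(8, 8, 2, 2)))
  conv <- cirf:::layer_conv(2L, 4L, 3L)
  bn <- cirf:::layer_batchnorm(4L)
  mha <- cirf:::layer_mha(4L, 2L)
  make_loss <- function(p) {
    h <- cirf:::tg_relu(bn$forward(conv$forward(p)))
    tok <- cirf:::tokens_from_grid(cirf:::tg_avgpool(h, 2L))
    cirf:::tg_mean(cirf:::tg_square(mha$forward(tok, 2L)))
  }
  expect_grad_matches(make_loss, x, c(5, 64, 200), tol = 1e-4)
  # weight gradients too (reset accumulators from the check above first)
  cirf:::tg_zero_grad(c(cirf::module_parameters(conv), cirf::module_parameters(bn),
                        cirf::module_parameters(mha)))
  p <- cirf:::as_tg(x)
  loss <- make_loss(p)
  cirf:::tg_backward(loss)
  wgrad <- conv$params$w$grad
  expect_false(is.null(wgrad))
  wv <- conv$params$w$value
  num <- fd_grad(function(ww) {
    conv$params$w$value <- ww
    on.exit(conv$params$w$value <- wv)
    cirf:::val(make_loss(cirf:::as_tg(x)))
  }, wv, c(1, 20, 50))
  expect_equal(wgrad[c(1, 20, 50)], num, tolerance = 1e-4)
})

test_that("the fused attention cores match central differences", {
  withr::with_seed(31, {
    q <- matrix(rnorm(32), 8, 4); k <- matrix(rnorm(32), 8, 4); v <- matrix(rnorm(32), 8, 4)
    R <- matrix(rnorm(32), 8, 4)
  })
  f <- function(qq, kk, vv) sum(cirf:::val(cirf:::tg_mha_core(qq, kk, vv, 2L, 2L, 0.5)) * R)
  qp <- cirf:::tg_param(q); kp <- cirf:::tg_param(k); vp <- cirf:::tg_param(v)
  cirf:::tg_backward(cirf:::tg_mha_core(qp, kp, vp, 2L, 2L, 0.5), seed = R)
  eps <- 1e-6
  for (i in c(1, 10, 25)) {
    expect_equal(qp$grad[i], (f(q + eps * (seq_along(q) == i), k, v) -
                                f(q - eps * (seq_along(q) == i), k, v)) / (2 * eps),
                 tolerance = 1e-5)
    expect_equal(vp$grad[i], (f(q, k, v + eps * (seq_along(v) == i)) -
                                f(q, k, v - eps * (seq_along(v) == i))) / (2 * eps),
                 tolerance = 1e-5)
  }
  # channel attention with learned temperature and L2-normalized q/k
  withr::with_seed(32, {
    x <- array(rnorm(4 * 4 * 12 * 2), c(4, 4, 12, 2))
    R2 <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  })
  tau <- c(0.8, 1.3)
  f2 <- function(xx, tt) sum(cirf:::val(cirf:::tg_chattn_core(xx, tt, 2L)) * R2)
  xp <- cirf:::tg_param(x); tp <- cirf:::tg_param(tau)
  cirf:::tg_backward(cirf:::tg_chattn_core(xp, tp, 2L), seed = R2)
  for (i in c(1, 100, 250, 380)) {
    d <- array(0, dim(x)); d[i] <- eps
    expect_equal(xp$grad[i], (f2(x + d, tau) - f2(x - d, tau)) / (2 * eps), tolerance = 1e-5)
  }
  expect_equal(tp$grad[1], (f2(x, tau + c(eps, 0)) - f2(x, tau - c(eps, 0))) / (2 * eps),
               tolerance = 1e-5)
})

test_that("no-grad mode builds no tape and dropout is seed-reproducible", {
  x <- cirf:::tg_param(matrix(runif(16), 4, 4))
  y <- cirf:::with_no_grad(cirf:::tg_square(x))
  expect_false(y$requires_grad)
  expect_length(y$parents, 0L)
  d1 <- withr::with_seed(5, cirf:::val(cirf:::tg_dropout(matrix(1, 10, 10), 0.5, TRUE)))
  d2 <- withr::with_seed(5, cirf:::val(cirf:::tg_dropout(matrix(1, 10, 10), 0.5, TRUE)))
  expect_identical(d1, d2)
  expect_true(any(d1 == 0))
  expect_equal(cirf:::val(cirf:::tg_dropout(matrix(1, 4, 4), 0.5, FALSE)), matrix(1, 4, 4))
})

test_that("layer norm of a constant map gives zero tokens and unit stats otherwise", {
  ln <- cirf:::layer_layernorm(6L)
  cst <- matrix(3.7, 5, 6)
  expect_lt(max(abs(cirf:::val(ln$forward(cst)))), 1e-2)  # eps-guarded zero
  withr::with_seed(6, m <- matrix(rnorm(60), 10, 6))
  y <- cirf:::val(ln$forward(m))
  expect_lt(max(abs(rowMeans(y))), 1e-4)
  expect_lt(max(abs(apply(y, 1, function(r) mean(r^2)) - 1)), 1e-3)
})
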