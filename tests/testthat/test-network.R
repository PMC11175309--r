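# Architecture contracts at desk scale (64 px); the acceptance suite
# re-checks the headline shape contract at 256 px.

small_model <- function(seed = 0L, size = 64L) {
  cirf_model(model_config(image_size = size), seed = seed)
}

test_that("the encoder decomposes any divisible input into 64-channel base/detail", {
  m <- small_model()
  for (hw in list(c(32L, 32L), c(64L, 32L), c(64L, 64L))) {
    for (n in c(1L, 2L)) {
      x <- withr::with_seed(n, array(runif(prod(hw) * n), c(hw[1], hw[2], 1L, n)))
      e <- pde_forward(x, m)
      expect_equal(dim(e$base), c(hw[1], hw[2], 64L, n))
      expect_equal(dim(e$detail), c(hw[1], hw[2], 64L, n))
      expect_true(all(is.finite(e$base)) && all(is.finite(e$detail)))
    }
  }
  expect_error(pde_forward(array(0.5, c(48, 48, 1, 1)), m), "divisible by 32")
})

test_that("eval-mode encoder forwards are deterministic; train mode drops out reproducibly", {
  m <- small_model()
  x <- withr::with_seed(1, array(runif(32 * 32), c(32, 32, 1, 1)))
  e1 <- pde_forward(x, m)  # pde_forward runs without gradient recording
  cirf:::set_training(m, FALSE)
  e2 <- pde_forward(x, m)
  expect_identical(e1$base, e2$base)
  cirf:::set_training(m, TRUE)
  t1 <- withr::with_seed(3, cirf:::val(m$children$encoder$forward(cirf:::as_tg(x))$base))
  t2 <- withr::with_seed(3, cirf:::val(m$children$encoder$forward(cirf:::as_tg(x))$base))
  expect_identical(t1, t2)  # seeded dropout reproduces
})

test_that("cross-branch interaction transforms preserve the token/grid contracts", {
  # detail -> base: pooled grid flattens to exactly the ViT token count
  m <- small_model()
  x <- withr::with_seed(2, array(runif(64 * 64 * 2), c(64, 64, 1, 2)))
  invisible(pde_forward(x, m))  # exercises the interaction path (stack 2)
  gh <- 64 / 16
  cb <- withr::with_seed(4, array(rnorm(32 * 32 * 64 * 2), c(32, 32, 64, 2)))
  pooled <- cirf:::val(cirf:::tg_avgpool(cirf:::as_tg(cb), 8L))
  expect_equal(dim(pooled), c(gh, gh, 64, 2))
  tok <- cirf:::tokens_from_grid(cirf:::as_tg(pooled))
  expect_equal(nrow(cirf:::val(tok)), gh * gh * 2)       # token count matches grid
  # base -> detail: interpolation of a constant token grid is constant
  cst <- cirf:::as_tg(array(2.5, c(4, 4, 8, 1)))
  up <- cirf:::val(cirf:::tg_interp_to(cst, 32L, 32L))
  expect_equal(range(up), c(2.5, 2.5))
  # batch-norm eval mode uses running statistics (differs from train mode)
  bn <- cirf:::layer_batchnorm(8L)
  zin <- cirf:::as_tg(withr::with_seed(5, array(rnorm(4 * 4 * 8 * 2, 3, 2), c(4, 4, 8, 2))))
  ytrain <- cirf:::val(bn$forward(zin))
  bn$training <- FALSE
  yeval <- cirf:::val(bn$forward(zin))
  expect_gt(max(abs(ytrain - yeval)), 1e-3)
})

test_that("base fusion block is shape-preserving with normalized attention", {
  m <- small_model()
  x <- withr::with_seed(6, array(rnorm(32 * 32 * 64 * 2), c(32, 32, 64, 2)))
  y <- bfb_forward(x, m)
  expect_equal(dim(y), dim(x))
  z0a <- bfb_forward(array(0, dim(x)), m)
  z0b <- bfb_forward(array(0, dim(x)), m)
  expect_identical(z0a, z0b)  # deterministic bias response
  # attention rows are a softmax: they sum to one
  sm <- cirf:::val(cirf:::tg_softmax_rows(matrix(rnorm(64), 8, 8)))
  expect_equal(rowSums(sm), rep(1, 8), tolerance = 1e-6)
})

test_that("detail fusion block output is capped to [0,6] even for x100 inputs", {
  m <- small_model()
  x <- withr::with_seed(7, array(rnorm(32 * 32 * 64 * 2), c(32, 32, 64, 2)))
  for (xx in list(x, 100 * x)) {
    y <- dfb_forward(xx, m)
    expect_lte(max(y), 6)
    expect_gte(min(y), 0)
  }
  # the residual line is live: zeroing it changes the output
  y1 <- dfb_forward(x, m)
  saved <- m$children$dfb$children$res$params$w$value
  m$children$dfb$children$res$params$w$value <- saved * 0
  y2 <- dfb_forward(x, m)
  m$children$dfb$children$res$params$w$value <- saved
  expect_gt(max(abs(y1 - y2)), 1e-6)
})

test_that("decoders map 128 channels to a [0,1] image and have disjoint weights", {
  m <- small_model()
  feat <- withr::with_seed(8, array(rnorm(32 * 32 * 128 * 2), c(32, 32, 128, 2)))
  tf <- dfd_forward(feat, m)
  expect_equal(dim(tf), c(32L, 32L, 1L, 2L))
  expect_true(all(tf >= 0 & tf <= 1))
  tr <- drd_forward(feat, m)
  expect_equal(dim(tr), c(32L, 32L, 1L, 2L))
  expect_error(dfd_forward(feat[, , 1:64, , drop = FALSE], m), "channels")
  # DFD and DRD parameters are distinct tensors
  pf <- module_parameters(m$children$dfd)
  pr <- module_parameters(m$children$drd)
  for (i in seq_along(pf)) expect_false(identical(pf[[i]], pr[[i]]))
  expect_identical(dfd_forward(feat, m), dfd_forward(feat, m))
})

test_that("fusion is swap-symmetric, bounded and skips the reconstruction branch", {
  m <- small_model()
  withr::with_seed(9, {
    a <- matrix(runif(64 * 64), 64)
    b <- matrix(runif(64 * 64), 64)
  })
  calls0 <- m$children$drd$n_calls
  f1 <- fuse(a, b, m)
  expect_identical(m$children$drd$n_calls, calls0)  # reconstruction branch cut off
  f2 <- fuse(b, a, m)
  expect_identical(f1, f2)  # feature summation commutes exactly
  expect_true(all(is.finite(f1)) && all(f1 >= 0 & f1 <= 1))
  expect_identical(f1, fuse(a, b, m))
})

test_that("reconstruction runs through the same encoder instance as fusion", {
  m <- small_model()
  expect_identical(m$children$encoder$mid,
                   environment(m$children$encoder$forward)$m$mid)
  # the encoder reachable from both dataflows is one object
  enc_calls <- m$children$encoder$n_calls
  a <- withr::with_seed(10, matrix(runif(32 * 32), 32))
  invisible(fuse(a, a, m))
  expect_identical(m$children$encoder$n_calls, enc_calls + 2L)
  invisible(reconstruct(a, m, mask_ratio = 0))
  expect_identical(m$children$encoder$n_calls, enc_calls + 3L)
  # with mask_ratio = 0 the encoder consumes the raw image: the
  # reconstruction equals a direct decode of its features
  e <- pde_forward(a, m)
  feat <- array(c(e$base, e$detail), c(32, 32, 128, 1))
  expect_equal(reconstruct(a, m, mask_ratio = 0), drd_forward(feat, m), tolerance = 1e-12)
})

test_that("a reconstruction-only gradient step changes the fusion output", {
  m <- small_model(seed = 3L)
  opt <- cirf:::adam_new(module_parameters(m), lr = 1e-2)
  withr::with_seed(11, {
    a <- matrix(runif(32 * 32), 32)
    b <- matrix(runif(32 * 32), 32)
  })
  f_before <- fuse(a, b, m)
  cirf:::set_training(m, TRUE)
  withr::with_seed(12, {
    r <- cirf:::reconstruct_tg(array(a, c(32, 32, 1, 1)), m, 0)
    L <- rec_loss(r, array(a, c(32, 32, 1, 1)), loss_weights())
    cirf:::tg_backward(L)
  })
  cirf:::adam_step(opt)
  cirf:::tg_zero_grad(opt$params)
  f_after <- fuse(a, b, m)
  expect_gt(max(abs(f_after - f_before)), 1e-9)  # shared encoder moved
})

test_that("checkpoints round-trip the whole model", {
  m <- small_model(seed = 7L)
  withr::with_seed(13, {
    a <- matrix(runif(32 * 32), 32)
    b <- matrix(runif(32 * 32), 32)
  })
  f1 <- fuse(a, b, m)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_model(m, ck)
  m2 <- load_model(ck)
  expect_identical(fuse(a, b, m2), f1)
  expect_error(load_model("no-such-file.rds"), "not found")
})
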