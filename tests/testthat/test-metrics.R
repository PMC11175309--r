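test_that("SD, PSNR, SCD, MI and rSFe match brute-force oracles to 1e-9", {
  for (seed in 1:12) {
    tr <- random_triple(seed, n = sample(16:32, 1))
    expect_equal(fq_sd(tr$f), oracle_sd(tr$f), tolerance = 1e-9)
    expect_equal(fq_psnr(tr$a, tr$b, tr$f), oracle_psnr(tr$a, tr$b, tr$f), tolerance = 1e-9)
    expect_equal(fq_scd(tr$a, tr$b, tr$f), oracle_scd(tr$a, tr$b, tr$f), tolerance = 1e-9)
    expect_equal(fq_rsfe(tr$a, tr$b, tr$f)$rsfe, oracle_rsfe(tr$a, tr$b, tr$f), tolerance = 1e-9)
  }
  for (seed in 1:4) {
    tr <- random_triple(seed, 16L)
    expect_equal(fq_mi(tr$a, tr$b, tr$f), oracle_mi(tr$a, tr$b, tr$f), tolerance = 1e-9)
  }
})

test_that("SSIM, QAB/F and VIFF match independent implementations to 1e-6", {
  for (seed in 1:3) {
    tr <- random_triple(seed, 32L)
    expect_equal(fq_ssim(tr$a, tr$b, tr$f), oracle_ssim(tr$a, tr$b, tr$f), tolerance = 1e-6)
    expect_equal(fq_qabf(tr$a, tr$b, tr$f), oracle_qabf(tr$a, tr$b, tr$f), tolerance = 1e-6)
    expect_equal(fq_viff(tr$a, tr$b, tr$f), oracle_viff(tr$a, tr$b, tr$f), tolerance = 1e-6)
  }
})

test_that("hand-derivable metric values come out exactly", {
  half <- matrix(rep(c(0, 1), each = 128), 16, 16)
  expect_equal(fq_sd(half), 127.5)
  expect_equal(fq_sd(matrix(0.25, 8, 8)), 0)
  # MI of a two-level image with itself: 1 bit per source term
  expect_equal(fq_mi(half, half, half), 2)
  # all-zero sources against an all-255 fusion: ratio 1, 0 dB
  expect_equal(fq_psnr(matrix(0, 8, 8), matrix(0, 8, 8), matrix(1, 8, 8)), 0)
  # one source at MSE 0, one at 255^2: 10*log10(2)
  expect_equal(fq_psnr(matrix(0, 8, 8), matrix(1, 8, 8), matrix(0, 8, 8)),
               10 * log10(2), tolerance = 1e-12)
  # F = A + B makes both difference correlations exactly 1
  withr::with_seed(3, {
    a <- matrix(runif(256, 0, 0.5), 16, 16)
    b <- matrix(runif(256, 0, 0.5), 16, 16)
  })
  expect_equal(fq_scd(a, b, a + b), 2, tolerance = 1e-12)
  # with fully shared anatomy (B = A), a sign-flipped fusion anti-correlates
  # both difference images
  expect_equal(fq_scd(a, a, 1 - 2 * a), -2, tolerance = 1e-12)
  # constant fused image loses all spatial frequency
  expect_equal(fq_rsfe(a, b, matrix(0.5, 16, 16))$rsfe, -1)
  # zero-variance SCD operands are defined as zero
  cst <- matrix(0.5, 16, 16)
  expect_equal(fq_scd(cst, cst, cst), 0)
})

test_that("independent low-alphabet noise carries almost no mutual information", {
  vals <- sapply(1:10, function(s) {
    withr::with_seed(s, {
      x <- matrix(floor(runif(128 * 128) * 16) / 15, 128, 128)
      y <- matrix(floor(runif(128 * 128) * 16) / 15, 128, 128)
    })
    fq_mi(x, x, y)
  })
  expect_lt(max(vals), 0.1)
})

test_that("VIFF decreases monotonically with additive noise", {
  p <- synth_pair(4, 64)
  noisy <- function(sd) {
    withr::with_seed(11, n <- matrix(rnorm(64 * 64, 0, sd), 64, 64))
    pmin(pmax(p$a + n, 0), 1)
  }
  v <- c(fq_viff(p$a, p$a, p$a),
         fq_viff(p$a, p$a, noisy(0.02)),
         fq_viff(p$a, p$a, noisy(0.08)))
  expect_true(all(diff(v) < 0))
  expect_equal(v[1], 1, tolerance = 1e-6)
  # blur also loses visual information
  blur <- cirf:::conv_same(p$a, cirf:::gauss_kernel(2))
  expect_lt(fq_viff(p$a, p$a, blur), 1)
})

test_that("every metric is symmetric in swapping the two sources", {
  for (seed in 1:5) {
    tr <- random_triple(seed, 32L)
    r1 <- evaluate_all(tr$a, tr$b, tr$f)
    r2 <- evaluate_all(tr$b, tr$a, tr$f)
    for (nm in c("sd", "psnr", "scd", "mi", "ssim", "qabf", "viff", "rsfe")) {
      expect_equal(r1[[nm]], r2[[nm]], tolerance = 1e-12, label = nm)
    }
  }
})

test_that("metric ranges hold over random triples", {
  for (seed in 1:100) {
    tr <- random_triple(seed, 16L)
    expect_gte(fq_sd(tr$f), 0)
    expect_gte(fq_mi(tr$a, tr$b, tr$f), 0)
    s <- fq_scd(tr$a, tr$b, tr$f)
    expect_true(s >= -2 && s <= 2)
    q <- fq_qabf(tr$a, tr$b, tr$f)
    expect_true(q >= 0 && q <= 1)
  }
})

test_that("metrics are translation covariant on periodically wrapped images", {
  # periodic content so that a cyclic roll introduces no seam
  n <- 32L
  xs <- matrix(rep(1:n, each = n), n) / n
  ys <- matrix(rep(1:n, n), n) / n
  a <- 0.5 + 0.35 * sin(2 * pi * 3 * xs) * cos(2 * pi * 2 * ys)
  b <- 0.5 + 0.3 * cos(2 * pi * 4 * xs + 1) * sin(2 * pi * 3 * ys + 0.5)
  b <- (b - min(b)) / (max(b) - min(b))
  f <- (a + b) / 2
  roll <- function(m, dy, dx) m[c((dy + 1):n, 1:dy), c((dx + 1):n, 1:dx)]
  a2 <- roll(a, 5, 9); b2 <- roll(b, 5, 9); f2 <- roll(f, 5, 9)
  # pointwise and histogram metrics: exact
  expect_equal(fq_sd(f2), fq_sd(f), tolerance = 1e-12)
  expect_equal(fq_psnr(a2, b2, f2), fq_psnr(a, b, f), tolerance = 1e-12)
  expect_equal(fq_scd(a2, b2, f2), fq_scd(a, b, f), tolerance = 1e-12)
  expect_equal(fq_mi(a2, b2, f2), fq_mi(a, b, f), tolerance = 1e-12)
  # windowed metrics sample a shifted set of border windows; small bounded
  # absolute drift
  expect_lt(abs(fq_ssim(a2, b2, f2) - fq_ssim(a, b, f)), 0.02)
  expect_lt(abs(fq_viff(a2, b2, f2) - fq_viff(a, b, f)), 0.02)
  expect_lt(abs(fq_qabf(a2, b2, f2) - fq_qabf(a, b, f)), 0.05)
  expect_lt(abs(fq_rsfe(a2, b2, f2)$rsfe - fq_rsfe(a, b, f)$rsfe), 0.005)
})

test_that("degenerate inputs are handled as documented", {
  cst <- matrix(0.5, 16, 16)
  expect_warning(q <- fq_qabf(cst, cst, cst), "constant")
  expect_equal(q, 0)
  expect_error(fq_rsfe(cst, cst, cst), "constant")
  expect_error(fq_ssim(matrix(0.1, 8, 8), matrix(0.1, 8, 8), matrix(0.1, 8, 8)), "window")
  expect_error(fq_viff(matrix(0.1, 16, 16), matrix(0.1, 16, 16), matrix(0.1, 16, 16)), "32")
})

test_that("evaluate_all compiles the individual metrics and handles color", {
  tr <- structured_triple(8, 64L)
  r <- evaluate_all(tr$a, tr$b, tr$f)
  expect_equal(r$sd, fq_sd(tr$f))
  expect_equal(r$scd, fq_scd(tr$a, tr$b, tr$f))
  expect_equal(r$qabf, fq_qabf(tr$a, tr$b, tr$f))
  expect_equal(r$rsfe_abs, abs(r$rsfe))
  # RGB source is evaluated on its luma channel
  pc <- synth_pair(8, 64, "pseudo-color")
  rc <- evaluate_all(pc$a, pc$color_b, tr$f)
  rg <- evaluate_all(pc$a, pc$b, tr$f)
  expect_equal(unclass(rc)[1:8], unclass(rg)[1:8], tolerance = 1e-12)
})
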