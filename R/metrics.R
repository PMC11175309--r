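# Evaluation-grade fusion-quality metrics. Every metric takes the two source
# images A, B and the fused image F as [0,1] matrices and evaluates on the
# 8-bit scale (x255) where the literature defines it that way. These are the
# exact (non-differentiable) definitions; the training losses use smooth
# surrogates (see losses.R).

to255 <- function(x) 255 * x

pearson0 <- function(x, y) {
  # Pearson correlation with zero-variance operands defined as 0
  x <- as.numeric(x); y <- as.numeric(y)
  sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
  if (sx <= 0 || sy <= 0) return(0)
  sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
}

conv_valid <- function(m, k) {
  x <- array(m, c(nrow(m), ncol(m), 1L, 1L))
  y <- cpp_conv2d_fwd(x, matrix(k, length(k), 1L), nrow(k), ncol(k), 1L, 0L)
  matrix(y, dim(y)[1], dim(y)[2])
}

#' Standard deviation of a fused image
#'
#' Population standard deviation of pixel intensities on the 8-bit scale;
#' a contrast measure.
#'
#' @param f fused image, `[0,1]` matrix
#' @return standard deviation in 8-bit intensity units
#' @export
fq_sd <- function(f) {
  assert_image(f, "f")
  x <- to255(f)
  sqrt(mean((x - mean(x))^2))
}

#' Peak signal-to-noise ratio of a fusion
#'
#' The mean squared errors of F against each source are averaged, and
#' `10*log10(255^2 / meanMSE)` reported. `Inf` when both MSEs are zero.
#'
#' @param a,b source images, `[0,1]` matrices
#' @param f fused image
#' @return PSNR in dB
#' @export
fq_psnr <- function(a, b, f) {
  stopifnot(all(dim(a) == dim(f)), all(dim(b) == dim(f)))
  m1 <- mean((to255(a) - to255(f))^2)
  m2 <- mean((to255(b) - to255(f))^2)
  mm <- (m1 + m2) / 2
  if (mm == 0) return(Inf)
  10 * log10(255^2 / mm)
}

#' Sum of correlations of differences (SCD)
#'
#' `r(F - B, A) + r(F - A, B)` with Pearson r; correlations with a
#' zero-variance operand count as 0. Range `[-2, 2]`.
#'
#' @inheritParams fq_psnr
#' @return dimensionless value in `[-2,2]`
#' @export
fq_scd <- function(a, b, f) {
  pearson0(f - b, a) + pearson0(f - a, b)
}

mi_pair <- function(x, y) {
  qx <- as.integer(round(to255(x))); qy <- as.integer(round(to255(y)))
  n <- length(qx)
  joint <- tabulate(qx * 256L + qy + 1L, 65536L) / n
  px <- tabulate(qx + 1L, 256L) / n
  py <- tabulate(qy + 1L, 256L) / n
  nz <- joint > 0
  pxy <- joint[nz]
  ox <- outer(py, px)[nz]  # joint index runs qy-fastest
  sum(pxy * log2(pxy / ox))
}

#' Mutual information of a fusion
#'
#' `I(A;F) + I(B;F)` from 256-bin joint histograms of the 8-bit quantized
#' images, in bits.
#'
#' @inheritParams fq_psnr
#' @return mutual information in bits, >= 0
#' @export
fq_mi <- function(a, b, f) {
  mi_pair(a, f) + mi_pair(b, f)
}

ssim_pair <- function(x, y, k1 = 0.01, k2 = 0.03, L = 255, sigma = 1.5, win = 11L) {
  if (nrow(x) < win || ncol(x) < win) stop("image smaller than the SSIM window (", win, ")")
  w <- gauss_kernel(sigma, win)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  mx <- conv_valid(x, w); my <- conv_valid(y, w)
  sxx <- conv_valid(x * x, w) - mx^2
  syy <- conv_valid(y * y, w) - my^2
  sxy <- conv_valid(x * y, w) - mx * my
  map <- ((2 * mx * my + c1) * (2 * sxy + c2)) / ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(map)
}

#' Fusion SSIM
#'
#' Mean of `SSIM(A,F)` and `SSIM(B,F)` with the standard Gaussian 11x11
#' window (sigma 1.5), K1 = 0.01, K2 = 0.03, dynamic range 255.
#'
#' @inheritParams fq_psnr
#' @return dimensionless value in `[-1,1]`
#' @export
fq_ssim <- function(a, b, f) {
  (ssim_pair(to255(a), to255(f)) + ssim_pair(to255(b), to255(f))) / 2
}

# Xydeas-Petrovic sigmoid constants; each sigmoid is normalized by its value
# at perfect preservation so that F = A = B scores exactly 1.
.qabf_const <- list(Gg = 0.9994, kg = -15, dg = 0.5, Ga = 0.9879, ka = -22, da = 0.8)

qabf_sigmoids <- function(gaf, aaf) {
  cc <- .qabf_const
  qg <- cc$Gg / (1 + exp(cc$kg * (gaf - cc$dg)))
  qa <- cc$Ga / (1 + exp(cc$ka * (aaf - cc$da)))
  qg1 <- cc$Gg / (1 + exp(cc$kg * (1 - cc$dg)))
  qa1 <- cc$Ga / (1 + exp(cc$ka * (1 - cc$da)))
  (qg / qg1) * (qa / qa1)
}

qabf_edges <- function(x) {
  gx <- conv_same(x, .sobel_x)
  gy <- conv_same(x, .sobel_y)
  g <- sqrt(gx^2 + gy^2)
  al <- atan2(gy, gx)
  al <- al - pi * round(al / pi)  # orientation mod pi, in (-pi/2, pi/2]
  list(g = g, a = al)
}

qabf_source <- function(es, ef) {
  ga <- es$g; gf <- ef$g
  gaf <- ifelse(ga > gf, gf / ga, ifelse(gf > 0, ga / gf, 1))
  aaf <- abs(abs(es$a - ef$a) - pi / 2) * 2 / pi
  qabf_sigmoids(gaf, aaf)
}

#' Edge-preservation metric QAB/F
#'
#' Per-pixel Sobel edge strength and orientation of F are compared with
#' each source through sigmoid preservation maps, and combined weighted by
#' source edge strength. Returns a value in `[0,1]`; all-constant sources
#' (zero total edge weight) score 0 with a warning.
#'
#' @inheritParams fq_psnr
#' @return dimensionless value in `[0,1]`
#' @export
fq_qabf <- function(a, b, f) {
  if (stats::var(as.numeric(a)) == 0 && stats::var(as.numeric(b)) == 0) {
    warning("both sources are constant; QAB/F undefined, returning 0")
    return(0)
  }
  ea <- qabf_edges(to255(a)); eb <- qabf_edges(to255(b)); ef <- qabf_edges(to255(f))
  qa <- qabf_source(ea, ef)
  qb <- qabf_source(eb, ef)
  wsum <- sum(ea$g + eb$g)
  if (wsum == 0) {
    warning("both sources are constant; QAB/F undefined, returning 0")
    return(0)
  }
  sum(qa * ea$g + qb * eb$g) / wsum
}

vifp_pair <- function(ref, dist, sigma_nsq = 2) {
  num <- 0; den <- 0
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    win <- gauss_kernel(N / 5, N)
    if (scale > 1) {
      # same-padded low-pass keeps 4 scales usable from 32 px upward
      ref <- conv_same(ref, win); dist <- conv_same(dist, win)
      ref <- ref[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2), drop = FALSE]
      dist <- dist[seq(1, nrow(dist), 2), seq(1, ncol(dist), 2), drop = FALSE]
    }
    if (nrow(ref) < N || ncol(ref) < N)
      stop("image too small for 4-scale VIFF (needs >= 32 px)")
    mu1 <- conv_valid(ref, win); mu2 <- conv_valid(dist, win)
    s1 <- pmax(conv_valid(ref * ref, win) - mu1^2, 0)
    s2 <- pmax(conv_valid(dist * dist, win) - mu2^2, 0)
    s12 <- conv_valid(ref * dist, win) - mu1 * mu2
    g <- s12 / (s1 + 1e-10)
    sv <- s2 - g * s12
    z <- s1 < 1e-10
    g[z] <- 0; sv[z] <- s2[z]; s1[z] <- 0
    z2 <- s2 < 1e-10
    g[z2] <- 0; sv[z2] <- 0
    neg <- g < 0
    sv[neg] <- s2[neg]; g[neg] <- 0
    sv[sv <= 1e-10] <- 1e-10
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  num / den
}

#' Visual information fidelity for fusion (VIFF)
#'
#' Pixel-domain multi-scale visual information fidelity (4 scales,
#' Gaussian low-pass and downsample-by-2, noise variance 2) of F against
#' each source, averaged. Equals 1 when F matches both sources.
#'
#' @inheritParams fq_psnr
#' @return dimensionless value >= 0
#' @export
fq_viff <- function(a, b, f) {
  (vifp_pair(to255(a), to255(f)) + vifp_pair(to255(b), to255(f))) / 2
}

sf_terms <- function(x) {
  h <- nrow(x); w <- ncol(x)
  wd <- 1 / sqrt(2)
  list(
    rf = x[, 2:w, drop = FALSE] - x[, 1:(w - 1), drop = FALSE],
    cf = x[2:h, , drop = FALSE] - x[1:(h - 1), , drop = FALSE],
    mdf = x[2:h, 2:w, drop = FALSE] - x[1:(h - 1), 1:(w - 1), drop = FALSE],
    sdf = x[2:h, 1:(w - 1), drop = FALSE] - x[1:(h - 1), 2:w, drop = FALSE],
    wd = wd
  )
}

sf_combine <- function(rf, cf, mdf, sdf, wd) {
  sqrt(mean(rf^2) + mean(cf^2) + wd * mean(mdf^2) + wd * mean(sdf^2))
}

#' Ratio of spatial frequency error (rSFe)
#'
#' Spatial frequency of F from four directional first-difference fields
#' (rows, columns, and both diagonals weighted 1/sqrt(2)), compared with a
#' reference built from the element-wise maximum of the absolute source
#' differences: `rSFe = (SF_F - SF_R)/SF_R`. Zero is ideal; positive
#' values indicate injected noise, negative values lost detail.
#'
#' @inheritParams fq_psnr
#' @return list with `rsfe` (signed) and `abs_rsfe`
#' @export
fq_rsfe <- function(a, b, f) {
  ta <- sf_terms(to255(a)); tb <- sf_terms(to255(b)); tf <- sf_terms(to255(f))
  sff <- sf_combine(tf$rf, tf$cf, tf$mdf, tf$sdf, tf$wd)
  sfr <- sf_combine(pmax(abs(ta$rf), abs(tb$rf)), pmax(abs(ta$cf), abs(tb$cf)),
                    pmax(abs(ta$mdf), abs(tb$mdf)), pmax(abs(ta$sdf), abs(tb$sdf)), ta$wd)
  if (sfr == 0) stop("both sources are constant; rSFe undefined")
  r <- (sff - sfr) / sfr
  list(rsfe = r, abs_rsfe = abs(r))
}

#' Evaluate all eight fusion-quality metrics
#'
#' Computes SD, PSNR, SCD, MI, SSIM, QAB/F, VIFF and rSFe for one
#' (A, B, F) triple. RGB inputs are evaluated on their luma (Y) channel.
#'
#' @param a,b source images: `[0,1]` matrices or `H x W x 3` RGB arrays
#' @param f fused image, same convention
#' @return object of class `cirf_metrics`: list with fields `sd`, `psnr`,
#'   `scd`, `mi`, `ssim`, `qabf`, `viff`, `rsfe`, `rsfe_abs`
#' @export
evaluate_all <- function(a, b, f) {
  gray <- function(x) if (length(dim(x)) == 3L) rgb_to_yuv(x)$y else x
  a <- gray(a); b <- gray(b); f <- gray(f)
  stopifnot(all(dim(a) == dim(f)), all(dim(b) == dim(f)))
  rs <- fq_rsfe(a, b, f)
  out <- list(
    sd = fq_sd(f),
    psnr = fq_psnr(a, b, f),
    scd = fq_scd(a, b, f),
    mi = fq_mi(a, b, f),
    ssim = fq_ssim(a, b, f),
    qabf = fq_qabf(a, b, f),
    viff = fq_viff(a, b, f),
    rsfe = rs$rsfe,
    rsfe_abs = rs$abs_rsfe
  )
  class(out) <- "cirf_metrics"
  out
}

#' @export
print.cirf_metrics <- function(x, ...) {
  v <- unlist(x[c("sd", "psnr", "scd", "mi", "ssim", "qabf", "viff", "rsfe")])
  cat(sprintf("%-5s %10.4f\n", names(v), v), sep = "")
  invisible(x)
}

#' @export
as.data.frame.cirf_metrics <- function(x, ...) {
  data.frame(sd = x$sd, psnr = x$psnr, scd = x$scd, mi = x$mi, ssim = x$ssim,
             qabf = x$qabf, viff = x$viff, rsfe = x$rsfe)
}
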