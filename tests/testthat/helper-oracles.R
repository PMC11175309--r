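# Independent brute-force oracles for the fusion-quality metrics, written as
# direct transcriptions of the published formulas (plain loops, no shared
# code with the package implementations), plus small fixture generators.

random_triple <- function(seed, n = 16L) {
  withr::with_seed(seed, list(
    a = matrix(runif(n * n), n, n),
    b = matrix(runif(n * n), n, n),
    f = matrix(runif(n * n), n, n)
  ))
}

# smooth, structured triple (synthetic-pair based) for window metrics
structured_triple <- function(seed, n = 64L) {
  p <- cirf::synth_pair(seed, n)
  f <- (p$a + p$b) / 2
  list(a = p$a, b = p$b, f = f)
}

oracle_sd <- function(f) {
  x <- 255 * as.numeric(f)
  sqrt(sum((x - mean(x))^2) / length(x))
}

oracle_psnr <- function(a, b, f) {
  m1 <- mean((255 * a - 255 * f)^2)
  m2 <- mean((255 * b - 255 * f)^2)
  if ((m1 + m2) == 0) return(Inf)
  10 * log10(255^2 / ((m1 + m2) / 2))
}

oracle_pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  xc <- x - mean(x); yc <- y - mean(y)
  den <- sqrt(sum(xc^2)) * sqrt(sum(yc^2))
  if (den == 0) return(0)
  sum(xc * yc) / den
}

oracle_scd <- function(a, b, f) {
  oracle_pearson(f - b, a) + oracle_pearson(f - a, b)
}

oracle_mi <- function(a, b, f) {
  mi1 <- function(x, y) {
    qx <- round(255 * as.numeric(x)); qy <- round(255 * as.numeric(y))
    n <- length(qx)
    joint <- matrix(0, 256, 256)
    for (i in seq_len(n)) joint[qx[i] + 1, qy[i] + 1] <- joint[qx[i] + 1, qy[i] + 1] + 1
    joint <- joint / n
    px <- rowSums(joint); py <- colSums(joint)
    s <- 0
    for (i in 1:256) for (j in 1:256) {
      if (joint[i, j] > 0) s <- s + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
    }
    s
  }
  mi1(a, f) + mi1(b, f)
}

# plain 2-d correlation helpers for the oracle implementations
oracle_conv_valid <- function(m, k) {
  kh <- nrow(k); kw <- ncol(k)
  ho <- nrow(m) - kh + 1; wo <- ncol(m) - kw + 1
  out <- matrix(0, ho, wo)
  for (i in seq_len(ho)) for (j in seq_len(wo)) {
    out[i, j] <- sum(m[i:(i + kh - 1), j:(j + kw - 1)] * k)
  }
  out
}

oracle_conv_same <- function(m, k) {
  p <- (nrow(k) - 1) / 2
  mp <- matrix(0, nrow(m) + 2 * p, ncol(m) + 2 * p)
  mp[p + seq_len(nrow(m)), p + seq_len(ncol(m))] <- m
  oracle_conv_valid(mp, k)
}

oracle_gauss <- function(sigma, size) {
  r <- (size - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

oracle_ssim <- function(a, b, f) {
  pair <- function(x, y) {
    x <- 255 * x; y <- 255 * y
    w <- oracle_gauss(1.5, 11)
    c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
    mx <- oracle_conv_valid(x, w); my <- oracle_conv_valid(y, w)
    sxx <- oracle_conv_valid(x * x, w) - mx^2
    syy <- oracle_conv_valid(y * y, w) - my^2
    sxy <- oracle_conv_valid(x * y, w) - mx * my
    mean(((2 * mx * my + c1) * (2 * sxy + c2)) /
           ((mx^2 + my^2 + c1) * (sxx + syy + c2)))
  }
  (pair(a, f) + pair(b, f)) / 2
}

oracle_qabf <- function(a, b, f) {
  sobx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  soby <- t(sobx)
  edges <- function(x) {
    x <- 255 * x
    gx <- oracle_conv_same(x, sobx); gy <- oracle_conv_same(x, soby)
    g <- sqrt(gx^2 + gy^2)
    al <- atan2(gy, gx)
    al <- al - pi * round(al / pi)
    list(g = g, a = al)
  }
  Gg <- 0.9994; kg <- -15; dg <- 0.5; Ga <- 0.9879; ka <- -22; da <- 0.8
  qg1 <- Gg / (1 + exp(kg * (1 - dg)))
  qa1 <- Ga / (1 + exp(ka * (1 - da)))
  ea <- edges(a); eb <- edges(b); ef <- edges(f)
  num <- 0; den <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    for (src in list(ea, eb)) {
      gs <- src$g[i, j]; gf <- ef$g[i, j]
      gaf <- if (gs > gf) gf / gs else if (gf > 0) gs / gf else 1
      aaf <- abs(abs(src$a[i, j] - ef$a[i, j]) - pi / 2) * 2 / pi
      qg <- Gg / (1 + exp(kg * (gaf - dg)))
      qa <- Ga / (1 + exp(ka * (aaf - da)))
      num <- num + (qg / qg1) * (qa / qa1) * gs
      den <- den + gs
    }
  }
  if (den == 0) 0 else num / den
}

oracle_vifp <- function(ref, dist, sigma_nsq = 2) {
  num <- 0; den <- 0
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    win <- oracle_gauss(N / 5, N)
    if (scale > 1) {
      ref <- oracle_conv_same(ref, win); dist <- oracle_conv_same(dist, win)
      ref <- ref[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2), drop = FALSE]
      dist <- dist[seq(1, nrow(dist), 2), seq(1, ncol(dist), 2), drop = FALSE]
    }
    mu1 <- oracle_conv_valid(ref, win); mu2 <- oracle_conv_valid(dist, win)
    s1 <- pmax(oracle_conv_valid(ref * ref, win) - mu1^2, 0)
    s2 <- pmax(oracle_conv_valid(dist * dist, win) - mu2^2, 0)
    s12 <- oracle_conv_valid(ref * dist, win) - mu1 * mu2
    g <- s12 / (s1 + 1e-10)
    sv <- s2 - g * s12
    z <- s1 < 1e-10; g[z] <- 0; sv[z] <- s2[z]; s1[z] <- 0
    z2 <- s2 < 1e-10; g[z2] <- 0; sv[z2] <- 0
    neg <- g < 0; sv[neg] <- s2[neg]; g[neg] <- 0
    sv[sv <= 1e-10] <- 1e-10
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  num / den
}

oracle_viff <- function(a, b, f) {
  (oracle_vifp(255 * a, 255 * f) + oracle_vifp(255 * b, 255 * f)) / 2
}

oracle_rsfe <- function(a, b, f) {
  dirs <- function(x) {
    x <- 255 * x
    h <- nrow(x); w <- ncol(x)
    list(
      rf = x[, 2:w] - x[, 1:(w - 1)],
      cf = x[2:h, ] - x[1:(h - 1), ],
      md = x[2:h, 2:w] - x[1:(h - 1), 1:(w - 1)],
      sd = x[2:h, 1:(w - 1)] - x[1:(h - 1), 2:w]
    )
  }
  wd <- 1 / sqrt(2)
  sf <- function(d) sqrt(mean(d$rf^2) + mean(d$cf^2) + wd * mean(d$md^2) + wd * mean(d$sd^2))
  da <- dirs(a); db <- dirs(b); df <- dirs(f)
  dr <- list(rf = pmax(abs(da$rf), abs(db$rf)), cf = pmax(abs(da$cf), abs(db$cf)),
             md = pmax(abs(da$md), abs(db$md)), sd = pmax(abs(da$sd), abs(db$sd)))
  (sf(df) - sf(dr)) / sf(dr)
}
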