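# Data handling: image I/O and intensity conventions, YUV pseudo-color
# support, dataset splitting and augmentation, patch masking, and the
# synthetic multi-modal phantom generator used for desk-scale experiments.

# run expr with a temporary RNG state seeded by `seed`
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

assert_image <- function(img, name = "img") {
  if (!is.matrix(img) || !is.numeric(img)) stop(name, " must be a numeric matrix")
  if (any(!is.finite(img))) stop(name, " contains non-finite values")
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9) stop(name, " must lie in [0,1]")
  invisible(img)
}

## ---- image I/O --------------------------------------------------------------

#' Read a grayscale or RGB image
#'
#' Reads PNG or TIFF images into the package's intensity convention:
#' grayscale images become an `H x W` matrix in `[0,1]`, RGB images an
#' `H x W x 3` array in `[0,1]`. Alpha channels are dropped.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`
#' @return numeric matrix (grayscale) or 3-d array (RGB)
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L) x <- x[, , 1:3, drop = FALSE]
    if (dim(x)[3] == 1L) x <- x[, , 1L]
    # grayscale stored as RGB triplets
    if (length(dim(x)) == 3L && max(abs(x[, , 1] - x[, , 2])) < 1e-9 &&
        max(abs(x[, , 1] - x[, , 3])) < 1e-9) x <- x[, , 1L]
  }
  x
}

#' Write a grayscale or RGB image
#'
#' PNG output is 8-bit; TIFF output may be 8- or 16-bit. Values are
#' quantized to the requested bit depth before writing so that a
#' read-back reproduces the stored values exactly.
#'
#' @param img matrix (grayscale) or `H x W x 3` array (RGB) in `[0,1]`
#' @param path output path; format chosen by extension
#' @param bits bit depth, 8 or 16 (16 is TIFF-only)
#' @return `path`, invisibly
#' @export
write_image <- function(img, path, bits = 8L) {
  if (any(!is.finite(img))) stop("image contains non-finite values")
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  q <- 2^bits - 1
  imgq <- round(img * q) / q
  if (ext == "png") {
    if (bits != 8L) stop("PNG output is 8-bit only; use TIFF for 16-bit")
    png::writePNG(imgq, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(imgq, path, bits.per.sample = as.integer(bits))
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

## ---- YUV pseudo-color handling ---------------------------------------------

# BT.601 analog YUV forward matrix; inverse computed exactly from it
.yuv_fwd <- rbind(
  c(0.299, 0.587, 0.114),
  0.492111 * (c(0, 0, 1) - c(0.299, 0.587, 0.114)),
  0.877283 * (c(1, 0, 0) - c(0.299, 0.587, 0.114))
)
.yuv_inv <- solve(.yuv_fwd)

#' Convert an RGB image to YUV
#'
#' BT.601 analog YUV: `Y = 0.299 R + 0.587 G + 0.114 B`, with U and V the
#' scaled blue/red color differences centred at zero. Only the Y (luma)
#' channel takes part in fusion; U and V are carried through unchanged.
#'
#' @param img `H x W x 3` RGB array in `[0,1]`
#' @return list with matrix components `y` (in `[0,1]`), `u`, `v`
#' @export
rgb_to_yuv <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) stop("expected an H x W x 3 RGB array")
  d <- dim(img)
  m <- matrix(img, d[1] * d[2], 3L)
  yuv <- m %*% t(.yuv_fwd)
  list(
    y = matrix(pmin(pmax(yuv[, 1], 0), 1), d[1], d[2]),
    u = matrix(yuv[, 2], d[1], d[2]),
    v = matrix(yuv[, 3], d[1], d[2])
  )
}

#' Convert YUV channels back to RGB
#'
#' Exact inverse of [rgb_to_yuv()]; the result is clipped to `[0,1]`.
#'
#' @param y,u,v matrices of identical shape
#' @return `H x W x 3` RGB array
#' @export
yuv_to_rgb <- function(y, u, v) {
  if (!all(dim(y) == dim(u)) || !all(dim(y) == dim(v))) stop("Y, U, V shapes differ")
  d <- dim(y)
  m <- cbind(as.numeric(y), as.numeric(u), as.numeric(v)) %*% t(.yuv_inv)
  array(pmin(pmax(m, 0), 1), c(d[1], d[2], 3L))
}

## ---- augmentation -----------------------------------------------------------

rot90ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
rot90cw <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
fliplr <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flipud <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

#' Six-fold rotation/mirror augmentation
#'
#' Expands one image into six: the original, 90-degree counterclockwise,
#' 180-degree, and 90-degree clockwise rotations, and the left-right and
#' up-down mirrors, in that fixed order.
#'
#' @param img numeric matrix
#' @return list of 6 matrices
#' @export
augment_six <- function(img) {
  stopifnot(is.matrix(img))
  list(img, rot90ccw(img), rot180(img), rot90cw(img), fliplr(img), flipud(img))
}

## ---- random patch masking ---------------------------------------------------

#' Mask random image patches
#'
#' Sets a fraction of non-overlapping square patches to a fill value, the
#' masked-image-modeling style augmentation used by the reconstruction
#' branch. The number of masked patches is `round(ratio * n_patches)`.
#'
#' @param img numeric matrix with sides divisible by `patch`
#' @param ratio fraction of patches to mask, in `[0,1]`
#' @param seed integer seed; the same seed reproduces the same mask
#' @param patch patch side in pixels (default 16)
#' @param fill fill value for masked pixels (default 0)
#' @return masked copy of `img`
#' @export
random_mask <- function(img, ratio, seed, patch = 16L, fill = 0) {
  stopifnot(is.matrix(img))
  if (!is.finite(ratio) || ratio < 0 || ratio > 1) stop("ratio must lie in [0,1]")
  h <- nrow(img); w <- ncol(img)
  if (h %% patch != 0L || w %% patch != 0L)
    stop("image sides must be divisible by the mask patch size (", patch, ")")
  nh <- h %/% patch; nw <- w %/% patch
  np <- nh * nw
  k <- round(ratio * np)
  if (k == 0L) return(img)
  sel <- local_seed(seed, sample.int(np, k))
  out <- img
  for (s in sel) {
    i <- (s - 1L) %% nh
    j <- (s - 1L) %/% nh
    out[(i * patch + 1L):((i + 1L) * patch), (j * patch + 1L):((j + 1L) * patch)] <- fill
  }
  out
}

## ---- dataset splitting ------------------------------------------------------

#' Split a dataset into train and test indices
#'
#' Randomly partitions `1:n_total` into a test set of size `n_test` and a
#' training set replicated `augmentation_fold` times (each replicate
#' standing for one augmented copy), the 8:1-plus-augmentation protocol
#' used for training.
#'
#' @param spec list with `n_total`, `n_test`, `augmentation_fold` (1 or 6)
#' @param seed integer seed
#' @return list with integer vectors `train` and `test`
#' @export
split_dataset <- function(spec, seed) {
  n_total <- spec$n_total; n_test <- spec$n_test
  fold <- spec$augmentation_fold %||% 1L
  if (!fold %in% c(1L, 6L)) stop("augmentation_fold must be 1 or 6")
  if (n_test <= 0L || n_test >= n_total) stop("need 0 < n_test < n_total")
  idx <- local_seed(seed, sample.int(n_total))
  test <- sort(idx[seq_len(n_test)])
  train <- sort(idx[(n_test + 1L):n_total])
  list(train = rep(train, times = fold), test = test)
}

## ---- synthetic multi-modal phantom ------------------------------------------

gauss_kernel <- function(sigma, size = 2 * ceiling(3 * sigma) + 1) {
  r <- (size - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

conv_same <- function(m, k) {
  x <- array(m, c(nrow(m), ncol(m), 1L, 1L))
  wm <- matrix(k, length(k), 1L)
  y <- cpp_conv2d_fwd(x, wm, nrow(k), ncol(k), 1L, as.integer((nrow(k) - 1) / 2))
  matrix(y, nrow(m), ncol(m))
}

.sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx (columns)
.sobel_y <- t(.sobel_x)                                    # d/dy (rows)

sobel_mag <- function(m) {
  gx <- conv_same(m, .sobel_x)
  gy <- conv_same(m, .sobel_y)
  sqrt(gx^2 + gy^2)
}

rescale01 <- function(m) {
  rng <- range(m)
  if (diff(rng) < .Machine$double.eps) return(m * 0)
  (m - rng[1]) / diff(rng)
}

hot_colormap <- function(m) {
  cl <- function(x) pmin(pmax(x, 0), 1)
  array(c(cl(3 * m), cl(3 * m - 1), cl(3 * m - 2)), c(dim(m), 3L))
}

#' Generate a co-registered synthetic multi-modal image pair
#'
#' Draws a latent "anatomy" of random smooth elliptical structures over a
#' background gradient, then renders two modalities sharing that anatomy:
#' modality A emphasizes smooth tissue-class contrast (low-frequency rich,
#' like T1 MR), modality B emphasizes edges and fine texture of the same
#' structures (high-frequency rich, like T2 MR or CT bone windows). The
#' `pseudo-color` profile additionally wraps modality B in a hot colormap
#' to emulate SPECT/PET, with the pair's grayscale B channel set to its
#' luma.
#'
#' @param seed integer seed; output is bit-reproducible given the seed
#' @param size image side in pixels (>= 64)
#' @param profile `"grayscale-pair"` or `"pseudo-color"`
#' @return list with matrices `a`, `b` and, for pseudo-color, array `color_b`
#' @export
synth_pair <- function(seed, size = 256L, profile = c("grayscale-pair", "pseudo-color")) {
  profile <- match.arg(profile)
  if (size < 64L) stop("size must be >= 64")
  local_seed(seed, {
    n <- as.integer(size)
    xs <- matrix(rep(seq_len(n), each = n), n, n) / n   # column coordinate
    ys <- matrix(rep(seq_len(n), times = n), n, n) / n  # row coordinate
    latent <- 0.25 * (xs + ys) / 2
    k <- sample(6:10, 1L)
    for (i in seq_len(k)) {
      cx <- runif(1, 0.15, 0.85); cy <- runif(1, 0.15, 0.85)
      sx <- runif(1, 0.04, 0.18); sy <- runif(1, 0.04, 0.18)
      th <- runif(1, 0, pi)
      amp <- runif(1, 0.35, 1)
      xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
      yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
      latent <- latent + amp * exp(-0.5 * ((xr / sx)^2 + (yr / sy)^2))
    }
    ln <- rescale01(latent)
    # modality A: smooth tissue-contrast rendering
    a <- rescale01(conv_same(ln, gauss_kernel(2)) + 0.03 * conv_same(matrix(stats::rnorm(n * n), n, n), gauss_kernel(3)))
    # modality B: edge- and texture-enhanced rendering of the same anatomy
    edges <- rescale01(sobel_mag(ln))
    texture <- rescale01(conv_same(matrix(stats::rnorm(n * n), n, n), gauss_kernel(0.6))) * ln
    b <- rescale01(0.55 * ln + 0.30 * edges + 0.15 * texture)
    if (profile == "pseudo-color") {
      cb <- hot_colormap(b)
      list(a = a, b = rgb_to_yuv(cb)$y, color_b = cb)
    } else {
      list(a = a, b = b)
    }
  })
}

#' Generate a directory of synthetic image pairs
#'
#' Writes `n` pairs as `{i:04d}_a.png` / `{i:04d}_b.png` (RGB for the
#' pseudo-color profile).
#'
#' @inheritParams synth_pair
#' @param out output directory, created if missing
#' @param n number of pairs
#' @return character vector of written paths, invisibly
#' @export
synth_dataset <- function(out, n, size = 256L, seed = 0L,
                          profile = c("grayscale-pair", "pseudo-color")) {
  profile <- match.arg(profile)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_len(n)) {
    p <- synth_pair(seed + i - 1L, size, profile)
    fa <- file.path(out, sprintf("%04d_a.png", i))
    fb <- file.path(out, sprintf("%04d_b.png", i))
    write_image(p$a, fa)
    write_image(if (profile == "pseudo-color") p$color_b else p$b, fb)
    paths <- c(paths, fa, fb)
  }
  invisible(paths)
}
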