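# Fixed multi-scale convolutional feature encoders shared by the trainable
# heads. All segmentation features are horizontally flip-equivariant
# (symmetric kernels, no signed x terms), which is what makes the trained
# segmenter side-insensitive; the landmark encoder runs on side-canonical
# right-leg crops and may therefore use signed gradients and x-position
# terms.

# per-pixel features of a downscaled [0,1] image; returns an H*W x F matrix
seg_features <- function(mat_ds) {
  b1 <- gauss_blur(mat_ds, 1)
  b2 <- gauss_blur(mat_ds, 2)
  b4 <- gauss_blur(mat_ds, 4)
  b8 <- gauss_blur(mat_ds, 8)
  g1 <- sqrt(grad_x(b1)^2 + grad_y(b1)^2)
  g3 <- sqrt(grad_x(gauss_blur(mat_ds, 3))^2 + grad_y(gauss_blur(mat_ds, 3))^2)
  g <- pixel_grid(dim(mat_ds))
  yn <- g$y / (nrow(mat_ds) - 1)
  xc <- abs(g$x / (ncol(mat_ds) - 1) - 0.5)  # |distance from vertical midline|
  cbind(I = c(mat_ds), b1 = c(b1), b2 = c(b2), b4 = c(b4), b8 = c(b8),
        g1 = c(g1), g3 = c(g3), band = c(b1 - b8), y = c(yn), y2 = c(yn^2),
        xc = c(xc))
}

# landmark-head features of a prepared 256x256 crop, computed at 128x128
lm_features <- function(crop256) {
  m <- block_mean_ds2(crop256)
  b1 <- gauss_blur(m, 1)
  b2 <- gauss_blur(m, 2)
  b4 <- gauss_blur(m, 4)
  b8 <- gauss_blur(m, 8)
  gx <- grad_x(b2); gy <- grad_y(b2)
  gm <- sqrt(gx^2 + gy^2)
  # structure tensor at sigma 3: corner-selective responses
  sxx <- gauss_blur(gx * gx, 3)
  syy <- gauss_blur(gy * gy, 3)
  sxy <- gauss_blur(gx * gy, 3)
  cornerness <- sxx * syy - sxy^2
  g <- pixel_grid(dim(m))
  xn <- g$x / (ncol(m) - 1)
  yn <- g$y / (nrow(m) - 1)
  cbind(I = c(m), b1 = c(b1), b2 = c(b2), b4 = c(b4), b8 = c(b8),
        gx = c(gx), gy = c(gy), gm = c(gm),
        sxx = c(sxx), syy = c(syy), sxy = c(sxy), corner = c(cornerness),
        x = c(xn), y = c(yn), x2 = c(xn^2), y2 = c(yn^2), xy = c(xn * yn),
        Ix = c(m * xn), Iy = c(m * yn),
        gmx = c(gm * xn), gmy = c(gm * yn))
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-8] <- 1
  list(mean = mu, sd = sd)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mean, "-"), 2, st$sd, "/")
}
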