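# Internal helpers: 2-D vector algebra, small image operators.
#
# Conventions (package-wide): images are numeric matrices indexed [row, col]
# = [y + 1, x + 1]; points are continuous 0-based (x, y) with the centre of
# pixel [r, c] at (c - 1, r - 1); x grows rightward, y downward; boxes are
# half-open [x0, x1) x [y0, y1).

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# rotation matrix acting on (x, y) column vectors; positive angle rotates
# (0, 1) (straight down) toward -x, matching the varus sign convention for a
# right leg in standard display orientation
rot2 <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 100) stop("zero-length direction vector")
  v / n
}

# perpendicular of d rotated +90 deg in (x, y) with y down: (-dy, dx)
perp2 <- function(d) c(-d[2], d[1])

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# unsigned angle between two rays (degrees, in [0, 180]); atan2-based for
# full precision near 0 and 180
ray_angle <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  abs(rad2deg(atan2(cross2(a, b), sum(a * b))))
}

# signed rotation (degrees, in (-180, 180]) carrying ray a onto ray b
rot_angle <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  rad2deg(atan2(cross2(a, b), sum(a * b)))
}

is_point <- function(p) is.numeric(p) && length(p) == 2 && all(is.finite(p))

## ---- box helpers (half-open, 0-based) -------------------------------------

#' Half-open bounding box
#'
#' Boxes are `[x0, x1) x [y0, y1)` in 0-based image coordinates.
#'
#' @param x0,y0,x1,y1 box edges.
#' @return named numeric vector.
#' @export
box_make <- function(x0, y0, x1, y1) {
  c(x0 = unname(x0), y0 = unname(y0), x1 = unname(x1), y1 = unname(y1))
}

box_center <- function(box) c((box["x0"] + box["x1"]) / 2, (box["y0"] + box["y1"]) / 2)

box_width <- function(box) unname(box["x1"] - box["x0"])
box_height <- function(box) unname(box["y1"] - box["y0"])

# tight half-open bounding box of a logical mask matrix
mask_box <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box")
  box_make(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
}

box_union <- function(a, b) {
  box_make(min(a["x0"], b["x0"]), min(a["y0"], b["y0"]),
           max(a["x1"], b["x1"]), max(a["y1"], b["y1"]))
}

#' Intersection-over-union of two masks
#'
#' @param a,b logical matrices of equal size.
#' @return IoU in \[0, 1\] (0 when both are empty).
#' @export
mask_iou <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(0)
  inter / uni
}

## ---- pixel grids and rasterization primitives -----------------------------

# matrices of pixel-centre coordinates for an H x W image
pixel_grid <- function(dim) {
  h <- dim[1]; w <- dim[2]
  list(
    x = matrix(rep(0:(w - 1), each = h), h, w),
    y = matrix(rep(0:(h - 1), times = w), h, w)
  )
}

# squared distance from each pixel centre to the segment p1-p2
dist2_segment <- function(gx, gy, p1, p2) {
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 < 1e-12) {
    return((gx - p1[1])^2 + (gy - p1[2])^2)
  }
  t <- ((gx - p1[1]) * d[1] + (gy - p1[2]) * d[2]) / len2
  t <- clamp(t, 0, 1)
  (gx - (p1[1] + t * d[1]))^2 + (gy - (p1[2] + t * d[2]))^2
}

raster_capsule <- function(grid, p1, p2, halfwidth) {
  dist2_segment(grid$x, grid$y, p1, p2) <= halfwidth^2
}

raster_disc <- function(grid, center, radius) {
  (grid$x - center[1])^2 + (grid$y - center[2])^2 <= radius^2
}

# oriented rectangle: centre of the "base" edge at p0, edge direction u
# (unit), spanning [-hw, hw] along u and [0, h] along v (unit, perpendicular)
raster_rect <- function(grid, p0, u, v, hw, h) {
  rx <- grid$x - p0[1]; ry <- grid$y - p0[2]
  du <- rx * u[1] + ry * u[2]
  dv <- rx * v[1] + ry * v[2]
  abs(du) <= hw & dv >= 0 & dv <= h
}

# disc clipped to the half-plane on the +v side of the line through p0
raster_dome <- function(grid, center, radius, p0, v) {
  inside <- raster_disc(grid, center, radius)
  side <- (grid$x - p0[1]) * v[1] + (grid$y - p0[2]) * v[2] >= 0
  inside & side
}

## ---- separable Gaussian filtering (reflect boundary) ----------------------

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# dense band matrix applying a symmetric kernel with reflect padding along a
# dimension of size n; flip-equivariant by construction (J B J = B for the
# exchange matrix J when the kernel is symmetric)
conv_band <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    # reflect indices at the borders (no repeated edge sample)
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    for (j in seq_along(idx)) B[i, idx[j]] <- B[i, idx[j]] + kernel[j]
  }
  B
}

.conv_cache <- new.env(parent = emptyenv())

conv_band_cached <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  if (is.null(.conv_cache[[key]])) {
    .conv_cache[[key]] <- conv_band(n, gauss_kernel(sigma))
  }
  .conv_cache[[key]]
}

gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  Br <- conv_band_cached(nrow(mat), sigma)
  Bc <- conv_band_cached(ncol(mat), sigma)
  Br %*% mat %*% t(Bc)
}

# central-difference gradients (replicated edges)
grad_x <- function(mat) {
  w <- ncol(mat)
  (mat[, c(2:w, w)] - mat[, c(1, 1:(w - 1))]) / 2
}

grad_y <- function(mat) {
  h <- nrow(mat)
  (mat[c(2:h, h), ] - mat[c(1, 1:(h - 1)), ]) / 2
}

# 2x2 block mean downscale (requires even dims; pads by edge replication)
block_mean_ds2 <- function(mat) {
  h <- nrow(mat); w <- ncol(mat)
  if (h %% 2L == 1L) { mat <- rbind(mat, mat[h, , drop = FALSE]); h <- h + 1L }
  if (w %% 2L == 1L) { mat <- cbind(mat, mat[, w, drop = FALSE]); w <- w + 1L }
  (mat[seq(1, h, 2), seq(1, w, 2)] + mat[seq(2, h, 2), seq(1, w, 2)] +
     mat[seq(1, h, 2), seq(2, w, 2)] + mat[seq(2, h, 2), seq(2, w, 2)]) / 4
}

# nearest-neighbour integer upscale by factor k
upscale_nn <- function(mat, k) {
  mat[rep(seq_len(nrow(mat)), each = k), rep(seq_len(ncol(mat)), each = k)]
}

## ---- bilinear warping ------------------------------------------------------

# warp mat into an out_dim image: output pixel p maps to input coord
# A %*% p + b (both 0-based pixel-centre coordinates)
warp_bilinear <- function(mat, A, b, out_dim) {
  g <- pixel_grid(out_dim)
  xi <- A[1, 1] * g$x + A[1, 2] * g$y + b[1]
  yi <- A[2, 1] * g$x + A[2, 2] * g$y + b[2]
  h <- nrow(mat); w <- ncol(mat)
  xi <- clamp(xi, 0, w - 1); yi <- clamp(yi, 0, h - 1)
  x0 <- floor(xi); y0 <- floor(yi)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- xi - x0; fy <- yi - y0
  v <- mat[cbind(c(y0) + 1, c(x0) + 1)] * c((1 - fx) * (1 - fy)) +
    mat[cbind(c(y0) + 1, c(x1) + 1)] * c(fx * (1 - fy)) +
    mat[cbind(c(y1) + 1, c(x0) + 1)] * c((1 - fx) * fy) +
    mat[cbind(c(y1) + 1, c(x1) + 1)] * c(fx * fy)
  matrix(v, out_dim[1], out_dim[2])
}

# bilinear resize of a matrix to out_dim; corner-aligned (output pixel p
# samples the input at scale * p), matching the crop coordinate transform
resize_bilinear <- function(mat, out_dim) {
  sy <- nrow(mat) / out_dim[1]
  sx <- ncol(mat) / out_dim[2]
  A <- matrix(c(sx, 0, 0, sy), 2, 2)
  warp_bilinear(mat, A, c(0, 0), out_dim)
}

flip_h <- function(mat) mat[, rev(seq_len(ncol(mat))), drop = FALSE]

connected_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  t(EBImage::imageData(lab))
}
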