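# Heatmap-regression landmark placement on prepared 256 x 256 crops.
#
# One model per region (proximal femur 9, native knee 20, TKA 15, talus 2
# landmarks). Each model is a fixed multi-scale convolutional encoder
# followed by a trained linear (1 x 1 convolution) decoding layer that
# produces one heatmap per landmark at 128 x 128 (Gaussian targets);
# decoding takes the argmax refined by separable parabolic sub-pixel
# interpolation. Training
# augments crops by random rotation (+/-10 deg) and scaling (0.9-1.1) with
# landmark coordinates co-transformed, and runs seeded momentum SGD over
# per-sample normal-equation blocks (one update per crop per epoch), so
# epochs are cheap and the loss history is exact.

HEAT_DIM <- 128L
CROP_DIM <- 256L
TPL_HALF <- 32L       # template half-size (crop px) for subpixel refinement
TPL_COARSE_SIGMA <- 4 # blur of the coarse alignment pass

# normalized square patch sampled from a crop at continuous centre (x, y)
sample_patch <- function(img, x, y, half) {
  xs <- x + (-half:half); ys <- y + (-half:half)
  h <- nrow(img); w <- ncol(img)
  xs <- clamp(xs, 0, w - 1); ys <- clamp(ys, 0, h - 1)
  gx <- matrix(rep(xs, each = length(ys)), length(ys))
  gy <- matrix(rep(ys, length(xs)), length(ys))
  x0 <- floor(gx); y0 <- floor(gy)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- gx - x0; fy <- gy - y0
  v <- img[cbind(c(y0) + 1, c(x0) + 1)] * c((1 - fx) * (1 - fy)) +
    img[cbind(c(y0) + 1, c(x1) + 1)] * c(fx * (1 - fy)) +
    img[cbind(c(y1) + 1, c(x0) + 1)] * c((1 - fx) * fy) +
    img[cbind(c(y1) + 1, c(x1) + 1)] * c(fx * fy)
  m <- matrix(v, length(ys))
  (m - mean(m)) / max(stats::sd(m), 1e-6)
}

# one Lucas-Kanade translation alignment of a template at (x, y)
lk_align <- function(img, tpl, x, y, iters = 25) {
  n <- nrow(tpl)
  Tx <- (tpl[, c(2:n, n)] - tpl[, c(1, 1:(n - 1))]) / 2
  Ty <- (tpl[c(2:n, n), ] - tpl[c(1, 1:(n - 1)), ]) / 2
  Hm <- matrix(c(sum(Tx * Tx), sum(Tx * Ty), sum(Tx * Ty), sum(Ty * Ty)), 2)
  Hi <- solve(Hm + diag(1e-9, 2))
  for (it in seq_len(iters)) {
    P <- sample_patch(img, x, y, (n - 1) / 2)
    d <- Hi %*% c(sum(Tx * (P - tpl)), sum(Ty * (P - tpl)))
    d <- clamp(d, -4, 4)
    x <- x - d[1]; y <- y - d[2]
    if (sqrt(sum(d^2)) < 0.01) break
  }
  c(x, y)
}

# learn per-landmark refinement templates (fine + blurred coarse) from
# ground-truth-centred training patches
learn_templates <- function(pixels_list, xy_list, K) {
  tpl <- vector("list", K)
  for (k in seq_len(K)) {
    acc <- 0; cnt <- 0
    for (i in seq_along(pixels_list)) {
      xy <- xy_list[[i]]
      if (any(is.na(xy[k, ]))) next
      acc <- acc + sample_patch(pixels_list[[i]], xy[k, 1], xy[k, 2], TPL_HALF)
      cnt <- cnt + 1
    }
    if (cnt > 0) {
      fine <- acc / cnt
      tpl[[k]] <- list(fine = fine, coarse = gauss_blur(fine, TPL_COARSE_SIGMA))
    }
  }
  tpl
}

# circular FFT correlation of an image with a kernel, output centred on the
# kernel-centre position
xcorr_raw <- function(img, ker) {
  h <- nrow(img); w <- ncol(img)
  th <- nrow(ker); tw <- ncol(ker)
  Pm <- matrix(0, h, w)
  Pm[1:th, 1:tw] <- ker[th:1, tw:1]
  out <- Re(stats::fft(stats::fft(img) * stats::fft(Pm), inverse = TRUE)) / (h * w)
  sr <- (th - 1) %/% 2 + 1; sc <- (tw - 1) %/% 2 + 1
  out[((seq_len(h) + sr - 2) %% h) + 1, ((seq_len(w) + sc - 2) %% w) + 1]
}

# normalized cross-correlation map of a template over an image: local means
# and energies from FFT box sums, so the response is contrast-invariant
ncc_map <- function(img, tpl, var_floor = 0.0025) {
  # replicate-pad so border positions are valid (matches the edge-clamped
  # patch sampling) and circular FFT wrap-around cannot contaminate them
  half <- (nrow(tpl) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  ri <- c(rep(1L, half), seq_len(h), rep(h, half))
  ci <- c(rep(1L, half), seq_len(w), rep(w, half))
  pim <- img[ri, ci]
  t0 <- tpl - mean(tpl)
  n <- length(tpl)
  box <- matrix(1, nrow(tpl), ncol(tpl))
  num <- xcorr_raw(pim, t0)
  s1 <- xcorr_raw(pim, box)
  s2 <- xcorr_raw(pim^2, box)
  # variance floor suppresses spurious responses in flat (noise-only)
  # regions, where plain NCC normalization explodes
  denom <- sqrt((pmax(s2 - s1^2 / n, 0) + var_floor * n) * sum(t0^2))
  out <- num / denom
  out[half + seq_len(h), half + seq_len(w)]
}

# shape-constrained regularization of decoded positions: robust weighted
# affine fit of the training mean configuration onto the detections, with
# outliers (or missing landmarks) replaced by their shape-predicted
# positions. The affine absorbs the anisotropic crop scaling; iterative
# reweighting suppresses confused detections (similar-looking landmarks).
shape_regularize <- function(lms, mean_shape, outlier_px = 12) {
  K <- nrow(mean_shape)
  if (K < 4) return(lms)
  obs <- cbind(lms$x, lms$y)
  w <- ifelse(is.na(obs[, 1]), 0, pmax(lms$confidence, 1e-3))
  if (sum(w > 0) < 4) return(lms)
  X <- cbind(mean_shape, 1)
  pred <- obs
  fit <- function(ww) {
    ok <- ww > 0 & !is.na(obs[, 1])
    if (sum(ok) < 4) return(NULL)
    tryCatch(
      qr.solve(X[ok, , drop = FALSE] * ww[ok], obs[ok, , drop = FALSE] * ww[ok]),
      error = function(e) NULL)
  }
  for (it in 1:5) {
    A <- fit(w)
    if (is.null(A)) return(lms)
    pred <- X %*% A
    r <- sqrt(rowSums((obs - pred)^2))
    w <- ifelse(is.na(r), 0, pmax(lms$confidence, 1e-3) * exp(-(r / 6)^2))
  }
  # final refit on clear inliers only, so a coherent minority of confused
  # detections (e.g. medial/lateral swaps) cannot shear the fit
  r <- sqrt(rowSums((obs - pred)^2))
  inl <- !is.na(r) & r < 10
  if (sum(inl) >= 6) {
    A <- fit(ifelse(inl, 1, 0))
    if (!is.null(A)) {
      pred <- X %*% A
      r <- sqrt(rowSums((obs - pred)^2))
    }
  }
  replace <- is.na(obs[, 1]) | r > outlier_px
  lms$x[replace] <- pred[replace, 1]
  lms$y[replace] <- pred[replace, 2]
  lms$confidence[replace & is.na(obs[, 1])] <- 0.25
  lms
}

# 1-D profile sampled from a crop along a direction (bilinear), normalized;
# the window may be asymmetric around the point
sample_profile <- function(img, p, dirv, len, step = 1, lo = -len, hi = len) {
  t <- seq(lo, hi, by = step)
  xs <- clamp(p[1] + dirv[1] * t, 0, ncol(img) - 1)
  ys <- clamp(p[2] + dirv[2] * t, 0, nrow(img) - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, ncol(img) - 1); y1 <- pmin(y0 + 1, nrow(img) - 1)
  fx <- xs - x0; fy <- ys - y0
  v <- img[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, x1 + 1)] * fx * (1 - fy) +
    img[cbind(y1 + 1, x0 + 1)] * (1 - fx) * fy +
    img[cbind(y1 + 1, x1 + 1)] * fx * fy
  (v - mean(v)) / max(stats::sd(v), 1e-6)
}

# best sub-step shift of a 1-D template within a longer observed profile
profile_shift <- function(obs, tpl, step = 1) {
  nt <- length(tpl); no <- length(obs)
  off <- (no - nt) %/% 2
  sh <- -off:off
  sc <- vapply(sh, function(s) {
    o <- obs[(1:nt) + off + s]
    sum(o * tpl) / max(sqrt(sum(o^2) * sum(tpl^2)), 1e-9)
  }, numeric(1))
  i <- which.max(sc)
  d <- 0
  if (i > 1 && i < length(sc)) {
    den <- sc[i - 1] - 2 * sc[i] + sc[i + 1]
    if (abs(den) > 1e-12) d <- 0.5 * (sc[i - 1] - sc[i + 1]) / den
  }
  list(shift = (sh[i] + d) * step, score = sc[i])
}

## ---- role-aware refinements at original-pixel pitch -----------------------
#
# A prepared crop is an anisotropically magnified view; structures have
# constant size in the image frame. The refinements below therefore work on
# the crop resampled back to its pre-resize (original-pitch) geometry,
# where templates are scale-free, and map the results back to crop
# coordinates.

# original-pitch view of a prepared crop plus the coordinate scales
orig_view <- function(pixels, crop_size) {
  list(img = resize_bilinear(pixels, crop_size),
       sx = CROP_DIM / crop_size[2], sy = CROP_DIM / crop_size[1])
}

to_orig <- function(p, ov) cbind(p[, 1] / ov$sx, p[, 2] / ov$sy)
to_crop <- function(p, ov) cbind(p[, 1] * ov$sx, p[, 2] * ov$sy)

HEAD_TPL_HALF <- 24L  # original px; covers the femoral head and margin

# learn the femoral-head disc model: mean original-pitch patch centred on
# the true head centre, plus each contour point's polar position
learn_head_disc <- function(pix_list, xy_list, crop_sizes, schema) {
  sel <- which(schema$role == "head_contour")
  if (length(sel) < 3) return(NULL)
  acc <- 0; ang <- matrix(0, 0, length(sel)); rad <- NULL
  for (i in seq_along(pix_list)) {
    ov <- orig_view(pix_list[[i]], crop_sizes[[i]])
    xy <- to_orig(xy_list[[i]], ov)
    ctr <- colMeans(xy[sel, , drop = FALSE])
    if (any(is.na(ctr))) next
    acc <- acc + sample_patch(ov$img, ctr[1], ctr[2], HEAD_TPL_HALF)
    d <- sweep(xy[sel, , drop = FALSE], 2, ctr)
    ang <- rbind(ang, atan2(d[, 2], d[, 1]))
    rad <- c(rad, sqrt(rowSums(d^2)))
  }
  if (nrow(ang) == 0) return(NULL)
  tpl <- acc / nrow(ang)
  list(template = tpl, coarse = gauss_blur(tpl, 2),
       angles = atan2(colMeans(sin(ang)), colMeans(cos(ang))),
       radius = mean(rad), idx = sel)
}

# head-disc refinement: align the disc template at original pitch to find
# the head centre, then place the contour points on the fitted circle at
# their canonical polar angles -- the downstream circle fit only uses the
# centre, which this estimates far more robustly than five independent
# point detections on a uniform disc edge
refine_head_disc <- function(lms, pixels, crop_size, disc) {
  if (is.null(disc)) return(lms)
  sel <- disc$idx
  if (sum(!is.na(lms$x[sel])) < 3) return(lms)
  ov <- orig_view(pixels, crop_size)
  xy <- to_orig(cbind(lms$x[sel], lms$y[sel]), ov)
  c0 <- colMeans(xy, na.rm = TRUE)
  # local grid search with the blurred template, then fine alignment
  bl <- gauss_blur(ov$img, 2)
  best <- c0; bv <- -Inf
  for (dy in seq(-10, 10, by = 2)) for (dx in seq(-10, 10, by = 2)) {
    P <- sample_patch(bl, c0[1] + dx, c0[2] + dy, HEAD_TPL_HALF)
    v <- sum(P * disc$coarse)
    if (v > bv) { bv <- v; best <- c0 + c(dx, dy) }
  }
  ctr <- lk_align(bl, disc$coarse, best[1], best[2])
  ctr <- lk_align(ov$img, disc$template, ctr[1], ctr[2])
  if (vnorm(ctr - c0) > 16) ctr <- best
  pts <- cbind(ctr[1] + disc$radius * cos(disc$angles),
               ctr[2] + disc$radius * sin(disc$angles))
  pts <- to_crop(pts, ov)
  lms$x[sel] <- pts[, 1]
  lms$y[sel] <- pts[, 2]
  lms
}

# the talus pair is absent deliberately: its landmarks are sharp visible
# corners that the patch templates already localize optimally
LINE_PAIR_ROLES <- list(
  c("condyle_tangent_medial", "condyle_tangent_lateral"),
  c("plateau_edge_medial", "plateau_edge_lateral"),
  c("tray_edge_medial", "tray_edge_lateral")
)

# learn perpendicular edge profiles for each medial/lateral joint-line pair
# present in the schema: mean original-pitch profile across the line at
# interior stations (the same construction used at inference)
learn_line_pairs <- function(pix_list, xy_list, crop_sizes, schema,
                             stations = c(0.15, 0.35, 0.5, 0.65, 0.85)) {
  out <- list()
  for (pair in LINE_PAIR_ROLES) {
    ka <- match(pair[1], schema$role); kb <- match(pair[2], schema$role)
    if (is.na(ka) || is.na(kb)) next
    # determine which side of the line the structure lies on (brighter side)
    side_votes <- 0
    for (i in seq_along(pix_list)) {
      ov <- orig_view(pix_list[[i]], crop_sizes[[i]])
      xy <- to_orig(xy_list[[i]], ov)
      a <- xy[ka, ]; b <- xy[kb, ]
      if (any(is.na(c(a, b)))) next
      tv <- (b - a) / vnorm(b - a)
      nv <- perp2(tv); if (nv[2] < 0) nv <- -nv
      m <- a + 0.5 * (b - a)
      up <- sample_profile(ov$img, m + 3 * nv, nv, 0.5, 0.5)
      # raw (un-normalized) comparison via direct bilinear samples
      g <- function(q) {
        xi <- clamp(q[1], 0, ncol(ov$img) - 1); yi <- clamp(q[2], 0, nrow(ov$img) - 1)
        ov$img[round(yi) + 1, round(xi) + 1]
      }
      side_votes <- side_votes + sign(g(m + 3 * nv) - g(m - 3 * nv))
    }
    s_in <- if (side_votes >= 0) 1 else -1  # structure side along nv
    # asymmetric window: 2 px outside the edge to 6 px into the structure
    lo <- -2; hi <- 6
    acc <- 0; cnt <- 0
    for (i in seq_along(pix_list)) {
      ov <- orig_view(pix_list[[i]], crop_sizes[[i]])
      xy <- to_orig(xy_list[[i]], ov)
      a <- xy[ka, ]; b <- xy[kb, ]
      if (any(is.na(c(a, b)))) next
      tv <- (b - a) / vnorm(b - a)
      nv <- s_in * { v <- perp2(tv); if (v[2] < 0) -v else v }
      for (t in stations) {
        acc <- acc + sample_profile(ov$img, a + t * (b - a), nv, NA, 0.5,
                                    lo = lo, hi = hi)
        cnt <- cnt + 1
      }
    }
    if (cnt == 0) next
    out[[length(out) + 1L]] <- list(ka = ka, kb = kb, profile = acc / cnt,
                                    stations = stations, s_in = s_in,
                                    lo = lo, hi = hi)
  }
  if (length(out) == 0) NULL else out
}

# snap each joint-line endpoint pair onto the edge refit from perpendicular
# profile matches at interior stations: the pair's perpendicular offsets
# (which set the measured joint-line angle) are corrected while the
# along-line positions are kept
refine_line_pairs <- function(lms, pixels, crop_size, pairs) {
  if (is.null(pairs)) return(lms)
  ov <- orig_view(pixels, crop_size)
  for (pr in pairs) {
    a <- to_orig(cbind(lms$x[pr$ka], lms$y[pr$ka]), ov)[1, ]
    b <- to_orig(cbind(lms$x[pr$kb], lms$y[pr$kb]), ov)[1, ]
    if (any(is.na(c(a, b))) || vnorm(b - a) < 6) next
    tv <- (b - a) / vnorm(b - a)
    nv <- pr$s_in * { v <- perp2(tv); if (v[2] < 0) -v else v }
    ts <- pr$stations
    shifts <- numeric(0); wts <- numeric(0); used <- numeric(0)
    for (t in ts) {
      # average a small tangential band of profiles to suppress pixel noise
      p0 <- a + t * (b - a)
      obs <- (sample_profile(ov$img, p0 - tv, nv, NA, 0.5,
                             lo = pr$lo - 2.5, hi = pr$hi + 2.5) +
                sample_profile(ov$img, p0, nv, NA, 0.5,
                               lo = pr$lo - 2.5, hi = pr$hi + 2.5) +
                sample_profile(ov$img, p0 + tv, nv, NA, 0.5,
                               lo = pr$lo - 2.5, hi = pr$hi + 2.5)) / 3
      bs <- profile_shift(obs, pr$profile, 0.5)
      if (bs$score > 0.5 && abs(bs$shift) <= 2.5) {
        shifts <- c(shifts, bs$shift); wts <- c(wts, bs$score); used <- c(used, t)
      }
    }
    if (length(used) < 2) next
    # weighted line in (t, shift): shift(t) = c0 + c1 t, with one round of
    # residual-based rejection against a station that locked onto a wrong
    # parallel edge
    line_fit <- function(u, s, w) {
      W <- diag(w, nrow = length(w))
      X <- cbind(1, u)
      tryCatch(solve(t(X) %*% W %*% X, t(X) %*% W %*% s),
               error = function(e) NULL)
    }
    cf <- line_fit(used, shifts, wts)
    if (is.null(cf)) next
    res <- abs(shifts - (cf[1] + cf[2] * used))
    keepst <- res < 0.75
    if (sum(keepst) >= 2 && any(!keepst)) {
      cf2 <- line_fit(used[keepst], shifts[keepst], wts[keepst])
      if (!is.null(cf2)) cf <- cf2
    }
    a2 <- a + (cf[1] + cf[2] * 0) * nv
    b2 <- b + (cf[1] + cf[2] * 1) * nv
    pa <- to_crop(rbind(a2), ov); pb <- to_crop(rbind(b2), ov)
    lms$x[pr$ka] <- pa[1, 1]; lms$y[pr$ka] <- pa[1, 2]
    lms$x[pr$kb] <- pb[1, 1]; lms$y[pr$kb] <- pb[1, 2]
  }
  lms
}

# template refinement of decoded landmark positions: shape regularization,
# then per landmark a local NCC search followed by coarse (blurred) and
# fine Lucas-Kanade alignment
refine_landmarks <- function(lms, pixels, templates, mean_shape = NULL,
                             search = NULL, refine_ok = NULL) {
  shaped <- !is.null(mean_shape) && nrow(mean_shape) >= 4
  if (shaped) lms <- shape_regularize(lms, mean_shape)
  # without a shape prior the raw peaks can be far off: search wider
  if (is.null(search)) search <- if (shaped) 10 else 48
  blurred <- gauss_blur(pixels, TPL_COARSE_SIGMA)
  for (k in seq_len(nrow(lms))) {
    if (is.na(lms$x[k]) || is.null(templates[[k]])) next
    if (shaped && !is.null(refine_ok) && !refine_ok[k]) next
    cm <- ncc_map(blurred, templates[[k]]$coarse)
    # restrict to a window around the current (shape-consistent) estimate
    xs <- unique(clamp(round(lms$x[k]) + (-search:search), 0, ncol(pixels) - 1))
    ys <- unique(clamp(round(lms$y[k]) + (-search:search), 0, nrow(pixels) - 1))
    win <- cm[ys + 1, xs + 1, drop = FALSE]
    idx <- which(win == max(win), arr.ind = TRUE)[1, ]
    # weak correlation evidence: keep the shape-consistent position
    if (shaped && max(win) < 0.45) next
    p0 <- c(xs[idx[2]], ys[idx[1]])
    p <- lk_align(blurred, templates[[k]]$coarse, p0[1], p0[2])
    p <- lk_align(pixels, templates[[k]]$fine, p[1], p[2])
    # guard against divergence of the alignment
    if (sqrt(sum((p - p0)^2)) <= 16) {
      lms$x[k] <- p[1]; lms$y[k] <- p[2]
    } else {
      lms$x[k] <- p0[1]; lms$y[k] <- p0[2]
    }
  }
  lms
}

#' Training configuration for landmark models
#'
#' @param epochs gradient-descent epochs.
#' @param lr learning rate.
#' @param seed integer seed (augmentation draws).
#' @param sigma Gaussian target sigma in crop pixels (at 256 x 256).
#' @param augment number of augmented copies per training crop.
#' @param rotate_max,scale_range augmentation ranges (degrees; scale
#'   factors).
#' @return list of class `lm_config`.
#' @export
lm_config <- function(epochs = 30, lr = 0.1, seed = 0L, sigma = 4,
                      augment = 1L, rotate_max = 10, scale_range = c(0.9, 1.1)) {
  structure(list(epochs = epochs, lr = lr, seed = as.integer(seed),
                 sigma = sigma, augment = as.integer(augment),
                 rotate_max = rotate_max, scale_range = scale_range),
            class = "lm_config")
}

# Gaussian heatmap targets on the 128 grid for crop-frame (256) landmarks;
# returns (HEAT_DIM^2) x K matrix. Missing landmarks get all-zero channels.
heatmap_targets <- function(xy256, sigma256) {
  g <- pixel_grid(c(HEAT_DIM, HEAT_DIM))
  s <- sigma256 / 2
  K <- nrow(xy256)
  Y <- matrix(0, HEAT_DIM * HEAT_DIM, K)
  for (k in seq_len(K)) {
    if (any(is.na(xy256[k, ]))) next
    mx <- xy256[k, 1] / 2; my <- xy256[k, 2] / 2
    Y[, k] <- c(exp(-((g$x - mx)^2 + (g$y - my)^2) / (2 * s^2)))
  }
  Y
}

# rotate/scale a prepared crop about its centre; returns new pixels and the
# co-transformed landmark coordinates (both 256 frame)
augment_crop <- function(pixels, xy256, angle_deg, scale) {
  ctr <- (CROP_DIM - 1) / 2
  A <- rot2(angle_deg) * scale            # output -> input mapping
  b <- c(ctr, ctr) - A %*% c(ctr, ctr)
  px <- warp_bilinear(pixels, A, as.vector(b), c(CROP_DIM, CROP_DIM))
  Ainv <- solve(A)
  xy <- t(Ainv %*% (t(xy256) - as.vector(b)))
  list(pixels = px, xy = xy)
}

#' Train a landmark heatmap model for one region
#'
#' @param region region kind (see [landmark_schema()]).
#' @param crops list of prepared 256 x 256 `region_crop`s (see
#'   [prepare_model_input()]).
#' @param landmark_sets list (parallel to `crops`) of crop-frame
#'   [landmark_set()]s matching the region schema.
#' @param config a [lm_config()].
#' @return object of class `landmark_model`.
#' @export
train_landmark_model <- function(region, crops, landmark_sets,
                                 config = lm_config()) {
  region <- match.arg(region, REGIONS)
  if (length(crops) == 0) stop("empty training set", call. = FALSE)
  stopifnot(length(crops) == length(landmark_sets))
  schema <- landmark_schema(region)
  for (ls in landmark_sets) {
    if (!identical(lm_region(ls), region) || nrow(ls) != nrow(schema)) {
      stop(sprintf("landmark sets must match the %s schema (%d landmarks)",
                   region, nrow(schema)), call. = FALSE)
    }
  }
  set.seed(config$seed)
  K <- nrow(schema)

  samples <- list()
  for (i in seq_along(crops)) {
    px <- if (inherits(crops[[i]], "region_crop")) crops[[i]]$pixels else crops[[i]]
    stopifnot(all(dim(px) == CROP_DIM))
    xy <- cbind(landmark_sets[[i]]$x, landmark_sets[[i]]$y)
    samples[[length(samples) + 1L]] <- list(pixels = px, xy = xy)
    for (a in seq_len(config$augment)) {
      ang <- stats::runif(1, -config$rotate_max, config$rotate_max)
      sc <- stats::runif(1, config$scale_range[1], config$scale_range[2])
      samples[[length(samples) + 1L]] <- augment_crop(px, xy, ang, sc)
    }
  }

  # first pass: global feature moments for standardization
  F <- ncol(lm_features(matrix(0.5, CROP_DIM, CROP_DIM)))
  xsum <- numeric(F); xsq <- numeric(F); n <- 0
  feats <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    X <- lm_features(samples[[i]]$pixels)
    feats[[i]] <- X
    xsum <- xsum + colSums(X)
    xsq <- xsq + colSums(X^2)
    n <- n + nrow(X)
  }
  mu <- xsum / n
  sdv <- sqrt(pmax(xsq / n - mu^2, 1e-12)); sdv[sdv < 1e-6] <- 1

  # second pass: per-sample normal-equation blocks of the standardized
  # design (bias column included); one epoch = one shuffled pass with a
  # momentum-SGD step per sample, so epochs are cheap and deterministic
  m <- length(samples)
  Hs <- vector("list", m); Gs <- vector("list", m); ssy <- numeric(m)
  for (i in seq_len(m)) {
    X <- cbind(1, sweep(sweep(feats[[i]], 2, mu, "-"), 2, sdv, "/"))
    Y <- heatmap_targets(samples[[i]]$xy, config$sigma)
    ni <- nrow(X)
    Hs[[i]] <- crossprod(X) / ni
    Gs[[i]] <- crossprod(X, Y) / ni
    ssy[i] <- sum(Y^2) / ni
    feats[[i]] <- NA  # release
  }
  H_full <- Reduce(`+`, Hs) / m
  G_full <- Reduce(`+`, Gs) / m
  ssy_full <- sum(ssy) / m

  W <- matrix(0, F + 1L, K)
  V <- W
  loss_hist <- numeric(config$epochs)
  loss_of <- function(W) {
    (ssy_full - 2 * sum(W * G_full) + sum(W * (H_full %*% W))) / K
  }
  loss_start <- loss_of(W)
  for (e in seq_len(config$epochs)) {
    for (i in sample.int(m)) {
      grad <- Hs[[i]] %*% W - Gs[[i]]
      V <- 0.9 * V - config$lr * grad
      W <- W + V
    }
    loss_hist[e] <- loss_of(W)
  }

  # subpixel refinement templates and the mean landmark configuration,
  # both from the (un-augmented) training crops
  xy_list <- lapply(landmark_sets, function(ls) cbind(ls$x, ls$y))
  pix_list <- lapply(crops, function(cr) {
    if (inherits(cr, "region_crop")) cr$pixels else cr
  })
  crop_sizes <- lapply(crops, function(cr) {
    if (inherits(cr, "region_crop")) cr$transform$crop_size else dim(cr)
  })
  templates <- learn_templates(pix_list, xy_list, K)
  head_disc <- learn_head_disc(pix_list, xy_list, crop_sizes, schema)
  line_pairs <- learn_line_pairs(pix_list, xy_list, crop_sizes, schema)
  # two-landmark regions: learn the mean offset vector between the pair at
  # original pitch, used as a geometric consistency guard at inference
  pair_vec <- NULL
  if (K == 2L) {
    vs <- matrix(NA_real_, length(pix_list), 2)
    for (i in seq_along(pix_list)) {
      ov <- orig_view(pix_list[[i]], crop_sizes[[i]])
      xy <- to_orig(xy_list[[i]], ov)
      vs[i, ] <- xy[2, ] - xy[1, ]
    }
    pair_vec <- colMeans(vs, na.rm = TRUE)
  }
  mean_shape <- Reduce(`+`, xy_list) / length(xy_list)

  # per-landmark check of the refinement stage on its own training crops:
  # landmarks whose local appearance cannot pin them down (e.g. points on a
  # self-similar edge, where template alignment slides) keep their
  # shape-model position at inference instead
  refine_ok <- rep(TRUE, K)
  if (length(pix_list) >= 5) {
    self_err <- matrix(NA_real_, length(pix_list), K)
    for (i in seq_along(pix_list)) {
      blurred <- gauss_blur(pix_list[[i]], TPL_COARSE_SIGMA)
      for (k in seq_len(K)) {
        if (is.null(templates[[k]]) || any(is.na(xy_list[[i]][k, ]))) next
        p <- lk_align(blurred, templates[[k]]$coarse,
                      xy_list[[i]][k, 1], xy_list[[i]][k, 2])
        p <- lk_align(pix_list[[i]], templates[[k]]$fine, p[1], p[2])
        self_err[i, k] <- sqrt(sum((p - xy_list[[i]][k, ])^2))
      }
    }
    med <- apply(self_err, 2, stats::median, na.rm = TRUE)
    refine_ok <- is.finite(med) & med <= 4
    # head-contour points feed a circle fit: alignment can only slide them
    # along the circle (tangentially), which the fit is insensitive to, so
    # refinement always helps their radial accuracy
    refine_ok[schema$role == "head_contour"] <- TRUE
  }
  shape_sd <- sqrt(Reduce(`+`, lapply(xy_list, function(xy) (xy - mean_shape)^2)) /
                     max(1, length(xy_list) - 1))

  structure(list(
    region = region, schema = schema, W = W,
    feat_mean = mu, feat_sd = sdv, config = config,
    templates = templates, mean_shape = mean_shape, shape_sd = shape_sd,
    refine_ok = refine_ok, head_disc = head_disc, line_pairs = line_pairs,
    pair_vec = pair_vec,
    loss_initial = loss_start, loss_history = loss_hist, n_train = length(crops),
    n_samples = length(samples)
  ), class = "landmark_model")
}

#' @export
print.landmark_model <- function(x, ...) {
  cat(sprintf(paste0("<landmark_model> region=%s (%d landmarks), %d crops ",
                     "(%d with augmentation), %d epochs, final loss %.5f\n"),
              x$region, nrow(x$schema), x$n_train, x$n_samples,
              length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Decode landmark heatmaps to coordinates
#'
#' Per landmark: location = argmax refined by separable parabolic
#' interpolation over the 3 x 3 neighbourhood; confidence = channel peak /
#' global maximum over all
#' channels. Channels whose confidence falls below `peak_threshold` (or
#' that are non-positive everywhere) are flagged missing (`NA`
#' coordinates).
#'
#' @param heatmaps H x W x K array (one channel per schema entry).
#' @param region region kind, fixing the schema.
#' @param peak_threshold confidence threshold below which a landmark is
#'   missing.
#' @param scale factor mapping heatmap coordinates to crop coordinates
#'   (2 for 128 -> 256).
#' @return crop-frame [landmark_set()].
#' @export
decode_heatmaps <- function(heatmaps, region, peak_threshold = 0.2, scale = 1) {
  schema <- landmark_schema(region)
  K <- nrow(schema)
  if (length(dim(heatmaps)) != 3 || dim(heatmaps)[3] != K) {
    stop(sprintf("expected %d heatmap channels for region %s", K, region),
         call. = FALSE)
  }
  gmax <- max(heatmaps)
  res <- data.frame(name = schema$name, role = schema$role,
                    x = NA_real_, y = NA_real_, confidence = 0)
  h <- dim(heatmaps)[1]; w <- dim(heatmaps)[2]
  for (k in seq_len(K)) {
    hm <- heatmaps[, , k]
    pk <- max(hm)
    conf <- if (gmax > 0) pk / gmax else 0
    if (pk <= 0 || conf < peak_threshold) next
    idx <- which(hm == pk, arr.ind = TRUE)[1, ]
    r <- idx[1]; c <- idx[2]
    # sub-pixel refinement over the 3 x 3 neighbourhood: separable parabolic
    # interpolation through the argmax along each axis (exact for symmetric
    # peaks; a plain centre of mass over a window centred on the integer
    # argmax is biased by the window asymmetry)
    para <- function(wm, w0, wp) {
      den <- wm - 2 * w0 + wp
      if (den >= -1e-12) 0 else clamp(0.5 * (wm - wp) / den, -0.5, 0.5)
    }
    dx <- if (c > 1 && c < w) para(hm[r, c - 1], pk, hm[r, c + 1]) else 0
    dy <- if (r > 1 && r < h) para(hm[r - 1, c], pk, hm[r + 1, c]) else 0
    cx <- (c - 1) + dx
    cy <- (r - 1) + dy
    res$x[k] <- cx * scale
    res$y[k] <- cy * scale
    res$confidence[k] <- conf
  }
  landmark_set(region, res, frame = "crop")
}

# forward pass: heatmaps of a prepared crop under a landmark model
landmark_heatmaps <- function(model, pixels) {
  X <- lm_features(pixels)
  Xs <- cbind(1, sweep(sweep(X, 2, model$feat_mean, "-"), 2, model$feat_sd, "/"))
  H <- Xs %*% model$W
  array(H, c(HEAT_DIM, HEAT_DIM, ncol(H)))
}

#' Detect landmarks on a prepared crop
#'
#' Forward pass of the region's heatmap model followed by
#' [decode_heatmaps()]. The caller chooses the knee model (native vs TKA)
#' by the presence of implant labels in the leg group; [run_measure()] does
#' this automatically.
#'
#' @param crop a prepared `region_crop`.
#' @param model a `landmark_model` whose region matches the crop.
#' @param peak_threshold see [decode_heatmaps()].
#' @param refine apply the template-based subpixel refinement stage
#'   (correlation search + two-scale Lucas-Kanade alignment against the
#'   mean appearance templates learned at training).
#' @return crop-frame [landmark_set()].
#' @export
detect_landmarks <- function(crop, model, peak_threshold = 0.2,
                             refine = TRUE) {
  stopifnot(inherits(crop, "region_crop"), inherits(model, "landmark_model"))
  if (!identical(crop$region, model$region)) {
    stop(sprintf("crop region '%s' does not match model region '%s'",
                 crop$region, model$region), call. = FALSE)
  }
  hm <- landmark_heatmaps(model, crop$pixels)
  if (!is.null(model$mean_shape)) {
    hm <- apply_position_prior(hm, model$mean_shape, model$shape_sd)
  }
  lms <- decode_heatmaps(hm, model$region, peak_threshold, scale = 2)
  if (refine && !is.null(model$templates)) {
    lms <- refine_landmarks(lms, crop$pixels, model$templates,
                            model$mean_shape, refine_ok = model$refine_ok)
    cs <- crop$transform$crop_size
    lms <- refine_pair_guard(lms, crop$pixels, cs, model)
    lms <- refine_line_pairs(lms, crop$pixels, cs, model$line_pairs)
    lms <- refine_head_disc(lms, crop$pixels, cs, model$head_disc)
    # final consistency pass: a refined landmark that ended up grossly
    # inconsistent with the configuration of all the others (e.g. locked
    # onto a similar-looking neighbouring corner) is pulled back to its
    # shape-predicted position, and the affected joint lines re-snapped
    if (!is.null(model$mean_shape) && nrow(model$mean_shape) >= 4) {
      before <- cbind(lms$x, lms$y)
      lms <- shape_regularize(lms, model$mean_shape)
      moved <- !is.na(before[, 1]) &
        sqrt(rowSums((cbind(lms$x, lms$y) - before)^2)) > 1e-9
      if (any(moved)) {
        lms <- refine_line_pairs(lms, crop$pixels, cs, model$line_pairs)
      }
    }
  }
  lms
}

#' Ground-truth landmark oracle
#'
#' Maps the true image-frame landmarks of a phantom leg through a crop
#' transform into the crop frame, with confidence 1.
#'
#' @param gt a `leg_ground_truth`.
#' @param region region kind present in the ground truth.
#' @param transform the crop transform to map through.
#' @return crop-frame [landmark_set()].
#' @export
oracle_landmarks <- function(gt, region, transform) {
  lms <- gt$landmarks[[region]]
  if (is.null(lms)) {
    stop(sprintf("ground truth has no landmarks for region '%s'", region),
         call. = FALSE)
  }
  xy <- transform_image_to_crop(cbind(lms$x, lms$y), transform)
  out <- lms
  out$x <- xy[, 1]; out$y <- xy[, 2]
  out$confidence <- 1
  attr(out, "frame") <- "crop"
  out
}

# multiply heatmaps by a per-landmark Gaussian positional prior from the
# training distribution (mean +/- spread, crop frame); the crops are
# side-canonicalized, so the prior is tight and suppresses confusions
# between similar-looking landmarks (e.g. the mirrored contralateral
# corner) without affecting sub-pixel decoding
apply_position_prior <- function(heatmaps, mean_shape, shape_sd) {
  g <- pixel_grid(dim(heatmaps)[1:2])
  for (k in seq_len(dim(heatmaps)[3])) {
    sx <- max(2 * shape_sd[k, 1], 12) / 2  # 256 -> 128 scale
    sy <- max(2 * shape_sd[k, 2], 12) / 2
    mx <- mean_shape[k, 1] / 2; my <- mean_shape[k, 2] / 2
    pr <- exp(-((g$x - mx)^2 / (2 * sx^2) + (g$y - my)^2 / (2 * sy^2)))
    heatmaps[, , k] <- heatmaps[, , k] * pr
  }
  heatmaps
}

# geometric consistency guard for two-landmark regions: when the detected
# pair's offset vector deviates grossly from the learned one, the detection
# that matches its appearance template worse is re-anchored on the other
# one and re-aligned locally
refine_pair_guard <- function(lms, pixels, crop_size, model, tol = 6) {
  if (is.null(model$pair_vec) || nrow(lms) != 2 || any(is.na(lms$x))) return(lms)
  ov <- orig_view(pixels, crop_size)
  xy <- to_orig(cbind(lms$x, lms$y), ov)
  if (vnorm((xy[2, ] - xy[1, ]) - model$pair_vec) <= tol) return(lms)
  tpl_score <- function(k, p_orig) {
    pc <- to_crop(rbind(p_orig), ov)[1, ]
    P <- sample_patch(pixels, pc[1], pc[2], TPL_HALF)
    t0 <- model$templates[[k]]$fine
    sum(P * t0) / max(sqrt(sum(P^2) * sum(t0^2)), 1e-9)
  }
  # candidate A: trust point 1; candidate B: trust point 2
  candA <- rbind(xy[1, ], xy[1, ] + model$pair_vec)
  candB <- rbind(xy[2, ] - model$pair_vec, xy[2, ])
  scA <- tpl_score(1, candA[1, ]) + tpl_score(2, candA[2, ])
  scB <- tpl_score(1, candB[1, ]) + tpl_score(2, candB[2, ])
  cand <- if (scA >= scB) candA else candB
  fix <- if (scA >= scB) 2L else 1L
  pc <- to_crop(rbind(cand[fix, ]), ov)[1, ]
  p <- lk_align(gauss_blur(pixels, TPL_COARSE_SIGMA),
                model$templates[[fix]]$coarse, pc[1], pc[2])
  p <- lk_align(pixels, model$templates[[fix]]$fine, p[1], p[2])
  if (vnorm(p - pc) > 16) p <- pc
  lms$x[fix] <- p[1]; lms$y[fix] <- p[2]
  lms
}
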