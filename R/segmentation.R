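# Instance segmentation of bones and implant components.
#
# The trainable operator is deliberately small: a fixed multi-scale
# convolutional feature encoder followed by a trained per-pixel multinomial
# logistic head, with connected-component instancing, score thresholding
# and per-label non-maximum suppression. It trains on a CPU in minutes and
# satisfies the stage contract (labeled instance masks with boxes and
# scores); a ground-truth oracle (oracle_segment) isolates the downstream
# stages from the learned one.

new_segmentation_result <- function(label, mask, score) {
  structure(list(label = label, mask = mask, box = mask_box(mask),
                 score = score),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s score=%.2f box=[%g,%g)x[%g,%g) area=%d\n",
              x$label, x$score, x$box["x0"], x$box["x1"], x$box["y0"],
              x$box["y1"], sum(x$mask)))
  invisible(x)
}

#' Training configuration for the segmenter
#'
#' @param epochs gradient-descent epochs.
#' @param lr learning rate.
#' @param seed integer seed driving flip-augmentation choice and any
#'   stochastic part of training.
#' @param subsample keep every `subsample`-th pixel (per axis, after the
#'   2x downscale) when assembling the training matrix.
#' @return list of class `seg_config`.
#' @export
seg_config <- function(epochs = 30, lr = 0.3, seed = 0L, subsample = 2L) {
  structure(list(epochs = epochs, lr = lr, seed = as.integer(seed),
                 subsample = as.integer(subsample)), class = "seg_config")
}

# integer label map (0 = background) from a named list of logical masks;
# implant labels take precedence over bone where they overlap
label_map <- function(masks, dim) {
  lab <- matrix(0L, dim[1], dim[2])
  for (nm in names(masks)) {
    k <- match(nm, SEG_LABELS)
    if (is.na(k)) {
      stop(sprintf("unknown structure label '%s' (vocabulary: %s)", nm,
                   paste(SEG_LABELS, collapse = ", ")), call. = FALSE)
    }
  }
  for (nm in intersect(BONE_LABELS, names(masks))) {
    lab[masks[[nm]]] <- match(nm, SEG_LABELS)
  }
  for (nm in intersect(c("implant_femoral", "implant_tibial"), names(masks))) {
    lab[masks[[nm]]] <- match(nm, SEG_LABELS)
  }
  lab
}

#' Train the instance segmenter
#'
#' Trains the per-pixel multinomial logistic head on normalized images with
#' per-structure ground-truth masks. Horizontal flipping is applied to half
#' of the training set (exactly `floor(n/2)` images, chosen by the seed)
#' so the model is insensitive to the leg side; the feature encoder is
#' additionally flip-equivariant by construction. Training is full-batch
#' gradient descent with momentum on class-balanced cross-entropy; the
#' per-epoch loss history is stored on the model.
#'
#' @param images list of normalized \[0, 1\] image matrices (>= 2).
#' @param masks list (parallel to `images`) of named lists of logical
#'   structure masks; names from the vocabulary femur, tibia, fibula,
#'   talus, implant_femoral, implant_tibial.
#' @param config a [seg_config()].
#' @return object of class `segmenter_model` (serializable with
#'   [save_model()]).
#' @export
train_segmenter <- function(images, masks, config = seg_config()) {
  if (length(images) < 2) stop("need at least 2 annotated images", call. = FALSE)
  stopifnot(length(images) == length(masks))
  n <- length(images)
  set.seed(config$seed)
  n_flip <- n %/% 2L
  flip_idx <- sort(sample.int(n, n_flip))

  Xs <- vector("list", n); ys <- vector("list", n)
  for (i in seq_len(n)) {
    img <- images[[i]]
    lab <- label_map(masks[[i]], dim(img))
    if (i %in% flip_idx) {
      img <- flip_h(img)
      lab <- flip_h(lab)
    }
    img_ds <- block_mean_ds2(img)
    lab_ds <- lab[seq(1, nrow(lab), 2), seq(1, ncol(lab), 2)]
    # align dims with the (edge-padded) block mean
    lab_ds <- lab_ds[seq_len(nrow(img_ds)), seq_len(ncol(img_ds))]
    X <- seg_features(img_ds)
    ss <- config$subsample
    keep_r <- seq(1, nrow(img_ds), ss); keep_c <- seq(1, ncol(img_ds), ss)
    keep <- as.vector(outer(keep_r, (keep_c - 1) * nrow(img_ds), "+"))
    Xs[[i]] <- X[keep, , drop = FALSE]
    ys[[i]] <- c(lab_ds)[keep]
  }
  st <- standardize_fit(do.call(rbind, Xs))
  K <- length(SEG_LABELS) + 1L
  counts <- pmax(tabulate(unlist(ys) + 1L, nbins = K), 1)
  wclass <- sum(counts) / (K * counts)
  batches <- lapply(seq_len(n), function(i) {
    X <- cbind(1, standardize_apply(Xs[[i]], st))
    y <- ys[[i]]
    Y <- matrix(0, nrow(X), K)
    Y[cbind(seq_along(y), y + 1L)] <- 1
    wrow <- wclass[y + 1L]
    list(X = X, Y = Y, yi = y + 1L, w = wrow, wsum = sum(wrow))
  })

  batch_probs <- function(b, W) {
    Z <- b$X %*% W
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z)
    P / rowSums(P)
  }
  full_loss <- function(W) {
    num <- 0; den <- 0
    for (b in batches) {
      P <- batch_probs(b, W)
      num <- num - sum(b$w * log(pmax(P[cbind(seq_along(b$yi), b$yi)], 1e-12)))
      den <- den + b$wsum
    }
    num / den
  }

  # one epoch = one shuffled pass over the images with a momentum-SGD
  # update per image
  W <- matrix(0, ncol(batches[[1]]$X), K)
  V <- W
  loss_hist <- numeric(config$epochs)
  loss_start <- full_loss(W)
  for (e in seq_len(config$epochs)) {
    for (i in sample.int(n)) {
      b <- batches[[i]]
      P <- batch_probs(b, W)
      G <- crossprod(b$X, (P - b$Y) * b$w) / b$wsum
      V <- 0.9 * V - config$lr * G
      W <- W + V
    }
    loss_hist[e] <- full_loss(W)
  }

  structure(list(
    W = W, standardizer = st, labels = SEG_LABELS, config = config,
    loss_initial = loss_start, loss_history = loss_hist,
    n_flipped = n_flip, flip_idx = flip_idx,
    n_train = n, min_area = 150
  ), class = "segmenter_model")
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf(paste0("<segmenter_model> %d training images (%d flipped), ",
                     "%d epochs, final loss %.4f\n"),
              x$n_train, x$n_flipped, length(x$loss_history),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

# per-pixel class probabilities of a normalized image, at the 2x-downscaled
# grid; returns list(probs = array ds_h x ds_w x K, dim_ds)
segmenter_probs <- function(model, pixels) {
  img_ds <- block_mean_ds2(pixels)
  X <- cbind(1, standardize_apply(seg_features(img_ds), model$standardizer))
  Z <- X %*% model$W
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z); P <- P / rowSums(P)
  K <- ncol(P)
  arr <- array(P, c(nrow(img_ds), ncol(img_ds), K))
  # light spatial smoothing of the probability maps (flip-equivariant)
  for (k in seq_len(K)) arr[, , k] <- gauss_blur(arr[, , k], 1)
  arr
}

#' Segment a radiograph
#'
#' Runs the trained per-pixel classifier, forms instances by connected
#' components of the per-label argmax map, drops low-score and small
#' instances, and applies per-label non-maximum suppression keeping at most
#' two instances per bone label (bilateral images). An empty list is a
#' valid outcome and feeds the detection-rate accounting.
#'
#' @param rg a [radiograph()] or a normalized pixel matrix.
#' @param model a `segmenter_model`.
#' @param score_threshold instances below this mean probability are dropped.
#' @param nms_iou mask-IoU above which the lower-scoring same-label
#'   instance is suppressed.
#' @return list of `segmentation_result`.
#' @export
segment <- function(rg, model, score_threshold = 0.5, nms_iou = 0.5) {
  pixels <- if (inherits(rg, "radiograph")) normalized_pixels(rg) else rg
  h <- nrow(pixels); w <- ncol(pixels)
  probs <- segmenter_probs(model, pixels)

  # pool the two implant channels for the argmax: the components are
  # distinguished afterwards by their proximal/distal order, which is far
  # more reliable than a per-pixel y-feature decision
  n_bone <- length(BONE_LABELS)
  pool <- array(0, c(dim(probs)[1:2], n_bone + 2L))
  pool[, , seq_len(n_bone + 1L)] <- probs[, , seq_len(n_bone + 1L)]
  pool[, , n_bone + 2L] <- probs[, , n_bone + 2L] + probs[, , n_bone + 3L]
  Kp <- dim(pool)[3]
  cls <- matrix(max.col(matrix(pool, ncol = Kp), ties.method = "first") - 1L,
                dim(pool)[1], dim(pool)[2])

  instances <- function(k) {
    sel <- cls == k
    if (!any(sel)) return(list())
    comp <- connected_components(sel)
    pk <- pool[, , k + 1L]
    res <- list()
    for (ci in seq_len(max(comp))) {
      cmask <- comp == ci
      if (sum(cmask) * 4 < model$min_area) next
      score <- mean(pk[cmask])
      if (score < score_threshold) next
      res[[length(res) + 1L]] <- list(mask = cmask, score = score)
    }
    # drop slivers: components much smaller than the largest same-label one
    if (length(res) > 1) {
      areas <- vapply(res, function(r) sum(r$mask), numeric(1))
      res <- res[areas >= 0.25 * max(areas)]
    }
    res
  }
  to_full <- function(cmask) upscale_nn(cmask, 2L)[seq_len(h), seq_len(w), drop = FALSE]

  out <- list()
  for (k in seq_len(n_bone)) {
    for (inst in instances(k)) {
      full <- to_full(inst$mask)
      if (!any(full)) next
      out[[length(out) + 1L]] <- new_segmentation_result(BONE_LABELS[k], full,
                                                         inst$score)
    }
  }

  # implant components: per x-cluster, proximal = femoral, distal = tibial
  imp <- instances(n_bone + 1L)
  if (length(imp) > 0) {
    cx <- vapply(imp, function(r) mean(which(r$mask, arr.ind = TRUE)[, 2]), 0)
    cy <- vapply(imp, function(r) mean(which(r$mask, arr.ind = TRUE)[, 1]), 0)
    grp <- cumsum(c(1, diff(sort(cx)) > ncol(cls) / 4))[order(order(cx))]
    for (g in unique(grp)) {
      idx <- which(grp == g)
      idx <- idx[order(cy[idx])]
      if (length(idx) >= 2) {
        out[[length(out) + 1L]] <- new_segmentation_result(
          "implant_femoral", to_full(imp[[idx[1]]]$mask), imp[[idx[1]]]$score)
        out[[length(out) + 1L]] <- new_segmentation_result(
          "implant_tibial", to_full(imp[[idx[2]]]$mask), imp[[idx[2]]]$score)
      } else {
        parts <- split_implant_component(imp[[idx[1]]]$mask)
        if (is.null(parts)) {
          # single unsplittable component: label by channel evidence
          pf <- mean(probs[, , n_bone + 2L][imp[[idx[1]]]$mask])
          pt <- mean(probs[, , n_bone + 3L][imp[[idx[1]]]$mask])
          lab <- if (pf >= pt) "implant_femoral" else "implant_tibial"
          out[[length(out) + 1L]] <- new_segmentation_result(
            lab, to_full(imp[[idx[1]]]$mask), imp[[idx[1]]]$score)
        } else {
          out[[length(out) + 1L]] <- new_segmentation_result(
            "implant_femoral", to_full(parts$proximal), imp[[idx[1]]]$score)
          out[[length(out) + 1L]] <- new_segmentation_result(
            "implant_tibial", to_full(parts$distal), imp[[idx[1]]]$score)
        }
      }
    }
  }

  # per-label NMS keeping at most 2 instances per label (bilateral case); a
  # second same-label instance must belong to the other leg, i.e. be
  # horizontally distant -- nearby fragments (misclassified neighbouring
  # structure parts) are suppressed in favour of the higher-scoring instance
  keep <- rep(TRUE, length(out))
  labs <- vapply(out, `[[`, "", "label")
  for (lab in unique(labs)) {
    idx <- which(labs == lab)
    idx <- idx[order(vapply(out[idx], `[[`, 0, "score"), decreasing = TRUE)]
    taken <- list()
    for (i in idx) {
      xc <- box_center(out[[i]]$box)[1]
      ok <- length(taken) < 2 &&
        !any(vapply(taken, function(t) {
          mask_iou(t$mask, out[[i]]$mask) > nms_iou ||
            abs(t$xc - xc) < w / 4
        }, logical(1)))
      if (ok) {
        taken <- c(taken, list(list(mask = out[[i]]$mask, xc = xc)))
      } else {
        keep[i] <- FALSE
      }
    }
  }
  out[keep]
}

# split a bridged femoral+tibial implant component at its waist row;
# returns NULL when no clear waist exists
split_implant_component <- function(cmask) {
  rows <- which(rowSums(cmask) > 0)
  if (length(rows) < 10) return(NULL)
  widths <- rowSums(cmask)[rows]
  mid <- rows[rows > stats::quantile(rows, 0.2) & rows < stats::quantile(rows, 0.8)]
  if (length(mid) == 0) return(NULL)
  wmid <- rowSums(cmask)[mid]
  cut <- mid[which.min(wmid)]
  if (min(wmid) > 0.6 * max(widths)) return(NULL)
  prox <- cmask; prox[cut:nrow(cmask), ] <- FALSE
  dist <- cmask; dist[1:(cut - 1), ] <- FALSE
  if (!any(prox) || !any(dist)) return(NULL)
  list(proximal = prox, distal = dist)
}

#' Ground-truth segmentation oracle
#'
#' Converts phantom ground truth into segmentation results (score 1,
#' tight boxes), so the cropping, landmark and geometry stages can be
#' exercised independently of the learned segmenter.
#'
#' @param gt a `leg_ground_truth` or a `leg_phantom` (all legs are
#'   converted).
#' @return list of `segmentation_result`.
#' @export
oracle_segment <- function(gt) {
  legs <- if (inherits(gt, "leg_phantom")) gt$legs else list(gt)
  out <- list()
  for (leg in legs) {
    for (nm in names(leg$masks)) {
      out[[length(out) + 1L]] <- new_segmentation_result(nm, leg$masks[[nm]], 1.0)
    }
  }
  out
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint containing config, weights and the label
#' vocabulary (the model object itself).
#'
#' @param model a `segmenter_model` or `landmark_model`.
#' @param path checkpoint path.
#' @return `path` (save) or the model object (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
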