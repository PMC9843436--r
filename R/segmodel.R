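# ---- local image statistics (integral-image box filters) --------------------

# summed-area table with a zero border row/column
sat <- function(m) {
  h <- nrow(m); w <- ncol(m)
  S <- matrix(0, h + 1, w + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  S
}

# mean over a (2r+1)^2 window, clipped at the borders (normalized by the
# actual window size)
box_mean <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  S <- sat(m)
  r0 <- pmax(seq_len(h) - r, 1L); r1 <- pmin(seq_len(h) + r, h)
  c0 <- pmax(seq_len(w) - r, 1L); c1 <- pmin(seq_len(w) + r, w)
  s <- S[r1 + 1L, c1 + 1L, drop = FALSE] - S[r0, c1 + 1L, drop = FALSE] -
    S[r1 + 1L, c0, drop = FALSE] + S[r0, c0, drop = FALSE]
  s / outer(r1 - r0 + 1L, c1 - c0 + 1L)
}

box_sd <- function(m, r) {
  v <- box_mean(m * m, r) - box_mean(m, r)^2
  sqrt(pmax(v, 0))
}

# central-difference gradients (zero at borders)
grad_xy <- function(g) {
  h <- nrow(g); w <- ncol(g)
  gy <- matrix(0, h, w); gx <- matrix(0, h, w)
  if (h > 2) gy[2:(h - 1), ] <- (g[3:h, ] - g[1:(h - 2), ]) / 2
  if (w > 2) gx[, 2:(w - 1)] <- (g[, 3:w] - g[, 1:(w - 2)]) / 2
  list(gx = gx, gy = gy)
}

#' Per-pixel texture features
#'
#' The hand-crafted local statistics on which the desk-scale segmenter
#' operates: luminance and RGB channels, multi-scale box means and standard
#' deviations, a dark-blob (center-surround) response, gradient energy, and
#' structure-tensor orientation coherence. All features are locally
#' computable, matching the statistics planted by the synthetic texture
#' generator.
#'
#' @param pixels h x w x 3 array (0-255).
#' @return h x w x F numeric array of features.
#' @export
pixel_features <- function(pixels) {
  g <- rgb_to_gray(pixels) / 255
  r <- pixels[, , 1] / 255; gg <- pixels[, , 2] / 255; b <- pixels[, , 3] / 255
  m3 <- box_mean(g, 3)
  gr <- grad_xy(g)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  jxx <- box_mean(gr$gx^2, 3); jyy <- box_mean(gr$gy^2, 3)
  jxy <- box_mean(gr$gx * gr$gy, 3)
  coher <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / (jxx + jyy + 1e-8)
  feats <- list(
    gray = g, red = r, green = gg, blue = b,
    mean5 = box_mean(g, 2), sd3 = box_sd(g, 1), sd5 = box_sd(g, 2),
    sd11 = box_sd(g, 5), blob = g - m3, grad = box_mean(mag, 3),
    coherence = coher, mean15 = box_mean(g, 7)
  )
  array(unlist(feats), dim = c(nrow(g), ncol(g), length(feats)),
        dimnames = list(NULL, NULL, names(feats)))
}

# ---- loss: weighted categorical cross-entropy + Lovasz-Softmax --------------

# gradient of the Lovasz extension of the Jaccard loss, given the
# ground-truth indicator vector sorted by decreasing error
lovasz_grad <- function(gt_sorted) {
  p <- length(gt_sorted)
  gts <- sum(gt_sorted)
  intersection <- gts - cumsum(gt_sorted)
  union <- gts + cumsum(1 - gt_sorted)
  jaccard <- 1 - intersection / union
  if (p > 1) jaccard[2:p] <- jaccard[2:p] - jaccard[1:(p - 1)]
  jaccard
}

#' Lovasz-Softmax loss
#'
#' Surrogate for the per-class Jaccard (IoU) loss: for each class present
#' in the labels, the per-pixel errors (1 - p for pixels of the class, p
#' otherwise) are sorted in decreasing order and combined with the gradient
#' of the Lovasz extension of the Jaccard set function; the class losses
#' are averaged.
#'
#' @param prob N x K probability matrix (rows sum to 1).
#' @param labels integer class indices (1..K), length N.
#' @param return_grad also return the gradient with respect to the
#'   probabilities (N x K), used by the trainer.
#' @return scalar loss, or list(loss, grad).
#' @export
lovasz_softmax_loss <- function(prob, labels, return_grad = FALSE) {
  K <- ncol(prob)
  present <- sort(unique(labels))
  losses <- numeric(0)
  grad <- if (return_grad) matrix(0, nrow(prob), K) else NULL
  for (c in present) {
    fg <- as.numeric(labels == c)
    errors <- abs(fg - prob[, c])
    ord <- order(errors, decreasing = TRUE)
    g <- lovasz_grad(fg[ord])
    losses <- c(losses, sum(errors[ord] * g))
    if (return_grad) {
      d <- numeric(length(fg))
      d[ord] <- g
      # d errors / d p_c = -1 on the class, +1 off the class
      grad[, c] <- grad[, c] + d * ifelse(fg == 1, -1, 1) / length(present)
    }
  }
  loss <- mean(losses)
  if (return_grad) list(loss = loss, grad = grad) else loss
}

#' Weighted cross-entropy plus Lovasz-Softmax loss
#'
#' The segmentation training loss: `sum_c w_c CE_c + lovasz_weight *
#' LovaszSoftmax`, where the weighted cross-entropy term is the mean over
#' pixels of `w_y * (-log p_y)`. Probabilities are clamped at an epsilon
#' before the log.
#'
#' @param prob N x K probability matrix (or h x w x K array).
#' @param labels integer class indices (vector or matrix).
#' @param class_weights positive per-class weights (default all 1).
#' @param lovasz_weight non-negative multiplier of the Lovasz term.
#' @param eps clamp for log.
#' @return scalar loss (non-negative).
#' @export
weighted_ce_plus_lovasz <- function(prob, labels, class_weights = NULL,
                                    lovasz_weight = 0.5, eps = 1e-12) {
  if (length(dim(prob)) == 3) {
    prob <- matrix(prob, ncol = dim(prob)[3])
  }
  labels <- as.integer(labels)
  K <- ncol(prob)
  if (is.null(class_weights)) class_weights <- rep(1, K)
  abort_if(any(class_weights <= 0), "class weights must be positive")
  abort_if(lovasz_weight < 0, "lovasz_weight must be >= 0")
  p_true <- prob[cbind(seq_along(labels), labels)]
  if (any(p_true <= eps)) {
    message("clamping zero probabilities at the true class")
    p_true <- pmax(p_true, eps)
  }
  ce <- mean(class_weights[labels] * (-log(p_true)))
  lov <- if (lovasz_weight > 0) lovasz_softmax_loss(prob, labels) else 0
  ce + lovasz_weight * lov
}

# ---- segmenter: multinomial logistic head over pixel features ---------------

#' Segmentation training configuration
#'
#' @param patch_size training patch edge length (default 384; tests and the
#'   synthetic studies use smaller patches).
#' @param loss_weights per-class cross-entropy weights (`NULL` = equal).
#' @param lovasz_weight multiplier of the Lovasz-Softmax term (default 0.5;
#'   0 reduces the loss to weighted cross-entropy exactly).
#' @param learning_rate gradient-descent step on the softmax head.
#' @param epochs maximum epochs (default 50).
#' @param early_stop_patience epochs without validation-loss improvement
#'   before termination (default 5).
#' @param pixels_per_patch pixels subsampled from each training patch.
#' @param seed integer seed.
#' @return a `SegTrainConfig`.
#' @export
seg_train_config <- function(patch_size = 384, loss_weights = NULL,
                             lovasz_weight = 0.5, learning_rate = 0.5,
                             epochs = 50, early_stop_patience = 5,
                             pixels_per_patch = 300, seed = 1L) {
  abort_if(!is.null(loss_weights) && any(loss_weights <= 0),
           "loss weights must be positive")
  structure(list(patch_size = patch_size, loss_weights = loss_weights,
                 lovasz_weight = lovasz_weight, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 pixels_per_patch = as.integer(pixels_per_patch),
                 seed = as.integer(seed)),
            class = "SegTrainConfig")
}

# flatten (patch, label) pairs into a feature matrix and label vector,
# subsampling pixels per patch
collect_pixel_data <- function(pairs, class_labels, n_per_patch) {
  xs <- list(); ys <- list()
  for (pr in pairs) {
    f <- pixel_features(pr$pixels)
    F <- dim(f)[3]
    X <- matrix(f, ncol = F)
    y <- match_labels(pr$labels, class_labels)
    keep <- sample.int(length(y), min(n_per_patch, length(y)))
    xs[[length(xs) + 1L]] <- X[keep, , drop = FALSE]
    ys[[length(ys) + 1L]] <- y[keep]
  }
  list(X = do.call(rbind, xs), y = unlist(ys))
}

match_labels <- function(labels, class_labels) {
  lab_classes <- attr(labels, "classes")
  if (is.null(lab_classes)) return(as.integer(labels))
  idx <- match(lab_classes, class_labels)
  out <- idx[as.integer(labels)]
  abort_if(anyNA(out), "label map contains classes outside the model vocabulary")
  out
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train the pixel segmenter
#'
#' A multinomial logistic (linear softmax) head over the local texture
#' features of [pixel_features()], optimized by full-batch gradient descent
#' on the weighted cross-entropy plus Lovasz-Softmax loss, with early
#' termination on the validation loss and the best-validation checkpoint
#' returned. Deterministic given `config$seed`.
#'
#' @param train_pairs list of `list(pixels, labels)` with same-size label
#'   crops.
#' @param val_pairs validation pairs (same structure).
#' @param config a [seg_train_config()].
#' @param class_labels class vocabulary of the model (default the classes
#'   present in the training labels, in canonical order).
#' @return a `segmenter` model with the fitted weights, feature
#'   standardization, class order, and a checkpoint digest.
#' @export
train_segmenter <- function(train_pairs, val_pairs, config = seg_train_config(),
                            class_labels = NULL) {
  abort_if(length(train_pairs) == 0, "no training patches")
  for (pr in train_pairs) {
    abort_if(!all(dim(pr$pixels)[1:2] == dim(pr$labels)),
             "training patch and label crop differ in size")
  }
  with_seed(config$seed, {
    if (is.null(class_labels)) {
      present <- unique(unlist(lapply(train_pairs, function(pr) {
        cls <- attr(pr$labels, "classes")
        if (is.null(cls)) unique(as.integer(pr$labels)) else cls[sort(unique(as.integer(pr$labels)))]
      })))
      class_labels <- intersect(class_order(), present)
      if (length(class_labels) == 0) class_labels <- sort(present)
    }
    K <- length(class_labels)
    tr <- collect_pixel_data(train_pairs, class_labels, config$pixels_per_patch)
    va <- collect_pixel_data(val_pairs, class_labels, config$pixels_per_patch)
    seen <- sort(unique(tr$y))
    if (length(seen) < K) {
      warning(sprintf("classes absent from training labels: %s (their loss weights are idle)",
                      paste(class_labels[setdiff(seq_len(K), seen)], collapse = ", ")))
    }
    w_c <- config$loss_weights
    if (is.null(w_c)) w_c <- rep(1, K)
    mu <- colMeans(tr$X)
    sdv <- pmax(apply(tr$X, 2, stats::sd), 1e-8)
    Xtr <- cbind(1, sweep(sweep(tr$X, 2, mu), 2, sdv, "/"))
    Xva <- cbind(1, sweep(sweep(va$X, 2, mu), 2, sdv, "/"))
    W <- matrix(0, ncol(Xtr), K)
    eval_loss <- function(W, X, y) {
      weighted_ce_plus_lovasz(softmax_rows(X %*% W), y, w_c,
                              config$lovasz_weight)
    }
    best_loss <- init_loss <- eval_loss(W, Xva, va$y)
    best_W <- W
    stall <- 0L
    n <- nrow(Xtr)
    Y <- matrix(0, n, K); Y[cbind(seq_len(n), tr$y)] <- 1
    for (epoch in seq_len(config$epochs)) {
      P <- softmax_rows(Xtr %*% W)
      Gp <- (P - Y) * (w_c[tr$y] / n)          # d(weighted CE)/d logits
      if (config$lovasz_weight > 0) {
        lv <- lovasz_softmax_loss(P, tr$y, return_grad = TRUE)
        # chain through softmax: dL/dz_k = p_k (g_k - sum_c g_c p_c)
        inner <- rowSums(lv$grad * P)
        Gp <- Gp + config$lovasz_weight * P * (lv$grad - inner)
      }
      W <- W - config$learning_rate * crossprod(Xtr, Gp)
      vl <- eval_loss(W, Xva, va$y)
      if (vl < best_loss - 1e-9) {
        best_loss <- vl; best_W <- W; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) break
      }
    }
    model <- structure(list(W = best_W, feature_mean = mu, feature_sd = sdv,
                            class_order = class_labels, config = config,
                            val_loss = best_loss, initial_val_loss = init_loss),
                       class = "segmenter")
    model$digest <- object_digest(model[c("W", "feature_mean", "feature_sd",
                                          "class_order")])
    model
  })
}

#' Per-pixel class probabilities for one patch
#'
#' @param model a `segmenter`.
#' @param pixels h x w x 3 array.
#' @return h x w x K probability array.
#' @export
predict_pixels <- function(model, pixels) {
  f <- pixel_features(pixels)
  X <- cbind(1, sweep(sweep(matrix(f, ncol = dim(f)[3]), 2,
                            model$feature_mean), 2, model$feature_sd, "/"))
  P <- softmax_rows(X %*% model$W)
  array(P, dim = c(dim(pixels)[1], dim(pixels)[2], ncol(P)))
}

#' Segment a whole slide by patch stitching
#'
#' Overlapping patches are predicted independently; per-pixel class
#' probabilities are averaged over all covering patches and the argmax
#' taken, which avoids seam artifacts. A slide smaller than the patch size
#' is edge-padded, predicted as a single patch, and cropped back.
#'
#' @param model a `segmenter`.
#' @param slide a `SlideImage`.
#' @param patch_size patch edge length (default the training patch size).
#' @param stride stride between patch origins (default `patch_size / 2`).
#' @return a `SegmentationMap`: list with `labels` (integer matrix, classes
#'   attached) and `prob` (h x w x K averaged probabilities).
#' @export
predict_slide <- function(model, slide, patch_size = model$config$patch_size,
                          stride = max(1L, patch_size %/% 2L)) {
  pix <- slide$pixels
  h <- dim(pix)[1]; w <- dim(pix)[2]
  K <- length(model$class_order)
  if (h < patch_size || w < patch_size) {
    ph <- max(h, patch_size); pw <- max(w, patch_size)
    padded <- pix[c(seq_len(h), rep(h, ph - h)),
                  c(seq_len(w), rep(w, pw - w)), , drop = FALSE]
    P <- predict_pixels(model, padded)[seq_len(h), seq_len(w), , drop = FALSE]
  } else {
    starts <- function(n) {
      s <- seq(0L, n - patch_size, by = stride)
      if (s[length(s)] != n - patch_size) s <- c(s, n - patch_size)
      as.integer(s)
    }
    acc <- array(0, dim = c(h, w, K))
    cnt <- matrix(0, h, w)
    for (r0 in starts(h)) {
      for (c0 in starts(w)) {
        rr <- r0 + seq_len(patch_size); cc <- c0 + seq_len(patch_size)
        acc[rr, cc, ] <- acc[rr, cc, , drop = FALSE] +
          predict_pixels(model, pix[rr, cc, , drop = FALSE])
        cnt[rr, cc] <- cnt[rr, cc] + 1
      }
    }
    P <- acc / array(cnt, dim = c(h, w, K))
  }
  labels <- matrix(max.col(matrix(P, ncol = K)), h, w)
  attr(labels, "classes") <- model$class_order
  structure(list(labels = labels, class_order = model$class_order, prob = P),
            class = "SegmentationMap")
}

#' Tissue composition of a segmentation map
#'
#' Percentages of each non-background class among non-background pixels;
#' they sum to 100 up to rounding. An all-background map returns zeros with
#' a warning.
#'
#' @param seg_map a `SegmentationMap` or label matrix with a `classes`
#'   attribute.
#' @return named numeric vector of percentages.
#' @export
tissue_percentages <- function(seg_map) {
  labels <- if (inherits(seg_map, "SegmentationMap")) seg_map$labels else seg_map
  classes <- attr(labels, "classes")
  if (is.null(classes) && inherits(seg_map, "SegmentationMap")) {
    classes <- seg_map$class_order
  }
  abort_if(length(labels) == 0, "empty segmentation map")
  tissue <- setdiff(classes, "background")
  counts <- tabulate(as.integer(labels), nbins = length(classes))
  names(counts) <- classes
  total <- sum(counts[tissue])
  if (total == 0) {
    warning("all-background segmentation map")
    return(stats::setNames(rep(0, length(tissue)), tissue))
  }
  100 * counts[tissue] / total
}

#' Intersection-over-union segmentation scores
#'
#' Per-class IoU, the unweighted mean over classes present in the truth,
#' and the class-abundance weighted IoU `sum_c f_c IoU_c` where `f_c` is
#' the truth pixel fraction of class `c`. Classes absent from both maps are
#' excluded.
#'
#' @param pred_map,truth_map label matrices (or `SegmentationMap`s) of the
#'   same shape.
#' @return list with `per_class`, `mean_iou`, `weighted_iou`.
#' @export
iou_scores <- function(pred_map, truth_map) {
  pl <- if (inherits(pred_map, "SegmentationMap")) pred_map$labels else pred_map
  tl <- if (inherits(truth_map, "SegmentationMap")) truth_map$labels else truth_map
  abort_if(!all(dim(pl) == dim(tl)), "maps differ in shape")
  classes <- attr(tl, "classes")
  if (is.null(classes)) classes <- attr(pl, "classes")
  if (is.null(classes)) classes <- as.character(seq_len(max(pl, tl)))
  K <- length(classes)
  pv <- as.integer(pl); tv <- as.integer(tl)
  per <- rep(NA_real_, K); names(per) <- classes
  for (c in seq_len(K)) {
    p <- pv == c; t <- tv == c
    u <- sum(p | t)
    if (u == 0) next  # absent from both: excluded
    per[c] <- sum(p & t) / u
  }
  in_truth <- tabulate(tv, nbins = K) > 0
  mean_iou <- mean(per[in_truth])
  f <- tabulate(tv, nbins = K) / length(tv)
  weighted_iou <- sum(f[in_truth] * per[in_truth])
  list(per_class = per, mean_iou = mean_iou, weighted_iou = weighted_iou)
}
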