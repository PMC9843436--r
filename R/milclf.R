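# ---- patch-level summary features ------------------------------------------

#' Patch summary features
#'
#' Per-patch statistics used by the desk-scale patch classifier and the
#' survival head: channel means, luminance mean/sd, dark-pixel fractions at
#' three cuts (nucleus-density proxies), multi-scale local-sd energies,
#' center-surround blob contrast, and mean orientation coherence.
#'
#' @param patch a `Patch` or h x w x 3 pixel array (0-255).
#' @return named numeric feature vector.
#' @export
patch_features <- function(patch) {
  pix <- if (inherits(patch, "Patch")) patch$pixels else patch
  g <- rgb_to_gray(pix) / 255
  gr <- grad_xy(g)
  jxx <- box_mean(gr$gx^2, 3); jyy <- box_mean(gr$gy^2, 3)
  jxy <- box_mean(gr$gx * gr$gy, 3)
  coher <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / (jxx + jyy + 1e-8)
  c(mean_r = mean(pix[, , 1]) / 255,
    mean_g = mean(pix[, , 2]) / 255,
    mean_b = mean(pix[, , 3]) / 255,
    mean_gray = mean(g), sd_gray = stats::sd(as.vector(g)),
    dark45 = mean(g < 0.45), dark55 = mean(g < 0.55), dark65 = mean(g < 0.65),
    energy3 = mean(box_sd(g, 1)), energy5 = mean(box_sd(g, 2)),
    energy11 = mean(box_sd(g, 5)),
    blob_contrast = mean(abs(g - box_mean(g, 3))),
    coherence = mean(coher))
}

patch_feature_matrix <- function(patches) {
  t(vapply(patches, patch_features, patch_features(patches[[1]])))
}

# ---- MIL losses -------------------------------------------------------------

#' MIL loss configuration
#'
#' @param variant `"topk"` (keep the top fraction of each class's samples
#'   by true-class score) or `"meansd"` (skip samples whose true-class
#'   score falls below mean - sd_multiplier * sd of the batch's true-class
#'   scores).
#' @param keep_fraction fraction kept per class for `"topk"` (default 0.7).
#' @param sd_multiplier multiplier for `"meansd"` (default 1).
#' @param batch_size training batch size (default 144).
#' @return a `MILLossConfig`.
#' @export
mil_loss_config <- function(variant = c("topk", "meansd"), keep_fraction = 0.7,
                            sd_multiplier = 1.0, batch_size = 144L) {
  variant <- match.arg(variant)
  abort_if(keep_fraction <= 0 || keep_fraction > 1,
           "keep_fraction must be in (0, 1]")
  abort_if(sd_multiplier < 0, "sd_multiplier must be >= 0")
  structure(list(variant = variant, keep_fraction = keep_fraction,
                 sd_multiplier = sd_multiplier,
                 batch_size = as.integer(batch_size)),
            class = "MILLossConfig")
}

# internal: which samples contribute to the MIL loss (logical mask)
mil_keep_mask <- function(prob, labels, config) {
  n <- nrow(prob)
  s_true <- prob[cbind(seq_len(n), labels)]
  keep <- rep(FALSE, n)
  if (config$variant == "topk") {
    for (c in unique(labels)) {
      idx <- which(labels == c)
      k <- ceiling(config$keep_fraction * length(idx))
      abort_if(k < 1, "keep count is zero for class %d", c)
      ord <- idx[order(s_true[idx], decreasing = TRUE)]
      keep[ord[seq_len(k)]] <- TRUE
    }
  } else {
    cutoff <- mean(s_true) - config$sd_multiplier * stats::sd(s_true)
    if (is.na(cutoff)) cutoff <- -Inf
    keep <- s_true >= cutoff
    if (!any(keep)) {
      warning("mean/sd skip excluded every sample; falling back to full-batch loss")
      keep <- rep(TRUE, n)
    }
  }
  keep
}

mil_ce <- function(prob, labels, keep, eps = 1e-12) {
  per_class <- tapply(seq_along(labels)[keep], labels[keep], function(idx) {
    mean(-log(pmax(prob[cbind(idx, labels[idx])], eps)))
  })
  mean(per_class)
}

#' Top-k multiple-instance-learning loss
#'
#' Per class, samples are ranked by their true-class prediction score and
#' only the top `ceil(keep_fraction * n_c)` contribute; the cross-entropy
#' is averaged over the kept samples of each class and then over classes.
#' With `keep_fraction = 1`, or when all scores are identical, this is the
#' plain (class-balanced) cross-entropy.
#'
#' @param prob N x K probability matrix.
#' @param labels integer class indices (1..K).
#' @param config a [mil_loss_config()] with `variant = "topk"`.
#' @return scalar loss; attribute `keep` holds the contribution mask.
#' @export
mil_topk_loss <- function(prob, labels, config = mil_loss_config("topk")) {
  keep <- mil_keep_mask(prob, labels, config)
  structure(mil_ce(prob, labels, keep), keep = keep)
}

#' Mean/SD skip multiple-instance-learning loss
#'
#' Samples whose true-class score falls below `mean - sd_multiplier * sd`
#' (statistics over the batch's true-class scores) are skipped; the loss is
#' the average cross-entropy over the rest. If every sample would be
#' skipped the loss falls back to the full batch with a warning.
#'
#' @inheritParams mil_topk_loss
#' @export
mil_meansd_skip_loss <- function(prob, labels,
                                 config = mil_loss_config("meansd")) {
  abort_if(nrow(prob) < 2, "mean/sd skip needs a batch of at least 2")
  keep <- mil_keep_mask(prob, labels, config)
  structure(mean(-log(pmax(prob[cbind(which(keep), labels[keep])], 1e-12))),
            keep = keep)
}

# ---- patch classifier -------------------------------------------------------

#' Train a patch classifier with a MIL loss
#'
#' A multinomial logistic head over [patch_features()], optimized by seeded
#' minibatch gradient descent. Each batch's loss is the configured MIL
#' variant: the gradient flows only through the samples the MIL rule keeps.
#'
#' @param patches list of training patches (or a precomputed feature
#'   matrix).
#' @param labels integer class labels (1..n_classes) per training patch.
#' @param config a [mil_loss_config()].
#' @param n_classes number of classes.
#' @param epochs training epochs (default 40).
#' @param learning_rate gradient step (default 0.5).
#' @param seed integer seed; training is deterministic given the seed.
#' @return a `patch_classifier`.
#' @export
train_patch_classifier <- function(patches, labels, config = mil_loss_config("topk"),
                                   n_classes = max(labels), epochs = 40,
                                   learning_rate = 0.5, seed = 1L) {
  abort_if(length(unique(labels)) < 2, "training set contains a single class")
  X <- if (is.matrix(patches)) patches else patch_feature_matrix(patches)
  abort_if(nrow(X) != length(labels), "patches and labels differ in length")
  labels <- as.integer(labels)
  K <- n_classes
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- cbind(1, sweep(sweep(X, 2, mu), 2, sdv, "/"))
  n <- nrow(Xs)
  W <- matrix(0, ncol(Xs), K)
  with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      bstarts <- seq(1, n, by = config$batch_size)
      for (b in bstarts) {
        idx <- ord[b:min(b + config$batch_size - 1L, n)]
        if (length(idx) < 2) next
        Xb <- Xs[idx, , drop = FALSE]
        yb <- labels[idx]
        P <- softmax_rows(Xb %*% W)
        keep <- mil_keep_mask(P, yb, config)
        kept <- which(keep)
        Y <- matrix(0, length(kept), K)
        Y[cbind(seq_along(kept), yb[kept])] <- 1
        G <- (P[kept, , drop = FALSE] - Y) / length(kept)
        W <- W - learning_rate * crossprod(Xb[kept, , drop = FALSE], G)
      }
    }
  })
  structure(list(W = W, feature_mean = mu, feature_sd = sdv, n_classes = K,
                 config = config,
                 digest = object_digest(list(W, mu, sdv))),
            class = "patch_classifier")
}

#' Predict class probabilities for patches
#'
#' @param object a `patch_classifier` (or ensemble).
#' @param patches list of patches or feature matrix.
#' @param ... unused.
#' @return N x K probability matrix.
#' @export
predict.patch_classifier <- function(object, patches, ...) {
  X <- if (is.matrix(patches)) patches else patch_feature_matrix(patches)
  Xs <- cbind(1, sweep(sweep(X, 2, object$feature_mean), 2,
                       object$feature_sd, "/"))
  softmax_rows(Xs %*% object$W)
}

#' Select the best models and average their outputs
#'
#' Keeps the `k_select` models with the highest validation metric (ties
#' broken toward the lower fold index) and returns an ensemble whose
#' predicted probabilities are the arithmetic mean of the members'.
#'
#' @param models list of models supporting `predict`.
#' @param val_metrics numeric validation metric per model (higher is
#'   better), e.g. balanced accuracy.
#' @param k_select number of models kept.
#' @return a `model_ensemble`.
#' @export
ensemble_select_and_average <- function(models, val_metrics, k_select) {
  abort_if(length(models) < k_select, "fewer models than k_select")
  abort_if(length(models) != length(val_metrics),
           "one metric per model required")
  ord <- order(-val_metrics, seq_along(models))
  sel <- ord[seq_len(k_select)]
  structure(list(members = models[sel], selected = sel,
                 val_metrics = val_metrics[sel]),
            class = "model_ensemble")
}

#' @rdname ensemble_select_and_average
#' @param object a `model_ensemble`.
#' @param patches patches or feature matrix.
#' @param ... unused.
#' @export
predict.model_ensemble <- function(object, patches, ...) {
  preds <- lapply(object$members, function(m) predict(m, patches))
  Reduce(`+`, preds) / length(preds)
}

# ---- slide-level aggregation: positive ratio and calls ----------------------

#' Slide-level positive ratio
#'
#' The fraction of a slide's patches whose argmax prediction is the
#' positive class: `n_positive / n_patches`. 300 positive of 1,000 patches
#' gives 0.3.
#'
#' @param prob N x K probability matrix for one slide's patches (or an
#'   integer vector of argmax classes).
#' @param positive_class column index (or value) of the positive class.
#' @param slide_id identifier carried into the result.
#' @return a `SlidePrediction` (without a call until thresholded).
#' @export
positive_ratio <- function(prob, positive_class, slide_id = "slide") {
  if (is.matrix(prob)) {
    abort_if(nrow(prob) == 0, "no patches for slide")
    pred <- max.col(prob)
  } else {
    abort_if(length(prob) == 0, "no patches for slide")
    pred <- prob
  }
  n <- length(pred)
  npos <- sum(pred == positive_class)
  structure(list(slide_id = slide_id, n_patches = n, n_positive = npos,
                 positive_ratio = npos / n, call = NA_character_,
                 threshold_used = NA_real_),
            class = "SlidePrediction")
}

#' Categorical call from positive ratios
#'
#' A slide is called positive when its ratio is greater than or equal to
#' the threshold (boundary inclusive).
#'
#' @param ratios numeric vector of positive ratios (or a single
#'   `SlidePrediction`).
#' @param threshold ratio threshold in `[0, 1]` (e.g. 0.2, 0.1, or a
#'   validation-derived value such as 0.043574).
#' @return character vector of `"positive"`/`"negative"` (or the updated
#'   `SlidePrediction`).
#' @export
classify_by_ratio <- function(ratios, threshold) {
  abort_if(threshold < 0 || threshold > 1, "threshold must be in [0, 1]")
  if (inherits(ratios, "SlidePrediction")) {
    ratios$call <- if (ratios$positive_ratio >= threshold) "positive" else "negative"
    ratios$threshold_used <- threshold
    return(ratios)
  }
  ifelse(ratios >= threshold, "positive", "negative")
}

#' Threshold selection by the geometric mean of sensitivity and specificity
#'
#' Candidate thresholds are the midpoints of consecutive sorted unique
#' validation ratios (plus cuts below the minimum and above the maximum);
#' the candidate maximizing `sqrt(sensitivity * specificity)` is returned,
#' ties resolved toward the smallest threshold.
#'
#' @param ratios validation positive ratios.
#' @param labels binary labels (1/TRUE = positive).
#' @return list with `threshold`, `gm`, `sensitivity`, `specificity`.
#' @export
threshold_by_geometric_mean <- function(ratios, labels) {
  labels <- as.integer(as.logical(labels))
  abort_if(length(unique(labels)) < 2, "both classes must be present")
  u <- sort(unique(ratios))
  abort_if(length(u) < 2, "degenerate ratios: a threshold cannot separate a single value")
  cand <- c(u[1] - (u[2] - u[1]) / 2, (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + (u[length(u)] - u[length(u) - 1]) / 2)
  cand <- pmin(pmax(cand, 0), 1)
  best <- list(threshold = NA_real_, gm = -1)
  for (t in cand) {
    call <- as.integer(ratios >= t)
    sens <- sum(call == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(call == 0 & labels == 0) / sum(labels == 0)
    gm <- sqrt(sens * spec)
    if (gm > best$gm + 1e-12) {
      best <- list(threshold = t, gm = gm, sensitivity = sens,
                   specificity = spec)
    }
  }
  best
}

# ---- TMA aggregation --------------------------------------------------------

#' Core-level call by simple patch-vote majority
#'
#' The core call is the class with the majority of patch argmax votes; a
#' tie goes to the class with the higher mean probability. The core's class
#' probability vector (mean over patches) is returned for downstream
#' consensus.
#'
#' @param prob N x K probability matrix over one core's patches.
#' @param classes optional class names for the columns.
#' @return list with `call` (column index or name), `votes`, `mean_prob`.
#' @export
tma_core_predict <- function(prob, classes = colnames(prob)) {
  abort_if(!is.matrix(prob) || nrow(prob) == 0, "core has no patch predictions")
  K <- ncol(prob)
  votes <- tabulate(max.col(prob), nbins = K)
  mean_prob <- colMeans(prob)
  top <- which(votes == max(votes))
  call <- if (length(top) == 1) top else top[which.max(mean_prob[top])]
  if (!is.null(classes)) {
    names(votes) <- classes; names(mean_prob) <- classes
    call <- classes[call]
  }
  list(call = call, votes = votes, mean_prob = mean_prob)
}

#' Patient consensus by per-class geometric mean over cores
#'
#' For a patient with several cores, each class's probabilities are
#' combined by the geometric mean across cores and the argmax taken; a
#' single-core patient uses that core's call. Zero probabilities are
#' epsilon-floored before the geometric mean.
#'
#' @param core_probs list of per-core class probability vectors (equal
#'   length).
#' @param eps floor applied before taking logs (default 1e-12).
#' @return list with `call` (index or name) and `geomean` probabilities.
#' @export
patient_consensus_geomean <- function(core_probs, eps = 1e-12) {
  abort_if(length(core_probs) == 0, "patient has no cores")
  M <- do.call(rbind, core_probs)
  if (any(M <= eps)) message("epsilon-flooring zero core probabilities")
  M <- pmax(M, eps)
  gm <- exp(colMeans(log(M)))
  call <- which.max(gm)
  if (!is.null(colnames(M))) call <- colnames(M)[call]
  list(call = call, geomean = gm)
}
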