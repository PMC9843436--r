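#' Experiment configuration
#'
#' Desk-scale defaults for the end-to-end synthetic studies. Each task
#' reproduces one experiment shape: `"segmentation"` (pixel segmenter +
#' IoU), `"fusion"` (FP-like vs FN-like patch classifier with top-k MIL and
#' slide-level calls), `"tp53"`/`"ras"`/`"myod1"` (mutation calling from
#' the slide positive ratio; `ras` uses the mean/SD skip MIL and a tumor
#' -fraction patch filter, `myod1` picks its threshold by the geometric
#' mean on validation slides), and `"survival"` (Cox head, fold-ensembled
#' hazards, 12-year censoring, constrained cutoff search).
#'
#' @param task one of segmentation, fusion, tp53, ras, myod1, survival.
#' @param n_slides cohort size.
#' @param slide_px slide edge length.
#' @param patch_size patch edge length.
#' @param patches_per_slide patches sampled per slide.
#' @param folds cross-validation folds (test chunks are disjoint across
#'   folds).
#' @param repeats independent repeats of the fold layout.
#' @param split_fractions (train, val, test) fractions summing to 1.
#' @param threshold positive-ratio threshold for the mutation tasks
#'   (`NA` = derive by geometric mean on validation, as for `myod1`).
#' @param mutant_prevalence,mutant_fraction_range cohort mixing controls
#'   for the mutation and survival tasks.
#' @param log_hazard_coefficient planted survival effect.
#' @param seed master seed.
#' @param out_dir optional run directory for the manifest and metrics.
#' @return an `ExperimentConfig`.
#' @export
experiment_config <- function(task = c("fusion", "segmentation", "tp53", "ras",
                                       "myod1", "survival"),
                              n_slides = 30, slide_px = 96, patch_size = 24,
                              patches_per_slide = 20, folds = 1L, repeats = 1L,
                              split_fractions = c(0.8, 0.1, 0.1),
                              threshold = NA_real_, mutant_prevalence = 0.5,
                              mutant_fraction_range = c(0.25, 0.6),
                              log_hazard_coefficient = 1.5, seed = 1L,
                              out_dir = NULL) {
  task <- match.arg(task)
  abort_if(abs(sum(split_fractions) - 1) > 1e-8,
           "split fractions must sum to 1")
  abort_if(folds < 1, "folds must be >= 1")
  if (is.na(threshold)) {
    threshold <- switch(task, tp53 = 0.2, ras = 0.1, NA_real_)
  }
  # the survival study plants a near-clonal mutant fraction so a strong
  # coefficient yields a strong log-hazard spread between the two arms
  if (task == "survival" && missing(mutant_fraction_range)) {
    mutant_fraction_range <- c(0.7, 0.95)
  }
  structure(list(task = task, n_slides = as.integer(n_slides),
                 slide_px = as.integer(slide_px),
                 patch_size = as.integer(patch_size),
                 patches_per_slide = as.integer(patches_per_slide),
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 split_fractions = split_fractions, threshold = threshold,
                 mutant_prevalence = mutant_prevalence,
                 mutant_fraction_range = mutant_fraction_range,
                 log_hazard_coefficient = log_hazard_coefficient,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "ExperimentConfig")
}

#' Digest of the semantic fields of a config
#'
#' Changes iff a semantic field (anything but the output directory)
#' changes.
#'
#' @param config an `ExperimentConfig`.
#' @return character digest.
#' @export
config_digest <- function(config) {
  object_digest(config[setdiff(names(config), "out_dir")])
}

#' Stratified fold assignments with a held-out test chunk per fold
#'
#' Samples are permuted within each class (seeded); fold `f`'s test set is
#' the `f`-th disjoint chunk of `test_fraction * n` samples, so test sets
#' across folds never overlap and cover at most 100% of the cohort. The
#' remainder of each fold is split into validation and training at the
#' given fractions.
#'
#' @param ids sample identifiers.
#' @param labels stratification labels (`NULL` = one stratum).
#' @param folds number of folds; `folds * test_fraction` must be <= 1.
#' @param split_fractions (train, val, test) fractions.
#' @param seed integer seed.
#' @return data.frame with `fold`, `id`, `role`
#'   (`"train"`/`"val"`/`"test"`).
#' @export
make_folds <- function(ids, labels = NULL, folds = 1L,
                       split_fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (is.null(labels)) labels <- rep("all", length(ids))
  abort_if(length(ids) != length(labels), "ids and labels differ in length")
  te_frac <- split_fractions[3]; va_frac <- split_fractions[2]
  abort_if(folds * te_frac > 1 + 1e-9,
           "folds * test fraction exceeds the cohort")
  out <- list()
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      abort_if(length(idx) < folds,
               "class '%s' has fewer samples than folds", cls)
      perm <- sample(idx)
      n_c <- length(perm)
      n_te <- max(1L, round(te_frac * n_c))
      abort_if(folds * n_te > n_c,
               "class '%s' too small for %d disjoint test chunks", cls, folds)
      n_va <- round(va_frac * n_c)
      for (f in seq_len(folds)) {
        test <- perm[((f - 1L) * n_te + 1L):(f * n_te)]
        rest <- setdiff(perm, test)
        val <- rest[seq_len(min(n_va, length(rest)))]
        train <- setdiff(rest, val)
        out[[length(out) + 1L]] <- data.frame(
          fold = f,
          id = ids[c(train, val, test)],
          role = rep(c("train", "val", "test"),
                     c(length(train), length(val), length(test))),
          stringsAsFactors = FALSE)
      }
    }
  })
  df <- do.call(rbind, out)
  df[order(df$fold, match(df$id, ids)), ]
}

#' Audit a fold manifest for train/test leakage
#'
#' @param manifest output of [make_folds()].
#' @return `TRUE` when, in every fold, train/val and test are disjoint and
#'   every sample has exactly one role; errors otherwise.
#' @export
audit_folds <- function(manifest) {
  for (f in unique(manifest$fold)) {
    m <- manifest[manifest$fold == f, ]
    abort_if(anyDuplicated(m$id) > 0,
             "fold %d assigns a sample more than one role", f)
    test <- m$id[m$role == "test"]
    rest <- m$id[m$role != "test"]
    abort_if(length(intersect(test, rest)) > 0, "fold %d leaks test samples", f)
  }
  TRUE
}

# ---- end-to-end synthetic experiments ---------------------------------------

# derive reproducible sub-seeds from the master seed (kept below 2^31)
sub_seed <- function(seed, k) {
  (as.numeric(seed) * 1009 + 97 * k) %% 2147483647
}

# patches + labels for a cohort: patch label = slide-level label index
cohort_patches <- function(cohort, config, label_from, min_tumor_fraction = 0,
                           seed = 1L) {
  feats <- list(); labs <- integer(0); slide_of <- character(0)
  for (i in seq_len(nrow(cohort$table))) {
    sl <- cohort$slides[[i]]
    mask <- otsu_foreground(sl$image)
    ps <- extract_patches(sl$image, mask, config$patch_size,
                          n_patches = config$patches_per_slide,
                          min_tissue_fraction = 0.5,
                          min_tumor_fraction = min_tumor_fraction,
                          labelmap = if (min_tumor_fraction > 0) sl$labels else NULL,
                          seed = sub_seed(seed, i))
    if (length(ps) == 0) next
    X <- patch_feature_matrix(ps)
    feats[[length(feats) + 1L]] <- X
    labs <- c(labs, rep(label_from(cohort$table[i, ]), nrow(X)))
    slide_of <- c(slide_of, rep(cohort$table$slide_id[i], nrow(X)))
  }
  list(X = do.call(rbind, feats), y = labs, slide = slide_of)
}

#' Run one synthetic end-to-end experiment
#'
#' Executes generate, tile, balance, train, predict, aggregate, evaluate
#' for the configured task and returns a `RunManifest` with the config
#' digest, fold assignments, and metric summaries. Deterministic given the
#' config. When `config$out_dir` is set, the manifest (JSON) and metrics
#' (CSV) are written there.
#'
#' @param config an [experiment_config()].
#' @return a `RunManifest` list.
#' @export
run_experiment <- function(config) {
  res <- switch(config$task,
    fusion = run_fusion_task(config),
    segmentation = run_segmentation_task(config),
    tp53 = ,
    ras = ,
    myod1 = run_mutation_task(config),
    survival = run_survival_task(config))
  manifest <- list(task = config$task, config_digest = config_digest(config),
                   folds = res$folds, metrics = res$metrics,
                   details = res$details)
  class(manifest) <- "RunManifest"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(task = config$task,
                              config_digest = config_digest(config),
                              metrics = res$metrics),
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(metric = names(unlist(res$metrics)),
                                value = unlist(res$metrics)),
                     file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  manifest
}

run_fusion_task <- function(config) {
  spec <- cohort_spec(config$n_slides,
                      class_balance = c(FP_like = 0.5, FN_like = 0.5),
                      mutant_prevalence = 0, seed = sub_seed(config$seed, 1))
  cohort <- generate_cohort(spec, slide_px = config$slide_px)
  dat <- cohort_patches(cohort, config,
                        label_from = function(row) match(row$class,
                                                         c("FP_like", "FN_like")),
                        seed = sub_seed(config$seed, 2))
  folds <- make_folds(cohort$table$slide_id, cohort$table$class,
                      folds = config$folds,
                      split_fractions = config$split_fractions,
                      seed = sub_seed(config$seed, 3))
  audit_folds(folds)
  f1 <- folds[folds$fold == 1, ]
  role_of <- stats::setNames(f1$role, f1$id)
  in_role <- function(r) dat$slide %in% f1$id[f1$role == r]
  clf <- train_patch_classifier(dat$X[in_role("train"), , drop = FALSE],
                                dat$y[in_role("train")],
                                config = mil_loss_config("topk"),
                                n_classes = 2,
                                seed = sub_seed(config$seed, 4))
  test_ids <- f1$id[f1$role == "test"]
  slide_score <- vapply(test_ids, function(id) {
    P <- predict(clf, dat$X[dat$slide == id, , drop = FALSE])
    mean(P[, 1])  # mean FP-like probability
  }, numeric(1))
  truth <- cohort$table$class[match(test_ids, cohort$table$slide_id)]
  patch_test <- in_role("test")
  acc <- mean(max.col(predict(clf, dat$X[patch_test, , drop = FALSE])) ==
                dat$y[patch_test])
  metrics <- list(slide_auc = roc_auc(slide_score, truth == "FP_like"),
                  patch_accuracy = acc)
  list(folds = folds, metrics = metrics, details = list(model = clf))
}

run_segmentation_task <- function(config) {
  spec <- cohort_spec(config$n_slides,
                      class_balance = c(FP_like = 0.5, FN_like = 0.5),
                      mutant_prevalence = 0, seed = sub_seed(config$seed, 1))
  cohort <- generate_cohort(spec, slide_px = config$slide_px)
  folds <- make_folds(cohort$table$slide_id, cohort$table$class,
                      folds = config$folds,
                      split_fractions = config$split_fractions,
                      seed = sub_seed(config$seed, 3))
  audit_folds(folds)
  f1 <- folds[folds$fold == 1, ]
  pairs_for <- function(role) {
    ids <- f1$id[f1$role == role]
    lapply(ids, function(id) {
      sl <- cohort$slides[[id]]
      list(pixels = sl$image$pixels, labels = sl$labels)
    })
  }
  cfg <- seg_train_config(patch_size = config$patch_size, epochs = 30,
                          seed = sub_seed(config$seed, 4))
  model <- train_segmenter(pairs_for("train"), pairs_for("val"), cfg)
  test_ids <- f1$id[f1$role == "test"]
  ious <- vapply(test_ids, function(id) {
    sl <- cohort$slides[[id]]
    sm <- predict_slide(model, sl$image, patch_size = config$patch_size)
    sc <- iou_scores(sm$labels, project_labels(sl$labels, model$class_order))
    c(sc$mean_iou, sc$weighted_iou)
  }, numeric(2))
  metrics <- list(mean_iou = mean(ious[1, ]), weighted_iou = mean(ious[2, ]))
  list(folds = folds, metrics = metrics, details = list(model = model))
}

# re-index a label map onto a model's class vocabulary
project_labels <- function(labels, classes) {
  out <- matrix(match(attr(labels, "classes")[as.integer(labels)], classes),
                nrow(labels), ncol(labels))
  attr(out, "classes") <- classes
  out
}

run_mutation_task <- function(config) {
  min_tf <- if (config$task == "ras") 0.66 else 0
  variant <- if (config$task == "ras") "meansd" else "topk"
  spec <- cohort_spec(config$n_slides,
                      class_balance = c(FN_like = 1),
                      mutant_prevalence = config$mutant_prevalence,
                      mutant_fraction_dist = function(n)
                        stats::runif(n, config$mutant_fraction_range[1],
                                     config$mutant_fraction_range[2]),
                      seed = sub_seed(config$seed, 1))
  cohort <- generate_cohort(spec, slide_px = config$slide_px)
  dat <- cohort_patches(cohort, config,
                        label_from = function(row) row$mutant + 1L,
                        min_tumor_fraction = min_tf,
                        seed = sub_seed(config$seed, 2))
  folds <- make_folds(cohort$table$slide_id, cohort$table$mutant,
                      folds = config$folds,
                      split_fractions = config$split_fractions,
                      seed = sub_seed(config$seed, 3))
  audit_folds(folds)
  f1 <- folds[folds$fold == 1, ]
  in_role <- function(r) dat$slide %in% f1$id[f1$role == r]
  clf <- train_patch_classifier(dat$X[in_role("train"), , drop = FALSE],
                                dat$y[in_role("train")],
                                config = mil_loss_config(variant),
                                n_classes = 2,
                                seed = sub_seed(config$seed, 4))
  ratio_of <- function(ids) {
    vapply(ids, function(id) {
      P <- predict(clf, dat$X[dat$slide == id, , drop = FALSE])
      positive_ratio(P, positive_class = 2, slide_id = id)$positive_ratio
    }, numeric(1))
  }
  threshold <- config$threshold
  if (is.na(threshold)) {
    val_ids <- f1$id[f1$role == "val"]
    threshold <- threshold_by_geometric_mean(
      ratio_of(val_ids),
      cohort$table$mutant[match(val_ids, cohort$table$slide_id)])$threshold
  }
  test_ids <- f1$id[f1$role == "test"]
  ratios <- ratio_of(test_ids)
  truth <- cohort$table$mutant[match(test_ids, cohort$table$slide_id)]
  calls <- classify_by_ratio(ratios, threshold)
  cm <- confusion_matrix(ifelse(truth == 1, "positive", "negative"), calls,
                         c("negative", "positive"))
  ss <- sensitivity_specificity(cm, "positive")
  metrics <- list(threshold = threshold,
                  slide_auc = if (length(unique(truth)) == 2)
                    roc_auc(ratios, truth == 1) else NA_real_,
                  sensitivity = ss$sensitivity, specificity = ss$specificity)
  list(folds = folds, metrics = metrics,
       details = list(model = clf, ratios = ratios, truth = truth))
}

run_survival_task <- function(config) {
  spec <- cohort_spec(config$n_slides,
                      class_balance = c(FN_like = 1),
                      mutant_prevalence = config$mutant_prevalence,
                      mutant_fraction_dist = function(n)
                        stats::runif(n, config$mutant_fraction_range[1],
                                     config$mutant_fraction_range[2]),
                      survival = list(baseline_rate = 0.15,
                                      log_hazard_coefficient =
                                        config$log_hazard_coefficient,
                                      censoring_rate = 0.03,
                                      max_followup_years = 25),
                      seed = sub_seed(config$seed, 1))
  cohort <- generate_cohort(spec, slide_px = config$slide_px)
  feats <- lapply(seq_len(nrow(cohort$table)), function(i) {
    sl <- cohort$slides[[i]]
    ps <- extract_patches(sl$image, otsu_foreground(sl$image),
                          config$patch_size,
                          n_patches = config$patches_per_slide,
                          seed = sub_seed(config$seed, 100 + i))
    if (length(ps) == 0) NULL else patch_feature_matrix(ps)
  })
  names(feats) <- cohort$table$slide_id
  records <- data.frame(subject_id = cohort$table$slide_id,
                        time_years = cohort$table$time_years,
                        event = cohort$table$event, stringsAsFactors = FALSE)
  records <- censor_at(records, 12)
  records <- tertile_partition(records, seed = sub_seed(config$seed, 5))
  # fold-ensembled hazards: each fold trains without its test chunk and
  # predicts everyone; the per-subject ensemble is the fold mean
  folds <- make_folds(records$subject_id, records$efs_group,
                      folds = config$folds,
                      split_fractions = config$split_fractions,
                      seed = sub_seed(config$seed, 6))
  audit_folds(folds)
  fold_preds <- list()
  heldout <- data.frame()
  for (f in seq_len(config$folds)) {
    ff <- folds[folds$fold == f, ]
    tr_ids <- ff$id[ff$role %in% c("train", "val")]
    m <- train_survival_model(feats[tr_ids],
                              records[records$subject_id %in% tr_ids, ],
                              seed = sub_seed(config$seed, 200 + f))
    fold_preds[[f]] <- predict(m, feats[!vapply(feats, is.null, logical(1))])
    te_ids <- ff$id[ff$role == "test"]
    heldout <- rbind(heldout,
                     data.frame(subject_id = te_ids,
                                hazard = fold_preds[[f]][te_ids]))
  }
  records$hazard <- as.numeric(ensemble_hazard(fold_preds)[records$subject_id])
  cs <- cutoff_search(records)
  ci <- survival::concordance(survival::Surv(time_years, event) ~ hazard,
                              data = records, reverse = TRUE)$concordance
  ho <- merge(heldout,
              records[, c("subject_id", "time_years", "event")], by = "subject_id")
  ci_ho <- survival::concordance(survival::Surv(time_years, event) ~ hazard,
                                 data = ho, reverse = TRUE)$concordance
  metrics <- list(concordance = ci, concordance_heldout = ci_ho,
                  p_multi = cs$p_multi,
                  best_C_L = if (is.null(cs$best)) NA_real_ else cs$best[["C_L"]],
                  best_C_H = if (is.null(cs$best)) NA_real_ else cs$best[["C_H"]])
  list(folds = folds, metrics = metrics,
       details = list(records = records, search = cs))
}
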