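softmax2 <- function(z) exp(z) / rowSums(exp(z))

test_that("top-k MIL loss keeps exactly ceil(keep_fraction * n_c) per class", {
  set.seed(2)
  p <- softmax2(matrix(rnorm(40), 20, 2))
  y <- rep(1:2, each = 10)
  l <- mil_topk_loss(p, y, mil_loss_config("topk", keep_fraction = 0.7))
  keep <- attr(l, "keep")
  expect_equal(sum(keep[y == 1]), 7)
  expect_equal(sum(keep[y == 2]), 7)
  # the kept samples are those with the highest true-class scores
  s1 <- p[y == 1, 1]
  expect_setequal(which(keep[y == 1]), order(s1, decreasing = TRUE)[1:7])
})

test_that("top-k MIL loss degenerates to plain cross-entropy in the limits", {
  # identical scores: ranking is vacuous
  p <- matrix(rep(c(0.7, 0.3), each = 12), 12, 2)
  y <- rep(1:2, times = c(8, 4))
  plain <- mean(c(mean(-log(p[y == 1, 1])), mean(-log(p[y == 2, 2]))))
  expect_equal(as.numeric(mil_topk_loss(p, y, mil_loss_config("topk", 0.7))),
               plain)
  # keep_fraction 1 on a class-balanced batch equals unweighted CE
  set.seed(3)
  pb <- softmax2(matrix(rnorm(24), 12, 2))
  yb <- rep(1:2, each = 6)
  expect_equal(as.numeric(mil_topk_loss(pb, yb, mil_loss_config("topk", 1))),
               mean(-log(pb[cbind(1:12, yb)])))
})

test_that("mean/SD skip excludes low-score samples and has the stated limits", {
  p <- rbind(c(0.9, 0.1), c(0.9, 0.1), c(0.9, 0.1), c(0.1, 0.9))
  y <- c(1L, 1L, 1L, 1L)
  # true-class scores {.9,.9,.9,.1}: mean .7, sd .4 -> cutoff .3 skips the .1
  l <- mil_meansd_skip_loss(p, y, mil_loss_config("meansd", sd_multiplier = 1))
  expect_equal(attr(l, "keep"), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(as.numeric(l), -log(0.9))
  # all scores equal: sd = 0, nothing skipped
  pe <- matrix(rep(c(0.6, 0.4), each = 4), 4, 2)
  le <- mil_meansd_skip_loss(pe, rep(1L, 4), mil_loss_config("meansd"))
  expect_true(all(attr(le, "keep")))
  expect_equal(as.numeric(le), -log(0.6))
  # huge multiplier: plain CE over everything
  set.seed(4)
  pr <- softmax2(matrix(rnorm(20), 10, 2))
  yr <- rep(1:2, 5)
  lr <- mil_meansd_skip_loss(pr, yr,
                             mil_loss_config("meansd", sd_multiplier = 100))
  expect_equal(as.numeric(lr), mean(-log(pr[cbind(1:10, yr)])))
})

test_that("patch classifier recovers three separable texture classes", {
  dat <- make_patch_data(c("FP_like", "FN_like", "normal"),
                         n_slides_per_class = 5, seed0 = 10)
  test <- make_patch_data(c("FP_like", "FN_like", "normal"),
                          n_slides_per_class = 2, seed0 = 900)
  clf <- train_patch_classifier(dat$X, dat$y, mil_loss_config("topk"),
                                n_classes = 3, seed = 1)
  acc <- mean(max.col(predict(clf, test$X)) == test$y)
  expect_gte(acc, 0.9)
  # determinism
  clf2 <- train_patch_classifier(dat$X, dat$y, mil_loss_config("topk"),
                                 n_classes = 3, seed = 1)
  expect_identical(clf$digest, clf2$digest)
  expect_equal(predict(clf, test$X), predict(clf2, test$X))
})

test_that("label-permuted training collapses to chance accuracy", {
  dat <- make_patch_data(c("FP_like", "FN_like", "normal"),
                         n_slides_per_class = 5, seed0 = 10)
  test <- make_patch_data(c("FP_like", "FN_like", "normal"),
                          n_slides_per_class = 2, seed0 = 900)
  yp <- histomil:::with_seed(99, sample(dat$y))
  clf <- train_patch_classifier(dat$X, yp, mil_loss_config("topk"),
                                n_classes = 3, seed = 1)
  acc <- mean(max.col(predict(clf, test$X)) == test$y)
  expect_lt(abs(acc - 1 / 3), 0.12)
})

test_that("single-class training sets are rejected", {
  expect_error(train_patch_classifier(matrix(rnorm(20), 10, 2), rep(1L, 10)),
               "single class")
})

test_that("ensemble selection averages the top models deterministically", {
  mk <- function(p1) {
    structure(list(p = p1), class = "const_model")
  }
  assign("predict.const_model",
         function(object, patches, ...) {
           matrix(rep(c(object$p, 1 - object$p), each = 2), 2, 2)
         }, envir = globalenv())
  on.exit(rm("predict.const_model", envir = globalenv()))
  models <- list(mk(0.8), mk(0.6), mk(0.5), mk(0.9), mk(0.7))
  ens <- ensemble_select_and_average(models, c(0.9, 0.7, 0.5, 0.8, 0.7), 3)
  # ties at 0.7 resolve toward the lower fold index (model 2 over model 5)
  expect_equal(ens$selected, c(1, 4, 2))
  P <- predict(ens, list())
  expect_equal(P[1, 1], mean(c(0.8, 0.9, 0.6)))
  # identical members reproduce any single member
  same <- ensemble_select_and_average(list(mk(0.4), mk(0.4), mk(0.4)),
                                      c(1, 1, 1), 3)
  expect_equal(predict(same, list()), matrix(rep(c(0.4, 0.6), each = 2), 2, 2))
})

test_that("positive ratio follows the worked count example and its invariances", {
  pred <- c(rep(2L, 300), rep(1L, 700))
  sp <- positive_ratio(pred, positive_class = 2)
  expect_equal(sp$positive_ratio, 0.3)
  expect_equal(sp$n_patches, 1000)
  # order invariance and duplication invariance
  expect_equal(positive_ratio(rev(pred), 2)$positive_ratio, 0.3)
  expect_equal(positive_ratio(c(pred, pred), 2)$positive_ratio, 0.3)
  expect_equal(positive_ratio(rep(1L, 50), 2)$positive_ratio, 0)
  expect_equal(positive_ratio(rep(2L, 50), 2)$positive_ratio, 1)
  expect_error(positive_ratio(integer(0), 2), "no patches")
})

test_that("ratio calls respect the inclusive threshold and are monotone", {
  expect_equal(classify_by_ratio(0.3, 0.2), "positive")
  expect_equal(classify_by_ratio(0, 0.01), "negative")
  expect_equal(classify_by_ratio(0.2, 0.2), "positive")  # boundary inclusive
  set.seed(8)
  ratios <- runif(30)
  t1 <- classify_by_ratio(ratios, 0.3)
  t2 <- classify_by_ratio(ratios, 0.6)
  # raising the threshold never converts a negative to positive
  expect_false(any(t1 == "negative" & t2 == "positive"))
})

test_that("geometric-mean threshold separates clean validation sets", {
  ratios <- c(0.0, 0.05, 0.1, 0.5, 0.7, 0.9)
  labels <- c(0, 0, 0, 1, 1, 1)
  res <- threshold_by_geometric_mean(ratios, labels)
  expect_equal(res$gm, 1)
  expect_gt(res$threshold, 0.1)
  expect_lte(res$threshold, 0.3)  # smallest candidate inside the gap
  expect_error(threshold_by_geometric_mean(rep(0.2, 5), c(0, 1, 0, 1, 0)),
               "degenerate")
})

test_that("geometric-mean search agrees with a brute-force threshold sweep", {
  set.seed(12)
  ratios <- round(runif(10), 2)
  labels <- rbinom(10, 1, 0.5)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  res <- threshold_by_geometric_mean(ratios, labels)
  grid <- seq(0, 1, by = 1e-4)
  gms <- vapply(grid, function(t) {
    call <- as.integer(ratios >= t)
    sqrt(sum(call & labels) / sum(labels) *
           sum(!call & !labels) / sum(!labels))
  }, numeric(1))
  expect_equal(res$gm, max(gms), tolerance = 1e-9)
})

test_that("null-label geometric mean stays near one half", {
  gms <- vapply(1:10, function(s) {
    histomil:::with_seed(1000 + s, {
      ratios <- runif(200)
      labels <- rbinom(200, 1, 0.5)
      threshold_by_geometric_mean(ratios, labels)$gm
    })
  }, numeric(1))
  expect_lt(abs(mean(gms) - 0.5), 0.1)
})

test_that("core votes and patient geometric-mean consensus follow the stated rules", {
  # 7 of 10 votes for class 1
  p <- rbind(matrix(rep(c(0.8, 0.2), each = 7), 7, 2),
             matrix(rep(c(0.3, 0.7), each = 3), 3, 2))
  core <- tma_core_predict(p, classes = c("FP_like", "FN_like"))
  expect_equal(core$call, "FP_like")
  expect_equal(unname(core$votes), c(7, 3))
  # oracle recount
  expect_equal(unname(core$votes),
               unname(as.vector(table(factor(max.col(p), levels = 1:2)))))
  # 5-5 tie resolved by higher mean probability
  ptie <- rbind(matrix(rep(c(0.9, 0.1), each = 5), 5, 2),
                matrix(rep(c(0.35, 0.65), each = 5), 5, 2))
  expect_equal(tma_core_predict(ptie, c("A", "B"))$call, "A")
  # patient consensus: sqrt products decide
  cons <- patient_consensus_geomean(list(c(0.6, 0.4), c(0.2, 0.8)))
  expect_equal(unname(cons$geomean),
               c(sqrt(0.6 * 0.2), sqrt(0.4 * 0.8)), tolerance = 1e-12)
  expect_equal(cons$call, 2)
  # identical cores and single cores return the core call
  expect_equal(patient_consensus_geomean(list(c(0.7, 0.3), c(0.7, 0.3)))$call, 1)
  expect_equal(patient_consensus_geomean(list(c(0.2, 0.8)))$call, 2)
})

test_that("unanimous core argmax always survives the geometric mean", {
  set.seed(15)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    n_cores <- sample(2:4, 1)
    target <- sample(k, 1)
    cores <- lapply(seq_len(n_cores), function(j) {
      p <- runif(k)
      p[target] <- max(p) + runif(1, 0.01, 0.5)
      p / sum(p)
    })
    expect_equal(patient_consensus_geomean(cores)$call, target)
  }
})
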