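test_that("tertile partition cuts 264 cases into 88/88/88 with 71/17 splits", {
  rec <- make_surv_records(264, seed = 1)
  part <- tertile_partition(rec, seed = 2)
  expect_equal(as.integer(table(part$efs_group)[c("short", "intermediate", "long")]),
               c(88L, 88L, 88L))
  for (g in c("short", "intermediate", "long")) {
    sp <- table(part$split[part$efs_group == g])
    expect_equal(unname(sp[["train"]]), 71)
    expect_equal(unname(sp[["val"]]), 17)
  }
  small <- tertile_partition(make_surv_records(9, seed = 3), seed = 1)
  expect_equal(as.integer(table(small$efs_group)), c(3L, 3L, 3L))
  expect_error(tertile_partition(make_surv_records(2, seed = 1)), "at least 3")
})

test_that("tertile boundaries equal the sort-and-slice oracle", {
  rec <- make_surv_records(30, seed = 4)
  part <- tertile_partition(rec, seed = 1)
  ord <- order(rec$time_years)
  expect_setequal(part$subject_id[part$efs_group == "short"],
                  rec$subject_id[ord[1:10]])
  expect_setequal(part$subject_id[part$efs_group == "long"],
                  rec$subject_id[ord[21:30]])
})

test_that("Cox partial likelihood matches closed forms and an independent fit", {
  # two subjects, one event first, equal hazards
  expect_equal(cox_partial_likelihood_loss(c(0.3, 0.3), c(1, 2), c(1, 0)),
               log(2))
  expect_message(l0 <- cox_partial_likelihood_loss(c(1, 2), c(1, 2), c(0, 0)),
                 "no events")
  expect_equal(l0, 0)
  expect_error(cox_partial_likelihood_loss(c(Inf, 0), c(1, 2), c(1, 1)),
               "non-finite")
  # 5-subject case with ties against the Breslow likelihood of coxph
  t5 <- c(2, 2, 3, 5, 5); e5 <- c(1, 1, 0, 1, 1); h5 <- c(0.4, -0.2, 0.1, 0.8, -0.5)
  fit <- survival::coxph(survival::Surv(t5, e5) ~ offset(h5),
                         method = "breslow")
  expect_equal(cox_partial_likelihood_loss(h5, t5, e5), -fit$loglik[1])
})

test_that("Cox loss is invariant to a constant hazard shift", {
  set.seed(5)
  h <- rnorm(12); t <- rexp(12); e <- rbinom(12, 1, 0.7)
  if (sum(e) == 0) e[1] <- 1
  expect_equal(cox_partial_likelihood_loss(h, t, e),
               cox_partial_likelihood_loss(h + 3.7, t, e))
})

test_that("survival head recovers a planted effect and is deterministic", {
  # subject 'patches': noisy copies of the subject's risk feature
  histomil:::with_seed(6, {
    # train on a 120-subject cohort; measure generalization on a large
    # independent draw so the concordance estimate itself is stable
    n <- 520
    f <- runif(n, -1, 1)
    rate <- 0.2 * exp(1.5 * f)
    rec <- data.frame(subject_id = sprintf("s%03d", 1:n),
                      time_years = rexp(n, rate), event = 1L)
    feats <- lapply(1:n, function(i) {
      cbind(feat = f[i] + rnorm(6, 0, 0.15), junk = rnorm(6))
    })
    names(feats) <- rec$subject_id
    tr <- 1:120; te <- 121:520
    m <- train_survival_model(feats[tr], rec[tr, ], seed = 1)
    m2 <- train_survival_model(feats[tr], rec[tr, ], seed = 1)
    expect_identical(m$digest, m2$digest)
    h <- predict(m, feats[te])
    expect_true(all(abs(h) <= 1))
    d <- rec[te, ]; d$h <- h
    ci <- survival::concordance(survival::Surv(time_years, event) ~ h,
                                data = d, reverse = TRUE)$concordance
    expect_gte(ci, 0.7)
    # null control: shuffled outcomes give chance concordance
    rec0 <- rec
    rec0$time_years <- sample(rec0$time_years)
    m0 <- train_survival_model(feats[tr], rec0[tr, ], seed = 1)
    d0 <- rec0[te, ]; d0$h <- predict(m0, feats[te])
    ci0 <- survival::concordance(survival::Surv(time_years, event) ~ h,
                                 data = d0, reverse = TRUE)$concordance
    expect_lt(abs(ci0 - 0.5), 0.12)
  })
})

test_that("subjects without patches are excluded with a warning", {
  rec <- make_surv_records(10, seed = 7)
  feats <- lapply(1:10, function(i) matrix(rnorm(4), 2, 2))
  names(feats) <- rec$subject_id
  feats[[3]] <- matrix(numeric(0), 0, 2)
  expect_warning(train_survival_model(feats, rec,
                                      surv_train_config(epochs = 2),
                                      seed = 1),
                 "zero patches")
})

test_that("fold-ensembled hazards are clipped means of the available folds", {
  expect_equal(unname(ensemble_hazard(matrix(0.4, 20, 3))), rep(0.4, 3))
  expect_equal(unname(ensemble_hazard(rbind(c(-1, -1), c(1, 1)))), c(0, 0))
  set.seed(8)
  M <- matrix(runif(20 * 5, -1, 1), 20, 5)
  expect_equal(ensemble_hazard(M), colMeans(M))
  # missing folds are ignored
  M[1, 2] <- NA
  expect_equal(unname(ensemble_hazard(M)[2]), mean(M[-1, 2]))
})

test_that("log-rank test matches the hand-computed two-group fixture", {
  # A: events at 1, 3; B: events at 2, 4 -> O_A = 2, E_A = 4/3, V = 13/18
  t <- c(1, 3, 2, 4); e <- rep(1, 4); g <- c("A", "A", "B", "B")
  res <- log_rank_test(t, e, g)
  expect_equal(res$statistic, 8 / 13, tolerance = 1e-9)
  expect_equal(res$p, pchisq(8 / 13, 1, lower.tail = FALSE))
  # identical groups: statistic 0, p 1
  same <- log_rank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                        rep(c("x", "y"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  # three pooled identical groups
  three <- log_rank_test(rep(c(1, 2, 4), 3), rep(c(1, 0, 1), 3),
                         rep(c("a", "b", "c"), each = 3))
  expect_equal(three$statistic, 0, tolerance = 1e-12)
  expect_equal(three$df, 2)
  # no events anywhere
  none <- log_rank_test(c(1, 2, 3, 4), rep(0, 4), c(1, 1, 2, 2))
  expect_equal(none$statistic, 0)
  expect_equal(none$p, 1)
})

test_that("Kaplan-Meier estimates match the hand product-limit table", {
  # events at 1, 3, 4, 6; censored at 2, 5
  t <- 1:6; e <- c(1, 0, 1, 1, 0, 1)
  km <- km_estimate(t, e)
  expect_equal(km$surv[km$time == 1], 5 / 6)
  expect_equal(km$surv[km$time == 3], 5 / 6 * 3 / 4)
  expect_equal(km$surv[km$time == 4], 5 / 6 * 3 / 4 * 2 / 3)
  expect_equal(km$surv[km$time == 6], 0)
  # no censoring: empirical survivor fraction
  km2 <- km_estimate(c(1, 2, 3, 4), rep(1, 4))
  expect_equal(km2$surv, c(0.75, 0.5, 0.25, 0))
  # all censored: survival stays at 1
  km3 <- km_estimate(c(1, 2, 3), rep(0, 3))
  expect_true(all(km3$surv == 1))
})

test_that("the 12-year censoring rule converts only beyond-horizon records", {
  rec <- data.frame(subject_id = c("a", "b", "c"),
                    time_years = c(4835 / 365.25, 5, 10),
                    event = c(1L, 1L, 0L))
  out <- censor_at(rec, 12)
  expect_equal(out$time_years, c(12, 5, 10))
  expect_equal(out$event, c(0L, 1L, 0L))
})

test_that("risk-group assignment is monotone in the hazard", {
  set.seed(9)
  h <- sort(runif(50, -1, 1))
  g <- assign_risk_groups(h, -0.2, 0.4)
  expect_true(all(diff(as.integer(g)) >= 0))
  expect_error(assign_risk_groups(h, 0.5, 0.3), "below")
})

test_that("the cutoff lattice enumerates 28 C_L values and 658 pairs", {
  histomil:::with_seed(10, {
    n <- 60
    rec <- data.frame(subject_id = sprintf("s%02d", 1:n),
                      time_years = rexp(n, 0.2), event = rep(1L, n),
                      hazard = runif(n, -1, 1))
    cs <- cutoff_search(rec)
    expect_equal(length(unique(cs$ledger$C_L)), 28)
    expect_equal(nrow(cs$ledger), 658)
    # independent lattice count: sum over C_L of (0.95 - C_L)/0.05
    cls <- seq(-0.9, 0.45, by = 0.05)
    expect_equal(sum(round((0.95 - cls) / 0.05)), 658)
    # result is invariant to subject ordering
    perm <- sample(n)
    cs2 <- cutoff_search(rec[perm, ])
    expect_equal(cs$best, cs2$best)
    expect_equal(cs$p_multi, cs2$p_multi)
  })
})

test_that("a group forced beyond half the cohort empties the search", {
  # all hazards identical: some group always holds 100% of subjects
  rec <- data.frame(subject_id = sprintf("s%02d", 1:20),
                    time_years = rexp(20, 0.2) + 0.01, event = 1L,
                    hazard = rep(0, 20))
  cs <- cutoff_search(rec)
  expect_null(cs$best)
  expect_true(all(!cs$ledger$pass))
  expect_true(all(grepl("size", cs$ledger$reason)))
})

test_that("planted three-group cohorts are recovered across seeds", {
  one_seed <- function(s) {
    histomil:::with_seed(3000 + s, {
      n_per <- 30
      centers <- c(-0.5, 0, 0.5)
      rates <- c(0.05, 0.25, 1.0)
      rec <- data.frame(
        subject_id = sprintf("s%03d", 1:(3 * n_per)),
        time_years = rexp(3 * n_per, rep(rates, each = n_per)),
        event = 1L,
        hazard = pmin(pmax(rep(centers, each = n_per) +
                             rnorm(3 * n_per, 0, 0.1), -1), 1))
      cs <- cutoff_search(rec)
      if (is.null(cs$best)) return(c(hit = 0, bracket = 0))
      c(hit = as.numeric(cs$p_multi < 0.01),
        bracket = as.numeric(cs$best[["C_L"]] > -0.5 &&
                               cs$best[["C_L"]] < 0 &&
                               cs$best[["C_H"]] > 0 &&
                               cs$best[["C_H"]] < 0.5))
    })
  }
  res <- vapply(1:10, one_seed, c(hit = 0, bracket = 0))
  expect_gte(sum(res["hit", ]), 8)
  expect_gte(sum(res["bracket", ]), 8)
})

test_that("balanced batches draw near-equal counts from every stratum", {
  g <- rep(c("short", "intermediate", "long"), times = c(20, 20, 20))
  batches <- make_balanced_batches(g, 12, seed = 2)
  for (b in batches) {
    expect_equal(as.integer(table(g[b])), rep(4L, 3))
  }
})
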