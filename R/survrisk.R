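# ---- records and partitioning ----------------------------------------------

#' Validate a survival records data frame
#'
#' Records carry `subject_id`, `time_years` (> 0), `event` (0/1), and
#' optionally `hazard` in `[-1, 1]`.
#'
#' @param records data.frame.
#' @param require_hazard demand the hazard column.
#' @return the records invisibly.
#' @export
validate_records <- function(records, require_hazard = FALSE) {
  abort_if(!all(c("time_years", "event") %in% names(records)),
           "records need time_years and event columns")
  abort_if(any(records$time_years <= 0), "times must be positive")
  abort_if(!all(records$event %in% c(0, 1)), "event must be 0/1")
  if (require_hazard) {
    abort_if(is.null(records$hazard), "records need a hazard column")
    abort_if(any(abs(records$hazard) > 1 + 1e-9), "hazards must lie in [-1, 1]")
  }
  invisible(records)
}

#' Partition a cohort into survival-time tertiles with train/val splits
#'
#' Cases sorted by follow-up time are cut into three near-equal groups
#' (shortest, intermediate, longest) — 264 cases give 88/88/88 — and each
#' group is split into training and validation at the given fraction (the
#' default 17/88 reproduces a 71/17 split per group of 88). Used for
#' balanced sampling across outcome strata during training.
#'
#' @param records survival records.
#' @param val_frac validation fraction within each group (default 17/88).
#' @param seed seed for the within-group split.
#' @return records with `efs_group` (`"short"`, `"intermediate"`, `"long"`)
#'   and `split` (`"train"`/`"val"`) columns.
#' @export
tertile_partition <- function(records, val_frac = 17 / 88, seed = 1L) {
  validate_records(records)
  n <- nrow(records)
  abort_if(n < 3, "need at least 3 records for tertiles")
  ord <- order(records$time_years)
  sizes <- rep(n %/% 3, 3) + c(seq_len(3) <= n %% 3)
  grp <- rep(c("short", "intermediate", "long"), times = sizes)
  records$efs_group <- NA_character_
  records$efs_group[ord] <- grp
  records$split <- "train"
  with_seed(seed, {
    for (g in unique(grp)) {
      idx <- which(records$efs_group == g)
      nv <- round(val_frac * length(idx))
      if (nv > 0) records$split[sample(idx, nv)] <- "val"
    }
  })
  records
}

#' Balanced minibatches across outcome groups
#'
#' Stratified batch construction: each batch draws (near) equal numbers
#' from every group, so no training step is overweight with short- or
#' long-follow-up cases.
#'
#' @param groups group label per subject.
#' @param batch_size subjects per batch.
#' @param seed seed.
#' @return list of integer index vectors.
#' @export
make_balanced_batches <- function(groups, batch_size, seed = 1L) {
  g <- split(seq_along(groups), groups)
  per <- max(1L, batch_size %/% length(g))
  with_seed(seed, {
    pools <- lapply(g, sample)
    n_batches <- ceiling(max(lengths(pools)) / per)
    lapply(seq_len(n_batches), function(b) {
      unlist(lapply(pools, function(p) {
        take <- ((b - 1L) * per + seq_len(per) - 1L) %% length(p) + 1L
        p[take]
      }), use.names = FALSE)
    })
  })
}

# ---- Cox partial likelihood -------------------------------------------------

#' Negative log Cox partial likelihood (Breslow ties)
#'
#' `L = -sum_{i: event} [ h_i - log sum_{j: t_j >= t_i} exp(h_j) ]`.
#' A batch with no events has loss 0 by convention.
#'
#' @param hazards numeric scores, one per subject.
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @return scalar loss.
#' @export
cox_partial_likelihood_loss <- function(hazards, times, events) {
  abort_if(any(!is.finite(hazards)), "non-finite hazards")
  abort_if(length(hazards) != length(times) || length(times) != length(events),
           "inputs must have equal length")
  if (sum(events) == 0) {
    message("no events in batch: partial likelihood defined as 0")
    return(0)
  }
  loss <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    loss <- loss - (hazards[i] - log(sum(exp(hazards[risk]))))
  }
  loss
}

# gradient of the negative log partial likelihood with respect to hazards
cox_loss_grad <- function(hazards, times, events) {
  n <- length(hazards)
  g <- numeric(n)
  if (sum(events) == 0) return(g)
  eh <- exp(hazards)
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    denom <- sum(eh[risk])
    g[i] <- g[i] - 1
    g[risk] <- g[risk] + eh[risk] / denom
  }
  g
}

# ---- survival model ---------------------------------------------------------

#' Survival training configuration
#'
#' @param epochs gradient-descent epochs (default 150).
#' @param learning_rate step size (default 0.1).
#' @param batch_size subjects per balanced batch; `NULL` = full batch.
#' @param weight_decay L2 penalty on the head weights (default 0.05). With
#'   a linear head and desk-scale cohorts the ridge term keeps a
#'   no-signal fit near the constant-hazard solution instead of
#'   overfitting noise.
#' @return list config.
#' @export
surv_train_config <- function(epochs = 150, learning_rate = 0.1,
                              batch_size = NULL, weight_decay = 0.05) {
  list(epochs = as.integer(epochs), learning_rate = learning_rate,
       batch_size = batch_size, weight_decay = weight_decay)
}

#' Train the survival head
#'
#' A linear head over patch features with a Cox proportional-hazards
#' output: each subject's score is the mean head output over the subject's
#' patches, squashed to `[-1, 1]` by `tanh`, and the negative log partial
#' likelihood (Breslow ties) is minimized by seeded gradient descent. When
#' `records` carry an `efs_group` column and a batch size is configured,
#' batches are balanced across the outcome groups.
#'
#' @param subject_features named list: one patch-feature matrix per
#'   subject (rows = patches). Subjects with zero patches are excluded
#'   with a warning.
#' @param records survival records with `subject_id` matching the list
#'   names.
#' @param config a [surv_train_config()].
#' @param seed integer seed.
#' @return a `survival_model`.
#' @export
train_survival_model <- function(subject_features, records,
                                 config = surv_train_config(), seed = 1L) {
  validate_records(records)
  npatch <- vapply(subject_features, function(m) if (is.null(m)) 0L else nrow(m),
                   integer(1))
  if (any(npatch == 0)) {
    warning(sprintf("excluding %d subject(s) with zero patches", sum(npatch == 0)))
    subject_features <- subject_features[npatch > 0]
  }
  ids <- intersect(records$subject_id, names(subject_features))
  records <- records[match(ids, records$subject_id), ]
  # mean patch-feature vector per subject: the linear head commutes with
  # the within-subject average
  Xbar <- t(vapply(subject_features[ids], colMeans,
                   numeric(ncol(subject_features[[ids[1]]]))))
  mu <- colMeans(Xbar)
  sdv <- pmax(apply(Xbar, 2, stats::sd), 1e-8)
  Xs <- cbind(1, sweep(sweep(Xbar, 2, mu), 2, sdv, "/"))
  w <- numeric(ncol(Xs))
  n <- nrow(Xs)
  batches_of <- function(seed_epoch) {
    if (!is.null(config$batch_size) && !is.null(records$efs_group)) {
      make_balanced_batches(records$efs_group, config$batch_size, seed_epoch)
    } else {
      list(seq_len(n))
    }
  }
  with_seed(seed, {
    for (epoch in seq_len(config$epochs)) {
      for (idx in batches_of(sample.int(.Machine$integer.max, 1))) {
        s <- as.vector(Xs[idx, , drop = FALSE] %*% w)
        h <- tanh(s)
        g_h <- cox_loss_grad(h, records$time_years[idx], records$event[idx])
        g_s <- g_h * (1 - h^2)
        pen <- config$weight_decay * c(0, w[-1])  # intercept unpenalized
        w <- w - config$learning_rate *
          (as.vector(crossprod(Xs[idx, , drop = FALSE], g_s)) / length(idx) + pen)
      }
    }
  })
  structure(list(w = w, feature_mean = mu, feature_sd = sdv,
                 digest = object_digest(list(w, mu, sdv))),
            class = "survival_model")
}

#' Predict subject hazards in [-1, 1]
#'
#' @param object a `survival_model`.
#' @param subject_features named list of patch-feature matrices.
#' @param ... unused.
#' @return named hazard vector.
#' @export
predict.survival_model <- function(object, subject_features, ...) {
  Xbar <- t(vapply(subject_features, colMeans,
                   numeric(length(object$feature_mean))))
  Xs <- cbind(1, sweep(sweep(Xbar, 2, object$feature_mean), 2,
                       object$feature_sd, "/"))
  h <- tanh(as.vector(Xs %*% object$w))
  stats::setNames(h, names(subject_features))
}

#' Ensemble hazard over cross-validation folds
#'
#' Arithmetic mean of the available per-fold hazard predictions for each
#' subject (missing folds ignored), clipped to `[-1, 1]`.
#'
#' @param fold_hazards matrix (folds x subjects) or list of named vectors;
#'   `NA` marks a fold that did not predict a subject.
#' @return one hazard per subject.
#' @export
ensemble_hazard <- function(fold_hazards) {
  if (is.list(fold_hazards)) {
    ids <- unique(unlist(lapply(fold_hazards, names)))
    M <- do.call(rbind, lapply(fold_hazards, function(v) v[ids]))
    colnames(M) <- ids
    fold_hazards <- M
  }
  h <- colMeans(fold_hazards, na.rm = TRUE)
  abort_if(any(is.nan(h)), "some subjects predicted by no fold")
  pmin(pmax(h, -1), 1)
}

# ---- log-rank, Kaplan-Meier, censoring --------------------------------------

#' K-sample log-rank test
#'
#' Standard log-rank chi-square with `k - 1` degrees of freedom, computed
#' with [survival::survdiff()]. With no events anywhere the statistic is 0
#' and p = 1 by convention.
#'
#' @param times follow-up times.
#' @param events 0/1 indicators.
#' @param groups group label per subject (>= 2 non-empty groups).
#' @return list with `statistic`, `df`, `p`.
#' @export
log_rank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  k <- nlevels(droplevels(groups))
  abort_if(k < 2, "need at least two non-empty groups")
  if (sum(events) == 0) {
    return(list(statistic = 0, df = k - 1, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ droplevels(groups))
  stat <- sd$chisq
  if (!is.finite(stat)) stat <- 0
  list(statistic = stat, df = k - 1,
       p = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()]; censored subjects leave the risk set
#' without a survival step.
#'
#' @param times follow-up times.
#' @param events 0/1 indicators.
#' @return a `KMCurve`: list with `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_estimate <- function(times, events) {
  abort_if(length(times) == 0, "no records")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event),
            class = "KMCurve")
}

#' Administrative censoring at a horizon
#'
#' Any record with follow-up beyond the horizon and no event at or before
#' it becomes censored at the horizon (default 12 years); an event beyond
#' the horizon is likewise converted to a censoring at the horizon, since
#' no event was reported within it.
#'
#' @param records survival records.
#' @param horizon_years censoring horizon (> 0).
#' @return updated records.
#' @export
censor_at <- function(records, horizon_years = 12) {
  abort_if(horizon_years <= 0, "horizon must be positive")
  validate_records(records)
  late <- records$time_years > horizon_years
  records$event[late] <- 0L
  records$time_years[late] <- horizon_years
  records
}

# ---- risk groups and cutoff search ------------------------------------------

#' Assign three risk groups from hazard cutoffs
#'
#' `hazard <= C_L` is low risk, `C_L < hazard <= C_H` intermediate, and
#' `hazard > C_H` high risk.
#'
#' @param hazard numeric hazards in `[-1, 1]`.
#' @param c_low,c_high cutoffs with `c_low < c_high`.
#' @return factor with levels low/intermediate/high.
#' @export
assign_risk_groups <- function(hazard, c_low, c_high) {
  abort_if(c_low >= c_high, "C_L must be below C_H")
  cut(hazard, breaks = c(-Inf, c_low, c_high, Inf),
      labels = c("low", "intermediate", "high"))
}

#' Constrained two-cutoff risk-group search
#'
#' Exhaustively evaluates every cutoff pair on the lattice: `C_L` in
#' `[-0.9, 0.5)` and `C_H` in `(C_L, 0.95]`, both at step 0.05 (the grid is
#' indexed by integers to avoid floating drift: 28 `C_L` values, 658 pairs
#' in total). For each pair the cohort is split into low/intermediate/high
#' and three log-rank tests are run (multivariate, low vs intermediate,
#' intermediate vs high). A pair passes when the two pairwise p-values are
#' below `p_pair_max`, no group holds less than `min_frac` of subjects,
#' and no group holds more than `max_frac`. Among passing pairs the one
#' with the lowest multivariate p is returned, ties resolved toward the
#' smallest `C_L`, then smallest `C_H`.
#'
#' @param records survival records with a `hazard` column in `[-1, 1]`.
#' @param c_low_range inclusive-exclusive range for `C_L` (default
#'   `c(-0.9, 0.5)`).
#' @param c_high_max inclusive maximum for `C_H` (default 0.95).
#' @param step grid step (default 0.05).
#' @param p_pair_max pairwise log-rank constraint (default 0.2).
#' @param min_frac,max_frac group-size constraints (defaults 0.1 and 0.5).
#' @return a `CutoffSearchResult`: list with `best` (`NULL` when no pair
#'   passes), `p_multi`, `p_low_int`, `p_int_high`, and `ledger` (one row
#'   per evaluated pair with its pass/fail reason).
#' @export
cutoff_search <- function(records, c_low_range = c(-0.9, 0.5),
                          c_high_max = 0.95, step = 0.05, p_pair_max = 0.2,
                          min_frac = 0.1, max_frac = 0.5) {
  validate_records(records, require_hazard = TRUE)
  n <- nrow(records)
  abort_if(n < 10, "cutoff search needs at least 10 subjects")
  # integer lattice: value = (base + k * s100) / 100
  s100 <- round(step * 100)
  lo <- round(c_low_range[1] * 100)
  hi_open <- round(c_low_range[2] * 100)
  hmax <- round(c_high_max * 100)
  cl_idx <- seq(lo, hi_open - s100, by = s100)
  rows <- list()
  for (cl in cl_idx) {
    for (ch in seq(cl + s100, hmax, by = s100)) {
      c_low <- cl / 100; c_high <- ch / 100
      grp <- assign_risk_groups(records$hazard, c_low, c_high)
      sizes <- table(grp)
      row <- data.frame(C_L = c_low, C_H = c_high,
                        n_low = sizes[["low"]],
                        n_int = sizes[["intermediate"]],
                        n_high = sizes[["high"]],
                        p_multi = NA_real_, p_LI = NA_real_, p_IH = NA_real_,
                        pass = FALSE, reason = "", stringsAsFactors = FALSE)
      if (any(sizes < min_frac * n)) {
        row$reason <- "group below minimum size"
      } else if (any(sizes > max_frac * n)) {
        row$reason <- "group above maximum size"
      } else {
        li <- grp %in% c("low", "intermediate")
        ih <- grp %in% c("intermediate", "high")
        row$p_multi <- log_rank_test(records$time_years, records$event, grp)$p
        row$p_LI <- log_rank_test(records$time_years[li], records$event[li],
                                  grp[li])$p
        row$p_IH <- log_rank_test(records$time_years[ih], records$event[ih],
                                  grp[ih])$p
        if (row$p_LI >= p_pair_max) {
          row$reason <- "low vs intermediate p too high"
        } else if (row$p_IH >= p_pair_max) {
          row$reason <- "intermediate vs high p too high"
        } else {
          row$pass <- TRUE
          row$reason <- "pass"
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  ledger <- do.call(rbind, rows)
  passing <- ledger[ledger$pass, , drop = FALSE]
  if (nrow(passing) == 0) {
    return(structure(list(best = NULL, p_multi = NA_real_,
                          p_low_int = NA_real_, p_int_high = NA_real_,
                          ledger = ledger),
                     class = "CutoffSearchResult"))
  }
  best <- passing[order(passing$p_multi, passing$C_L, passing$C_H), ][1, ]
  structure(list(best = c(C_L = best$C_L, C_H = best$C_H),
                 p_multi = best$p_multi, p_low_int = best$p_LI,
                 p_int_high = best$p_IH, ledger = ledger),
            class = "CutoffSearchResult")
}
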