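test_that("grouped folds are balanced and keep participants intact", {
  plan <- make_group_folds(sprintf("p%02d", 1:36), k = 9, seed = 1)
  expect_equal(as.numeric(table(plan$folds)), rep(4, 9))
  plan2 <- make_group_folds(sprintf("p%02d", 1:75), k = 5, seed = 1)
  expect_equal(as.numeric(table(plan2$folds)), rep(15, 5))
  # each participant appears exactly once
  expect_equal(sort(names(plan$folds)), sprintf("p%02d", 1:36))
  # seed-reproducible and input-order invariant
  plan3 <- make_group_folds(rev(sprintf("p%02d", 1:36)), k = 9, seed = 1)
  expect_identical(plan$folds, plan3$folds)
  expect_error(make_group_folds(letters[1:5], k = 1), "between 2")
  expect_error(make_group_folds(letters[1:5], k = 6), "between 2")
})

test_that("rank-based AUC equals brute-force pairwise counting, ties included", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(41)
  for (i in 1:500) {
    n <- sample(2:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(scores, labels)$auc, ref_auc(scores, labels))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("the ROC curve runs from (0,0) to (1,1) and is monotone", {
  set.seed(43)
  roc <- roc_auc(runif(100), rbinom(100, 1, 0.4))
  cv <- roc$curve
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
})

test_that("rank-based AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  for (i in 1:20) {
    labels <- rbinom(80, 1, 0.5); labels[1:2] <- c(0, 1)
    scores <- round(runif(80), 2)
    expect_equal(roc_auc(scores, labels)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("the Youden threshold maximizes TPR minus FPR with low-FPR ties", {
  scores <- c(0.1, 0.4, 0.35, 0.8); labels <- c(0, 0, 1, 1)
  roc <- roc_auc(scores, labels)
  thr <- optimal_threshold(roc)
  m <- metrics_report(scores, labels, thr)
  expect_equal(m$tpr - m$fpr, ref_best_j(scores, labels))
  # perfect separation reaches J = 1
  roc2 <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  thr2 <- optimal_threshold(roc2)
  expect_gt(thr2, 0.2); expect_lte(thr2, 0.8)
  cv <- roc2$curve
  expect_equal(max(cv$tpr - cv$fpr), 1)
  # constant scores: no skill, J = 0
  roc3 <- roc_auc(rep(0.5, 8), rep(c(0, 1), 4))
  cv3 <- roc3$curve
  expect_equal(max(cv3$tpr - cv3$fpr), 0)
  set.seed(53)
  for (i in 1:100) {
    labels <- rbinom(40, 1, 0.5); labels[1:2] <- c(0, 1)
    scores <- round(runif(40), 1)
    roc <- roc_auc(scores, labels)
    m <- metrics_report(scores, labels, optimal_threshold(roc))
    expect_equal(m$tpr - m$fpr, ref_best_j(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("the metrics battery matches hand-computed confusion arithmetic", {
  # TP=3, FP=1, TN=4, FN=2
  scores <- c(rep(0.9, 3), 0.9, rep(0.1, 4), rep(0.1, 2))
  labels <- c(1, 1, 1, 0, 0, 0, 0, 0, 1, 1)
  m <- metrics_report(scores, labels, threshold = 0.5)
  expect_equal(unname(m$confusion), c(3, 1, 4, 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$tpr, 0.6)
  expect_equal(m$fpr, 0.2)
  expect_equal(m$npv, 2 / 3)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  mcc_ref <- (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6)
  expect_equal(m$mcc, mcc_ref)
})

test_that("perfect and chance-level predictions bracket the metrics", {
  labels <- rep(c(1, 0), 50)
  perfect <- metrics_report(labels, labels, threshold = 0.5)
  expect_equal(perfect$mcc, 1); expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  set.seed(59)
  rand <- metrics_report(runif(4000), rbinom(4000, 1, 0.5), threshold = 0.5)
  expect_lt(abs(rand$mcc), 0.05)
})

test_that("threshold extremes give the ROC curve endpoints", {
  set.seed(61)
  scores <- runif(50); labels <- rbinom(50, 1, 0.5); labels[1:2] <- c(0, 1)
  lo <- metrics_report(scores, labels, threshold = -Inf)
  expect_equal(lo$tpr, 1); expect_equal(lo$fpr, 1)
  hi <- metrics_report(scores, labels, threshold = Inf)
  expect_equal(hi$tpr, 0); expect_equal(hi$fpr, 0)
})

test_that("no-skill accuracy is the rounded majority-class percentage", {
  expect_identical(no_skill_accuracy(376, 711), 53)
  expect_identical(no_skill_accuracy(557, 1508), 63)
  expect_identical(no_skill_accuracy(5, 10), 50)
  expect_identical(no_skill_accuracy(0, 10), 100)
  expect_error(no_skill_accuracy(3, 0), "positive")
  expect_error(no_skill_accuracy(11, 10), "between")
})

test_that("the McNemar statistic uses continuity-corrected discordant counts", {
  # b = c = 10: (|0| - 1)^2 / 20
  a <- c(rep(TRUE, 10), rep(FALSE, 10), TRUE, FALSE)
  b <- c(rep(FALSE, 10), rep(TRUE, 10), TRUE, FALSE)
  t1 <- mcnemar_test(a, b)
  expect_equal(t1$statistic, 0.05)
  # b = 20, c = 5: (15 - 1)^2 / 25
  a2 <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 3))
  b2 <- c(rep(FALSE, 20), rep(TRUE, 5), rep(TRUE, 3))
  t2 <- mcnemar_test(a2, b2)
  expect_equal(t2$statistic, 7.84)
  # agrees with the standard implementation
  tab <- table(factor(a2, c(FALSE, TRUE)), factor(b2, c(FALSE, TRUE)))
  ref <- stats::mcnemar.test(tab, correct = TRUE)
  expect_equal(t2$statistic, unname(ref$statistic))
  expect_equal(t2$p_value, unname(ref$p.value))
  # no discordance: degenerate, p = 1
  t3 <- mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_true(t3$degenerate)
  expect_equal(t3$p_value, 1)
  expect_equal(t3$statistic, 0)
})

test_that("grid tuning returns the argmax with a first-best tie rule", {
  set.seed(67)
  cfg <- default_config("study1"); cfg$n_participants <- 12L
  st <- generate_study(cfg, seed = 3)
  pids <- unique(st$logs$participant_id)
  budget <- tuning_budget("grid", steps = 20)
  res <- tune_parameters(st, model_spec("weighted_br"),
                         train_pids = pids[1:8], test_pids = pids[9:12],
                         budget = budget)
  expect_equal(nrow(res$trace), 20)
  expect_equal(res$best[["gamma"]],
               res$trace$gamma[which.max(res$trace$auc)])
  expect_equal(res$best_auc, max(res$trace$auc, na.rm = TRUE))
  # a single-step budget returns that single draw
  b1 <- tuning_budget("random", steps = 1, seed = 5)
  res1 <- tune_parameters(st, model_spec("theory"), pids[1:8], pids[9:12],
                          b1, fold_seed = 5)
  expect_equal(nrow(res1$trace), 1)
  expect_equal(unname(res1$best), unname(unlist(
    res1$trace[1, c("hdp", "hgp", "adp", "agp_beh", "agp_rem")])))
})

test_that("theory tuning's fast path agrees with feature-table evaluation", {
  cfg <- default_config("study1"); cfg$n_participants <- 10L
  st <- generate_study(cfg, seed = 6)
  pids <- unique(st$logs$participant_id)
  budget <- tuning_budget("random", steps = 8, seed = 2)
  res <- tune_parameters(st, model_spec("theory"), pids[1:7], pids[8:10],
                         budget, fold_seed = 2)
  # independently evaluate each candidate through the public surface
  for (s in seq_len(8)) {
    par <- res$trace[s, c("hdp", "hgp", "adp", "agp_beh", "agp_rem")]
    sp <- model_spec("theory",
                     hp = habit_params(par$hdp, par$hgp),
                     ap = access_params(par$adp, par$agp_beh, par$agp_rem))
    logs <- st$logs[st$logs$participant_id %in% pids[1:10], ]
    tab <- build_feature_table(logs, st$surveys, sp)
    tr <- tab[tab$participant_id %in% pids[1:7], ]
    te <- tab[tab$participant_id %in% pids[8:10], ]
    attr(tr, "features") <- attr(tab, "features")
    fit <- fit_logistic(tr)
    expect_equal(res$trace$auc[s],
                 roc_auc(predict_proba(fit, te), te$target)$auc,
                 tolerance = 1e-10)
  }
})

test_that("nested CV predicts every predictable row exactly once, leak-free", {
  cfg <- default_config("study1"); cfg$n_participants <- 12L
  st <- generate_study(cfg, seed = 7)
  plan <- make_group_folds(st$logs$participant_id, k = 4, seed = 2)
  res <- nested_cv(st, model_spec("past_br"), plan)
  tab <- build_feature_table(st$logs, st$surveys, model_spec("past_br"))
  expect_equal(nrow(res$predictions), nrow(tab))
  expect_equal(anyDuplicated(res$predictions[c("participant_id", "day")]), 0L)
  # every participant's predictions come from the fold it was assigned to
  expect_true(all(res$predictions$fold ==
                    plan$folds[res$predictions$participant_id]))
})

test_that("non-tunable specs reduce to plain grouped k-fold", {
  cfg <- default_config("study1"); cfg$n_participants <- 12L
  st <- generate_study(cfg, seed = 8)
  plan <- make_group_folds(st$logs$participant_id, k = 3, seed = 4)
  res <- nested_cv(st, model_spec("survey"), plan)
  expect_null(res$tuned)
  # manual grouped k-fold gives identical pooled predictions
  tab <- build_feature_table(st$logs, st$surveys, model_spec("survey"))
  manual <- do.call(rbind, lapply(1:3, function(f) {
    te_pids <- names(plan$folds)[plan$folds == f]
    tr <- tab[!(tab$participant_id %in% te_pids), ]
    te <- tab[tab$participant_id %in% te_pids, ]
    attr(tr, "features") <- attr(tab, "features")
    data.frame(participant_id = te$participant_id, day = te$day,
               prob = predict_proba(fit_logistic(tr), te))
  }))
  merged <- merge(res$predictions, manual, by = c("participant_id", "day"))
  expect_equal(merged$prob.x, merged$prob.y, tolerance = 1e-12)
})

test_that("nested CV is deterministic under a fixed plan and budget", {
  cfg <- default_config("study1"); cfg$n_participants <- 12L
  st <- generate_study(cfg, seed = 9)
  plan <- make_group_folds(st$logs$participant_id, k = 3, seed = 5)
  budget <- tuning_budget("random", steps = 25, seed = 3)
  r1 <- nested_cv(st, model_spec("theory"), plan, budget)
  r2 <- nested_cv(st, model_spec("theory"), plan, budget)
  expect_equal(r1$predictions, r2$predictions)
  expect_equal(r1$tuned, r2$tuned)
  expect_true(all(r1$tuned[c("hdp", "hgp", "adp", "agp_beh",
                             "agp_rem")] >= 0))
  expect_true(all(r1$tuned[c("hdp", "hgp", "adp", "agp_beh",
                             "agp_rem")] <= 1))
})

test_that("model comparison produces a full table and symmetric McNemar pairs", {
  cfg <- default_config("study1"); cfg$n_participants <- 15L
  st <- generate_study(cfg, seed = 10)
  plan <- make_group_folds(st$logs$participant_id, k = 3, seed = 6)
  specs <- list(past_br = model_spec("past_br"),
                past_br7 = model_spec("past_br7"),
                survey = model_spec("survey"))
  comp <- compare_models(st, specs, plan)
  expect_equal(nrow(comp$table), 3)
  expect_setequal(names(comp$table),
                  c("model", "auc", "mcc", "accuracy", "tpr", "fpr",
                    "precision", "f1", "npv", "threshold"))
  expect_equal(nrow(comp$mcnemar), 3)
  # a model against itself is a degenerate McNemar with p = 1
  comp2 <- compare_models(st, list(a = model_spec("past_br"),
                                   b = model_spec("past_br")), plan)
  expect_equal(comp2$mcnemar$p_value, 1)
})

test_that("cross-dataset transfer checks schemas and self-transfer is in-sample", {
  cfg <- default_config("study1"); cfg$n_participants <- 12L
  st <- generate_study(cfg, seed = 11)
  res <- cross_dataset_evaluate(st, st, model_spec("past_br"), k = 3)
  tab <- build_feature_table(st$logs, st$surveys, model_spec("past_br"))
  fit <- fit_logistic(tab)
  expect_equal(res$predictions$prob, unname(predict_proba(fit, tab)),
               tolerance = 1e-12)
  # schema mismatch between feature sets is rejected at the fit stage
  st2 <- generate_study(cfg, seed = 12)
  expect_error({
    tr <- build_feature_table(st$logs, st$surveys, model_spec("theory",
      hp = habit_params(0.1, 0.2), ap = access_params(0.3, 0.1, 0.2)))
    fit_t <- fit_logistic(tr)
    te <- build_feature_table(st2$logs, st2$surveys, model_spec("survey"))
    predict_proba(fit_t, te)
  }, "lacks columns")
})
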