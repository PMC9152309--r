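# Two-level hierarchical grouped cross-validation with AUC-driven
# hyperparameter search, ROC/threshold machinery, the classification
# metrics battery, McNemar model comparison, no-skill baselines, and
# cross-dataset transfer.

#' Bundle logs and surveys into a study object
#'
#' @param logs behavior-log data frame (see
#'   \code{\link{build_feature_table}}).
#' @param surveys survey data frame, or \code{NULL}.
#' @return A list of class \code{habit_study}.
#' @export
habit_study <- function(logs, surveys = NULL) {
  stopifnot(is.data.frame(logs),
            all(c("participant_id", "day", "beh") %in% names(logs)))
  structure(list(logs = logs, surveys = surveys), class = "habit_study")
}

#' @export
as_habit_study <- function(x) UseMethod("as_habit_study")
#' @export
as_habit_study.habit_study <- function(x) x
#' @export
as_habit_study.habit_synth_study <- function(x) habit_study(x$logs, x$surveys)

#' Participant-grouped fold assignment
#'
#' Randomly partitions participants into \code{k} folds of sizes
#' differing by at most one, so that any one participant's days are
#' always confined to a single fold. The assignment depends only on
#' the sorted set of participant ids and the seed, not on input order.
#'
#' @param participants vector of participant ids (duplicates allowed).
#' @param k number of folds, between 2 and the number of distinct
#'   participants.
#' @param seed integer seed for the shuffle.
#' @return A list of class \code{habit_cv_plan} with \code{k},
#'   \code{seed}, and \code{folds} (named integer vector: fold index
#'   per participant).
#' @export
make_group_folds <- function(participants, k, seed = 1L) {
  pids <- sort(unique(as.character(participants)))
  if (k < 2L || k > length(pids))
    stop("'k' must be between 2 and the number of participants",
         call. = FALSE)
  set.seed(seed)
  shuffled <- sample(pids)
  folds <- setNames(rep(seq_len(k), length.out = length(pids)), shuffled)
  structure(list(k = k, seed = seed, folds = folds[pids]),
            class = "habit_cv_plan")
}

#' Search budget for hyperparameter tuning
#'
#' @param method \code{"random"} (each tunable drawn from U(0,1) per
#'   step, used for the five dynamics parameters) or \code{"grid"}
#'   (used for the discount \eqn{\gamma}, default grid 0.01..1.00 by
#'   0.01).
#' @param steps number of search steps (defines the grid resolution or
#'   random draws).
#' @param seed seed for the random draws.
#' @param grid optional explicit grid of values for \code{"grid"}.
#' @return A list of class \code{habit_tuning_budget}.
#' @export
tuning_budget <- function(method = c("random", "grid"), steps = NULL,
                          seed = 1L, grid = NULL) {
  method <- match.arg(method)
  if (is.null(steps)) steps <- if (method == "random") 1000L else 100L
  if (steps <= 0) stop("'steps' must be positive", call. = FALSE)
  if (method == "grid" && is.null(grid)) grid <- seq_len(steps) / steps
  structure(list(method = method, steps = as.integer(steps),
                 seed = as.integer(seed), grid = grid),
            class = "habit_tuning_budget")
}

#' Rank-based AUC with ROC curve
#'
#' Area under the ROC curve computed from midranks (equivalent to the
#' Mann-Whitney statistic), so tied scores receive half credit. Also
#' returns the full curve: one \code{(fpr, tpr)} point per distinct
#' threshold, where a case is called positive when its score is
#' \eqn{\ge} the threshold.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels (1 = positive).
#' @return A list of class \code{habit_roc} with \code{auc} and
#'   \code{curve} (data frame \code{threshold}, \code{fpr},
#'   \code{tpr}).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("undefined metric: both classes must be present", call. = FALSE)
  r <- rank(scores)                       # midranks give ties half credit
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(x) sum(scores >= x & labels == 1L), numeric(1))
  fp <- vapply(thr, function(x) sum(scores >= x & labels == 0L), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(auc = auc, curve = curve), class = "habit_roc")
}

#' @export
print.habit_roc <- function(x, ...) {
  cat("<habit_roc> AUC =", round(x$auc, 4), "over",
      nrow(x$curve) - 1L, "distinct thresholds\n")
  invisible(x)
}

#' Youden-optimal classification threshold
#'
#' Chooses the threshold maximizing Youden's \eqn{J = TPR - FPR} over
#' the ROC curve; among ties the point with the lower FPR (the more
#' conservative classifier) wins.
#'
#' @param roc a \code{habit_roc} object from \code{\link{roc_auc}}.
#' @return The threshold value (a score; predictions \eqn{\ge} it are
#'   positive).
#' @export
optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "habit_roc"))
  cv <- roc$curve
  j <- cv$tpr - cv$fpr
  best <- which(j == max(j))
  best <- best[which.min(cv$fpr[best])]
  cv$threshold[best]
}

#' Classification metrics at a threshold
#'
#' Confusion-matrix metrics for scores dichotomized at
#' \code{threshold} (score \eqn{\ge} threshold = positive): Matthews
#' correlation, accuracy, TPR, FPR, precision, F1, and negative
#' predictive value, together with the rank-based AUC of the raw
#' scores. Ratios with zero denominators are reported as \code{NA} and
#' flagged.
#'
#' @param scores prediction scores.
#' @param labels binary labels (1 = positive).
#' @param threshold classification threshold; defaults to the
#'   Youden-optimal one.
#' @return A list of class \code{habit_metrics}.
#' @export
metrics_report <- function(scores, labels, threshold = NULL) {
  roc <- roc_auc(scores, labels)
  if (is.null(threshold)) threshold <- optimal_threshold(roc)
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tpr <- safe_div(tp, tp + fn); fpr <- safe_div(fp, fp + tn)
  prec <- safe_div(tp, tp + fp); npv <- safe_div(tn, tn + fn)
  f1 <- if (is.na(prec) || is.na(tpr) || prec + tpr == 0) NA_real_
        else 2 * prec * tpr / (prec + tpr)
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
             sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (mcc_den == 0) NA_real_
         else (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  structure(list(
    auc = roc$auc, mcc = mcc,
    accuracy = (tp + tn) / length(labels),
    tpr = tpr, fpr = fpr, precision = prec, f1 = f1, npv = npv,
    threshold = threshold,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    undefined = c(tpr = is.na(tpr), fpr = is.na(fpr),
                  precision = is.na(prec), npv = is.na(npv))),
    class = "habit_metrics")
}

#' @export
print.habit_metrics <- function(x, ...) {
  v <- unlist(x[c("auc", "mcc", "accuracy", "tpr", "fpr", "precision",
                  "f1", "npv", "threshold")])
  print(round(v, 4))
  invisible(x)
}

#' Accuracy of the majority-class no-skill model
#'
#' The accuracy (as a rounded percentage) of a classifier that always
#' predicts the majority class -- the class-prevalence baseline every
#' fitted model must beat.
#'
#' @param n_positive number of positive cases.
#' @param n_total total number of cases.
#' @return Integer percentage.
#' @examples
#' no_skill_accuracy(376, 711)   # 53
#' no_skill_accuracy(557, 1508)  # 63
#' @export
no_skill_accuracy <- function(n_positive, n_total) {
  if (n_total <= 0) stop("'n_total' must be positive", call. = FALSE)
  if (n_positive < 0 || n_positive > n_total)
    stop("'n_positive' must be between 0 and 'n_total'", call. = FALSE)
  round(100 * max(n_positive, n_total - n_positive) / n_total)
}

#' McNemar test between two paired classifiers
#'
#' Tests whether two models' correct/incorrect predictions on the same
#' observations are compatible with the models being equally good,
#' using the continuity-corrected statistic
#' \eqn{\chi^2 = (|b - c| - 1)^2 / (b + c)} on the discordant counts
#' \eqn{b} (A correct, B wrong) and \eqn{c} (A wrong, B correct), with
#' one degree of freedom.
#'
#' @param correct_a,correct_b logical/binary vectors: per-row
#'   correctness of models A and B on the same rows.
#' @return A list with \code{b}, \code{c}, \code{statistic},
#'   \code{p_value}, and \code{degenerate} (\code{TRUE} when there is
#'   no discordant pair, in which case the statistic is 0 and p is 1).
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  a <- as.logical(correct_a); b_ <- as.logical(correct_b)
  b <- sum(a & !b_); cc <- sum(!a & b_)
  if (b + cc == 0L)
    return(list(b = b, c = cc, statistic = 0, p_value = 1,
                degenerate = TRUE))
  stat <- (abs(b - cc) - 1)^2 / (b + cc)
  list(b = b, c = cc, statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

# --- nested cross-validation ------------------------------------------------

.spec_is_tunable <- function(spec) spec$name %in% c("weighted_br", "theory")

# Materialize a spec with concrete parameter values.
.spec_with_params <- function(spec, par) {
  if (spec$name == "theory")
    model_spec("theory",
               hp = habit_params(par[["hdp"]], par[["hgp"]]),
               ap = access_params(par[["adp"]], par[["agp_beh"]],
                                  par[["agp_rem"]]))
  else if (spec$name == "weighted_br")
    model_spec("weighted_br", gamma = par[["gamma"]])
  else spec
}

# Candidate parameter draws for one tuning run.
.tuning_candidates <- function(spec, budget, fold_seed) {
  if (spec$name == "theory") {
    if (budget$method != "random")
      stop("theory parameters are tuned by random search", call. = FALSE)
    set.seed(fold_seed)
    m <- matrix(runif(budget$steps * 5L), ncol = 5L,
                dimnames = list(NULL, c("hdp", "hgp", "adp", "agp_beh",
                                        "agp_rem")))
    m
  } else if (spec$name == "weighted_br") {
    if (budget$method != "grid")
      stop("gamma is tuned by grid search", call. = FALSE)
    matrix(budget$grid, ncol = 1L, dimnames = list(NULL, "gamma"))
  } else {
    stop("spec '", spec$name, "' has no tunable parameters", call. = FALSE)
  }
}

# AUC value alone (midrank formula), skipping curve construction; the
# tuning loop calls this thousands of times.
.auc_value <- function(scores, labels) {
  n_pos <- sum(labels == 1L); n_neg <- length(labels) - n_pos
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Quiet logistic fit returning the coefficient vector (or NULL when the
# fit is impossible); separation warnings are tolerated here because a
# poorly separated candidate simply scores a poor inner AUC.
.fit_beta_quiet <- function(X, y, ridge = 0) {
  if (length(unique(y)) < 2L) return(NULL)
  beta <- tryCatch(
    if (ridge > 0) .fit_logit_ridge(X, y, ridge)$beta
    else suppressWarnings(glm.fit(X, y, family = binomial())$coefficients),
    error = function(e) NULL)
  if (!is.null(beta)) beta[is.na(beta)] <- 0   # aliased columns
  beta
}

# Precomputed structures for repeated theory-model evaluation: the wide
# behavior/reminder matrices, initial states, and the row index of every
# predictable participant-day.
.theory_context <- function(logs, surveys, default_hs0 = 0) {
  wide <- .log_matrices(logs)
  base <- .baseline_surveys(surveys, wide$pids)
  hs1 <- (base$srbai - 1) / 6
  hs1[is.na(hs1)] <- default_hs0
  n <- length(wide$pids); T <- wide$T
  grid <- expand.grid(pid_idx = seq_len(n), day = 2:T,
                      KEEP.OUT.ATTRS = FALSE)
  target <- 1 - wide$beh[cbind(grid$pid_idx, grid$day)]
  keep <- !is.na(target)
  list(wide = wide, hs1 = hs1, rem_eff = pmax(wide$rem, wide$lab),
       pid = wide$pids[grid$pid_idx[keep]],
       idx = cbind(grid$pid_idx, grid$day)[keep, , drop = FALSE],
       target = as.numeric(target[keep]))
}

# Design matrix (intercept, hs, acc) for one candidate parameter vector.
.theory_design <- function(ctx, par) {
  st <- .propagate_states(
    ctx$wide$beh, ctx$wide$cue, ctx$rem_eff, ctx$hs1,
    rep(1, nrow(ctx$wide$beh)),
    hp = list(hdp = par[["hdp"]], hgp = par[["hgp"]]),
    ap = list(adp = par[["adp"]], agp_beh = par[["agp_beh"]],
              agp_rem = par[["agp_rem"]]))
  cbind(1, st$hs[ctx$idx], st$acc[ctx$idx])
}

# Fit on train rows, return AUC of predictions on test rows (NA when
# the fit or metric is undefined).
.fit_and_auc <- function(train_rows, test_rows, features, ridge = 0) {
  attr(train_rows, "features") <- features
  fit <- tryCatch(fit_logistic(train_rows, ridge = ridge),
                  error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  p <- predict_proba(fit, test_rows)
  tryCatch(roc_auc(p, test_rows$target)$auc, error = function(e) NA_real_)
}

#' Tune a model's free parameters on inner train/test splits
#'
#' Evaluates each candidate parameter vector by computing the feature
#' table under it, fitting the classifier on the inner-training
#' participants, and scoring AUC on the inner-test participants. A
#' candidate's score is the mean AUC across the supplied inner splits
#' (a single split reproduces the one-reserved-group scheme; the
#' default inside \code{\link{nested_cv}} rotates the reserved group
#' over all training folds). The first candidate achieving the maximal
#' score wins (a deterministic tie-break). Used internally by
#' \code{\link{nested_cv}} and \code{\link{cross_dataset_evaluate}},
#' but exported for tuning-curve inspection.
#'
#' @param study a \code{habit_study} (or synthetic study).
#' @param spec a tunable \code{\link{model_spec}} (\code{"theory"} or
#'   \code{"weighted_br"}).
#' @param train_pids,test_pids participant ids of the inner training
#'   and inner test groups (convenience for a single split; ignored
#'   when \code{splits} is given).
#' @param budget a \code{\link{tuning_budget}}.
#' @param fold_seed seed for the candidate draws.
#' @param ridge optional ridge stabilizer passed to the inner fits.
#' @param splits optional list of inner splits, each a list with
#'   \code{train} and \code{test} participant-id vectors.
#' @return A list with \code{best} (named parameter vector),
#'   \code{best_auc}, and \code{trace} (data frame of all candidates
#'   and their mean inner AUC).
#' @export
tune_parameters <- function(study, spec, train_pids = NULL,
                            test_pids = NULL, budget,
                            fold_seed = budget$seed, ridge = 0,
                            splits = NULL) {
  study <- as_habit_study(study)
  if (is.null(splits)) {
    if (is.null(train_pids) || is.null(test_pids))
      stop("supply either 'splits' or train/test participant ids",
           call. = FALSE)
    splits <- list(list(train = train_pids, test = test_pids))
  }
  cand <- .tuning_candidates(spec, budget, fold_seed)
  aucs <- numeric(nrow(cand))
  sub_pids <- unique(unlist(splits))
  logs <- study$logs[study$logs$participant_id %in% sub_pids, ]
  surveys <- if (!is.null(study$surveys))
    study$surveys[study$surveys$participant_id %in% sub_pids, ] else NULL
  if (spec$name == "theory") {
    ctx <- .theory_context(logs, surveys)
    masks <- lapply(splits, function(sp)
      list(tr = ctx$pid %in% sp$train, te = ctx$pid %in% sp$test))
    for (s in seq_len(nrow(cand))) {
      X <- .theory_design(ctx, cand[s, ])
      vals <- vapply(masks, function(m) {
        beta <- .fit_beta_quiet(X[m$tr, , drop = FALSE],
                                ctx$target[m$tr], ridge)
        if (is.null(beta)) return(NA_real_)
        .auc_value(plogis(drop(X[m$te, , drop = FALSE] %*% beta)),
                   ctx$target[m$te])
      }, numeric(1))
      aucs[s] <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }
  } else {
    for (s in seq_len(nrow(cand))) {
      sp_par <- .spec_with_params(spec, cand[s, ])
      tab <- build_feature_table(logs, surveys, sp_par)
      vals <- vapply(splits, function(sp) {
        tr <- tab[tab$participant_id %in% sp$train, ]
        te <- tab[tab$participant_id %in% sp$test, ]
        .fit_and_auc(tr, te, attr(tab, "features"), ridge)
      }, numeric(1))
      aucs[s] <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }
  }
  if (all(is.na(aucs)))
    stop("tuning failed: no candidate produced a valid fit", call. = FALSE)
  best <- which.max(aucs)   # first maximum wins
  list(best = cand[best, ], best_auc = aucs[best],
       trace = data.frame(cand, auc = aucs))
}

#' Nested participant-grouped cross-validation
#'
#' The outer loop holds out one fold of participants for testing and
#' trains on the remaining \eqn{k - 1} folds. For tunable models the
#' training folds are split again: one fold (the next in cyclic order)
#' becomes the inner tuning-test group and the other \eqn{k - 2} folds
#' the inner training group; the free parameters maximizing inner-test
#' AUC are then used to refit on all \eqn{k - 1} training folds before
#' predicting the held-out fold. Out-of-fold predictions are pooled
#' across the outer folds, covering every predictable row exactly
#' once.
#'
#' @param study a \code{habit_study} or synthetic study.
#' @param spec a \code{\link{model_spec}}; non-tunable specs skip the
#'   inner loop.
#' @param plan a \code{\link{make_group_folds}} plan over the study's
#'   participants.
#' @param budget a \code{\link{tuning_budget}} (required for tunable
#'   specs).
#' @param ridge optional ridge stabilizer for fold fits.
#' @param keep_trace keep each fold's full tuning trace (for
#'   tuning-curve plots).
#' @param inner \code{"rotate"} (default) scores a candidate by its
#'   mean AUC over all \eqn{k - 1} inner splits, each reserving one
#'   training fold in turn; \code{"single"} reserves only the next
#'   fold in cyclic order. Rotation averages away the selection noise
#'   a single small tuning-test group produces on plateaued
#'   objectives.
#' @return A list of class \code{habit_cv_result} with
#'   \code{predictions} (pooled out-of-fold: participant, day, fold,
#'   prob, label), \code{tuned} (per-fold tuned parameters and inner
#'   AUC), \code{mean_params}, and optionally \code{traces}.
#' @export
nested_cv <- function(study, spec, plan, budget = NULL, ridge = 0,
                      keep_trace = FALSE, inner = c("rotate", "single")) {
  inner <- match.arg(inner)
  study <- as_habit_study(study)
  stopifnot(inherits(plan, "habit_cv_plan"))
  tunable <- .spec_is_tunable(spec)
  if (tunable && is.null(budget))
    stop("tunable spec needs a tuning budget", call. = FALSE)
  folds <- plan$folds
  k <- plan$k
  preds <- vector("list", k); tuned <- vector("list", k)
  traces <- if (keep_trace) vector("list", k) else NULL
  fixed_tab <- if (!tunable) build_feature_table(study$logs, study$surveys,
                                                 spec) else NULL
  for (f in seq_len(k)) {
    test_pids <- names(folds)[folds == f]
    train_folds <- setdiff(seq_len(k), f)
    par <- NULL
    if (tunable) {
      inner_test_folds <- if (inner == "rotate") train_folds
                          else if ((f %% k + 1L) %in% train_folds) f %% k + 1L
                          else train_folds[1L]
      splits <- lapply(inner_test_folds, function(g)
        list(train = names(folds)[folds %in% setdiff(train_folds, g)],
             test = names(folds)[folds == g]))
      fold_seed <- (as.numeric(budget$seed) + f * 9973) %% .MAXINT
      tune <- tune_parameters(study, spec, budget = budget,
                              fold_seed = fold_seed, ridge = ridge,
                              splits = splits)
      par <- tune$best
      tuned[[f]] <- data.frame(fold = f, t(par), inner_auc = tune$best_auc)
      if (keep_trace) traces[[f]] <- cbind(fold = f, tune$trace)
    }
    sp <- if (tunable) .spec_with_params(spec, par) else spec
    tab <- if (tunable) build_feature_table(study$logs, study$surveys, sp)
           else fixed_tab
    tr <- tab[!(tab$participant_id %in% test_pids), ]
    te <- tab[tab$participant_id %in% test_pids, ]
    if (nrow(te) == 0L) {
      warning("fold ", f, " has no predictable rows; skipped", call. = FALSE)
      next
    }
    attr(tr, "features") <- attr(tab, "features")
    fit <- fit_logistic(tr, ridge = ridge)
    preds[[f]] <- data.frame(participant_id = te$participant_id,
                             day = te$day, fold = f,
                             prob = predict_proba(fit, te),
                             label = te$target)
  }
  tuned <- if (tunable) do.call(rbind, tuned) else NULL
  mean_params <- if (tunable)
    colMeans(tuned[, setdiff(names(tuned), c("fold", "inner_auc")),
                   drop = FALSE]) else NULL
  structure(list(spec = spec$name, predictions = do.call(rbind, preds),
                 tuned = tuned, mean_params = mean_params,
                 traces = if (keep_trace) do.call(rbind, traces) else NULL,
                 plan = plan),
            class = "habit_cv_result")
}

#' @export
print.habit_cv_result <- function(x, ...) {
  cat("<habit_cv_result>", x$spec, "-", nrow(x$predictions),
      "pooled out-of-fold predictions over", x$plan$k, "folds\n")
  if (!is.null(x$mean_params)) {
    cat("  mean tuned parameters:\n")
    print(round(x$mean_params, 3))
  }
  invisible(x)
}

#' Cross-dataset transfer evaluation
#'
#' Trains a model on one full study and evaluates it once on another.
#' Tunable parameters are chosen by plain participant-grouped k-fold
#' cross-validation on the whole training study (pooled out-of-fold
#' AUC as the objective), after which the model is refit on all
#' training data and applied to the test study.
#'
#' @param train_study,test_study \code{habit_study} (or synthetic
#'   study) objects with matching schemas.
#' @param spec a \code{\link{model_spec}}.
#' @param k folds for the tuning cross-validation on the training
#'   study.
#' @param budget a \code{\link{tuning_budget}} for tunable specs.
#' @param seed seed for fold assignment and candidate draws.
#' @param ridge optional ridge stabilizer.
#' @return A list with \code{metrics} (a \code{habit_metrics} on the
#'   test study), \code{tuned} parameters (or \code{NULL}), and the
#'   test-set \code{predictions}.
#' @export
cross_dataset_evaluate <- function(train_study, test_study, spec, k = 5L,
                                   budget = NULL, seed = 1L, ridge = 0) {
  train_study <- as_habit_study(train_study)
  test_study <- as_habit_study(test_study)
  par <- NULL
  if (.spec_is_tunable(spec)) {
    if (is.null(budget))
      stop("tunable spec needs a tuning budget", call. = FALSE)
    plan <- make_group_folds(train_study$logs$participant_id, k, seed)
    cand <- .tuning_candidates(spec, budget,
                               (as.numeric(budget$seed) + 7L) %% .MAXINT)
    aucs <- numeric(nrow(cand))
    if (spec$name == "theory") {
      ctx <- .theory_context(train_study$logs, train_study$surveys)
      fold_of_row <- plan$folds[ctx$pid]
      for (s in seq_len(nrow(cand))) {
        X <- .theory_design(ctx, cand[s, ])
        prob <- rep(NA_real_, length(ctx$target))
        for (f in seq_len(k)) {
          te <- fold_of_row == f
          beta <- .fit_beta_quiet(X[!te, , drop = FALSE],
                                  ctx$target[!te], ridge)
          if (!is.null(beta))
            prob[te] <- plogis(drop(X[te, , drop = FALSE] %*% beta))
        }
        ok <- !is.na(prob)
        aucs[s] <- .auc_value(prob[ok], ctx$target[ok])
      }
    } else {
      for (s in seq_len(nrow(cand))) {
        sp <- .spec_with_params(spec, cand[s, ])
        tab <- build_feature_table(train_study$logs, train_study$surveys, sp)
        pooled <- lapply(seq_len(k), function(f) {
          te_pids <- names(plan$folds)[plan$folds == f]
          tr <- tab[!(tab$participant_id %in% te_pids), ]
          te <- tab[tab$participant_id %in% te_pids, ]
          attr(tr, "features") <- attr(tab, "features")
          fit <- tryCatch(fit_logistic(tr, ridge = ridge),
                          error = function(e) NULL)
          if (is.null(fit)) return(NULL)
          data.frame(prob = predict_proba(fit, te), label = te$target)
        })
        pooled <- do.call(rbind, pooled)
        aucs[s] <- if (is.null(pooled)) NA_real_
                   else tryCatch(roc_auc(pooled$prob, pooled$label)$auc,
                                 error = function(e) NA_real_)
      }
    }
    par <- cand[which.max(aucs), ]
  }
  sp <- if (is.null(par)) spec else .spec_with_params(spec, par)
  train_tab <- build_feature_table(train_study$logs, train_study$surveys, sp)
  test_tab <- build_feature_table(test_study$logs, test_study$surveys, sp)
  if (!setequal(attr(train_tab, "features"), attr(test_tab, "features")))
    stop("feature schema mismatch between studies", call. = FALSE)
  fit <- fit_logistic(train_tab, ridge = ridge)
  prob <- predict_proba(fit, test_tab)
  list(metrics = metrics_report(prob, test_tab$target),
       tuned = par,
       predictions = data.frame(participant_id = test_tab$participant_id,
                                day = test_tab$day, prob = prob,
                                label = test_tab$target))
}

#' Compare several model specifications on one study
#'
#' Runs \code{\link{nested_cv}} for every specification, computes each
#' model's metrics from its pooled out-of-fold predictions at its own
#' Youden-optimal threshold, and performs all pairwise McNemar tests
#' on the per-row correctness vectors (each model judged at its own
#' threshold).
#'
#' @param study a \code{habit_study} or synthetic study.
#' @param specs named list of \code{\link{model_spec}} objects.
#' @param plan a \code{\link{make_group_folds}} plan.
#' @param budgets named list of \code{\link{tuning_budget}}s for the
#'   tunable specs (names matching \code{specs}).
#' @param ridge optional ridge stabilizer.
#' @return A list of class \code{habit_comparison} with \code{table}
#'   (one metrics row per model), \code{mcnemar} (data frame of
#'   pairwise tests), and \code{results} (the per-spec
#'   \code{habit_cv_result}s).
#' @export
compare_models <- function(study, specs, plan, budgets = list(), ridge = 0) {
  if (length(specs) < 2L) stop("need at least 2 specs", call. = FALSE)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$name, character(1))
  results <- lapply(names(specs), function(nm)
    nested_cv(study, specs[[nm]], plan, budget = budgets[[nm]],
              ridge = ridge))
  names(results) <- names(specs)
  rows <- list(); correct <- list()
  for (nm in names(results)) {
    pr <- results[[nm]]$predictions
    m <- metrics_report(pr$prob, pr$label)
    rows[[nm]] <- data.frame(model = nm, auc = m$auc, mcc = m$mcc,
                             accuracy = m$accuracy, tpr = m$tpr,
                             fpr = m$fpr, precision = m$precision,
                             f1 = m$f1, npv = m$npv,
                             threshold = m$threshold)
    key <- paste(pr$participant_id, pr$day)
    correct[[nm]] <- setNames((pr$prob >= m$threshold) == (pr$label == 1),
                              key)
  }
  pairs <- utils::combn(names(results), 2L)
  mc <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- correct[[pairs[1L, j]]]; b <- correct[[pairs[2L, j]]]
    common <- intersect(names(a), names(b))
    t <- mcnemar_test(a[common], b[common])
    data.frame(model_a = pairs[1L, j], model_b = pairs[2L, j],
               b = t$b, c = t$c, statistic = t$statistic,
               p_value = t$p_value)
  })
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 mcnemar = do.call(rbind, mc),
                 results = results),
            class = "habit_comparison")
}

#' @export
print.habit_comparison <- function(x, ...) {
  cat("<habit_comparison>\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
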