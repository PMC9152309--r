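# Independent reference implementations used as oracles. These stay
# deliberately naive and separate from the package's code paths.

# Literal transcription of the habit-strength update.
ref_step_habit <- function(hs, beh, cue, hdp, hgp) {
  hs - hs * hdp + (1 - hs) * beh * cue * hgp
}

# Literal transcription of the accessibility update (with the same
# clamp the package applies).
ref_step_access <- function(acc, beh, rem, adp, agp_beh, agp_rem) {
  v <- acc - acc * adp + (1 - acc) * (beh * agp_beh + rem * agp_rem)
  min(1, max(0, v))
}

# Brute-force AUC: average pairwise comparison over all
# positive-negative pairs, ties worth one half.
ref_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Exhaustive Youden scan over all candidate thresholds.
ref_best_j <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  j <- vapply(thr, function(t) {
    pred <- scores >= t
    tpr <- sum(pred & labels == 1) / sum(labels == 1)
    fpr <- sum(pred & labels == 0) / sum(labels == 0)
    tpr - fpr
  }, numeric(1))
  max(j)
}

# Tiny deterministic behavior log for feature tests: 2 participants,
# 8 days, one unobserved day each.
tiny_logs <- function() {
  data.frame(
    participant_id = rep(c("a", "b"), each = 8),
    day = rep(1:8, 2),
    beh = c(1, 1, 0, NA, 1, 0, 1, 1,
            0, 0, 1, 1, NA, 1, 0, 0),
    cue = 1,
    rem = rep(c(1, 1, 0, 0, 1, 0, 0, 0), 2),
    lab = rep(c(1, 0, 0, 0, 0, 0, 0, 0), 2))
}

tiny_surveys <- function() {
  data.frame(
    participant_id = rep(c("a", "b"), each = 2),
    day = rep(c(1, 7), 2),
    srbai = c(2.5, 4.0, 1.0, 3.0),
    att_instrumental = c(5, 5.5, 4, 4.5),
    att_affective = c(4, 4.5, 3, 3.5),
    self_report_rate = c(0.25, 0.6, 0.4, 0.3))
}

# Strong habit-to-behavior coupling configuration used for recovery
# experiments: behavior is driven almost entirely by habit strength.
recovery_config <- function() {
  cfg <- default_config("study2")
  cfg$coefs <- c(intercept = -2.0, weight_hs = 6.0, weight_acc = 1.0,
                 weight_individual = 0.5)
  cfg
}
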