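# Feature construction for one-step-ahead prediction of next-day
# non-adherence: survey features, past behavior rates (full-history,
# 7-day, discounted), and theory-derived latent states.

#' Cumulative past behavior rate
#'
#' Mean of the observed behavior indicators over all days before the
#' day being predicted. Unobserved (\code{NA}) days are excluded from
#' numerator and denominator. With no observed past day the
#' self-reported prior-week rate serves as the initial value.
#'
#' @param history binary vector of past behavior indicators (may contain
#'   \code{NA}); element \code{i} is day \code{i}, the last element the
#'   most recent day.
#' @param init_rate proportion in \eqn{[0, 1]} used when no past day is
#'   observed.
#' @return Proportion in \eqn{[0, 1]}.
#' @examples
#' past_br(c(1, 1, 0, 1))           # 0.75
#' past_br(c(1, NA, 0))             # 0.5
#' past_br(numeric(0), init_rate = 0.5)
#' @export
past_br <- function(history, init_rate = 0.5) {
  .check_unit(init_rate, "init_rate")
  obs <- history[!is.na(history)]
  if (length(obs) == 0L) return(init_rate)
  mean(obs)
}

#' Behavior rate over the last seven days
#'
#' Like \code{\link{past_br}} but restricted to the seven most recent
#' days. With fewer than seven past days it reduces to the full-history
#' rate; if all days in the window are unobserved it falls back to the
#' full-history rate as well.
#'
#' @inheritParams past_br
#' @return Proportion in \eqn{[0, 1]}.
#' @export
past_br7 <- function(history, init_rate = 0.5) {
  n <- length(history)
  if (n <= 7L) return(past_br(history, init_rate))
  window <- history[(n - 6L):n]
  if (all(is.na(window))) return(past_br(history, init_rate))
  mean(window, na.rm = TRUE)
}

#' Temporally discounted past behavior rate
#'
#' Weights past behavior by recency with a geometric discount:
#' \deqn{\sum_{i=1}^{t-1} B_i \, \gamma^{(t-i)} / (t-1)}
#' where \eqn{B_i} is the behavior indicator on day \eqn{i} and the
#' denominator counts past days. Unobserved days drop out of both sum
#' and count; with no observed past day the initial rate is returned.
#' Note the denominator is the day count, not the sum of weights, so
#' the feature shrinks as history grows; at \eqn{\gamma = 1} and full
#' observation it equals \code{\link{past_br}}.
#'
#' @param history binary vector of the \eqn{t-1} past behavior
#'   indicators (\code{NA} = unobserved).
#' @param gamma discount factor in \eqn{(0, 1]}.
#' @inheritParams past_br
#' @return Non-negative value bounded by \eqn{\gamma}.
#' @examples
#' weighted_br(c(1), gamma = 0.5)      # 0.5
#' weighted_br(c(1, 1), gamma = 0.5)   # 0.375
#' @export
weighted_br <- function(history, gamma, init_rate = 0.5) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma <= 0 || gamma > 1)
    stop("'gamma' must be in (0, 1]", call. = FALSE)
  .check_unit(init_rate, "init_rate")
  t <- length(history) + 1L
  obs <- which(!is.na(history))
  if (length(obs) == 0L) return(init_rate)
  sum(history[obs] * gamma^(t - obs)) / length(obs)
}

#' Latent-state features from a behavior log
#'
#' Propagates habit strength and memory accessibility through one
#' participant's log. The initial habit strength is the baseline
#' self-reported automaticity rescaled from the 1-7 scale to
#' \eqn{[0, 1]} via \eqn{(srbai - 1)/6}; initial accessibility is 1
#' (the behavior has just been introduced, so it is maximally
#' accessible). The row for day \eqn{t} holds the state \emph{entering}
#' day \eqn{t}, i.e. after the day-\eqn{(t-1)} update -- exactly the
#' information available for a one-step forecast of day \eqn{t}.
#' Unobserved days freeze the state. Reminders effective for
#' accessibility include laboratory-session contacts
#' (\code{rem = max(rem, lab)}).
#'
#' @param log data frame for one participant with columns \code{day},
#'   \code{beh} (binary, \code{NA} = unobserved), and optionally
#'   \code{cue} (default 1), \code{rem}, \code{lab} (default 0).
#' @param initial_srbai baseline automaticity on the 1-7 scale;
#'   \code{NA} falls back to \code{default_hs0} with a warning.
#' @param hp a \code{\link{habit_params}} object.
#' @param ap an \code{\link{access_params}} object.
#' @param default_hs0 initial habit strength used when no baseline
#'   survey exists; 0 by default (a new behavior carries no habit).
#' @return Data frame with columns \code{day} (1..T+1), \code{hs},
#'   \code{acc}; row \code{t} is the state entering day \code{t}.
#' @export
theory_features <- function(log, initial_srbai, hp, ap, default_hs0 = 0) {
  stopifnot(is.data.frame(log), "beh" %in% names(log))
  if (is.null(log$cue)) log$cue <- 1
  if (is.null(log$rem)) log$rem <- 0
  if (is.null(log$lab)) log$lab <- 0
  if (is.na(initial_srbai)) {
    warning("missing baseline automaticity; initial habit strength set to ",
            default_hs0, call. = FALSE)
    hs1 <- default_hs0
  } else {
    if (initial_srbai < 1 || initial_srbai > 7)
      stop("'initial_srbai' must be on the 1-7 scale", call. = FALSE)
    hs1 <- (initial_srbai - 1) / 6
  }
  states <- .propagate_states(
    beh = matrix(log$beh, nrow = 1L),
    cue = matrix(log$cue, nrow = 1L),
    rem = matrix(pmax(log$rem, log$lab), nrow = 1L),
    hs1 = hs1, acc1 = 1, hp = hp, ap = ap)
  data.frame(day = seq_len(ncol(states$hs)),
             hs = states$hs[1L, ], acc = states$acc[1L, ])
}

#' Model specification for one of the five feature sets
#'
#' @param name one of \code{"survey"}, \code{"past_br"},
#'   \code{"past_br7"}, \code{"weighted_br"}, \code{"theory"}.
#' @param gamma discount factor for the \code{"weighted_br"} model.
#' @param hp,ap dynamics parameters for the \code{"theory"} model.
#' @return An object of class \code{habit_model_spec}.
#' @export
model_spec <- function(name = c("survey", "past_br", "past_br7",
                                "weighted_br", "theory"),
                       gamma = NULL, hp = NULL, ap = NULL) {
  name <- match.arg(name)
  if (name == "weighted_br" && !is.null(gamma) &&
      (gamma <= 0 || gamma > 1))
    stop("'gamma' must be in (0, 1]", call. = FALSE)
  if (name == "theory") {
    if (!is.null(hp)) stopifnot(inherits(hp, "habit_params"))
    if (!is.null(ap)) stopifnot(inherits(ap, "access_params"))
  }
  structure(list(name = name, gamma = gamma, hp = hp, ap = ap),
            class = "habit_model_spec")
}

#' @export
print.habit_model_spec <- function(x, ...) {
  cat("<habit_model_spec>", x$name, "\n")
  if (!is.null(x$gamma)) cat("  gamma:", x$gamma, "\n")
  if (!is.null(x$hp)) cat("  habit params: hdp =", x$hp$hdp,
                          " hgp =", x$hp$hgp, "\n")
  if (!is.null(x$ap)) cat("  access params: adp =", x$ap$adp,
                          " agp_beh =", x$ap$agp_beh,
                          " agp_rem =", x$ap$agp_rem, "\n")
  invisible(x)
}

# Wide participant x day matrices from a long behavior log.
.log_matrices <- function(logs) {
  pids <- sort(unique(logs$participant_id))
  days <- sort(unique(logs$day))
  if (!identical(days, seq_len(max(days))))
    stop("days must be the contiguous range 1..T", call. = FALSE)
  T <- max(days)
  shape <- function(col, default) {
    m <- matrix(default, length(pids), T,
                dimnames = list(pids, NULL))
    m[cbind(match(logs$participant_id, pids), logs$day)] <- col
    m
  }
  list(pids = pids, T = T,
       beh = shape(logs$beh, NA_real_),
       cue = shape(if (is.null(logs$cue)) rep(1, nrow(logs)) else logs$cue, 1),
       rem = shape(if (is.null(logs$rem)) rep(0, nrow(logs)) else logs$rem, 0),
       lab = shape(if (is.null(logs$lab)) rep(0, nrow(logs)) else logs$lab, 0))
}

# Baseline (earliest) survey per participant, as a lookup data frame.
.baseline_surveys <- function(surveys, pids) {
  if (is.null(surveys) || nrow(surveys) == 0L)
    return(data.frame(participant_id = pids, srbai = NA_real_,
                      self_report_rate = NA_real_))
  first <- do.call(rbind, lapply(split(surveys, surveys$participant_id),
                                 function(s) s[which.min(s$day), ]))
  idx <- match(pids, first$participant_id)
  data.frame(participant_id = pids,
             srbai = first$srbai[idx],
             self_report_rate = first$self_report_rate[idx])
}

#' Build the feature table for a model specification
#'
#' Produces one row per predictable participant-day: the day being
#' predicted (\eqn{t \ge 2}), its model-specific features computed only
#' from information available before day \eqn{t} (plus the known
#' reminder/laboratory schedule), and the target \eqn{1 - Beh_t}
#' (non-adherence is the positive class). Days with a missing outcome
#' are dropped.
#'
#' Feature sets: \code{survey} carries forward the last completed
#' survey's automaticity and attitudes and adds the predicted day's
#' scheduled laboratory-session and reminder indicators; the three
#' behavior-rate models use their rate plus the same two schedule
#' indicators; \code{theory} uses habit strength and accessibility
#' only.
#'
#' @param logs behavior-log data frame: \code{participant_id},
#'   \code{day} (1-based, contiguous per participant), \code{beh}
#'   (binary, \code{NA} = unobserved), optional \code{cue}, \code{rem},
#'   \code{lab}.
#' @param surveys survey data frame: \code{participant_id}, \code{day},
#'   \code{srbai}, \code{att_instrumental}, \code{att_affective},
#'   \code{self_report_rate}; may be \code{NULL} for specs that do not
#'   need it.
#' @param spec a \code{\link{model_spec}}; tunable parameters
#'   (\code{gamma}, \code{hp}/\code{ap}) must be present.
#' @param default_hs0 fallback initial habit strength (see
#'   \code{\link{theory_features}}).
#' @param default_init_rate fallback prior-week rate when no baseline
#'   survey reports one.
#' @return Data frame with \code{participant_id}, \code{day},
#'   \code{target}, and the feature columns; the feature names are in
#'   \code{attr(, "features")}.
#' @export
build_feature_table <- function(logs, surveys = NULL, spec,
                                default_hs0 = 0, default_init_rate = 0.5) {
  stopifnot(inherits(spec, "habit_model_spec"))
  wide <- .log_matrices(logs)
  n <- length(wide$pids); T <- wide$T
  base <- .baseline_surveys(surveys, wide$pids)

  # target grid: predict days 2..T
  pred_days <- 2:T
  grid <- expand.grid(pid_idx = seq_len(n), day = pred_days,
                      KEEP.OUT.ATTRS = FALSE)
  grid$target <- 1 - wide$beh[cbind(grid$pid_idx, grid$day)]
  keep <- !is.na(grid$target)

  feats <- switch(
    spec$name,
    theory = {
      if (is.null(spec$hp) || is.null(spec$ap))
        stop("theory spec requires 'hp' and 'ap'", call. = FALSE)
      hs1 <- (base$srbai - 1) / 6
      if (anyNA(hs1)) {
        warning("missing baseline automaticity for some participants; ",
                "initial habit strength set to ", default_hs0, call. = FALSE)
        hs1[is.na(hs1)] <- default_hs0
      }
      st <- .propagate_states(wide$beh, wide$cue, pmax(wide$rem, wide$lab),
                              hs1, rep(1, n), spec$hp, spec$ap)
      data.frame(hs = st$hs[cbind(grid$pid_idx, grid$day)],
                 acc = st$acc[cbind(grid$pid_idx, grid$day)])
    },
    survey = {
      if (is.null(surveys)) stop("survey spec requires surveys", call. = FALSE)
      locf <- function(col) {
        m <- matrix(NA_real_, n, T)
        for (p in seq_len(n)) {
          s <- surveys[surveys$participant_id == wide$pids[p], ]
          s <- s[order(s$day), ]
          for (d in seq_len(T)) {
            done <- s$day[s$day < d]          # surveys completed before day d
            if (length(done))
              m[p, d] <- s[[col]][match(max(done), s$day)]
          }
        }
        m
      }
      sr <- locf("srbai"); ai <- locf("att_instrumental")
      aa <- locf("att_affective")
      idx <- cbind(grid$pid_idx, grid$day)
      data.frame(srbai = sr[idx], att_instrumental = ai[idx],
                 att_affective = aa[idx],
                 lab = wide$lab[idx], rem = wide$rem[idx])
    },
    past_br = ,
    past_br7 = ,
    weighted_br = {
      init <- base$self_report_rate
      if (anyNA(init)) init[is.na(init)] <- default_init_rate
      rate <- matrix(NA_real_, n, T)
      for (p in seq_len(n)) {
        for (d in pred_days) {
          h <- wide$beh[p, seq_len(d - 1L)]
          rate[p, d] <- switch(spec$name,
            past_br = past_br(h, init[p]),
            past_br7 = past_br7(h, init[p]),
            weighted_br = {
              if (is.null(spec$gamma))
                stop("weighted_br spec requires 'gamma'", call. = FALSE)
              weighted_br(h, spec$gamma, init[p])
            })
        }
      }
      idx <- cbind(grid$pid_idx, grid$day)
      out <- data.frame(br = rate[idx], lab = wide$lab[idx],
                        rem = wide$rem[idx])
      names(out)[1] <- switch(spec$name, past_br = "br", past_br7 = "br7",
                              weighted_br = "wbr")
      out
    })

  res <- cbind(data.frame(participant_id = wide$pids[grid$pid_idx],
                          day = grid$day, target = grid$target),
               feats)[keep, , drop = FALSE]
  res <- res[order(res$participant_id, res$day), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, features = names(feats))
}
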