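# Synthetic-study generator emulating the two toothbrushing
# intervention designs: latent habit/accessibility dynamics drive
# daily behavior through a logistic link, weekly surveys track the
# latent states with noise, and days go missing at random.

.MAXINT <- 2147483647

# Independent per-participant seed stream derived from one global seed,
# so a participant's data do not depend on cohort size.
.participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 104729) %% (.MAXINT - 1)) + 1L
}

#' Default synthetic-study configuration
#'
#' Returns the generator configuration emulating one of the two
#' toothbrushing interventions: \code{"study1"} (36 analyzable
#' participants, 21 days, app reminders daily in week 1 and on
#' alternate days in week 2, weekly surveys) or \code{"study2"} (75
#' analyzable participants, 21 days, an introduction and an
#' intervention laboratory session, surveys around those contacts and
#' two emailed follow-ups, no daily reminder schedule). True dynamics
#' parameters default to \code{hdp = 0.10}, \code{hgp = 0.20},
#' \code{adp = 0.28}, \code{agp_beh = 0.13}, \code{agp_rem = 0.26}.
#'
#' Behavior is generated from the latent states through a logistic
#' model: \eqn{P(Beh_t = 1) = logit^{-1}(b_0 + b_{HS} HS_t + b_{Acc}
#' Acc_t + b_{ind} z_i)} with a standard-normal individual effect
#' \eqn{z_i}.
#'
#' @param study \code{"study1"} or \code{"study2"}.
#' @return A list of class \code{habit_synth_config} with components
#'   \code{n_participants}, \code{n_days}, \code{hp}, \code{ap},
#'   \code{coefs} (intercept, weight_hs, weight_acc,
#'   weight_individual), \code{hs0_shape} (Beta shape pair),
#'   \code{reminder_schedule}, \code{lab_schedule},
#'   \code{survey_days}, \code{survey_noise_sd}, \code{p_missing},
#'   \code{seed}.
#' @export
default_config <- function(study = c("study1", "study2")) {
  study <- match.arg(study)
  T <- 21L
  rem <- integer(T)
  lab <- integer(T)
  if (study == "study1") {
    n <- 36L
    rem[1:7] <- 1L                   # daily reminders, week 1
    rem[c(9L, 11L, 13L)] <- 1L       # alternate days, week 2
    lab[1L] <- 1L                    # introduction meeting
    survey_days <- c(1L, 7L, 14L, 21L)
  } else {
    n <- 75L
    lab[c(1L, 8L)] <- 1L             # introduction + intervention session
    survey_days <- c(1L, 8L, 15L, 21L)
  }
  rem[survey_days] <- 1L             # survey notifications act as reminders
  structure(list(
    study = study,
    n_participants = n,
    n_days = T,
    hp = habit_params(hdp = 0.10, hgp = 0.20),
    ap = access_params(adp = 0.28, agp_beh = 0.13, agp_rem = 0.26),
    # intercepts calibrated so study1 is near class balance and study2
    # brushes on roughly two thirds of days, matching the two designs
    coefs = c(intercept = if (study == "study1") -1.8 else -1.0,
              weight_hs = 3.5, weight_acc = 0.8,
              weight_individual = 0.8),
    hs0_shape = c(1, 5),
    reminder_schedule = rem,
    lab_schedule = lab,
    survey_days = survey_days,
    survey_noise_sd = 0.5,
    p_missing = 0.05,
    seed = 1L
  ), class = "habit_synth_config")
}

#' Generate a synthetic intervention study
#'
#' Simulates daily behavior for every participant from the latent
#' habit/accessibility dynamics under the true parameters in
#' \code{config}: the initial habit strength is drawn from the
#' configured Beta distribution (new-habit cohorts start weak), initial
#' accessibility is 1, and each day's behavior is Bernoulli with
#' log-odds linear in the current latent states and a participant
#' effect. The realized behavior feeds back into the state update.
#' Surveys on the configured days report automaticity as
#' \eqn{1 + 6 HS_t} plus clipped Gaussian noise, attitudes from a
#' participant-level latent attitude, and the previous week's observed
#' behavior rate. Each day is unobserved independently with probability
#' \code{p_missing} (the latent dynamics still see the true behavior --
#' the day happened, it just was not recorded).
#'
#' The same \code{config} and \code{seed} always regenerate identical
#' data, and each participant's stream depends only on (seed,
#' participant index).
#'
#' @param config a \code{\link{default_config}}-style configuration.
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return A list of class \code{habit_synth_study} with components
#'   \code{logs} (behavior-log data frame), \code{surveys},
#'   \code{truth} (per participant-day latent \code{hs}, \code{acc},
#'   \code{p_beh}, \code{beh_true}), and \code{effects}
#'   (per-participant individual effects).
#' @export
generate_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "habit_synth_config"))
  n <- config$n_participants; T <- config$n_days
  co <- config$coefs
  logs <- vector("list", n); surveys <- vector("list", n)
  truth <- vector("list", n); effects <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.participant_seed(seed, i))
    pid <- sprintf("P%03d", i)
    hs <- rbeta(1, config$hs0_shape[1], config$hs0_shape[2])
    acc <- 1
    z <- rnorm(1)
    att <- rnorm(1, mean = 5, sd = 1)
    effects[i] <- z
    beh <- integer(T); p_beh <- numeric(T)
    hs_t <- numeric(T); acc_t <- numeric(T)
    rem_eff <- pmax(config$reminder_schedule, config$lab_schedule)
    for (t in seq_len(T)) {
      hs_t[t] <- hs; acc_t[t] <- acc
      p <- plogis(co[["intercept"]] + co[["weight_hs"]] * hs +
                  co[["weight_acc"]] * acc + co[["weight_individual"]] * z)
      p_beh[t] <- p
      beh[t] <- rbinom(1, 1, p)
      hs <- step_habit(hs, beh[t], 1, config$hp)
      acc <- step_accessibility(acc, beh[t], rem_eff[t], config$ap)
    }
    missing <- runif(T) < config$p_missing
    beh_obs <- ifelse(missing, NA_integer_, beh)
    logs[[i]] <- data.frame(
      participant_id = pid, day = seq_len(T), beh = beh_obs,
      cue = 1L, rem = config$reminder_schedule, lab = config$lab_schedule)
    clip17 <- function(x) pmin(7, pmax(1, x))
    sv <- lapply(config$survey_days, function(d) {
      sr_window <- max(1L, d - 6L):d
      rate <- mean(beh[seq_len(T) %in% sr_window])
      if (d == 1L)  # baseline: pre-study week, habit essentially absent
        rate <- rbinom(1, 7, 0.1 + 0.3 * hs_t[1]) / 7
      data.frame(
        participant_id = pid, day = d,
        srbai = clip17(1 + 6 * hs_t[d] + rnorm(1, 0, config$survey_noise_sd)),
        att_instrumental = clip17(att + rnorm(1, 0, config$survey_noise_sd)),
        att_affective = clip17(att - 0.5 + rnorm(1, 0, config$survey_noise_sd)),
        self_report_rate = min(1, max(0, rate)))
    })
    surveys[[i]] <- do.call(rbind, sv)
    truth[[i]] <- data.frame(participant_id = pid, day = seq_len(T),
                             hs = hs_t, acc = acc_t, p_beh = p_beh,
                             beh_true = beh)
  }
  structure(list(config = config, seed = seed,
                 logs = do.call(rbind, logs),
                 surveys = do.call(rbind, surveys),
                 truth = do.call(rbind, truth),
                 effects = data.frame(
                   participant_id = sprintf("P%03d", seq_len(n)),
                   effect = effects)),
            class = "habit_synth_study")
}

#' @export
print.habit_synth_study <- function(x, ...) {
  cat("<habit_synth_study>", x$config$study, "-",
      x$config$n_participants, "participants x", x$config$n_days, "days\n")
  cat("  observed days:", sum(!is.na(x$logs$beh)), "of", nrow(x$logs), "\n")
  invisible(x)
}

#' Case-prevalence summary of a (synthetic or real) study
#'
#' Summarizes the prediction problem's class balance under the
#' non-adherence-positive coding: counts of positive (behavior absent)
#' and negative (behavior performed) observed days, per-participant
#' behavior rates, and the daily behavior-rate curve.
#'
#' @param study a \code{habit_synth_study}, or any behavior-log data
#'   frame with \code{participant_id}, \code{day}, \code{beh}.
#' @return A list with \code{n_observed}, \code{n_positive},
#'   \code{n_negative}, \code{positive_fraction},
#'   \code{participant_rates}, and \code{daily_rate}.
#' @export
prevalence_report <- function(study) {
  logs <- if (inherits(study, "habit_synth_study")) study$logs else study
  stopifnot(is.data.frame(logs), all(c("participant_id", "day", "beh")
                                     %in% names(logs)))
  obs <- logs[!is.na(logs$beh), ]
  if (nrow(obs) == 0L) stop("no observed days", call. = FALSE)
  rates <- tapply(obs$beh, obs$participant_id, mean)
  daily <- tapply(obs$beh, obs$day, mean)
  list(n_observed = nrow(obs),
       n_positive = sum(obs$beh == 0),
       n_negative = sum(obs$beh == 1),
       positive_fraction = mean(obs$beh == 0),
       participant_rates = data.frame(participant_id = names(rates),
                                      rate = as.numeric(rates)),
       daily_rate = data.frame(day = as.integer(names(daily)),
                               rate = as.numeric(daily)))
}
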