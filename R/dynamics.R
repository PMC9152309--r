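.check_unit <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
  invisible(x)
}

.check_binary <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !(x %in% c(0, 1)))
    stop(sprintf("'%s' must be 0 or 1", name), call. = FALSE)
  invisible(x)
}

#' Habit-dynamics parameters
#'
#' Constructors for the parameter sets governing the two latent-state
#' recurrences: habit strength (a decay parameter \code{hdp} and a gain
#' parameter \code{hgp}) and memory accessibility (a decay parameter
#' \code{adp} and two gain parameters, \code{agp_beh} for behavior
#' executions and \code{agp_rem} for reminders). All parameters are
#' dimensionless per-day rates in \eqn{[0, 1]}.
#'
#' @param hdp habit decay parameter in \eqn{[0, 1]}.
#' @param hgp habit gain parameter in \eqn{[0, 1]}.
#' @return An object of class \code{habit_params}.
#' @examples
#' habit_params(hdp = 0.10, hgp = 0.20)
#' @export
habit_params <- function(hdp, hgp) {
  .check_unit(hdp, "hdp"); .check_unit(hgp, "hgp")
  structure(list(hdp = hdp, hgp = hgp), class = "habit_params")
}

#' @rdname habit_params
#' @param adp accessibility decay parameter in \eqn{[0, 1]}.
#' @param agp_beh accessibility gain per behavior execution, in \eqn{[0, 1]}.
#' @param agp_rem accessibility gain per reminder, in \eqn{[0, 1]}.
#' @export
access_params <- function(adp, agp_beh, agp_rem) {
  .check_unit(adp, "adp"); .check_unit(agp_beh, "agp_beh")
  .check_unit(agp_rem, "agp_rem")
  structure(list(adp = adp, agp_beh = agp_beh, agp_rem = agp_rem),
            class = "access_params")
}

#' One-day habit-strength update
#'
#' Advances habit strength \eqn{HS} by one time step:
#' \deqn{HS_{t+1} = HS_t - HS_t \cdot HDP + (1 - HS_t) \cdot Beh_t \cdot Cue_t \cdot HGP}
#' Habit strength decays proportionally every day and grows toward 1 only
#' on days when the behavior is executed in the presence of its cue.
#'
#' @param hs current habit strength in \eqn{[0, 1]}.
#' @param beh behavior indicator, 0 or 1.
#' @param cue cue (context) indicator, 0 or 1; under the stable-context
#'   assumption this is 1 every day.
#' @param params a \code{\link{habit_params}} object.
#' @return Updated habit strength, guaranteed to stay in \eqn{[0, 1]}.
#' @examples
#' step_habit(0.5, beh = 1, cue = 1, habit_params(0.1, 0.2))
#' @export
step_habit <- function(hs, beh, cue = 1, params) {
  .check_unit(hs, "hs")
  .check_binary(beh, "beh"); .check_binary(cue, "cue")
  stopifnot(inherits(params, "habit_params"))
  hs - hs * params$hdp + (1 - hs) * beh * cue * params$hgp
}

#' One-day memory-accessibility update
#'
#' Advances memory accessibility \eqn{Acc} by one time step:
#' \deqn{Acc_{t+1} = Acc_t - Acc_t \cdot ADP + (1 - Acc_t)(Beh_t \cdot AGP_{beh} + Rem_t \cdot AGP_{rem})}
#' Accessibility decays as a natural memory process and is restored by
#' executing the behavior or by external reminders. Because the two gain
#' parameters can sum above 1, the result is clamped to \eqn{[0, 1]}.
#'
#' @param acc current accessibility in \eqn{[0, 1]}.
#' @param beh behavior indicator, 0 or 1.
#' @param rem reminder indicator, 0 or 1.
#' @param params an \code{\link{access_params}} object.
#' @return Updated accessibility in \eqn{[0, 1]}.
#' @export
step_accessibility <- function(acc, beh, rem, params) {
  .check_unit(acc, "acc")
  .check_binary(beh, "beh"); .check_binary(rem, "rem")
  stopifnot(inherits(params, "access_params"))
  out <- acc - acc * params$adp +
    (1 - acc) * (beh * params$agp_beh + rem * params$agp_rem)
  min(1, max(0, out))
}

#' Fixed point of the habit recurrence under constant practice
#'
#' With the behavior performed in context every day (\eqn{Beh = Cue = 1}),
#' habit strength converges geometrically to the equilibrium where daily
#' decay balances daily gain: \eqn{HS^* = HGP / (HDP + HGP)}.
#'
#' @param params a \code{\link{habit_params}} object with
#'   \code{hdp + hgp > 0}.
#' @return The equilibrium habit strength in \eqn{[0, 1]}.
#' @examples
#' habit_fixed_point(habit_params(0.1, 0.2))  # 2/3
#' @export
habit_fixed_point <- function(params) {
  stopifnot(inherits(params, "habit_params"))
  if (params$hdp + params$hgp <= 0)
    stop("degenerate parameters: hdp + hgp must be > 0", call. = FALSE)
  params$hgp / (params$hdp + params$hgp)
}

#' Simulate the coupled habit/accessibility dynamics over a schedule
#'
#' Iterates \code{\link{step_habit}} and \code{\link{step_accessibility}}
#' over a day-by-day schedule of behavior, cue and reminder indicators.
#' Days flagged unobserved freeze the state: no decay and no gain are
#' applied, since nothing is known about what happened.
#'
#' @param schedule a data frame with columns \code{beh}, \code{cue},
#'   \code{rem} (binary) and optionally \code{observed} (logical,
#'   default \code{TRUE}; a row with \code{beh = NA} is also treated as
#'   unobserved).
#' @param init named list or vector with initial state \code{hs} and
#'   \code{acc}, both in \eqn{[0, 1]}.
#' @param hp a \code{\link{habit_params}} object.
#' @param ap an \code{\link{access_params}} object.
#' @return A data frame with one row per schedule step and columns
#'   \code{step}, \code{hs}, \code{acc}: the state *after* each day's
#'   update.
#' @examples
#' sched <- data.frame(beh = rep(c(1, 0), each = 60), cue = 1, rem = 0)
#' traj <- simulate_dynamics(sched, init = c(hs = 0, acc = 1),
#'                           hp = habit_params(0.1, 0.2),
#'                           ap = access_params(0.28, 0.13, 0.26))
#' @export
simulate_dynamics <- function(schedule, init, hp, ap) {
  if (!is.data.frame(schedule) || nrow(schedule) == 0L)
    stop("'schedule' must be a non-empty data frame", call. = FALSE)
  if (is.null(schedule$cue)) schedule$cue <- 1
  if (is.null(schedule$rem)) schedule$rem <- 0
  observed <- if (is.null(schedule$observed)) rep(TRUE, nrow(schedule)) else schedule$observed
  observed <- observed & !is.na(schedule$beh)
  hs <- .check_unit(unname(init[["hs"]]), "init hs")
  acc <- .check_unit(unname(init[["acc"]]), "init acc")
  n <- nrow(schedule)
  out_hs <- numeric(n); out_acc <- numeric(n)
  for (t in seq_len(n)) {
    if (observed[t]) {
      hs_new <- step_habit(hs, schedule$beh[t], schedule$cue[t], hp)
      acc <- step_accessibility(acc, schedule$beh[t], schedule$rem[t], ap)
      hs <- hs_new
    }
    out_hs[t] <- hs; out_acc[t] <- acc
  }
  data.frame(step = seq_len(n), hs = out_hs, acc = out_acc)
}

# Vectorized state propagation over a participant x day grid.
# beh/cue/rem are n x T matrices (beh may contain NA = unobserved day),
# hs1/acc1 length-n initial states. Returns hs/acc as n x (T+1) matrices
# whose column t is the state ENTERING day t (column 1 = the initial
# state); column t is therefore the feature available to predict day t.
.propagate_states <- function(beh, cue, rem, hs1, acc1, hp, ap) {
  n <- nrow(beh); T <- ncol(beh)
  hs <- matrix(0, n, T + 1L); acc <- matrix(0, n, T + 1L)
  hs[, 1L] <- hs1; acc[, 1L] <- acc1
  for (t in seq_len(T)) {
    b <- beh[, t]; obs <- !is.na(b)
    b0 <- ifelse(obs, b, 0)
    h <- hs[, t]
    h_new <- h - h * hp$hdp + (1 - h) * b0 * cue[, t] * hp$hgp
    a <- acc[, t]
    a_new <- a - a * ap$adp +
      (1 - a) * (b0 * ap$agp_beh + rem[, t] * ap$agp_rem)
    a_new <- pmin(1, pmax(0, a_new))
    hs[, t + 1L] <- ifelse(obs, h_new, h)
    acc[, t + 1L] <- ifelse(obs, a_new, a)
  }
  list(hs = hs, acc = acc)
}
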