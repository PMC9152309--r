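# Logistic regression classifier for next-day non-adherence, with
# probability prediction and standardized-coefficient feature
# importance.

.feature_names <- function(rows) {
  f <- attr(rows, "features")
  if (is.null(f))
    f <- setdiff(names(rows), c("participant_id", "day", "target", "fold"))
  f
}

#' Fit a logistic regression classifier on a feature table
#'
#' Plain maximum-likelihood logistic regression of the binary target on
#' the feature columns. An optional small ridge penalty is available to
#' stabilize fits on tiny folds where quasi-separation can occur; the
#' default is unpenalized. Perfect separation does not abort the fit --
#' the returned object carries \code{converged = FALSE}.
#'
#' @param rows feature table as produced by
#'   \code{\link{build_feature_table}} (needs a binary \code{target}
#'   column and feature columns, named in \code{attr(rows,
#'   "features")} or inferred as all non-id columns).
#' @param ridge non-negative L2 penalty on the coefficients (not the
#'   intercept); 0 for plain maximum likelihood.
#' @return An object of class \code{habit_logit} with
#'   \code{coefficients} (intercept first), \code{features},
#'   \code{converged}, \code{iterations}.
#' @export
fit_logistic <- function(rows, ridge = 0) {
  feats <- .feature_names(rows)
  y <- rows$target
  if (length(y) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("degenerate fit: target has the single class ", unique(y),
         call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(rows[feats]))
  storage.mode(X) <- "double"
  fit <- if (ridge > 0) .fit_logit_ridge(X, y, ridge) else .fit_logit_ml(X, y)
  # collinear/constant columns are aliased out by the fit (NA
  # coefficient); treat them as zero contribution, like predict.glm
  aliased <- is.na(fit$beta)
  fit$beta[aliased] <- 0
  structure(list(coefficients = setNames(fit$beta, colnames(X)),
                 features = feats, converged = fit$converged,
                 aliased = setNames(aliased, colnames(X)),
                 iterations = fit$iter, ridge = ridge),
            class = "habit_logit")
}

# Maximum-likelihood fit via stats::glm.fit; a separation warning
# ("fitted probabilities numerically 0 or 1") demotes the converged
# flag, but the fit is still returned.
.fit_logit_ml <- function(X, y) {
  separated <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  # a training score that separates the classes perfectly means the
  # likelihood has no finite maximum even if IRLS stopped quietly
  eta <- fit$linear.predictors
  if (!separated && length(unique(y)) == 2L &&
      min(eta[y == 1]) > max(eta[y == 0]))
    separated <- TRUE
  list(beta = unname(fit$coefficients),
       converged = isTRUE(fit$converged) && !separated,
       iter = fit$iter)
}

# IRLS with a ridge penalty on the non-intercept terms (glm.fit has no
# penalized path); used only for the opt-in stabilizer on tiny folds.
.fit_logit_ridge <- function(X, y, ridge, maxit = 50L, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxit)) {
    iter <- it
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      solve(XtW %*% X + pen, XtW %*% z),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
    # diverging coefficients signal separation; stop inflating
    if (max(abs(beta)) > 1e6) break
  }
  list(beta = beta, converged = converged, iter = iter)
}

#' @export
print.habit_logit <- function(x, ...) {
  cat("<habit_logit> features:", paste(x$features, collapse = ", "), "\n")
  print(round(x$coefficients, 4))
  if (!x$converged) cat("  (fit did not converge -- possible separation)\n")
  invisible(x)
}

#' Predicted probabilities from a fitted classifier
#'
#' @param model a \code{habit_logit} object.
#' @param rows feature table containing the model's feature columns.
#' @return Numeric vector of probabilities in \eqn{(0, 1)}.
#' @export
predict_proba <- function(model, rows) {
  stopifnot(inherits(model, "habit_logit"))
  missing <- setdiff(model$features, names(rows))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- cbind(1, as.matrix(rows[model$features]))
  plogis(drop(X %*% model$coefficients))
}

#' Standardized-coefficient feature importance
#'
#' Importance of feature \eqn{j} is \eqn{|\beta_j| \cdot sd(x_j)} over
#' the supplied rows -- the magnitude of the coefficient a standardized
#' fit would carry. Reported alongside ratios to a reference feature
#' so statements like "habit strength is \eqn{r} times more important
#' than accessibility" can be read off directly.
#'
#' @param model a \code{habit_logit}.
#' @param rows feature table to take feature scales from.
#' @param reference feature name the ratios are relative to; defaults
#'   to the last feature.
#' @return Data frame with \code{feature}, \code{importance},
#'   \code{ratio}.
#' @export
feature_importance <- function(model, rows, reference = NULL) {
  stopifnot(inherits(model, "habit_logit"))
  sds <- vapply(model$features, function(f) sd(rows[[f]]), numeric(1))
  if (any(sds == 0))
    warning("zero-variance feature(s): ",
            paste(model$features[sds == 0], collapse = ", "), call. = FALSE)
  imp <- abs(model$coefficients[-1L]) * sds
  if (is.null(reference)) reference <- model$features[length(model$features)]
  if (!reference %in% model$features)
    stop("unknown reference feature: ", reference, call. = FALSE)
  ref <- imp[[match(reference, model$features)]]
  data.frame(feature = model$features, importance = unname(imp),
             ratio = if (ref > 0) unname(imp) / ref else NA_real_)
}
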