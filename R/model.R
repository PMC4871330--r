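# Logistic lameness models: maximum-likelihood fitting with odds ratios at
# field-relevant increments, ROC-based cutoff selection, and frozen published
# model equations for direct scoring without refitting.

#' Fit a logistic lameness model
#'
#' Fits lameness (a logical response) on one or more behavioral variables by
#' maximum-likelihood logistic regression, and attaches the quantities used
#' to judge a lameness detector: odds ratios with 95% Wald confidence
#' intervals and Wald p values (scaled to per-variable increments such as
#' 30 min of eating time or 0.1 m/s of walking speed), McFadden and
#' Nagelkerke pseudo-R-squared, and a ROC analysis of the linear predictor
#' with the max(sensitivity + specificity) cutoff.
#'
#' @param formula Model formula, e.g.
#'   `lame ~ standing_bouts + walking_speed_calc`.
#' @param data Data frame of per-cow averaged summaries.
#' @param increments Named vector of unit increases at which odds ratios are
#'   reported; defaults come from [behavior_variables()] (1 for unknown
#'   variables).
#' @return An object of class `lameness_model` with
#'   print/summary/coef/predict/plot/residuals/simulate methods.
#' @export
lameness_model <- function(formula, data, increments = NULL) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.logical(y)
  if (sum(y) < 2 || sum(!y) < 2)
    stop("need at least 2 cows in each class")
  separation_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  separation <- separation_warned || !fit$converged
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  vars <- names(beta)[-1]
  reg <- behavior_variables()
  inc <- stats::setNames(rep(1, length(vars)), vars)
  known <- intersect(vars, reg$variable)
  inc[known] <- reg$or_increment[match(known, reg$variable)]
  if (!is.null(increments)) inc[names(increments)] <- increments
  z <- beta[vars] / se[vars]
  or_table <- data.frame(
    variable = vars, coefficient = beta[vars], se = se[vars],
    increment = inc[vars],
    or = exp(beta[vars] * inc[vars]),
    or_low = exp((beta[vars] - 1.96 * se[vars]) * inc[vars]),
    or_high = exp((beta[vars] + 1.96 * se[vars]) * inc[vars]),
    p_wald = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  # OR confidence bounds are ordered low < high regardless of the
  # coefficient sign because the increment is positive.
  n <- length(y)
  ll <- -fit$deviance / 2; ll0 <- -fit$null.deviance / 2
  pseudo_r2 <- c(mcfadden = 1 - fit$deviance / fit$null.deviance,
                 nagelkerke = (1 - exp(2 * (ll0 - ll) / n)) /
                   (1 - exp(2 * ll0 / n)))
  roc <- roc_analysis(stats::predict(fit, type = "link"), y, direction = "high")
  structure(list(call = match.call(), formula = formula, fit = fit,
                 intercept = unname(beta[1]), coefficients = beta[vars],
                 or_table = or_table, pseudo_r2 = pseudo_r2, roc = roc,
                 cutoff = roc$cutoff, separation = separation,
                 n = n, n_lame = sum(y)),
            class = "lameness_model")
}

#' @export
print.lameness_model <- function(x, ...) {
  cat("Logistic lameness model:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d (%d lame); intercept %.4f\n", x$n, x$n_lame, x$intercept))
  tab <- x$or_table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-20s beta %9.4f  OR %.2f (%.2f-%.2f per %g)  P_Wald %.4f\n",
                tab$variable[i], tab$coefficient[i], tab$or[i], tab$or_low[i],
                tab$or_high[i], tab$increment[i], tab$p_wald[i]))
  cat(sprintf("  AUC %.3f | cutoff %.4g: sens %.1f%%, spec %.1f%% | R2 McFadden %.2f, Nagelkerke %.2f\n",
              x$roc$auc, x$cutoff, x$roc$sensitivity, x$roc$specificity,
              x$pseudo_r2["mcfadden"], x$pseudo_r2["nagelkerke"]))
  if (x$separation)
    cat("  WARNING: quasi-complete separation detected; estimates unreliable\n")
  invisible(x)
}

#' @export
summary.lameness_model <- function(object, ...) {
  out <- list(or_table = object$or_table, pseudo_r2 = object$pseudo_r2,
              roc = object$roc, separation = object$separation,
              glm_summary = summary(object$fit))
  class(out) <- "summary.lameness_model"
  out
}

#' @export
print.summary.lameness_model <- function(x, ...) {
  print(x$or_table, digits = 4)
  cat("pseudo-R2:", sprintf("%s %.3f", names(x$pseudo_r2), x$pseudo_r2), "\n")
  print(x$roc)
  invisible(x)
}

#' @export
coef.lameness_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict from a lameness model
#'
#' @param object A `lameness_model` (fitted or frozen).
#' @param newdata Data frame with the model's variables.
#' @param type `"link"` (linear-predictor score), `"response"` (lameness
#'   probability) or `"class"` (logical lame call at `cutoff`).
#' @param cutoff Linear-predictor cutoff for `type = "class"`; defaults to
#'   the model's selected cutoff.  Scores exactly on the cutoff are called
#'   non-lame.
#' @param ... Unused.
#' @export
predict.lameness_model <- function(object, newdata = NULL,
                                   type = c("link", "response", "class"),
                                   cutoff = NULL, ...) {
  type <- match.arg(type)
  lp <- if (is.null(newdata)) stats::predict(object$fit, type = "link")
        else .linear_predictor(object, newdata)
  switch(type,
         link = lp,
         response = stats::plogis(lp),
         class = lp > (cutoff %||% object$cutoff))
}

.linear_predictor <- function(object, newdata) {
  vars <- names(object$coefficients)
  miss <- setdiff(vars, names(newdata))
  if (length(miss)) stop("newdata is missing variables: ",
                         paste(miss, collapse = ", "))
  lp <- rep(object$intercept, nrow(newdata))
  for (v in vars) lp <- lp + object$coefficients[[v]] * newdata[[v]]
  lp
}

#' @export
residuals.lameness_model <- function(object, type = "deviance", ...) {
  stats::residuals(object$fit, type = type)
}

#' @export
plot.lameness_model <- function(x, ...) plot(x$roc, ...)

#' Simulate lameness labels from a fitted model
#'
#' Draws Bernoulli lameness outcomes from the model's predicted
#' probabilities; used e.g. to check parameter recovery by refitting.
#'
#' @param object A `lameness_model`.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional integer seed.
#' @param newdata Data frame of predictor values (default: the training data).
#' @param ... Unused.
#' @return Data frame with `nsim` logical columns.
#' @export
simulate.lameness_model <- function(object, nsim = 1, seed = NULL,
                                    newdata = NULL, ...) {
  p <- predict(object, newdata = newdata, type = "response")
  draw <- function() stats::runif(length(p)) < p
  sims <- if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
          else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  stats::setNames(as.data.frame(sims), paste0("sim_", seq_len(nsim)))
}

#' Frozen published lameness models
#'
#' The two multivariable model equations reported for this detection task,
#' with their printed coefficients and linear-predictor cutoffs; scoring is
#' pure arithmetic, no fitting.  Model `"A"` uses the accelerometer variables
#' only (standing bouts and calculated walking speed; default cutoff -0.06);
#' model `"B"` adds eating time from the noseband sensor (default cutoff
#' -0.49).  A cow is called lame when its linear-predictor score exceeds the
#' cutoff.
#'
#' @param id `"A"` or `"B"`.
#' @return An object of class `c("frozen_lameness_model", "lameness_model")`
#'   usable with [predict.lameness_model()] and [evaluate_model()].
#' @export
frozen_model <- function(id = c("A", "B")) {
  id <- match.arg(id)
  spec <- switch(id,
    A = list(intercept = 25.6859,
             coefficients = c(standing_bouts = -0.1143,
                              walking_speed_calc = -20.9763),
             cutoffs = c(-0.06, 1.77, -2.08)),
    B = list(intercept = 26.3199,
             coefficients = c(eating_time = -0.0091,
                              standing_bouts = -0.1043,
                              walking_speed_calc = -18.8167),
             cutoffs = c(-0.49, 2.09, -2.08)))
  structure(list(model_id = id, intercept = spec$intercept,
                 coefficients = spec$coefficients,
                 cutoffs = spec$cutoffs, cutoff = spec$cutoffs[1]),
            class = c("frozen_lameness_model", "lameness_model"))
}

#' @export
print.frozen_lameness_model <- function(x, ...) {
  cat("Frozen lameness model", x$model_id, "\n")
  cat("  score =", format(x$intercept),
      paste(sprintf("%+g * %s", x$coefficients, names(x$coefficients)),
            collapse = " "), "\n")
  cat("  cutoffs:", paste(x$cutoffs, collapse = ", "),
      "(default", x$cutoff, "); lame when score > cutoff\n")
  invisible(x)
}

#' @export
predict.frozen_lameness_model <- function(object, newdata,
                                          type = c("link", "response", "class"),
                                          cutoff = NULL, ...) {
  type <- match.arg(type)
  lp <- .linear_predictor(object, newdata)
  switch(type,
         link = lp,
         response = stats::plogis(lp),
         class = lp > (cutoff %||% object$cutoff))
}

#' Score cows with a model and evaluate against labels
#'
#' Computes each cow's linear-predictor score and lame call at the cutoff
#' (strictly greater than; ties are non-lame).  Rows with missing predictor
#' values get a missing call and are excluded from the metrics, which are
#' reported when labels are supplied.
#'
#' @param model A `lameness_model` or `frozen_lameness_model`.
#' @param data Per-cow averaged summaries.
#' @param labels Optional logical lameness labels.
#' @param cutoff Linear-predictor cutoff (default: the model's).
#' @return List with `scores`, `calls`, `cutoff`, and (with labels)
#'   `sensitivity`, `specificity`, `proportion_correct` (percent) and the
#'   confusion counts.
#' @export
evaluate_model <- function(model, data, labels = NULL, cutoff = NULL) {
  cutoff <- cutoff %||% model$cutoff
  vars <- names(model$coefficients)
  complete <- stats::complete.cases(data[vars])
  scores <- rep(NA_real_, nrow(data))
  scores[complete] <- .linear_predictor(model, data[complete, , drop = FALSE])
  calls <- scores > cutoff
  out <- list(scores = scores, calls = calls, cutoff = cutoff,
              n_missing = sum(!complete))
  if (!is.null(labels)) {
    labels <- as.logical(labels)
    ok <- complete & !is.na(labels)
    tp <- sum(calls[ok] & labels[ok]); fn <- sum(!calls[ok] & labels[ok])
    tn <- sum(!calls[ok] & !labels[ok]); fp <- sum(calls[ok] & !labels[ok])
    out$confusion <- c(tp = tp, fp = fp, tn = tn, fn = fn)
    out$sensitivity <- 100 * tp / (tp + fn)
    out$specificity <- 100 * tn / (tn + fp)
    out$proportion_correct <- 100 * (tp + tn) / sum(ok)
    out$auc <- .auc_rank(scores[ok], labels[ok])
  }
  out
}
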