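# Multivariable model building: correlation-filtered candidate admission and
# stepwise backward elimination, with a ROC trace of every step.

#' Build a multivariable lameness model from screened candidates
#'
#' The candidate variables (typically those significant in the two-group
#' comparisons) are first ranked by their univariable ROC AUC (ties broken by
#' the smaller Wald p).  Walking down that ranking, a variable is admitted
#' only if its pairwise Spearman correlation with every already admitted
#' variable stays strictly inside (-`rho_max`, `rho_max`); correlated
#' candidates therefore never share a model.  The admitted set is then
#' reduced by stepwise backward elimination: while the largest Wald p is at
#' or above `alpha` (and more than one variable remains), that variable is
#' removed; the trace records the model AUC before and after each removal so
#' the cost of dropping a variable is visible.
#'
#' @param data Per-cow averaged summaries.
#' @param labels Logical lameness labels (defaults to `data$lame`).
#' @param candidates Character vector of candidate variable names.
#' @param alpha Wald significance level for elimination (default 0.05).
#' @param rho_max Correlation bound for co-admission (default 0.5, strict).
#' @return An object of class `model_selection`: `final` (the selected
#'   [lameness_model()]), `initial` (the pre-elimination model), the
#'   univariable ranking, the admitted/excluded sets and the elimination
#'   `trace`.
#' @export
build_multivariable <- function(data, labels = data$lame, candidates,
                                alpha = 0.05, rho_max = 0.5) {
  miss <- setdiff(candidates, names(data))
  if (length(miss)) stop("candidates not in data: ", paste(miss, collapse = ", "))
  labels <- as.logical(labels)
  dat <- data[candidates]
  dat$.lame <- labels

  uni <- do.call(rbind, lapply(candidates, function(v) {
    ok <- !is.na(dat[[v]])
    m <- lameness_model(stats::as.formula(paste(".lame ~", v)), dat[ok, ])
    data.frame(variable = v, auc = m$roc$auc, p_wald = m$or_table$p_wald[1],
               or = m$or_table$or[1])
  }))
  uni <- uni[order(-uni$auc, uni$p_wald), ]
  rownames(uni) <- NULL

  rho <- spearman_matrix(data, candidates)
  admitted <- character(0); excluded <- list()
  for (v in uni$variable) {
    conflicts <- admitted[abs(rho[v, admitted]) >= rho_max]
    if (length(conflicts) == 0) admitted <- c(admitted, v)
    else excluded[[v]] <- conflicts
  }

  fit_on <- function(vars) {
    ok <- stats::complete.cases(dat[vars])
    lameness_model(stats::as.formula(
      paste(".lame ~", paste(vars, collapse = " + "))), dat[ok, ])
  }
  if (length(admitted) < 2) {
    best <- fit_on(uni$variable[1])
    return(structure(list(final = best, initial = best, univariable = uni,
                          admitted = admitted, excluded = excluded,
                          trace = NULL, rho = rho,
                          note = "no admissible variable pair; best univariable model returned"),
                     class = "model_selection"))
  }
  current <- admitted
  model <- fit_on(current)
  initial <- model
  trace <- list()
  repeat {
    p <- stats::setNames(model$or_table$p_wald, model$or_table$variable)
    if (length(current) <= 1 || max(p) < alpha) break
    drop_var <- names(which.max(p))
    reduced <- fit_on(setdiff(current, drop_var))
    trace[[length(trace) + 1L]] <- data.frame(
      removed = drop_var, p_wald = max(p),
      auc_before = model$roc$auc, auc_after = reduced$roc$auc)
    current <- setdiff(current, drop_var)
    model <- reduced
  }
  structure(list(final = model, initial = initial, univariable = uni,
                 admitted = admitted, excluded = excluded,
                 trace = if (length(trace)) do.call(rbind, trace) else NULL,
                 rho = rho, note = NULL),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Multivariable model selection\n")
  cat("  admitted:", paste(x$admitted, collapse = ", "), "\n")
  if (length(x$excluded))
    for (v in names(x$excluded))
      cat("  excluded", v, "(correlated with",
          paste(x$excluded[[v]], collapse = ", "), ")\n")
  if (!is.null(x$trace)) {
    cat("  eliminated:\n")
    for (i in seq_len(nrow(x$trace)))
      cat(sprintf("    - %s (P_Wald %.3f; AUC %.3f -> %.3f)\n",
                  x$trace$removed[i], x$trace$p_wald[i],
                  x$trace$auc_before[i], x$trace$auc_after[i]))
  }
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  cat("final model:\n")
  print(x$final)
  invisible(x)
}
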