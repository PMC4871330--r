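# ROC analysis with the max(sensitivity + specificity) cutoff rule, and
# fixed-threshold classification of single variables.

#' ROC analysis of a lameness score
#'
#' Sweeps every observed score as a candidate cutoff, computes sensitivity
#' (true-positive rate among lame cows) and specificity (true-negative rate
#' among non-lame cows) at each, and the AUC by the rank (Mann-Whitney)
#' construction with midrank tie handling: the AUC equals the probability
#' that a random lame cow outscores a random non-lame cow, ties counting
#' half.  The selected cutoff maximizes sensitivity + specificity; ties are
#' broken in favor of higher specificity, then of the more conservative
#' (fewer-lame-calls) cutoff.  Classification at a cutoff is strict: a score
#' exactly on the cutoff is called non-lame.
#'
#' @param scores Numeric scores, one per cow.
#' @param labels Logical (or 0/1) lameness labels.
#' @param direction `"high"` if lame cows score high (`lame` when
#'   score > cutoff), `"low"` if lame cows score low (`lame` when
#'   score < cutoff), or `"auto"` to pick the direction with AUC >= 0.5.
#' @return An object of class `roc_result`: the threshold sweep
#'   (`threshold`, `sensitivity`, `specificity`), `auc`, the selected
#'   `cutoff` and its `sensitivity`, `specificity` and `proportion_correct`
#'   (all in percent).
#' @export
roc_analysis <- function(scores, labels, direction = c("auto", "high", "low")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (any(is.na(scores)) || any(is.na(labels))) stop("missing scores or labels")
  if (!any(labels) || all(labels))
    stop("both classes must be present for ROC analysis")
  auc_high <- .auc_rank(scores, labels)
  if (direction == "auto") direction <- if (auc_high >= 0.5) "high" else "low"
  auc <- if (direction == "high") auc_high else 1 - auc_high
  pos <- scores[labels]; neg <- scores[!labels]
  if (direction == "high") {
    thr <- c(-Inf, sort(unique(scores)))
    sens <- vapply(thr, function(c) mean(pos > c), 0)
    spec <- vapply(thr, function(c) mean(neg <= c), 0)
  } else {
    thr <- c(sort(unique(scores)), Inf)
    sens <- vapply(thr, function(c) mean(pos < c), 0)
    spec <- vapply(thr, function(c) mean(neg >= c), 0)
  }
  sweep <- data.frame(threshold = thr, sensitivity = 100 * sens,
                      specificity = 100 * spec)
  j <- sens + spec
  best <- which(j == max(j))
  best <- best[spec[best] == max(spec[best])]
  best <- if (direction == "high") best[length(best)] else best[1]
  cutoff <- thr[best]
  pc <- (sum(if (direction == "high") pos > cutoff else pos < cutoff) +
           sum(if (direction == "high") neg <= cutoff else neg >= cutoff)) /
    length(scores)
  structure(list(sweep = sweep, auc = auc, direction = direction,
                 cutoff = cutoff, sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best],
                 proportion_correct = 100 * pc,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

# Mann-Whitney AUC (lame-high orientation) with midranks for ties.
.auc_rank <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC analysis (%d lame / %d non-lame, direction = %s)\n",
              x$n_pos, x$n_neg, x$direction))
  cat(sprintf("  AUC %.3f; cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%, correct %.1f%%\n",
              x$auc, x$cutoff, x$sensitivity, x$specificity,
              x$proportion_correct))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, add = FALSE, ...) {
  fpr <- 1 - x$sweep$specificity / 100
  tpr <- x$sweep$sensitivity / 100
  ord <- order(fpr, tpr)
  if (add) graphics::lines(fpr[ord], tpr[ord], type = "s", ...)
  else {
    graphics::plot(fpr[ord], tpr[ord], type = "s",
                   xlab = "1 - specificity", ylab = "Sensitivity",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  }
  invisible(x)
}

#' Write a ROC sweep as CSV
#'
#' @param roc A `roc_result`.
#' @param path File path.
#' @export
write_roc_csv <- function(roc, path) {
  utils::write.csv(roc$sweep, path, row.names = FALSE)
  invisible(path)
}

#' Classify at a fixed single-variable cutoff
#'
#' Calls a cow lame when its value is strictly below (`direction = "below"`,
#' the case for variables whose odds ratio is below 1, e.g. eating time or
#' walking speed) or strictly above (`direction = "above"`, e.g. lying time,
#' stride duration) the cutoff.  Values exactly on the cutoff are classified
#' non-lame.
#'
#' @param values Numeric variable values.
#' @param labels Logical lameness labels.
#' @param cutoff Threshold on the variable's natural scale.
#' @param direction `"below"` or `"above"`.
#' @return List with `sensitivity`, `specificity`, `proportion_correct`
#'   (percent), the confusion counts and the per-cow calls.
#' @export
threshold_classify <- function(values, labels, cutoff,
                               direction = c("below", "above")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  call_lame <- if (direction == "below") values < cutoff else values > cutoff
  tp <- sum(call_lame & labels); fn <- sum(!call_lame & labels)
  tn <- sum(!call_lame & !labels); fp <- sum(call_lame & !labels)
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       proportion_correct = 100 * (tp + tn) / length(values),
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       calls = call_lame)
}
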