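# Group-comparison statistics: two-group tests with normality/variance
# routing, four-group comparisons with Bonferroni-corrected post-hoc tests
# and a compact letter display, descriptive tables, and the Spearman
# correlation matrix used to screen model candidates.

# Quartile-based IQR with linear-interpolation quantiles (type 7 throughout).
iqr_linear <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))

.describe <- function(x) {
  c(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
    iqr = iqr_linear(x), n = length(x))
}

# Shapiro-Wilk normality gate; constant samples are routed nonparametric.
.is_normal <- function(x, alpha) {
  if (length(unique(x)) < 3) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}

#' Two-group comparison with normality and variance routing
#'
#' Routes each variable to the appropriate two-sample test: if both groups
#' pass Shapiro-Wilk normality (at `routing_alpha`), an F test decides
#' between the equal-variance t test and the Aspin-Welch unequal-variance
#' test; otherwise the Wilcoxon rank sum test is used.  Two-sided throughout.
#'
#' @param x,y Numeric samples for the two groups (each n >= 3).
#' @param alpha Significance level for the comparison itself (default 0.05).
#' @param routing_alpha Level used by the normality and variance-equality
#'   gates (default 0.05).
#' @param exact_threshold Passed to [wilcoxon_rank_sum()].
#' @return An object of class `comparison_result`: test used
#'   (`t_equal_var`, `aspin_welch` or `wilcoxon`), statistic, p value,
#'   significance flag and per-group descriptives.
#' @export
two_group_test <- function(x, y, alpha = 0.05, routing_alpha = 0.05,
                           exact_threshold = 10) {
  if (length(x) < 3 || length(y) < 3)
    stop("each group needs at least 3 observations for test routing")
  normal <- .is_normal(x, routing_alpha) && .is_normal(y, routing_alpha)
  if (normal) {
    equal_var <- stats::var.test(x, y)$p.value >= routing_alpha
    ht <- stats::t.test(x, y, var.equal = equal_var)
    test <- if (equal_var) "t_equal_var" else "aspin_welch"
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    wt <- wilcoxon_rank_sum(x, y, exact_threshold = exact_threshold)
    test <- "wilcoxon"
    statistic <- wt$statistic
    p <- wt$p_value
  }
  structure(list(test = test, statistic = statistic, p_value = p,
                 significant = p < alpha, alpha = alpha,
                 descriptives = rbind(x = .describe(x), y = .describe(y))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Two-group comparison:", x$test,
      sprintf("statistic = %.4g, p = %.4g%s\n", x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  print(round(x$descriptives, 3))
  invisible(x)
}

#' Wilcoxon rank sum test
#'
#' Exact two-sided p value (by full enumeration of rank assignments, as
#' provided by the exact distribution) when the smaller group has at most
#' `exact_threshold` observations and the data are free of ties; otherwise
#' the normal approximation with continuity and tie correction.
#'
#' @param x,y Numeric samples.
#' @param exact_threshold Largest min(n) for which the exact p is computed
#'   (default 10).
#' @return List with `statistic` (rank-sum W of the first sample, counting
#'   pairs, as in [stats::wilcox.test()]), `p_value`, and `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_threshold = 10) {
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  ties <- any(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) <= exact_threshold && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
       exact = exact)
}

# Dunn's rank-based multiple-comparison Z test after Kruskal-Wallis, with
# midrank tie correction; significance against the Bonferroni-corrected
# critical Z over all pairwise comparisons.
dunn_test <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  z_crit <- stats::qnorm(1 - alpha / (2 * m))
  res <- data.frame(a = pairs[1, ], b = pairs[2, ], z = NA_real_,
                    p_adj = NA_real_, significant = NA)
  for (k in seq_len(m)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    res$z[k] <- z
    res$p_adj[k] <- min(1, m * 2 * stats::pnorm(-abs(z)))
    res$significant[k] <- abs(z) > z_crit
  }
  res
}

# Compact letter display: groups share a letter iff their pairwise comparison
# is non-significant (insert-and-absorb construction).
letter_display <- function(levels, pair_a, pair_b, significant) {
  sig <- matrix(FALSE, length(levels), length(levels),
                dimnames = list(levels, levels))
  for (k in seq_along(pair_a)) {
    sig[pair_a[k], pair_b[k]] <- significant[k]
    sig[pair_b[k], pair_a[k]] <- significant[k]
  }
  # Insert-and-absorb: when a group conflicts with a letter column, the
  # column is duplicated with the conflicting members removed so every
  # non-significant pair ends up sharing at least one letter.
  cols <- list(levels[1])
  for (g in levels[-1]) {
    spawned <- list()
    for (ci in seq_along(cols)) {
      if (!any(sig[g, cols[[ci]]])) cols[[ci]] <- c(cols[[ci]], g)
      else spawned[[length(spawned) + 1L]] <-
          c(cols[[ci]][!sig[g, cols[[ci]]]], g)
    }
    cols <- c(cols, spawned)
    # absorb columns contained in another column
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) for (j in seq_along(cols))
      if (i != j && keep[j] && all(cols[[i]] %in% cols[[j]]) &&
          !(all(cols[[j]] %in% cols[[i]]) && i < j))
        keep[i] <- FALSE
    cols <- cols[keep]
  }
  letters_out <- stats::setNames(rep("", length(levels)), levels)
  for (ci in seq_along(cols))
    for (g in cols[[ci]])
      letters_out[g] <- paste0(letters_out[g], letters[ci])
  vapply(letters_out, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""),
         "")
}

#' Four-group comparison with multiplicity-corrected pairwise tests
#'
#' Compares the lameness groups (C, LI, LII, LIII).  If every group passes
#' Shapiro-Wilk normality the omnibus test is one-way ANOVA with pairwise
#' pooled-SD t tests, Bonferroni corrected; otherwise Kruskal-Wallis followed
#' by Dunn's pairwise Z tests against the Bonferroni-corrected critical Z.
#' Groups that share no letter in the compact letter display differ
#' significantly.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `four_group_result`: route, omnibus statistic
#'   and p, pairwise table, letters, and per-group descriptives.
#' @export
four_group_compare <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- groups[keep]
  if (!is.factor(groups)) groups <- factor(groups)
  sizes <- table(groups)
  if (any(sizes == 0)) {
    warning("dropping empty groups: ",
            paste(names(sizes)[sizes == 0], collapse = ", "))
    groups <- droplevels(groups)
  }
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  normal <- all(tapply(values, groups, .is_normal, alpha = 0.05))
  lev <- levels(groups)
  if (normal) {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    omnibus_p <- an[["Pr(>F)"]][1]
    statistic <- an[["F value"]][1]
    pt <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)
    pairs <- utils::combn(lev, 2)
    p_adj <- vapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      v <- pt$p.value[b, a]
      if (is.null(v) || is.na(v)) pt$p.value[a, b] else v
    }, 0)
    pairwise <- data.frame(a = pairs[1, ], b = pairs[2, ], p_adj = p_adj,
                           significant = p_adj < alpha)
    route <- "anova_bonferroni"
  } else {
    kw <- stats::kruskal.test(values, groups)
    omnibus_p <- kw$p.value
    statistic <- unname(kw$statistic)
    pairwise <- dunn_test(values, groups, alpha = alpha)
    route <- "kruskal_wallis_dunn"
  }
  letters_cld <- letter_display(lev, pairwise$a, pairwise$b, pairwise$significant)
  desc <- t(vapply(lev, function(g) .describe(values[groups == g]), numeric(5)))
  structure(list(route = route, statistic = statistic, omnibus_p = omnibus_p,
                 significant = omnibus_p < alpha, pairwise = pairwise,
                 letters = letters_cld, descriptives = desc, alpha = alpha),
            class = "four_group_result")
}

#' @export
print.four_group_result <- function(x, ...) {
  cat("Four-group comparison:", x$route,
      sprintf("omnibus p = %.4g%s\n", x$omnibus_p,
              if (x$significant) " *" else ""))
  cat("letters:", paste(names(x$letters), x$letters, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Pairwise Spearman correlation matrix
#'
#' Midrank-tied Spearman correlations between behavioral variables across
#' cows; used to forbid correlated predictors (|rho| >= 0.5) from entering
#' the same logistic model.  Constant variables yield `NA` with a warning.
#'
#' @param data Data frame of per-cow averaged summaries.
#' @param variables Character vector of columns to correlate.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(data, variables = NULL) {
  if (is.null(variables))
    variables <- intersect(behavior_variables()$variable, names(data))
  if (nrow(data) < 3) stop("need at least 3 cows")
  m <- as.matrix(data[variables])
  constant <- apply(m, 2, function(col) stats::sd(col, na.rm = TRUE) == 0)
  if (any(constant))
    warning("constant variables, correlation undefined: ",
            paste(variables[constant], collapse = ", "))
  rho <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- 1
  rho[constant, ] <- NA; rho[, constant] <- NA
  diag(rho)[constant] <- NA
  rho
}

#' Descriptive and inferential comparison table over all variables
#'
#' Builds the two-group (lame vs non-lame) comparison table: per-group mean,
#' SD, median and IQR plus the routed test and its p value for every
#' behavioral variable present in the data.
#'
#' @param data Per-cow averaged summaries with a logical `lame` column.
#' @param variables Variables to compare (default: all present).
#' @param alpha Significance level.
#' @return Data frame with one row per variable.
#' @export
compare_groups <- function(data, variables = NULL, alpha = 0.05) {
  if (is.null(variables))
    variables <- intersect(behavior_variables()$variable, names(data))
  rows <- lapply(variables, function(v) {
    x <- data[[v]][!data$lame]; y <- data[[v]][data$lame]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    ct <- two_group_test(x, y, alpha = alpha)
    data.frame(variable = v,
               mean_C = mean(x), sd_C = stats::sd(x),
               median_C = stats::median(x), iqr_C = iqr_linear(x),
               mean_L = mean(y), sd_L = stats::sd(y),
               median_L = stats::median(y), iqr_L = iqr_linear(y),
               test = ct$test, p_value = ct$p_value,
               significant = ct$significant)
  })
  do.call(rbind, rows)
}
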