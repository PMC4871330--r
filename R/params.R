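# Cohort parameterization: per-group means/SDs of the behavioral variables,
# correlation constraints, and lameness-score (NRS) distributions.

# Published group moments (mean, SD) of the averaged 24-hour summaries for
# non-lame (C) and lame (L) multiparous Holstein cows, in canonical units
# (times min/d, chews and bouts counts/d, stride duration ms, stride
# distance cm).  Stride duration SD for group C is taken from the printed
# IQR (0.14 s => IQR/1.349 = 104 ms); the printed SD (0.84 s) is
# inconsistent with the IQR, with group L (150 ms), and with the walking
# speed SD it implies, and is treated as a typographical error.
.group_C_moments <- function() {
  list(
    mean = c(eating_time = 378.61, ruminating_time = 583.23,
             eating_chews = 29270, ruminating_chews = 40760, bolus = 614.50,
             chews_per_minute = 75.74, chews_per_bolus = 65.87,
             lying_time = 679.65, walking_time = 41.74,
             lying_bouts = 9.79, standing_bouts = 119.63, walking_bouts = 111.17,
             strides = 1075.17, stride_duration = 1830, stride_distance = 131),
    sd = c(eating_time = 71.40, ruminating_time = 56.28,
           eating_chews = 7210, ruminating_chews = 4190, bolus = 60.74,
           chews_per_minute = 4.70, chews_per_bolus = 3.80,
           lying_time = 74.13, walking_time = 5.99,
           lying_bouts = 1.60, standing_bouts = 17.17, walking_bouts = 16.28,
           strides = 151.51, stride_duration = 104, stride_distance = 14)
  )
}

.group_L_moments <- function() {
  list(
    mean = c(eating_time = 301.93, ruminating_time = 537.37,
             eating_chews = 22320, ruminating_chews = 36900, bolus = 533.96,
             chews_per_minute = 73.97, chews_per_bolus = 69.85,
             lying_time = 784.38, walking_time = 37.85,
             lying_bouts = 9.54, standing_bouts = 97.91, walking_bouts = 89.79,
             strides = 950.82, stride_duration = 1970, stride_distance = 106),
    sd = c(eating_time = 57.16, ruminating_time = 59.63,
           eating_chews = 4780, ruminating_chews = 5780, bolus = 120.76,
           chews_per_minute = 5.65, chews_per_bolus = 13.91,
           lying_time = 130.56, walking_time = 7.06,
           lying_bouts = 3.35, standing_bouts = 17.73, walking_bouts = 16.97,
           strides = 176.15, stride_duration = 150, stride_distance = 16)
  )
}

#' Parameters for one cohort group
#'
#' Bundles the marginal moments, sample size, NRS score distribution and
#' correlation constraints that the cohort simulator realizes for one
#' lameness group.
#'
#' @param label Group label, one of `"C"`, `"L"`, `"LI"`, `"LII"`, `"LIII"`.
#' @param n Number of cows in the group.
#' @param mean,sd Named numeric vectors of per-variable means and SDs (canonical
#'   units; see [behavior_variables()]).  Derived variables (`standing_time`,
#'   `lying_bout_duration`, `walking_speed_calc`) must not be parameterized:
#'   they are computed from their components.
#' @param nrs_values,nrs_probs Support and probabilities of the final gait
#'   score (NRS, half-point grid 1--5) within the group.
#' @param correlations List of length-3 vectors `c(var_a, var_b, spearman_rho)`
#'   inducing rank correlation between pairs of drawn variables via a Gaussian
#'   copula; unlisted pairs are independent.
#' @return An object of class `group_params`.
#' @export
group_params <- function(label, n, mean, sd,
                         nrs_values, nrs_probs = NULL,
                         correlations = list(c("standing_bouts", "walking_bouts", 0.98))) {
  stopifnot(length(n) == 1L, n >= 1)
  if (is.null(nrs_probs)) nrs_probs <- rep(1 / length(nrs_values), length(nrs_values))
  drawn <- setdiff(behavior_variables()$variable,
                   c("standing_time", "lying_bout_duration", "walking_speed_calc"))
  missing_vars <- setdiff(drawn, names(mean))
  if (length(missing_vars))
    stop("group ", label, ": missing mean for ", paste(missing_vars, collapse = ", "))
  if (any(sd[names(sd)] < 0)) stop("SDs must be >= 0")
  if (any(abs(vapply(correlations, function(p) as.numeric(p[[3]]), 0)) > 1))
    stop("|rho| must be <= 1")
  if (!isTRUE(all.equal(sum(nrs_probs), 1))) stop("nrs_probs must sum to 1")
  if (any(!as.numeric(nrs_values) %in% seq(1, 5, by = 0.5)))
    stop("NRS values must lie on the half-point grid 1..5")
  # Mean daily time budget must be realizable: lying + walking < 1440 so the
  # derived standing time is positive.
  if (mean[["lying_time"]] + mean[["walking_time"]] >= 1440)
    stop("group ", label, ": mean lying + walking time exceeds the 1440-min day")
  structure(list(label = label, n = as.integer(n),
                 mean = mean[drawn], sd = sd[drawn],
                 nrs_values = as.numeric(nrs_values), nrs_probs = nrs_probs,
                 correlations = correlations),
            class = "group_params")
}

#' Default cohort parameters
#'
#' The study conditions the simulator emulates: 12 non-lame (group C) and 41
#' lame (group L) cows with the published per-variable means and SDs, a
#' standing~walking bout Spearman correlation of 0.98, and gait scores on the
#' half-point NRS grid (group C mean 1.75, group L spanning 2.5--4.5).
#'
#' With `split_lame = TRUE` the lame group is divided into severity subgroups
#' LI (n = 19, NRS 2.5--3), LII (n = 11, NRS 3.5) and LIII (n = 11, NRS >= 4).
#' Bout-count means are graded across the subgroups (mild cows closer to
#' non-lame) while other variables keep the common lame-group mean; subgroup
#' SDs are shrunk so the pooled lame-group moments still match the published
#' values.
#'
#' @param split_lame Split group L into LI/LII/LIII severity subgroups?
#' @return A list of [group_params()] objects.
#' @export
cohort_params <- function(split_lame = FALSE) {
  C <- .group_C_moments()
  L <- .group_L_moments()
  # Group C gait scores: support {1, 1.5, 2} weighted to the published mean
  # 1.75 and median 2.
  gC <- group_params("C", 12, C$mean, C$sd,
                     nrs_values = c(1, 1.5, 2), nrs_probs = c(0.17, 0.17, 0.66))
  if (!split_lame) {
    gL <- group_params("L", 41, L$mean, L$sd,
                       nrs_values = c(2.5, 3, 3.5, 4, 4.5),
                       nrs_probs = c(19 / 82, 19 / 82, 11 / 41, 5.5 / 41, 5.5 / 41))
    return(list(gC, gL))
  }
  # Severity gradient for the bout counts: effect fractions relative to the
  # overall C-L difference, chosen so the subgroup sizes (19/11/11) average
  # back to the lame-group mean.
  frac <- c(LI = 0.55, LII = 1.25, LIII = 1.50)
  nsub <- c(LI = 19, LII = 11, LIII = 11)
  graded <- c("standing_bouts", "walking_bouts")
  sub_mean <- function(g) {
    m <- L$mean
    m[graded] <- C$mean[graded] + frac[[g]] * (L$mean[graded] - C$mean[graded])
    m
  }
  # Within-subgroup SD for graded variables: remove the between-subgroup
  # variance so the pooled lame-group SD matches the published value.
  sub_sd <- local({
    s <- L$sd
    for (v in graded) {
      mu <- vapply(names(nsub), function(g) sub_mean(g)[[v]], 0)
      between <- sum(nsub * (mu - L$mean[[v]])^2) / sum(nsub)
      s[v] <- sqrt(max(L$sd[[v]]^2 - between, (0.5 * L$sd[[v]])^2))
    }
    s
  })
  list(gC,
       group_params("LI", 19, sub_mean("LI"), sub_sd,
                    nrs_values = c(2.5, 3)),
       group_params("LII", 11, sub_mean("LII"), sub_sd,
                    nrs_values = 3.5, nrs_probs = 1),
       group_params("LIII", 11, sub_mean("LIII"), sub_sd,
                    nrs_values = c(4, 4.5)))
}

#' Read or write cohort parameters as JSON
#'
#' @param params A list of [group_params()] objects.
#' @param path File path.
#' @return `read_cohort_params()` returns a list of [group_params()] objects.
#' @export
write_cohort_params <- function(params, path) {
  payload <- lapply(params, function(g) {
    g <- unclass(g)
    g$mean <- as.list(g$mean)   # keep names: serialize as JSON objects
    g$sd <- as.list(g$sd)
    g$correlations <- lapply(g$correlations, as.list)
    g
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_params
#' @export
read_cohort_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(g) {
    cors <- lapply(g$correlations, function(p)
      list(p[[1]], p[[2]], as.numeric(p[[3]])))
    group_params(g$label, g$n, unlist(g$mean), unlist(g$sd),
                 nrs_values = unlist(g$nrs_values),
                 nrs_probs = unlist(g$nrs_probs),
                 correlations = cors)
  })
}
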