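# Hourly -> daily -> averaged-summary aggregation, day/accelerometer
# selection, and gait-score (NRS) grouping.

#' Weighted mean
#'
#' `sum(a * x) / sum(x)`, the aggregation used for per-event rates
#' (chews per minute, chews per bolus) and per-stride statistics (stride
#' duration, stride distance) when collapsing hours into days or days into a
#' per-cow average: hours with more events carry proportionally more weight.
#'
#' @param a Values to average.
#' @param x Non-negative weights (event counts or minutes), same length.
#' @return The weighted mean, or `NA` if all weights are zero (flagged with a
#'   warning rather than returning 0).
#' @export
weighted_mean <- function(a, x) {
  if (length(a) != length(x)) stop("values and weights must have equal length")
  if (any(x < 0, na.rm = TRUE)) stop("weights must be >= 0")
  keep <- !is.na(x) & x > 0
  if (!any(keep)) {
    warning("all weights are zero; weighted mean is undefined")
    return(NA_real_)
  }
  if (any(is.na(a[keep]))) return(NA_real_)
  sum(a[keep] * x[keep]) / sum(x[keep])
}

#' Collapse 24 hourly rows into a daily summary
#'
#' Sums every behavioral variable over the day except chews per minute, chews
#' per bolus, stride duration and stride distance, whose daily values are
#' weighted means (weights: ruminating time, bolus count, strides, strides).
#' Two derived variables are attached: calculated walking speed
#' (10 x stride distance \[cm\] / stride duration \[ms\], in m/s) and lying
#' bout duration (lying time / lying bouts, min/bout).
#'
#' @param hourly Data frame with exactly 24 rows (hours 0--23) for one
#'   cow-day, as produced by [summarize_hourly()].
#' @return One-row data frame with the daily variables.
#' @export
daily_summary <- function(hourly) {
  missing_hours <- setdiff(0:23, hourly$hour)
  if (length(missing_hours))
    stop("missing hours: ", paste(missing_hours, collapse = ", "))
  if (nrow(hourly) != 24) stop("expected exactly 24 hourly rows")
  reg <- behavior_variables()
  out <- list(cow_id = hourly$cow_id[1] %||% NA, day = hourly$day[1] %||% NA)
  for (i in seq_len(nrow(reg))) {
    v <- reg$variable[i]
    if (!v %in% names(hourly)) next
    out[[v]] <- switch(reg$daily[i],
      sum = sum(hourly[[v]]),
      wmean = suppressWarnings(weighted_mean(hourly[[v]], hourly[[reg$weight_by[i]]])),
      NULL)
  }
  out <- as.data.frame(out[!vapply(out, is.null, TRUE)], stringsAsFactors = FALSE)
  add_derived_variables(out)
}

# Recompute the two derived variables from their components.
add_derived_variables <- function(df) {
  if (all(c("lying_time", "lying_bouts") %in% names(df)))
    df$lying_bout_duration <- ifelse(df$lying_bouts > 0,
                                     df$lying_time / df$lying_bouts, NA_real_)
  if (all(c("stride_distance", "stride_duration") %in% names(df)))
    df$walking_speed_calc <- ifelse(
      !is.na(df$stride_duration) & df$stride_duration > 0,
      10 * df$stride_distance / df$stride_duration, NA_real_)
  df
}

#' Select recording days and an accelerometer for each cow
#'
#' Flagged days (heat, insemination, illness) are discarded first.  A cow
#' with fewer than two clean days is excluded.  Otherwise two days are chosen
#' (the two available, or two picked uniformly at random when three are), and
#' one of the accelerometers is chosen uniformly at random.  Randomness is
#' seeded per cow from the master seed, so every selection is reproducible.
#'
#' @param flags Data frame with `cow_id`, `day`, `flag` (`"ok"` or an
#'   exclusion cause).
#' @param seed Integer master seed.
#' @param n_accelerometers Number of accelerometers per cow (default 2).
#' @return Data frame with one row per cow: `cow_id`, `excluded`, `day1`,
#'   `day2`, `accelerometer`.
#' @export
select_days_and_sensor <- function(flags, seed = 1, n_accelerometers = 2L) {
  cows <- unique(flags$cow_id)
  rows <- lapply(seq_along(cows), function(i) {
    f <- flags[flags$cow_id == cows[i], , drop = FALSE]
    clean <- sort(f$day[f$flag == "ok"])
    if (length(clean) < 2)
      return(data.frame(cow_id = cows[i], excluded = TRUE,
                        day1 = NA_integer_, day2 = NA_integer_,
                        accelerometer = NA_integer_))
    with_seed(derive_seed(seed, i), {
      days <- if (length(clean) == 2) clean else sort(sample(clean, 2))
      acc <- sample.int(n_accelerometers, 1)
      data.frame(cow_id = cows[i], excluded = FALSE,
                 day1 = days[1], day2 = days[2], accelerometer = acc)
    })
  })
  do.call(rbind, rows)
}

#' Average two daily summaries into one per-cow record
#'
#' Sum variables are averaged arithmetically.  Weighted-mean variables are
#' re-weighted across the two days by their daily weight totals (ruminating
#' time, boluses, strides), which keeps them equal to the statistic computed
#' from the pooled raw events rather than a naive mean of two daily means.
#' Derived variables are recomputed from the averaged components.  A day with
#' no strides contributes nothing to the stride statistics; if both days lack
#' strides the stride variables are missing.
#'
#' @param day_a,day_b One-row daily summaries for the same cow.
#' @return One-row data frame, the averaged 24-hour summary.
#' @export
averaged_summary <- function(day_a, day_b) {
  if (!identical(day_a$cow_id, day_b$cow_id))
    stop("cannot average summaries of different cows: ",
         day_a$cow_id, " vs ", day_b$cow_id)
  reg <- behavior_variables()
  out <- list(cow_id = day_a$cow_id)
  for (i in seq_len(nrow(reg))) {
    v <- reg$variable[i]
    if (!v %in% names(day_a) || reg$daily[i] == "derived") next
    out[[v]] <- if (reg$daily[i] == "sum") {
      (day_a[[v]] + day_b[[v]]) / 2
    } else {
      w <- reg$weight_by[i]
      suppressWarnings(weighted_mean(c(day_a[[v]], day_b[[v]]),
                                     c(day_a[[w]], day_b[[w]])))
    }
  }
  add_derived_variables(as.data.frame(out, stringsAsFactors = FALSE))
}

#' Final gait score and lameness group from observer scores
#'
#' The mean of the six observer scores (two recordings x three observers on
#' the 1--5 half-point numerical rating scale) is rounded to the nearest half
#' point, ties rounding up.  Cows with a final NRS of 2 or less are non-lame
#' (group C); 2.5--3 mildly lame (LI); 3.5 moderately lame (LII); 4 or more
#' severely lame (LIII).
#'
#' @param scores Numeric vector of six scores on the half-point grid 1--5.
#' @return List with `nrs`, `group` and `lame`.
#' @export
nrs_group <- function(scores) {
  if (length(scores) != 6) stop("expected six observer scores")
  if (any(!scores %in% seq(1, 5, by = 0.5)))
    stop("scores must lie on the half-point grid 1..5")
  nrs <- round_half_point(mean(scores))
  group <- if (nrs <= 2) "C" else if (nrs <= 3) "LI" else if (nrs == 3.5) "LII" else "LIII"
  list(nrs = nrs, group = group, lame = nrs >= 2.5)
}

#' Build per-cow averaged summaries from a simulated cohort
#'
#' Runs the day-level analysis path: applies the day flags (all days are
#' treated as clean if none were injected), selects two days and one
#' accelerometer per cow, averages the two daily summaries, and attaches the
#' final NRS, lameness group and lame flag recomputed from the observer
#' scores.
#'
#' @param cohort A `cow_cohort`, optionally after [inject_day_flags()].
#' @param seed Integer seed for the random day/accelerometer selection.
#' @return Data frame with one row per retained cow (the averaged 24-hour
#'   summary plus `nrs`, `group`, `lame`); the selection table is attached as
#'   attribute `"selection"`.
#' @export
build_averaged_summaries <- function(cohort, seed = 1) {
  stopifnot(inherits(cohort, "cow_cohort"))
  flags <- cohort$flags %||% cbind(unique(cohort$daily[c("cow_id", "day")]),
                                   flag = "ok", stringsAsFactors = FALSE)
  sel <- select_days_and_sensor(flags, seed = seed)
  kept <- sel[!sel$excluded, , drop = FALSE]
  if (nrow(kept) == 0) {
    out <- data.frame(cow_id = character(0))
    attr(out, "selection") <- sel
    return(out)
  }
  daily <- cohort$daily
  key <- paste(daily$cow_id, daily$day)
  A <- daily[match(paste(kept$cow_id, kept$day1), key), , drop = FALSE]
  B <- daily[match(paste(kept$cow_id, kept$day2), key), , drop = FALSE]
  reg <- behavior_variables()
  out <- data.frame(cow_id = kept$cow_id, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(reg))) {
    v <- reg$variable[i]
    if (!v %in% names(daily) || reg$daily[i] == "derived") next
    out[[v]] <- if (reg$daily[i] == "sum") (A[[v]] + B[[v]]) / 2 else {
      wa <- A[[reg$weight_by[i]]]; wb <- B[[reg$weight_by[i]]]
      num <- ifelse(wa > 0, A[[v]] * wa, 0) + ifelse(wb > 0, B[[v]] * wb, 0)
      ifelse(wa + wb > 0, num / (wa + wb), NA_real_)
    }
  }
  out <- add_derived_variables(out)
  obs <- as.matrix(cohort$cows[match(kept$cow_id, cohort$cows$cow_id),
                               paste0("obs", 1:6)])
  scores <- apply(obs, 1, function(s) unlist(nrs_group(as.numeric(s))))
  out$nrs <- as.numeric(scores["nrs", ])
  out$group <- as.character(scores["group", ])
  out$lame <- as.logical(scores["lame", ])
  rownames(out) <- NULL
  attr(out, "selection") <- sel
  out
}
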