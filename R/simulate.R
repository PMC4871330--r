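# Synthetic cohort and behavioral event-stream simulation.
#
# Two-level design: cows (and their per-day behavioral targets) are drawn
# first from the group-level moments; a concrete posture/stride event stream
# realizing a day's targets can then be synthesized so that segmentation and
# aggregation are testable end-to-end without any recorded raw data.

# Physical bounds used when truncating marginal draws.
.var_bounds <- function() {
  list(
    eating_time = c(0, 1440), ruminating_time = c(0, 1440),
    eating_chews = c(0, Inf), ruminating_chews = c(0, Inf), bolus = c(0, Inf),
    chews_per_minute = c(1, Inf), chews_per_bolus = c(1, Inf),
    lying_time = c(0, 1435), walking_time = c(0, 300),
    lying_bouts = c(1, Inf), standing_bouts = c(0, Inf), walking_bouts = c(0, Inf),
    strides = c(0, Inf), stride_duration = c(200, 3999), stride_distance = c(10, Inf)
  )
}

.count_vars <- c("eating_chews", "ruminating_chews", "bolus", "lying_bouts",
                 "standing_bouts", "walking_bouts", "strides")

# Draw an n x p matrix of correlated standard normals: independent columns
# except the pairs listed in `correlations`, which get a Gaussian copula with
# Pearson correlation matched to the requested Spearman rho.
.draw_z <- function(n, vars, correlations) {
  z <- matrix(stats::rnorm(n * length(vars)), nrow = n,
              dimnames = list(NULL, vars))
  for (p in correlations) {
    a <- p[[1]]; b <- p[[2]]; rho_s <- as.numeric(p[[3]])
    r <- 2 * sin(pi * rho_s / 6)  # Spearman -> Pearson for bivariate normal
    z[, b] <- r * z[, a] + sqrt(1 - r^2) * z[, b]
  }
  z
}

# Apply physical bounds to drawn values; out-of-bound elements are redrawn
# from their (truncated) marginal.  Truncation essentially never binds at the
# default parameters, so copula correlations are preserved in practice.
.apply_bounds <- function(x, mean, sd) {
  bounds <- .var_bounds()
  for (v in colnames(x)) {
    b <- bounds[[v]]
    bad <- which(x[, v] < b[1] | x[, v] > b[2])
    if (length(bad))
      x[bad, v] <- rtruncnorm(length(bad), mean[[v]], max(sd[[v]], 1e-12),
                              b[1], b[2])
  }
  x
}

# Six observer gait scores whose half-point-rounded mean equals `nrs`:
# some score pairs are jittered +/- 0.5 symmetrically (clamped inside 1..5).
.observer_scores <- function(nrs) {
  s <- rep(nrs, 6)
  k <- sample(0:2, 1)
  if (k > 0 && nrs - 0.5 >= 1 && nrs + 0.5 <= 5) {
    idx <- sample(6, 2 * k)
    s[idx[seq_len(k)]] <- nrs - 0.5
    s[idx[k + seq_len(k)]] <- nrs + 0.5
  }
  s
}

#' Simulate a cohort of cows with per-day behavioral targets
#'
#' Draws cow-level behavioral profiles from the group parameters (truncated
#' normal marginals, Gaussian-copula correlation for the constrained pairs),
#' then adds correlated day-to-day deviations around each cow's profile.
#' Standing time, lying bout duration and calculated walking speed are derived
#' per day from their components, so the 1440-min daily time budget holds by
#' construction and counts are non-negative integers.
#'
#' @param params List of [group_params()]; defaults to the study conditions
#'   ([cohort_params()]).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param days Recording days per cow (>= 2).
#' @param day_sd_frac Within-cow day-to-day SD as a fraction of the
#'   between-cow SD.  Day deviations carry the same copula correlation as the
#'   cow-level draws, so rank correlations survive daily averaging.
#' @return An object of class `cow_cohort`: list with `cows` (one row per cow:
#'   id, group, six observer scores, final NRS, lame flag), `daily` (one row
#'   per cow-day with all behavioral variables) and the generating `params`.
#' @export
simulate_cohort <- function(params = cohort_params(), seed = 1, days = 3,
                            day_sd_frac = 0.2) {
  stopifnot(days >= 2)
  drawn <- setdiff(behavior_variables()$variable,
                   c("standing_time", "lying_bout_duration", "walking_speed_calc"))
  cows <- NULL; daily <- NULL
  with_seed(seed, {
    cow_no <- 0L
    for (g in params) {
      stopifnot(inherits(g, "group_params"))
      z <- .draw_z(g$n, drawn, g$correlations)
      base <- sweep(sweep(z, 2, g$sd[drawn], "*"), 2, g$mean[drawn], "+")
      base <- .apply_bounds(base, g$mean, g$sd)
      nrs <- g$nrs_values[sample.int(length(g$nrs_values), g$n,
                                     replace = TRUE, prob = g$nrs_probs)]
      obs <- t(vapply(nrs, .observer_scores, numeric(6)))
      ids <- sprintf("cow%03d", cow_no + seq_len(g$n))
      cow_no <- cow_no + g$n
      cows <- rbind(cows, data.frame(
        cow_id = ids, group = g$label, obs, nrs = nrs,
        lame = nrs >= 2.5, stringsAsFactors = FALSE))
      for (i in seq_len(g$n)) {
        dev <- .draw_z(days, drawn, g$correlations)
        day_vals <- sweep(sweep(dev, 2, day_sd_frac * g$sd[drawn], "*"),
                          2, base[i, ], "+")
        day_vals <- .apply_bounds(day_vals, g$mean, g$sd)
        df <- as.data.frame(day_vals)
        df[.count_vars] <- lapply(df[.count_vars], function(x) as.integer(round(x)))
        df <- .finalize_day(df)
        daily <- rbind(daily, cbind(cow_id = ids[i], day = seq_len(days), df,
                                    stringsAsFactors = FALSE))
      }
    }
  })
  names(cows)[3:8] <- paste0("obs", 1:6)
  structure(list(cows = cows, daily = daily, params = params,
                 seed = seed, days = days, day_sd_frac = day_sd_frac),
            class = "cow_cohort")
}

# Derive the dependent variables for simulated day rows and enforce
# event-level feasibility (strides must fit inside the walking time at the
# drawn stride duration, with inter-stride gaps of at most 4 s).
.finalize_day <- function(df) {
  stride_ok <- df$walking_bouts > 0
  df$strides <- ifelse(stride_ok, pmax(df$strides, 3L * df$walking_bouts), 0L)
  df$walking_bouts[df$strides == 0L] <- 0L
  d_s <- df$stride_duration / 1000
  lo <- df$strides * d_s / 60                       # all strides back-to-back
  hi <- ((df$strides - df$walking_bouts) * 4 + df$walking_bouts * d_s) / 60
  w <- df$walking_time
  w <- pmin(pmax(w, lo * 1.02 + 0.1), hi * 0.98)
  w[df$strides == 0L] <- 0
  df$walking_time <- pmin(w, 1439 - df$lying_time)
  df$standing_time <- 1440 - df$lying_time - df$walking_time
  df$lying_bout_duration <- ifelse(df$lying_bouts > 0,
                                   df$lying_time / df$lying_bouts, NA_real_)
  df$walking_speed_calc <- ifelse(df$strides > 0,
                                  10 * df$stride_distance / df$stride_duration,
                                  NA_real_)
  df
}

#' @export
print.cow_cohort <- function(x, ...) {
  cat("Simulated cow cohort:", nrow(x$cows), "cows x", x$days, "days\n")
  print(table(group = x$cows$group))
  cat("lame:", sum(x$cows$lame), "| non-lame:", sum(!x$cows$lame),
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' Flag simulated days for exclusion causes
#'
#' Marks each cow-day as `heat`, `insemination`, `ill` or `ok` with the given
#' per-day probabilities.  Flagged days are discarded before day selection,
#' mirroring field practice of dropping days with estrus, insemination or
#' obvious illness.
#'
#' @param cohort A `cow_cohort`.
#' @param rates Named probabilities for `heat`, `insemination`, `ill`
#'   (each in \[0,1\], summing to at most 1).
#' @param seed Integer seed.
#' @return The cohort with a `flags` data frame (`cow_id`, `day`, `flag`).
#' @export
inject_day_flags <- function(cohort,
                             rates = c(heat = 0.02, insemination = 0.01, ill = 0.02),
                             seed = 1) {
  stopifnot(inherits(cohort, "cow_cohort"),
            all(rates >= 0), all(rates <= 1), sum(rates) <= 1)
  keys <- unique(cohort$daily[c("cow_id", "day")])
  flags <- with_seed(seed,
    sample(c(names(rates), "ok"), nrow(keys), replace = TRUE,
           prob = c(rates, 1 - sum(rates))))
  cohort$flags <- cbind(keys, flag = flags, stringsAsFactors = FALSE)
  rownames(cohort$flags) <- NULL
  cohort
}

# Proportional allocation of `total` over slots with per-slot capacities,
# redistributing any overflow until every slot respects its cap.
.alloc_capped <- function(total, w, cap) {
  if (total > sum(cap) + 1e-9) stop("allocation exceeds total capacity")
  x <- total * w / sum(w)
  for (it in 1:200) {
    over <- x > cap
    if (!any(over)) break
    excess <- sum(x[over] - cap[over])
    x[over] <- cap[over]
    room <- pmax(cap - x, 0); room[over] <- 0
    if (sum(room) <= 1e-12) break
    x <- x + excess * room / sum(room)
  }
  pmin(x, cap)
}

# Split `total` into `n` parts, each at least `minimum`, with random
# Gamma-weight proportions.
.random_split <- function(total, n, minimum = 0, shape = 4) {
  if (n == 0L) return(numeric(0))
  spare <- total - n * minimum
  if (spare < 0) stop("cannot split ", total, " into ", n,
                      " parts of at least ", minimum)
  w <- stats::rgamma(n, shape = shape) + 1e-9
  minimum + spare * w / sum(w)
}

#' Synthesize a posture/stride event stream realizing daily targets
#'
#' Builds one cow-day of classified sensor events (lying/upright posture
#' intervals covering the 86400-s day, plus stride events inside upright
#' phases) whose segmentation reproduces the target bout counts and state
#' times.  The day is laid out as lying bouts alternating with upright blocks;
#' each walking bout is a run of strides with inter-stride gaps of at most
#' 4 s, followed by a standing phase.  Standing-bout counts are tuned by
#' making some post-walking pauses sub-threshold (<= 4 s) or by inserting
#' sub-threshold (30 s) lying breaks that split a standing phase without
#' adding a lying bout.
#'
#' @param targets A one-row data frame or list with `lying_time`,
#'   `walking_time` (min), `lying_bouts`, `standing_bouts`, `walking_bouts`,
#'   `strides`, `stride_duration` (ms), `stride_distance` (cm).
#' @param seed Integer seed.
#' @return An object of class `event_stream`: list with `cow_id`, `day`,
#'   `posture` (`start_s`, `end_s`, `state` lying/upright) and `strides`
#'   (`timestamp_s`, `stride_duration_ms`, `stride_distance_cm`).
#' @export
simulate_event_stream <- function(targets, seed = 1) {
  tg <- as.list(targets)
  n_ly <- as.integer(tg$lying_bouts)
  n_wb <- as.integer(tg$walking_bouts)
  n_sb <- as.integer(tg$standing_bouts %||% (n_wb + max(n_ly, 1L)))
  S <- as.integer(tg$strides)
  d <- tg$stride_duration / 1000
  lying_s <- tg$lying_time * 60
  walking_s <- tg$walking_time * 60
  standing_s <- 86400 - lying_s - walking_s
  if (standing_s < 0)
    stop("infeasible targets: lying + walking time exceeds the 1440-min day")
  if (S > 0 && n_wb == 0)
    stop("infeasible targets: strides requested but no walking bouts")
  if (n_wb > 0 && S < 3 * n_wb)
    stop("infeasible targets: fewer than 3 strides per walking bout")
  if (n_wb > 0 && d >= 4)
    stop("infeasible targets: stride duration of ", tg$stride_duration,
         " ms cannot satisfy the 4-s inter-stride rule")
  if (n_wb > 0) {
    if (walking_s < S * d - 1e-9)
      stop("infeasible targets: walking time too small for ", S,
           " strides of ", tg$stride_duration, " ms")
    if (walking_s > (S - n_wb) * 4 + n_wb * d + 1e-9)
      stop("infeasible targets: walking time too large for the 4-s ",
           "inter-stride gap limit")
  } else if (walking_s > 1e-9) {
    stop("infeasible targets: walking time without walking bouts")
  }

  n_blocks <- max(n_ly, 1L)
  delta <- n_sb - (n_wb + n_blocks)
  n_short_stand <- max(0L, -delta)       # post-walking pauses made <= 4 s
  n_lying_breaks <- max(0L, delta)       # sub-threshold lying splits
  if (n_short_stand > n_wb)
    stop("infeasible targets: standing bouts fewer than lying bouts alone")
  if (n_ly > 0 && lying_s - 30 * n_lying_breaks < 60 * n_ly)
    stop("infeasible targets: lying time too small for the requested ",
         "lying and standing bout counts")
  if (n_ly == 0 && (lying_s > 0 || n_lying_breaks > 0) &&
      lying_s - 30 * n_lying_breaks < 0)
    stop("infeasible targets: lying time budget cannot host standing splits")

  with_seed(seed, {
    # Lying bout durations (each > 50 s; minimum 60 s for margin).
    main_lying <- lying_s - 30 * n_lying_breaks
    ly_dur <- .random_split(main_lying, n_ly, minimum = 60)
    # Strides per walking bout (>= 3 each).
    extra_strides <- S - 3L * n_wb
    n_str <- if (n_wb > 0)
      3L + as.vector(stats::rmultinom(1, extra_strides, rep(1, n_wb)))
    else integer(0)
    # Per-bout slack beyond back-to-back strides, capped by the 4-s rule.
    slack_total <- walking_s - S * d
    cap <- pmax((n_str - 1) * (4 - d) * 0.98, 0)
    slack <- if (n_wb > 0) {
      sl <- if (sum(cap) > 0) slack_total * cap / sum(cap) else rep(0, n_wb)
      pmin(sl, cap)
    } else numeric(0)
    # Walking bouts per upright block.
    wb_in_block <- if (n_wb > 0)
      as.vector(stats::rmultinom(1, n_wb, rep(1, n_blocks)))
    else rep(0L, n_blocks)
    # Standing segments: one leading segment per block, one after each walking
    # bout; `n_short_stand` of the post-walking segments are sub-threshold;
    # `n_lying_breaks` leading segments are split in two by a 30-s lying break.
    short_after <- rep(FALSE, n_wb)
    if (n_short_stand > 0) short_after[sample(n_wb, n_short_stand)] <- TRUE
    short_gap <- if (n_wb > 0) max(4 - d + 0.05, 0.1) else 0
    n_long_stand <- n_blocks + (n_wb - n_short_stand) + n_lying_breaks
    long_budget <- standing_s - n_short_stand * short_gap
    st_dur <- .random_split(long_budget, n_long_stand, minimum = 55)

    posture <- list(); strides <- list()
    t <- 0; si <- 1L; wi <- 0L; li <- 1L
    emit <- function(state, dur) {
      posture[[length(posture) + 1L]] <<- c(t, t + dur, state)
      t <<- t + dur
    }
    next_stand <- function() { v <- st_dur[si]; si <<- si + 1L; v }
    breaks_in_block <- if (n_lying_breaks > 0)
      as.vector(stats::rmultinom(1, n_lying_breaks, rep(1, n_blocks)))
    else rep(0L, n_blocks)
    for (b in seq_len(n_blocks)) {
      if (n_ly > 0) emit("lying", ly_dur[b])
      # Leading standing segment, optionally split by sub-threshold (30 s)
      # lying breaks: each break adds lying time but no lying bout, and the
      # standing phase on either side is long enough to count.
      for (k in seq_len(breaks_in_block[b])) {
        emit("upright", next_stand())
        emit("lying", 30)
      }
      emit("upright", next_stand())
      k <- wb_in_block[b]
      for (j in seq_len(k)) {
        wi <- wi + 1L
        n_i <- n_str[wi]
        # Spread the bout's slack evenly over the inter-stride gaps with
        # mean-zero jitter so no single gap can breach the 4-s chain rule.
        per_gap <- if (n_i > 1) slack[wi] / (n_i - 1) else 0
        gap_cap <- (4 - d) * 0.98
        eps <- if (n_i > 2) {
          e <- stats::runif(n_i - 1, -1, 1)
          e <- e - mean(e)           # keep the bout's total slack exact
          bound <- 0.95 * min(per_gap, max(gap_cap - per_gap, 0))
          m <- max(abs(e))
          if (m > 0) e * bound / m else e
        } else rep(0, max(n_i - 1, 0))
        gaps <- d + per_gap + eps
        starts <- t + cumsum(c(0, gaps))
        dur_ms <- tg$stride_duration +
          pmax(pmin(stats::rnorm(n_i, 0, 0.03 * tg$stride_duration),
                    0.2 * tg$stride_duration), -0.2 * tg$stride_duration)
        dur_ms <- dur_ms - mean(dur_ms) + tg$stride_duration
        dist_cm <- tg$stride_distance +
          stats::rnorm(n_i, 0, 0.05 * tg$stride_distance)
        dist_cm <- dist_cm - mean(dist_cm) + tg$stride_distance
        strides[[length(strides) + 1L]] <- data.frame(
          timestamp_s = starts, stride_duration_ms = dur_ms,
          stride_distance_cm = dist_cm)
        span <- (starts[n_i] - starts[1]) + dur_ms[n_i] / 1000
        # Walking itself is upright; the posture channel stays "upright".
        # A sub-threshold pause must still break the stride chain (> 4 s
        # between strides) without qualifying as a standing bout (<= 4 s),
        # accounting for the realized last stride duration.
        pause <- if (short_after[wi])
          min(max(4 - dur_ms[n_i] / 1000 + 0.05, 0.1), 4)
        else next_stand()
        emit("upright", span + pause)
      }
    }
    posture <- do.call(rbind, lapply(posture, function(p)
      data.frame(start_s = as.numeric(p[1]), end_s = as.numeric(p[2]),
                 state = p[3], stringsAsFactors = FALSE)))
    # Merge adjacent upright rows and rescale to end exactly at 86400 s.
    posture <- .merge_posture(posture)
    drift <- 86400 - posture$end_s[nrow(posture)]
    posture$end_s[nrow(posture)] <- posture$end_s[nrow(posture)] + drift
    strides <- if (length(strides)) do.call(rbind, strides)
      else data.frame(timestamp_s = numeric(0), stride_duration_ms = numeric(0),
                      stride_distance_cm = numeric(0))
    structure(list(cow_id = tg$cow_id %||% "cow001", day = tg$day %||% 1L,
                   posture = posture, strides = strides),
              class = "event_stream")
  })
}

.merge_posture <- function(posture) {
  keep <- posture[1, , drop = FALSE]
  for (i in seq_len(nrow(posture))[-1]) {
    j <- nrow(keep)
    if (posture$state[i] == keep$state[j]) keep$end_s[j] <- posture$end_s[i]
    else keep <- rbind(keep, posture[i, ])
  }
  rownames(keep) <- NULL
  keep
}

#' @export
print.event_stream <- function(x, ...) {
  cat("Event stream for", x$cow_id, "day", x$day, "-",
      nrow(x$posture), "posture intervals,", nrow(x$strides), "strides\n")
  invisible(x)
}

# Distribute one day's halter totals over 24 hours.  Per-hour feeding time
# (eating + ruminating) is capped at 60 min; chew/bolus counts follow the
# allocated minutes; the two per-event rates keep weighted means equal to the
# daily targets.
simulate_hourly_halter <- function(targets, seed = 1) {
  tg <- as.list(targets)
  feed <- tg$eating_time + tg$ruminating_time
  if (feed > 1440) stop("infeasible targets: feeding time exceeds the day")
  with_seed(seed, {
    w <- stats::rgamma(24, shape = 2) + 1e-9
    alloc <- .alloc_capped(feed, w, rep(60, 24))
    p_eat <- tg$eating_time / feed
    share <- stats::rbeta(24, 5 * p_eat + 0.1, 5 * (1 - p_eat) + 0.1)
    eating <- .alloc_capped(tg$eating_time, share * w + 1e-9, alloc)
    ruminating <- pmax(alloc - eating, 0)
    draw_counts <- function(total, weights) {
      if (total <= 0 || sum(weights) <= 0) return(integer(24))
      as.vector(stats::rmultinom(1, total, weights + 1e-9))
    }
    e_chews <- draw_counts(tg$eating_chews, eating)
    r_chews <- draw_counts(tg$ruminating_chews, ruminating)
    bolus <- draw_counts(tg$bolus, ruminating)
    centered_rate <- function(rate, wgt) {
      eps <- stats::rnorm(24, 0, 0.03 * rate)
      if (sum(wgt) > 0) eps <- eps - sum(eps * wgt) / sum(wgt)
      rate + eps
    }
    data.frame(hour = 0:23, eating_time = eating, ruminating_time = ruminating,
               eating_chews = e_chews, ruminating_chews = r_chews, bolus = bolus,
               chews_per_minute = centered_rate(tg$chews_per_minute, ruminating),
               chews_per_bolus = centered_rate(tg$chews_per_bolus, bolus))
  })
}
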