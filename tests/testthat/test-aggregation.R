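test_that("weighted_mean follows the summary formula", {
  expect_equal(weighted_mean(c(2, 4), c(10, 30)), 3.5)
  a <- c(5, 7, 9); expect_equal(weighted_mean(a, c(2, 2, 2)), mean(a))
  expect_warning(wm <- weighted_mean(c(1, 2), c(0, 0)), "zero")
  expect_true(is.na(wm))
  expect_error(weighted_mean(c(1, 2), c(1, -1)), ">= 0")
  expect_error(weighted_mean(c(1, 2, 3), c(1, 2)), "equal length")
  # bounded by the range of values with positive weight
  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(24); x <- rpois(24, 3)
    if (all(x == 0)) next
    wm <- weighted_mean(a, x)
    expect_gte(wm, min(a[x > 0])); expect_lte(wm, max(a[x > 0]))
  }
})

make_hourly <- function(stride_distance = 131, stride_duration = 1830,
                        strides = 40, lying_bouts = c(1, rep(0, 23)),
                        lying_time = 30) {
  data.frame(cow_id = "cowX", day = 1, hour = 0:23,
             lying_time = lying_time, standing_time = 60 - lying_time - 2,
             walking_time = 2,
             lying_bouts = lying_bouts, standing_bouts = 5, walking_bouts = 4,
             strides = strides, stride_duration = stride_duration,
             stride_distance = stride_distance)
}

test_that("daily summaries reproduce the printed derived walking speeds", {
  dC <- daily_summary(make_hourly(131, 1830))
  expect_equal(round(dC$walking_speed_calc, 2), 0.72)
  dL <- daily_summary(make_hourly(106, 1970))
  expect_equal(round(dL$walking_speed_calc, 2), 0.54)
  expect_equal(dC$strides, 24 * 40)
  expect_equal(dC$lying_time, 720)
  expect_equal(dC$lying_bouts, 1)
})

test_that("daily summaries handle lying bout duration and no-stride days", {
  h <- make_hourly(lying_bouts = c(rep(1, 9), rep(0, 15)))
  d <- daily_summary(h)
  expect_equal(d$lying_bout_duration, 720 / 9)
  h0 <- make_hourly(strides = 0)
  h0$walking_time <- 0; h0$standing_time <- 60 - h0$lying_time
  d0 <- daily_summary(h0)
  expect_true(is.na(d0$walking_speed_calc))
  expect_true(is.na(d0$stride_duration))
  expect_equal(d0$walking_time, 0)
  expect_error(daily_summary(make_hourly()[-c(3, 8), ]), "missing hours: 2, 7")
})

test_that("hourly weighted means equal raw-stream statistics exactly", {
  co <- simulate_cohort(seed = 31)
  row <- co$daily[10, ]
  st <- simulate_event_stream(row, seed = 8)
  hourly <- summarize_hourly(st)
  d <- daily_summary(hourly)
  seg <- segment_events(st)
  counted <- seg$counted_strides
  expect_equal(d$stride_duration, mean(st$strides$stride_duration_ms[counted]),
               tolerance = 1e-9)
  expect_equal(d$stride_distance, mean(st$strides$stride_distance_cm[counted]),
               tolerance = 1e-9)
})

test_that("averaging two days re-weights event-based statistics", {
  day_a <- data.frame(cow_id = "c1", day = 1, lying_time = 700, lying_bouts = 10,
                      strides = 900, stride_duration = 1900,
                      stride_distance = 120, ruminating_time = 500,
                      chews_per_minute = 70, bolus = 600, chews_per_bolus = 66)
  day_b <- day_a
  day_b$day <- 2; day_b$lying_time <- 740; day_b$strides <- 1100
  day_b$stride_duration <- 2100
  avg <- averaged_summary(day_a, day_b)
  expect_equal(avg$lying_time, 720)
  expect_equal(avg$stride_duration, (900 * 1900 + 1100 * 2100) / 2000)
  expect_equal(avg$strides, 1000)
  # identical days: averaging is the identity
  same <- averaged_summary(day_a, day_a)
  for (v in c("lying_time", "stride_duration", "chews_per_minute"))
    expect_equal(same[[v]], day_a[[v]])
  day_c <- day_b; day_c$cow_id <- "c2"
  expect_error(averaged_summary(day_a, day_c), "different cows")
})

test_that("averaging then deriving equals deriving from re-weighted parts", {
  set.seed(4)
  for (i in 1:15) {
    w <- sample(200:1500, 2)
    dur <- runif(2, 1500, 2400); dist <- runif(2, 90, 150)
    a <- data.frame(cow_id = "c", day = 1, strides = w[1],
                    stride_duration = dur[1], stride_distance = dist[1])
    b <- data.frame(cow_id = "c", day = 2, strides = w[2],
                    stride_duration = dur[2], stride_distance = dist[2])
    avg <- averaged_summary(a, b)
    speed_direct <- 10 * weighted_mean(dist, w) / weighted_mean(dur, w)
    expect_equal(avg$walking_speed_calc, speed_direct, tolerance = 1e-12)
  }
})

test_that("day selection discards flagged days and excludes short records", {
  flags <- data.frame(
    cow_id = rep(c("a", "b", "c"), each = 3), day = rep(1:3, 3),
    flag = c("ok", "ok", "ok",      # a: 3 clean -> random pair
             "heat", "ok", "ok",    # b: the 2 clean days retained
             "heat", "ill", "ok"))  # c: excluded
  sel <- select_days_and_sensor(flags, seed = 11)
  a <- sel[sel$cow_id == "a", ]
  expect_false(a$excluded)
  expect_true(all(c(a$day1, a$day2) %in% 1:3) && a$day1 < a$day2)
  b <- sel[sel$cow_id == "b", ]
  expect_equal(c(b$day1, b$day2), c(2, 3))
  expect_true(sel[sel$cow_id == "c", "excluded"])
  expect_true(all(sel$accelerometer[!sel$excluded] %in% 1:2))
  expect_identical(sel, select_days_and_sensor(flags, seed = 11))
})

test_that("NRS rounding and group assignment follow the half-point scale", {
  r <- nrs_group(c(2.5, 3, 3, 3.5, 3.5, 4))   # mean 3.25 rounds up to 3.5
  expect_equal(r$nrs, 3.5); expect_equal(r$group, "LII"); expect_true(r$lame)
  r2 <- nrs_group(rep(2, 6))
  expect_equal(r2$nrs, 2); expect_equal(r2$group, "C"); expect_false(r2$lame)
  r3 <- nrs_group(c(4, 4, 4.5, 4.5, 5, 5))
  expect_equal(r3$nrs, 4.5); expect_equal(r3$group, "LIII")
  expect_error(nrs_group(c(1, 2, 3, 4, 5, 5.5)), "half-point")
  expect_error(nrs_group(c(1, 2, 3)), "six")
  # total function: every half-grid value maps to exactly one group
  for (v in seq(1, 5, by = 0.5)) {
    g <- nrs_group(rep(v, 6))
    expect_true(g$group %in% c("C", "LI", "LII", "LIII"))
    expect_equal(g$lame, v >= 2.5)
    expect_equal(sum(c("C", "LI", "LII", "LIII") == g$group), 1)
  }
})

test_that("cohort-level averaging matches the per-cow operation", {
  co <- simulate_cohort(seed = 18)
  avg <- build_averaged_summaries(co, seed = 19)
  sel <- attr(avg, "selection")
  for (i in c(1, 10, 25)) {
    k <- sel[!sel$excluded, ][i, ]
    dd <- co$daily[co$daily$cow_id == k$cow_id, ]
    ref <- averaged_summary(dd[dd$day == k$day1, ], dd[dd$day == k$day2, ])
    row <- avg[avg$cow_id == k$cow_id, ]
    for (v in setdiff(names(ref), "cow_id"))
      expect_equal(row[[v]], ref[[v]], label = paste("cow", k$cow_id, v))
  }
})

test_that("stored derived variables equal recomputation from components", {
  co <- simulate_cohort(seed = 12)
  avg <- build_averaged_summaries(co, seed = 13)
  expect_equal(avg$walking_speed_calc,
               10 * avg$stride_distance / avg$stride_duration)
  expect_equal(avg$lying_bout_duration, avg$lying_time / avg$lying_bouts)
  expect_equal(avg$lying_time + avg$standing_time + avg$walking_time,
               rep(1440, nrow(avg)), tolerance = 1)
})
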