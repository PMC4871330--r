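test_that("cohort simulation is deterministic under a seed", {
  a <- simulate_cohort(seed = 42)
  b <- simulate_cohort(seed = 42)
  expect_identical(a$daily, b$daily)
  expect_identical(a$cows, b$cows)
  c <- simulate_cohort(seed = 43)
  expect_false(identical(a$daily, c$daily))
})

test_that("every simulated day conserves the 1440-min time budget", {
  co <- simulate_cohort(cohort_params(split_lame = TRUE), seed = 5)
  budget <- with(co$daily, lying_time + standing_time + walking_time)
  expect_true(all(abs(budget - 1440) < 1))
  expect_true(all(co$daily$lying_bouts >= 0))
  expect_true(all(co$daily$strides >= 0))
  counts <- co$daily[c("lying_bouts", "standing_bouts", "walking_bouts",
                       "strides", "eating_chews", "bolus")]
  expect_true(all(vapply(counts, function(x) all(x == round(x)), TRUE)))
})

test_that("sample moments converge to the group parameters", {
  p <- cohort_params()
  p[[1]]$n <- 500L
  co <- simulate_cohort(p[1], seed = 9, day_sd_frac = 0)
  g <- p[[1]]
  for (v in c("lying_time", "eating_time", "standing_bouts",
              "stride_distance", "strides")) {
    se <- g$sd[[v]] / sqrt(g$n)
    expect_lt(abs(mean(co$daily[[v]][co$daily$day == 1]) - g$mean[[v]]),
              3 * se, label = paste("mean recovery for", v))
  }
})

test_that("the standing~walking bout correlation is recovered", {
  p <- cohort_params()
  p[[2]]$n <- 600L
  co <- simulate_cohort(p[2], seed = 10)
  d1 <- co$daily[co$daily$day == 1, ]
  rho <- cor(d1$standing_bouts, d1$walking_bouts, method = "spearman")
  expect_lt(abs(rho - 0.98), 0.05)
})

test_that("zero-SD groups yield identical cows and infeasible budgets error", {
  p <- cohort_params()[1]
  p[[1]]$sd[] <- 0
  p[[1]]$n <- 5L
  co <- simulate_cohort(p, seed = 2, day_sd_frac = 0)
  expect_equal(length(unique(co$daily$lying_time)), 1)
  expect_equal(length(unique(co$daily$eating_chews)), 1)
  bad_mean <- cohort_params()[[1]]$mean
  bad_mean["lying_time"] <- 1300; bad_mean["walking_time"] <- 200
  expect_error(group_params("C", 5, bad_mean, cohort_params()[[1]]$sd,
                            nrs_values = 2),
               "1440")
})

test_that("day flags hit their marginal rates and are reproducible", {
  p <- cohort_params()
  p[[2]]$n <- 334L  # ~1000 cow-days at 3 days/cow
  co <- simulate_cohort(p[2], seed = 3)
  ok <- inject_day_flags(co, rates = c(heat = 0, insemination = 0, ill = 0),
                         seed = 1)
  expect_true(all(ok$flags$flag == "ok"))
  heat <- inject_day_flags(co, rates = c(heat = 1, insemination = 0, ill = 0),
                           seed = 1)
  expect_true(all(heat$flags$flag == "heat"))
  some <- inject_day_flags(co, rates = c(heat = 0.1, insemination = 0, ill = 0),
                           seed = 4)
  frac <- mean(some$flags$flag == "heat")
  expect_gt(frac, 0.08); expect_lt(frac, 0.12)
  again <- inject_day_flags(co, rates = c(heat = 0.1, insemination = 0, ill = 0),
                            seed = 4)
  expect_identical(some$flags, again$flags)
})

test_that("event streams reproduce their daily targets through segmentation", {
  co <- simulate_cohort(seed = 21)
  set.seed(99)
  rows <- co$daily[sample(nrow(co$daily), 6), ]
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    st <- simulate_event_stream(row, seed = 100 + i)
    seg <- segment_events(st)
    tt <- seg$totals
    expect_equal(tt$lying_bouts, row$lying_bouts)
    expect_equal(tt$walking_bouts, row$walking_bouts)
    expect_lt(abs(tt$standing_bouts - row$standing_bouts),
              max(1, 0.05 * row$standing_bouts))
    expect_equal(tt$strides, row$strides)
    expect_lt(abs(tt$lying_time - row$lying_time), 0.02 * 1440)
    expect_lt(abs(tt$walking_time - row$walking_time),
              max(0.5, 0.02 * row$walking_time))
    # strides only inside upright intervals, gaps within bouts <= 4 s
    expect_silent(lamewatch:::validate_event_stream(st))
    wb <- seg$bouts[seg$bouts$type == "walking", ]
    for (k in seq_len(nrow(wb))) {
      ts <- st$strides$timestamp_s
      inb <- ts[ts >= wb$start_s[k] & ts <= wb$end_s[k]]
      if (length(inb) > 1) expect_true(all(diff(inb) <= 4 + 1e-9))
    }
  }
})

test_that("degenerate stream targets behave as specified", {
  quiet <- list(lying_time = 720, walking_time = 0, lying_bouts = 1,
                standing_bouts = 1, walking_bouts = 0, strides = 0,
                stride_duration = 1800, stride_distance = 130)
  st <- simulate_event_stream(quiet, seed = 1)
  expect_equal(nrow(st$strides), 0)
  seg <- segment_events(st)
  expect_equal(seg$totals$walking_bouts, 0)
  expect_equal(seg$totals$lying_bouts, 1)

  ex <- list(lying_time = 720, walking_time = 40, lying_bouts = 1,
             walking_bouts = 100, strides = 900,
             stride_duration = 2000, stride_distance = 130)
  seg2 <- segment_events(simulate_event_stream(ex, seed = 2))
  expect_equal(seg2$totals$lying_bouts, 1)
  expect_equal(seg2$totals$walking_bouts, 100)

  bad <- list(lying_time = 720, walking_time = 5, lying_bouts = 5,
              standing_bouts = 110, walking_bouts = 100, strides = 1000,
              stride_duration = 1900, stride_distance = 120)
  expect_error(simulate_event_stream(bad, seed = 3), "walking time too small")
})

test_that("lame-group targets yield the expected derived walking speed", {
  g <- cohort_params()[[2]]
  targets <- as.list(g$mean)
  targets$standing_bouts <- round(targets$standing_bouts)
  targets$walking_bouts <- round(targets$walking_bouts)
  targets$lying_bouts <- round(targets$lying_bouts)
  targets$strides <- round(targets$strides)
  st <- simulate_event_stream(targets, seed = 7)
  seg <- segment_events(st)
  speed <- 10 * seg$totals$stride_distance / seg$totals$stride_duration
  expect_lt(abs(speed - 0.54), 0.05)
})
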