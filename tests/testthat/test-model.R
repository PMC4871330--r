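test_that("a feature unrelated to lameness gets a near-null coefficient", {
  set.seed(20)
  d <- data.frame(x = rnorm(400), lame = runif(400) < 0.5)
  m <- lameness_model(lame ~ x, d)
  expect_lt(abs(m$coefficients[["x"]]), 0.25)
  expect_gt(m$or_table$or[1], 0.75); expect_lt(m$or_table$or[1], 1.3)
  expect_false(m$separation)
})

test_that("a single binary feature recovers the 2x2 cross-product odds ratio", {
  d <- data.frame(
    x = c(rep(1, 10 + 5), rep(0, 20 + 30)),
    lame = c(rep(TRUE, 10), rep(FALSE, 5), rep(TRUE, 20), rep(FALSE, 30)))
  m <- lameness_model(lame ~ x, d, increments = c(x = 1))
  expect_equal(m$or_table$or[1], (10 * 30) / (5 * 20), tolerance = 1e-6)
})

test_that("perfect separation is flagged rather than silently diverging", {
  d <- data.frame(x = c(1:10, 21:30), lame = rep(c(FALSE, TRUE), each = 10))
  m <- lameness_model(lame ~ x, d)
  expect_true(m$separation)
  expect_error(lameness_model(lame ~ x, data.frame(x = 1:5, lame = rep(TRUE, 5))),
               "each class")
})

test_that("odds ratios scale with the reporting increment", {
  co <- simulate_cohort(seed = 16)
  avg <- build_averaged_summaries(co, seed = 17)
  m <- lameness_model(lame ~ eating_time, avg)
  beta <- m$coefficients[["eating_time"]]
  expect_equal(m$or_table$increment[1], 30)   # reported per 30 min
  expect_equal(m$or_table$or[1], exp(30 * beta))
  expect_lt(m$or_table$or_low[1], m$or_table$or_high[1])
  expect_equal(coef(m)[["eating_time"]], beta)
  expect_length(residuals(m), nrow(avg))
})

test_that("fitting data simulated from the frozen equation recovers it", {
  set.seed(77)
  n <- 5000
  d <- data.frame(standing_bouts = rnorm(n, 105, 20),
                  walking_speed_calc = rnorm(n, 0.62, 0.12))
  truth <- frozen_model("A")
  p <- predict(truth, d, type = "response")
  d$lame <- runif(n) < p
  m <- lameness_model(lame ~ standing_bouts + walking_speed_calc, d)
  for (v in names(truth$coefficients)) {
    rel <- abs(m$coefficients[[v]] - truth$coefficients[[v]]) /
      abs(truth$coefficients[[v]])
    expect_lt(rel, 0.1, label = paste("recovery of", v))
  }
  expect_lt(abs(m$intercept - truth$intercept) / truth$intercept, 0.1)
})

test_that("simulate() draws labels consistent with fitted probabilities", {
  set.seed(30)
  d <- data.frame(x = rnorm(300))
  d$lame <- runif(300) < plogis(-0.5 + 1.2 * d$x)
  m <- lameness_model(lame ~ x, d)
  sims <- simulate(m, nsim = 20, seed = 5)
  expect_equal(dim(sims), c(300, 20))
  expect_lt(abs(mean(as.matrix(sims)) - mean(predict(m, type = "response"))),
            0.05)
  expect_identical(sims, simulate(m, nsim = 20, seed = 5))
})

test_that("ROC handles perfect, degenerate and tied scores", {
  r <- roc_analysis(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100); expect_equal(r$specificity, 100)
  tied <- roc_analysis(rep(1, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(tied$auc, 0.5)
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC equals the pairwise Mann-Whitney oracle", {
  set.seed(40)
  for (i in 1:25) {
    n <- sample(8:25, 1)
    scores <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, 0.1 * (i %% 2))
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- roc_analysis(scores, labels, direction = "high")
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12,
                 label = paste("fixture", i))
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:10) {
    scores <- c(rnorm(15), rnorm(20, 1))
    labels <- rep(c(FALSE, TRUE), c(15, 20))
    ours <- roc_analysis(scores, labels, direction = "high")$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("AUC and the optimal sens+spec are invariant to monotone transforms", {
  set.seed(42)
  scores <- rnorm(40); labels <- runif(40) < plogis(scores)
  if (!any(labels)) labels[1] <- TRUE
  if (all(labels)) labels[2] <- FALSE
  r1 <- roc_analysis(scores, labels, direction = "high")
  r2 <- roc_analysis(exp(scores), labels, direction = "high")
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  expect_equal(r1$sensitivity + r1$specificity,
               r2$sensitivity + r2$specificity, tolerance = 1e-9)
  # score negation flips the AUC on tie-free data
  r3 <- roc_analysis(-scores, labels, direction = "high")
  expect_equal(r1$auc + r3$auc, 1, tolerance = 1e-12)
})

test_that("confusion identities hold at the selected cutoff", {
  set.seed(43)
  scores <- rnorm(60); labels <- runif(60) < plogis(2 * scores)
  r <- roc_analysis(scores, labels, direction = "high")
  P <- sum(labels); N <- sum(!labels)
  correct <- r$sensitivity / 100 * P + r$specificity / 100 * N
  expect_equal(correct / (P + N) * 100, r$proportion_correct, tolerance = 1e-9)
})

test_that("threshold classification respects direction and strict cutoffs", {
  r <- threshold_classify(c(1, 2, 3, 4, 5), c(TRUE, TRUE, TRUE, FALSE, FALSE),
                          cutoff = 3.5, direction = "below")
  expect_equal(r$sensitivity, 100); expect_equal(r$specificity, 100)
  all_below <- threshold_classify(c(1, 2, 3), c(TRUE, FALSE, TRUE),
                                  cutoff = 10, direction = "below")
  expect_equal(all_below$sensitivity, 100); expect_equal(all_below$specificity, 0)
  # a value exactly on the cutoff is called non-lame
  on_cut <- threshold_classify(c(3.5, 1), c(TRUE, TRUE), 3.5, "below")
  expect_equal(on_cut$sensitivity, 50)
})

test_that("frozen model equations score the printed group means correctly", {
  A <- frozen_model("A")
  score_C <- predict(A, data.frame(standing_bouts = 119.63,
                                   walking_speed_calc = 0.72), type = "link")
  expect_equal(score_C, 25.6859 - 0.1143 * 119.63 - 20.9763 * 0.72,
               tolerance = 1e-12)
  expect_equal(score_C, -3.09, tolerance = 0.01)
  expect_false(predict(A, data.frame(standing_bouts = 119.63,
                                     walking_speed_calc = 0.72),
                       type = "class"))
  score_L <- predict(A, data.frame(standing_bouts = 97.91,
                                   walking_speed_calc = 0.54), type = "link")
  expect_equal(score_L, 3.17, tolerance = 0.01)
  expect_true(score_L > A$cutoff)
  B <- frozen_model("B")
  expect_equal(B$cutoff, -0.49)
  expect_named(B$coefficients,
               c("eating_time", "standing_bouts", "walking_speed_calc"))
})

test_that("evaluate_model reports missing rows and confusion metrics", {
  d <- data.frame(standing_bouts = c(120, 95, NA),
                  walking_speed_calc = c(0.75, 0.5, 0.6),
                  lame = c(FALSE, TRUE, TRUE))
  ev <- evaluate_model(frozen_model("A"), d, d$lame)
  expect_equal(ev$n_missing, 1)
  expect_true(is.na(ev$calls[3]))
  expect_equal(ev$sensitivity, 100); expect_equal(ev$specificity, 100)
})

test_that("frozen and refit two-variable models agree on discrimination", {
  co <- simulate_cohort(seed = 55)
  avg <- build_averaged_summaries(co, seed = 56)
  frozen_auc <- evaluate_model(frozen_model("A"), avg, avg$lame)$auc
  refit <- lameness_model(lame ~ standing_bouts + walking_speed_calc, avg)
  expect_lt(abs(frozen_auc - refit$roc$auc), 0.03)
})
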