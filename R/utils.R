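# Internal helpers shared across modules.

#' Registry of behavioral variables
#'
#' Canonical names, units and aggregation rules for the sensor variables used
#' throughout the package.  Halter variables come from the noseband sensor,
#' accelerometer variables from the leg-mounted 3D accelerometer; derived
#' variables are computed from the others.  `daily` says how 24 one-hour rows
#' collapse into a day: plain sums, weighted means (weighted by `weight_by`),
#' or a derived recomputation.  `or_increment` is the unit increase at which
#' odds ratios are reported (e.g. per 30 min, per 1000 chews, per 0.1 m/s).
#'
#' @return A data frame with one row per variable: `variable`, `label`,
#'   `unit`, `source`, `daily`, `weight_by`, `or_increment`.
#' @export
behavior_variables <- function() {
  v <- function(variable, label, unit, source, daily, weight_by, or_increment)
    data.frame(variable = variable, label = label, unit = unit, source = source,
               daily = daily, weight_by = weight_by, or_increment = or_increment,
               stringsAsFactors = FALSE)
  rbind(
    v("eating_time",        "Eating time",         "min/d",    "halter", "sum",     NA, 30),
    v("ruminating_time",    "Ruminating time",     "min/d",    "halter", "sum",     NA, 30),
    v("eating_chews",       "Eating chews",        "1/d",      "halter", "sum",     NA, 1000),
    v("ruminating_chews",   "Ruminating chews",    "1/d",      "halter", "sum",     NA, 1000),
    v("bolus",              "Bolus",               "1/d",      "halter", "sum",     NA, 10),
    v("chews_per_minute",   "Chews per minute",    "1/min",    "halter", "wmean",   "ruminating_time", 1),
    v("chews_per_bolus",    "Chews per bolus",     "1/bolus",  "halter", "wmean",   "bolus", 1),
    v("lying_time",         "Lying time",          "min/d",    "accelerometer", "sum", NA, 30),
    v("standing_time",      "Standing time",       "min/d",    "accelerometer", "sum", NA, 30),
    v("walking_time",       "Walking time",        "min/d",    "accelerometer", "sum", NA, 30),
    v("lying_bouts",        "Lying bouts",         "1/d",      "accelerometer", "sum", NA, 1),
    v("standing_bouts",     "Standing bouts",      "1/d",      "accelerometer", "sum", NA, 10),
    v("walking_bouts",      "Walking bouts",       "1/d",      "accelerometer", "sum", NA, 10),
    v("lying_bout_duration","Lying bout duration", "min/bout", "derived", "derived", NA, 30),
    v("strides",            "Strides",             "1/d",      "accelerometer", "sum", NA, 100),
    v("stride_duration",    "Stride duration",     "ms",       "accelerometer", "wmean", "strides", 100),
    v("stride_distance",    "Stride distance",     "cm",       "accelerometer", "wmean", "strides", 10),
    v("walking_speed_calc", "Walking speed_calc",  "m/s",      "derived", "derived", NA, 0.1)
  )
}

# Variables measured by the accelerometer (including derived locomotion ones);
# the candidate set for "accelerometer-only" models.
accelerometer_variables <- function() {
  reg <- behavior_variables()
  reg$variable[reg$source == "accelerometer" |
                 reg$variable %in% c("lying_bout_duration", "walking_speed_calc")]
}

halter_variables <- function() {
  reg <- behavior_variables()
  reg$variable[reg$source == "halter"]
}

# Truncated-normal draws by rejection; truncation rarely binds at the default
# parameter sets so rejection is cheap and keeps the stream reproducible.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) stop("sd must be >= 0")
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad),
                           if (length(mean) > 1L) mean[bad] else mean,
                           if (length(sd) > 1L) sd[bad] else sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal rejection failed to converge; ",
                             "bounds are too far from the mean")
  }
  x
}

# Derive a per-unit RNG seed from a master seed, keeping within 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 1103 * as.double(index)) %% 2147483647)
}

# Evaluate `expr` under a temporary seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round() half-up on a 0.5 grid (base round() is banker's rounding).
round_half_point <- function(x) floor(x * 2 + 0.5) / 2

`%||%` <- function(a, b) if (is.null(a)) b else a
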