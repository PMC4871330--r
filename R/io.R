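# Table readers/writers and the end-to-end pipeline driver.

# Normalize a header name: lower case, alphanumerics only.
.norm_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

# Dictionary from normalized header to canonical column name.
.column_map <- function() {
  reg <- behavior_variables()
  base <- stats::setNames(reg$variable, .norm_name(reg$variable))
  lab <- stats::setNames(reg$variable, .norm_name(reg$label))
  extra <- c(cowid = "cow_id", cow = "cow_id", id = "cow_id", animal = "cow_id",
             animalid = "cow_id", day = "day", hour = "hour", nrs = "nrs",
             gaitscore = "nrs", group = "group", lame = "lame",
             walkingspeed = "walking_speed_calc", boli = "bolus",
             lyingboutduration = "lying_bout_duration",
             flag = "flag", accelerometer = "accelerometer")
  # unit-suffixed variants, e.g. "eatingtimemind" for "Eating time, min/d"
  unit <- stats::setNames(reg$variable,
                          .norm_name(paste0(reg$label, reg$unit)))
  c(base, lab, unit, extra)
}

#' Read a behavioral summary table from CSV
#'
#' Layout-tolerant reader for hourly, 24-hour or per-cow averaged summary
#' tables.  Headers are matched case- and punctuation-insensitively against
#' the canonical variable names, their display labels and unit-suffixed
#' variants; unmapped columns are kept under their original names with a
#' warning.  Times must be non-negative and hourly state times at most
#' 60 min.
#'
#' @param path CSV file path.
#' @param level `"hourly"`, `"daily"` or `"averaged"`; decides the mandatory
#'   identifier columns (`cow_id` always; `day` for hourly/daily; `hour` for
#'   hourly).
#' @return Data frame with canonical column names.
#' @export
read_summary_table <- function(path, level = c("averaged", "daily", "hourly")) {
  level <- match.arg(level)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty input table: ", path)
  map <- .column_map()
  normed <- .norm_name(names(df))
  mapped <- map[normed]
  unmapped <- names(df)[is.na(mapped)]
  names(df)[!is.na(mapped)] <- mapped[!is.na(mapped)]
  if (length(unmapped))
    warning("unmapped columns kept as-is: ", paste(unmapped, collapse = ", "))
  mandatory <- switch(level, hourly = c("cow_id", "day", "hour"),
                      daily = c("cow_id", "day"), averaged = "cow_id")
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  times <- intersect(c("eating_time", "ruminating_time", "lying_time",
                       "standing_time", "walking_time"), names(df))
  for (v in times) {
    if (any(df[[v]] < 0, na.rm = TRUE)) stop("negative times in column ", v)
    if (level == "hourly" && any(df[[v]] > 60 + 1e-9, na.rm = TRUE))
      stop("hourly ", v, " exceeds 60 min")
  }
  if ("lame" %in% names(df)) df$lame <- as.logical(df$lame)
  message(sprintf("read %d rows, %d cows from %s", nrow(df),
                  length(unique(df$cow_id)), basename(path)))
  df
}

#' Write a summary table as CSV
#'
#' Numeric columns are serialized at full precision so a write/read round
#' trip preserves values.
#'
#' @param data Data frame.
#' @param path Output path.
#' @export
write_summary_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param seed Master seed; every random step (cohort draw, day flags, day
#'   and accelerometer selection, event streams) derives its own seed from it.
#' @param params Cohort parameters ([cohort_params()]); the default splits
#'   the lame group into severity subgroups so four-group comparisons run.
#' @param days Recording days per cow.
#' @param flag_rates Per-day probabilities for [inject_day_flags()].
#' @param alpha Significance level used throughout.
#' @param rho_max Correlation bound for model co-admission.
#' @param use_event_streams If `TRUE`, each cow-day is realized as a posture/
#'   stride event stream, segmented and re-aggregated (slower, exercises the
#'   full path); if `FALSE` the day-level targets are used directly.
#' @param output_dir Optional directory for CSV artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, params = cohort_params(split_lame = TRUE),
                            days = 3,
                            flag_rates = c(heat = 0.02, insemination = 0.01,
                                           ill = 0.02),
                            alpha = 0.05, rho_max = 0.5,
                            use_event_streams = FALSE, output_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(seed = seed, params = params, days = days,
                 flag_rates = flag_rates, alpha = alpha, rho_max = rho_max,
                 use_event_streams = use_event_streams,
                 output_dir = output_dir),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Simulation -> (optional event-stream segmentation) -> day selection and
#' averaging -> group comparisons -> univariable models -> correlation-
#' filtered backward selection -> frozen-model evaluation.  Deterministic
#' under the config seed.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_bundle` with all stage outputs; if
#'   `output_dir` is set, CSV artifacts are written there as a side effect.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- .stage("simulate", simulate_cohort(config$params,
                                               seed = config$seed,
                                               days = config$days))
  cohort <- .stage("flags", inject_day_flags(cohort, rates = config$flag_rates,
                                             seed = derive_seed(config$seed, 1)))
  if (config$use_event_streams)
    cohort <- .stage("segment", .rebuild_daily_from_streams(cohort, config$seed))
  averaged <- .stage("aggregate", build_averaged_summaries(
    cohort, seed = derive_seed(config$seed, 2)))
  bundle <- list(config = config, cohort = cohort, averaged = averaged,
                 selection_log = attr(averaged, "selection"))
  if (is.null(averaged) || nrow(averaged) == 0 ||
      length(unique(averaged$lame)) < 2) {
    bundle$note <- "no analyzable cohort (fewer than two outcome classes)"
    class(bundle) <- "pipeline_bundle"
    return(bundle)
  }
  vars <- intersect(behavior_variables()$variable, names(averaged))
  bundle$comparisons <- .stage("compare",
                               compare_groups(averaged, vars, config$alpha))
  bundle$four_group <- .stage("four_group", lapply(
    stats::setNames(nm = c("standing_bouts", "walking_speed_calc")),
    function(v) four_group_compare(averaged[[v]], averaged$group, config$alpha)))
  sig <- bundle$comparisons$variable[bundle$comparisons$significant]
  bundle$univariable <- .stage("univariable", lapply(
    stats::setNames(nm = sig), function(v) {
      ok <- !is.na(averaged[[v]])
      m <- lameness_model(stats::as.formula(paste("lame ~", v)), averaged[ok, ])
      # single-variable ROC on the natural scale, direction from the OR sign
      nat <- roc_analysis(averaged[[v]][ok], averaged$lame[ok])
      list(model = m, natural_roc = nat)
    }))
  accel_sig <- intersect(sig, accelerometer_variables())
  bundle$multivariable <- if (length(sig) >= 2)
    .stage("multivariable", build_multivariable(averaged, averaged$lame, sig,
                                                config$alpha, config$rho_max))
  bundle$multivariable_accel <- if (length(accel_sig) >= 2)
    .stage("multivariable_accel",
           build_multivariable(averaged, averaged$lame, accel_sig,
                               config$alpha, config$rho_max))
  bundle$frozen <- .stage("frozen", lapply(
    stats::setNames(nm = c("A", "B")), function(id) {
      m <- frozen_model(id)
      evaluate_model(m, averaged, averaged$lame)
    }))
  class(bundle) <- "pipeline_bundle"
  if (!is.null(config$output_dir)) write_pipeline_outputs(bundle, config$output_dir)
  bundle
}

# Replace the day-level accelerometer targets by what segmentation of a
# synthesized event stream actually measures (full end-to-end path).
.rebuild_daily_from_streams <- function(cohort, seed) {
  daily <- cohort$daily
  for (i in seq_len(nrow(daily))) {
    row <- daily[i, ]
    st <- simulate_event_stream(row, seed = derive_seed(seed, 100 + i))
    hh <- simulate_hourly_halter(row, seed = derive_seed(seed, 200 + i))
    hourly <- summarize_hourly(st, hh)
    ds <- daily_summary(hourly)
    for (v in setdiff(names(ds), c("cow_id", "day")))
      daily[i, v] <- ds[[v]]
  }
  cohort$daily <- daily
  cohort
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Render a human-readable pipeline report
#'
#' @param bundle A `pipeline_bundle`.
#' @return Character vector of report lines.
#' @export
render_report <- function(bundle) {
  out <- c("== Lameness detection pipeline report ==",
           sprintf("seed %d | %d cows simulated | %d analyzable",
                   bundle$config$seed, nrow(bundle$cohort$cows),
                   if (is.null(bundle$averaged)) 0L else nrow(bundle$averaged)))
  if (!is.null(bundle$note)) return(c(out, bundle$note))
  out <- c(out, "", "-- Group comparison (non-lame vs lame) --")
  cmp <- bundle$comparisons
  out <- c(out, sprintf("%-20s %9s %8s %9s %8s  %-12s %8s", "variable",
                        "mean_C", "sd_C", "mean_L", "sd_L", "test", "p"))
  out <- c(out, sprintf("%-20s %9.2f %8.2f %9.2f %8.2f  %-12s %8.4f%s",
                        cmp$variable, cmp$mean_C, cmp$sd_C, cmp$mean_L,
                        cmp$sd_L, cmp$test, cmp$p_value,
                        ifelse(cmp$significant, " *", "")))
  out <- c(out, "", "-- Severity groups (compact letters) --")
  for (v in names(bundle$four_group)) {
    fg <- bundle$four_group[[v]]
    out <- c(out, sprintf("%s [%s, omnibus p %.4f]: %s", v, fg$route,
                          fg$omnibus_p,
                          paste(names(fg$letters), fg$letters, sep = "=",
                                collapse = " ")))
  }
  out <- c(out, "", "-- Univariable models (natural-scale cutoffs) --")
  for (v in names(bundle$univariable)) {
    u <- bundle$univariable[[v]]
    out <- c(out, sprintf(
      "%-20s OR %5.2f  P %.4f  AUC %.2f  cutoff %8.4g  sens %5.1f  spec %5.1f",
      v, u$model$or_table$or[1], u$model$or_table$p_wald[1], u$natural_roc$auc,
      u$natural_roc$cutoff, u$natural_roc$sensitivity,
      u$natural_roc$specificity))
  }
  out <- c(out, "", "-- Multivariable selection --")
  for (nm in c("multivariable", "multivariable_accel")) {
    lbl <- if (nm == "multivariable") "all candidates" else "accelerometer only"
    sel <- bundle[[nm]]
    out <- c(out, if (is.null(sel)) sprintf("[%s] skipped", lbl)
             else sprintf("[%s] final: %s (AUC %.2f)", lbl,
                          paste(names(sel$final$coefficients), collapse = " + "),
                          sel$final$roc$auc))
  }
  out <- c(out, "", "-- Frozen published models --")
  for (id in names(bundle$frozen)) {
    f <- bundle$frozen[[id]]
    out <- c(out, sprintf(
      "model %s at cutoff %5.2f: sens %5.1f%%  spec %5.1f%%  correct %5.1f%%  AUC %.3f",
      id, f$cutoff, f$sensitivity, f$specificity, f$proportion_correct, f$auc))
  }
  out
}

#' Write pipeline artifacts as CSV
#'
#' @param bundle A `pipeline_bundle`.
#' @param dir Output directory (created if needed).
#' @export
write_pipeline_outputs <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_summary_table(bundle$averaged, file.path(dir, "averaged_summaries.csv"))
  write_summary_table(bundle$selection_log, file.path(dir, "day_selection.csv"))
  write_summary_table(bundle$cohort$flags, file.path(dir, "day_flags.csv"))
  if (!is.null(bundle$comparisons))
    write_summary_table(bundle$comparisons, file.path(dir, "comparisons.csv"))
  if (!is.null(bundle$univariable)) {
    uni <- do.call(rbind, lapply(names(bundle$univariable), function(v) {
      u <- bundle$univariable[[v]]
      data.frame(variable = v, or = u$model$or_table$or[1],
                 or_low = u$model$or_table$or_low[1],
                 or_high = u$model$or_table$or_high[1],
                 p_wald = u$model$or_table$p_wald[1],
                 auc = u$natural_roc$auc, cutoff = u$natural_roc$cutoff,
                 sensitivity = u$natural_roc$sensitivity,
                 specificity = u$natural_roc$specificity,
                 proportion_correct = u$natural_roc$proportion_correct)
    }))
    write_summary_table(uni, file.path(dir, "univariable_models.csv"))
    for (v in names(bundle$univariable))
      write_roc_csv(bundle$univariable[[v]]$natural_roc,
                    file.path(dir, paste0("roc_", v, ".csv")))
  }
  frozen <- do.call(rbind, lapply(names(bundle$frozen), function(id) {
    f <- bundle$frozen[[id]]
    data.frame(model = id, cutoff = f$cutoff, sensitivity = f$sensitivity,
               specificity = f$specificity,
               proportion_correct = f$proportion_correct, auc = f$auc)
  }))
  write_summary_table(frozen, file.path(dir, "frozen_models.csv"))
  writeLines(render_report(bundle), file.path(dir, "report.txt"))
  invisible(dir)
}
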