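# Bout segmentation of classified posture/stride event streams.
#
# Rules (all inequalities strict at the thresholds):
#   * walking bout: a maximal run of >= 3 strides whose successive
#     inter-stride gaps do not exceed 4 s; strides outside such runs are not
#     counted in the "strides" variable;
#   * lying bout: a maximal lying interval strictly longer than 50 s;
#   * standing bout: an upright, non-walking period lasting > 50 s when the
#     preceding state is lying (or the start of the day) and > 4 s when the
#     preceding state is walking.
# Sub-threshold periods are not bouts but their time still counts toward the
# state's total, so lying + standing + walking time always closes the 1440-min
# daily budget.

validate_event_stream <- function(stream) {
  if (!inherits(stream, "event_stream"))
    stop("expected an event_stream object")
  p <- stream$posture
  if (nrow(p) == 0) stop("empty posture channel")
  if (any(p$end_s <= p$start_s)) stop("posture intervals must have end > start")
  if (nrow(p) > 1) {
    if (any(abs(p$start_s[-1] - p$end_s[-nrow(p)]) > 1e-6))
      stop("posture intervals must be contiguous and non-overlapping")
  }
  if (!all(p$state %in% c("lying", "upright")))
    stop("posture states must be 'lying' or 'upright'")
  s <- stream$strides
  if (nrow(s) > 0) {
    if (is.unsorted(s$timestamp_s)) stop("stride events must be time-ordered")
    if (any(s$stride_duration_ms <= 0) || any(s$stride_distance_cm <= 0))
      stop("stride duration and distance must be positive")
    up <- p[p$state == "upright", , drop = FALSE]
    idx <- findInterval(s$timestamp_s, up$start_s)
    inside <- idx >= 1 & s$timestamp_s < up$end_s[pmax(idx, 1)]
    if (!all(inside)) stop("stride events must fall inside upright intervals")
  }
  invisible(stream)
}

#' Detect walking bouts from ordered stride events
#'
#' A walking bout is a maximal run of at least 3 strides in which the time
#' between consecutive strides never exceeds 4 s.  Strides not belonging to
#' such a run are not counted.
#'
#' @param strides Data frame with `timestamp_s`, `stride_duration_ms` and
#'   (optionally) `stride_distance_cm`, ordered by time.
#' @param max_gap_s Maximum inter-stride gap within a bout (default 4 s).
#' @param min_strides Minimum strides per bout (default 3).
#' @return Data frame of bouts: `type`, `start_s`, `end_s`, `n_strides`.
#' @export
detect_walking_bouts <- function(strides, max_gap_s = 4, min_strides = 3L) {
  empty <- data.frame(type = character(0), start_s = numeric(0),
                      end_s = numeric(0), n_strides = integer(0))
  if (is.null(strides) || nrow(strides) == 0) return(empty)
  t <- strides$timestamp_s
  if (is.unsorted(t)) stop("stride events must be time-ordered")
  run_id <- cumsum(c(1, diff(t) > max_gap_s))
  out <- lapply(split(seq_along(t), run_id), function(idx) {
    if (length(idx) < min_strides) return(NULL)
    last <- idx[length(idx)]
    data.frame(type = "walking", start_s = t[idx[1]],
               end_s = t[last] + strides$stride_duration_ms[last] / 1000,
               n_strides = length(idx))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

#' Detect lying bouts from posture intervals
#'
#' Each maximal lying interval strictly longer than `min_s` (50 s) yields one
#' lying bout; shorter lying intervals count toward lying time but not toward
#' the bout count.
#'
#' @param posture Data frame with `start_s`, `end_s`, `state`.
#' @param min_s Minimum duration in seconds (strict).
#' @return Data frame of bouts: `type`, `start_s`, `end_s`, `n_strides` (NA).
#' @export
detect_lying_bouts <- function(posture, min_s = 50) {
  ly <- posture[posture$state == "lying" &
                  (posture$end_s - posture$start_s) > min_s, , drop = FALSE]
  if (nrow(ly) == 0)
    return(data.frame(type = character(0), start_s = numeric(0),
                      end_s = numeric(0), n_strides = integer(0)))
  data.frame(type = "lying", start_s = ly$start_s, end_s = ly$end_s,
             n_strides = NA_integer_, row.names = NULL)
}

#' Detect standing bouts from posture intervals and walking bouts
#'
#' Candidate standing periods are the upright intervals minus the walking
#' bouts.  A candidate qualifies as a standing bout if it lasts more than
#' 50 s when the cow was previously lying (the start of the day is treated
#' the same way) or more than 4 s when the cow was previously walking.
#'
#' @param posture Data frame with `start_s`, `end_s`, `state`.
#' @param walking_bouts Output of [detect_walking_bouts()].
#' @return Data frame of bouts: `type`, `start_s`, `end_s`, `n_strides` (NA).
#' @export
detect_standing_bouts <- function(posture, walking_bouts) {
  empty <- data.frame(type = character(0), start_s = numeric(0),
                      end_s = numeric(0), n_strides = integer(0))
  up <- posture[posture$state == "upright", , drop = FALSE]
  if (nrow(up) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(up))) {
    u0 <- up$start_s[i]; u1 <- up$end_s[i]
    wb <- walking_bouts[walking_bouts$start_s >= u0 - 1e-9 &
                          walking_bouts$end_s <= u1 + 1e-9, , drop = FALSE]
    if (nrow(wb) > 0 &&
        (any(wb$start_s < u0 - 1e-9) || any(wb$end_s > u1 + 1e-9)))
      stop("walking bout overlaps an upright interval boundary")
    cuts_start <- c(u0, wb$end_s)
    cuts_end <- c(wb$start_s, u1)
    after <- c("lying", rep("walking", nrow(wb)))
    for (j in seq_along(cuts_start)) {
      dur <- cuts_end[j] - cuts_start[j]
      if (dur <= 1e-9) next
      thr <- if (after[j] == "lying") 50 else 4
      if (dur > thr)
        out[[length(out) + 1L]] <- data.frame(
          type = "standing", start_s = cuts_start[j], end_s = cuts_end[j],
          n_strides = NA_integer_)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Segment one cow-day event stream into bouts and state totals
#'
#' Applies the walking, lying and standing bout rules and returns bouts plus
#' daily state totals.  Walking time is the summed extent of the walking
#' bouts (first stride start to last stride end); upright time not spent
#' walking is standing time, so the three state times sum to the full day.
#'
#' @param stream An `event_stream`.
#' @return An object of class `segmented_day`: list with `bouts` (data frame)
#'   and `totals` (lying/standing/walking time in min, bout counts, counted
#'   strides, mean stride duration ms and distance cm over counted strides).
#' @export
segment_events <- function(stream) {
  validate_event_stream(stream)
  p <- stream$posture
  s <- stream$strides
  up <- p[p$state == "upright", , drop = FALSE]
  # Chain strides within a single upright interval only: a posture change to
  # lying always breaks a walking bout.
  wb <- if (nrow(s) > 0) {
    iv <- findInterval(s$timestamp_s, up$start_s)
    do.call(rbind, lapply(split(s, iv), detect_walking_bouts))
  } else detect_walking_bouts(s)
  if (is.null(wb)) wb <- detect_walking_bouts(s[0, , drop = FALSE])
  rownames(wb) <- NULL
  wb <- wb[order(wb$start_s), , drop = FALSE]
  lb <- detect_lying_bouts(p)
  sb <- detect_standing_bouts(p, wb)
  day_s <- max(p$end_s) - min(p$start_s)
  lying_s <- sum(p$end_s[p$state == "lying"] - p$start_s[p$state == "lying"])
  walking_s <- sum(wb$end_s - wb$start_s)
  counted <- integer(0)
  if (nrow(wb) > 0 && nrow(s) > 0) {
    for (k in seq_len(nrow(wb)))
      counted <- c(counted, which(s$timestamp_s >= wb$start_s[k] - 1e-9 &
                                    s$timestamp_s <= wb$end_s[k] + 1e-9))
    counted <- unique(counted)
  }
  totals <- list(
    lying_time = lying_s / 60,
    standing_time = (day_s - lying_s - walking_s) / 60,
    walking_time = walking_s / 60,
    lying_bouts = nrow(lb), standing_bouts = nrow(sb), walking_bouts = nrow(wb),
    strides = length(counted),
    stride_duration = if (length(counted))
      mean(s$stride_duration_ms[counted]) else NA_real_,
    stride_distance = if (length(counted))
      mean(s$stride_distance_cm[counted]) else NA_real_)
  bouts <- rbind(lb, sb, wb)
  bouts <- bouts[order(bouts$start_s), , drop = FALSE]
  rownames(bouts) <- NULL
  structure(list(cow_id = stream$cow_id, day = stream$day,
                 bouts = bouts, totals = totals, counted_strides = counted),
            class = "segmented_day")
}

#' @export
print.segmented_day <- function(x, ...) {
  cat("Segmented day for", x$cow_id, "day", x$day, "\n")
  t <- x$totals
  cat(sprintf("  lying %.1f min (%d bouts), standing %.1f min (%d bouts), walking %.1f min (%d bouts)\n",
              t$lying_time, t$lying_bouts, t$standing_time, t$standing_bouts,
              t$walking_time, t$walking_bouts))
  cat(sprintf("  %d counted strides, mean duration %.0f ms, mean distance %.1f cm\n",
              t$strides, t$stride_duration %||% NA, t$stride_distance %||% NA))
  invisible(x)
}

# Overlap (seconds) of [a0,a1) intervals with window [w0,w1).
.overlap_s <- function(a0, a1, w0, w1) sum(pmax(pmin(a1, w1) - pmax(a0, w0), 0))

#' Hourly summaries of one cow-day
#'
#' Splits the segmented day into 24 one-hour rows.  State durations are split
#' across hour boundaries; bout counts are attributed to the hour containing
#' the bout start; stride count and mean stride duration/distance cover the
#' counted strides whose timestamps fall in the hour.  Halter variables
#' (noseband sensor), if supplied as a 24-row data frame, are carried through.
#'
#' @param stream An `event_stream`.
#' @param halter_hourly Optional 24-row data frame of hourly halter variables
#'   (`hour` 0..23 plus eating/ruminating columns).
#' @return Data frame with one row per hour.
#' @export
summarize_hourly <- function(stream, halter_hourly = NULL) {
  seg <- segment_events(stream)
  b <- seg$bouts
  s <- stream$strides
  p <- stream$posture
  counted <- seg$counted_strides
  rows <- lapply(0:23, function(h) {
    w0 <- h * 3600; w1 <- w0 + 3600
    ly <- p$state == "lying"
    lying <- .overlap_s(p$start_s[ly], p$end_s[ly], w0, w1) / 60
    wb <- b$type == "walking"
    walking <- .overlap_s(b$start_s[wb], b$end_s[wb], w0, w1) / 60
    in_hour <- function(type) sum(b$type == type & b$start_s >= w0 & b$start_s < w1)
    sc <- counted[s$timestamp_s[counted] >= w0 & s$timestamp_s[counted] < w1]
    data.frame(hour = h, lying_time = lying, standing_time = 60 - lying - walking,
               walking_time = walking,
               lying_bouts = in_hour("lying"), standing_bouts = in_hour("standing"),
               walking_bouts = in_hour("walking"), strides = length(sc),
               stride_duration = if (length(sc)) mean(s$stride_duration_ms[sc]) else NA_real_,
               stride_distance = if (length(sc)) mean(s$stride_distance_cm[sc]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(halter_hourly)) {
    stopifnot(nrow(halter_hourly) == 24)
    out <- cbind(out, halter_hourly[match(out$hour, halter_hourly$hour),
                                    setdiff(names(halter_hourly), "hour"),
                                    drop = FALSE])
  }
  cbind(cow_id = stream$cow_id, day = stream$day, out,
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Read or write an event stream as CSV
#'
#' The CSV schema has one row per event: `cow_id`, `day`, `channel`
#' (`posture` or `stride`), `start_s`, `end_s`, `state`, plus
#' `stride_duration_ms` and `stride_distance_cm` on stride rows.
#'
#' @param stream An `event_stream`.
#' @param path File path.
#' @return `read_event_stream()` returns an `event_stream`.
#' @export
write_event_stream <- function(stream, path) {
  p <- data.frame(cow_id = stream$cow_id, day = stream$day, channel = "posture",
                  start_s = stream$posture$start_s, end_s = stream$posture$end_s,
                  state = stream$posture$state,
                  stride_duration_ms = NA_real_, stride_distance_cm = NA_real_)
  s <- if (nrow(stream$strides) > 0)
    data.frame(cow_id = stream$cow_id, day = stream$day, channel = "stride",
               start_s = stream$strides$timestamp_s, end_s = NA_real_,
               state = NA_character_,
               stride_duration_ms = stream$strides$stride_duration_ms,
               stride_distance_cm = stream$strides$stride_distance_cm)
  else NULL
  utils::write.csv(rbind(p, s), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_stream
#' @export
read_event_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cow_id", "day", "channel", "start_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event-stream CSV missing columns: ",
                         paste(miss, collapse = ", "))
  p <- df[df$channel == "posture", , drop = FALSE]
  s <- df[df$channel == "stride", , drop = FALSE]
  structure(list(cow_id = df$cow_id[1], day = df$day[1],
                 posture = data.frame(start_s = p$start_s, end_s = p$end_s,
                                      state = p$state, stringsAsFactors = FALSE),
                 strides = data.frame(timestamp_s = s$start_s,
                                      stride_duration_ms = s$stride_duration_ms,
                                      stride_distance_cm = s$stride_distance_cm)),
            class = "event_stream")
}
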