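# Fixture builders and independent brute-force oracles used across tests.

# Build an event_stream from posture segments (list of c(duration_s, state))
# and stride specs (data frame timestamp_s / stride_duration_ms /
# stride_distance_cm).  The posture timeline is padded with a final upright
# interval to cover the full day.
make_stream <- function(segments, strides = NULL, day_s = 86400) {
  t <- 0; rows <- list()
  for (seg in segments) {
    rows[[length(rows) + 1L]] <- data.frame(
      start_s = t, end_s = t + seg[[1]], state = seg[[2]])
    t <- t + as.numeric(seg[[1]])
  }
  if (t < day_s) {
    last_state <- rows[[length(rows)]]$state
    pad_state <- if (last_state == "upright") "upright" else "upright"
    rows[[length(rows) + 1L]] <- data.frame(start_s = t, end_s = day_s,
                                            state = pad_state)
  }
  posture <- do.call(rbind, rows)
  # merge adjacent same-state rows
  keep <- posture[1, ]
  for (i in seq_len(nrow(posture))[-1]) {
    j <- nrow(keep)
    if (posture$state[i] == keep$state[j]) keep$end_s[j] <- posture$end_s[i]
    else keep <- rbind(keep, posture[i, ])
  }
  if (is.null(strides))
    strides <- data.frame(timestamp_s = numeric(0),
                          stride_duration_ms = numeric(0),
                          stride_distance_cm = numeric(0))
  structure(list(cow_id = "cowT", day = 1L, posture = keep, strides = strides),
            class = "event_stream")
}

make_strides <- function(timestamps, duration_ms = 1500, distance_cm = 120) {
  data.frame(timestamp_s = timestamps,
             stride_duration_ms = rep_len(duration_ms, length(timestamps)),
             stride_distance_cm = rep_len(distance_cm, length(timestamps)))
}

# Brute-force segmentation oracle: an explicit chronological scan that
# re-derives every bout boundary from first principles, independently of the
# vectorized implementation.
oracle_segment <- function(stream) {
  p <- stream$posture
  s <- stream$strides
  # walking bouts: scan strides one by one, chaining while the gap <= 4 s and
  # both strides sit in the same upright interval
  interval_of <- function(ts) {
    for (i in seq_len(nrow(p)))
      if (ts >= p$start_s[i] && ts < p$end_s[i]) return(i)
    NA_integer_
  }
  walking <- list(); run <- c()
  flush <- function(run) {
    if (length(run) >= 3) {
      last <- run[length(run)]
      walking[[length(walking) + 1L]] <<- c(
        start = s$timestamp_s[run[1]],
        end = s$timestamp_s[last] + s$stride_duration_ms[last] / 1000,
        n = length(run))
    }
  }
  if (nrow(s) > 0) {
    run <- 1L
    for (i in seq_len(nrow(s))[-1]) {
      same_iv <- identical(interval_of(s$timestamp_s[i]),
                           interval_of(s$timestamp_s[i - 1]))
      if (s$timestamp_s[i] - s$timestamp_s[i - 1] <= 4 && same_iv)
        run <- c(run, i)
      else { flush(run); run <- i }
    }
    flush(run)
  }
  wb <- if (length(walking)) do.call(rbind, walking) else
    matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("start", "end", "n")))
  # lying bouts
  lying <- p[p$state == "lying", , drop = FALSE]
  lb <- lying[lying$end_s - lying$start_s > 50, , drop = FALSE]
  # standing bouts: walk the timeline of upright intervals, cutting out
  # walking bouts, tracking the preceding state
  standing <- list()
  for (i in seq_len(nrow(p))) {
    if (p$state[i] != "upright") next
    cuts <- c(p$start_s[i])
    prev <- "lying"   # upright intervals start after lying or at day start
    inside <- wb[wb[, "start"] >= p$start_s[i] - 1e-9 &
                   wb[, "end"] <= p$end_s[i] + 1e-9, , drop = FALSE]
    pos <- p$start_s[i]
    consider <- function(from, to, prev) {
      thr <- if (prev == "lying") 50 else 4
      if (to - from > thr + 1e-12)
        standing[[length(standing) + 1L]] <<- c(start = from, end = to)
    }
    for (k in seq_len(nrow(inside))) {
      consider(pos, inside[k, "start"], prev)
      pos <- inside[k, "end"]; prev <- "walking"
    }
    consider(pos, p$end_s[i], prev)
  }
  counted <- if (nrow(wb) > 0) sum(wb[, "n"]) else 0
  list(lying_bouts = nrow(lb), standing_bouts = length(standing),
       walking_bouts = nrow(wb), strides = counted,
       lying_time = sum(lying$end_s - lying$start_s) / 60,
       walking_time = if (nrow(wb)) sum(wb[, "end"] - wb[, "start"]) / 60 else 0,
       walking_starts = if (nrow(wb)) unname(wb[, "start"]) else numeric(0))
}

# Exact two-sided Wilcoxon rank-sum p value by full enumeration of all
# choose(n1+n2, n1) group assignments.
oracle_wilcoxon_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  r <- rank(all_v)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(all_v), n1)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(all_v) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Pairwise Mann-Whitney AUC oracle: mean over all lame/non-lame pairs of
# 1[pos > neg] + 0.5 * 1[pos == neg].
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Small random event stream (<= ~50 events) exercising all bout rules.
random_small_stream <- function(seed) {
  set.seed(seed)
  segments <- list()
  t_total <- 0
  n_seg <- sample(2:7, 1)
  state <- sample(c("lying", "upright"), 1)
  for (i in seq_len(n_seg)) {
    dur <- sample(c(10, 30, 45, 49, 50, 51, 55, 120, 400, 3000), 1)
    segments[[i]] <- list(dur, state)
    t_total <- t_total + dur
    state <- if (state == "lying") "upright" else "lying"
  }
  st <- make_stream(segments)
  up <- st$posture[st$posture$state == "upright", , drop = FALSE]
  strides <- NULL
  for (i in seq_len(nrow(up))) {
    n <- sample(0:8, 1)
    if (n == 0) next
    gaps <- sample(c(1, 1.5, 2, 3.5, 4, 4.1, 5, 8), n, replace = TRUE)
    ts <- up$start_s[i] + 0.5 + cumsum(gaps)
    ts <- ts[ts < up$end_s[i] - 2]
    if (length(ts)) strides <- rbind(strides, make_strides(ts, 900, 110))
  }
  if (!is.null(strides)) {
    strides <- strides[order(strides$timestamp_s), ]
    st$strides <- strides
  }
  st
}

# Compact synthetic cohort params for fast pipeline tests.
small_params <- function() {
  p <- cohort_params(split_lame = FALSE)
  p[[1]]$n <- 6L; p[[2]]$n <- 10L
  p
}
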