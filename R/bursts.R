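#' Burst-calling parameters
#'
#' Each baseline-zeroed trajectory is smoothed by a lowess (locally weighted
#' linear regression, tricube weights, no robustifying iterations) within a
#' window of `lowess_window_frames` timeframes.  A burst starts when the
#' smoothed trace rises above `threshold` and ends when it drops back to or
#' below it; touching bursts are divided at interior valleys (see
#' [split_touching_bursts()]); candidates shorter than
#' `min_duration_frames` are discarded as false positives.
#'
#' The threshold is intentionally a required, explicit input: it is an
#' intensity in trace units and depends on the imaging calibration.
#' [default_burst_threshold()] offers a data-driven heuristic.
#'
#' @param threshold burst-calling intensity threshold (trace units, >= 0).
#' @param lowess_window_frames smoothing window in timeframes (>= 2).
#' @param min_duration_frames minimum retained burst duration (frames).
#' @return an object of class `burst_call_config`.
#' @export
burst_call_config <- function(threshold, lowess_window_frames = 10L,
                              min_duration_frames = 5L) {
  assert_scalar_num(threshold, "threshold", 0)
  assert_scalar_num(lowess_window_frames, "lowess_window_frames", 2,
                    integer = TRUE)
  assert_scalar_num(min_duration_frames, "min_duration_frames", 1,
                    integer = TRUE)
  structure(list(threshold = threshold,
                 lowess_window_frames = as.integer(lowess_window_frames),
                 min_duration_frames = as.integer(min_duration_frames)),
            class = "burst_call_config")
}

#' Heuristic burst threshold from sub-median fluctuations
#'
#' Estimates the noise floor of a baseline-zeroed trace as the median
#' absolute deviation (around the trace median) of the values at or below
#' the median — i.e. of the quiescent fluctuations — and places the
#' threshold `k` such MADs above the median.
#'
#' @param x baseline-zeroed trace values.
#' @param k multiplier (default 3).
#' @return a single threshold value.
#' @export
default_burst_threshold <- function(x, k = 3) {
  m <- stats::median(x)
  sub <- x[x <= m]
  m + k * stats::mad(sub, center = m)
}

#' Smooth a trajectory with a fixed-window lowess
#'
#' Locally weighted linear regression (tricube weights, 0 robustifying
#' iterations) with span equal to `lowess_window_frames / length(trace)`,
#' evaluated at every frame.  Exact on constant and linear trajectories.
#' Traces shorter than the window are smoothed with the span clamped to the
#' full trace, with a warning.
#'
#' @param x numeric trace values (one per frame).
#' @param config a [burst_call_config()].
#' @return smoothed numeric vector of the same length.
#' @export
smooth_trace <- function(x, config) {
  n <- length(x)
  w <- config$lowess_window_frames
  if (n < w) {
    warning("trace shorter than smoothing window; span clamped to trace")
    f <- 1
  } else {
    f <- w / n
  }
  stats::lowess(seq_len(n), x, f = f, iter = 0, delta = 0)$y
}

#' Divide touching bursts at interior valleys
#'
#' Within a supra-threshold run of the smoothed series, a division point is
#' any interior frame `t` whose value strictly decreased over the prior two
#' frames (`s[t-2] > s[t-1] > s[t]`) and strictly increases over the next
#' two (`s[t] < s[t+1] < s[t+2]`), indices taken within the run.  The run is
#' divided there, the valley frame starting the later fragment; the rule is
#' applied left-to-right and re-evaluated on the remaining fragment.
#' Plateau valleys (non-strict) do not divide.
#'
#' @param s smoothed values of one supra-threshold run.
#' @return list of integer index vectors (relative to the run) partitioning
#'   the run.
#' @export
split_touching_bursts <- function(s) {
  n <- length(s)
  if (n >= 5L) {
    for (t in 3:(n - 2L)) {
      if (s[t - 2L] > s[t - 1L] && s[t - 1L] > s[t] &&
          s[t] < s[t + 1L] && s[t + 1L] < s[t + 2L]) {
        rest <- split_touching_bursts(s[t:n])
        return(c(list(seq_len(t - 1L)),
                 lapply(rest, function(ix) ix + t - 1L)))
      }
    }
  }
  list(seq_len(n))
}

#' Call bursts in a single trace
#'
#' Smooths the baseline-zeroed trace ([smooth_trace()]), takes maximal runs
#' of frames with smoothed value strictly above the threshold, divides
#' touching bursts at valleys ([split_touching_bursts()]), discards
#' fragments shorter than `min_duration_frames`, and integrates the
#' baseline-zeroed raw trace over each retained interval as the burst size.
#'
#' @param raw baseline-zeroed raw trace values (one per frame).
#' @param config a [burst_call_config()].
#' @return data.frame with `start`, `end` (inclusive frames), `duration`,
#'   `size`.
#' @export
call_bursts <- function(raw, config) {
  stopifnot(inherits(config, "burst_call_config"))
  sm <- smooth_trace(raw, config)
  runs <- runs_true(sm > config$threshold)
  out <- list()
  for (k in seq_len(nrow(runs))) {
    a <- runs$start[k]; b <- runs$end[k]
    frags <- split_touching_bursts(sm[a:b])
    for (ix in frags) {
      if (length(ix) >= config$min_duration_frames) {
        s <- a + ix[1L] - 1L; e <- a + ix[length(ix)] - 1L
        out[[length(out) + 1L]] <-
          data.frame(start = s, end = e, duration = e - s + 1L,
                     size = sum(raw[s:e]))
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      duration = integer(), size = numeric()))
  do.call(rbind, out)
}

#' Call bursts for every trace in a trace table
#'
#' @param traces a `spot_traces` data.frame (see [build_traces()]).
#' @param config a [burst_call_config()].
#' @return data.frame: `lineage_id`, `channel`, `start`, `end`, `duration`,
#'   `size`.
#' @export
call_all_bursts <- function(traces, config) {
  grp <- split(traces, list(traces$lineage_id, traces$channel), drop = TRUE)
  out <- lapply(grp, function(g) {
    g <- g[order(g$frame), ]
    b <- call_bursts(g$baseline_zeroed, config)
    b$start <- g$frame[b$start]; b$end <- g$frame[b$end]
    if (nrow(b)) cbind(data.frame(lineage_id = g$lineage_id[1L],
                                  channel = g$channel[1L]), b)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(lineage_id = integer(), channel = character(),
                      start = integer(), end = integer(),
                      duration = integer(), size = numeric())
  out <- out[order(out$lineage_id, out$channel, out$start), ]
  rownames(out) <- NULL
  out
}

#' Per-nucleus burst summary
#'
#' Burst frequency is the total number of retained bursts per nucleus over
#' the analysed window; total output is the integral (sum) of the
#' baseline-zeroed raw trajectory over all time points; onset is the first
#' burst start (NA when never active).
#'
#' @param bursts data.frame from [call_all_bursts()].
#' @param traces the matching `spot_traces` data.frame.
#' @return data.frame: `lineage_id`, `channel`, `burst_frequency`,
#'   `total_output`, `onset`, `ever_active`.
#' @export
summarize_nuclei <- function(bursts, traces) {
  grp <- split(traces, list(traces$lineage_id, traces$channel), drop = TRUE)
  out <- lapply(grp, function(g) {
    b <- bursts[bursts$lineage_id == g$lineage_id[1L] &
                bursts$channel == g$channel[1L], , drop = FALSE]
    data.frame(lineage_id = g$lineage_id[1L], channel = g$channel[1L],
               burst_frequency = nrow(b),
               total_output = sum(g$baseline_zeroed),
               onset = if (nrow(b)) min(b$start) else NA_integer_,
               ever_active = nrow(b) > 0L)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$lineage_id, out$channel), ]
  rownames(out) <- NULL
  out
}

#' Cumulative fraction of ever-active nuclei
#'
#' Fraction of nuclei whose first burst started at or before each frame; a
#' monotone non-decreasing step function whose final value is the
#' ever-active fraction.
#'
#' @param summaries data.frame from [summarize_nuclei()] (one channel).
#' @param n_frames number of frames of the analysed window.
#' @return numeric vector of length `n_frames`.
#' @export
cumulative_active_fraction <- function(summaries, n_frames) {
  n <- nrow(summaries)
  if (!n) return(rep(0, n_frames))
  vapply(seq_len(n_frames), function(t)
    sum(!is.na(summaries$onset) & summaries$onset <= t) / n, numeric(1))
}

#' Frames covered by retained bursts, per lineage
#'
#' @param bursts data.frame from [call_all_bursts()] (one channel).
#' @param n_frames number of frames.
#' @return logical matrix `[lineage, frame]` with lineage ids as rownames.
#' @export
burst_occupancy <- function(bursts, n_frames) {
  ids <- sort(unique(bursts$lineage_id))
  occ <- matrix(FALSE, length(ids), n_frames,
                dimnames = list(as.character(ids), NULL))
  for (k in seq_len(nrow(bursts)))
    occ[as.character(bursts$lineage_id[k]),
        bursts$start[k]:bursts$end[k]] <- TRUE
  occ
}

#' Instantaneous activity over currently bursting nuclei
#'
#' Per-frame mean of the baseline-zeroed signal over the nuclei that are
#' within a retained burst at that frame; frames with no active nucleus are
#' reported as `NA`.
#'
#' @param traces `spot_traces` data.frame (one channel).
#' @param bursts matching bursts data.frame (same channel).
#' @return data.frame: `frame`, `mean_activity`, `n_active`.
#' @export
instantaneous_activity <- function(traces, bursts) {
  frames <- sort(unique(traces$frame))
  n_frames <- max(frames)
  occ <- burst_occupancy(bursts, n_frames)
  out <- data.frame(frame = frames, mean_activity = NA_real_, n_active = 0L)
  for (k in seq_along(frames)) {
    t <- frames[k]
    act <- rownames(occ)[occ[, t]]
    if (length(act)) {
      v <- traces$baseline_zeroed[traces$frame == t &
                                  traces$lineage_id %in% as.integer(act)]
      out$mean_activity[k] <- mean(v)
      out$n_active[k] <- length(v)
    }
  }
  out
}

#' Mean activity over all analysed nuclei
#'
#' Per-frame mean of the baseline-zeroed signal over every analysed trace;
#' frames absent from excluded lineages are simply not represented.
#'
#' @param traces `spot_traces` data.frame (one channel).
#' @return data.frame: `frame`, `mean_activity`, `n`.
#' @export
mean_activity <- function(traces) {
  agg <- stats::aggregate(baseline_zeroed ~ frame, data = traces, FUN = mean)
  cnt <- stats::aggregate(baseline_zeroed ~ frame, data = traces, FUN = length)
  data.frame(frame = agg$frame, mean_activity = agg$baseline_zeroed,
             n = cnt$baseline_zeroed)
}

#' Two-group comparison by the two-sided Wilcoxon rank-sum test
#'
#' Computes the two-sided rank-sum p-value (exact where sample sizes permit
#' and there are no ties) and a Bonferroni-adjusted p-value
#' `min(1, p * n_comparisons)`.
#'
#' @param values_a,values_b numeric samples of per-nucleus statistics.
#' @param n_comparisons number of comparisons in the family (default 1).
#' @return list with `statistic`, `p_value`, `adjusted_p`.
#' @export
compare_groups <- function(values_a, values_b, n_comparisons = 1L) {
  if (!length(values_a) || !length(values_b))
    stop("both samples must be non-empty", call. = FALSE)
  if (length(unique(c(values_a, values_b))) == 1L) {
    ## fully tied pooled sample: no evidence of a difference
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p_value = 1, adjusted_p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       adjusted_p = min(1, wt$p.value * n_comparisons))
}
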