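#' Robust baseline and noise estimate for a current trace
#'
#' The baseline is the mode of a kernel-smoothed histogram of the samples
#' (the dominant closed-state level); if two near-equal modes are present the
#' lower one is chosen and the result is flagged. The noise SD is a median
#' absolute deviation (x 1.4826) of the samples near the baseline.
#'
#' @param trace a `current_trace` (or plain numeric vector of samples)
#' @return list with `baseline_pA`, `noise_sd_pA`, `bimodal` flag
#' @export
estimate_baseline <- function(trace) {
  x <- if (inherits(trace, "current_trace")) trace$current_pA else as.numeric(trace)
  if (length(x) < 1000) stop("trace too short for baseline estimation")
  if (stats::sd(x) == 0)
    return(list(baseline_pA = x[1], noise_sd_pA = 0, bimodal = FALSE))
  d <- stats::density(x, n = 2048)
  pk <- which(diff(sign(diff(d$y))) == -2) + 1L
  if (length(pk) == 0) pk <- which.max(d$y)
  main <- pk[which.max(d$y[pk])]
  big <- pk[d$y[pk] > 0.5 * d$y[main]]
  bimodal <- length(big) > 1
  mode_x <- d$x[min(big)]                    # lower mode on ambiguity
  r <- x - mode_x
  s0 <- stats::mad(r, center = 0)
  if (s0 > 0) {
    rr <- r[abs(r) < 4 * s0]
    s0 <- stats::mad(rr, center = 0)
    mode_x <- mode_x + stats::median(rr)
    s0 <- 1.4826 * stats::median(abs(r[abs(r - stats::median(rr)) < 4 * s0] -
                                       stats::median(rr)))
  }
  list(baseline_pA = mode_x, noise_sd_pA = s0, bimodal = bimodal)
}

#' Threshold-based event detection
#'
#' Finds maximal runs where the absolute deviation from baseline exceeds
#' `threshold_k * noise_sd` (an absolute floor of 0.5 pA is used when the
#' noise estimate is zero). Runs separated by less than the debounce gap are
#' merged (so rapid flickering stays one event); runs shorter than
#' `min_duration_s` are dropped. Intervals are half-open in samples.
#'
#' @param trace a `current_trace`
#' @param baseline_pA,noise_sd_pA baseline and noise; estimated with
#'   [estimate_baseline()] when NULL
#' @param threshold_k detection threshold in noise SDs (> 0)
#' @param min_duration_s minimum event duration (default 10 ms)
#' @param merge_gap_s debounce gap (default 50 ms)
#' @return data.frame with `start_idx`, `end_idx` (half-open), `start_s`,
#'   `end_s`, `duration_s`
#' @export
detect_events <- function(trace, baseline_pA = NULL, noise_sd_pA = NULL,
                          threshold_k = 5, min_duration_s = 0.010,
                          merge_gap_s = 0.050) {
  stopifnot(inherits(trace, "current_trace"), threshold_k > 0)
  if (is.null(baseline_pA) || is.null(noise_sd_pA)) {
    bl <- estimate_baseline(trace)
    if (is.null(baseline_pA)) baseline_pA <- bl$baseline_pA
    if (is.null(noise_sd_pA)) noise_sd_pA <- bl$noise_sd_pA
  }
  thr <- if (noise_sd_pA <= 0) 0.5 else threshold_k * noise_sd_pA
  fs <- trace$sampling_hz
  above <- abs(trace$current_pA - baseline_pA) > thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0) return(.empty_events())
  gap_n <- round(merge_gap_s * fs)
  merged <- runs[1, , drop = FALSE]
  for (k in seq_len(nrow(runs))[-1]) {
    if (runs[k, 1] - merged[nrow(merged), 2] - 1L <= gap_n)
      merged[nrow(merged), 2] <- runs[k, 2]
    else merged <- rbind(merged, runs[k, ])
  }
  dur <- (merged[, 2] - merged[, 1] + 1L) / fs
  keep <- dur >= min_duration_s
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0) return(.empty_events())
  data.frame(start_idx = merged[, 1], end_idx = merged[, 2] + 1L,
             start_s = (merged[, 1] - 1L) / fs, end_s = merged[, 2] / fs,
             duration_s = (merged[, 2] - merged[, 1] + 1L) / fs)
}

.empty_events <- function() {
  data.frame(start_idx = integer(), end_idx = integer(),
             start_s = numeric(), end_s = numeric(), duration_s = numeric())
}

#' Change-point segmentation of an event window into sub-levels
#'
#' Binary segmentation minimizing within-segment variance with a
#' BIC-type penalty scaled by the noise variance. Each accepted segment
#' reports its (edge-trimmed) mean current, dwell, within-segment SD and a
#' stability flag: stable iff the SD is at most `stable_sd_mult` times the
#' reference noise and the dwell is at least `stable_dwell_s`. Adjacent
#' segments whose means differ by less than 4 noise SDs are re-merged, so a
#' flat window always yields a single level.
#'
#' @param x samples of the event window
#' @param fs sampling rate (Hz)
#' @param noise_sd_pA reference noise SD (a floor of 0.2 pA guards the
#'   zero-noise case)
#' @param min_seg_s minimum segment length in seconds
#' @param stable_sd_mult,stable_dwell_s stability thresholds
#' @param max_segments recursion cap
#' @return data.frame with `start_idx`, `end_idx` (half-open, window-local),
#'   `dwell_s`, `mean_pA`, `sd_pA`, `stable`
#' @export
segment_levels <- function(x, fs, noise_sd_pA, min_seg_s = 0.0015,
                           stable_sd_mult = 1.5, stable_dwell_s = 0.050,
                           max_segments = 80) {
  x <- as.numeric(x)
  n <- length(x)
  sigma <- max(noise_sd_pA, 0.2)
  min_len <- max(4L, round(min_seg_s * fs))
  if (n < 2 * min_len) {
    return(.levels_df(1L, n + 1L, x, fs, sigma, stable_sd_mult, stable_dwell_s))
  }
  pen <- 40 * sigma^2 * log(n)     # stiff penalty: filtered noise is correlated
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  seg_sse <- function(l, r) {      # inclusive indices
    s <- cs[r] - if (l > 1) cs[l - 1] else 0
    s2 <- cs2[r] - if (l > 1) cs2[l - 1] else 0
    s2 - s^2 / (r - l + 1)
  }
  cuts <- c()
  recurse <- function(l, r) {
    if (length(cuts) + 1L >= max_segments) return(invisible())
    if (r - l + 1L < 2 * min_len) return(invisible())
    ks <- (l + min_len - 1L):(r - min_len)
    if (length(ks) == 0) return(invisible())
    sse0 <- seg_sse(l, r)
    gains <- vapply(ks, function(k) sse0 - seg_sse(l, k) - seg_sse(k + 1L, r),
                    numeric(1))
    kbest <- ks[which.max(gains)]
    if (max(gains) > pen) {
      cuts <<- c(cuts, kbest)
      recurse(l, kbest)
      recurse(kbest + 1L, r)
    }
    invisible()
  }
  recurse(1L, n)
  bounds <- sort(unique(c(1L, cuts + 1L, n + 1L)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  # re-merge adjacent segments with indistinguishable means
  means <- vapply(seq_along(starts), function(i)
    .trimmed_mean(x, starts[i], ends[i] - 1L), numeric(1))
  keep_cut <- rep(TRUE, length(starts) - 1L)
  if (length(starts) > 1) {
    i <- 1L
    while (i < length(starts)) {
      if (abs(means[i + 1] - means[i]) < 4 * sigma) {
        starts <- starts[-(i + 1)]
        ends <- ends[-i]
        means[i] <- .trimmed_mean(x, starts[i], ends[i] - 1L)
        means <- means[-(i + 1)]
      } else i <- i + 1L
    }
  }
  .levels_df(starts, ends, x, fs, sigma, stable_sd_mult, stable_dwell_s)
}

.trimmed_mean <- function(x, l, r) {
  len <- r - l + 1L
  tr <- min(5L, len %/% 4L)
  mean(x[(l + tr):(r - tr)])
}

.levels_df <- function(starts, ends, x, fs, sigma, sd_mult, dwell_min) {
  mean_pA <- numeric(length(starts)); sd_pA <- numeric(length(starts))
  for (i in seq_along(starts)) {
    l <- starts[i]; r <- ends[i] - 1L
    len <- r - l + 1L
    tr <- min(5L, len %/% 4L)
    xi <- x[(l + tr):(r - tr)]
    mean_pA[i] <- mean(xi)
    sd_pA[i] <- if (length(xi) > 1) stats::sd(xi) else 0
  }
  dwell <- (ends - starts) / fs
  data.frame(start_idx = starts, end_idx = ends, dwell_s = dwell,
             mean_pA = mean_pA, sd_pA = sd_pA,
             stable = sd_pA <= sd_mult * sigma & dwell >= dwell_min)
}

#' Classify an idealized event
#'
#' Three-way classification from the sub-level table: step-like iff the
#' stable open levels form exactly one conductance group and unstable time is
#' at most 10% of the event; multi-level iff the stable open levels form two
#' or more distinct groups; erratic otherwise (flickering / unstable
#' openings). Open levels are those deviating from baseline by more than
#' `open_thr_pA`; distinct groups are separated by more than 4 noise SDs.
#'
#' @param levels a [segment_levels()] data.frame
#' @param baseline_pA baseline current
#' @param noise_sd_pA reference noise SD
#' @param open_thr_pA threshold separating open from closed levels
#' @param unstable_budget maximum tolerated unstable fraction for step-like
#' @return one of "step_like", "multi_level", "erratic"
#' @export
classify_event <- function(levels, baseline_pA, noise_sd_pA, open_thr_pA,
                           unstable_budget = 0.10) {
  stopifnot(nrow(levels) >= 1)
  sigma <- max(noise_sd_pA, 0.2)
  open <- abs(levels$mean_pA - baseline_pA) > open_thr_pA
  total <- sum(levels$dwell_s)
  unstable_frac <- sum(levels$dwell_s[!levels$stable]) / total
  so <- levels[open & levels$stable, , drop = FALSE]
  if (nrow(so) == 0) return("erratic")
  m <- sort(so$mean_pA)
  groups <- 1L + sum(diff(m) > 4 * sigma)
  if (groups >= 2) return("multi_level")
  if (unstable_frac <= unstable_budget) "step_like" else "erratic"
}

# refine a raw threshold boundary to the half-amplitude crossing of the
# adjacent open level (the idealization convention); indices are inclusive
.refine_edges <- function(x, baseline, i0, i1) {
  lvl_s <- mean(x[min(i0 + 5L, i1):min(i0 + 40L, i1)])
  lvl_e <- mean(x[max(i1 - 40L, i0):max(i1 - 5L, i0)])
  half_s <- 0.5 * abs(lvl_s - baseline)
  half_e <- 0.5 * abs(lvl_e - baseline)
  lo <- max(1L, i0 - 10L); hi <- min(length(x), i1 + 10L)
  ws <- lo:min(i0 + 10L, i1)
  cand_s <- ws[abs(x[ws] - baseline) >= half_s]
  we <- max(i1 - 10L, i0):hi
  cand_e <- we[abs(x[we] - baseline) >= half_e]
  c(if (length(cand_s)) cand_s[1] else i0,
    if (length(cand_e)) cand_e[length(cand_e)] else i1)
}

#' Idealize a full trace into classified channel events
#'
#' The complete single-channel pipeline: baseline/noise estimation, event
#' detection, change-point sub-level segmentation, and three-way
#' classification. Event boundaries are refined to the half-amplitude
#' crossing of the adjacent open level and compensated for the known group
#' delay of the acquisition filter. The open current of an event is the
#' dwell-weighted mean of its stable open sub-levels (excluding edge
#' transients); for events with no stable level (erratic) the dwell-weighted
#' mean of all open sub-levels is used. Conductance is the
#' baseline-subtracted open current over the voltage. `n_levels` counts the
#' distinct stable open conductance groups (or, for events with no stable
#' level, the open sub-levels).
#'
#' @param trace a `current_trace`
#' @param voltage_mV applied voltage (defaults to the trace protocol's)
#' @param threshold_k,min_duration_s,merge_gap_s passed to [detect_events()]
#' @param ... passed to [segment_levels()]
#' @return data.frame of class `channel_events`: `start_s`, `end_s`,
#'   `duration_s`, `class`, `mean_open_pA`, `conductance_nS`, `n_levels`,
#'   plus attributes `levels` (per-event sub-level tables), `baseline`
#' @export
analyze_trace <- function(trace, voltage_mV = trace$protocol$voltage_mV,
                          threshold_k = 5, min_duration_s = 0.010,
                          merge_gap_s = 0.050, ...) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.null(voltage_mV) || voltage_mV == 0) stop("voltage must be nonzero")
  bl <- estimate_baseline(trace)
  ev <- detect_events(trace, bl$baseline_pA, bl$noise_sd_pA,
                      threshold_k, min_duration_s, merge_gap_s)
  thr <- if (bl$noise_sd_pA <= 0) 0.5 else threshold_k * bl$noise_sd_pA
  fs <- trace$sampling_hz
  # DC group delay of the 4-pole Bessel acquisition filter, in samples
  fc <- trace$protocol$filter_hz
  delay_n <- if (is.null(fc)) 0L else
    as.integer(round(fs * sum(-Re(1 / .bessel4_poles)) / (2 * pi * fc)))
  n_ev <- nrow(ev)
  cls <- character(n_ev); open_pA <- numeric(n_ev); n_lv <- integer(n_ev)
  start_s <- numeric(n_ev); end_s <- numeric(n_ev)
  lv_list <- vector("list", n_ev)
  sigma <- max(bl$noise_sd_pA, 0.2)
  for (k in seq_len(n_ev)) {
    w <- trace$current_pA[ev$start_idx[k]:(ev$end_idx[k] - 1L)]
    lv <- segment_levels(w, fs, bl$noise_sd_pA, ...)
    cls[k] <- classify_event(lv, bl$baseline_pA, bl$noise_sd_pA, thr)
    open <- abs(lv$mean_pA - bl$baseline_pA) > thr
    use <- if (any(open & lv$stable)) open & lv$stable else open
    open_pA[k] <- if (any(use))
      sum(lv$mean_pA[use] * lv$dwell_s[use]) / sum(lv$dwell_s[use])
    else max(abs(w - bl$baseline_pA)) + bl$baseline_pA
    st_open <- sort(lv$mean_pA[open & lv$stable])
    n_lv[k] <- if (length(st_open) > 0)
      1L + sum(diff(st_open) > 4 * sigma) else sum(open)
    edges <- .refine_edges(trace$current_pA, bl$baseline_pA,
                           ev$start_idx[k], ev$end_idx[k] - 1L)
    start_s[k] <- (edges[1] - 1L - delay_n) / fs
    end_s[k] <- (edges[2] - delay_n) / fs
    lv_list[[k]] <- lv
  }
  out <- data.frame(start_s = start_s, end_s = end_s,
                    duration_s = end_s - start_s, class = cls,
                    mean_open_pA = open_pA,
                    conductance_nS = (open_pA - bl$baseline_pA) / voltage_mV,
                    n_levels = n_lv, stringsAsFactors = FALSE)
  attr(out, "levels") <- lv_list
  attr(out, "baseline") <- bl
  class(out) <- c("channel_events", "data.frame")
  out
}

#' Conductance summary of step-like events
#'
#' Collects the open-state conductances of step-like events, summarizes them
#' as median and IQR (via [median_iqr()], the shared code path), and bins
#' them into a histogram.
#'
#' @param events a `channel_events` data.frame (or any data.frame with
#'   `class` and `conductance_nS`)
#' @param bin_width_nS histogram bin width (default 0.05 nS)
#' @return an object of class `conductance_summary`: list with `values_nS`,
#'   `n`, `median`, `q1`, `q3`, `breaks`, `counts`, `empty` flag
#' @export
event_conductances <- function(events, bin_width_nS = 0.05) {
  g <- events$conductance_nS[events$class == "step_like"]
  if (length(g) == 0) {
    out <- list(values_nS = numeric(), n = 0L, median = NA_real_,
                q1 = NA_real_, q3 = NA_real_, breaks = numeric(),
                counts = integer(), empty = TRUE)
    class(out) <- "conductance_summary"
    return(out)
  }
  q <- median_iqr(g)
  breaks <- seq(0, ceiling(max(g) / bin_width_nS) * bin_width_nS,
                by = bin_width_nS)
  h <- graphics::hist(g, breaks = breaks, plot = FALSE)
  out <- list(values_nS = g, n = length(g), median = q[["median"]],
              q1 = q[["q1"]], q3 = q[["q3"]],
              breaks = h$breaks, counts = h$counts, empty = FALSE)
  class(out) <- "conductance_summary"
  out
}

#' @export
print.conductance_summary <- function(x, ...) {
  if (x$empty) {
    cat("conductance summary: no step-like events\n")
  } else {
    cat(sprintf(
      "step-like conductance: median (IQR) = %.2f (%.2f-%.2f) nS, n = %d\n",
      x$median, x$q1, x$q3, x$n))
  }
  invisible(x)
}

#' Compare event-duration distributions against a cutoff
#'
#' Reports, per group, the fraction of events whose duration exceeds the
#' cutoff (1 s by default, the criterion separating genuine channel openings
#' from transient fusion events) and a two-sided Brunner-Munzel comparison of
#' the two duration distributions.
#'
#' @param durations_a,durations_b event durations in seconds (non-empty)
#' @param cutoff_s duration criterion
#' @param labels group labels
#' @return list with per-group `n`, `frac_over`, counts, the `bm_test`, and a
#'   `low_power` flag when either group has fewer than 10 events
#' @export
duration_analysis <- function(durations_a, durations_b, cutoff_s = 1.0,
                              labels = c("A", "B")) {
  stopifnot(length(durations_a) >= 1, length(durations_b) >= 1)
  bm <- if (length(durations_a) >= 2 && length(durations_b) >= 2)
    brunner_munzel(durations_a, durations_b) else NULL
  structure(list(
    labels = labels, cutoff_s = cutoff_s,
    n = c(length(durations_a), length(durations_b)),
    n_over = c(sum(durations_a > cutoff_s), sum(durations_b > cutoff_s)),
    frac_over = c(mean(durations_a > cutoff_s), mean(durations_b > cutoff_s)),
    bm_test = bm,
    low_power = length(durations_a) < 10 || length(durations_b) < 10
  ), class = "duration_analysis")
}

#' @export
print.duration_analysis <- function(x, ...) {
  cat(sprintf("event durations vs %.1f s cutoff\n", x$cutoff_s))
  for (i in 1:2)
    cat(sprintf("  %s: %d/%d events (%.0f%%) longer than cutoff\n",
                x$labels[i], x$n_over[i], x$n[i], 100 * x$frac_over[i]))
  if (!is.null(x$bm_test))
    cat(sprintf("  Brunner-Munzel: W = %.3f, p = %.4g\n",
                x$bm_test$statistic, x$bm_test$p.value))
  if (x$low_power) cat("  note: a group has fewer than 10 events (low power)\n")
  invisible(x)
}
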