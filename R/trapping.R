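#' Dwell (residence) events inside an axial window
#'
#' Finds maximal continuous runs of frames in which an ion's z coordinate
#' lies inside a window (typically the constriction region), per ion. Runs
#' separated by at most `gap_frames` outside frames are merged; runs shorter
#' than `min_duration_ns` are discarded. Durations use the half-open
#' convention: duration = (first frame after the run - first frame of the
#' run) in time units, so a run of k frames at save interval s has duration
#' k*s.
#'
#' @param traj an `ion_trajectory`
#' @param window z interval c(lo, hi) in nm; defaults to the trajectory's
#'   constriction window (trap center +/- half-width) when one is configured
#' @param min_duration_ns minimum duration to keep (>= 0)
#' @param gap_frames merge runs separated by at most this many outside frames
#' @return data.frame with `ion_id`, `species`, `entry_time_ns`,
#'   `exit_time_ns`, `duration_ns`
#' @export
dwell_events <- function(traj, window = NULL, min_duration_ns = 0,
                         gap_frames = 0) {
  stopifnot(inherits(traj, "ion_trajectory"), min_duration_ns >= 0,
            gap_frames >= 0)
  if (is.null(window)) {
    trap <- traj$config$trap
    if (is.null(trap))
      stop("no window given and the trajectory has no constriction configured")
    window <- c(trap$center_z - trap$half_width_nm,
                trap$center_z + trap$half_width_nm)
  }
  window <- as.numeric(window)
  if (length(window) != 2 || window[1] >= window[2]) stop("empty window")
  time_ns <- traj$time_ns
  nf <- length(time_ns)
  dt <- if (nf > 1) time_ns[2] - time_ns[1] else 0
  out <- vector("list", length(traj$ion_id))
  for (j in seq_along(traj$ion_id)) {
    inside <- traj$z[, j] >= window[1] & traj$z[, j] <= window[2]
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    if (gap_frames > 0 && nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (k in 2:nrow(runs)) {
        if (runs[k, 1] - merged[nrow(merged), 2] - 1L <= gap_frames)
          merged[nrow(merged), 2] <- runs[k, 2]
        else merged <- rbind(merged, runs[k, ])
      }
      runs <- merged
    }
    entry <- time_ns[runs[, 1]]
    # half-open exit: first frame after the run (extrapolated past the end)
    exit <- ifelse(runs[, 2] < nf, time_ns[pmin(runs[, 2] + 1L, nf)],
                   time_ns[nf] + dt)
    dur <- exit - entry
    keep <- dur >= min_duration_ns & dur > 0
    if (!any(keep)) next
    out[[j]] <- data.frame(ion_id = traj$ion_id[j], species = traj$species[j],
                           entry_time_ns = entry[keep],
                           exit_time_ns = exit[keep],
                           duration_ns = dur[keep], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(ion_id = integer(), species = character(),
                      entry_time_ns = numeric(), exit_time_ns = numeric(),
                      duration_ns = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary statistics of dwell events
#'
#' @param events a [dwell_events()] data.frame
#' @param species optional species selector ("K+" or "Cl-")
#' @return list with `n`, `mean_ns`, `median_ns`, `max_ns`,
#'   `total_occupancy_ns`; moments are NA (flagged) when there are no events
#' @export
dwell_summary <- function(events, species = NULL) {
  if (!is.null(species)) events <- events[events$species == species, , drop = FALSE]
  n <- nrow(events)
  if (n == 0)
    return(list(n = 0L, mean_ns = NA_real_, median_ns = NA_real_,
                max_ns = NA_real_, total_occupancy_ns = 0))
  d <- events$duration_ns
  list(n = n, mean_ns = mean(d), median_ns = stats::median(d),
       max_ns = max(d), total_occupancy_ns = sum(d))
}

#' Compare conduction and trapping between two conditions
#'
#' Runs the permeation analysis and the dwell analysis on two sets of
#' replicate trajectories (e.g. wild-type-like constriction vs unobstructed
#' mutant surrogate) over the same window and voltage, and reports
#' per-condition conductance aggregates, per-species dwell summaries, the
#' conductance difference, and the Cl- mean-dwell ratio. An optional
#' Brunner-Munzel test compares the pooled Cl- dwell durations.
#'
#' @param cond_a,cond_b lists of `ion_trajectory` replicates
#' @param labels character vector of two condition labels
#' @param window z interval c(lo, hi) for the dwell analysis; defaults to the
#'   constriction window of condition a's first trajectory
#' @param geom optional [pore_geometry()] for crossing counting
#' @param min_duration_ns dwell filter passed to [dwell_events()]
#' @param test logical; run a Brunner-Munzel test on Cl- dwell durations
#' @return an object of class `trap_comparison`
#' @export
compare_conditions <- function(cond_a, cond_b, labels = c("A", "B"),
                               window = NULL, geom = NULL,
                               min_duration_ns = 0, test = FALSE) {
  stopifnot(length(cond_a) >= 1, length(cond_b) >= 1, length(labels) == 2)
  V <- unique(c(vapply(cond_a, function(t) t$voltage_mV, numeric(1)),
                vapply(cond_b, function(t) t$voltage_mV, numeric(1))))
  if (length(V) != 1) stop("conditions recorded at different voltages")
  if (is.null(window)) {
    trap <- cond_a[[1]]$config$trap
    if (is.null(trap)) stop("no window given and condition a has no constriction")
    window <- c(trap$center_z - trap$half_width_nm,
                trap$center_z + trap$half_width_nm)
  }
  one_condition <- function(trajs) {
    est <- aggregate_replicates(lapply(trajs, estimate_conductance, geom = geom))
    dw <- do.call(rbind, lapply(trajs, dwell_events, window = window,
                                min_duration_ns = min_duration_ns))
    list(conductance = est,
         dwell_K = dwell_summary(dw, "K+"),
         dwell_Cl = dwell_summary(dw, "Cl-"),
         dwell_events = dw)
  }
  a <- one_condition(cond_a); b <- one_condition(cond_b)
  ratio <- if (is.na(b$dwell_Cl$mean_ns) || b$dwell_Cl$n == 0) {
    Inf
  } else if (is.na(a$dwell_Cl$mean_ns)) 0 else
    a$dwell_Cl$mean_ns / b$dwell_Cl$mean_ns
  bm <- NULL
  if (test) {
    da <- a$dwell_events$duration_ns[a$dwell_events$species == "Cl-"]
    db <- b$dwell_events$duration_ns[b$dwell_events$species == "Cl-"]
    if (length(da) >= 2 && length(db) >= 2) bm <- brunner_munzel(da, db)
  }
  structure(list(labels = labels, voltage_mV = V, window = window,
                 a = a, b = b,
                 G_diff_nS = a$conductance$G_mean_nS - b$conductance$G_mean_nS,
                 cl_dwell_ratio = ratio,
                 cl_dwell_ratio_flagged = !is.finite(ratio),
                 bm_test = bm),
            class = "trap_comparison")
}

#' @export
print.trap_comparison <- function(x, ...) {
  cat(sprintf("condition comparison at %+g mV, window [%.2f, %.2f] nm\n",
              x$voltage_mV, x$window[1], x$window[2]))
  for (side in c("a", "b")) {
    s <- x[[side]]
    lab <- x$labels[match(side, c("a", "b"))]
    cat(sprintf("  %s: G = %.3f +/- %.3f nS; Cl- dwell n = %d, mean = %s ns\n",
                lab, s$conductance$G_mean_nS, s$conductance$G_sd_nS,
                s$dwell_Cl$n,
                if (is.na(s$dwell_Cl$mean_ns)) "NA"
                else sprintf("%.3f", s$dwell_Cl$mean_ns)))
  }
  cat(sprintf("  G(%s) - G(%s) = %.3f nS; Cl- mean-dwell ratio %s/%s = %s\n",
              x$labels[1], x$labels[2], x$G_diff_nS, x$labels[1], x$labels[2],
              if (is.finite(x$cl_dwell_ratio))
                sprintf("%.2f", x$cl_dwell_ratio) else "Inf (flagged)"))
  if (!is.null(x$bm_test))
    cat(sprintf("  Brunner-Munzel on Cl- dwells: p = %.4g\n", x$bm_test$p.value))
  invisible(x)
}
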