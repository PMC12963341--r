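#' Acquisition and event-mixture protocol for synthetic recordings
#'
#' Describes the emulated planar-bilayer acquisition chain (+150 mV, 20 kHz
#' sampling, 4 kHz low-pass by default) and the ground-truth event mixture:
#' step-like openings (a single stable conductance level), multi-level
#' openings (2-3 stacked stable levels), and erratic openings (rapid
#' sub-100-ms flickering). Step conductances follow a two-piece log-normal
#' whose median and both quartiles equal the requested values exactly.
#' In `control` mode only short rectangular transients are generated
#' (emulating transient liposome fusion, most lasting under a second).
#'
#' @param voltage_mV applied voltage
#' @param sampling_hz sampling rate
#' @param filter_hz low-pass cutoff (must be below Nyquist)
#' @param duration_s recording length in seconds
#' @param baseline_pA closed-state current
#' @param noise_sd_pA white noise SD before filtering (> 0 for realistic
#'   traces, 0 allowed for idealization tests)
#' @param event_rate_hz mean event rate (exponential gaps)
#' @param mixture class probabilities, named step_like/multi_level/erratic,
#'   summing to 1
#' @param cond_median_nS,cond_iqr_nS median and c(Q1, Q3) of the step
#'   conductance law
#' @param dur_meanlog,dur_sdlog log-normal event-duration parameters for the
#'   channel mode; defaults put about 54% of durations above 1 s
#' @param control logical; generate only short fusion-like transients whose
#'   duration law (`control_dur_meanlog/sdlog`) puts about 85% below 1 s
#' @param control_dur_meanlog,control_dur_sdlog control duration law
#' @param seed default seed used by the generator functions
#' @return an object of class `trace_protocol`
#' @export
trace_protocol <- function(voltage_mV = 150, sampling_hz = 20000,
                           filter_hz = 4000, duration_s = 60,
                           baseline_pA = 0, noise_sd_pA = 1,
                           event_rate_hz = 0.25,
                           mixture = c(step_like = 0.55, multi_level = 0.25,
                                       erratic = 0.20),
                           cond_median_nS = 0.17,
                           cond_iqr_nS = c(0.12, 0.32),
                           dur_meanlog = qnorm(63 / 116), dur_sdlog = 1,
                           control = FALSE,
                           control_dur_meanlog = qnorm(0.15),
                           control_dur_sdlog = 1,
                           seed = NULL) {
  stopifnot(sampling_hz > 0, filter_hz > 0, filter_hz < sampling_hz / 2,
            duration_s > 0, noise_sd_pA >= 0, event_rate_hz > 0,
            length(mixture) == 3, all(mixture >= 0),
            cond_median_nS > 0, length(cond_iqr_nS) == 2,
            cond_iqr_nS[1] < cond_median_nS, cond_median_nS < cond_iqr_nS[2])
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture must sum to 1")
  names(mixture) <- c("step_like", "multi_level", "erratic")
  structure(list(voltage_mV = voltage_mV, sampling_hz = sampling_hz,
                 filter_hz = filter_hz, duration_s = duration_s,
                 baseline_pA = baseline_pA, noise_sd_pA = noise_sd_pA,
                 event_rate_hz = event_rate_hz, mixture = mixture,
                 cond_median_nS = cond_median_nS, cond_iqr_nS = cond_iqr_nS,
                 dur_meanlog = dur_meanlog, dur_sdlog = dur_sdlog,
                 control = isTRUE(control),
                 control_dur_meanlog = control_dur_meanlog,
                 control_dur_sdlog = control_dur_sdlog,
                 seed = seed),
            class = "trace_protocol")
}

# two-piece log-normal: equal-mass halves with separate log-scale on each
# side of the median, so the median and both quartiles match the requested
# values exactly
.cond_sigmas <- function(protocol) {
  z75 <- stats::qnorm(0.75)
  mu <- log(protocol$cond_median_nS)
  c(mu = mu,
    sig_lo = (mu - log(protocol$cond_iqr_nS[1])) / z75,
    sig_hi = (log(protocol$cond_iqr_nS[2]) - mu) / z75)
}

#' Sample step conductances from the protocol's two-piece log-normal
#'
#' @param n number of draws
#' @param protocol a [trace_protocol()]
#' @return conductances in nS
#' @export
rcond_step <- function(n, protocol) {
  p <- .cond_sigmas(protocol)
  s <- sample(c(-1, 1), n, replace = TRUE)
  mag <- abs(stats::rnorm(n))
  exp(p[["mu"]] + ifelse(s < 0, -p[["sig_lo"]], p[["sig_hi"]]) * mag)
}

#' Quantile function of the step-conductance law
#'
#' @param q probabilities
#' @param protocol a [trace_protocol()]
#' @return conductance quantiles in nS
#' @export
qcond_step <- function(q, protocol) {
  p <- .cond_sigmas(protocol)
  z <- stats::qnorm(q)
  exp(p[["mu"]] + ifelse(z < 0, p[["sig_lo"]], p[["sig_hi"]]) * z)
}

#' Generate ground-truth labelled channel events
#'
#' Draws non-overlapping events from the protocol's class mixture.
#' Step-like: one level, conductance from the step law, duration from the
#' channel duration law. Multi-level: 2-3 stacked levels (each an additional
#' conductance draw), each level dwelling at least 100 ms. Erratic: 5-20
#' openings of 5-40 ms separated by closed gaps of 5-40 ms, flagged unstable.
#' Control mode: single-level rectangular transients with the short control
#' duration law.
#'
#' @param protocol a [trace_protocol()]
#' @param seed RNG seed (defaults to the protocol seed)
#' @return an object of class `truth_events`: data.frame with `event`,
#'   `class`, `start_s`, `end_s`, `duration_s`, `n_levels` and a `levels`
#'   attribute (per event, data.frame of `G_nS`, `dwell_s`, `open`, `stable`)
#' @export
generate_events <- function(protocol, seed = protocol$seed) {
  stopifnot(inherits(protocol, "trace_protocol"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  med_dur <- exp(if (protocol$control) protocol$control_dur_meanlog
                 else protocol$dur_meanlog)
  if (protocol$event_rate_hz * med_dur > 0.5)
    stop("event rate too high to place events without overlap")
  min_gap <- 0.3
  events <- list(); levels <- list()
  t_cur <- 0; k <- 0
  repeat {
    gap <- min_gap + stats::rexp(1, protocol$event_rate_hz)
    start <- t_cur + gap
    ev <- .draw_event(protocol)
    end <- start + ev$duration
    if (end > protocol$duration_s - 0.05) break
    k <- k + 1
    events[[k]] <- data.frame(event = k, class = ev$class, start_s = start,
                              end_s = end, duration_s = ev$duration,
                              n_levels = nrow(ev$levels),
                              stringsAsFactors = FALSE)
    levels[[k]] <- ev$levels
    t_cur <- end
  }
  if (k == 0) {
    out <- data.frame(event = integer(), class = character(),
                      start_s = numeric(), end_s = numeric(),
                      duration_s = numeric(), n_levels = integer(),
                      stringsAsFactors = FALSE)
  } else out <- do.call(rbind, events)
  attr(out, "levels") <- levels
  attr(out, "protocol") <- protocol
  class(out) <- c("truth_events", "data.frame")
  out
}

.draw_event <- function(protocol) {
  if (protocol$control) {
    dur <- stats::rlnorm(1, protocol$control_dur_meanlog,
                         protocol$control_dur_sdlog)
    dur <- max(dur, 0.02)
    lv <- data.frame(G_nS = rcond_step(1, protocol), dwell_s = dur,
                     open = TRUE, stable = TRUE)
    return(list(class = "step_like", duration = dur, levels = lv))
  }
  # every class draws its total duration from the same channel duration law,
  # so the mixture-wide fraction of long (> 1 s) events matches the law
  cls <- sample(names(protocol$mixture), 1, prob = protocol$mixture)
  dur <- stats::rlnorm(1, protocol$dur_meanlog, protocol$dur_sdlog)
  if (cls == "step_like") {
    dur <- max(dur, 0.08)
    lv <- data.frame(G_nS = rcond_step(1, protocol), dwell_s = dur,
                     open = TRUE, stable = TRUE)
    list(class = cls, duration = dur, levels = lv)
  } else if (cls == "multi_level") {
    n_lev <- sample(2:3, 1)
    dur <- max(dur, 0.15 * n_lev + 0.05)    # room for >=100 ms per level
    # split the total into n_lev dwells of at least 100 ms each
    w <- stats::rexp(n_lev) + 0.2
    dw <- 0.1 + (dur - 0.1 * n_lev) * w / sum(w)
    inc <- rcond_step(n_lev, protocol)
    lv <- data.frame(G_nS = cumsum(inc),    # stacked insertions
                     dwell_s = dw, open = TRUE, stable = TRUE)
    list(class = cls, duration = sum(dw), levels = lv)
  } else {
    dur <- max(dur, 0.45)                   # room for >= 5 flickers
    # alternate open/closed flickers of 5-40 ms until the duration is filled
    n_seg <- 2 * ceiling(dur / 0.045) + 9
    dwell <- stats::runif(n_seg, 0.005, 0.040)
    n_keep <- which(cumsum(dwell) >= dur)[1]
    if (is.na(n_keep)) n_keep <- n_seg
    n_keep <- max(n_keep, 9)                # >= 5 open flickers
    if (n_keep %% 2 == 0) n_keep <- n_keep + 1  # start and end open
    dwell <- dwell[seq_len(n_keep)] * dur / sum(dwell[seq_len(n_keep)])
    G <- rcond_step(1, protocol)
    open <- seq_along(dwell) %% 2 == 1
    lv <- data.frame(G_nS = ifelse(open, G, 0), dwell_s = dwell,
                     open = open, stable = FALSE)
    list(class = cls, duration = sum(dwell), levels = lv)
  }
}

# ---- 4-pole Bessel-type low-pass -------------------------------------------

# magnitude-normalized 4th-order Bessel analog prototype (-3 dB at 1 rad/s)
.bessel4_poles <- c(complex(real = -0.9952087612269394, imaginary =  1.2571057394546721),
                    complex(real = -1.3700678305514277, imaginary =  0.4102497174937882),
                    complex(real = -1.3700678305514277, imaginary = -0.4102497174937882),
                    complex(real = -0.9952087612269394, imaginary = -1.2571057394546721))

# polynomial coefficients (descending powers of z^-1) from roots
.poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  Re(p)
}

#' Apply the 4-pole Bessel-type low-pass filter
#'
#' Digital approximation of the patch-clamp hardware filter: the standard
#' magnitude-normalized 4th-order Bessel analog prototype mapped with a
#' prewarped bilinear transform and normalized to unit DC gain. Zero initial
#' conditions, so the first ~1/cutoff seconds show filter settling.
#'
#' @param x signal samples
#' @param fc cutoff frequency (Hz)
#' @param fs sampling rate (Hz)
#' @return filtered samples
#' @export
lowpass_bessel4 <- function(x, fc, fs) {
  stopifnot(fc > 0, fc < fs / 2)
  wa <- 2 * fs * tan(pi * fc / fs)          # prewarped analog cutoff, rad/s
  pa <- .bessel4_poles * wa
  zd <- (1 + pa / (2 * fs)) / (1 - pa / (2 * fs))
  a <- .poly_from_roots(zd)
  b <- c(1, 4, 6, 4, 1)                     # 4 zeros at z = -1
  b <- b * sum(a) / sum(b)                  # unit DC gain
  as.numeric(signal::filter(b, a, x))
}

#' Render a sampled current trace from ground-truth events
#'
#' Builds the ideal piecewise-constant current (baseline plus G*V for every
#' open level), adds white Gaussian noise of the protocol SD, passes the sum
#' through the 4-pole Bessel-type low-pass at the protocol cutoff, and
#' samples at the protocol rate. Deterministic for a fixed seed.
#'
#' @param events a [generate_events()] result
#' @param protocol a [trace_protocol()]
#' @param seed RNG seed for the noise (defaults to protocol seed + 1)
#' @return an object of class `current_trace`: list with `current_pA`,
#'   `sampling_hz`, `n`, and the protocol
#' @export
render_trace <- function(events, protocol, seed = NULL) {
  stopifnot(inherits(protocol, "trace_protocol"))
  if (is.null(seed))
    seed <- if (!is.null(protocol$seed)) protocol$seed + 1L else NULL
  if (!is.null(seed)) set.seed(as.integer(seed))
  fs <- protocol$sampling_hz
  n <- round(protocol$duration_s * fs)
  ideal <- rep(protocol$baseline_pA, n)
  lvs <- attr(events, "levels")
  if (nrow(events) > 0 && max(events$end_s) > protocol$duration_s + 1e-9)
    stop("events extend beyond the protocol duration")
  for (k in seq_len(nrow(events))) {
    t0 <- events$start_s[k]
    lv <- lvs[[k]]
    for (j in seq_len(nrow(lv))) {
      i0 <- floor(t0 * fs) + 1L
      i1 <- min(floor((t0 + lv$dwell_s[j]) * fs), n)
      if (lv$open[j] && i1 >= i0)
        ideal[i0:i1] <- ideal[i0:i1] + lv$G_nS[j] * protocol$voltage_mV
      t0 <- t0 + lv$dwell_s[j]
    }
  }
  noisy <- ideal + if (protocol$noise_sd_pA > 0)
    stats::rnorm(n, 0, protocol$noise_sd_pA) else 0
  filtered <- lowpass_bessel4(noisy, protocol$filter_hz, fs)
  structure(list(current_pA = filtered, sampling_hz = fs, n = n,
                 protocol = protocol),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current_trace: %d samples at %g kHz (%.1f s), %+g mV\n",
              x$n, x$sampling_hz / 1000, x$n / x$sampling_hz,
              x$protocol$voltage_mV))
  invisible(x)
}

#' Sample times of a current trace
#'
#' @param trace a `current_trace`
#' @return time of each sample in seconds (first sample at 0)
#' @export
trace_times <- function(trace) {
  (seq_len(trace$n) - 1) / trace$sampling_hz
}
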