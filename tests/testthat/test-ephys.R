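test_that("baseline estimation finds the closed-state level, not the mixture mean", {
  set.seed(41)
  # pure noise around 5 pA
  tr <- structure(list(current_pA = rnorm(50000, 5, 1), sampling_hz = 20000,
                       n = 50000, protocol = NULL), class = "current_trace")
  bl <- estimate_baseline(tr)
  expect_lt(abs(bl$baseline_pA - 5), 0.25)
  expect_lt(abs(bl$noise_sd_pA - 1) / 1, 0.05)

  # constant trace
  trc <- structure(list(current_pA = rep(0, 2000), sampling_hz = 20000,
                        n = 2000, protocol = NULL), class = "current_trace")
  blc <- estimate_baseline(trc)
  expect_equal(blc$baseline_pA, 0)
  expect_equal(blc$noise_sd_pA, 0)

  # 90% closed / 10% open: baseline tracks the closed level
  cur <- c(rnorm(45000, 0, 1), rnorm(5000, 30, 1))
  tr2 <- structure(list(current_pA = cur, sampling_hz = 20000, n = 50000,
                        protocol = NULL), class = "current_trace")
  bl2 <- estimate_baseline(tr2)
  expect_lt(abs(bl2$baseline_pA), 0.3)
})

test_that("detection count is monotone in threshold and minimum duration", {
  p <- trace_protocol(duration_s = 120, seed = 55)
  truth <- generate_events(p)
  trace <- render_trace(truth, p)
  bl <- estimate_baseline(trace)
  n_by_k <- sapply(c(3, 5, 8, 15),
                   function(k) nrow(detect_events(trace, bl$baseline_pA,
                                                  bl$noise_sd_pA, threshold_k = k)))
  expect_true(all(diff(n_by_k) <= 0))
  n_by_d <- sapply(c(0.005, 0.02, 0.2, 1),
                   function(d) nrow(detect_events(trace, bl$baseline_pA,
                                                  bl$noise_sd_pA,
                                                  min_duration_s = d)))
  expect_true(all(diff(n_by_d) <= 0))
})

test_that("zero-noise idealization recovers events exactly", {
  p <- trace_protocol(duration_s = 120, noise_sd_pA = 0, event_rate_hz = 0.25,
                      seed = 77)
  truth <- generate_events(p)
  # ensure all three classes are present in the fixture
  expect_setequal(unique(truth$class),
                  c("step_like", "multi_level", "erratic"))
  trace <- render_trace(truth, p)
  events <- analyze_trace(trace)
  expect_equal(nrow(events), nrow(truth))
  m <- match_events(truth, events)
  expect_false(anyNA(m))
  fs <- p$sampling_hz
  # boundaries within 2 samples of ground truth
  expect_true(all(abs(events$start_s[m] - truth$start_s) <= 2 / fs + 1e-9))
  expect_true(all(abs(events$end_s[m] - truth$end_s) <= 2 / fs + 1e-9))
  # classes recovered exactly
  expect_equal(events$class[m], truth$class)
  # step-like conductances within 1% of truth
  step <- truth$class == "step_like"
  g_true <- vapply(attr(truth, "levels")[step], function(l) l$G_nS[1],
                   numeric(1))
  expect_true(all(abs(events$conductance_nS[m][step] - g_true) / g_true < 0.01))
  # step-like events carry exactly one accepted level
  expect_true(all(events$n_levels[m][step] == 1))
})

test_that("segmentation resolves two plateaus and flags heavy flicker", {
  fs <- 20000
  # two-plateau window, step of 10 noise SDs at the midpoint
  set.seed(61)
  x <- c(rnorm(3000, 10, 1), rnorm(3000, 20, 1))
  lv <- segment_levels(x, fs, noise_sd_pA = 1)
  expect_equal(nrow(lv), 2)
  expect_lt(abs(lv$start_idx[2] - 3001), 5)
  expect_true(all(lv$stable))
  # flat window: one level regardless of noise draw
  flat <- segment_levels(rnorm(4000, 15, 1), fs, 1)
  expect_equal(nrow(flat), 1)
  # 5 ms alternations: every level unstable
  flick <- rep(c(rep(25, 100), rep(0, 100)), 10) + rnorm(2000, 0, 1)
  lvf <- segment_levels(flick, fs, 1)
  expect_false(any(lvf$stable))
})

test_that("classification matches the three-pattern definitions", {
  mk_lv <- function(mean_pA, dwell_s, stable) data.frame(
    start_idx = 1, end_idx = 2, dwell_s = dwell_s, mean_pA = mean_pA,
    sd_pA = 0.5, stable = stable)
  thr <- 5
  expect_equal(classify_event(mk_lv(30, 2, TRUE), 0, 1, thr), "step_like")
  two <- rbind(mk_lv(30, 1, TRUE), mk_lv(60, 1, TRUE))
  expect_equal(classify_event(two, 0, 1, thr), "multi_level")
  # one stable level but most of the event unstable: erratic
  messy <- rbind(mk_lv(30, 0.2, TRUE), mk_lv(28, 1.8, FALSE))
  expect_equal(classify_event(messy, 0, 1, thr), "erratic")
  # nothing stable and nothing open: erratic
  expect_equal(classify_event(mk_lv(1, 1, FALSE), 0, 1, thr), "erratic")
})

test_that("noisy traces at recording-like SNR are recovered faithfully", {
  p <- trace_protocol(duration_s = 200, noise_sd_pA = 1, event_rate_hz = 0.25,
                      seed = 91)
  truth <- generate_events(p)
  trace <- render_trace(truth, p)
  events <- analyze_trace(trace)
  keep <- truth$duration_s >= 0.010
  m <- match_events(truth[keep, ], events)
  expect_gte(mean(!is.na(m)), 0.95)
  ok <- !is.na(m)
  expect_gte(mean(events$class[m[ok]] == truth$class[keep][ok]), 0.90)
})

test_that("classification survives baseline shifts and time reversal", {
  p <- trace_protocol(duration_s = 90, seed = 13)
  truth <- generate_events(p)
  trace <- render_trace(truth, p)
  ev <- analyze_trace(trace)
  shifted <- trace
  shifted$current_pA <- trace$current_pA + 12.5
  ev_s <- analyze_trace(shifted)
  expect_equal(ev_s$class, ev$class)
  expect_equal(ev_s$conductance_nS, ev$conductance_nS, tolerance = 0.02)
  reversed <- trace
  reversed$current_pA <- rev(trace$current_pA)
  ev_r <- analyze_trace(reversed)
  expect_equal(sort(ev_r$class), sort(ev$class))
})

test_that("step-like conductance summaries use the shared quantile path", {
  ev <- data.frame(class = c("step_like", "step_like", "step_like",
                             "multi_level"),
                   conductance_nS = c(0.1, 0.2, 0.3, 0.9))
  cs <- event_conductances(ev)
  expect_equal(cs$n, 3)
  q <- median_iqr(c(0.1, 0.2, 0.3))
  expect_equal(cs$median, q[["median"]])
  expect_equal(cs$q1, q[["q1"]])
  expect_equal(sum(cs$counts), 3)
  # one event at 30 pA above baseline and 150 mV means 0.2 nS
  one <- data.frame(class = "step_like", conductance_nS = 30 / 150)
  expect_equal(event_conductances(one)$median, 0.2)
  empty <- event_conductances(ev[ev$class == "erratic", ])
  expect_true(empty$empty)
})

test_that("duration analysis reports fractions and the rank test", {
  d <- c(0.5, 1.5, 2, 0.2, 3)
  da <- duration_analysis(d, d)
  expect_equal(da$frac_over[1], da$frac_over[2])
  expect_equal(da$bm_test$estimate, 0.5)
  expect_equal(da$bm_test$p.value, 1)
  # complete separation: extreme relative effect
  da2 <- duration_analysis(c(10, 11, 12), c(1, 2, 3))
  expect_equal(da2$bm_test$estimate, 0)
  expect_true(da2$low_power)
  expect_equal(da2$n_over, c(3, 2))
  da3 <- duration_analysis(c(2, 2, 2), c(0.1, 0.2, 0.3), cutoff_s = 1)
  expect_equal(da3$n_over, c(3, 0))
})
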