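test_that("dwell events partition the inside-window frames exactly", {
  # hand-built path: inside the window [5, 6] on frames 11-20 (0-based 10-19)
  z <- rep(2, 40)
  z[11:20] <- 5.5
  tr <- mk_z_traj(cbind(z), box_z = 12, dt_ns = 0.01)
  ev <- dwell_events(tr, window = c(5, 6))
  expect_equal(nrow(ev), 1)
  # half-open convention: 10 frames at 10 ps each
  expect_equal(ev$duration_ns, 0.10, tolerance = 1e-9)
  expect_equal(ev$entry_time_ns, 0.10, tolerance = 1e-9)

  # never inside
  expect_equal(nrow(dwell_events(mk_z_traj(cbind(rep(2, 30)), box_z = 12),
                                 window = c(5, 6))), 0)
  # min_duration larger than every run empties the list
  expect_equal(nrow(dwell_events(tr, window = c(5, 6), min_duration_ns = 1)), 0)
  expect_error(dwell_events(tr, window = c(6, 5)), "empty window")

  # brute-force check: with min_duration 0 and gap 0, total event frames
  # equal the inside-frame count, and events are disjoint per ion
  set.seed(31)
  for (i in 1:20) {
    z <- 6 + cumsum(rnorm(200, sd = 0.4))
    z <- pmin(pmax(z, 0.1), 11.9)
    trr <- mk_z_traj(cbind(z), box_z = 12, dt_ns = 0.01)
    ev <- dwell_events(trr, window = c(5, 7))
    n_frames_in <- sum(z >= 5 & z <= 7)
    expect_equal(sum(round(ev$duration_ns / 0.01)), n_frames_in)
    if (nrow(ev) > 1)
      expect_true(all(diff(ev$entry_time_ns) > 0) &&
                    all(ev$entry_time_ns[-1] >= ev$exit_time_ns[-nrow(ev)]))
  }
})

test_that("dwell filters are monotone in min_duration and gap tolerance", {
  set.seed(32)
  z <- 6 + cumsum(rnorm(500, sd = 0.5))
  z <- pmin(pmax(z, 0.1), 11.9)
  tr <- mk_z_traj(cbind(z), box_z = 12, dt_ns = 0.01)
  counts_md <- sapply(c(0, 0.02, 0.05, 0.1),
                      function(m) nrow(dwell_events(tr, c(5, 7), min_duration_ns = m)))
  expect_true(all(diff(counts_md) <= 0))
  counts_gap <- sapply(c(0, 1, 3, 10),
                       function(g) nrow(dwell_events(tr, c(5, 7), gap_frames = g)))
  expect_true(all(diff(counts_gap) <= 0))
  # occupancy bound: total dwell time cannot exceed trajectory span
  ev <- dwell_events(tr, c(5, 7))
  expect_lte(sum(ev$duration_ns), max(tr$time_ns) - min(tr$time_ns) + 0.01)
})

test_that("dwell summaries compute the documented statistics", {
  ev <- data.frame(species = rep("Cl-", 3), duration_ns = c(1, 2, 3))
  s <- dwell_summary(ev)
  expect_equal(s$n, 3)
  expect_equal(s$mean_ns, 2)
  expect_equal(s$median_ns, 2)
  expect_equal(s$max_ns, 3)
  expect_equal(s$total_occupancy_ns, 6)
  empty <- dwell_summary(ev[0, ])
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean_ns))
  one <- dwell_summary(ev[2, ])
  expect_equal(one$mean_ns, one$median_ns)
  expect_equal(one$mean_ns, one$max_ns)
  # species selector
  ev2 <- rbind(ev, data.frame(species = "K+", duration_ns = 10))
  expect_equal(dwell_summary(ev2, "K+")$n, 1)
  expect_equal(dwell_summary(ev2, "Cl-")$total_occupancy_ns, 6)
})

test_that("identical conditions compare as exactly equal", {
  cfg <- quick_config(duration_ns = 3, trap = trap_config(depth_kT = 4))
  trajs <- make_replicates(cfg, seeds = 1:2)
  cmp <- compare_conditions(trajs, trajs, labels = c("same", "same"))
  expect_equal(cmp$G_diff_nS, 0)
  expect_equal(cmp$cl_dwell_ratio, 1)
  expect_false(cmp$cl_dwell_ratio_flagged)
})

test_that("constriction vs open pore shows the expected contrast", {
  wt_cfg <- quick_config(duration_ns = 10, trap = trap_config(depth_kT = 4))
  mut_cfg <- quick_config(duration_ns = 10)
  wt <- make_replicates(wt_cfg, seeds = 1:3)
  mut <- make_replicates(mut_cfg, seeds = 4:6)
  win <- c(wt_cfg$trap$center_z - 0.3, wt_cfg$trap$center_z + 0.3)
  cmp <- compare_conditions(wt, mut, labels = c("constricted", "open"),
                            window = win, test = TRUE)
  expect_lt(cmp$G_diff_nS, 0)          # open pore conducts more
  expect_gt(cmp$cl_dwell_ratio, 1)     # anions linger at the constriction
  expect_s3_class(cmp$bm_test, "bm_test")
  # degenerate side: a condition with no Cl- dwell events flags the ratio
  none <- mk_z_traj(matrix(2, 50, 2), box_z = 10, species = c("K+", "Cl-"),
                    slab = c(3, 6))
  cmp2 <- compare_conditions(wt, list(none), window = win)
  expect_true(is.infinite(cmp2$cl_dwell_ratio))
  expect_true(cmp2$cl_dwell_ratio_flagged)
  # mismatched voltages are rejected
  bad <- mk_z_traj(matrix(2, 50, 1), box_z = 10, voltage_mV = 100,
                   slab = c(3, 6))
  expect_error(compare_conditions(wt, list(bad), window = win),
               "different voltages")
})
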