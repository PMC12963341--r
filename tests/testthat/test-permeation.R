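test_that("unwrap_z restores continuity across the periodic boundary", {
  expect_equal(unwrap_z(c(1.0, 1.2, 1.4), 12), c(1.0, 1.2, 1.4))
  expect_equal(unwrap_z(c(11.8, 0.2), 12), c(11.8, 12.2))
  expect_equal(unwrap_z(c(0.2, 11.8), 12), c(0.2, -0.2))
  expect_error(unwrap_z(numeric(), 12), "empty")
  expect_error(unwrap_z(c(12.5), 12), "\\[0, box_z\\)")

  # round trip: wrapping the unwrapped walk recovers the input, and
  # consecutive unwrapped differences stay within half a box
  set.seed(11)
  for (i in 1:25) {
    z <- cumsum(rnorm(300, sd = 0.8))
    zw <- z - 12 * floor(z / 12)
    zu <- unwrap_z(zw, 12)
    expect_equal(zu - 12 * floor(zu / 12), zw, tolerance = 1e-12)
    expect_true(all(abs(diff(zu)) <= 6 + 1e-12))
    expect_true(all(abs((zu - zw) / 12 - round((zu - zw) / 12)) < 1e-9))
  }
})

test_that("crossing detection implements two-plane hysteresis", {
  g <- pore_geometry(4, 8)
  # monotone pass
  tr <- mk_z_traj(cbind(seq(0.5, 11.5, length.out = 60)), box_z = 12)
  ev <- detect_crossings(tr, g)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "+Z")
  # a dip inside the slab that never returns below the lower plane does not
  # double count
  tr2 <- mk_z_traj(cbind(c(seq(0.5, 7, length.out = 20),
                           seq(7, 3, length.out = 10),
                           seq(3, 11.5, length.out = 20))), box_z = 12)
  ev2 <- detect_crossings(tr2, g)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$direction, "+Z")
  # dithering between the planes never fires
  tr3 <- mk_z_traj(cbind(rep(c(5, 7), 50)), box_z = 12)
  expect_equal(nrow(detect_crossings(tr3, g)), 0)
  # entry time precedes exit time
  expect_true(all(ev2$entry_time_ns < ev2$exit_time_ns))
})

test_that("crossings through the periodic boundary are counted correctly", {
  g <- pore_geometry(4, 8)
  # two successive +Z passes, recycled through the boundary between them
  path <- c(seq(2, 11, length.out = 30),         # first pass, ends top
            seq(11, 11.9, length.out = 5),        # drifts to the boundary
            seq(0.1, 2, length.out = 5),          # re-enters from below (wrap)
            seq(2, 11, length.out = 30))          # second pass
  ev <- detect_crossings(mk_z_traj(cbind(path), box_z = 12), g)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$direction == "+Z"))
  # the wrap jump itself is not an event: a resident of the top reservoir
  # wandering across the boundary produces nothing
  path2 <- c(seq(9, 11.9, length.out = 20), seq(0.1, 3.5, length.out = 20),
             seq(3.5, 0.5, length.out = 10), seq(0.5, 11, length.out = 3) * 0 + 1)
  ev2 <- detect_crossings(mk_z_traj(cbind(path2), box_z = 12), g)
  expect_equal(nrow(ev2), 0)
})

test_that("detector agrees exactly with the brute-force finite-state oracle", {
  set.seed(101)
  g <- pore_geometry(498, 502)
  n_mismatch <- 0
  for (i in 1:1000) {
    z <- 500 + cumsum(rnorm(sample(50:300, 1), sd = 1.5))
    z <- pmin(pmax(z, 1), 999)        # keep inside the huge box: no wraps
    ev <- detect_crossings(mk_z_traj(cbind(z)), g)
    oracle <- fsm_crossings(z, g$z_lo, g$z_hi)
    if (!(nrow(ev) == length(oracle) && all(ev$direction == oracle)))
      n_mismatch <- n_mismatch + 1
  }
  expect_equal(n_mismatch, 0)
})

test_that("detection is invariant to rigid shifts, relabelling and reversal", {
  set.seed(202)
  z <- 500 + cumsum(rnorm(400, sd = 2))
  z <- pmin(pmax(z, 10), 990)
  g <- pore_geometry(498, 503)
  ev <- detect_crossings(mk_z_traj(cbind(z)), g)
  # translate trajectory and geometry together
  ev_sh <- detect_crossings(mk_z_traj(cbind(z + 37.5)),
                            pore_geometry(498 + 37.5, 503 + 37.5))
  expect_equal(ev_sh$direction, ev$direction)
  # adding a second ion (the reversed path) leaves ion 1's events untouched
  tr2 <- mk_z_traj(cbind(z, rev(z)))
  ev2 <- detect_crossings(tr2, g)
  e1 <- ev2[ev2$ion_id == 1, c("direction", "entry_time_ns", "exit_time_ns")]
  rownames(e1) <- NULL
  expect_equal(e1, ev[, c("direction", "entry_time_ns", "exit_time_ns")])
  # time reversal maps +Z events onto -Z events one-to-one
  ev_rev <- detect_crossings(mk_z_traj(cbind(rev(z))), g)
  expect_equal(sum(ev_rev$direction == "+Z"), sum(ev$direction == "-Z"))
  expect_equal(sum(ev_rev$direction == "-Z"), sum(ev$direction == "+Z"))
})

test_that("directional counting excludes wrong-direction crossings", {
  ev <- data.frame(
    species = c(rep("K+", 4), rep("Cl-", 2)),
    direction = c("+Z", "+Z", "+Z", "-Z", "-Z", "-Z"))
  ct <- count_directional(ev)
  expect_equal(ct$N_K, 3)
  expect_equal(ct$N_Cl, 2)
  expect_equal(ct$N_K_reverse, 1)
  ct0 <- count_directional(ev[0, ])
  expect_equal(ct0$N_K + ct0$N_Cl, 0)
  # all-Cl- +Z gives zero productive counts
  ct2 <- count_directional(data.frame(species = rep("Cl-", 5),
                                      direction = rep("+Z", 5)))
  expect_equal(ct2$N_K, 0)
  expect_equal(ct2$N_Cl, 0)
  expect_equal(ct2$N_Cl_reverse, 5)
})

test_that("current and conductance follow the counting equation exactly", {
  expect_equal(compute_current(0, 0, 123), 0)
  expect_equal(compute_current(1, 0, 1), 160.2, tolerance = 1e-12)
  # consistency with the triplicate-mean scale: 130 crossings in 500 ns
  expect_equal(compute_current(65, 65, 500), 41.652, tolerance = 1e-9)
  expect_true(abs(compute_current(65, 65, 500) - 41.54) < 1)

  expect_equal(compute_conductance(41.54, 150), 41.54 / 150)
  expect_equal(round(compute_conductance(41.54, 150), 2), 0.28)
  expect_equal(round(compute_conductance(60.02, 150), 2), 0.40)
  expect_equal(compute_conductance(0, 150), 0)
  expect_error(compute_current(1, 1, 0), "positive")
  expect_error(compute_conductance(1, 0), "nonzero")

  # machine-precision identities over random integer counts
  set.seed(5)
  for (i in 1:200) {
    nk <- sample(0:500, 1); ncl <- sample(0:500, 1)
    dt <- runif(1, 1, 1000); v <- runif(1, 10, 300)
    I <- compute_current(nk, ncl, dt)
    expect_equal(I, (nk + ncl) * 1.602e-19 / (dt * 1e-9) * 1e12,
                 tolerance = 1e-13)
    expect_equal(compute_conductance(I, v), I / v, tolerance = 1e-13)
  }
})

test_that("replicate aggregation reports mean and sample SD", {
  mk <- function(I) structure(list(I_pA = I, G_nS = I / 150, V_mV = 150),
                              class = "conductance_estimate")
  agg <- aggregate_replicates(list(mk(40), mk(42), mk(44)))
  expect_equal(agg$I_mean_pA, 42)
  expect_equal(agg$I_sd_pA, 2)
  expect_equal(agg$n, 3)
  one <- aggregate_replicates(list(mk(40)))
  expect_equal(one$I_sd_pA, 0)
  expect_true(one$single_replicate)
  expect_equal(aggregate_replicates(list(mk(7), mk(7)))$G_sd_nS, 0)
  bad <- list(mk(40), structure(list(I_pA = 1, G_nS = 1, V_mV = 100),
                                class = "conductance_estimate"))
  expect_error(aggregate_replicates(bad), "mixed voltages")
})

test_that("Kabsch RMSD is zero for congruent sets and exact without fitting", {
  set.seed(9)
  A <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_rmsd(A, A), 0, tolerance = 1e-12)
  # rigid motion: rotation about z by 0.7 rad plus translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- A %*% t(R) + matrix(rep(c(1, -2, 3), each = 10), ncol = 3)
  expect_lt(kabsch_rmsd(A, B, superpose = TRUE), 1e-10)
  # without superposition a pure d-translation gives exactly d
  C <- A; C[, 1] <- C[, 1] + 0.25
  expect_equal(kabsch_rmsd(A, C, superpose = FALSE), 0.25, tolerance = 1e-12)
  expect_error(kabsch_rmsd(A[1:2, ], B[1:2, ]), "at least 3")
  expect_error(kabsch_rmsd(A, B[1:5, ]), "matching")
})

test_that("Kabsch RMSD agrees with the bio3d reference implementation", {
  set.seed(10)
  for (i in 1:10) {
    A <- matrix(rnorm(45), ncol = 3)
    B <- A + matrix(rnorm(45, sd = 0.3), ncol = 3)
    ours <- kabsch_rmsd(A, B, superpose = TRUE)
    ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
    expect_lt(abs(ours - ref), 5.01e-4)  # bio3d rounds to 3 decimals
  }
})

test_that("rmsd_series tracks deformation, not rigid drift", {
  set.seed(12)
  A <- matrix(rnorm(60), ncol = 3)
  flat <- function(m) as.vector(t(m))
  # static structure
  tr <- rbind(flat(A), flat(A), flat(A))
  expect_equal(rmsd_series(tr), rep(0, 3), tolerance = 1e-12)
  # linear drift without internal deformation superposes away
  tr2 <- rbind(flat(A), flat(A + 1), flat(A + 2))
  expect_true(all(rmsd_series(tr2) < 1e-10))
  # per-frame values equal direct kabsch_rmsd calls
  B <- A + matrix(rnorm(60, sd = 0.2), ncol = 3)
  C <- A + matrix(rnorm(60, sd = 0.5), ncol = 3)
  tr3 <- rbind(flat(A), flat(B), flat(C))
  s <- rmsd_series(tr3)
  expect_equal(s[1], 0, tolerance = 1e-12)
  expect_equal(s[2], kabsch_rmsd(A, B), tolerance = 1e-12)
  expect_equal(s[3], kabsch_rmsd(A, C), tolerance = 1e-12)
  expect_error(rmsd_series(tr3, ref_frame = 9), "reference frame")
})
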