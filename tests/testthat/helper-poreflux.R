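# Shared fixtures and independent oracles, all built in code at test time.

# wrap a set of z paths (columns = ions) into a minimal ion_trajectory
mk_z_traj <- function(zmat, box_z = 1000, species = NULL, voltage_mV = 150,
                      dt_ns = 0.01, box_xy = c(6, 6), slab = NULL) {
  zmat <- as.matrix(zmat)
  n <- ncol(zmat)
  if (is.null(species)) species <- rep("K+", n)
  cfg <- NULL
  if (!is.null(slab)) cfg <- list(slab_nm = slab)
  structure(list(
    time_ns = (seq_len(nrow(zmat)) - 1) * dt_ns,
    ion_id = seq_len(n), species = species,
    x = matrix(box_xy[1] / 2, nrow(zmat), n),
    y = matrix(box_xy[2] / 2, nrow(zmat), n),
    z = zmat, box_nm = c(box_xy, box_z), voltage_mV = voltage_mV,
    seed = 0L, config = cfg
  ), class = "ion_trajectory")
}

# independent brute-force oracle for crossing detection on non-wrapping
# paths: an explicit per-frame finite-state walk with an armed flag
fsm_crossings <- function(z, z_lo, z_hi) {
  state <- NA_character_  # last reservoir side visited: "below" / "above"
  events <- character()
  for (v in z) {
    side <- if (v < z_lo) "below" else if (v > z_hi) "above" else "mid"
    if (side == "mid") next
    if (!is.na(state) && side != state)
      events <- c(events, if (side == "above") "+Z" else "-Z")
    state <- side
  }
  events
}

# small, fast simulator configuration for unit tests (a 4x4x10 nm box holds
# ~77 ion pairs at 1 M)
quick_config <- function(duration_ns = 4, voltage_mV = 150, trap = NULL,
                         save_interval_ns = 0.01, ...) {
  sim_config(box_nm = c(4, 4, 10), slab_nm = c(3, 6), pore_radius_nm = 0.45,
             duration_ns = duration_ns, voltage_mV = voltage_mV, trap = trap,
             save_interval_ns = save_interval_ns, ...)
}

# net signed current (pA) carried through the counting planes, both species
# and both directions, for zero-field symmetry checks
net_current_pA <- function(traj, geom = NULL) {
  ev <- detect_crossings(traj, geom)
  n_pos <- sum(ev$species == "K+" & ev$direction == "+Z") +
    sum(ev$species == "Cl-" & ev$direction == "-Z")
  n_neg <- sum(ev$species == "K+" & ev$direction == "-Z") +
    sum(ev$species == "Cl-" & ev$direction == "+Z")
  dt <- max(traj$time_ns) - min(traj$time_ns)
  (n_pos - n_neg) * poreflux::pf_constants$e_C / (dt * 1e-9) * 1e12
}

# greedy overlap matching of detected events to ground truth; returns for
# each truth row the index of the detected event with maximal overlap (NA if
# none overlaps)
match_events <- function(truth, detected) {
  vapply(seq_len(nrow(truth)), function(i) {
    ov <- pmin(truth$end_s[i], detected$end_s) -
      pmax(truth$start_s[i], detected$start_s)
    if (length(ov) == 0 || max(ov) <= 0) return(NA_integer_)
    which.max(ov)
  }, integer(1))
}
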