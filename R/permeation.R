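#' Counting geometry for directional translocations
#'
#' Two z-planes bounding the membrane/pore span along the pore (Z) axis. A
#' complete crossing passes from below the lower plane to above the upper
#' plane (+Z) or the reverse (-Z), with two-plane hysteresis: the traversal
#' arms at the first plane and fires only at the second, so dithering at a
#' single plane is never double-counted.
#'
#' @param z_lo,z_hi lower/upper plane positions in nm, `z_lo < z_hi`
#' @param radial_cutoff_nm optional radial distance from the box axis (nm);
#'   when set, a crossing only counts if the ion stayed within this radius
#'   while between the planes
#' @return an object of class `pore_geometry`
#' @export
pore_geometry <- function(z_lo, z_hi, radial_cutoff_nm = NULL) {
  stopifnot(is.numeric(z_lo), is.numeric(z_hi), z_lo < z_hi)
  if (!is.null(radial_cutoff_nm)) stopifnot(radial_cutoff_nm > 0)
  structure(list(z_lo = z_lo, z_hi = z_hi,
                 radial_cutoff_nm = radial_cutoff_nm),
            class = "pore_geometry")
}

#' Unwrap a periodic z coordinate series
#'
#' Minimal-image unwrapping: consecutive displacements are corrected by the
#' multiple of the box length that brings them into (-box_z/2, box_z/2]. A
#' single-frame jump of exactly box_z/2 is treated as no wrap (the tie rule).
#'
#' @param z_series wrapped z values in `[0, box_z)`
#' @param box_z box length in nm
#' @return unwrapped (continuous) series; element-wise it differs from the
#'   input by integer multiples of `box_z`
#' @examples
#' unwrap_z(c(11.8, 0.2), 12)  # 11.8, 12.2
#' @export
unwrap_z <- function(z_series, box_z) {
  z_series <- as.numeric(z_series)
  if (length(z_series) == 0) stop("empty series")
  stopifnot(box_z > 0)
  if (any(z_series < 0 | z_series >= box_z))
    stop("wrapped values must lie in [0, box_z)")
  if (length(z_series) == 1) return(z_series)
  dz <- diff(z_series)
  # round() halves go to even: round(+-0.5) = 0, i.e. a half-box jump is no wrap
  dz <- dz - box_z * round(dz / box_z)
  c(z_series[1], z_series[1] + cumsum(dz))
}

# reservoir index of each unwrapped z for the condensed-state crossing count:
# reservoir k spans (z_hi + k*box, z_lo + (k+1)*box); frames between the
# planes get NA
.reservoir_id <- function(zu, z_lo, z_hi, box_z) {
  u <- (zu - z_hi) / box_z
  fu <- u - floor(u)
  resv_frac <- (box_z - (z_hi - z_lo)) / box_z
  id <- ifelse(fu < resv_frac, floor(u), NA_real_)
  id
}

#' Detect complete directional translocations
#'
#' Applies minimal-image unwrapping to each ion's z series and counts
#' complete passages across the two counting planes using the two-plane
#' hysteresis scheme (arm at the first plane, fire at the second). The
#' periodic box is handled by tracking which reservoir image the ion occupies,
#' so an ion recycled through the boundary is not miscounted, and recrossings
#' after a completed event count as new events. A single saved frame that
#' jumps across both planes still counts once (flagged in the `gap` column).
#'
#' @param traj an `ion_trajectory` (wrapped coordinates)
#' @param geom a [pore_geometry()]; default uses the trajectory's membrane
#'   slab faces
#' @return data.frame of crossing events with columns `ion_id`, `species`,
#'   `direction` ("+Z"/"-Z"), `entry_time_ns` (last frame on the entry side),
#'   `exit_time_ns` (first frame on the exit side) and `gap` (TRUE when the
#'   passage spanned a single frame interval)
#' @export
detect_crossings <- function(traj, geom = NULL) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (is.null(geom)) {
    slab <- traj$config$slab_nm
    if (is.null(slab)) stop("no geometry given and trajectory has no slab metadata")
    geom <- pore_geometry(slab[1], slab[2])
  }
  stopifnot(inherits(geom, "pore_geometry"))
  box_z <- traj$box_nm[3]
  zr <- range(traj$z)
  if (geom$z_lo >= box_z || geom$z_hi <= 0 ||
      geom$z_lo < 0 || geom$z_hi > box_z) {
    warning("counting planes lie outside the trajectory z-range; zero events")
    return(.empty_crossings())
  }
  time_ns <- traj$time_ns
  n_ions <- length(traj$ion_id)
  out <- vector("list", n_ions)
  cx <- traj$box_nm[1] / 2; cy <- traj$box_nm[2] / 2
  for (j in seq_len(n_ions)) {
    zu <- unwrap_z(traj$z[, j], box_z)
    rid <- .reservoir_id(zu, geom$z_lo, geom$z_hi, box_z)
    keep <- which(!is.na(rid))
    if (length(keep) < 2) next
    r <- rid[keep]
    d <- diff(r)
    ch <- which(d != 0)
    if (length(ch) == 0) next
    dir <- ifelse(d[ch] > 0, "+Z", "-Z")
    n_ev <- abs(d[ch])            # sparse frames can span several images
    entry <- time_ns[keep[ch]]
    exit <- time_ns[keep[ch + 1]]
    gap <- (keep[ch + 1] - keep[ch]) == 1L
    ev <- data.frame(
      ion_id = traj$ion_id[j], species = traj$species[j],
      direction = rep(dir, n_ev),
      entry_time_ns = rep(entry, n_ev), exit_time_ns = rep(exit, n_ev),
      gap = rep(gap, n_ev), stringsAsFactors = FALSE
    )
    if (!is.null(geom$radial_cutoff_nm)) {
      ok <- vapply(seq_len(nrow(ev)), function(k) {
        fr <- which(time_ns >= ev$entry_time_ns[k] & time_ns <= ev$exit_time_ns[k])
        fr <- fr[traj$z[fr, j] > geom$z_lo & traj$z[fr, j] < geom$z_hi]
        if (length(fr) == 0) return(TRUE)
        all(sqrt((traj$x[fr, j] - cx)^2 + (traj$y[fr, j] - cy)^2) <=
              geom$radial_cutoff_nm)
      }, logical(1))
      ev <- ev[ok, , drop = FALSE]
    }
    out[[j]] <- ev
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(.empty_crossings())
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev[order(ev$entry_time_ns, ev$ion_id), , drop = FALSE]
}

.empty_crossings <- function() {
  data.frame(ion_id = integer(), species = character(),
             direction = character(), entry_time_ns = numeric(),
             exit_time_ns = numeric(), gap = logical(),
             stringsAsFactors = FALSE)
}

#' Directional crossing counts
#'
#' Tallies the productive counts of the current equation: `N_K` = K+ passing
#' in +Z, `N_Cl` = Cl- passing in -Z. Counter-productive crossings (K+ in -Z,
#' Cl- in +Z) are reported separately and never subtracted, matching the
#' counting equation literally.
#'
#' @param events a crossing-event data.frame from [detect_crossings()]
#' @return list with `N_K`, `N_Cl`, `N_K_reverse`, `N_Cl_reverse`
#' @export
count_directional <- function(events) {
  list(
    N_K  = sum(events$species == "K+"  & events$direction == "+Z"),
    N_Cl = sum(events$species == "Cl-" & events$direction == "-Z"),
    N_K_reverse  = sum(events$species == "K+"  & events$direction == "-Z"),
    N_Cl_reverse = sum(events$species == "Cl-" & events$direction == "+Z")
  )
}

#' Ionic current from directional crossing counts
#'
#' `I = (N_K + N_Cl) e / dt` with e the elementary charge (1.602e-19 C),
#' returned in pA.
#'
#' @param N_K,N_Cl productive crossing counts
#' @param dt_ns observation time in ns (> 0)
#' @return current in pA
#' @examples
#' compute_current(1, 0, 1)  # 160.2 pA
#' @export
compute_current <- function(N_K, N_Cl, dt_ns) {
  if (any(dt_ns <= 0)) stop("dt must be positive")
  (N_K + N_Cl) * pf_constants$e_C / (dt_ns * 1e-9) * 1e12
}

#' Conductance from current and voltage (Ohm's law)
#'
#' `G = I / V`, in nS for I in pA and V in mV.
#'
#' @param I_pA current in pA
#' @param V_mV applied voltage in mV (nonzero)
#' @return conductance in nS
#' @examples
#' compute_conductance(41.54, 150)  # 0.2769 nS, rounds to 0.28
#' @export
compute_conductance <- function(I_pA, V_mV) {
  if (any(V_mV == 0)) stop("voltage must be nonzero")
  I_pA / V_mV
}

#' Full conductance estimate for one trajectory
#'
#' Runs [detect_crossings()], [count_directional()], [compute_current()] and
#' [compute_conductance()] on one trajectory.
#'
#' @param traj an `ion_trajectory`
#' @param geom optional [pore_geometry()]; defaults to the membrane slab faces
#' @return an object of class `conductance_estimate`: list with the counts,
#'   `dt_ns`, `V_mV`, `I_pA`, `G_nS` and the event table
#' @export
estimate_conductance <- function(traj, geom = NULL) {
  ev <- detect_crossings(traj, geom)
  cts <- count_directional(ev)
  dt <- max(traj$time_ns) - min(traj$time_ns)
  I <- compute_current(cts$N_K, cts$N_Cl, dt)
  structure(list(N_K = cts$N_K, N_Cl = cts$N_Cl,
                 N_K_reverse = cts$N_K_reverse,
                 N_Cl_reverse = cts$N_Cl_reverse,
                 dt_ns = dt, V_mV = traj$voltage_mV,
                 I_pA = I, G_nS = compute_conductance(I, traj$voltage_mV),
                 events = ev, n = 1L),
            class = "conductance_estimate")
}

#' @export
print.conductance_estimate <- function(x, ...) {
  if (!is.null(x$I_mean_pA)) {
    cat(sprintf("conductance estimate (aggregate of %d replicates)\n", x$n))
    cat(sprintf("  I = %.2f +/- %.2f pA,  G = %.2f +/- %.3f nS at %+g mV\n",
                x$I_mean_pA, x$I_sd_pA, x$G_mean_nS, x$G_sd_nS, x$V_mV))
  } else {
    cat(sprintf("conductance estimate: N_K = %d, N_Cl = %d over %.1f ns\n",
                x$N_K, x$N_Cl, x$dt_ns))
    cat(sprintf("  I = %.2f pA,  G = %.2f nS at %+g mV", x$I_pA, x$G_nS, x$V_mV))
    if (x$N_K_reverse + x$N_Cl_reverse > 0)
      cat(sprintf("  (counter-productive: %d K+, %d Cl-)",
                  x$N_K_reverse, x$N_Cl_reverse))
    cat("\n")
  }
  invisible(x)
}

#' Aggregate replicate conductance estimates
#'
#' Mean and sample SD (n-1 denominator) of current and conductance across
#' replicates; a single replicate gets SD 0 by convention and is flagged.
#'
#' @param estimates list of [estimate_conductance()] results sharing a voltage
#' @return `conductance_estimate` aggregate with per-replicate values,
#'   means, SDs and n
#' @export
aggregate_replicates <- function(estimates) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, logical(1), "conductance_estimate")))
  V <- vapply(estimates, function(e) e$V_mV, numeric(1))
  if (length(unique(V)) != 1) stop("replicates have mixed voltages")
  I <- vapply(estimates, function(e) e$I_pA, numeric(1))
  G <- vapply(estimates, function(e) e$G_nS, numeric(1))
  mi <- mean_sd_sem(I); mg <- mean_sd_sem(G)
  structure(list(I_pA = I, G_nS = G, V_mV = V[1],
                 I_mean_pA = mi[["mean"]], I_sd_pA = mi[["sd"]],
                 G_mean_nS = mg[["mean"]], G_sd_nS = mg[["sd"]],
                 n = length(estimates),
                 single_replicate = length(estimates) == 1L),
            class = "conductance_estimate")
}

#' Kabsch-superposed RMSD between two coordinate sets
#'
#' With `superpose = TRUE`, the optimal least-squares rigid-body rotation and
#' translation (proper rotation enforced through the SVD determinant
#' correction) is applied before computing the RMSD; otherwise the raw RMSD
#' of matched atoms is returned.
#'
#' @param reference,frame n x 3 coordinate matrices with matched row order
#' @param superpose logical
#' @return RMSD in the coordinate units
#' @export
kabsch_rmsd <- function(reference, frame, superpose = TRUE) {
  reference <- as.matrix(reference); frame <- as.matrix(frame)
  if (!all(dim(reference) == dim(frame)))
    stop("coordinate sets must have matching dimensions")
  if (ncol(reference) != 3) stop("coordinates must be n x 3")
  n <- nrow(reference)
  if (superpose) {
    if (n < 3) stop("superposition needs at least 3 atoms")
    rc <- colMeans(reference); fc <- colMeans(frame)
    A <- sweep(reference, 2, rc); B <- sweep(frame, 2, fc)
    H <- crossprod(B, A)               # 3x3 covariance
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    Dm <- diag(c(1, 1, d))
    R <- sv$v %*% Dm %*% t(sv$u)
    B <- B %*% t(R)
    sqrt(mean(rowSums((B - A)^2)))
  } else {
    sqrt(mean(rowSums((frame - reference)^2)))
  }
}

#' RMSD time series against a reference frame
#'
#' Per-frame [kabsch_rmsd()] of a multi-frame coordinate set against one of
#' its own frames (the structural-stability readout of a trajectory).
#'
#' @param traj_xyz frames x (3*n_atoms) matrix, columns ordered
#'   x1,y1,z1,x2,... (the layout used by common trajectory readers), or a
#'   3-dimensional array frames x atoms x 3
#' @param ref_frame index of the reference frame
#' @param superpose logical, passed to [kabsch_rmsd()]
#' @return numeric vector of per-frame RMSD values; the reference frame's
#'   entry is 0
#' @export
rmsd_series <- function(traj_xyz, ref_frame = 1, superpose = TRUE) {
  if (is.array(traj_xyz) && length(dim(traj_xyz)) == 3) {
    nf <- dim(traj_xyz)[1]
    get <- function(i) traj_xyz[i, , ]
  } else {
    traj_xyz <- as.matrix(traj_xyz)
    if (ncol(traj_xyz) %% 3 != 0) stop("column count must be a multiple of 3")
    nf <- nrow(traj_xyz)
    get <- function(i) matrix(traj_xyz[i, ], ncol = 3, byrow = TRUE)
  }
  if (nf == 0) stop("empty trajectory")
  if (ref_frame < 1 || ref_frame > nf) stop("reference frame does not exist")
  ref <- get(ref_frame)
  vapply(seq_len(nf), function(i) kabsch_rmsd(ref, get(i), superpose),
         numeric(1))
}
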