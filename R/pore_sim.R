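#' Constriction (trap) configuration for the pore simulator
#'
#' Models a charged constriction as a Gaussian potential well in z acting on
#' one ion species (anions by default), optionally combined with
#' single-occupancy exclusion: while a well-bound ion resides in the
#' constriction window, the window is sterically closed to all other ions.
#' The exclusion term is what lets a binding site actually impede
#' steady-state flux — an attractive well alone traps individual ions but
#' adds no resistance for non-interacting particles. Setting `depth_kT = 0`
#' (or `trap = NULL` in [sim_config()]) disables the constriction entirely,
#' which is the surrogate for the double-glycine mutant.
#'
#' @param depth_kT well depth in units of kT (>= 0)
#' @param center_z z position of the well center in nm; default (NA) places
#'   it mid-slab when attached to a [sim_config()]
#' @param half_width_nm Gaussian sigma and half-span of the exclusion window,
#'   in nm
#' @param species affected species, "Cl-" or "K+"
#' @param exclusive logical; enable single-occupancy exclusion of the window
#' @return an object of class `trap_config`
#' @export
trap_config <- function(depth_kT = 4, center_z = NA_real_, half_width_nm = 0.3,
                        species = c("Cl-", "K+"), exclusive = TRUE) {
  species <- match.arg(species)
  stopifnot(is.numeric(depth_kT), length(depth_kT) == 1, depth_kT >= 0,
            is.numeric(half_width_nm), half_width_nm > 0)
  structure(list(depth_kT = depth_kT, center_z = center_z,
                 half_width_nm = half_width_nm, species = species,
                 exclusive = isTRUE(exclusive)),
            class = "trap_config")
}

#' Configuration for the Brownian-dynamics pore simulator
#'
#' Defines the simulation box, the membrane slab and cylindrical pore
#' geometry, the electrolyte, the applied transmembrane voltage and the
#' integration/saving time grid. The axial field is confined to the membrane
#' slab (field strength V / slab thickness); the reservoirs are field-free
#' and z is periodic, so ions that exit on one side are recycled on the
#' other. Defaults emulate the study conditions of the companion analyses:
#' 1.0 M KCl at 298.15 K under +150 mV, 500 ns per replicate.
#'
#' @param box_nm box dimensions c(x, y, z) in nm
#' @param slab_nm membrane slab z-bounds c(lo, hi) in nm; must lie strictly
#'   inside the box
#' @param pore_radius_nm pore radius in nm (> 0)
#' @param temperature_K temperature in K
#' @param conc_M KCl concentration in mol/L
#' @param voltage_mV applied voltage across the slab, trans side positive
#' @param D_K,D_Cl diffusion coefficients in nm^2/ns (defaults are the
#'   standard infinite-dilution values 1.96e-9 and 2.03e-9 m^2/s)
#' @param trap a [trap_config()] or NULL for an unobstructed pore
#' @param dt_ns integration time step in ns
#' @param duration_ns total simulated time in ns
#' @param save_interval_ns interval between saved frames in ns (a multiple of
#'   `dt_ns`)
#' @param seed default RNG seed used by [simulate_ions()] when none is given
#' @return an object of class `sim_config`
#' @export
sim_config <- function(box_nm = c(6, 6, 12), slab_nm = c(4, 8),
                       pore_radius_nm = 0.45, temperature_K = 298.15,
                       conc_M = 1.0, voltage_mV = 150,
                       D_K = 1.96, D_Cl = 2.03,
                       trap = NULL, dt_ns = 0.001, duration_ns = 500,
                       save_interval_ns = 0.01, seed = NULL) {
  stopifnot(length(box_nm) == 3, all(box_nm > 0),
            length(slab_nm) == 2, slab_nm[1] < slab_nm[2],
            slab_nm[1] > 0, slab_nm[2] < box_nm[3],
            pore_radius_nm > 0, temperature_K > 0, conc_M > 0,
            D_K > 0, D_Cl > 0, dt_ns > 0, duration_ns > 0,
            save_interval_ns >= dt_ns)
  if (duration_ns < save_interval_ns)
    stop("duration must cover at least one save interval")
  n_sub <- save_interval_ns / dt_ns
  if (abs(n_sub - round(n_sub)) > 1e-8)
    stop("save_interval_ns must be an integer multiple of dt_ns")
  # a single step's RMS displacement must stay well below the pore radius
  if (sqrt(2 * max(D_K, D_Cl) * dt_ns) >= pore_radius_nm)
    stop("time step too large: single-step RMS displacement exceeds the pore radius")
  if (!is.null(trap)) {
    if (!inherits(trap, "trap_config")) stop("trap must be a trap_config()")
    if (is.na(trap$center_z)) trap$center_z <- mean(slab_nm)
    if (trap$center_z <= slab_nm[1] || trap$center_z >= slab_nm[2])
      stop("trap center must lie inside the membrane slab")
    if (trap$depth_kT == 0) trap <- NULL
  }
  structure(list(box_nm = as.numeric(box_nm), slab_nm = as.numeric(slab_nm),
                 pore_radius_nm = pore_radius_nm,
                 temperature_K = temperature_K, conc_M = conc_M,
                 voltage_mV = voltage_mV, D_K = D_K, D_Cl = D_Cl,
                 trap = trap, dt_ns = dt_ns, duration_ns = duration_ns,
                 save_interval_ns = save_interval_ns, seed = seed),
            class = "sim_config")
}

# ion counts from concentration and box volume, charge neutral by construction
.ion_counts <- function(config) {
  v_nm3 <- prod(config$box_nm)
  n_pairs <- round(.number_density_nm3(config$conc_M) * v_nm3)
  if (n_pairs < 1) stop("box too small for the requested concentration")
  n_pairs
}

# uniform initial positions in the allowed region (outside the solid membrane)
.init_positions <- function(n, config) {
  box <- config$box_nm; slab <- config$slab_nm; R <- config$pore_radius_nm
  cx <- box[1] / 2; cy <- box[2] / 2
  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- 2L * (n - filled) + 16L
    xs <- stats::runif(m, 0, box[1])
    ys <- stats::runif(m, 0, box[2])
    zs <- stats::runif(m, 0, box[3])
    bad <- zs > slab[1] & zs < slab[2] &
      sqrt((xs - cx)^2 + (ys - cy)^2) > R
    xs <- xs[!bad]; ys <- ys[!bad]; zs <- zs[!bad]
    k <- min(length(xs), n - filled)
    if (k > 0) {
      idx <- filled + seq_len(k)
      x[idx] <- xs[seq_len(k)]; y[idx] <- ys[seq_len(k)]; z[idx] <- zs[seq_len(k)]
      filled <- filled + k
    }
  }
  list(x = x, y = y, z = z)
}

#' Simulate ion trajectories through the pore
#'
#' Propagates K+ and Cl- ions by overdamped Euler-Maruyama Langevin steps:
#' per axis, drift `(D/kT) F dt` plus a Gaussian displacement of variance
#' `2 D dt`. The axial electric force q E acts only inside the membrane slab
#' (E = V / slab thickness), oriented so that positive applied voltage drives
#' K+ in +Z and Cl- in -Z, the productive directions for the counting
#' equation. Ions reflect off the pore wall and the membrane faces; all three
#' axes are periodic, so reservoirs recycle. Identical seeds give bitwise
#' identical trajectories.
#'
#' @param config a [sim_config()]
#' @param seed integer RNG seed; defaults to `config$seed`
#' @return an object of class `ion_trajectory`: list with `time_ns`,
#'   `ion_id`, `species` ("K+"/"Cl-"), frame-by-ion coordinate matrices
#'   `x`, `y`, `z` (wrapped, nm), `box_nm`, `voltage_mV`, `seed`, `config`
#' @export
simulate_ions <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) stop("a seed is required (in the config or as an argument)")
  set.seed(as.integer(seed))

  n_pairs <- .ion_counts(config)
  n <- 2L * n_pairs
  species <- rep(c("K+", "Cl-"), each = n_pairs)
  charge <- ifelse(species == "K+", 1, -1)
  D <- ifelse(species == "K+", config$D_K, config$D_Cl)

  pos <- .init_positions(n, config)

  slab_thick <- diff(config$slab_nm)
  vt <- thermal_voltage_mV(config$temperature_K)
  fE <- charge * (config$voltage_mV / vt) / slab_thick  # (F/kT) in 1/nm

  trap <- config$trap
  trap_on <- !is.null(trap)
  trap_species <- if (trap_on) species == trap$species else rep(FALSE, n)

  n_steps <- round(config$duration_ns / config$dt_ns)
  save_every <- round(config$save_interval_ns / config$dt_ns)
  n_steps <- (n_steps %/% save_every) * save_every

  res <- bd_core(n_steps, save_every,
                 pos$x, pos$y, pos$z, D, fE,
                 config$box_nm, config$slab_nm[1], config$slab_nm[2],
                 config$pore_radius_nm, config$dt_ns,
                 trap_on,
                 if (trap_on) trap$center_z else 0,
                 if (trap_on) trap$half_width_nm else 1,
                 if (trap_on) trap$depth_kT else 0,
                 trap_species, trap_on && trap$exclusive)

  n_frames <- nrow(res$x)
  structure(list(
    time_ns = (seq_len(n_frames) - 1) * config$save_interval_ns,
    ion_id = seq_len(n), species = species,
    x = res$x, y = res$y, z = res$z,
    box_nm = config$box_nm, voltage_mV = config$voltage_mV,
    seed = as.integer(seed), config = config
  ), class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("ion_trajectory: %d frames x %d ions (%d K+, %d Cl-)\n",
              length(x$time_ns), length(x$ion_id),
              sum(x$species == "K+"), sum(x$species == "Cl-")))
  cat(sprintf("  %.3f ns span, box %.1f x %.1f x %.1f nm, %+g mV, seed %d\n",
              max(x$time_ns), x$box_nm[1], x$box_nm[2], x$box_nm[3],
              x$voltage_mV, x$seed))
  if (!is.null(x$config$trap))
    cat(sprintf("  constriction: %.1f kT well for %s at z = %.2f nm\n",
                x$config$trap$depth_kT, x$config$trap$species,
                x$config$trap$center_z))
  invisible(x)
}

#' Closed-form bulk conductance of an ideal cylindrical pore
#'
#' Nernst-Einstein reference: `G = (e^2/kT) (c_K D_K + c_Cl D_Cl) pi r^2 / L`
#' with number densities c, pore radius r and slab thickness L. Used as the
#' analytic validation limit for the unobstructed simulator; it neglects
#' access resistance and concentration polarization, so simulated values sit
#' somewhat below it.
#'
#' @param config a [sim_config()] without a trap
#' @return conductance in nS
#' @export
nernst_einstein_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$trap))
    stop("reference is defined for a no-trap configuration")
  L_m <- diff(config$slab_nm) * 1e-9
  if (L_m <= 0) stop("zero slab thickness")
  kT <- pf_constants$kB_J * config$temperature_K
  c_m3 <- .number_density_nm3(config$conc_M) * 1e27       # ions / m^3
  D_K_m2s <- config$D_K * 1e-9                            # nm^2/ns -> m^2/s
  D_Cl_m2s <- config$D_Cl * 1e-9
  r_m <- config$pore_radius_nm * 1e-9
  G_S <- (pf_constants$e_C^2 / kT) * c_m3 * (D_K_m2s + D_Cl_m2s) *
    pi * r_m^2 / L_m
  G_S * 1e9
}

#' Independent simulation replicates
#'
#' One trajectory per seed, emulating replicate runs with independent initial
#' conditions.
#'
#' @param config a [sim_config()]
#' @param seeds vector of distinct integer seeds (its length sets the number
#'   of replicates)
#' @return list of [simulate_ions()] trajectories
#' @export
make_replicates <- function(config, seeds) {
  seeds <- as.integer(seeds)
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  lapply(seeds, function(s) simulate_ions(config, seed = s))
}
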