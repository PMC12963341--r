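# Shared plumbing: readers/writers, config hashing, the end-to-end report().
# JSON carries structured reports, TSV carries tabular event/trajectory data;
# every pipeline output gets a manifest with seeds and a config hash.

.schema_version <- "1"

# FNV-1a hash of a canonical JSON rendering; stable across sessions.
# 32-bit state kept as a double, so the xor and the modular multiply are
# done in pieces that stay inside exact double-precision integer range.
.config_hash <- function(obj) {
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 12, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 65536; hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), as.integer(b))
    # (hi*2^16 + lo) * p mod 2^32, without exceeding 2^53
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  hi <- (h - h %% 65536) / 65536
  sprintf("%04x%04x", as.integer(hi), as.integer(h %% 65536))
}

#' Write an ion trajectory as TSV plus JSON sidecar
#'
#' The TSV has columns frame, time_ns, ion_id, species, x_nm, y_nm, z_nm
#' (long format, one row per ion per frame); the sidecar (`<prefix>.json`)
#' carries box, voltage, seed, the full configuration and its hash.
#'
#' @param traj an `ion_trajectory`
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`
#' @return invisibly, the two file paths
#' @export
write_trajectory <- function(traj, prefix) {
  stopifnot(inherits(traj, "ion_trajectory"))
  nf <- length(traj$time_ns); ni <- length(traj$ion_id)
  dt <- data.table::data.table(
    frame = rep(seq_len(nf) - 1L, each = ni),
    time_ns = rep(traj$time_ns, each = ni),
    ion_id = rep(traj$ion_id, nf),
    species = rep(traj$species, nf),
    x_nm = as.vector(t(traj$x)), y_nm = as.vector(t(traj$y)),
    z_nm = as.vector(t(traj$z))
  )
  tsv <- paste0(prefix, ".tsv"); meta <- paste0(prefix, ".json")
  data.table::fwrite(dt, tsv, sep = "\t")
  cfg <- traj$config
  jsonlite::write_json(list(
    schema_version = .schema_version,
    box_nm = traj$box_nm, voltage_mV = traj$voltage_mV, seed = traj$seed,
    config = unclass(cfg), config_hash = .config_hash(unclass(cfg))
  ), meta, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(tsv = tsv, meta = meta))
}

#' Read an ion trajectory from the TSV dialect
#'
#' Validates the trajectory invariants on read: required columns, strictly
#' increasing complete frames, every ion present in every frame, known
#' species codes, and wrapped coordinates within the box. Malformed input is
#' rejected with the offending frame or column named, never silently
#' coerced.
#'
#' @param path TSV file written by [write_trajectory()] (or any file in the
#'   same dialect)
#' @param meta_path JSON sidecar path; defaults to `path` with `.tsv`
#'   replaced by `.json`
#' @param box_nm box dimensions, required if there is no sidecar
#' @param voltage_mV applied voltage, required if there is no sidecar
#' @param species_map named character vector mapping file species codes to
#'   "K+"/"Cl-"; MD-style names are included by default
#' @return an `ion_trajectory`
#' @export
read_trajectory_table <- function(path, meta_path = NULL, box_nm = NULL,
                                  voltage_mV = NULL,
                                  species_map = c("K+" = "K+", "Cl-" = "Cl-",
                                                  "K" = "K+", "CL" = "Cl-",
                                                  "POT" = "K+", "CLA" = "Cl-")) {
  if (is.null(meta_path)) meta_path <- sub("\\.tsv$", ".json", path)
  meta <- NULL
  if (file.exists(meta_path)) meta <- jsonlite::read_json(meta_path)
  if (is.null(box_nm)) {
    if (is.null(meta)) stop("box dimensions needed: no sidecar found at ", meta_path)
    box_nm <- as.numeric(unlist(meta$box_nm))
  }
  if (is.null(voltage_mV))
    voltage_mV <- if (!is.null(meta)) as.numeric(meta$voltage_mV) else NA_real_
  dt <- data.table::fread(path, sep = "\t")
  need <- c("frame", "time_ns", "ion_id", "species", "x_nm", "y_nm", "z_nm")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  sp_raw <- as.character(dt$species)
  unknown <- setdiff(unique(sp_raw), names(species_map))
  if (length(unknown) > 0)
    stop("unknown species codes: ", paste(unknown, collapse = ", "),
         " (first at row ", which(sp_raw %in% unknown)[1], ")")
  frames <- sort(unique(dt$frame))
  if (length(frames) > 1 && any(diff(frames) != 1))
    stop("gap in frames: frame ", frames[which(diff(frames) != 1)[1]] + 1,
         " is missing")
  ids <- sort(unique(dt$ion_id))
  counts <- table(dt$frame)
  if (length(unique(as.integer(counts))) != 1 ||
      as.integer(counts[1]) != length(ids))
    stop("ion count is not conserved across frames")
  data.table::setorderv(dt, c("frame", "ion_id"))
  nf <- length(frames); ni <- length(ids)
  tvec <- dt$time_ns[seq(1, nrow(dt), by = ni)]
  if (nf > 1 && any(diff(tvec) <= 0)) stop("frame times are not strictly increasing")
  shape <- function(v) matrix(v, nrow = nf, ncol = ni, byrow = TRUE)
  x <- shape(dt$x_nm); y <- shape(dt$y_nm); z <- shape(dt$z_nm)
  if (any(x < 0 | x >= box_nm[1]) || any(y < 0 | y >= box_nm[2]) ||
      any(z < 0 | z >= box_nm[3]))
    stop("wrapped coordinates fall outside [0, box)")
  species <- unname(species_map[sp_raw[seq_len(ni)]])
  cfg <- if (!is.null(meta) && !is.null(meta$config)) {
    cf <- meta$config
    cf$box_nm <- as.numeric(unlist(cf$box_nm))
    cf$slab_nm <- as.numeric(unlist(cf$slab_nm))
    if (!is.null(cf$trap)) {
      cf$trap <- structure(lapply(cf$trap, function(v)
        if (is.list(v)) unlist(v) else v), class = "trap_config")
    }
    structure(cf, class = "sim_config")
  } else NULL
  structure(list(time_ns = tvec, ion_id = ids, species = species,
                 x = x, y = y, z = z, box_nm = box_nm,
                 voltage_mV = voltage_mV,
                 seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NA_integer_,
                 config = cfg),
            class = "ion_trajectory")
}

#' Read ion records from standard MD trajectory files
#'
#' Extracts ion coordinates from a topology (PDB) plus coordinates (a
#' multi-model PDB or a DCD file) using the bio3d readers, selecting atoms by
#' residue/atom name through a configurable name map, and converts to the
#' package's trajectory container (angstrom to nm). For DCD input the unit
#' cell is read per frame, not assumed constant.
#'
#' @param topology path to a PDB file defining the atoms
#' @param coords optional path to a DCD trajectory; when NULL the topology is
#'   read as a multi-model PDB and models become frames
#' @param name_map named character vector mapping residue names to species
#' @param voltage_mV applied voltage metadata
#' @param box_nm fallback box when no unit cell is present in the files
#' @param time_step_ns time between frames
#' @return an `ion_trajectory`
#' @export
read_md_trajectory <- function(topology, coords = NULL,
                               name_map = c("K" = "K+", "POT" = "K+",
                                            "CL" = "Cl-", "CLA" = "Cl-"),
                               voltage_mV = NA_real_, box_nm = NULL,
                               time_step_ns = 1) {
  pdb <- bio3d::read.pdb(topology, multi = is.null(coords))
  sel <- which(pdb$atom$resid %in% names(name_map))
  if (length(sel) == 0)
    stop("no ions matching the name map in ", topology)
  species <- unname(name_map[pdb$atom$resid[sel]])
  if (!is.null(coords)) {
    dcd <- bio3d::read.dcd(coords, cell = TRUE, verbose = FALSE)
    cell <- attr(dcd, "cell")
    if (ncol(dcd) != nrow(pdb$atom) * 3)
      stop("atom count mismatch between topology and coordinate file")
    xyz <- dcd
    box <- if (!is.null(cell)) cell[, 1:3, drop = FALSE] / 10 else NULL
  } else {
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    box <- NULL
    if (!is.null(pdb$cryst1) && !is.null(pdb$cryst1$abc))
      box <- matrix(rep(pdb$cryst1$abc / 10, each = nrow(xyz)), nrow = nrow(xyz))
  }
  if (is.null(box)) {
    if (is.null(box_nm)) stop("no unit cell in files; supply box_nm")
    box <- matrix(rep(box_nm, each = nrow(xyz)), nrow = nrow(xyz))
  }
  nf <- nrow(xyz)
  idx <- rbind(3 * (sel - 1) + 1, 3 * (sel - 1) + 2, 3 * (sel - 1) + 3)
  x <- xyz[, idx[1, ], drop = FALSE] / 10
  y <- xyz[, idx[2, ], drop = FALSE] / 10
  z <- xyz[, idx[3, ], drop = FALSE] / 10
  bx <- box[1, ]
  wrap <- function(m, L) m - L * floor(m / L)
  structure(list(time_ns = (seq_len(nf) - 1) * time_step_ns,
                 ion_id = seq_along(sel), species = species,
                 x = wrap(x, bx[1]), y = wrap(y, bx[2]), z = wrap(z, bx[3]),
                 box_nm = bx, box_per_frame_nm = box,
                 voltage_mV = voltage_mV, seed = NA_integer_, config = NULL),
            class = "ion_trajectory")
}

#' Write a current trace as CSV plus JSON sidecar
#'
#' CSV columns: time_s, current_pA. The sidecar records voltage, sampling
#' rate and filter cutoff.
#'
#' @param trace a `current_trace`
#' @param prefix output prefix; writes `<prefix>.csv` and `<prefix>.json`
#' @return invisibly, the file paths
#' @export
write_trace <- function(trace, prefix) {
  stopifnot(inherits(trace, "current_trace"))
  csv <- paste0(prefix, ".csv"); meta <- paste0(prefix, ".json")
  data.table::fwrite(data.table::data.table(
    time_s = trace_times(trace), current_pA = trace$current_pA), csv)
  p <- trace$protocol
  jsonlite::write_json(list(schema_version = .schema_version,
                            voltage_mV = p$voltage_mV,
                            rate_Hz = p$sampling_hz, filter_Hz = p$filter_hz),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, meta = meta))
}

#' Read a current trace from CSV plus JSON sidecar
#'
#' @param path CSV with columns time_s, current_pA
#' @param meta_path JSON sidecar; defaults to `path` with `.csv` replaced by
#'   `.json`
#' @return a `current_trace`
#' @export
read_trace <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", ".json", path)
  dt <- data.table::fread(path)
  if (!all(c("time_s", "current_pA") %in% names(dt)))
    stop("trace CSV must have columns time_s, current_pA")
  if (nrow(dt) < 2) stop("trace too short")
  dts <- diff(dt$time_s)
  if (max(abs(dts - dts[1])) > 1e-9) stop("sampling is not uniform")
  if (anyNA(dt$current_pA) || any(!is.finite(dt$current_pA)))
    stop("non-finite current samples")
  fs <- 1 / dts[1]
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  proto <- trace_protocol(
    voltage_mV = if (!is.null(meta)) as.numeric(meta$voltage_mV) else 150,
    sampling_hz = if (!is.null(meta)) as.numeric(meta$rate_Hz) else fs,
    filter_hz = if (!is.null(meta)) as.numeric(meta$filter_Hz) else fs / 5,
    duration_s = nrow(dt) / fs)
  structure(list(current_pA = as.numeric(dt$current_pA),
                 sampling_hz = fs, n = nrow(dt), protocol = proto),
            class = "current_trace")
}

#' Run a configured analysis arm end to end
#'
#' Chains simulate -> analyze -> summarize for the trajectory ("md") arm, the
#' recording ("ephys") arm, or both, and writes JSON reports, TSV event
#' tables, and a manifest (tool version, config hash, seeds, paths,
#' timestamp) into `out_dir`. All randomness flows from `seed`; rerunning
#' with the same config and seed reproduces the payloads byte for byte
#' (timestamps live only in the manifest).
#'
#' @param config a list (or path to a YAML file) with elements `arm`
#'   ("md", "ephys" or "both") and optional `md` / `ephys` sub-lists
#'   overriding [sim_config()] / [trace_protocol()] arguments, plus
#'   `md$n_replicates`
#' @param out_dir output directory (created if needed)
#' @param seed integer master seed
#' @return invisibly, a list with the written paths and the in-memory results
#' @export
report <- function(config, out_dir, seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$arm))
  arm <- match.arg(config$arm, c("md", "ephys", "both"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  paths <- character(); results <- list()

  if (arm %in% c("md", "both")) {
    md_cfg <- config$md %||% list()
    n_rep <- md_cfg$n_replicates %||% 3L
    md_cfg$n_replicates <- NULL
    sc <- do.call(sim_config, md_cfg)
    trajs <- make_replicates(sc, seeds = seed + seq_len(n_rep) - 1L)
    ests <- lapply(trajs, estimate_conductance)
    agg <- aggregate_replicates(ests)
    ev <- do.call(rbind, lapply(seq_along(ests), function(i)
      cbind(replicate = i, ests[[i]]$events)))
    ev_path <- file.path(out_dir, "crossings.tsv")
    data.table::fwrite(ev, ev_path, sep = "\t")
    md_report <- list(
      schema_version = .schema_version,
      replicates = lapply(ests, function(e)
        list(N_K = e$N_K, N_Cl = e$N_Cl, N_K_reverse = e$N_K_reverse,
             N_Cl_reverse = e$N_Cl_reverse, dt_ns = e$dt_ns,
             I_pA = e$I_pA, G_nS = e$G_nS)),
      aggregate = list(I_mean_pA = agg$I_mean_pA, I_sd_pA = agg$I_sd_pA,
                       G_mean_nS = agg$G_mean_nS, G_sd_nS = agg$G_sd_nS,
                       n = agg$n, V_mV = agg$V_mV))
    if (!is.null(sc$trap)) {
      dw <- do.call(rbind, lapply(trajs, dwell_events))
      md_report$dwell <- list(K = dwell_summary(dw, "K+"),
                              Cl = dwell_summary(dw, "Cl-"))
    }
    md_path <- file.path(out_dir, "md_report.json")
    jsonlite::write_json(md_report, md_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    paths <- c(paths, md_path, ev_path)
    results$md <- list(aggregate = agg, estimates = ests)
  }

  if (arm %in% c("ephys", "both")) {
    ep_cfg <- config$ephys %||% list()
    control <- isTRUE(ep_cfg$with_control); ep_cfg$with_control <- NULL
    proto <- do.call(trace_protocol, ep_cfg)
    truth <- generate_events(proto, seed = seed + 1000L)
    trace <- render_trace(truth, proto, seed = seed + 2000L)
    events <- analyze_trace(trace)
    cs <- event_conductances(events)
    ev_path <- file.path(out_dir, "events.tsv")
    data.table::fwrite(events, ev_path, sep = "\t")
    summ <- list(schema_version = .schema_version,
                 n_events = nrow(events),
                 class_counts = as.list(table(events$class)),
                 conductance = list(median_nS = cs$median, q1_nS = cs$q1,
                                    q3_nS = cs$q3, n = cs$n))
    if (control && nrow(events) >= 2) {
      cp <- proto; cp$control <- TRUE
      ctrl_truth <- generate_events(cp, seed = seed + 3000L)
      ctrl_trace <- render_trace(ctrl_truth, cp, seed = seed + 4000L)
      ctrl_events <- analyze_trace(ctrl_trace)
      if (nrow(ctrl_events) >= 2) {
        da <- duration_analysis(events$duration_s, ctrl_events$duration_s,
                                labels = c("channel", "control"))
        summ$durations <- list(
          frac_over_1s = da$frac_over[1], control_frac_over_1s = da$frac_over[2],
          bm_p = da$bm_test$p.value, bm_W = da$bm_test$statistic)
        results$ephys_control <- ctrl_events
      }
    }
    sum_path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summ, sum_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    paths <- c(paths, sum_path, ev_path)
    results$ephys <- list(events = events, conductance = cs)
  }

  manifest <- list(
    tool = "poreflux", version = as.character(utils::packageVersion("poreflux")),
    schema_version = .schema_version,
    config = config, config_hash = .config_hash(config),
    seed = seed, outputs = basename(paths),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(paths = c(paths, man_path), results = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
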