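# Brownian-dynamics generator of synthetic channel-translocation
# trajectories with ground-truth crossings, plus scripted deterministic
# trajectories for exact unit tests.
#
# The generator emulates the statistical structure of the simulated
# systems the analysis modules target: several permeant species diffusing
# in a periodic cubic box across a slab-embedded cylindrical channel,
# with species-specific channel affinity (an attractive well for the
# anion analog, a repulsive barrier for the cation analog, a neutral
# metabolite tracer) and an optional single-file blocking rule that
# caricatures competitive pore occupancy by the anion.  Reduced units:
# kT = 1 (map to 310 K in documentation only), lengths nm, times ns.

#' Brownian-dynamics generator parameters
#'
#' Defaults emulate the simulated hexamer systems: an ~11.5 nm periodic
#' cubic box, a 2 nm-thick slab (half-thickness 1 nm) pierced by a
#' 0.5 nm-radius channel, species at 150 mM (ions) and 175 mM
#' (metabolite tracer), an attractive 2 kT channel well for the anion
#' analog and a repulsive 2 kT barrier for the cation analog, and
#' diffusion coefficients of the order of small aqueous solutes.
#'
#' @param species Data frame with columns `label`, `count`, `D` (nm^2/ns),
#'   `U` (channel well depth in kT, negative = attractive), `blocker`
#'   (logical).  Default: anion analog Cl (U = -2, blocker), cation
#'   analog Na (U = +2), neutral tracer PD (U = 0) at the concentrations
#'   above.
#' @param box Cubic box edge (nm, periodic).
#' @param slab_half Slab half-thickness (nm).
#' @param channel_radius Channel radius (nm).
#' @param ramp Cosine-ramp width for the slab and channel edges (nm);
#'   smooth edges keep forces finite.
#' @param barrier Slab exclusion barrier height (kT).
#' @param c6_amp Amplitude of an optional six-fold azimuthal modulation of
#'   the channel well (0 = axially symmetric).
#' @param dt Time step (ns).
#' @param n_steps Number of integration steps.
#' @param stride Save every `stride`-th step (frame 0 always saved).
#' @param blocking Enable the single-file rule: at most one blocker in the
#'   channel, tracer entry rejected while it is occupied.
#' @param detection `pw_detection_cylinder` used for the ground-truth
#'   crossing log.
#' @return A `pw_bd_params` list.
#' @export
bd_params <- function(species = NULL, box = 11.5, slab_half = 1.0,
                      channel_radius = 0.5, ramp = 0.15, barrier = 8,
                      c6_amp = 0, dt = 2e-4, n_steps = 2e5, stride = 10,
                      blocking = FALSE, detection = detection_cylinder()) {
  if (is.null(species)) {
    v <- box^3
    species <- data.frame(
      label = c("Cl", "Na", "PD"),
      count = round(bulk_density(c(150, 150, 175)) * v),
      D = c(2.0, 1.3, 1.0),
      U = c(-2, 2, 0),
      blocker = c(TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE)
  }
  p <- structure(list(species = species, box = box, slab_half = slab_half,
                      channel_radius = channel_radius, ramp = ramp,
                      barrier = barrier, c6_amp = c6_amp, dt = dt,
                      n_steps = as.integer(n_steps),
                      stride = as.integer(stride),
                      blocking = blocking, detection = detection),
                 class = "pw_bd_params")
  validate_bd_params(p)
  p
}

validate_bd_params <- function(p) {
  if (p$box <= 2 * p$slab_half)
    stop("configuration error: box must exceed twice the slab thickness")
  if (p$channel_radius >= p$box / 4)
    stop("configuration error: channel radius must be < box/4")
  rms <- sqrt(2 * max(p$species$D) * p$dt)
  if (rms >= p$channel_radius / 2)
    stop("configuration error: RMS step ", signif(rms, 3),
         " nm must be < channel_radius/2; reduce dt")
  if (any(p$species$count < 0) || any(p$species$D <= 0))
    stop("configuration error: species counts must be >= 0 and D > 0")
  invisible(p)
}

#' Simulate Brownian-dynamics trajectories with ground truth
#'
#' Overdamped Langevin propagation
#' `x <- x + D*F*dt + sqrt(2*D*dt)*xi` (kT = 1) under the slab/channel
#' potential, periodic wrapping, deterministic given the RNG seed
#' (`set.seed()` before calling).  The generator logs true channel
#' crossings at every integration step with the same geometric region
#' rules as [detect_events()], so the analysis pipeline can be checked
#' against ground truth (exactly at stride 1).
#'
#' Particles start uniformly distributed in the bulk (outside the slab).
#'
#' @param params A `pw_bd_params`.
#' @param seed Optional integer; when given, `set.seed(seed)` is called.
#' @return A `pw_bd`: list with `tracks` (named list of `pw_tracks`, one
#'   per species), `times` (ns), `box`, `crossings` (data.frame `step`,
#'   `t_ns`, `particle`, `species`, `direction`), `channel_fraction`
#'   (per-species mean fraction of time in the channel), `params`.
#' @export
simulate_bd <- function(params = bd_params(), seed = NULL) {
  stopifnot(inherits(params, "pw_bd_params"))
  if (!is.null(seed)) set.seed(seed)
  sp <- params$species
  n <- sum(sp$count)
  if (n < 1) stop("configuration error: no particles")
  species_of <- rep(sp$label, sp$count)
  D <- rep(sp$D, sp$count)
  U <- rep(sp$U, sp$count)
  blocker <- rep(sp$blocker, sp$count)
  # uniform start in the bulk compartments (|z| > slab_half)
  half <- params$box / 2
  bulk_span <- half - params$slab_half
  x0 <- cbind(runif(n, -half, half), runif(n, -half, half),
              sample(c(-1, 1), n, replace = TRUE) *
                runif(n, params$slab_half, params$slab_half + bulk_span))
  res <- bd_core(x0, D, U, blocker, params$blocking,
                 params$box, params$slab_half, params$channel_radius,
                 params$ramp, params$ramp, params$barrier, params$c6_amp,
                 params$dt, params$n_steps, params$stride,
                 params$detection$radius, params$detection$zlim[1],
                 params$detection$zlim[2])
  nf <- res$n_frames
  times <- (seq_len(nf) - 1) * params$stride * params$dt
  boxm <- matrix(params$box, nf, 3)
  tracks <- lapply(seq_len(nrow(sp)), function(k) {
    idx <- which(species_of == sp$label[k])
    new_tracks(sp$label[k],
               res$coords[, idx, , drop = FALSE],
               paste0(sp$label[k], seq_along(idx)), times, boxm)
  })
  names(tracks) <- sp$label
  crossings <- data.frame(step = res$cross_step,
                          t_ns = res$cross_step * params$dt,
                          particle = res$cross_particle,
                          species = species_of[res$cross_particle],
                          direction = res$cross_dir,
                          stringsAsFactors = FALSE)
  chan_frac <- tapply(res$channel_steps / params$n_steps, species_of, mean)
  structure(list(tracks = tracks, times = times, box = params$box,
                 crossings = crossings,
                 channel_fraction = chan_frac[sp$label],
                 params = params),
            class = "pw_bd")
}

#' @export
print.pw_bd <- function(x, ...) {
  cat(sprintf("pw_bd: %d frames, %.4g ns, species: %s; %d true crossings\n",
              length(x$times), x$times[length(x$times)],
              paste(names(x$tracks), collapse = ", "), nrow(x$crossings)))
  invisible(x)
}

#' Channel/bulk density ratio for a generated system
#'
#' Measures the number density of a species in the channel core (where
#' the channel well is at full depth: radial distance below
#' `channel_radius - ramp`, |z| below `slab_half - ramp`) against the
#' density in the bulk reservoirs (|z| beyond `slab_half + margin`), from
#' the saved frames.  At equilibrium this ratio converges to the Boltzmann
#' factor `exp(-U/kT)` of the species' channel well.
#'
#' @param bd A `pw_bd`.
#' @param species Species label (default: first species).
#' @param margin Bulk exclusion margin beyond the slab face (nm).
#' @param burn_in Fraction of initial frames discarded as equilibration
#'   (particles start in the bulk, so the channel population needs time
#'   to reach its stationary level).
#' @return The density ratio (dimensionless).
#' @export
channel_enrichment <- function(bd, species = NULL, margin = 1,
                               burn_in = 0.25) {
  stopifnot(inherits(bd, "pw_bd"))
  p <- bd$params
  tr <- if (is.null(species)) bd$tracks[[1]] else bd$tracks[[species]]
  nf_all <- dim(tr$coords)[1]
  keep <- (floor(burn_in * nf_all) + 1L):nf_all
  co <- tr$coords[keep, , , drop = FALSE]
  z <- as.vector(co[, , 3])
  r <- sqrt(as.vector(co[, , 1])^2 + as.vector(co[, , 2])^2)
  rc <- p$channel_radius - p$ramp
  zc <- p$slab_half - p$ramp
  if (rc <= 0 || zc <= 0) stop("ramp leaves no full-depth channel core")
  core_vol <- pi * rc^2 * (2 * zc)
  bulk_span <- p$box / 2 - p$slab_half - margin
  if (bulk_span <= 0) stop("margin leaves no bulk region")
  bulk_vol <- p$box^2 * 2 * bulk_span
  nf <- length(keep)
  dens_core <- sum(r < rc & abs(z) < zc) / nf / core_vol
  dens_bulk <- sum(abs(z) > p$slab_half + margin) / nf / bulk_vol
  if (dens_bulk == 0) stop("no particles sampled in the bulk region")
  dens_core / dens_bulk
}

#' Build a trajectory from scripted paths
#'
#' Exact positions as given, for deterministic unit tests of the event
#' detector.  All paths must have the same length.
#'
#' @param paths Named list: each element an n x 3 matrix (nm), one per
#'   molecule.
#' @param dt_ns Time between frames (ns).
#' @param label Species label.
#' @param box Box edge (nm) recorded with the tracks.
#' @return A `pw_tracks`.
#' @export
scripted_trajectory <- function(paths, dt_ns = 0.1, label = "scripted",
                                box = 100) {
  lens <- vapply(paths, nrow, 1L)
  if (length(unique(lens)) != 1L)
    stop("input error: all scripted paths must have the same length")
  nf <- lens[1]; nm <- length(paths)
  coords <- array(0, dim = c(nf, nm, 3))
  for (m in seq_len(nm)) coords[, m, ] <- as.matrix(paths[[m]])
  ids <- if (!is.null(names(paths))) names(paths) else paste0("mol", seq_len(nm))
  new_tracks(label, coords, ids, (seq_len(nf) - 1) * dt_ns,
             matrix(box, nf, 3))
}

#' Write a multi-frame XYZ trajectory
#'
#' Coordinates are written in Angstrom (the XYZ convention); nm input is
#' scaled by 10.
#'
#' @param coords Array frames x atoms x 3 (nm), or a `pw_tracks`.
#' @param path Output file.
#' @param element Element symbol(s) recycled across atoms.
#' @export
write_xyz_traj <- function(coords, path, element = "C") {
  if (inherits(coords, "pw_tracks")) coords <- coords$coords
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  element <- rep_len(element, na)
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(as.character(na), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", element,
                       coords[f, , 1] * 10, coords[f, , 2] * 10,
                       coords[f, , 3] * 10), con)
  }
  invisible(path)
}

#' Write a minimal PDB topology for synthetic particles
#'
#' One HETATM per particle with the species label as residue name, so the
#' standard-format readers can be exercised end to end on generated data.
#'
#' @param bd A `pw_bd`, or a `pw_tracks`.
#' @param path Output file.
#' @param frame Frame index to write (default 1).
#' @export
write_pdb_topology <- function(bd, path, frame = 1L) {
  tracks <- if (inherits(bd, "pw_bd")) bd$tracks else list(bd)
  con <- file(path, "w"); on.exit(close(con))
  if (inherits(bd, "pw_bd"))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1",
                       bd$box * 10, bd$box * 10, bd$box * 10), con)
  serial <- 0L
  for (tr in tracks) {
    res <- toupper(substr(tr$label, 1, 3))
    for (m in seq_len(dim(tr$coords)[2])) {
      serial <- serial + 1L
      writeLines(sprintf(
        "HETATM%5d  C   %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial %% 100000L, res, serial %% 10000L,
        tr$coords[frame, m, 1] * 10, tr$coords[frame, m, 2] * 10,
        tr$coords[frame, m, 3] * 10), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
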