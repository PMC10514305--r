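# Fixture builders (tiny structure/trajectory files written at test time)
# and independent oracles used to cross-check the analysis implementations.

write_fixture_pdb <- function(path, xyz_ang, elety = "CA", resid = "ALA",
                              resno = seq_len(nrow(xyz_ang)), chain = "A",
                              box_ang = NULL) {
  lines <- character()
  if (!is.null(box_ang))
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1",
                     box_ang[1], box_ang[2], box_ang[3])
  elety <- rep_len(elety, nrow(xyz_ang))
  resid <- rep_len(resid, nrow(xyz_ang))
  chain <- rep_len(chain, nrow(xyz_ang))
  for (i in seq_len(nrow(xyz_ang))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, substr(elety[i], 1, 4), substr(resid[i], 1, 3), chain[i], resno[i],
      xyz_ang[i, 1], xyz_ang[i, 2], xyz_ang[i, 3]))
  }
  writeLines(c(lines, "END"), path)
  path
}

write_fixture_gro <- function(path, xyz_nm, elety = "CA", resid = "ALA",
                              resno = seq_len(nrow(xyz_nm)),
                              box_nm = c(10, 10, 10)) {
  elety <- rep_len(elety, nrow(xyz_nm))
  resid <- rep_len(resid, nrow(xyz_nm))
  lines <- c("fixture", sprintf("%5d", nrow(xyz_nm)))
  for (i in seq_len(nrow(xyz_nm))) {
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              resno[i], resid[i], elety[i], i,
                              xyz_nm[i, 1], xyz_nm[i, 2], xyz_nm[i, 3]))
  }
  writeLines(c(lines, sprintf("%10.5f%10.5f%10.5f", box_nm[1], box_nm[2],
                              box_nm[3])), path)
  path
}

write_fixture_xyz <- function(path, frames_ang) {
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames_ang) {
    writeLines(c(as.character(nrow(fr)), "frame"), con)
    writeLines(sprintf("C %.6f %.6f %.6f", fr[, 1], fr[, 2], fr[, 3]), con)
  }
  path
}

# single-frame pw_trajectory from an n x 3 coordinate matrix (nm)
new_test_traj <- function(xyz, box = c(10, 10, 10)) {
  porewatch:::new_trajectory(array(xyz, dim = c(1, nrow(xyz), 3)),
                             times = 0, box = matrix(box, 1, 3))
}

# tracks object straight from a frames x molecules x 3 array
tracks_from_array <- function(coords, dt = 0.1, label = "test", box = 100) {
  porewatch::scripted_trajectory(
    lapply(seq_len(dim(coords)[2]), function(m) {
      p <- coords[, m, , drop = FALSE]; dim(p) <- c(dim(coords)[1], 3); p
    }),
    dt_ns = dt, label = label, box = box)
}

# unbounded Gaussian random-walk tracks wandering through the cylinder
random_walk_tracks <- function(n_frames, n_mol, step_sd = 0.35, spread = 3) {
  coords <- array(0, dim = c(n_frames, n_mol, 3))
  for (m in seq_len(n_mol)) {
    start <- runif(3, -spread, spread)
    steps <- matrix(rnorm(3 * n_frames, 0, step_sd), n_frames, 3)
    steps[1, ] <- start
    coords[, m, ] <- apply(steps, 2, cumsum)
  }
  tracks_from_array(coords)
}

# channel enrichment estimates from half-run blocks of several replicas:
# discards the equilibration quarter of each run, then splits the rest in
# two blocks much longer than the well-residence correlation time, giving
# 2 x length(seeds) nearly independent ratio estimates
enrichment_blocks <- function(params, seeds) {
  unlist(lapply(seeds, function(s) {
    bd <- porewatch::simulate_bd(params, seed = s)
    nf <- length(bd$times)
    start <- floor(0.25 * nf) + 1L
    mids <- floor((start + nf) / 2)
    vapply(list(start:mids, (mids + 1L):nf), function(idx) {
      bd2 <- bd
      bd2$tracks[[1]]$coords <- bd$tracks[[1]]$coords[idx, , , drop = FALSE]
      porewatch::channel_enrichment(bd2, burn_in = 0)
    }, numeric(1))
  }))
}

# --- independent permeation oracle ------------------------------------------
# Run-length scan: an event is a maximal "inside" run whose flanking
# regions are opposite axial sides, plus direct below<->above jumps whose
# sampled straight-line path stays within the radius (and is not a
# periodic wrap).  Shares no code with detect_events().
oracle_events <- function(tracks, cyl, box_z = NULL) {
  nf <- dim(tracks$coords)[1]
  out <- data.frame(molecule = character(), direction = integer())
  for (m in seq_len(dim(tracks$coords)[2])) {
    p <- tracks$coords[, m, , drop = FALSE]; dim(p) <- c(nf, 3)
    r <- sqrt(p[, 1]^2 + p[, 2]^2)
    z <- p[, 3]
    reg <- ifelse(r > cyl$radius, "L",
                  ifelse(z < cyl$zlim[1], "B",
                         ifelse(z > cyl$zlim[2], "A", "I")))
    rl <- rle(reg)
    ends <- cumsum(rl$lengths)
    dirs <- integer()
    for (k in seq_along(rl$values)) {
      if (rl$values[k] != "I" || k == 1 || k == length(rl$values)) next
      before <- rl$values[k - 1]; after <- rl$values[k + 1]
      if (before == "B" && after == "A") dirs <- c(dirs, +1L)
      if (before == "A" && after == "B") dirs <- c(dirs, -1L)
    }
    # direct jumps
    for (f in which((reg[-nf] == "B" & reg[-1] == "A") |
                    (reg[-nf] == "A" & reg[-1] == "B"))) {
      if (!is.null(box_z) && abs(z[f + 1] - z[f]) > box_z / 2) next
      tt <- seq(0, 1, length.out = 201)
      seg <- outer(1 - tt, p[f, ]) + outer(tt, p[f + 1, ])
      zin <- seg[, 3] >= cyl$zlim[1] & seg[, 3] <= cyl$zlim[2]
      if (all(sqrt(seg[zin, 1]^2 + seg[zin, 2]^2) <= cyl$radius + 1e-9))
        dirs <- c(dirs, if (reg[f] == "B") +1L else -1L)
    }
    if (length(dirs))
      out <- rbind(out, data.frame(molecule = tracks$ids[m], direction = dirs))
  }
  out
}

# --- brute-force rigid superposition oracle ---------------------------------
# Numeric minimization of RMSD over axis-angle rotation + translation.
rodrigues <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

oracle_min_rmsd <- function(mobile, reference) {
  f <- function(par) {
    R <- rodrigues(par[1:3])
    fitted <- sweep(mobile %*% t(R), 2, par[4:6], "+")
    sqrt(mean(rowSums((fitted - reference)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(0.5, -0.3, 0.2, 0, 0, 0),
                     c(-1, 1, 2, 1, -1, 1))) {
    o <- stats::optim(start, f, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# hexamer-like CA reference: 6 protomers x 4 atoms, pore residue = 40
make_hexamer_ref <- function() {
  set.seed(2024)
  ref <- NULL
  resno <- NULL
  for (k in 0:5) {
    th <- k * pi / 3
    base <- c(cos(th), sin(th), 0)
    # residue 40 CA at radius 1 around origin; three more atoms outward
    pts <- rbind(base * 1.0,
                 base * 2.0 + c(0, 0, 0.3),
                 base * 3.0 + c(0.2, -0.1, -0.2),
                 base * 3.5 + c(-0.1, 0.2, 0.4))
    ref <- rbind(ref, pts)
    resno <- c(resno, c(40L, 41L, 42L, 43L))
  }
  list(ca = ref + matrix(rnorm(nrow(ref) * 3, 0, 0.02), ncol = 3),
       resno = resno)
}

rotz <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}
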