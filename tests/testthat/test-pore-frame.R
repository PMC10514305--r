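test_that("Kabsch superposition: identity, known transform, degenerate input", {
  ref <- make_hexamer_ref()$ca
  tf <- kabsch_superpose(ref, ref)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tf$translation, rep(0, 3), tolerance = 1e-9)
  expect_equal(tf$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)

  R30 <- rotz(30); v <- c(1.5, -0.7, 2.2)
  mobile <- sweep(ref %*% t(R30), 2, v, "+")
  tf2 <- kabsch_superpose(mobile, ref)
  expect_equal(tf2$rmsd, 0, tolerance = 1e-9)
  # recovered transform is the inverse of the applied one
  expect_equal(tf2$rotation, t(R30), tolerance = 1e-9)
  expect_equal(porewatch:::apply_transform(mobile, tf2), ref,
               tolerance = 1e-9, ignore_attr = TRUE)

  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
})

test_that("Kabsch residual matches a brute-force numeric minimizer", {
  set.seed(11)
  ref <- make_hexamer_ref()$ca
  for (sigma in c(0.05, 0.2)) {
    mobile <- sweep(ref %*% t(rotz(40)), 2, c(0.5, 0.5, -1), "+") +
      matrix(rnorm(length(ref), 0, sigma), ncol = 3)
    tf <- kabsch_superpose(mobile, ref)
    expect_equal(tf$rmsd, oracle_min_rmsd(mobile, ref), tolerance = 1e-6)
  }
})

test_that("Kabsch agrees with bio3d least-squares fitting", {
  set.seed(12)
  ref <- make_hexamer_ref()$ca
  mobile <- sweep(ref %*% t(rotz(25)), 2, c(1, 2, 3), "+") +
    matrix(rnorm(length(ref), 0, 0.1), ncol = 3)
  tf <- kabsch_superpose(mobile, ref)
  fitted <- suppressWarnings(bio3d::fit.xyz(
    fixed = as.vector(t(ref)), mobile = as.vector(t(mobile)),
    fixed.inds = seq_len(3 * nrow(ref)),
    mobile.inds = seq_len(3 * nrow(ref))))
  bio3d_rmsd <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) - ref)^2)))
  expect_equal(tf$rmsd, bio3d_rmsd, tolerance = 1e-6)
})

test_that("alignment maps frames into the pore frame with correct origin", {
  hex <- make_hexamer_ref()
  poredef <- pore_frame_definition(hex$ca,
                                   pore_index = which(hex$resno == 40))
  nca <- nrow(hex$ca)
  # frame identical to reference: tracks shift by pore centroid only
  ca <- array(hex$ca, dim = c(1, nca, 3))
  pts <- array(c(1, 2, 3), dim = c(1, 1, 3))
  tr <- tracks_from_array(array(c(1, 2, 3), dim = c(1, 1, 3)))
  al <- align_trajectory(tr, ca, poredef)
  centroid <- colMeans(hex$ca[which(hex$resno == 40), ])
  expect_equal(al$tracks[[1]]$coords[1, 1, ], c(1, 2, 3) - centroid,
               tolerance = 1e-9)
  expect_equal(al$rmsd, 0, tolerance = 1e-9)
  # instantaneous-origin switch agrees with the reference origin when the
  # frame is the reference, and differs when the pore centroid has moved
  pd_inst <- pore_frame_definition(hex$ca, pore_index = which(hex$resno == 40),
                                   origin = "instantaneous")
  al_inst <- align_trajectory(tr, ca, pd_inst)
  expect_equal(al_inst$tracks[[1]]$coords, al$tracks[[1]]$coords,
               tolerance = 1e-9)
  ca_shift <- ca
  ca_shift[1, which(hex$resno == 40), 3] <-
    ca_shift[1, which(hex$resno == 40), 3] + 0.2
  zi <- align_trajectory(tr, ca_shift, pd_inst)$tracks[[1]]$coords[1, 1, 3]
  zr <- align_trajectory(tr, ca_shift, poredef)$tracks[[1]]$coords[1, 1, 3]
  expect_false(isTRUE(all.equal(zi, zr)))
})

test_that("alignment is invariant to rigid motion of the raw frame", {
  set.seed(13)
  hex <- make_hexamer_ref()
  poredef <- pore_frame_definition(hex$ca, pore_index = which(hex$resno == 40))
  nca <- nrow(hex$ca)
  # a wobbled frame (not exactly the reference), plus molecule positions
  wob <- hex$ca + matrix(rnorm(nca * 3, 0, 0.05), ncol = 3)
  mol <- matrix(rnorm(9), 3, 3)
  base <- align_trajectory(tracks_from_array(array(mol, c(1, 3, 3))),
                           array(wob, c(1, nca, 3)), poredef)
  Rv <- rotz(73); v <- c(-2, 4, 1)
  wob2 <- sweep(wob %*% t(Rv), 2, v, "+")
  mol2 <- sweep(mol %*% t(Rv), 2, v, "+")
  moved <- align_trajectory(tracks_from_array(array(mol2, c(1, 3, 3))),
                            array(wob2, c(1, nca, 3)), poredef)
  expect_equal(moved$tracks[[1]]$coords, base$tracks[[1]]$coords,
               tolerance = 1e-9)
  expect_equal(moved$rmsd, base$rmsd, tolerance = 1e-9)
})

test_that("alignment is idempotent and never increases CA RMSD", {
  set.seed(14)
  hex <- make_hexamer_ref()
  poredef <- pore_frame_definition(hex$ca, pore_index = which(hex$resno == 40))
  nca <- nrow(hex$ca)
  nf <- 4
  ca <- array(0, c(nf, nca, 3))
  for (f in 1:nf) {
    ca[f, , ] <- sweep(hex$ca %*% t(rotz(f * 20)), 2, c(f, -f, 0.5 * f), "+") +
      matrix(rnorm(nca * 3, 0, 0.03), ncol = 3)
  }
  ca_tr <- tracks_from_array(ca)
  al <- align_trajectory(ca_tr, ca, poredef)
  rmsd_before <- sapply(1:nf, function(f) {
    d <- ca[f, , ] - hex$ca; sqrt(mean(rowSums(d^2)))
  })
  expect_true(all(al$rmsd <= rmsd_before + 1e-12))
  # aligning the aligned CA tracks again is the identity (up to the
  # constant origin shift, already applied)
  centroid <- colMeans(hex$ca[which(hex$resno == 40), ])
  aligned_ca <- al$tracks[[1]]$coords
  ca_restored <- aligned_ca
  for (f in 1:nf) ca_restored[f, , ] <- sweep(aligned_ca[f, , ], 2, centroid, "+")
  al2 <- align_trajectory(tracks_from_array(ca_restored),
                          ca_restored, poredef)
  expect_equal(al2$tracks[[1]]$coords, aligned_ca, tolerance = 1e-9)
})

test_that("orientation sign -1 negates d_pore", {
  hex <- make_hexamer_ref()
  pi40 <- which(hex$resno == 40)
  pd_plus <- pore_frame_definition(hex$ca, pore_index = pi40, orientation = 1)
  pd_minus <- pore_frame_definition(hex$ca, pore_index = pi40, orientation = -1)
  ca <- array(hex$ca, c(1, nrow(hex$ca), 3))
  tr <- tracks_from_array(array(c(0.3, 0.4, -0.6), c(1, 1, 3)))
  zp <- align_trajectory(tr, ca, pd_plus)$tracks[[1]]$coords[1, 1, 3]
  zm <- align_trajectory(tr, ca, pd_minus)$tracks[[1]]$coords[1, 1, 3]
  expect_equal(zm, -zp, tolerance = 1e-12)
})

test_that("pore coordinates are signed z and distance to axis", {
  pc <- pore_coordinates(rbind(c(0, 0, 0), c(0.3, 0.4, -0.6)))
  expect_equal(pc$d_pore, c(0, -0.6))
  expect_equal(pc$r, c(0, 0.5))
  set.seed(15)
  pts <- matrix(rnorm(30), 10, 3)
  pc2 <- pore_coordinates(pts)
  # geometric oracle: minimized distance from each point to sampled points
  # on the z axis
  axis_t <- seq(-50, 50, by = 0.001)
  oracle_r <- apply(pts, 1, function(p)
    min(sqrt(p[1]^2 + p[2]^2 + (p[3] - axis_t)^2)))
  expect_equal(pc2$r, oracle_r, tolerance = 1e-6)
  expect_equal(pc2$d_pore, pts[, 3])
})

test_that("pore frame definition validates the six pore CA atoms", {
  hex <- make_hexamer_ref()
  expect_error(pore_frame_definition(hex$ca, pore_index = 1:5),
               "exactly six")
  st <- load_structure(write_fixture_pdb(
    withr::local_tempfile(fileext = ".pdb"),
    hex$ca * 10, elety = "CA", resid = "ALA", resno = hex$resno))
  pd <- pore_frame_definition(st, pore_residue = 40)
  expect_equal(nrow(pd$ref_ca), nrow(hex$ca))
  expect_length(pd$pore_index, 6)
})
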