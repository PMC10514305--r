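test_that("PDB structures load with Angstrom-to-nm conversion and box", {
  xyz <- rbind(c(10, 20, 30), c(1, 2, 3), c(-5, 0, 12.5))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(f, xyz, box_ang = c(100, 100, 100))
  st <- load_structure(f)
  expect_s3_class(st, "pw_structure")
  expect_equal(nrow(st$atoms), 3)
  expect_equal(as.matrix(st$atoms[, c("x", "y", "z")]), xyz / 10,
               ignore_attr = TRUE)
  expect_equal(st$box, c(10, 10, 10))
})

test_that("GRO structures load in nm with the box line", {
  xyz <- rbind(c(1.5, 2.25, 3), c(0.1, 0.2, 0.3))
  f <- withr::local_tempfile(fileext = ".gro")
  write_fixture_gro(f, xyz, box_nm = c(8.5, 8.5, 8.5))
  st <- load_structure(f)
  expect_equal(as.matrix(st$atoms[, c("x", "y", "z")]), xyz,
               ignore_attr = TRUE)
  expect_equal(st$box, c(8.5, 8.5, 8.5))
})

test_that("truncated or malformed structure files raise format errors", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title", "5", "    1ALA   CA    1   1.000   2.000"), f)
  expect_error(load_structure(f), "truncated")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("not a pdb at all", f2)
  expect_error(load_structure(f2))
  expect_error(load_structure(f, dialect = "nonsense"))
})

test_that("XYZ trajectories load with synthesized times and unit scaling", {
  frames <- list(rbind(c(0, 0, 0), c(10, 0, 0)),
                 rbind(c(0, 0, 5), c(10, 0, 5)))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_fixture_xyz(f, frames)
  topo <- load_structure(write_fixture_pdb(
    withr::local_tempfile(fileext = ".pdb"), frames[[1]]))
  tr <- load_trajectory(f, topo, stride_ns = 0.1, box = c(10, 10, 10))
  expect_equal(tr$times, c(0, 0.1))
  expect_equal(tr$coords[2, 1, 3], 0.5)       # 5 Angstrom -> 0.5 nm
  expect_equal(dim(tr$coords), c(2, 2, 3))
  # single-frame trajectory is valid
  f1 <- write_fixture_xyz(withr::local_tempfile(fileext = ".xyz"), frames[1])
  tr1 <- load_trajectory(f1, topo, stride_ns = 0.1, box = c(10, 10, 10))
  expect_equal(dim(tr1$coords)[1], 1)
  # missing stride and times is a configuration error
  expect_error(load_trajectory(f, topo, box = c(10, 10, 10)),
               "stride_ns or times_ns")
})

test_that("trajectory validation rejects mismatches and bad coordinates", {
  frames <- list(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)))
  f <- write_fixture_xyz(withr::local_tempfile(fileext = ".xyz"), frames)
  topo2 <- load_structure(write_fixture_pdb(
    withr::local_tempfile(fileext = ".pdb"), frames[[1]][1:2, ]))
  expect_error(load_trajectory(f, topo2, stride_ns = 0.1),
               "atom-count mismatch")
  fbad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "c", "C 0 0 0", "C 1 nan 0"), fbad)
  topo3 <- load_structure(write_fixture_pdb(
    withr::local_tempfile(fileext = ".pdb"), frames[[1]][1:2, ]))
  expect_error(load_trajectory(fbad, topo3, stride_ns = 0.1,
                               box = c(10, 10, 10)), "non-finite")
})

test_that("centers of geometry: identity, midpoint, and periodic reassembly", {
  # topology: one monatomic ion + one 2-atom molecule + one straddler
  xyz <- rbind(c(1, 1, 1),            # ION, resno 1
               c(0, 0, 0), c(0, 0, 1),  # MOL, resno 2
               c(0, 0, 9.9), c(0, 0, 0.1))  # STR, resno 3, straddles z
  topo <- load_structure(write_fixture_gro(
    withr::local_tempfile(fileext = ".gro"), xyz,
    elety = "X", resid = c("ION", "MOL", "MOL", "STR", "STR"),
    resno = c(1, 2, 2, 3, 3), box_nm = c(10, 10, 10)))
  traj <- new_test_traj(xyz)
  ion <- centers_of_geometry(traj, select_species(topo, "ION"))
  expect_equal(ion$coords[1, 1, ], c(1, 1, 1))
  mol <- centers_of_geometry(traj, select_species(topo, "MOL"))
  expect_equal(mol$coords[1, 1, ], c(0, 0, 0.5))
  str <- centers_of_geometry(traj, select_species(topo, "STR"))
  # minimum-image reassembly: center at z = 10.0 (== 0.0), never 5.0
  expect_equal(str$coords[1, 1, ], c(0, 0, 10))
  expect_error(centers_of_geometry(traj, select_species(topo, "NOPE")))
})

test_that("centers of geometry are translation-equivariant and wrap-invariant", {
  set.seed(5)
  xyz <- matrix(runif(12, 0, 3), 4, 3)
  topo <- load_structure(write_fixture_gro(
    withr::local_tempfile(fileext = ".gro"), xyz, elety = "X",
    resid = "MOL", resno = c(1, 1, 2, 2), box_nm = c(10, 10, 10)))
  sel <- select_species(topo, "MOL")
  traj <- new_test_traj(xyz)
  base <- centers_of_geometry(traj, sel)
  v <- c(0.3, -1.2, 2.5)
  shifted <- new_test_traj(sweep(xyz, 2, v, "+"))
  expect_equal(centers_of_geometry(shifted, sel)$coords,
               sweep(base$coords, 3, v, "+"))
  # wrapping one atom by an integer box vector leaves centers unchanged
  wrapped_xyz <- xyz
  wrapped_xyz[2, 3] <- wrapped_xyz[2, 3] + 10
  wrapped <- centers_of_geometry(new_test_traj(wrapped_xyz), sel)
  expect_equal(wrapped$coords, base$coords)
})

test_that("track text round trip preserves coordinates and times", {
  set.seed(9)
  coords <- array(rnorm(5 * 3 * 3), dim = c(5, 3, 3))
  tr <- tracks_from_array(coords, dt = 0.2, label = "PD")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(tr, f)
  back <- read_tracks(f, label = "PD")
  expect_equal(back$coords, tr$coords)
  expect_equal(back$times, tr$times)
  expect_equal(back$ids, tr$ids)
})
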