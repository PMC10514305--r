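test_that("bulk density conversion matches hand unit conversion", {
  # 150 mM: 0.150 mol/L * N_A / 1e24 nm^3/L
  expect_equal(bulk_density(150), 0.150 * 6.02214076e23 * 1e-24)
  expect_equal(signif(bulk_density(150), 4), 0.09033)
  expect_equal(bulk_density(0), 0)
  expect_equal(signif(bulk_density(1000), 5), 0.60221)
  expect_error(bulk_density(-1), "concentration")
})

test_that("a static molecule occupies exactly one voxel at 1/voxel-volume", {
  coords <- array(rep(c(0.012, 0.037, -0.022), each = 6), dim = c(6, 1, 3))
  g <- accumulate_sdf(tracks_from_array(coords), xlim = c(-0.5, 0.5),
                      ylim = c(-0.5, 0.5), zlim = c(-0.5, 0.5),
                      bin_width = 0.05)
  expect_equal(sum(g$density > 0), 1)
  expect_equal(max(g$density), 1 / 0.05^3)   # 8000 nm^-3
  expect_equal(g$mean_count, 1)
  # empty species -> all-zero grid
  far <- array(50, dim = c(3, 1, 3))
  g0 <- accumulate_sdf(tracks_from_array(far), xlim = c(-1, 1),
                       ylim = c(-1, 1), zlim = c(-1, 1), bin_width = 0.1)
  expect_true(all(g0$density == 0))
  expect_error(accumulate_sdf(tracks_from_array(coords),
                              xlim = c(0, 0), bin_width = 0.05),
               "configuration error")
})

test_that("voxel mass is conserved exactly, pooled over replicas", {
  set.seed(41)
  mk <- function(nf, n) tracks_from_array(
    array(runif(nf * n * 3, -1.4, 1.4), dim = c(nf, n, 3)))
  reps <- list(mk(20, 25), mk(30, 25))
  g <- accumulate_sdf(reps, xlim = c(-1, 1), ylim = c(-1, 1),
                      zlim = c(-1, 1), bin_width = 0.1)
  # independent count of points inside the grid, frame-weighted
  total <- 0
  for (tr in reps) {
    inside <- abs(tr$coords[, , 1]) <= 1 & abs(tr$coords[, , 2]) <= 1 &
      abs(tr$coords[, , 3]) <= 1
    total <- total + sum(inside)
  }
  expect_equal(sum(g$density) * 0.1^3, total / 50, tolerance = 1e-9)
  expect_equal(g$mean_count, total / 50, tolerance = 1e-9)
  expect_equal(g$frames, 50)
})

test_that("uniform gas at 150 mM reproduces the bulk expectation", {
  set.seed(42)
  half <- 2.5; nf <- 250
  n <- round(bulk_density(150) * (2 * half)^3)
  coords <- array(runif(nf * n * 3, -half, half), dim = c(nf, n, 3))
  g <- accumulate_sdf(tracks_from_array(coords), xlim = c(-2, 2),
                      ylim = c(-2, 2), zlim = c(-2, 2), bin_width = 0.5)
  lambda <- bulk_density(150) * 0.5^3 * nf
  se <- sqrt(lambda) / (0.5^3 * nf)
  expect_lt(abs(mean(g$density) - bulk_density(150)), 3 * se / sqrt(length(g$density)))
})

test_that("threshold regions nest across ascending factors", {
  set.seed(43)
  coords <- array(rnorm(200 * 40 * 3, 0, 0.4), dim = c(200, 40, 3))
  g <- accumulate_sdf(tracks_from_array(coords), xlim = c(-1, 1),
                      ylim = c(-1, 1), zlim = c(-1, 1), bin_width = 0.1)
  bulk <- bulk_density(150)
  regs <- threshold_regions(g, bulk, factors = c(3, 10, 30))
  key <- function(v) paste(v[, 1], v[, 2], v[, 3])
  expect_true(all(key(regs$x30$voxels) %in% key(regs$x10$voxels)))
  expect_true(all(key(regs$x10$voxels) %in% key(regs$x3$voxels)))
  # uniform-at-bulk grid, sampled well enough that Poisson noise cannot
  # reach 10x bulk in any voxel: no 10x/30x enrichment
  half <- 2; nfu <- 400
  nu <- round(bulk_density(150) * (2 * half)^3)
  u <- array(runif(nfu * nu * 3, -half, half), dim = c(nfu, nu, 3))
  gu <- accumulate_sdf(tracks_from_array(u), xlim = c(-1, 1),
                       ylim = c(-1, 1), zlim = c(-1, 1), bin_width = 0.5)
  ru <- threshold_regions(gu, bulk, factors = c(10, 30))
  expect_equal(ru$x10$n_voxels, 0)
  expect_equal(ru$x30$n_voxels, 0)
  # constructed voxel at 31x bulk lands in both regions
  one <- array(rep(c(0.01, 0.01, 0.01), each = 10), dim = c(10, 1, 3))
  g1 <- accumulate_sdf(tracks_from_array(one), xlim = c(-0.5, 0.5),
                       ylim = c(-0.5, 0.5), zlim = c(-0.5, 0.5),
                       bin_width = 0.05)
  r1 <- threshold_regions(g1, bulk_nm3 = max(g1$density) / 31,
                          factors = c(10, 30))
  expect_equal(r1$x10$n_voxels, 1)
  expect_equal(r1$x30$n_voxels, 1)
})

test_that("density maps from a six-fold-symmetric well correlate under
           60-degree rotation", {
  p <- bd_params(species = data.frame(label = "T", count = 600, D = 2.5,
                                      U = -3, blocker = FALSE,
                                      stringsAsFactors = FALSE),
                 c6_amp = 0.5, n_steps = 1e5, stride = 10)
  bd <- simulate_bd(p, seed = 45)
  tr <- bd$tracks$T
  grid_of <- function(coords) {
    accumulate_sdf(tracks_from_array(coords), xlim = c(-0.6, 0.6),
                   ylim = c(-0.6, 0.6), zlim = c(-0.6, 0.6),
                   bin_width = 0.1)$density
  }
  g0 <- grid_of(tr$coords)
  rot <- tr$coords
  th <- pi / 3
  rot[, , 1] <- cos(th) * tr$coords[, , 1] - sin(th) * tr$coords[, , 2]
  rot[, , 2] <- sin(th) * tr$coords[, , 1] + cos(th) * tr$coords[, , 2]
  g60 <- grid_of(rot)
  expect_gt(cor(as.vector(g0), as.vector(g60)), 0.95)
  # sanity: the modulation is real — a 30-degree rotation anti-aligns it
  th <- pi / 6
  rot30 <- tr$coords
  rot30[, , 1] <- cos(th) * tr$coords[, , 1] - sin(th) * tr$coords[, , 2]
  rot30[, , 2] <- sin(th) * tr$coords[, , 1] + cos(th) * tr$coords[, , 2]
  g30 <- grid_of(rot30)
  expect_lt(cor(as.vector(g0), as.vector(g30)),
            cor(as.vector(g0), as.vector(g60)))
})

test_that("OpenDX export is well formed and round-trips voxel values", {
  coords <- array(rep(c(0, 0, 0), each = 4), dim = c(4, 1, 3))
  g <- accumulate_sdf(tracks_from_array(coords), xlim = c(-0.2, 0.2),
                      ylim = c(-0.2, 0.2), zlim = c(-0.2, 0.2),
                      bin_width = 0.1)
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, f)
  ln <- readLines(f)
  expect_match(ln[1], "gridpositions counts 4 4 4")
  vals <- as.numeric(unlist(strsplit(
    ln[(grep("data follows", ln) + 1):(grep("attribute", ln) - 1)], "\\s+")))
  expect_equal(sum(vals), sum(g$density))
  expect_equal(max(vals), max(g$density))
})
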