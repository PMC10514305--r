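# 3D spatial distribution functions on a fine grid, bulk expectation,
# and thresholded enrichment regions.

#' Bulk number density from concentration
#'
#' Converts a molar concentration to a number density per nm^3:
#' `c[mol/L] * N_A * 1e-24 [L/nm^3]`.  150 mM gives 0.09033 nm^-3, the
#' no-enrichment expectation used for Cl- at physiological-scale salt.
#'
#' @param concentration_mM Concentration in mM (>= 0), vectorized.
#' @return Number density in nm^-3.
#' @export
bulk_density <- function(concentration_mM) {
  if (any(concentration_mM < 0)) stop("input error: concentration must be >= 0")
  concentration_mM * 1e-3 * 6.02214076e23 * 1e-24
}

#' Accumulate a spatial distribution function
#'
#' Histograms molecule centres on a regular 3D grid in the aligned frame
#' and converts counts to a time-averaged number density per voxel:
#' counts / (frames * voxel volume).  Replicas are pooled frame-weighted
#' (time- and ensemble-average).  Voxels are half-open `[lo, hi)` with the
#' last bin closed along each axis; points outside the grid are ignored.
#'
#' @param tracks A `pw_tracks` in the pore frame, or a list of them
#'   (replicas).
#' @param xlim,ylim,zlim Grid extents (nm).
#' @param bin_width Voxel edge (nm), default 0.05; must divide each extent.
#' @return A `pw_density_grid`: list with `density` (3D array, nm^-3),
#'   `bin_width`, `xlim`, `ylim`, `zlim`, `frames`, `mean_count` (mean
#'   molecules inside the grid per frame).
#' @export
accumulate_sdf <- function(tracks, xlim = c(-2, 2), ylim = c(-2, 2),
                           zlim = c(-2, 2), bin_width = 0.05) {
  if (inherits(tracks, "pw_tracks")) tracks <- list(tracks)
  dims <- vapply(list(xlim, ylim, zlim), function(l) {
    n <- (l[2] - l[1]) / bin_width
    if (n <= 0 || abs(n - round(n)) > 1e-8)
      stop("configuration error: bin_width must divide each grid extent")
    as.integer(round(n))
  }, 1L)
  counts <- array(0, dim = dims)
  nf_total <- 0L
  lims <- list(xlim, ylim, zlim)
  for (tr in tracks) {
    nf <- dim(tr$coords)[1]
    nf_total <- nf_total + nf
    idx <- matrix(0L, length(tr$coords) / 3, 3)
    ok <- rep(TRUE, nrow(idx))
    for (d in 1:3) {
      v <- as.vector(tr$coords[, , d])
      lo <- lims[[d]][1]; hi <- lims[[d]][2]
      ok <- ok & v >= lo & v <= hi
      idx[, d] <- pmin(floor((v - lo) / bin_width) + 1L, dims[d])
    }
    idx <- idx[ok, , drop = FALSE]
    if (nrow(idx)) {
      flat <- idx[, 1] + dims[1] * (idx[, 2] - 1L) +
        dims[1] * dims[2] * (idx[, 3] - 1L)
      tab <- tabulate(flat, prod(dims))
      counts <- counts + array(tab, dim = dims)
    }
  }
  vol <- bin_width^3
  structure(list(density = counts / (nf_total * vol), bin_width = bin_width,
                 xlim = xlim, ylim = ylim, zlim = zlim, frames = nf_total,
                 mean_count = sum(counts) / nf_total),
            class = "pw_density_grid")
}

#' @export
print.pw_density_grid <- function(x, ...) {
  cat(sprintf("pw_density_grid: %s voxels @ %.3g nm, %d frames, mean count in grid %.4g\n",
              paste(dim(x$density), collapse = " x "), x$bin_width,
              x$frames, x$mean_count))
  invisible(x)
}

#' Thresholded enrichment regions
#'
#' For each factor, the set of voxels whose density is at least
#' `factor * bulk`.  Regions for ascending factors are nested by
#' construction.
#'
#' @param grid A `pw_density_grid`.
#' @param bulk_nm3 Bulk number density (nm^-3), > 0.
#' @param factors Enrichment factors, e.g. `c(10, 30)`.
#' @return A named list of `pw_enrichment_region`s, each a list with
#'   `factor`, `voxels` (matrix of array indices), `n_voxels`.
#' @export
threshold_regions <- function(grid, bulk_nm3, factors = c(10, 30)) {
  stopifnot(inherits(grid, "pw_density_grid"))
  if (bulk_nm3 <= 0) stop("bulk density must be > 0")
  out <- lapply(factors, function(f) {
    vox <- which(grid$density >= f * bulk_nm3, arr.ind = TRUE)
    structure(list(factor = f, voxels = vox, n_voxels = nrow(vox)),
              class = "pw_enrichment_region")
  })
  names(out) <- paste0("x", factors)
  out
}

#' Write a density grid in OpenDX format
#'
#' Plain-text OpenDX scalar field readable by common molecular viewers.
#' Grid positions are voxel centres in nm.
#'
#' @param grid A `pw_density_grid`.
#' @param path Output file.
#' @export
write_dx <- function(grid, path) {
  d <- dim(grid$density)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf("origin %g %g %g",
                     grid$xlim[1] + grid$bin_width / 2,
                     grid$ylim[1] + grid$bin_width / 2,
                     grid$zlim[1] + grid$bin_width / 2), con)
  writeLines(sprintf("delta %g 0 0\ndelta 0 %g 0\ndelta 0 0 %g",
                     grid$bin_width, grid$bin_width, grid$bin_width), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf(
    "object 3 class array type double rank 0 items %d data follows",
    prod(d)), con)
  # OpenDX order: z fastest
  vals <- as.vector(aperm(grid$density, c(3, 2, 1)))
  writeLines(paste(formatC(vals, format = "g"), collapse = "\n"), con)
  writeLines('attribute "dep" string "positions"\nobject "density" class field',
             con)
  invisible(path)
}
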