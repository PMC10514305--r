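# Axial occupancy profiles: time-averaged molecule counts (N_mol) in z
# bins of an analysis cylinder around the pore axis, replica aggregation,
# and enrichment relative to bulk.

#' Analysis cylinder specification
#'
#' The occupancy cylinder is centred on the pore axis: a molecule is
#' counted when its radial distance is at most `radius` and its `d_pore`
#' lies within `zlim` (both boundaries inclusive).  The default radius is
#' 0.7 nm; the axial extent only sets the profiled range, not the per-bin
#' values.
#'
#' @param radius Cylinder radius (nm), > 0.
#' @param zlim Axial range (nm), `c(lo, hi)` with `lo < hi`.
#' @return A `pw_cylinder`.
#' @export
cylinder_spec <- function(radius = 0.7, zlim = c(-3, 3)) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (zlim[1] >= zlim[2]) stop("zlim must satisfy lo < hi")
  structure(list(radius = radius, zlim = as.numeric(zlim)),
            class = "pw_cylinder")
}

#' Is a point inside the analysis cylinder?
#'
#' @param d_pore,r Pore coordinates (nm), vectorized.
#' @param spec A `pw_cylinder`.
#' @return Logical vector.
#' @export
in_cylinder <- function(d_pore, r, spec) {
  r <= spec$radius & d_pore >= spec$zlim[1] & d_pore <= spec$zlim[2]
}

#' Axial occupancy profile
#'
#' Per z bin, `N_mol` = (total molecule-frames whose centre lies in the
#' cylinder and bin) / (number of frames): the time-averaged number of
#' molecules of the species in that axial slice of the cylinder.
#' Molecules are assigned to bins by centre position, half-open bins
#' `[lo, hi)` with the last bin closed.
#'
#' @param aligned A `pw_aligned`, or a single `pw_tracks` already in the
#'   pore frame.
#' @param species Species label (when `aligned` is a `pw_aligned`).
#' @param spec A `pw_cylinder`.
#' @param bin_width Bin width along `d_pore` (nm, default 0.1); must divide
#'   the cylinder's axial extent.
#' @return A `pw_axial_profile`: data.frame with `bin_lo`, `bin_hi`,
#'   `n_mol`, `se`, plus attributes `species`, `spec`, `bin_width`,
#'   `n_replicates`, `frames`.
#' @export
axial_profile <- function(aligned, species = NULL, spec = cylinder_spec(),
                          bin_width = 0.1) {
  tracks <- resolve_tracks(aligned, species)
  nf <- dim(tracks$coords)[1]
  if (nf < 1) stop("input error: trajectory has no frames")
  nbins <- (spec$zlim[2] - spec$zlim[1]) / bin_width
  if (abs(nbins - round(nbins)) > 1e-8)
    stop("bin_width must divide the cylinder z extent")
  nbins <- as.integer(round(nbins))
  z <- as.vector(tracks$coords[, , 3])
  r <- sqrt(as.vector(tracks$coords[, , 1])^2 +
            as.vector(tracks$coords[, , 2])^2)
  inside <- in_cylinder(z, r, spec)
  zi <- z[inside]
  bin <- pmin(floor((zi - spec$zlim[1]) / bin_width) + 1L, nbins)
  counts <- tabulate(bin, nbins)
  edges <- spec$zlim[1] + bin_width * (0:nbins)
  prof <- data.frame(bin_lo = edges[-(nbins + 1L)], bin_hi = edges[-1L],
                     n_mol = counts / nf, se = 0)
  structure(prof, class = c("pw_axial_profile", "data.frame"),
            species = tracks$label, spec = spec, bin_width = bin_width,
            n_replicates = 1L, frames = nf)
}

resolve_tracks <- function(aligned, species) {
  if (inherits(aligned, "pw_tracks")) return(aligned)
  if (inherits(aligned, "pw_aligned")) {
    if (is.null(species)) {
      if (length(aligned$tracks) == 1L) return(aligned$tracks[[1]])
      stop("multiple species present; name one")
    }
    tr <- aligned$tracks[[species]]
    if (is.null(tr)) stop("species '", species, "' not found")
    return(tr)
  }
  stop("expected a pw_aligned or pw_tracks object")
}

#' Aggregate axial profiles across repeat simulations
#'
#' Per bin: mean `N_mol` across replicas and standard error
#' (sample SD / sqrt(n)).  With a single replica the SE is zero and a
#' warning is issued.
#'
#' @param profiles List of `pw_axial_profile`s with identical bins and
#'   species.
#' @return A `pw_axial_profile` with `n_replicates = length(profiles)`.
#' @export
aggregate_replicas <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "pw_axial_profile")))
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!isTRUE(all.equal(p$bin_lo, ref$bin_lo)) ||
        !isTRUE(all.equal(p$bin_hi, ref$bin_hi)))
      stop("input error: profiles have mismatched binning")
    if (!identical(attr(p, "species"), attr(ref, "species")))
      stop("input error: profiles are for different species")
  }
  n <- length(profiles)
  if (n == 1L) warning("single replica: standard errors are zero")
  m <- vapply(profiles, function(p) p$n_mol, numeric(nrow(ref)))
  m <- matrix(m, nrow = nrow(ref))
  out <- data.frame(bin_lo = ref$bin_lo, bin_hi = ref$bin_hi,
                    n_mol = rowMeans(m),
                    se = if (n > 1) apply(m, 1, stats::sd) / sqrt(n) else 0)
  structure(out, class = c("pw_axial_profile", "data.frame"),
            species = attr(ref, "species"), spec = attr(ref, "spec"),
            bin_width = attr(ref, "bin_width"), n_replicates = n,
            frames = sum(vapply(profiles, attr, 1L, "frames")))
}

#' Enrichment of an axial profile over bulk
#'
#' Ratio of observed `N_mol` per bin to the count an ideal solution at the
#' bulk concentration would place in the same bin volume,
#' `bulk_number_density * pi * radius^2 * bin_width`.
#'
#' @param profile A `pw_axial_profile`.
#' @param bulk_mM Bulk concentration (mM); converted with [bulk_density()].
#' @param bulk_nm3 Alternatively, bulk number density (per nm^3) directly.
#' @return The profile with columns `ratio` and `ratio_se` appended.
#' @export
enrichment_profile <- function(profile, bulk_mM = NULL, bulk_nm3 = NULL) {
  stopifnot(inherits(profile, "pw_axial_profile"))
  if (is.null(bulk_nm3)) {
    if (is.null(bulk_mM)) stop("supply bulk_mM or bulk_nm3")
    bulk_nm3 <- bulk_density(bulk_mM)
  }
  if (bulk_nm3 <= 0) stop("division error: bulk density must be > 0")
  spec <- attr(profile, "spec")
  expected <- bulk_nm3 * pi * spec$radius^2 * attr(profile, "bin_width")
  profile$ratio <- profile$n_mol / expected
  profile$ratio_se <- profile$se / expected
  profile
}
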