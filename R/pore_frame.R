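# Rigid-body superposition onto a crystallographic reference and the
# pore-axis coordinate system (d_pore along z, radial distance r).

#' Define the pore coordinate frame
#'
#' The pore frame is anchored to the crystallographic reference: all hexamer
#' C-alpha atoms are used for superposition, and the centroid of the six
#' C-alpha atoms of the pore-lining residue (one per protomer; residue 40
#' for the hexamer studied here) defines the origin, `d_pore = 0`.  The
#' orientation sign fixes which face is at positive `d_pore` (+1: the
#' concave face — the outside of an assembled compartment — is at
#' `d_pore > 0`).
#'
#' @param reference A `pw_structure` (the crystallographic reference), or a
#'   numeric matrix of C-alpha coordinates (n x 3, nm) if `pore_index` is
#'   given.
#' @param pore_residue Residue index whose C-alpha atoms define the origin
#'   (default 40).  Used when `reference` is a structure.
#' @param pore_index Row indices of the pore C-alpha atoms when `reference`
#'   is a coordinate matrix.
#' @param orientation +1 or -1; see above.
#' @param origin Either `"reference"` (origin fixed at the reference-frame
#'   pore centroid; default) or `"instantaneous"` (per-frame centroid of
#'   the aligned pore C-alpha atoms).
#' @return A `pw_poredef`.
#' @export
pore_frame_definition <- function(reference, pore_residue = 40L,
                                  pore_index = NULL,
                                  orientation = c(1, -1),
                                  origin = c("reference", "instantaneous")) {
  orientation <- match.arg(as.character(orientation[1]), c("1", "-1"))
  orientation <- as.numeric(orientation)
  origin <- match.arg(origin)
  if (inherits(reference, "pw_structure")) {
    ca <- which(reference$atoms$elety == "CA")
    if (!length(ca)) stop("reference structure has no CA atoms")
    ref_ca <- as.matrix(reference$atoms[ca, c("x", "y", "z")])
    pore_index <- which(reference$atoms$resno[ca] == pore_residue)
  } else {
    ref_ca <- as.matrix(reference)
    if (is.null(pore_index))
      stop("pore_index required when reference is a coordinate matrix")
  }
  if (length(pore_index) != 6L)
    stop("pore residue must contribute exactly six C-alpha atoms ",
         "(one per protomer); found ", length(pore_index))
  if (!all(is.finite(ref_ca))) stop("reference coordinates must be finite")
  structure(list(ref_ca = ref_ca, pore_index = as.integer(pore_index),
                 orientation = orientation, origin = origin),
            class = "pw_poredef")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the sum of
#' squared distances between `R %*% x + t` over the mobile points and the
#' reference points, via SVD of the cross-covariance with determinant
#' correction on the smallest singular vector so no reflection is ever
#' returned.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm), matched row by
#'   row, n >= 3, not collinear.
#' @return A `pw_transform`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (nm, residual after superposition).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("point sets must be matched n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("geometry error: need at least 3 points")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  X <- sweep(mobile, 2, mc); Y <- sweep(reference, 2, rc)
  # collinear/coincident mobile or reference sets have no unique rotation
  if (svd(X)$d[2] < 1e-10 * max(1, svd(X)$d[1]) ||
      svd(Y)$d[2] < 1e-10 * max(1, svd(Y)$d[1]))
    stop("geometry error: point set is degenerate (collinear or coincident)")
  H <- crossprod(X, Y)            # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- rc - as.vector(R %*% mc)
  fitted <- sweep(mobile %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "pw_transform")
}

apply_transform <- function(points, tf) {
  sweep(points %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Align molecule tracks into the pore frame
#'
#' Superposes each frame's hexamer C-alpha coordinates onto the reference
#' (Kabsch, all C-alpha atoms), applies the per-frame transform to every
#' species track, shifts the origin to the pore-residue C-alpha centroid,
#' and applies the orientation sign (z negated for orientation -1).
#'
#' @param tracks A `pw_tracks` or a (possibly named) list of them, all on
#'   the same frame grid.
#' @param ca_coords Array frames x nCA x 3 (nm) of the trajectory's hexamer
#'   C-alpha coordinates, matched row-for-row with `poredef$ref_ca`.
#' @param poredef A `pw_poredef`.
#' @return A `pw_aligned`: list with `tracks` (named list of `pw_tracks`
#'   in the pore frame), `transforms` (per-frame `pw_transform`s), `rmsd`
#'   (per-frame, nm), `poredef`, `times`.
#' @export
align_trajectory <- function(tracks, ca_coords, poredef) {
  stopifnot(inherits(poredef, "pw_poredef"))
  if (inherits(tracks, "pw_tracks")) tracks <- stats::setNames(list(tracks), tracks$label)
  nf <- dim(ca_coords)[1]
  if (dim(ca_coords)[2] != nrow(poredef$ref_ca))
    stop("topology error: ", dim(ca_coords)[2], " trajectory C-alpha atoms vs ",
         nrow(poredef$ref_ca), " reference C-alpha atoms")
  ref_origin <- colMeans(poredef$ref_ca[poredef$pore_index, , drop = FALSE])
  transforms <- vector("list", nf)
  rmsd <- numeric(nf)
  origins <- matrix(0, nf, 3)
  for (f in seq_len(nf)) {
    ca <- ca_coords[f, , , drop = FALSE]; dim(ca) <- dim(ca_coords)[2:3]
    tf <- kabsch_superpose(ca, poredef$ref_ca)
    transforms[[f]] <- tf
    rmsd[f] <- tf$rmsd
    origins[f, ] <- if (poredef$origin == "reference") ref_origin else
      colMeans(apply_transform(ca, tf)[poredef$pore_index, , drop = FALSE])
  }
  out <- lapply(tracks, function(tr) {
    nm <- dim(tr$coords)[2]
    ac <- array(0, dim = dim(tr$coords))
    for (f in seq_len(nf)) {
      pts <- tr$coords[f, , , drop = FALSE]; dim(pts) <- c(nm, 3)
      pts <- sweep(apply_transform(pts, transforms[[f]]), 2, origins[f, ])
      if (poredef$orientation < 0) pts[, 3] <- -pts[, 3]
      ac[f, , ] <- pts
    }
    new_tracks(tr$label, ac, tr$ids, tr$times, tr$box)
  })
  structure(list(tracks = out, transforms = transforms, rmsd = rmsd,
                 poredef = poredef,
                 times = tracks[[1]]$times),
            class = "pw_aligned")
}

#' @export
print.pw_aligned <- function(x, ...) {
  cat(sprintf("pw_aligned: %d frames, species: %s; mean CA fit RMSD %.4f nm\n",
              length(x$rmsd), paste(names(x$tracks), collapse = ", "),
              mean(x$rmsd)))
  invisible(x)
}

#' Pore coordinates of points in the aligned frame
#'
#' `d_pore` is the signed z coordinate (positive toward the concave face
#' under orientation +1); `r` is the distance from the pore axis.
#'
#' @param points n x 3 matrix (nm) in the aligned frame.
#' @return data.frame with columns `d_pore`, `r`.
#' @export
pore_coordinates <- function(points) {
  points <- matrix(points, ncol = 3)
  data.frame(d_pore = points[, 3],
             r = sqrt(points[, 1]^2 + points[, 2]^2))
}
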