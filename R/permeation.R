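# Bidirectional permeation-event detection and rate estimation.
#
# A permeation event is a molecule entering the detection cylinder from
# one axial side and exiting on the other.  The detection cylinder is
# deliberately wider (2 nm) than the occupancy cylinder so that a permeant
# cannot exit and re-enter laterally near the axial centre; lateral exits
# disarm the detector by default.

#' Detection cylinder for permeation counting
#'
#' @param radius Radius (nm), default 2.0.
#' @param zlim Axial bounds (nm), default `c(-0.6, 0.6)`.
#' @return A `pw_detection_cylinder`.
#' @export
detection_cylinder <- function(radius = 2.0, zlim = c(-0.6, 0.6)) {
  if (radius <= 0) stop("radius must be > 0")
  if (zlim[1] >= zlim[2]) stop("zlim must satisfy lo < hi")
  structure(list(radius = radius, zlim = as.numeric(zlim)),
            class = "pw_detection_cylinder")
}

REGION_BELOW <- 1L; REGION_INSIDE <- 2L; REGION_ABOVE <- 3L; REGION_LATERAL <- 4L

#' Classify a point relative to the detection cylinder
#'
#' Regions: `"below"` (d < z_lo, r <= radius), `"inside"`,
#' `"above"` (d > z_hi, r <= radius), `"outside-lateral"` (r > radius).
#' The radial boundary is inclusive, consistent with the occupancy
#' cylinder.
#'
#' @param d_pore,r Pore coordinates (nm), vectorized.
#' @param cyl A `pw_detection_cylinder`.
#' @param codes Return integer codes (1 below, 2 inside, 3 above,
#'   4 outside-lateral) instead of labels.
#' @return Character (or integer) vector of regions.
#' @export
classify_region <- function(d_pore, r, cyl = detection_cylinder(),
                            codes = FALSE) {
  reg <- rep.int(REGION_LATERAL, length(d_pore))
  inr <- r <= cyl$radius
  reg[inr & d_pore < cyl$zlim[1]] <- REGION_BELOW
  reg[inr & d_pore > cyl$zlim[2]] <- REGION_ABOVE
  reg[inr & d_pore >= cyl$zlim[1] & d_pore <= cyl$zlim[2]] <- REGION_INSIDE
  if (codes) reg else
    c("below", "inside", "above", "outside-lateral")[reg]
}

# Does the straight segment p1 -> p2 stay within `radius` while its z is
# inside [zlo, zhi]?  r(t)^2 is convex in t, so it suffices to check the
# ends of the sub-segment that overlaps the z slab.
segment_within_radius <- function(p1, p2, cyl) {
  z1 <- p1[3]; z2 <- p2[3]
  if (z1 == z2) return(FALSE)           # not a below<->above jump
  tt <- sort(c((cyl$zlim[1] - z1) / (z2 - z1), (cyl$zlim[2] - z1) / (z2 - z1)))
  tt <- pmin(pmax(tt, 0), 1)
  for (t in tt) {
    p <- p1 + t * (p2 - p1)
    if (sqrt(p[1]^2 + p[2]^2) > cyl$radius) return(FALSE)
  }
  TRUE
}

#' Detect completed pore traversals
#'
#' Runs a per-molecule finite-state machine over frame-wise regions:
#' arming on a below-to-inside or above-to-inside transition, firing an
#' event on a subsequent inside-to-opposite-side transition, disarming on
#' an inside-to-same-side transition and (by default) on a lateral exit.
#' Molecules that start inside are unarmed until they leave.  A direct
#' below-to-above jump within one frame stride is counted (and flagged
#' `interpolated`) only when the straight-line path stays within the
#' cylinder radius; when `box_z` is supplied, a jump whose z displacement
#' exceeds half the box length is treated as a periodic wrap, never a
#' crossing.
#'
#' @param tracks A `pw_tracks` in the pore frame (or a `pw_aligned` plus
#'   `species`).
#' @param cyl A `pw_detection_cylinder`.
#' @param species Species label when `tracks` is a `pw_aligned`.
#' @param disarm_on_lateral Cancel arming when an inside molecule exits
#'   laterally (default TRUE, the conservative reading).
#' @param box_z Periodic box length along z (nm), for the wrap guard.
#' @return A `pw_events` data.frame: `molecule`, `entry_frame`,
#'   `exit_frame`, `entry_side`, `exit_side`, `direction` (+1 for -z to
#'   +z), `interpolated`; attribute `duration_ns` = time spanned by the
#'   trajectory.
#' @export
detect_events <- function(tracks, cyl = detection_cylinder(), species = NULL,
                          disarm_on_lateral = TRUE, box_z = NULL) {
  tracks <- resolve_tracks(tracks, species)
  nf <- dim(tracks$coords)[1]
  if (nf < 2) stop("input error: need at least 2 frames")
  if (is.unsorted(tracks$times, strictly = TRUE))
    stop("input error: frames are not sorted by time")
  nm <- dim(tracks$coords)[2]
  ev <- list()
  for (m in seq_len(nm)) {
    pts <- tracks$coords[, m, , drop = FALSE]; dim(pts) <- c(nf, 3)
    reg <- classify_region(pts[, 3], sqrt(pts[, 1]^2 + pts[, 2]^2),
                           cyl, codes = TRUE)
    armed <- 0L         # 0 unarmed; -1 entered from below; +1 from above
    entry_frame <- NA_integer_
    prev <- reg[1]
    for (f in 2:nf) {
      cur <- reg[f]
      if (cur == prev) next
      if (prev == REGION_INSIDE) {
        if (armed != 0L &&
            ((cur == REGION_ABOVE && armed == -1L) ||
             (cur == REGION_BELOW && armed == +1L))) {
          ev[[length(ev) + 1L]] <- list(
            molecule = tracks$ids[m], entry_frame = entry_frame,
            exit_frame = f,
            entry_side = if (armed == -1L) "below" else "above",
            exit_side = if (cur == REGION_ABOVE) "above" else "below",
            direction = if (cur == REGION_ABOVE) +1L else -1L,
            interpolated = FALSE)
          armed <- 0L
        } else if (cur == REGION_LATERAL) {
          if (disarm_on_lateral) armed <- 0L
        } else {
          armed <- 0L   # exited same side (or re-below/above): disarm
        }
      } else if (cur == REGION_INSIDE) {
        if (prev == REGION_BELOW) { armed <- -1L; entry_frame <- f }
        else if (prev == REGION_ABOVE) { armed <- +1L; entry_frame <- f }
        # lateral entry: stays unarmed (armed unchanged only if it was 0;
        # a lateral detour with disarm_on_lateral = FALSE keeps arming)
        else if (disarm_on_lateral) armed <- 0L
      } else if ((prev == REGION_BELOW && cur == REGION_ABOVE) ||
                 (prev == REGION_ABOVE && cur == REGION_BELOW)) {
        dz <- pts[f, 3] - pts[f - 1L, 3]
        wrap <- !is.null(box_z) && abs(dz) > box_z / 2
        if (!wrap && segment_within_radius(pts[f - 1L, ], pts[f, ], cyl)) {
          ev[[length(ev) + 1L]] <- list(
            molecule = tracks$ids[m], entry_frame = f - 1L, exit_frame = f,
            entry_side = if (prev == REGION_BELOW) "below" else "above",
            exit_side = if (cur == REGION_ABOVE) "above" else "below",
            direction = if (cur == REGION_ABOVE) +1L else -1L,
            interpolated = TRUE)
        }
        armed <- 0L
      }
      prev <- cur
    }
  }
  out <- if (length(ev)) do.call(rbind, lapply(ev, as.data.frame)) else
    data.frame(molecule = character(), entry_frame = integer(),
               exit_frame = integer(), entry_side = character(),
               exit_side = character(), direction = integer(),
               interpolated = logical())
  structure(out, class = c("pw_events", "data.frame"),
            species = tracks$label,
            duration_ns = tracks$times[nf] - tracks$times[1])
}

#' Permeation rates from per-replica event counts
#'
#' Per replica, rate = events / duration.  Reports the mean rate across
#' replicas with its standard error (sample SD / sqrt(n)), and the pooled
#' rate (total events / total time).
#'
#' @param events List of `pw_events` (one per replica), or an integer
#'   vector of event counts.
#' @param durations_ns Per-replica simulated durations (ns); defaults to
#'   the `duration_ns` attributes of the event tables.
#' @return A `pw_rate`: list with `rate` (mean events/ns), `se`,
#'   `pooled_rate`, `total_events`, `total_time_ns`, `per_replica`.
#' @export
permeation_rate <- function(events, durations_ns = NULL) {
  if (inherits(events, "pw_events")) events <- list(events)
  if (is.list(events)) {
    counts <- vapply(events, nrow, 1L)
    if (is.null(durations_ns))
      durations_ns <- vapply(events, attr, numeric(1), "duration_ns")
  } else {
    counts <- as.integer(events)
    if (is.null(durations_ns)) stop("durations_ns required with raw counts")
  }
  if (any(durations_ns <= 0)) stop("input error: durations must be > 0")
  if (length(counts) != length(durations_ns))
    stop("input error: one duration per replica required")
  per <- counts / durations_ns
  n <- length(per)
  structure(list(rate = mean(per),
                 se = if (n > 1) stats::sd(per) / sqrt(n) else 0,
                 pooled_rate = sum(counts) / sum(durations_ns),
                 total_events = sum(counts),
                 total_time_ns = sum(durations_ns),
                 per_replica = per),
            class = "pw_rate")
}

#' @export
print.pw_rate <- function(x, ...) {
  cat(sprintf("permeation rate: %.4g +/- %.2g events/ns (%d events / %.4g ns, %d replicas)\n",
              x$rate, x$se, x$total_events, x$total_time_ns,
              length(x$per_replica)))
  invisible(x)
}
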