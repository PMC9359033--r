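#' Build the 2D outline of a placed leaf
#'
#' Constructs the geometric primitives of the leaf cross-section in
#' physical (source-frame) coordinates: the fitted tip circle, the body
#' rectangle, and the vertical partition chord where the circle meets the
#' top and bottom surfaces.  The tip region is the sliver of the disk
#' distal of the chord; the body is the rectangle proximal of it.  The
#' two regions partition the leaf interior.
#'
#' The circle center lies on the leaf midline at depth `scd + h/2`; its
#' distal-most point is the physical tip apex, placed so that the apex
#' projects to the requested tip-ray position.  The partition chord sits
#' at horizontal offset `sqrt(R^2 - (h/2)^2)` from the circle center.
#'
#' @param placement A [leaf_placement()].
#' @param machine A [machine_geometry()].
#' @return An object of class `leaf_outline`: a list with fields
#'   `center` (circle center, c(x, z)), `radius`, `chord_x` (partition
#'   chord abscissa), `top_z`, `bottom_z`, `body_x` (range of the body
#'   rectangle), `apex` (tip apex, c(x, z)), `bank` and `sliver_depth`
#'   (apex-to-chord distance).
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' ol <- leaf_outline(leaf_placement(hd, 0), machine_geometry())
#' ol$sliver_depth   # ~0.344 cm for the HDMLC
#' @export
leaf_outline <- function(placement, machine) {
  stopifnot(inherits(placement, "leaf_placement"),
            inherits(machine, "machine_geometry"))
  leaf <- placement$leaf
  if (machine$sad - machine$scd <= leaf$height)
    stop("leaf does not fit between collimator plane and isocenter")
  sgn <- if (placement$bank == "left") 1 else -1
  zm <- machine$scd + leaf$height / 2          # midline depth
  apex_x <- unproject_iso(placement$tip_iso, zm, machine)
  cx <- apex_x - sgn * leaf$radius
  half_chord_off <- sqrt(leaf$radius^2 - (leaf$height / 2)^2)
  chord_x <- cx + sgn * half_chord_off
  body_far <- chord_x - sgn * leaf$body_length
  structure(list(center = c(cx, zm), radius = leaf$radius,
                 chord_x = chord_x,
                 top_z = machine$scd, bottom_z = machine$scd + leaf$height,
                 body_x = sort(c(body_far, chord_x)),
                 apex = c(apex_x, zm), bank = placement$bank,
                 sliver_depth = leaf$radius - half_chord_off),
            class = "leaf_outline")
}

#' @export
print.leaf_outline <- function(x, ...) {
  cat(sprintf(
    "<leaf_outline> %s bank: circle (%.3f, %.3f) r %.2f; chord x %.4f; z [%.2f, %.2f]\n",
    x$bank, x$center[1], x$center[2], x$radius, x$chord_x, x$top_z, x$bottom_z))
  invisible(x)
}

# Interval of ray depths z for which s*z lies in [xlo, xhi].
# Returns c(lo, hi) with lo > hi when empty.  s is scalar.
.z_interval_xslab <- function(s, xlo, xhi) {
  if (s > 0) c(xlo / s, xhi / s)
  else if (s < 0) c(xhi / s, xlo / s)
  else if (xlo <= 0 && 0 <= xhi) c(-Inf, Inf)
  else c(Inf, -Inf)
}

#' Chord of a ray through a circle
#'
#' Intersects the ray from the point source toward isocenter-plane
#' position `iso_x` with a circle, returning the entry/exit points and
#' the chord length.  A tangent or disjoint ray yields chord length 0.
#'
#' @param iso_x Isocenter-plane position of the ray, cm.
#' @param center Circle center `c(x, z)`, cm.
#' @param radius Circle radius, cm.
#' @param machine A [machine_geometry()].
#' @return List with `length` (cm), `points` (2 x 2 matrix of entry and
#'   exit `(x, z)`, or NULL when there is no crossing), and `z` (depth
#'   interval, or NULL).
#' @examples
#' m <- machine_geometry(100, 51)
#' # vertical ray through the center of a unit circle on the CAX
#' ray_circle_chord(0, c(0, 54.3), 1, m)$length   # 2
#' @export
ray_circle_chord <- function(iso_x, center, radius, machine) {
  stopifnot(inherits(machine, "machine_geometry"), radius > 0)
  s <- iso_x / machine$sad
  # (s z - cx)^2 + (z - cz)^2 = r^2
  a <- 1 + s^2
  b <- -2 * (s * center[1] + center[2])
  cc <- center[1]^2 + center[2]^2 - radius^2
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) {
    pts <- NULL
    if (disc == 0) {
      z0 <- -b / (2 * a)
      pts <- rbind(c(s * z0, z0))
    }
    return(list(length = 0, points = pts, z = NULL))
  }
  z1 <- (-b - sqrt(disc)) / (2 * a)
  z2 <- (-b + sqrt(disc)) / (2 * a)
  list(length = (z2 - z1) * sqrt(a),
       points = rbind(c(s * z1, z1), c(s * z2, z2)),
       z = c(z1, z2))
}

#' Chord of a ray through an axis-aligned rectangle
#'
#' Slab-method intersection of the source ray with the rectangle
#' `[x[1], x[2]] x [z[1], z[2]]`.  A ray crossing the full height at
#' angle theta to the vertical has chord `height / cos(theta)`.
#'
#' @param iso_x Isocenter-plane position of the ray, cm.
#' @param x,z Rectangle extents, each `c(min, max)` in cm.
#' @param machine A [machine_geometry()].
#' @return List with `length`, `points`, `z` as in [ray_circle_chord()].
#' @examples
#' m <- machine_geometry(100, 51)
#' ray_box_chord(0, c(-5, 5), c(51, 57.6), m)$length   # 6.6
#' @export
ray_box_chord <- function(iso_x, x, z, machine) {
  stopifnot(inherits(machine, "machine_geometry"),
            length(x) == 2L, length(z) == 2L, x[1] <= x[2], z[1] <= z[2])
  s <- iso_x / machine$sad
  zi <- .z_interval_xslab(s, x[1], x[2])
  lo <- max(zi[1], z[1])
  hi <- min(zi[2], z[2])
  if (hi <= lo) return(list(length = 0, points = NULL, z = NULL))
  list(length = (hi - lo) * sqrt(1 + s^2),
       points = rbind(c(s * lo, lo), c(s * hi, hi)),
       z = c(lo, hi))
}

#' Tip/body path lengths for a vector of rays
#'
#' Vectorized workhorse behind the sweep: for each isocenter-plane
#' position, the in-leaf chord is split into its tip-region and
#' body-region parts by interval intersections along the depth axis.
#' [decompose_path()] wraps this for a single ray and adds surface
#' labels.
#'
#' @param xs Isocenter-plane ray positions, cm (vector).
#' @param placement A [leaf_placement()].
#' @param machine A [machine_geometry()].
#' @param outline Optional precomputed [leaf_outline()].
#' @return data.frame with columns `len_tip`, `len_body` (cm) and the
#'   depth intervals `z_tip_lo`, `z_tip_hi`, `z_body_lo`, `z_body_hi`
#'   (NA when the ray misses that region).
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' pl <- leaf_placement(hd, -2)
#' leaf_path_lengths(c(-2.5, -2.2, -1.9), pl, machine_geometry())
#' @export
leaf_path_lengths <- function(xs, placement, machine, outline = NULL) {
  if (is.null(outline)) outline <- leaf_outline(placement, machine)
  s <- xs / machine$sad
  cx <- outline$center[1]; cz <- outline$center[2]; r <- outline$radius
  sgn <- if (outline$bank == "left") 1 else -1

  # disk crossing interval in z
  a <- 1 + s^2
  b <- -2 * (s * cx + cz)
  cc <- cx^2 + cz^2 - r^2
  disc <- b^2 - 4 * a * cc
  hit <- disc > 0
  sq <- sqrt(pmax(disc, 0))
  zA <- (-b - sq) / (2 * a)
  zB <- (-b + sq) / (2 * a)

  # half-plane sgn * (x - chord_x) >= 0, i.e. the tip side of the chord
  ch <- outline$chord_x
  # z range where sgn * (s z - ch) >= 0
  ss <- sgn * s
  hp_lo <- ifelse(ss > 0, sgn * ch / ss, -Inf)
  hp_hi <- ifelse(ss > 0, Inf, ifelse(ss < 0, sgn * ch / ss, Inf))
  # s == 0: ray is the CAX, x = 0 throughout
  z0 <- s == 0
  if (any(z0)) {
    inside0 <- sgn * (0 - ch) >= 0
    hp_lo[z0] <- ifelse(inside0, -Inf, Inf)
    hp_hi[z0] <- ifelse(inside0, Inf, -Inf)
  }
  tip_lo <- pmax(zA, hp_lo)
  tip_hi <- pmin(zB, hp_hi)
  len_tip <- ifelse(hit, pmax(tip_hi - tip_lo, 0) * sqrt(a), 0)

  # body rectangle: x in body_x, z in [top, bottom]
  bx <- outline$body_x
  blo_x <- ifelse(s > 0, bx[1] / s, ifelse(s < 0, bx[2] / s, -Inf))
  bhi_x <- ifelse(s > 0, bx[2] / s, ifelse(s < 0, bx[1] / s, Inf))
  if (any(z0)) {
    in_body0 <- bx[1] <= 0 & 0 <= bx[2]
    blo_x[z0] <- ifelse(in_body0, -Inf, Inf)
    bhi_x[z0] <- ifelse(in_body0, Inf, -Inf)
  }
  body_lo <- pmax(blo_x, outline$top_z)
  body_hi <- pmin(bhi_x, outline$bottom_z)
  len_body <- pmax(body_hi - body_lo, 0) * sqrt(a)

  # a swept ray must never cross the proximal end face
  if (sgn > 0) {
    crosses_end <- len_body > 0 &
      ((s < 0 & bx[1] / s < outline$bottom_z) |
       (s > 0 & bx[1] > 0 & bx[1] / s > outline$top_z))
  } else {
    crosses_end <- len_body > 0 &
      ((s > 0 & bx[2] / s < outline$bottom_z) |
       (s < 0 & bx[2] < 0 & bx[2] / s > outline$top_z))
  }
  if (any(crosses_end))
    stop("ray crosses the proximal end face; increase body_length_cm")

  data.frame(len_tip = len_tip, len_body = len_body,
             z_tip_lo = ifelse(len_tip > 0, tip_lo, NA_real_),
             z_tip_hi = ifelse(len_tip > 0, tip_hi, NA_real_),
             z_body_lo = ifelse(len_body > 0, body_lo, NA_real_),
             z_body_hi = ifelse(len_body > 0, body_hi, NA_real_))
}

# classify a boundary point of the leaf interior
.surface_label <- function(x, z, outline, tol = 1e-9) {
  sgn <- if (outline$bank == "left") 1 else -1
  on_circle <- abs(sqrt((x - outline$center[1])^2 + (z - outline$center[2])^2) -
                     outline$radius) < 1e-6
  if (on_circle && sgn * (x - outline$chord_x) >= -tol) return("arc")
  if (abs(z - outline$top_z) < tol) return("top")
  if (abs(z - outline$bottom_z) < tol) return("bottom")
  "body-interior-boundary"
}

#' Decompose a ray path through the leaf into tip and body segments
#'
#' Intersects a single source ray with the placed leaf and splits the
#' interior chord at the tip/body partition chord, reporting the length
#' in each region, the entry and exit points, and the surfaces crossed
#' (`"arc"`, `"top"`, `"bottom"`, or `"none"` for a miss).  Because the
#' leaf cross-section is convex, the interior chord is a single segment
#' and `len_tip + len_body` equals its total length.
#'
#' @param iso_x Isocenter-plane position of the ray, cm (scalar).
#' @param placement A [leaf_placement()].
#' @param machine A [machine_geometry()].
#' @return An object of class `path_decomposition`: list with `len_tip`,
#'   `len_body`, `entry_surface`, `exit_surface`, `entry_point`,
#'   `exit_point` (each `c(x, z)` or NULL when the ray misses).
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' pl <- leaf_placement(hd, -2)
#' decompose_path(-2.2, pl, machine_geometry())
#' @export
decompose_path <- function(iso_x, placement, machine) {
  stopifnot(length(iso_x) == 1L)
  outline <- leaf_outline(placement, machine)
  pl <- leaf_path_lengths(iso_x, placement, machine, outline)
  s <- iso_x / machine$sad
  z_in <- suppressWarnings(min(pl$z_tip_lo, pl$z_body_lo, na.rm = TRUE))
  z_out <- suppressWarnings(max(pl$z_tip_hi, pl$z_body_hi, na.rm = TRUE))
  if (!is.finite(z_in) || pl$len_tip + pl$len_body <= 0) {
    res <- list(len_tip = 0, len_body = 0,
                entry_surface = "none", exit_surface = "none",
                entry_point = NULL, exit_point = NULL, iso_x = iso_x)
    return(structure(res, class = "path_decomposition"))
  }
  entry <- c(s * z_in, z_in)
  exit <- c(s * z_out, z_out)
  structure(list(len_tip = pl$len_tip, len_body = pl$len_body,
                 entry_surface = .surface_label(entry[1], entry[2], outline),
                 exit_surface = .surface_label(exit[1], exit[2], outline),
                 entry_point = entry, exit_point = exit, iso_x = iso_x),
            class = "path_decomposition")
}

#' @export
print.path_decomposition <- function(x, ...) {
  cat(sprintf(
    "<path_decomposition> ray %+.4f cm: tip %.4f cm (%s in), body %.4f cm (%s out)\n",
    x$iso_x, x$len_tip, x$entry_surface, x$len_body, x$exit_surface))
  invisible(x)
}
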