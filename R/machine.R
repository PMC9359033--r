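#' Machine geometry for a point-source treatment head
#'
#' Describes the beam-line geometry in the 2D plane containing the leaf
#' travel axis and the beam central axis (CAX): a point source at the
#' origin, with depth `z` increasing toward the isocenter plane.  The
#' proximal (top) leaf surface sits at `z = scd_cm`.
#'
#' @param sad_cm Source-axis distance in cm (source to isocenter plane).
#' @param scd_cm Source-collimator distance in cm (source to the proximal
#'   leaf surface).
#' @return An object of class `machine_geometry`.
#' @examples
#' machine_geometry()            # TrueBeam-like: SAD 100 cm, SCD 51 cm
#' machine_geometry(100, 53.5)
#' @export
machine_geometry <- function(sad_cm = 100, scd_cm = 51) {
  stopifnot(is.numeric(sad_cm), length(sad_cm) == 1L, is.finite(sad_cm),
            is.numeric(scd_cm), length(scd_cm) == 1L, is.finite(scd_cm))
  if (scd_cm <= 0 || scd_cm >= sad_cm)
    stop("machine geometry requires 0 < scd_cm < sad_cm")
  structure(list(sad = sad_cm, scd = scd_cm), class = "machine_geometry")
}

#' @export
print.machine_geometry <- function(x, ...) {
  cat(sprintf("<machine_geometry> SAD %.2f cm, SCD %.2f cm\n", x$sad, x$scd))
  invisible(x)
}

#' Leaf cross-section specification
#'
#' A leaf is modeled in 2D as a rectangle (the body) closed distally by a
#' fitted circle (the rounded end).  The circle is centered on the leaf
#' midline; its radius must be at least half the leaf height so that the
#' arc can span the full height.  Attenuation is characterized either by
#' the perpendicular (CAX) transmission `transmission`, from which the
#' linear attenuation coefficient is derived, or by `mu_per_cm` directly.
#'
#' @param height_cm Leaf height (beam direction) in cm.
#' @param tip_radius_cm Radius of the fitted tip circle in cm; must be
#'   `>= height_cm / 2`.
#' @param body_length_cm Length of rectangular body proximal of the
#'   tip/body partition chord, in cm.  It only needs to be long enough
#'   that no swept ray exits through the proximal end face.
#' @param transmission Perpendicular transmission through the full leaf
#'   height, in (0, 1).  Exactly one of `transmission`, `mu_per_cm` must
#'   be supplied.
#' @param mu_per_cm Linear attenuation coefficient in 1/cm.
#' @return An object of class `leaf_spec` with fields `height`, `radius`,
#'   `body_length`, `t_perp` and `mu` (the unspecified one of the last
#'   two is derived assuming simple exponential attenuation).
#' @examples
#' # Varian high-definition MLC leaf, flattened 6 MV beam
#' leaf_spec(6.60, 16.00, transmission = 0.0122)
#' @export
leaf_spec <- function(height_cm, tip_radius_cm, body_length_cm = 15,
                      transmission = NULL, mu_per_cm = NULL) {
  stopifnot(is.numeric(height_cm), height_cm > 0,
            is.numeric(tip_radius_cm), is.numeric(body_length_cm))
  if (tip_radius_cm < height_cm / 2)
    stop("tip_radius_cm must be >= height_cm / 2 so the fitted circle ",
         "spans the leaf height")
  if (body_length_cm <= 0) stop("body_length_cm must be positive")
  if (is.null(transmission) == is.null(mu_per_cm))
    stop("supply exactly one of 'transmission' or 'mu_per_cm'")
  if (is.null(mu_per_cm)) {
    mu_per_cm <- attenuation_coefficient(transmission, height_cm)
  } else {
    if (mu_per_cm <= 0) stop("mu_per_cm must be positive")
    transmission <- exp(-mu_per_cm * height_cm)
  }
  structure(list(height = height_cm, radius = tip_radius_cm,
                 body_length = body_length_cm,
                 t_perp = transmission, mu = mu_per_cm),
            class = "leaf_spec")
}

#' @export
print.leaf_spec <- function(x, ...) {
  cat(sprintf(
    "<leaf_spec> h %.3f cm, tip radius %.3f cm, body %.1f cm, T_perp %.4g (mu %.4g /cm)\n",
    x$height, x$radius, x$body_length, x$t_perp, x$mu))
  invisible(x)
}

#' Place a leaf at a tip position
#'
#' Positions a leaf so that the projection of its physical tip apex (the
#' distal-most point of the fitted circle, on the leaf midline) through
#' the point source onto the isocenter plane lands at `tip_iso_cm` -- the
#' tip-ray (TR) position, i.e. the leaf "position" in the usual machine
#' convention.  A left-bank leaf has its body extending toward negative
#' x; a right-bank leaf is the mirror image.
#'
#' @param leaf A [leaf_spec()].
#' @param tip_iso_cm Tip-ray position in the isocenter plane, cm.
#' @param bank `"right"` (default: body toward +x, tip facing -x)
#'   or `"left"` (the mirror image).
#' @return An object of class `leaf_placement`.
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' leaf_placement(hd, tip_iso_cm = -2)
#' @export
leaf_placement <- function(leaf, tip_iso_cm, bank = c("right", "left")) {
  stopifnot(inherits(leaf, "leaf_spec"),
            is.numeric(tip_iso_cm), length(tip_iso_cm) == 1L,
            is.finite(tip_iso_cm))
  bank <- match.arg(bank)
  structure(list(leaf = leaf, tip_iso = tip_iso_cm, bank = bank),
            class = "leaf_placement")
}

#' @export
print.leaf_placement <- function(x, ...) {
  cat(sprintf("<leaf_placement> TR %+.3f cm (%s bank)\n", x$tip_iso, x$bank))
  print(x$leaf)
  invisible(x)
}

#' Project physical coordinates to the isocenter plane (and back)
#'
#' A point at lateral position `x` and depth `z` from the point source
#' projects to `x * sad / z` in the isocenter plane.  All positions
#' reported by this package are isocenter-plane projections.
#'
#' @param x Lateral position(s), cm.
#' @param z Depth(s) from the source, cm; must satisfy `0 < z <= sad`.
#' @param machine A [machine_geometry()].
#' @return Projected (or unprojected) position(s) in cm.
#' @examples
#' m <- machine_geometry(sad_cm = 100, scd_cm = 50)
#' project_iso(1, 50, m)              # 2
#' unproject_iso(project_iso(1, 50, m), 50, m)
#' @export
project_iso <- function(x, z, machine) {
  stopifnot(inherits(machine, "machine_geometry"))
  if (any(z <= 0 | z > machine$sad))
    stop("projection depth z must satisfy 0 < z <= sad")
  x * machine$sad / z
}

#' @rdname project_iso
#' @export
unproject_iso <- function(x, z, machine) {
  stopifnot(inherits(machine, "machine_geometry"))
  if (any(z <= 0 | z > machine$sad))
    stop("projection depth z must satisfy 0 < z <= sad")
  x * z / machine$sad
}
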