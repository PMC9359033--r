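#' Linear attenuation coefficient from perpendicular transmission
#'
#' Assuming simple exponential attenuation, a perpendicular ray through
#' the full leaf height `h` transmits `t_perp = exp(-mu * h)`, so
#' `mu = -log(t_perp) / h`.
#'
#' @param t_perp Perpendicular (CAX) transmission, in (0, 1).
#' @param height_cm Leaf height in cm.
#' @return Attenuation coefficient in 1/cm.
#' @examples
#' attenuation_coefficient(0.0122, 6.60)  # ~0.668 /cm
#' @export
attenuation_coefficient <- function(t_perp, height_cm) {
  stopifnot(is.numeric(t_perp), is.numeric(height_cm))
  if (any(t_perp <= 0) || any(t_perp >= 1))
    stop("t_perp must lie strictly between 0 and 1")
  if (any(height_cm <= 0)) stop("height_cm must be positive")
  -log(t_perp) / height_cm
}

#' Linear attenuation coefficient from a half-value layer
#'
#' @param hvl_cm Half-value layer in cm (thickness halving the beam).
#' @return Attenuation coefficient `log(2) / hvl_cm` in 1/cm.
#' @examples
#' mu_from_hvl(0.950)
#' @export
mu_from_hvl <- function(hvl_cm) {
  stopifnot(is.numeric(hvl_cm))
  if (any(hvl_cm <= 0)) stop("hvl_cm must be positive")
  log(2) / hvl_cm
}

#' Transmission of a ray with a given in-leaf path length
#'
#' @param r Path length(s) inside the leaf, cm (`>= 0`).
#' @param mu Linear attenuation coefficient, 1/cm.
#' @return Transmission value(s) `exp(-mu * r)` in (0, 1].
#' @examples
#' transmit(0, 0.668)        # 1: open field
#' transmit(6.60, 0.668)     # perpendicular body transmission
#' @export
transmit <- function(r, mu) {
  stopifnot(is.numeric(r), is.numeric(mu))
  if (any(r < 0)) stop("path length r must be non-negative")
  if (any(mu <= 0)) stop("mu must be positive")
  exp(-mu * r)
}

#' Sweep a transmission curve across a parked leaf
#'
#' Casts rays from the point source to a uniform grid of isocenter-plane
#' positions spanning the leaf-tip region -- from just beyond the tangent
#' (visible) ray on the open-field side to just past the boundary ray on
#' the body side -- and converts each ray's in-leaf path length to a
#' transmission value by exponential attenuation.  The grid is anchored
#' at the analytic tangent-ray position so the tangent is always
#' bracketed regardless of step.
#'
#' @param placement A [leaf_placement()].
#' @param machine A [machine_geometry()].
#' @param step Sample spacing in the isocenter plane, cm.  Steps coarser
#'   than 1e-3 cm degrade the interpolated edge metrics and trigger a
#'   warning.
#' @param margin Extra window on each side beyond the boundary and
#'   visible rays, cm.
#' @return An object of class `transmission_curve`: a list with fields
#'   `tip_iso`, `xs` (ordered sample positions, cm), `ts` (transmission
#'   in (0, 1]), `step`, `vr`, `br`, plus the placement and machine.
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' cv <- sweep_curve(leaf_placement(hd, 0), machine_geometry(), step = 1e-3)
#' range(cv$ts)
#' @export
sweep_curve <- function(placement, machine, step = 1e-5, margin = 0.05) {
  stopifnot(inherits(placement, "leaf_placement"),
            inherits(machine, "machine_geometry"))
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a positive number")
  if (step > 1e-3)
    warning("sweep step > 1e-3 cm: interpolated edge metrics degraded")
  if (margin < 0.05) margin <- 0.05

  vr <- find_vr(placement, machine)
  br <- find_br(placement, machine)
  lo <- min(vr, br) - margin
  hi <- max(vr, br) + margin
  # grid anchored on the tangent-ray position
  xs <- vr + seq.int(floor((lo - vr) / step), ceiling((hi - vr) / step)) * step
  pl <- leaf_path_lengths(xs, placement, machine)
  ts <- transmit(pl$len_tip + pl$len_body, placement$leaf$mu)
  structure(list(tip_iso = placement$tip_iso, xs = xs, ts = ts,
                 step = step, vr = vr, br = br,
                 placement = placement, machine = machine),
            class = "transmission_curve")
}

#' @export
print.transmission_curve <- function(x, ...) {
  cat(sprintf(
    "<transmission_curve> TR %+.2f cm: %d samples at %.1e cm in [%.4f, %.4f]\n",
    x$tip_iso, length(x$xs), x$step, min(x$xs), max(x$xs)))
  invisible(x)
}

#' @export
as.data.frame.transmission_curve <- function(x, ...) {
  data.frame(tip_position_cm = x$tip_iso, x_iso_cm = x$xs,
             transmission = x$ts)
}
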