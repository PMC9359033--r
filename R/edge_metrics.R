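#' Visible-ray (tangent) position
#'
#' The visible ray (VR) is the last ray, sweeping from the open field
#' toward the leaf, whose transmission is unity: the ray from the point
#' source tangent to the rounded leaf end.  It defines the light-field
#' edge.  The tangent slope solves a quadratic in closed form; when the
#' tangent point would fall beyond the arc (past the circle/body
#' transition, possible at extreme off-axis positions), the silhouette
#' edge is the arc corner instead, and the ray through that corner is
#' returned.
#'
#' @param placement A [leaf_placement()].
#' @param machine A [machine_geometry()].
#' @return Isocenter-plane VR position, cm.
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' find_vr(leaf_placement(hd, 0), machine_geometry())
#' @export
find_vr <- function(placement, machine) {
  outline <- leaf_outline(placement, machine)
  cx <- outline$center[1]; cz <- outline$center[2]; r <- outline$radius
  sgn <- if (outline$bank == "left") 1 else -1
  # tangent lines x = s z to the circle: |cx - s cz| = r sqrt(1 + s^2)
  a <- cz^2 - r^2
  b <- -2 * cx * cz
  cc <- cx^2 - r^2
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) stop("source lies inside or on the tip circle")
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  s <- if (sgn > 0) max(roots) else min(roots)
  # tangent point: foot of the perpendicular from the circle center
  zt <- (s * cx + cz) / (1 + s^2)
  xt <- s * zt
  if (sgn * (xt - outline$chord_x) >= 0) return(s * machine$sad)
  # tangent point off the arc: silhouette is the nearer chord corner
  corner_z <- if (zt < cz) outline$top_z else outline$bottom_z
  project_iso(outline$chord_x, corner_z, machine)
}

#' Boundary-ray position
#'
#' The boundary ray (BR) is the first ray, sweeping from the open field
#' toward the leaf body, that intersects only the rectangular body --
#' entering through the top surface and exiting through the bottom with
#' zero path in the tip region.  It passes through the partition-chord
#' corner on the appropriate side and marks the body-side limit of
#' tip-influenced rays.
#'
#' @inheritParams find_vr
#' @return Isocenter-plane BR position, cm.
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' find_br(leaf_placement(hd, -2), machine_geometry())
#' @export
find_br <- function(placement, machine) {
  outline <- leaf_outline(placement, machine)
  sgn <- if (outline$bank == "left") 1 else -1
  # body-only <=> the whole slab stays on the body side of the chord:
  # sgn * s * z <= sgn * chord_x for z in [top, bottom]
  cand <- outline$chord_x / c(outline$top_z, outline$bottom_z)
  s <- if (sgn > 0) min(cand) else max(cand)
  s * machine$sad
}

# interpolated crossing of a sampled transmission curve at `level`,
# taken on the open-field side (nearest the tangent ray)
.curve_crossing <- function(curve, level) {
  xs <- curve$xs; ts <- curve$ts
  sgn <- if (curve$placement$bank == "left") 1 else -1
  if (sgn < 0) { xs <- rev(-xs); ts <- rev(ts) }  # open field toward +x
  below <- ts < level
  idx <- which(below[-length(below)] & !below[-1])
  if (!length(idx))
    stop(sprintf("transmission curve does not cross level %.3g; ",
                 level), "sweep window too narrow")
  i <- max(idx)
  x <- xs[i] + (level - ts[i]) * (xs[i + 1] - xs[i]) / (ts[i + 1] - ts[i])
  sgn * x
}

#' Half-attenuation ray position from a sampled curve
#'
#' The XR is the ray attenuated to 50% of the open-field intensity; it
#' defines the radiation beam edge.  The crossing is refined by linear
#' interpolation between the bracketing sweep samples.
#'
#' @param curve A [sweep_curve()] result.
#' @param level Transmission level of the crossing (default 0.5).
#' @return Isocenter-plane crossing position, cm.
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' cv <- sweep_curve(leaf_placement(hd, 0), machine_geometry(), step = 1e-4)
#' find_xr(cv)
#' @export
find_xr <- function(curve, level = 0.5) {
  stopifnot(inherits(curve, "transmission_curve"),
            is.numeric(level), level > 0, level < 1)
  .curve_crossing(curve, level)
}

#' Edge metrics for one leaf position
#'
#' Assembles, for a single tip-ray (TR) position, the characteristic ray
#' positions and the derived metrics:
#' \describe{
#'   \item{vr}{tangent (visible) ray -- the light-field edge;}
#'   \item{xr}{50% attenuation ray -- the radiation beam edge;}
#'   \item{br}{boundary ray -- first body-only ray;}
#'   \item{x80, x20}{80% and 20% transmission crossings;}
#'   \item{xvo}{radiation/light-field edge offset `|vr - xr|`;}
#'   \item{beb}{beam edge broadening, the 80%-20% width;}
#'   \item{tzw}{tip zone width `|vr - br|`, the projected extent of
#'     tip-influenced rays.}
#' }
#' All positions are isocenter-plane projections in cm.  VR and BR are
#' geometric (independent of attenuation); the transmission crossings
#' come from a swept curve (`method = "sweep"`) or from closed-form path
#' lengths with bracketed root finding (`method = "analytic"`).
#'
#' @inheritParams find_vr
#' @param step Sweep sample spacing, cm (sweep method only).
#' @param method `"sweep"` or `"analytic"`.
#' @return A one-row data.frame with columns `tr`, `vr`, `xr`, `br`,
#'   `x80`, `x20`, `xvo`, `beb`, `tzw`.
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' edge_metrics(leaf_placement(hd, 0), machine_geometry(), step = 1e-4)
#' @export
edge_metrics <- function(placement, machine, step = 1e-5,
                         method = c("sweep", "analytic")) {
  method <- match.arg(method)
  vr <- find_vr(placement, machine)
  br <- find_br(placement, machine)
  if (method == "sweep") {
    curve <- sweep_curve(placement, machine, step = step)
    xr <- find_xr(curve, 0.5)
    x80 <- find_xr(curve, 0.8)
    x20 <- find_xr(curve, 0.2)
  } else {
    cr <- analytic_crossings(placement, machine, c(0.5, 0.8, 0.2))
    xr <- cr[1]; x80 <- cr[2]; x20 <- cr[3]
  }
  sgn <- if (placement$bank == "left") 1 else -1
  ord <- sgn * c(br, x20, xr, x80, vr)
  if (any(diff(ord) < -1e-9))
    stop("edge-ray ordering violated: br <= x20 <= xr <= x80 <= vr ",
         "(toward the open field)")
  data.frame(tr = placement$tip_iso, vr = vr, xr = xr, br = br,
             x80 = x80, x20 = x20,
             xvo = sgn * (vr - xr), beb = abs(x80 - x20),
             tzw = sgn * (vr - br))
}

#' Analytic crossing positions (independent oracle)
#'
#' Computes level crossings of the transmission profile without any
#' sweeping: the total in-leaf path length `L(x)` of the ray toward
#' isocenter position `x` is evaluated in closed form from the
#' ray/circle and ray/rectangle chords, and the position with
#' `exp(-mu * L(x)) = level` is found by bracketed root finding between
#' the boundary and visible rays (bisection via [stats::uniroot()] to
#' 1e-10 cm).  This re-derivation is the validation reference for the
#' sweep-based metrics.
#'
#' @inheritParams find_vr
#' @param levels Transmission levels in (0, 1) to solve for.
#' @return Numeric vector of isocenter-plane positions, cm, one per
#'   level.
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' analytic_crossings(leaf_placement(hd, 0), machine_geometry(), 0.5)
#' @export
analytic_crossings <- function(placement, machine, levels = 0.5) {
  stopifnot(all(levels > 0), all(levels < 1))
  outline <- leaf_outline(placement, machine)
  mu <- placement$leaf$mu
  vr <- find_vr(placement, machine)
  br <- find_br(placement, machine)
  path_len <- function(x) {
    pl <- leaf_path_lengths(x, placement, machine, outline)
    pl$len_tip + pl$len_body
  }
  vapply(levels, function(level) {
    target <- -log(level) / mu
    f <- function(x) path_len(x) - target
    lo <- br; hi <- vr
    # deep levels can cross on the body side of the boundary ray
    sgn <- if (placement$bank == "left") 1 else -1
    tries <- 0
    while (f(lo) < 0) {
      lo <- lo - sgn * 0.1
      if ((tries <- tries + 1) > 200)
        stop(sprintf("no %.3g crossing: level below the body plateau", level))
    }
    stats::uniroot(f, lower = min(lo, hi), upper = max(lo, hi),
                   tol = 1e-10)$root
  }, numeric(1))
}
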