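#' Scan edge metrics across a range of leaf positions
#'
#' Computes [edge_metrics()] for a grid of tip-ray positions, emulating
#' a leaf stepped across the clinically available travel range.
#'
#' @param leaf A [leaf_spec()].
#' @param machine A [machine_geometry()].
#' @param trs Tip-ray grid, cm (default -20..20 in 1 cm steps).
#' @param step Sweep sample spacing, cm.
#' @param bank Leaf bank, `"left"` or `"right"`.
#' @param method Crossing method passed to [edge_metrics()].
#' @return A data.frame with one row per TR and the [edge_metrics()]
#'   columns.
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' scan_positions(hd, machine_geometry(), trs = -2:2, step = 1e-4)
#' @export
scan_positions <- function(leaf, machine, trs = -20:20, step = 1e-4,
                           bank = "right", method = "sweep") {
  stopifnot(inherits(leaf, "leaf_spec"), !is.unsorted(trs, strictly = TRUE))
  rows <- lapply(trs, function(tr) {
    edge_metrics(leaf_placement(leaf, tr, bank), machine,
                 step = step, method = method)
  })
  do.call(rbind, rows)
}

#' Detect where a metric series breaks from its quasi-static value
#'
#' Near the CAX the edge metrics of a rounded-end leaf are effectively
#' constant (the quasi-static zone).  This detector takes the value at
#' TR = 0 as the reference and reports, on each side, the first grid
#' position at which the metric deviates from the reference by more than
#' `tolerance` -- the break position.
#'
#' @param trs Tip-ray grid, cm, covering TR = 0.
#' @param values Metric value at each TR, cm.
#' @param tolerance Allowed deviation from the TR = 0 value, cm.
#'   The default, 0.005 cm, is a round value sitting well above the
#'   quasi-static plateau ripple (below 0.003 cm for the clinical HDMLC
#'   scan) and well below the post-break deviations.
#' @param metric Metric name recorded in the result.
#' @return An object of class `break_result`: list with `x_break_neg`
#'   and `x_break_pos` (cm; `NA` when the series never deviates on that
#'   side), `reference_value`, `tolerance`, `metric` and
#'   `method = "threshold"`.
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' sc <- scan_positions(hd, machine_geometry(), trs = seq(-20, 20, 2))
#' detect_x_break(sc$tr, sc$xvo, tolerance = 0.005, metric = "xvo")
#' @export
detect_x_break <- function(trs, values, tolerance = 0.005, metric = "xvo") {
  stopifnot(length(trs) == length(values), !is.unsorted(trs))
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be positive")
  i0 <- which(trs == 0)
  if (!length(i0)) stop("TR grid must cover TR = 0 (the reference)")
  ref <- values[i0[1]]
  dev <- abs(values - ref) > tolerance
  pos <- which(dev & trs > 0)
  neg <- which(dev & trs < 0)
  structure(list(
    x_break_pos = if (length(pos)) trs[min(pos)] else NA_real_,
    x_break_neg = if (length(neg)) trs[max(neg)] else NA_real_,
    reference_value = ref, tolerance = tolerance,
    metric = metric, method = "threshold"),
    class = "break_result")
}

#' @export
print.break_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "none" else sprintf("%+.2f cm", v)
  cat(sprintf(
    "<break_result> %s (%s): neg %s, pos %s (ref %.4f cm, tol %.3g cm)\n",
    x$metric, x$method, fmt(x$x_break_neg), fmt(x$x_break_pos),
    x$reference_value, x$tolerance))
  invisible(x)
}

# do both intersections of the level-crossing ray lie on the tip arc?
.level_ray_on_arc <- function(leaf, machine, tr, level, bank) {
  pl <- leaf_placement(leaf, tr, bank)
  x <- analytic_crossings(pl, machine, level)
  d <- decompose_path(x, pl, machine)
  d$entry_surface == "arc" && d$exit_surface == "arc"
}

#' Geometric break detector
#'
#' The constancy break is attributable to the level-crossing ray's
#' entry/exit points moving off the rounded leaf end and onto the leaf
#' body.  This detector finds, by bisection on the tip position, the TR
#' at which one intersection of the level ray first leaves the tip arc.
#' Level 0.5 (the beam-edge ray) targets the edge-offset break; level
#' 0.2 (the deeper 20% ray, which transitions first) targets the
#' edge-broadening break.
#'
#' @inheritParams scan_positions
#' @param level Transmission level of the probed ray, in (0, 1).
#' @param tr_max Search limit, cm.
#' @param tol Bisection tolerance on TR, cm.
#' @return A `break_result` with `method = "geometric"`.
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' detect_x_break_geometric(hd, machine_geometry(), level = 0.5)
#' @export
detect_x_break_geometric <- function(leaf, machine, level = 0.5,
                                     tr_max = 40, tol = 0.05,
                                     bank = "right") {
  stopifnot(level > 0, level < 1, tol > 0)
  if (!.level_ray_on_arc(leaf, machine, 0, level, bank))
    stop("level ray leaves the arc already at TR = 0; no quasi-static zone")
  one_side <- function(sgn) {
    hi <- sgn * tr_max
    if (.level_ray_on_arc(leaf, machine, hi, level, bank))
      return(NA_real_)  # no transition within the search range
    lo <- 0
    while (abs(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      if (.level_ray_on_arc(leaf, machine, mid, level, bank)) lo <- mid
      else hi <- mid
    }
    (lo + hi) / 2
  }
  structure(list(
    x_break_pos = one_side(+1), x_break_neg = one_side(-1),
    reference_value = NA_real_, tolerance = tol,
    metric = sprintf("level %.2f ray on arc", level),
    method = "geometric"),
    class = "break_result")
}

#' Break position as a function of leaf tip radius
#'
#' Repeats the threshold break detection for a family of leaves sharing
#' height, transmission and body length but differing in tip radius, and
#' tabulates the positive-side break position against radius.  Larger
#' tip radii break sooner (closer to the CAX); small radii push the
#' break far beyond the clinical travel range, so the TR search extends
#' to `tr_max` (non-physical positions are deliberately allowed).
#'
#' The default detector is the geometric one (`method = "geometric"`):
#' the break is the bisected TR at which the level ray (50% for XVO, 20%
#' for BEB) first leaves the tip arc.  The threshold detector walks
#' outward on a 1 cm TR grid from the CAX reference and stops at the
#' first deviation beyond `tolerance`; note that for small radii the
#' slow off-axis drift of the metric can cross a fixed absolute
#' tolerance before the sharp geometric transition does, so the
#' threshold variant is not guaranteed monotone in radius.  Crossings
#' use the closed-form path-length solver throughout.
#'
#' @param radii Tip radii to scan, cm; each must be `>= height/2`.
#' @param leaf Template [leaf_spec()] supplying height, transmission and
#'   body length.
#' @param machine A [machine_geometry()].
#' @param metric `"xvo"` or `"beb"`.
#' @param method `"geometric"` (default) or `"threshold"`.
#' @param tolerance Threshold deviation, cm (default 0.005, as in
#'   [detect_x_break()]; threshold method only).
#' @param tr_max Largest TR probed, cm.
#' @return A data.frame with columns `radius_cm` and `x_break_cm`
#'   (`NA` when no break occurs up to `tr_max`).
#' @examples
#' hd <- leaf_spec(6.60, 16.00, transmission = 0.0122)
#' radius_sweep(c(8, 12, 16), hd, machine_geometry())
#' @export
radius_sweep <- function(radii, leaf, machine, metric = c("xvo", "beb"),
                         method = c("geometric", "threshold"),
                         tolerance = NULL, tr_max = 120) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (any(radii < leaf$height / 2))
    stop("every radius must be >= height/2")
  if (is.null(tolerance)) tolerance <- 0.005
  level <- if (metric == "xvo") 0.5 else 0.2
  metric_at <- function(lf, tr) {
    pl <- leaf_placement(lf, tr)
    sgn <- -1  # right bank: open field toward -x of the tip
    if (metric == "xvo") {
      sgn * (find_vr(pl, machine) - analytic_crossings(pl, machine, 0.5))
    } else {
      cr <- analytic_crossings(pl, machine, c(0.8, 0.2))
      abs(cr[1] - cr[2])
    }
  }
  x_break <- vapply(radii, function(r) {
    # body long enough for the largest probed position
    need <- abs(tr_max) * (machine$scd + leaf$height) / machine$sad + r
    lf <- leaf_spec(leaf$height, r, max(leaf$body_length, need),
                    mu_per_cm = leaf$mu)
    if (method == "geometric") {
      br <- detect_x_break_geometric(lf, machine, level = level,
                                     tr_max = tr_max)
      return(br$x_break_pos)
    }
    ref <- metric_at(lf, 0)
    for (tr in seq(1, tr_max)) {
      if (abs(metric_at(lf, tr) - ref) > tolerance) return(tr)
    }
    NA_real_
  }, numeric(1))
  data.frame(radius_cm = radii, x_break_cm = x_break)
}
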