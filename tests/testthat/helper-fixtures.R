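# Shared fixtures and an independent brute-force path-length oracle.

tb_machine <- function() machine_geometry(sad_cm = 100, scd_cm = 51)

hdmlc_leaf <- function() leaf_spec(6.60, 16.00, transmission = 0.0122)

boyer_leaf <- function() leaf_spec(6.13, 8.00, mu_per_cm = mu_from_hvl(0.950))

# Midpoint-rule line integral of the leaf-interior indicator along the
# ray toward iso_x: independent of the interval arithmetic used by
# leaf_path_lengths.  Error is bounded by a few z-steps per boundary
# crossing.
brute_leaf_chord <- function(iso_x, placement, machine, n = 4e5) {
  ol <- leaf_outline(placement, machine)
  s <- iso_x / machine$sad
  z <- seq(ol$top_z, ol$bottom_z, length.out = n + 1)
  z <- (z[-1] + z[-length(z)]) / 2          # midpoints
  dz <- (ol$bottom_z - ol$top_z) / n
  x <- s * z
  sgn <- if (ol$bank == "left") 1 else -1
  in_disk <- (x - ol$center[1])^2 + (z - ol$center[2])^2 < ol$radius^2
  in_tip <- in_disk & sgn * (x - ol$chord_x) > 0
  in_body <- x > ol$body_x[1] & x < ol$body_x[2]
  c(tip = sum(in_tip), body = sum(in_body)) * dz * sqrt(1 + s^2)
}

# sweep-free reference for the tangent ray: last sample with unit
# transmission on a fine grid near the analytic value
sweep_vr <- function(placement, machine, step) {
  cv <- sweep_curve(placement, machine, step = step)
  unity <- cv$xs[cv$ts == 1]
  if (placement$bank == "right") max(unity) else min(unity)
}
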