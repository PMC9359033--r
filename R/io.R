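#' Load a machine/leaf configuration
#'
#' Reads a YAML key-value file describing one machine and leaf and
#' returns validated model objects.  Recognized keys: `sad_cm`,
#' `scd_cm`, `height_cm`, `tip_radius_cm`, `body_length_cm` (optional,
#' default 15), `bank` (optional, default `"right"`), and exactly one of
#' `transmission`, `mu_per_cm`, `hvl_cm` for the attenuation.
#'
#' Three reference configurations ship with the package (see
#' [mlc_config()]): `"hdmlc"` (16.00 cm tip radius, 6.60 cm height,
#' 1.22% transmission), `"millennium"` (as hdmlc with an 8.0 cm
#' radius), and `"boyer"` (8.00 cm radius, 6.13 cm height, 0.950 cm
#' half-value layer) used for validating the sweep against the
#' closed-form solver.
#'
#' @param path Path to a YAML config file.
#' @return A list of class `run_config` with elements `machine`
#'   ([machine_geometry()]), `leaf` ([leaf_spec()]), `bank`, and the raw
#'   key-value list as `raw`.
#' @examples
#' cfg <- load_config(mlc_config("hdmlc"))
#' cfg$leaf
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  need <- c("sad_cm", "scd_cm", "height_cm", "tip_radius_cm")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("config ", path, " is missing required key(s): ",
         paste(miss, collapse = ", "))
  att <- intersect(c("transmission", "mu_per_cm", "hvl_cm"), names(raw))
  if (length(att) != 1L)
    stop("config must contain exactly one of 'transmission', ",
         "'mu_per_cm', 'hvl_cm'")
  mu <- switch(att,
    transmission = attenuation_coefficient(raw$transmission, raw$height_cm),
    mu_per_cm = raw$mu_per_cm,
    hvl_cm = mu_from_hvl(raw$hvl_cm))
  machine <- machine_geometry(raw$sad_cm, raw$scd_cm)
  leaf <- leaf_spec(raw$height_cm, raw$tip_radius_cm,
                    body_length_cm = raw$body_length_cm %||% 15,
                    mu_per_cm = mu)
  bank <- raw$bank %||% "right"
  if (!bank %in% c("left", "right"))
    stop("config key 'bank' must be \"left\" or \"right\"")
  structure(list(machine = machine, leaf = leaf, bank = bank, raw = raw),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a shipped reference configuration
#'
#' @param name One of `"hdmlc"`, `"millennium"`, `"boyer"`.
#' @return Path to the installed YAML file.
#' @examples
#' readLines(mlc_config("boyer"))
#' @export
mlc_config <- function(name = c("hdmlc", "millennium", "boyer")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "mlcray",
                      mustWork = TRUE)
  path
}

.fixed <- function(x) formatC(x, format = "f", digits = 6)

#' Write a transmission curve to CSV with a JSON metadata sidecar
#'
#' Positions and transmissions are written fixed-format to 1e-6 so that
#' re-running an identical configuration reproduces the file byte for
#' byte.  The sidecar `<out>.meta.json` records the machine, leaf, bank
#' and the sweep step actually used.
#'
#' @param curve A [sweep_curve()] result.
#' @param out Output CSV path.
#' @return `out`, invisibly.
#' @export
write_curve_csv <- function(curve, out) {
  stopifnot(inherits(curve, "transmission_curve"))
  df <- as.data.frame(curve)
  df$tip_position_cm <- .fixed(df$tip_position_cm)
  df$x_iso_cm <- .fixed(df$x_iso_cm)
  df$transmission <- .fixed(df$transmission)
  utils::write.csv(df, out, row.names = FALSE, quote = FALSE)
  .write_meta(curve$placement, curve$machine, curve$step, out)
  invisible(out)
}

#' Write an edge-metrics table to CSV with a JSON metadata sidecar
#'
#' @param metrics A data.frame from [edge_metrics()] or
#'   [scan_positions()].
#' @param placement_info List with at least `machine`, `leaf`, `bank`,
#'   `step` used to produce the table (recorded in the sidecar).
#' @param out Output CSV path.
#' @return `out`, invisibly.
#' @export
write_metrics_csv <- function(metrics, placement_info, out) {
  df <- metrics
  names(df) <- paste0(names(metrics), "_cm")
  for (nm in names(df)) df[[nm]] <- .fixed(df[[nm]])
  utils::write.csv(df, out, row.names = FALSE, quote = FALSE)
  with(placement_info,
       .write_meta(list(leaf = leaf, bank = bank), machine, step, out))
  invisible(out)
}

.write_meta <- function(placement, machine, step, out) {
  meta <- list(
    package = "mlcray",
    version = as.character(utils::packageVersion("mlcray")),
    sad_cm = machine$sad, scd_cm = machine$scd,
    height_cm = placement$leaf$height,
    tip_radius_cm = placement$leaf$radius,
    body_length_cm = placement$leaf$body_length,
    transmission = placement$leaf$t_perp,
    mu_per_cm = placement$leaf$mu,
    bank = placement$bank,
    step_cm = step)
  jsonlite::write_json(meta, paste0(out, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read back a metrics CSV written by [write_metrics_csv()]
#'
#' @param path CSV path.
#' @return data.frame with numeric columns, names without the `_cm`
#'   suffix.
#' @export
read_metrics_csv <- function(path) {
  df <- utils::read.csv(path)
  names(df) <- sub("_cm$", "", names(df))
  df
}
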