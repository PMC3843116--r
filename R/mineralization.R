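# qBEI calibration chain: calcium weight fraction (psi_ca) -> hydroxyapatite
# mass fraction (psi_mi) -> mineral volume fraction (phi_mi) of the fibril
# array.  The mineral phase is idealized as stoichiometric hydroxyapatite
# Ca10(PO4)6(OH)2; the mass-to-volume step uses the empirical density
# relation phi = B * psi / (psi - A * rho_HA).

# Standard atomic masses (g/mol); the Ca mass share of hydroxyapatite is
# computed at runtime from these rather than hard-coded at lower precision.
.atomic_masses <- c(Ca = 40.078, P = 30.974, O = 15.999, H = 1.008)

.ca_share_hydroxyapatite <- function() {
  am <- .atomic_masses
  m_PO4 <- am[["P"]] + 4 * am[["O"]]
  m_OH <- am[["O"]] + am[["H"]]
  m_HA <- 10 * am[["Ca"]] + 6 * m_PO4 + 2 * m_OH
  10 * am[["Ca"]] / m_HA
}

#' qBEI mineral calibration constants
#'
#' Constants of the calcium-to-mineral-volume-fraction calibration:
#' the empirical density relation `phi = B * psi / (psi - A * rho_HA)`
#' with `A = 0.59` ml/g and `B = -0.75`, the hydroxyapatite density
#' `rho_HA = 3.16` g/cm^3, and the stoichiometric calcium mass share of
#' hydroxyapatite Ca10(PO4)6(OH)2 (~0.3989, computed from standard atomic
#' masses).
#'
#' @param A empirical constant, ml/g.
#' @param B empirical constant, dimensionless (negative on the
#'   physiological branch).
#' @param rho_HA hydroxyapatite density, g/cm^3.
#' @return Object of class `mineral_calibration`.
#' @examples
#' cal <- mineral_calibration()
#' ca_to_mineral_volume(0.25, cal)  # ~0.38
#' @export
mineral_calibration <- function(A = 0.59, B = -0.75, rho_HA = 3.16) {
  if (rho_HA <= 0) stop("rho_HA must be positive", call. = FALSE)
  ca_share <- .ca_share_hydroxyapatite()
  stopifnot(ca_share > 0, ca_share < 1)
  structure(list(A = A, B = B, rho_HA = rho_HA,
                 ca_mass_fraction_in_HA = ca_share),
            class = "mineral_calibration")
}

#' Calcium weight fraction to hydroxyapatite mass fraction
#'
#' Divides the calcium weight fraction by the stoichiometric calcium mass
#' share of hydroxyapatite.
#'
#' @param psi_ca calcium weight fraction(s), in `[0, ca_share]`.
#' @param cal a [mineral_calibration()].
#' @return Mineral (hydroxyapatite) mass fraction(s) in `[0, 1]`.
#' @export
ca_weight_to_mineral_mass_fraction <- function(psi_ca,
                                               cal = mineral_calibration()) {
  share <- cal$ca_mass_fraction_in_HA
  bad <- is.finite(psi_ca) & (psi_ca < 0 | psi_ca > share + 1e-12)
  if (any(bad))
    stop("infeasible composition: calcium weight fraction outside [0, ",
         format(share, digits = 6), "] (stoichiometric bound of pure ",
         "hydroxyapatite)", call. = FALSE)
  pmin(psi_ca / share, 1)
}

#' Hydroxyapatite mass fraction to mineral volume fraction
#'
#' Empirical density relation `phi = B * psi / (psi - A * rho_HA)`. The
#' relation has a pole at `psi = A * rho_HA` (~1.86 with defaults), well
#' above any mass fraction, but the domain is guarded defensively.
#'
#' @param psi_mi mineral mass fraction(s) in `[0, 1]`.
#' @param cal a [mineral_calibration()].
#' @return Mineral volume fraction(s) in `[0, 1]`.
#' @export
mineral_mass_to_volume_fraction <- function(psi_mi,
                                            cal = mineral_calibration()) {
  pole <- cal$A * cal$rho_HA
  bad <- is.finite(psi_mi) & (psi_mi < 0 | psi_mi >= pole - 1e-9)
  if (any(bad))
    stop("calibration-domain error: mineral mass fraction outside ",
         "[0, A*rho_HA)", call. = FALSE)
  phi <- cal$B * psi_mi / (psi_mi - pole)
  out <- is.finite(phi) & (phi < 0 | phi > 1)
  if (any(out))
    stop("calibration-domain error: resulting volume fraction outside [0, 1]",
         call. = FALSE)
  phi
}

#' @describeIn ca_weight_to_mineral_mass_fraction Full chain from calcium
#'   weight fraction to mineral volume fraction.
#' @export
ca_to_mineral_volume <- function(psi_ca, cal = mineral_calibration()) {
  mineral_mass_to_volume_fraction(
    ca_weight_to_mineral_mass_fraction(psi_ca, cal), cal)
}

#' Invert the density relation (volume to mass fraction)
#'
#' Closed-form inverse of [mineral_mass_to_volume_fraction()], used for
#' round-trip validation and to synthesize calcium maps from target volume
#' fractions.
#'
#' @param phi mineral volume fraction(s) in `[0, 1]`.
#' @param cal a [mineral_calibration()].
#' @return Mineral mass fraction(s).
#' @export
mineral_volume_to_mass_fraction <- function(phi, cal = mineral_calibration()) {
  # phi = B psi / (psi - A rho) => psi = phi A rho / (phi - B)
  phi * cal$A * cal$rho_HA / (phi - cal$B)
}

#' @describeIn mineral_volume_to_mass_fraction Volume fraction back to
#'   calcium weight fraction.
#' @export
mineral_volume_to_ca_weight <- function(phi, cal = mineral_calibration()) {
  mineral_volume_to_mass_fraction(phi, cal) * cal$ca_mass_fraction_in_HA
}

#' Georeferenced 2D scalar raster
#'
#' Raster container for calibrated maps (mineral volume fraction, fibril
#' angle, calcium weight fraction). Pixel centers lie at physical
#' coordinates `origin + (index - 0.5) * pixel_size` in micrometers, with
#' `values[i, j]` at x-index `i` and y-index `j`. Masked-out pixels
#' (`mask = FALSE`) represent thresholded meso/micro-porosity or background
#' and are excluded from every average; porosity is never encoded as a
#' field value of 0.
#'
#' @param values numeric matrix (dimensionless fraction or degrees).
#' @param pixel_size pixel edge length, micrometers (default 0.5).
#' @param origin physical coordinates (µm) of the corner of pixel (1,1);
#'   pixel centers are offset half a pixel inward.
#' @param mask logical matrix of per-pixel validity; default all `TRUE`.
#' @param quantity,units optional metadata strings.
#' @return Object of class `scalar_field`.
#' @export
scalar_field <- function(values, pixel_size = 0.5, origin = c(0, 0),
                         mask = NULL, quantity = "", units = "") {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(values)))
    stop("mask and values dimensions differ", call. = FALSE)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive", call. = FALSE)
  if (any(!is.finite(values[mask])))
    stop("non-finite values on masked-in pixels", call. = FALSE)
  structure(list(values = values, pixel_size = pixel_size,
                 origin = as.numeric(origin), mask = mask,
                 quantity = quantity, units = units),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Scalar field %s%s: %d x %d px at %.3g um/px (%.1f x %.1f um), %d masked out\n",
              x$quantity, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              d[1], d[2], x$pixel_size, d[1] * x$pixel_size,
              d[2] * x$pixel_size, sum(!x$mask)))
  invisible(x)
}

# physical coordinates of pixel centers along each axis
field_axis <- function(field, axis = 1) {
  n <- dim(field$values)[axis]
  field$origin[axis] + (seq_len(n) - 0.5) * field$pixel_size
}

#' Calibrate a calcium-weight-fraction raster to mineral volume fraction
#'
#' Applies the full calibration chain per pixel; the mask is propagated
#' unchanged. Pixels violating the calibration domain are reported with
#' their coordinates.
#'
#' @param ca_map `scalar_field` of calcium weight fraction.
#' @param cal a [mineral_calibration()].
#' @return `scalar_field` of mineral volume fraction.
#' @export
calibrate_field <- function(ca_map, cal = mineral_calibration()) {
  stopifnot(inherits(ca_map, "scalar_field"))
  v <- ca_map$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  idx <- which(ca_map$mask)
  res <- tryCatch(ca_to_mineral_volume(v[idx], cal), error = function(e) e)
  if (inherits(res, "error")) {
    # identify offending pixels for the error message
    ok <- vapply(v[idx], function(x)
      !inherits(tryCatch(ca_to_mineral_volume(x, cal),
                         error = function(e) e), "error"), logical(1))
    bad <- arrayInd(idx[!ok], dim(v))
    stop("calibration failed at ", sum(!ok), " pixel(s), first at (row,col) = (",
         bad[1, 1], ",", bad[1, 2], "): ", conditionMessage(res),
         call. = FALSE)
  }
  out[idx] <- res
  scalar_field(out, ca_map$pixel_size, ca_map$origin, ca_map$mask,
               quantity = "mineral volume fraction", units = "1")
}

#' Raster I/O: float TIFF with YAML sidecar, and masked CSV tables
#'
#' `write_field_tiff` stores the raster as a single-channel 32-bit float
#' TIFF plus a YAML sidecar (`<path>.yaml`) holding pixel size, origin,
#' quantity, units and the mask (masked-out pixels are written as NaN).
#' `read_field_tiff` reverses it. `write_field_csv` exports the masked-in
#' pixel table (x_um, y_um, value).
#'
#' @param field a `scalar_field`.
#' @param path output path.
#' @return The path, invisibly (`read_field_tiff`: a `scalar_field`).
#' @export
write_field_tiff <- function(field, path) {
  v <- field$values
  v[!field$mask] <- 0
  # TIFF samples are defined on [0, 1]; quantities such as angles in
  # degrees are rescaled on write and restored from the sidecar on read
  scale <- max(abs(v), 1)
  # tiff stores matrices row-major with rows = image rows; transpose so that
  # x runs along image width
  tiff::writeTIFF(t(v) / scale, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(pixel_size_um = field$pixel_size,
               origin_um = as.list(field$origin),
               quantity = field$quantity, units = field$units,
               value_scale = scale,
               masked_out_idx = as.integer(which(!field$mask)))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  v <- t(img)
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  v <- v * (meta$value_scale %||% 1)
  mask <- is.finite(v)
  mask[unlist(meta$masked_out_idx)] <- FALSE
  scalar_field(v, pixel_size = meta$pixel_size_um %||% 0.5,
               origin = unlist(meta$origin_um %||% c(0, 0)),
               mask = mask,
               quantity = meta$quantity %||% "", units = meta$units %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_field_tiff
#' @export
write_field_csv <- function(field, path) {
  idx <- which(field$mask, arr.ind = TRUE)
  df <- data.frame(
    x_um = field$origin[1] + (idx[, 1] - 0.5) * field$pixel_size,
    y_um = field$origin[2] + (idx[, 2] - 0.5) * field$pixel_size,
    value = field$values[field$mask])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
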