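# Site matching: rigid registration between imaging modalities and
# disk-averaged covariate extraction per indent.  Indent positions live in
# the light-microscope frame; a rigid transform maps that frame onto each
# raster's frame.  Covariates are averaged over the indenter interaction
# zone, a disk of radius 1.75 um (seven times the 500 nm indentation depth
# across its diameter).

#' In-plane rigid transform
#'
#' Translation (µm) plus rotation (degrees) about the physical origin of
#' the fixed frame: a point `p` maps to `R(alpha) p + (dx, dy)`.
#'
#' @param dx,dy translation in micrometers.
#' @param alpha in-plane rotation in degrees.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, alpha = 0) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(alpha))
  structure(list(dx = dx, dy = dy, alpha = alpha), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: dx = %.3f um, dy = %.3f um, alpha = %.3f deg\n",
              x$dx, x$dy, x$alpha))
  invisible(x)
}

transform_points <- function(tr, x, y) {
  a <- tr$alpha * pi / 180
  list(x = cos(a) * x - sin(a) * y + tr$dx,
       y = sin(a) * x + cos(a) * y + tr$dy)
}

invert_transform <- function(tr) {
  a <- tr$alpha * pi / 180
  # inverse of p -> R p + t is p -> R^T (p - t)
  rigid_transform(dx = -(cos(a) * tr$dx + sin(a) * tr$dy),
                  dy = -(-sin(a) * tr$dx + cos(a) * tr$dy),
                  alpha = -tr$alpha)
}

compose_transforms <- function(tr2, tr1) {
  # composition tr2 o tr1 (apply tr1 first)
  a2 <- tr2$alpha * pi / 180
  rigid_transform(dx = cos(a2) * tr1$dx - sin(a2) * tr1$dy + tr2$dx,
                  dy = sin(a2) * tr1$dx + cos(a2) * tr1$dy + tr2$dy,
                  alpha = tr1$alpha + tr2$alpha)
}

# Bilinear sample of a field at physical coordinates; NA outside or where
# any contributing pixel is masked out.
sample_field <- function(field, x, y) {
  px <- (x - field$origin[1]) / field$pixel_size + 0.5
  py <- (y - field$origin[2]) / field$pixel_size + 0.5
  nx <- nrow(field$values); ny <- ncol(field$values)
  i0 <- floor(px); j0 <- floor(py)
  fx <- px - i0; fy <- py - j0
  v <- field$values
  v[!field$mask] <- NA_real_
  get <- function(i, j) {
    out <- rep(NA_real_, length(i))
    ok <- i >= 1 & i <= nx & j >= 1 & j <= ny
    out[ok] <- v[cbind(i[ok], j[ok])]
    out
  }
  g00 <- get(i0, j0); g10 <- get(i0 + 1, j0)
  g01 <- get(i0, j0 + 1); g11 <- get(i0 + 1, j0 + 1)
  g00 * (1 - fx) * (1 - fy) + g10 * fx * (1 - fy) +
    g01 * (1 - fx) * fy + g11 * fx * fy
}

#' Resample a field under a rigid transform
#'
#' Returns the moving field expressed on the grid of `reference` after
#' mapping reference coordinates through `transform` (bilinear
#' interpolation; pixels falling outside or on masked-out source pixels are
#' masked out).
#'
#' @param moving `scalar_field` to resample.
#' @param transform a [rigid_transform()] mapping reference coordinates into
#'   the moving field's frame.
#' @param reference `scalar_field` whose grid defines the output (defaults
#'   to `moving`).
#' @return Resampled `scalar_field` on the reference grid.
#' @export
resample_field <- function(moving, transform, reference = moving) {
  xs <- field_axis(reference, 1)
  ys <- field_axis(reference, 2)
  g <- expand.grid(x = xs, y = ys)
  p <- transform_points(transform, g$x, g$y)
  v <- sample_field(moving, p$x, p$y)
  vm <- matrix(v, length(xs), length(ys))
  scalar_field(ifelse(is.na(vm), 0, vm), reference$pixel_size,
               reference$origin, mask = !is.na(vm),
               quantity = moving$quantity, units = moving$units)
}

#' Rigid registration of two rasters
#'
#' Finds the small rigid transform that maps fixed-frame coordinates onto
#' the moving field's frame so that the resampled moving field best matches
#' the fixed field: minimizes the normalized sum of squared differences over
#' the masked overlap, each modality z-scored over the overlap first (the
#' two images carry different physical quantities). Deterministic two-stage
#' optimizer: exhaustive coarse grid over the search window followed by
#' Nelder-Mead refinement.
#'
#' @param fixed,moving `scalar_field`s with overlapping physical extent.
#' @param initial starting [rigid_transform()] (e.g. from visual
#'   pre-registration).
#' @param window search half-widths around `initial`:
#'   `c(dx = , dy = , alpha = )` in µm, µm, degrees.
#' @param grid_step coarse grid step as a fraction of the window.
#' @return The optimal `rigid_transform`, with attributes `residual`
#'   (normalized SSD) and `n_overlap` (pixels in the final overlap).
#' @export
register_rigid <- function(fixed, moving, initial = rigid_transform(),
                           window = c(dx = 5, dy = 5, alpha = 2),
                           grid_step = 0.25) {
  stopifnot(inherits(fixed, "scalar_field"), inherits(moving, "scalar_field"))
  fv <- fixed$values; fv[!fixed$mask] <- NA_real_
  xs <- field_axis(fixed, 1); ys <- field_axis(fixed, 2)
  g <- expand.grid(x = xs, y = ys)

  objective <- function(par) {
    tr <- rigid_transform(par[1], par[2], par[3])
    p <- transform_points(tr, g$x, g$y)
    mv <- sample_field(moving, p$x, p$y)
    ok <- !is.na(mv) & !is.na(as.vector(fv))
    n <- sum(ok)
    if (n < 16) return(list(value = Inf, n = n))
    a <- as.vector(fv)[ok]; b <- mv[ok]
    sa <- sd(a); sb <- sd(b)
    if (sa == 0 || sb == 0) return(list(value = NA_real_, n = n))
    a <- (a - mean(a)) / sa; b <- (b - mean(b)) / sb
    list(value = mean((a - b)^2), n = n)
  }

  start <- c(initial$dx, initial$dy, initial$alpha)
  o0 <- objective(start)
  if (!is.finite(o0$value) && o0$n < 16)
    stop("registration-domain error: no overlap between fields under the ",
         "initial transform", call. = FALSE)
  if (is.na(o0$value))
    stop("uninformative-image error: zero-variance overlap", call. = FALSE)

  # coarse exhaustive grid
  grid1 <- function(i) {
    w <- window[i]
    if (w <= 0) return(start[i])
    start[i] + seq(-w, w, by = max(w * grid_step * 2, 1e-6))
  }
  cand <- as.matrix(expand.grid(grid1(1), grid1(2), grid1(3)))
  vals <- apply(cand, 1, function(p) objective(p)$value)
  best <- cand[which.min(vals), ]

  # local refinement within the window, over the free coordinates only
  # (zero-width window components stay fixed); out-of-window proposals are
  # projected back onto the window
  lo <- start - window; hi <- start + window
  free <- which(window > 0)
  par_full <- best
  if (length(free) > 0) {
    fit <- optim(best[free], function(pf) {
      p <- par_full
      p[free] <- pmin(pmax(pf, lo[free]), hi[free])
      v <- objective(p)$value
      if (!is.finite(v)) 1e10 else v
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-12, maxit = 1000))
    par_full[free] <- pmin(pmax(fit$par, lo[free]), hi[free])
  }

  res <- objective(par_full)
  out <- rigid_transform(par_full[1], par_full[2], par_full[3])
  attr(out, "residual") <- res$value
  attr(out, "n_overlap") <- res$n
  out
}

#' Indenter interaction zone
#'
#' Disk over which covariates are averaged per indent. The default radius
#' is 1.75 µm: the interaction diameter is seven times the 500 nm
#' indentation depth.
#'
#' @param r_in radius in micrometers.
#' @return Object of class `interaction_zone` with `r_in` and area `A_in`.
#' @export
interaction_zone <- function(r_in = 1.75) {
  if (!is.finite(r_in) || r_in <= 0)
    stop("interaction-zone radius must be positive", call. = FALSE)
  structure(list(r_in = r_in, A_in = pi * r_in^2), class = "interaction_zone")
}

#' Disk-averaged field value at an indent location
#'
#' Mean of the field over masked-in pixels whose centers lie within the
#' interaction-zone radius of `(x, y)` (center-in-disk rule, no
#' partial-pixel weighting).
#'
#' @param field a `scalar_field`.
#' @param x,y indent position, micrometers, in the field's frame.
#' @param zone an [interaction_zone()].
#' @return Disk-averaged value; errors if the disk contains no valid pixel.
#' @export
disk_average <- function(field, x, y, zone = interaction_zone()) {
  xs <- field_axis(field, 1); ys <- field_axis(field, 2)
  ix <- which(abs(xs - x) <= zone$r_in)
  iy <- which(abs(ys - y) <= zone$r_in)
  if (!length(ix) || !length(iy))
    stop("no-data error: interaction zone lies outside the field",
         call. = FALSE)
  dx2 <- (xs[ix] - x)^2
  dy2 <- (ys[iy] - y)^2
  within <- outer(dx2, dy2, "+") <= zone$r_in^2
  sub_mask <- field$mask[ix, iy, drop = FALSE] & within
  if (!any(sub_mask))
    stop("no-data error: interaction zone fully masked or outside the field",
         call. = FALSE)
  mean(field$values[ix, iy, drop = FALSE][sub_mask])
}

#' Construct an indent-site table
#'
#' Standard indent table: one row per indent with identifier, position in
#' the light-microscope frame, measured modulus, region label and quality
#' flag. Downstream columns (`phi_avg`, `theta_avg`, `E_pred`, `E_pred0`)
#' are appended by [extract_covariates()] and [predict_sites()].
#'
#' @param id identifiers.
#' @param x_um,y_um positions in micrometers.
#' @param E_meas_GPa measured indentation moduli (GPa) or `NA`.
#' @param region region labels among `"ost"`, `"int"`, `"mix"`.
#' @param quality quality flags among `"ok"`, `"surface_anomaly"`,
#'   `"curve_irregular"`, `"near_pore"`.
#' @return `data.frame` of class `indent_sites`.
#' @export
indent_sites <- function(id, x_um, y_um, E_meas_GPa = NA_real_,
                         region = "ost", quality = "ok") {
  region <- match.arg(region, c("ost", "int", "mix"), several.ok = TRUE)
  ok_flags <- c("ok", "surface_anomaly", "curve_irregular", "near_pore")
  if (!all(quality %in% ok_flags))
    stop("unknown quality flag(s): ",
         paste(setdiff(unique(quality), ok_flags), collapse = ", "),
         call. = FALSE)
  df <- data.frame(id = id, x_um = x_um, y_um = y_um,
                   E_meas_GPa = E_meas_GPa, region = region,
                   quality = quality, stringsAsFactors = FALSE)
  class(df) <- c("indent_sites", "data.frame")
  df
}

#' Filter indents by quality flag
#'
#' Retains sites with `quality == "ok"`, preserving order, and tallies the
#' rejections per reason.
#'
#' @param sites an indent table (see [indent_sites()]).
#' @return List with `retained` (the filtered table) and `log` (named
#'   rejection counts).
#' @export
filter_indents <- function(sites) {
  keep <- sites$quality == "ok"
  rejected <- sites$quality[!keep]
  log <- table(factor(rejected,
                      levels = c("surface_anomaly", "curve_irregular",
                                 "near_pore")))
  list(retained = sites[keep, , drop = FALSE],
       log = as.list(log))
}

#' Extract disk-averaged covariates for every indent
#'
#' For each site, maps the light-microscope position into each raster's
#' frame through the corresponding registered transform and disk-averages
#' the field over the interaction zone. Sites whose zone holds no valid
#' pixel are flagged `near_pore` rather than dropped.
#'
#' @param sites an indent table.
#' @param phi_field,theta_field `scalar_field`s of mineral volume fraction
#'   and fibril angle (degrees).
#' @param transforms list with elements `phi` and `theta`, each a
#'   [rigid_transform()] mapping indent coordinates into the respective
#'   field frame (identity by default).
#' @param zone an [interaction_zone()].
#' @return The table with `phi_avg` and `theta_avg` columns filled.
#' @export
extract_covariates <- function(sites, phi_field, theta_field,
                               transforms = list(phi = rigid_transform(),
                                                 theta = rigid_transform()),
                               zone = interaction_zone()) {
  n <- nrow(sites)
  phi_avg <- theta_avg <- rep(NA_real_, n)
  p_phi <- transform_points(transforms$phi, sites$x_um, sites$y_um)
  p_th <- transform_points(transforms$theta, sites$x_um, sites$y_um)
  for (i in seq_len(n)) {
    phi_avg[i] <- tryCatch(
      disk_average(phi_field, p_phi$x[i], p_phi$y[i], zone),
      error = function(e) NA_real_)
    theta_avg[i] <- tryCatch(
      disk_average(theta_field, p_th$x[i], p_th$y[i], zone),
      error = function(e) NA_real_)
  }
  no_data <- is.na(phi_avg) | is.na(theta_avg)
  sites$phi_avg <- phi_avg
  sites$theta_avg <- theta_avg
  sites$quality[no_data & sites$quality == "ok"] <- "near_pore"
  sites
}

#' Read/write indent tables as CSV
#'
#' Plain CSV with a provenance comment header (written fields: inputs hash
#' is out of scope; the header records the package version and time).
#'
#' @param sites an indent table.
#' @param path file path.
#' @return `read_indents_csv` returns an `indent_sites` data frame.
#' @export
write_indents_csv <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lamellar indent table, package version %s",
                     as.character(utils::packageVersion("lamellar"))), con)
  write.csv(sites, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indents_csv
#' @export
read_indents_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  class(df) <- c("indent_sites", "data.frame")
  df
}
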