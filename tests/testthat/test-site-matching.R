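test_that("rigid transforms compose and invert consistently", {
  tr <- rigid_transform(3, -2, 10)
  ti <- lamellar:::invert_transform(tr)
  comp <- lamellar:::compose_transforms(ti, tr)
  expect_equal(c(comp$dx, comp$dy, comp$alpha), c(0, 0, 0),
               tolerance = 1e-12)
  p <- lamellar:::transform_points(tr, 5, 7)
  back <- lamellar:::transform_points(ti, p$x, p$y)
  expect_equal(c(back$x, back$y), c(5, 7), tolerance = 1e-12)
})

test_that("disk average reproduces uniform, ramp and masked-enumeration oracles", {
  zone <- interaction_zone()
  expect_equal(zone$A_in, pi * 1.75^2)

  u <- scalar_field(matrix(0.38, 40, 40), 0.5)
  expect_equal(disk_average(u, 10, 10, zone), 0.38)

  # linear ramp: disk average equals the center value by symmetry
  xs <- (1:80 - 0.5) * 0.5
  ramp <- scalar_field(outer(xs, rep(1, 80)), 0.5)
  expect_equal(disk_average(ramp, 20, 20, zone), 20, tolerance = 0.05)

  # half-masked two-valued disk: mean over the unmasked half only,
  # verified by explicit enumeration of contributing pixels
  v <- matrix(1, 40, 40); v[, 21:40] <- 3
  mask <- matrix(TRUE, 40, 40); mask[, 21:40] <- FALSE
  f <- scalar_field(v, 0.5, mask = mask)
  got <- disk_average(f, 10, 10, zone)
  ys <- (1:40 - 0.5) * 0.5
  inside <- outer((xs[1:40] - 10)^2, (ys - 10)^2, "+") <= zone$r_in^2
  expect_equal(got, mean(v[inside & mask]))
  expect_equal(got, 1)

  expect_error(disk_average(f, 200, 200, zone), "no-data")
  expect_error(disk_average(scalar_field(v, 0.5,
                                         mask = matrix(FALSE, 40, 40)),
                            10, 10, zone), "no-data")
})

test_that("disk average converges to the exact integral on a bilinear field as pixels shrink", {
  # bilinear test field g(x, y) = 2 + 0.3 x + 0.1 y + 0.02 x y; its exact
  # disk mean about (x0, y0) is g(x0, y0): the linear terms average out by
  # symmetry and so does the bilinear cross term. Errors are averaged over
  # many disk centers because the center-in-disk rule has a fluctuating
  # boundary term at any fixed center.
  g <- function(x, y) 2 + 0.3 * x + 0.1 * y + 0.02 * x * y
  set.seed(1)
  cx <- runif(25, 6, 14); cy <- runif(25, 6, 14)
  errs <- sapply(c(0.5, 0.25, 0.125), function(px) {
    n <- round(20 / px)
    xs <- (1:n - 0.5) * px
    f <- scalar_field(outer(xs, xs, g), px)
    mean(mapply(function(a, b) abs(disk_average(f, a, b) - g(a, b)),
                cx, cy))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 4)
})

test_that("registration recovers identity, a known shift, and a noisy shift", {
  f <- smooth_field(96, 96, seed = 5)

  same <- register_rigid(f, f, window = c(dx = 2, dy = 2, alpha = 0))
  expect_lt(abs(same$dx), 0.05)
  expect_lt(abs(same$dy), 0.05)
  expect_lt(attr(same, "residual"), 1e-6)

  # ground truth: moving is f displaced by (3, -2); mapping fixed -> moving
  # frame is the inverse displacement
  tr <- rigid_transform(3, -2, 0)
  moved <- apply_misregistration(f, tr)
  rec <- register_rigid(f, moved, window = c(dx = 5, dy = 5, alpha = 0))
  expect_lt(abs(rec$dx - (-3)), 0.25)
  expect_lt(abs(rec$dy - 2), 0.25)

  set.seed(9)
  noisy_vals <- moved$values + 0.05 * sd(moved$values) *
    matrix(rnorm(length(moved$values)), nrow(moved$values))
  noisy <- scalar_field(noisy_vals, moved$pixel_size, moved$origin,
                        moved$mask)
  rec2 <- register_rigid(f, noisy, window = c(dx = 5, dy = 5, alpha = 0))
  expect_lt(abs(rec2$dx - (-3)), 0.5)
  expect_lt(abs(rec2$dy - 2), 0.5)
})

test_that("registration recovers a small rotation and is inverse-consistent", {
  f <- smooth_field(96, 96, seed = 6)
  tr <- rigid_transform(1.5, -1, 1)
  moved <- apply_misregistration(f, tr)
  ab <- register_rigid(f, moved, window = c(dx = 3, dy = 3, alpha = 2))
  truth <- lamellar:::invert_transform(tr)
  expect_lt(abs(ab$alpha - truth$alpha), 0.2)
  expect_lt(abs(ab$dx - truth$dx), 0.25)
  expect_lt(abs(ab$dy - truth$dy), 0.25)
  ba <- register_rigid(moved, f, window = c(dx = 3, dy = 3, alpha = 2))
  comp <- lamellar:::compose_transforms(ba, ab)
  expect_lt(abs(comp$dx), 0.25)
  expect_lt(abs(comp$dy), 0.25)
  expect_lt(abs(comp$alpha), 0.2)
})

test_that("registration errors on empty or flat overlap", {
  f <- smooth_field(48, 48, seed = 7)
  far <- scalar_field(f$values, f$pixel_size, origin = c(1000, 1000))
  expect_error(register_rigid(f, far, window = c(dx = 2, dy = 2, alpha = 0)),
               "overlap")
  flat <- scalar_field(matrix(1, 48, 48), 0.5)
  expect_error(register_rigid(flat, flat,
                              window = c(dx = 2, dy = 2, alpha = 0)),
               "uninformative")
})

test_that("indent filtering retains ok sites, preserves order and logs reasons", {
  s <- indent_sites(id = 1:6, x_um = 1:6, y_um = 1:6,
                    quality = c("ok", "surface_anomaly", "ok",
                                "curve_irregular", "near_pore", "ok"))
  out <- filter_indents(s)
  expect_equal(out$retained$id, c(1, 3, 6))
  expect_equal(out$log$surface_anomaly, 1)
  expect_equal(out$log$curve_irregular, 1)
  expect_equal(out$log$near_pore, 1)

  all_ok <- indent_sites(1:3, 1:3, 1:3)
  expect_equal(nrow(filter_indents(all_ok)$retained), 3)
  none <- indent_sites(1:3, 1:3, 1:3, quality = rep("near_pore", 3))
  expect_equal(nrow(filter_indents(none)$retained), 0)
  expect_error(indent_sites(1, 1, 1, quality = "meh"), "quality")
})

test_that("covariate extraction fills uniform values and round-trips a misregistration", {
  phi_f <- scalar_field(matrix(0.38, 120, 120), 0.5)
  th_f <- scalar_field(matrix(32.3, 120, 120), 0.5)
  s <- indent_sites(1:5, seq(10, 50, by = 10), seq(10, 50, by = 10))
  out <- extract_covariates(s, phi_f, th_f)
  expect_equal(out$phi_avg, rep(0.38, 5))
  expect_equal(out$theta_avg, rep(32.3, 5))

  # known misregistration corrected by registration: covariates match the
  # identity case to half-pixel tolerance
  f <- smooth_field(120, 120, seed = 8)
  phi_s <- scalar_field(0.38 + 0.02 * f$values, 0.5)
  tr <- rigid_transform(2, -1.5, 0)
  disp <- apply_misregistration(phi_s, tr)
  rec <- register_rigid(phi_s, disp, window = c(dx = 4, dy = 4, alpha = 0))
  ident <- extract_covariates(s, phi_s, th_f)
  corrected <- extract_covariates(s, disp, th_f,
                                  transforms = list(phi = rec,
                                                    theta = rigid_transform()))
  expect_lt(max(abs(corrected$phi_avg - ident$phi_avg)), 0.02 * 0.5)

  # a site over a fully masked pore is flagged, not dropped
  mask <- matrix(TRUE, 120, 120)
  mask[15:25, 15:25] <- FALSE
  pore_f <- scalar_field(matrix(0.38, 120, 120), 0.5, mask = mask)
  s2 <- extract_covariates(indent_sites(1, 10, 10), pore_f, th_f)
  expect_equal(s2$quality, "near_pore")
  expect_true(is.na(s2$phi_avg))
})

test_that("indent tables round-trip through CSV", {
  s <- indent_sites(1:3, c(1.5, 2.5, 3.5), c(4, 5, 6),
                    E_meas_GPa = c(20, 22, 24),
                    region = c("ost", "int", "mix"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_indents_csv(s, p)
  s2 <- read_indents_csv(p)
  expect_equal(s2$x_um, s$x_um)
  expect_equal(s2$region, s$region)
})
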