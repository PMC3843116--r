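test_that("Eshelby sphere matches the textbook closed form to 1e-10", {
  for (nu in c(0.1, 0.28, 0.3, 0.45)) {
    S <- eshelby_spheroid(nu, 1)
    expect_equal(S[1, 1], (7 - 5 * nu) / (15 * (1 - nu)), tolerance = 1e-10)
    expect_equal(S[1, 2], (5 * nu - 1) / (15 * (1 - nu)), tolerance = 1e-10)
    expect_equal(S[4, 4] / 2, (4 - 5 * nu) / (15 * (1 - nu)),
                 tolerance = 1e-10)
    expect_equal(S[1, 1], S[3, 3], tolerance = 1e-10)
  }
})

test_that("Eshelby prolate tensor approaches the infinite-cylinder closed form", {
  nu <- 0.3
  S <- eshelby_spheroid(nu, 1e6)
  d <- 8 * (1 - nu)
  expect_equal(S[1, 1], (5 - 4 * nu) / d, tolerance = 1e-4)
  expect_equal(S[1, 2], (4 * nu - 1) / d, tolerance = 1e-4)
  expect_equal(S[1, 3], nu / (2 * (1 - nu)), tolerance = 1e-4)
  expect_equal(S[3, 3], 0, tolerance = 1e-4)
  expect_equal(S[3, 1], 0, tolerance = 1e-4)
  expect_equal(S[6, 6] / 2, (3 - 4 * nu) / d, tolerance = 1e-4)
  expect_equal(S[4, 4] / 2, 1 / 4, tolerance = 1e-4)
})

test_that("Eshelby tensor rejects oblate shapes and is transversely isotropic", {
  expect_error(eshelby_spheroid(0.3, 0.5), "aspect")
  S <- eshelby_spheroid(0.3, 14)
  expect_equal(S[1, 1], S[2, 2], tolerance = 1e-12)
  expect_equal(S[1, 3], S[2, 3], tolerance = 1e-12)
  expect_equal(S[4, 4], S[5, 5], tolerance = 1e-12)
  # Mandel TI relation for the in-plane shear block
  expect_equal(S[6, 6], S[1, 1] - S[1, 2], tolerance = 1e-10)
})

test_that("numerical Hill polarization agrees with the closed-form route", {
  for (ar in c(1, 3, 14)) {
    Cm <- isotropic_stiffness(110.5, 0.28)
    # the polar integrand sharpens with aspect ratio; scale the rule with it
    P_num <- hill_polarization(Cm, ar, n_polar = 128, n_azimuth = 64)
    P_cf <- eshelby_spheroid(0.28, ar) %*% solve(Cm$M)
    expect_lt(max(abs(P_num - P_cf)), 5e-5 * max(abs(P_cf)))
  }
})

test_that("Mori-Tanaka limits: zero fraction, identical phases, spherical voids", {
  Cm <- isotropic_stiffness(110.5, 0.28)
  Ci <- isotropic_stiffness(5, 0.3)
  expect_equal(mori_tanaka(Cm, Ci, 0, 1)$M, Cm$M)
  same <- mori_tanaka(Cm, Cm, 0.4, 14)
  expect_lt(max(abs(same$M - Cm$M)), 1e-10 * max(abs(Cm$M)))

  # spherical voids at f = 0.3: MT equals the Hashin-Shtrikman upper bound
  # for the bulk modulus (independent closed form), and exceeds Reuss (= 0)
  f <- 0.3
  void <- stiffness_tensor(matrix(0, 6, 6), check = FALSE)
  Ceff <- mori_tanaka(Cm, void, f, 1)
  K_eff <- sum(Ceff$M[1:3, 1:3]) / 9
  ec <- isotropic_constants(Cm)
  K_m <- ec["E"] / (3 * (1 - 2 * ec["nu"]))
  G_m <- ec["E"] / (2 * (1 + ec["nu"]))
  K_hs <- unname(K_m + f * (0 - K_m) /
                   (1 + (1 - f) * (0 - K_m) / (K_m + 4 * G_m / 3)))
  expect_equal(K_eff, K_hs, tolerance = 1e-8)
  expect_gt(K_eff, 0)
  expect_true(is_positive_definite(Ceff))
})

test_that("closed-form route refuses an anisotropic matrix; isotropized/numeric agree on defaults", {
  Cti <- fibril_array_stiffness(table1_params(), phi = 0.38)
  Ci <- isotropic_stiffness(5, 0.3)
  expect_error(mori_tanaka(Cti, Ci, 0.3, 10, method = "closed_form"),
               "isotropic")
  a <- mori_tanaka(Cti, Ci, 0.3, 10, method = "isotropized")
  b <- mori_tanaka(Cti, Ci, 0.3, 10, method = "numeric",
                   n_polar = 96, n_azimuth = 96)
  # the two polarization routes are distinct approximations; on a mildly
  # anisotropic matrix they must agree closely
  expect_lt(max(abs(a$M - b$M)) / max(abs(a$M)), 0.05)
})

test_that("phase partition matches the arithmetic oracle and flags infeasibility", {
  p <- table1_params(phi_mineral = 0.38)
  part <- partition_phases(p)
  expect_equal(part$f_min_in_fibril, 0.25 * 0.38 / 0.53, tolerance = 1e-12)
  expect_equal(part$f_void_in_ef, 1 - 0.75 * 0.38 / 0.47, tolerance = 1e-12)
  expect_equal(round(part$f_min_in_fibril, 4), 0.1792)
  expect_equal(round(part$f_void_in_ef, 4), 0.3936)

  p0 <- partition_phases(table1_params(), phi = 0)
  expect_equal(p0$f_min_in_fibril, 0)
  expect_equal(p0$f_void_in_ef, 1)

  expect_error(partition_phases(
    table1_params(q_mineral = 0.75, f_fibril = 0.25, phi_mineral = 0.34)),
    "infeasible")
})

test_that("fibril-array stiffness is transversely isotropic with the stiff axis along the fibrils", {
  for (phi in c(0.30, 0.38, 0.45)) {
    C <- fibril_array_stiffness(table1_params(), phi = phi)
    expect_lt(check_transverse_isotropy(C), 1e-6)
    expect_true(is_positive_definite(C))
    V <- as.matrix(C, "voigt")
    # axial Young's modulus exceeds transverse
    S <- solve(V)
    expect_gt(1 / S[3, 3], 1 / S[1, 1])
  }
})

test_that("array stiffness is monotone in mineralization and bounded by the constituents", {
  phis <- seq(0.2, 0.45, by = 0.05)
  diags <- sapply(phis, function(phi)
    diag(fibril_array_stiffness(table1_params(), phi = phi)$M))
  expect_true(all(diff(t(diags)) > 0))
  # eigenvalues below the stiffest constituent (mineral), above zero
  Cmax <- max(eigen(isotropic_stiffness(110.5, 0.28)$M,
                    only.values = TRUE)$values)
  for (phi in c(0.2, 0.45)) {
    ev <- eigen(fibril_array_stiffness(table1_params(), phi = phi)$M,
                symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0 & ev < Cmax))
  }
})

test_that("extra-fibrillar foam stiffness vanishes with its mineral fraction", {
  # as phi -> 0 (with q < 1) the foam is almost all void and the model
  # reports a degenerate material rather than returning garbage
  expect_error(fibril_array_stiffness(table1_params(), phi = 1e-9),
               "degenerate")
  # approaching the limit from feasible phi, the foam softens monotonically
  foam_E <- sapply(c(0.3, 0.2, 0.1, 0.05), function(phi) {
    part <- partition_phases(table1_params(), phi = phi)
    Cef <- mori_tanaka(isotropic_stiffness(110.5, 0.28),
                       stiffness_tensor(matrix(0, 6, 6), check = FALSE),
                       part$f_void_in_ef, 1)
    isotropic_constants(Cef)[["E"]]
  })
  expect_true(all(diff(foam_E) < 0))
  expect_lt(foam_E[4] / foam_E[1], 0.2)
})

test_that("level collapse: q = 1, f_fibril = 1 reduces to one Mori-Tanaka step", {
  p <- table1_params(q_mineral = 1, f_fibril = 1, phi_mineral = 0.38)
  C <- fibril_array_stiffness(p)
  direct <- mori_tanaka(isotropic_stiffness(5, 0.3),
                        isotropic_stiffness(110.5, 0.28), 0.38, 14)
  expect_lt(max(abs(C$M - direct$M)), 1e-8 * max(abs(direct$M)))
})

test_that("model object predicts and prints", {
  m <- fibril_array_model(0.38)
  pr <- predict(m, theta = c(0, 32.3, 73.2))
  expect_length(pr, 3)
  expect_true(all(diff(pr) < 0))
  expect_output(print(m), "axial indentation modulus")
})
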