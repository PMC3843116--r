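# Three-level mean-field model of the mineralized collagen fibril array:
#   (a) mineralized fibril: prolate hydroxyapatite spheroids (aspect ratio 14)
#       aligned in an isotropic collagen matrix;
#   (b) extra-fibrillar matrix: mineral foam, spherical voids in mineral;
#   (c) fibril array: highly elongated fibril spheroids (aspect ratio 100)
#       embedded in the extra-fibrillar foam.
# Each level is a Mori-Tanaka estimate with aligned spheroidal inclusions,
# symmetry axis e3, so the result is transversely isotropic about the fibril
# axis.

#' Fibril-array model parameters
#'
#' The constituent and microstructural parameters of the three-level
#' fibril-array homogenization. Defaults are the values used for average
#' human lamellar bone: collagen E = 5 GPa, nu = 0.3; mineral E = 110.5 GPa,
#' nu = 0.28; mineral platelet aspect ratio 14 inside the fibril; spherical
#' voids (aspect ratio 1) in the extra-fibrillar matrix; fibril aspect ratio
#' 100 and fibril volume fraction 0.53 in the array; mineral quota 0.25 (the
#' share of total mineral volume residing inside the fibrils).
#'
#' @param E_collagen,nu_collagen collagen Young's modulus (GPa) and Poisson
#'   ratio.
#' @param E_mineral,nu_mineral mineral (hydroxyapatite) Young's modulus (GPa)
#'   and Poisson ratio.
#' @param ar_mineral aspect ratio of the mineral platelets in the fibril
#'   (>= 1, prolate).
#' @param ar_void aspect ratio of the voids in the extra-fibrillar matrix.
#' @param ar_fibril aspect ratio of the fibrils in the array.
#' @param f_fibril fibril volume fraction in the fibril array.
#' @param q_mineral mineral quota: fraction of the total mineral volume that
#'   lies within the fibrils.
#' @param phi_mineral total mineral volume fraction of the fibril array
#'   (the qBEI-derived covariate); may be `NA` in a template and supplied
#'   later.
#' @return Object of class `fibril_array_params` (a validated list).
#' @examples
#' p <- fibril_array_params(phi_mineral = 0.38)
#' partition_phases(p)
#' @export
fibril_array_params <- function(E_collagen = 5, nu_collagen = 0.3,
                                E_mineral = 110.5, nu_mineral = 0.28,
                                ar_mineral = 14, ar_void = 1,
                                ar_fibril = 100, f_fibril = 0.53,
                                q_mineral = 0.25, phi_mineral = NA_real_) {
  p <- list(E_collagen = E_collagen, nu_collagen = nu_collagen,
            E_mineral = E_mineral, nu_mineral = nu_mineral,
            ar_mineral = ar_mineral, ar_void = ar_void,
            ar_fibril = ar_fibril, f_fibril = f_fibril,
            q_mineral = q_mineral, phi_mineral = phi_mineral)
  for (nm in c("E_collagen", "E_mineral"))
    if (p[[nm]] <= 0) stop(nm, " must be positive", call. = FALSE)
  for (nm in c("nu_collagen", "nu_mineral"))
    if (p[[nm]] <= -1 || p[[nm]] >= 0.5)
      stop(nm, " must lie in (-1, 0.5)", call. = FALSE)
  for (nm in c("ar_mineral", "ar_void", "ar_fibril"))
    if (p[[nm]] < 1) stop(nm, " must be >= 1 (prolate or sphere)",
                          call. = FALSE)
  for (nm in c("f_fibril", "q_mineral"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(nm, " must lie in [0, 1]", call. = FALSE)
  if (!is.na(p$phi_mineral) && (p$phi_mineral < 0 || p$phi_mineral > 1))
    stop("phi_mineral must lie in [0, 1]", call. = FALSE)
  structure(p, class = "fibril_array_params")
}

#' @export
print.fibril_array_params <- function(x, ...) {
  cat("Fibril-array model parameters\n")
  for (nm in names(x)) cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Eshelby tensor of an aligned spheroid in an isotropic matrix
#'
#' Closed-form interior Eshelby tensor for a spheroidal inclusion (symmetry
#' axis e3) embedded in an isotropic matrix, returned as a 6x6 matrix in
#' Mandel notation. The tensor has the minor symmetries by construction but
#' not the major one.
#'
#' @param nu_matrix Poisson ratio of the matrix, in (-1, 0.5).
#' @param aspect_ratio spheroid aspect ratio a = axial length / equatorial
#'   diameter; `1` is a sphere, `> 1` prolate. Oblate shapes are not
#'   supported.
#' @return 6x6 Mandel matrix of the Eshelby tensor (dimensionless).
#' @examples
#' S <- eshelby_spheroid(0.3, 1)     # sphere
#' S[1, 1] * 15 * (1 - 0.3)          # equals 7 - 5 * 0.3
#' @export
eshelby_spheroid <- function(nu_matrix, aspect_ratio) {
  nu <- nu_matrix
  w <- aspect_ratio
  if (!is.finite(nu) || nu <= -1 || nu >= 0.5)
    stop("matrix Poisson ratio must lie in (-1, 0.5)", call. = FALSE)
  if (!is.finite(w) || w < 1)
    stop("aspect ratio must be >= 1 (oblate spheroids unsupported)",
         call. = FALSE)
  if (abs(w - 1) < 1e-9) {
    d <- 15 * (1 - nu)
    Siiii <- (7 - 5 * nu) / d
    Siijj <- (5 * nu - 1) / d
    Sijij <- (4 - 5 * nu) / d
    S <- matrix(0, 6, 6)
    S[1:3, 1:3] <- Siijj + (Siiii - Siijj) * diag(3)
    diag(S)[4:6] <- 2 * Sijij
    return(S)
  }
  # Prolate spheroid, semi-axes a1 = a2 = 1, a3 = w (Routh/Eshelby I-integrals)
  e <- sqrt(w^2 - 1)
  I1 <- 2 * pi * w * (w * e - acosh(w)) / e^3
  I3 <- 4 * pi - 2 * I1
  I13 <- (I1 - I3) / (w^2 - 1)
  I12 <- (4 * pi - I13) / 4          # 3*I11 + I12 + I13 = 4*pi, I11 = I12
  I11 <- I12
  I33 <- (4 * pi / w^2 - 2 * I13) / 3
  a1s <- 1; a3s <- w^2
  q <- 8 * pi * (1 - nu)
  k <- 1 - 2 * nu
  S1111 <- (3 * a1s * I11 + k * I1) / q
  S1122 <- (a1s * I12 - k * I1) / q
  S1133 <- (a3s * I13 - k * I1) / q
  S3333 <- (3 * a3s * I33 + k * I3) / q
  S3311 <- (a1s * I13 - k * I3) / q
  S1212 <- ((a1s + a1s) * I12 + k * (I1 + I1)) / (2 * q)
  S1313 <- ((a1s + a3s) * I13 + k * (I1 + I3)) / (2 * q)
  S <- matrix(0, 6, 6)
  S[1, 1] <- S[2, 2] <- S1111
  S[1, 2] <- S[2, 1] <- S1122
  S[1, 3] <- S[2, 3] <- S1133
  S[3, 1] <- S[3, 2] <- S3311
  S[3, 3] <- S3333
  S[4, 4] <- S[5, 5] <- 2 * S1313
  S[6, 6] <- 2 * S1212
  S
}

#' Hill polarization tensor by angular integration
#'
#' Numerical Hill (Walpole) polarization tensor of an aligned spheroid
#' (symmetry axis e3) in an arbitrary anisotropic matrix, computed by
#' quadrature of the inverse acoustic tensor over the unit sphere. For an
#' isotropic matrix it equals the closed-form Eshelby tensor composed with
#' the matrix compliance (`eshelby_spheroid(nu, a) %*% solve(Cm)`), which is
#' used as its validation oracle. This route supports level-(c)
#' homogenization with a genuinely anisotropic matrix.
#'
#' @param C_matrix matrix stiffness (`stiffness_tensor` or 6x6 Mandel).
#' @param aspect_ratio spheroid aspect ratio (>= 1).
#' @param n_polar,n_azimuth quadrature resolution (Gauss-Legendre x periodic
#'   trapezoid). The polar integrand sharpens near the equator as the
#'   aspect ratio grows; raise `n_polar` accordingly (128 covers aspect
#'   ratios up to ~20 at 1e-6 relative accuracy).
#' @return 6x6 Mandel matrix of the polarization tensor (1/GPa).
#' @export
hill_polarization <- function(C_matrix, aspect_ratio,
                              n_polar = 128, n_azimuth = 64) {
  Cm <- .as_stiffness(C_matrix)
  C4 <- mandel_to_array(Cm$M)
  a3 <- aspect_ratio
  gl <- .gauss_legendre(n_polar)
  phis <- seq(0, 2 * pi, length.out = n_azimuth + 1)[seq_len(n_azimuth)]
  P4 <- array(0, dim = c(3, 3, 3, 3))
  for (iu in seq_len(n_polar)) {
    u <- gl$nodes[iu]; su <- sqrt(1 - u^2)
    for (ip in seq_len(n_azimuth)) {
      n <- c(su * cos(phis[ip]), su * sin(phis[ip]), u)
      K <- matrix(0, 3, 3)
      for (i in 1:3) for (k in 1:3)
        K[i, k] <- sum(C4[i, , k, ] * outer(n, n))
      Ki <- solve(K)
      den <- (n[1]^2 + n[2]^2 + a3^2 * n[3]^2)^1.5
      wq <- gl$weights[iu] * (2 * pi / n_azimuth) * a3 / (4 * pi) / den
      Nt <- array(0, dim = c(3, 3, 3, 3))
      for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
        Nt[i, j, k, l] <- 0.25 * (Ki[i, k] * n[j] * n[l] +
                                  Ki[j, k] * n[i] * n[l] +
                                  Ki[i, l] * n[j] * n[k] +
                                  Ki[j, l] * n[i] * n[k])
      P4 <- P4 + wq * Nt
    }
  }
  array_to_mandel(P4)
}

# Gauss-Legendre nodes/weights on [-1, 1]; Newton iteration on Legendre
# polynomials (standard Golub-Welsch-free construction).
.gauss_legendre <- function(n) {
  i <- seq_len(n)
  x <- cos(pi * (i - 0.25) / (n + 0.5))
  for (it in 1:100) {
    p0 <- rep(1, n); p1 <- x
    for (k in 2:n) {
      p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
      p0 <- p1; p1 <- p2
    }
    dp <- n * (x * p1 - p0) / (x^2 - 1)
    dx <- p1 / dp
    x <- x - dx
    if (max(abs(dx)) < 1e-15) break
  }
  list(nodes = x, weights = 2 / ((1 - x^2) * (n * (x * p1 - p0) /
                                                (x^2 - 1))^2))
}

#' Mori-Tanaka effective stiffness for aligned spheroidal inclusions
#'
#' Two-phase Mori-Tanaka estimate
#' `C_eff = C_m + f (C_i - C_m) A [(1-f) I + f A]^-1` with the dilute
#' concentration tensor `A = [I + P (C_i - C_m)]^-1`, where `P` is the Hill
#' polarization tensor of the inclusion shape in the matrix.
#'
#' @param C_matrix,C_inclusion matrix and inclusion stiffness
#'   (`stiffness_tensor` or 6x6 Mandel matrix; pass a zero matrix for voids).
#' @param f inclusion volume fraction in `[0, 1]`.
#' @param aspect_ratio aligned-spheroid aspect ratio (symmetry axis e3).
#' @param method `"closed_form"` uses the analytic Eshelby tensor and
#'   requires an isotropic matrix; `"isotropized"` projects an anisotropic
#'   matrix onto its closest isotropic tensor before computing `P` (the
#'   stiffnesses entering the concentration relation are unchanged);
#'   `"numeric"` integrates `P` for the anisotropic matrix directly.
#' @param ... passed to [hill_polarization()] for `method = "numeric"`.
#' @return Effective `stiffness_tensor`.
#' @export
mori_tanaka <- function(C_matrix, C_inclusion, f, aspect_ratio,
                        method = c("closed_form", "isotropized", "numeric"),
                        ...) {
  method <- match.arg(method)
  Cm <- .as_stiffness(C_matrix)
  Ci <- .as_stiffness(C_inclusion)
  if (!is.finite(f) || f < 0 || f > 1)
    stop("inclusion volume fraction must lie in [0, 1]", call. = FALSE)
  if (f == 0) return(Cm)
  P <- switch(method,
    closed_form = {
      dev <- check_transverse_isotropy(Cm, axis = c(1, 0, 0), n_angles = 4)
      if (dev > 1e-8)
        stop("closed-form Eshelby tensor requires an isotropic matrix ",
             "(deviation ", format(dev), "); use method = 'isotropized' ",
             "or 'numeric'", call. = FALSE)
      nu <- isotropic_constants(Cm)["nu"]
      eshelby_spheroid(nu, aspect_ratio) %*% solve(Cm$M)
    },
    isotropized = {
      Ciso <- isotropize(Cm)
      nu <- isotropic_constants(Ciso)["nu"]
      eshelby_spheroid(nu, aspect_ratio) %*% solve(Ciso$M)
    },
    numeric = hill_polarization(Cm, aspect_ratio, ...))
  dC <- Ci$M - Cm$M
  A <- tryCatch(solve(diag(6) + P %*% dC),
                error = function(e)
                  stop("singular concentration system in Mori-Tanaka step (f=",
                       f, ", aspect=", aspect_ratio, "): ",
                       conditionMessage(e), call. = FALSE))
  Ceff <- Cm$M + f * dC %*% A %*% solve((1 - f) * diag(6) + f * A)
  Ceff <- (Ceff + t(Ceff)) / 2
  stiffness_tensor(Ceff, symmetry = "general", check = FALSE)
}

#' Phase partition of mineral between fibrils and extra-fibrillar matrix
#'
#' Splits the total mineral volume fraction `phi_mineral` of the fibril
#' array between the fibril interior (mineral quota `q_mineral`) and the
#' extra-fibrillar matrix, yielding the two level-specific volume fractions:
#' `f_min_in_fibril = q * phi / f_fibril` and
#' `f_void_in_ef = 1 - (1 - q) * phi / (1 - f_fibril)`.
#'
#' @param p a [fibril_array_params()] object with `phi_mineral` set (or
#'   supply `phi`).
#' @param phi optional override of `p$phi_mineral`.
#' @return List with `f_min_in_fibril` and `f_void_in_ef`, both in `[0, 1]`.
#' @export
partition_phases <- function(p, phi = NULL) {
  stopifnot(inherits(p, "fibril_array_params"))
  phi <- if (is.null(phi)) p$phi_mineral else phi
  if (is.na(phi) || phi < 0 || phi > 1)
    stop("phi_mineral must be set in [0, 1]", call. = FALSE)
  f_min <- if (phi == 0) 0 else p$q_mineral * phi / p$f_fibril
  # no extra-fibrillar volume: its void fraction is 0 by convention, but
  # only if no mineral is assigned to it
  f_void <- if (p$f_fibril == 1) {
    if ((1 - p$q_mineral) * phi > 0) NaN else 0
  } else {
    1 - (1 - p$q_mineral) * phi / (1 - p$f_fibril)
  }
  if (is.nan(f_min) || is.nan(f_void) ||
      f_min > 1 || f_min < 0 || f_void > 1 || f_void < 0)
    stop(sprintf(paste0("infeasible phase partition: f_min_in_fibril = %.4f, ",
                        "f_void_in_ef = %.4f (q = %.3f, f_fibril = %.3f, ",
                        "phi = %.3f)"),
                 f_min, f_void, p$q_mineral, p$f_fibril, phi), call. = FALSE)
  list(f_min_in_fibril = f_min, f_void_in_ef = f_void)
}

.is_partition_feasible <- function(p, phi = NULL) {
  phi <- if (is.null(phi)) p$phi_mineral else phi
  f_min <- p$q_mineral * phi / p$f_fibril
  f_void <- 1 - (1 - p$q_mineral) * phi / (1 - p$f_fibril)
  f_min >= 0 && f_min <= 1 && f_void >= 0 && f_void <= 1
}

#' Transversely isotropic stiffness of the mineralized fibril array
#'
#' Chains the three Mori-Tanaka homogenizations: (a) mineral platelets in
#' collagen (the mineralized fibril), (b) spherical voids in mineral (the
#' extra-fibrillar foam) and (c) fibrils in foam (the fibril array). The
#' foam produced by level (b) is isotropic (isotropic phases, spherical
#' inclusions), so the closed-form Eshelby tensor applies at every level;
#' `method` controls the level-(c) treatment should a non-spherical void
#' phase ever make the foam anisotropic.
#'
#' @param p a [fibril_array_params()] object.
#' @param phi optional mineral volume fraction overriding `p$phi_mineral`.
#' @param method level-(c) polarization route when the matrix is not
#'   isotropic: see [mori_tanaka()].
#' @return A transversely isotropic `stiffness_tensor` (fibril axis e3).
#' @examples
#' C <- fibril_array_stiffness(fibril_array_params(), phi = 0.38)
#' @export
fibril_array_stiffness <- function(p, phi = NULL,
                                   method = c("isotropized", "numeric")) {
  method <- match.arg(method)
  part <- partition_phases(p, phi)
  if (part$f_void_in_ef > 1 - 1e-6)
    stop("degenerate extra-fibrillar matrix: void fraction reaches 1 ",
         "(phi too small for q < 1)", call. = FALSE)
  C_col <- isotropic_stiffness(p$E_collagen, p$nu_collagen)
  C_min <- isotropic_stiffness(p$E_mineral, p$nu_mineral)
  C_void <- stiffness_tensor(matrix(0, 6, 6), check = FALSE)
  C_fib <- mori_tanaka(C_col, C_min, part$f_min_in_fibril, p$ar_mineral)
  C_ef <- mori_tanaka(C_min, C_void, part$f_void_in_ef, p$ar_void)
  iso_dev <- check_transverse_isotropy(C_ef, axis = c(1, 0, 0), n_angles = 4)
  step_c_method <- if (iso_dev <= 1e-8) "closed_form" else method
  C_arr <- mori_tanaka(C_ef, C_fib, p$f_fibril, p$ar_fibril,
                       method = step_c_method)
  stiffness_tensor(C_arr$M, symmetry = "transverse_isotropic", check = FALSE)
}

#' Fibril-array material model with virtual-indentation predictions
#'
#' Convenience model object bundling the parameter set, the homogenized
#' stiffness tensor and the virtual-indentation response. `predict()` on the
#' returned object evaluates the indentation modulus at given out-of-plane
#' fibril angles.
#'
#' @param phi mineral volume fraction of the fibril array.
#' @param params a [fibril_array_params()] template (its `phi_mineral` is
#'   ignored in favor of `phi`).
#' @param ... passed to [fibril_array_stiffness()].
#' @return Object of class `fibril_array_model` with elements `params`,
#'   `phi`, `partition`, `stiffness`.
#' @examples
#' m <- fibril_array_model(0.38)
#' predict(m, theta = c(0, 32.3))
#' @export
fibril_array_model <- function(phi, params = fibril_array_params(), ...) {
  structure(list(params = params, phi = phi,
                 partition = partition_phases(params, phi),
                 stiffness = fibril_array_stiffness(params, phi, ...)),
            class = "fibril_array_model")
}

#' @param object a `fibril_array_model`.
#' @param theta out-of-plane fibril angle(s) in degrees.
#' @rdname fibril_array_model
#' @export
predict.fibril_array_model <- function(object, theta = 0, ...) {
  modulus_vs_theta(object$stiffness, theta)
}

#' @param x a `fibril_array_model`.
#' @rdname fibril_array_model
#' @export
print.fibril_array_model <- function(x, ...) {
  cat(sprintf("Fibril-array model, phi_mineral = %.4f\n", x$phi))
  cat(sprintf("  mineral in fibril: %.4f, voids in extra-fibrillar: %.4f\n",
              x$partition$f_min_in_fibril, x$partition$f_void_in_ef))
  cat(sprintf("  axial indentation modulus: %.2f GPa\n",
              indentation_modulus(x$stiffness, theta = 0)))
  invisible(x)
}
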