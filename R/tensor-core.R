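# Fourth-order elasticity tensors are stored as 6x6 matrices in the
# orthonormal Mandel basis: component order (11, 22, 33, 23, 13, 12) with
# sqrt(2) weights on the shear rows/columns.  In this basis matrix inversion
# equals tensor inversion and the Frobenius inner product equals the tensor
# inner product, which removes all factor-of-2 bookkeeping from the
# Eshelby / Mori-Tanaka algebra.  Voigt notation is accepted and emitted only
# at I/O boundaries.  Moduli are in GPa; the fibril axis is e3.

.mandel_pairs <- matrix(c(1L, 1L, 2L, 2L, 3L, 3L, 2L, 3L, 1L, 3L, 1L, 2L),
                        ncol = 2L, byrow = TRUE)
.mandel_w <- c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2))

#' Stiffness tensor in Mandel notation
#'
#' Wraps a 6x6 matrix of elastic moduli (GPa) as a classed stiffness tensor.
#' The internal representation is the orthonormal Mandel basis; matrices in
#' Voigt notation are converted on input.
#'
#' @param M 6x6 numeric matrix, symmetric (component order 11, 22, 33, 23,
#'   13, 12).
#' @param notation `"mandel"` (default) or `"voigt"` describing `M`.
#' @param symmetry symmetry tag: `"general"`, `"isotropic"` or
#'   `"transverse_isotropic"` (about e3). Purely descriptive; invariants are
#'   checked by [check_transverse_isotropy()].
#' @param check if `TRUE`, verify symmetry of `M` (relative tolerance 1e-10
#'   scaled by the matrix norm).
#' @return An object of class `stiffness_tensor`: a list with elements
#'   `M` (6x6 Mandel matrix) and `symmetry`.
#' @examples
#' C <- isotropic_stiffness(E = 20, nu = 0.3)
#' as.matrix(C, notation = "voigt")
#' @export
stiffness_tensor <- function(M, notation = c("mandel", "voigt"),
                             symmetry = c("general", "isotropic",
                                          "transverse_isotropic"),
                             check = TRUE) {
  notation <- match.arg(notation)
  symmetry <- match.arg(symmetry)
  M <- as.matrix(M)
  if (!all(dim(M) == c(6L, 6L)) || !is.numeric(M))
    stop("stiffness matrix must be a numeric 6x6 matrix", call. = FALSE)
  if (notation == "voigt") M <- voigt_to_mandel(M)
  if (check) {
    scale <- max(abs(M), 1e-300)
    if (max(abs(M - t(M))) > 1e-10 * scale)
      stop("stiffness matrix is not symmetric", call. = FALSE)
    M <- (M + t(M)) / 2
  }
  structure(list(M = M, symmetry = symmetry), class = "stiffness_tensor")
}

#' @export
as.matrix.stiffness_tensor <- function(x, notation = c("mandel", "voigt"),
                                       ...) {
  notation <- match.arg(notation)
  if (notation == "voigt") mandel_to_voigt(x$M) else x$M
}

#' @export
print.stiffness_tensor <- function(x, digits = 4, ...) {
  cat("Stiffness tensor (", x$symmetry, "), GPa, Mandel notation\n", sep = "")
  print(round(x$M, digits))
  invisible(x)
}

.as_stiffness <- function(C) {
  if (inherits(C, "stiffness_tensor")) return(C)
  stiffness_tensor(C)
}

#' Convert between Voigt and Mandel 6x6 matrices
#'
#' The Mandel matrix carries a factor sqrt(2) on each shear row/column
#' relative to the Voigt stiffness matrix.
#'
#' @param V,M 6x6 matrix in Voigt / Mandel notation.
#' @return 6x6 matrix in the other notation.
#' @export
voigt_to_mandel <- function(V) {
  w <- outer(.mandel_w, .mandel_w)
  V * w
}

#' @rdname voigt_to_mandel
#' @export
mandel_to_voigt <- function(M) {
  w <- outer(.mandel_w, .mandel_w)
  M / w
}

# 6x6 Mandel <-> full 3x3x3x3 array (minor + major symmetric input assumed
# only for the minor symmetries; Eshelby-type tensors lacking major symmetry
# are handled too).
mandel_to_array <- function(M) {
  C4 <- array(0, dim = c(3, 3, 3, 3))
  for (I in 1:6) for (J in 1:6) {
    v <- M[I, J] / (.mandel_w[I] * .mandel_w[J])
    i <- .mandel_pairs[I, 1]; j <- .mandel_pairs[I, 2]
    k <- .mandel_pairs[J, 1]; l <- .mandel_pairs[J, 2]
    C4[i, j, k, l] <- v; C4[j, i, k, l] <- v
    C4[i, j, l, k] <- v; C4[j, i, l, k] <- v
  }
  C4
}

array_to_mandel <- function(C4) {
  M <- matrix(0, 6, 6)
  for (I in 1:6) for (J in 1:6) {
    i <- .mandel_pairs[I, 1]; j <- .mandel_pairs[I, 2]
    k <- .mandel_pairs[J, 1]; l <- .mandel_pairs[J, 2]
    M[I, J] <- C4[i, j, k, l] * .mandel_w[I] * .mandel_w[J]
  }
  M
}

#' Isotropic stiffness tensor from engineering constants
#'
#' @param E Young's modulus in GPa, positive.
#' @param nu Poisson ratio, in (-1, 0.5).
#' @return A `stiffness_tensor` with `symmetry = "isotropic"`.
#' @examples
#' isotropic_stiffness(5, 0.3)    # collagen
#' isotropic_stiffness(110.5, 0.28) # hydroxyapatite mineral
#' @export
isotropic_stiffness <- function(E, nu) {
  if (!is.finite(E) || E <= 0)
    stop("Young's modulus must be positive", call. = FALSE)
  if (!is.finite(nu) || nu <= -1 || nu >= 0.5)
    stop("Poisson ratio must lie in (-1, 0.5)", call. = FALSE)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  M <- diag(c(rep(lam + 2 * mu, 3), rep(2 * mu, 3)))
  M[1:3, 1:3] <- M[1:3, 1:3] + lam * (1 - diag(3))
  stiffness_tensor(M, symmetry = "isotropic", check = FALSE)
}

#' Recover engineering constants from an isotropic stiffness tensor
#'
#' @param C a `stiffness_tensor` (assumed isotropic; not verified beyond the
#'   entries used).
#' @return Named vector `c(E =, nu =)`.
#' @export
isotropic_constants <- function(C) {
  M <- .as_stiffness(C)$M
  mu <- M[4, 4] / 2
  lam <- M[1, 2]
  E <- mu * (3 * lam + 2 * mu) / (lam + mu)
  nu <- lam / (2 * (lam + mu))
  c(E = E, nu = nu)
}

#' Rotation matrix about an axis
#'
#' Rodrigues formula; right-handed rotation by `angle_deg` degrees about
#' `axis`.
#'
#' @param axis length-3 numeric vector (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 proper orthogonal matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

is_rotation <- function(R, tol = 1e-10) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(R %*% t(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

#' Rotate a stiffness tensor
#'
#' Applies `C'_ijkl = R_ip R_jq R_kr R_ls C_pqrs`. With `R` the matrix whose
#' rows are the new basis vectors expressed in the old basis, this returns
#' the tensor's components in the new frame.
#'
#' @param C a `stiffness_tensor` (or 6x6 Mandel matrix).
#' @param R 3x3 proper orthogonal matrix.
#' @return Rotated `stiffness_tensor`.
#' @export
rotate_stiffness <- function(C, R) {
  C <- .as_stiffness(C)
  if (!is_rotation(R))
    stop("R is not a proper rotation (orthogonality/det check failed)",
         call. = FALSE)
  C4 <- mandel_to_array(C$M)
  for (k in 1:4) {
    C4 <- array(R %*% matrix(C4, nrow = 3), dim = c(3, 3, 3, 3))
    C4 <- aperm(C4, c(2, 3, 4, 1))
  }
  sym <- if (C$symmetry == "isotropic") "isotropic" else "general"
  stiffness_tensor(array_to_mandel(C4), symmetry = sym, check = FALSE)
}

#' Deviation from transverse isotropy about an axis
#'
#' Rotates the tensor by a sampled set of angles about `axis` and returns the
#' maximum relative Frobenius deviation from the unrotated tensor. Zero means
#' the tensor is exactly transversely isotropic about `axis`.
#'
#' @param C a `stiffness_tensor`.
#' @param axis unit 3-vector (default fibril axis e3).
#' @param n_angles number of sampled rotation angles in (0, 180) degrees.
#' @return Maximum relative deviation (dimensionless scalar).
#' @export
check_transverse_isotropy <- function(C, axis = c(0, 0, 1), n_angles = 12) {
  C <- .as_stiffness(C)
  nrmC <- sqrt(sum(C$M^2))
  angs <- seq(0, 180, length.out = n_angles + 2)[2:(n_angles + 1)]
  dev <- 0
  for (a in angs) {
    Crot <- rotate_stiffness(C, rotation_about_axis(axis, a))
    dev <- max(dev, sqrt(sum((Crot$M - C$M)^2)) / nrmC)
  }
  dev
}

#' Closest isotropic tensor (Frobenius projection)
#'
#' Projects a stiffness tensor onto the isotropic subspace spanned by the
#' volumetric and deviatoric projectors.
#'
#' @param C a `stiffness_tensor`.
#' @return Isotropic `stiffness_tensor`.
#' @export
isotropize <- function(C) {
  M <- .as_stiffness(C)$M
  j <- c(1, 1, 1, 0, 0, 0) / sqrt(3)
  J <- outer(j, j)
  K <- diag(6) - J
  cJ <- sum(J * M)            # <J,J> = 1
  cK <- sum(K * M) / 5        # <K,K> = 5
  stiffness_tensor(cJ * J + cK * K, symmetry = "isotropic", check = FALSE)
}

is_positive_definite <- function(C, tol = 1e-10) {
  ev <- eigen((.as_stiffness(C)$M + t(.as_stiffness(C)$M)) / 2,
              symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(abs(ev))
}

#' Read/write stiffness tensors as plain-text CSV
#'
#' The file holds a comment header declaring notation and units followed by a
#' headerless 6x6 matrix.
#'
#' @param C a `stiffness_tensor`.
#' @param path file path.
#' @param notation `"mandel"` or `"voigt"` for the on-disk matrix.
#' @return `read_stiffness_csv` returns a `stiffness_tensor`;
#'   `write_stiffness_csv` returns `path` invisibly.
#' @export
write_stiffness_csv <- function(C, path, notation = c("mandel", "voigt")) {
  notation <- match.arg(notation)
  M <- as.matrix(.as_stiffness(C), notation = notation)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# notation: %s", notation), con)
  writeLines("# units: GPa", con)
  write.table(format(M, digits = 17), con, sep = ",", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stiffness_csv
#' @export
read_stiffness_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  notation <- "mandel"
  m <- regmatches(hdr, regexpr("notation:\\s*(mandel|voigt)", hdr))
  if (length(m) && nzchar(m[1]))
    notation <- sub("notation:\\s*", "", m[1])
  M <- as.matrix(read.csv(textConnection(lines[!grepl("^#", lines)]),
                          header = FALSE))
  dimnames(M) <- NULL
  stiffness_tensor(M, notation = notation)
}
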