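# Shared fixtures: all built in code at test time.

# deterministic random proper rotation
random_rotation <- function(seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rotation_about_axis(ax, runif(1, 0, 360))
}

# random symmetric positive definite stiffness in Mandel form
random_spd_stiffness <- function(seed = 1, scale = 10) {
  set.seed(seed)
  A <- matrix(rnorm(36), 6, 6)
  stiffness_tensor(crossprod(A) + scale * diag(6), check = FALSE)
}

# smooth synthetic raster with structure, for registration tests
smooth_field <- function(nx = 96, ny = 96, pixel_size = 0.5, seed = 1,
                         origin = c(0, 0)) {
  set.seed(seed)
  w <- matrix(rnorm(nx * ny), nx, ny)
  k <- 7
  kern <- outer(dnorm(seq(-3, 3, length.out = k)),
                dnorm(seq(-3, 3, length.out = k)))
  kern <- kern / sum(kern)
  pad <- function(m) m[c((nx - k + 2):nx, 1:nx, 1:(k - 1)),
                       c((ny - k + 2):ny, 1:ny, 1:(k - 1))]
  wp <- pad(w)
  s <- matrix(0, nx, ny)
  for (i in 1:k) for (j in 1:k)
    s <- s + kern[i, j] * wp[i:(i + nx - 1), j:(j + ny - 1)]
  scalar_field(s, pixel_size, origin)
}

table1_params <- function(...) fibril_array_params(...)

# direct (non-interpolated) model evaluation
direct_modulus <- function(phi, theta, params = fibril_array_params()) {
  vapply(seq_along(phi), function(i)
    indentation_modulus(fibril_array_stiffness(params, phi = phi[i]),
                        theta = rep_len(theta, length(phi))[i]),
    numeric(1))
}
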