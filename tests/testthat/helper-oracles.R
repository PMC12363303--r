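# Independent numerical oracle for the true ellipsoid surface area:
# Simpson's rule over the parametrized surface element. Kept independent of
# the package's own quadrature (different rule, different code path).
oracle_ellipsoid_surface <- function(a, b, c, n = 200L) {
  n <- 2L * n  # Simpson needs an even panel count
  theta <- seq(0, pi, length.out = n + 1L)
  phi <- seq(0, 2 * pi, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  f <- function(th, ph) {
    sin(th) * sqrt(b^2 * c^2 * sin(th)^2 * cos(ph)^2 +
                     a^2 * c^2 * sin(th)^2 * sin(ph)^2 +
                     a^2 * b^2 * cos(th)^2)
  }
  vals <- outer(theta, phi, f)
  (t(w) %*% vals %*% w)[1, 1] * (pi / n / 3) * (2 * pi / n / 3)
}

# small noiseless phantom used across recovery tests (1 mm isotropic)
small_phantom_spec <- function(noise_sd = 0, seed = 7L, cap = c(10, 8, 4)) {
  phantom_spec(grid_shape = c(64, 56, 48), spacing = c(1, 1, 1),
               bleb_center = c(32, 28, 16), bleb_axes = c(20, 15, 8),
               cap_axes = cap, noise_sd = noise_sd, seed = seed)
}

dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
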