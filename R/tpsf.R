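#' Temporal point spread function of a diffusive slab in transmission
#'
#' Diffusion-approximation solution for a homogeneous slab with extrapolated
#' boundaries, evaluated as a finite sum of image sources (the standard
#' transmittance dialect: isotropic source at one transport mean free path
#' inside the entry face, detector on the exit face). Absorption enters as a
#' pure `exp(-mua * v * t)` factor, which is what makes the modified
#' Beer-Lambert analysis of dynamic absorption changes exact at the level of
#' the time-resolved measurement.
#'
#' @param t_ns Times in ns (vector).
#' @param mu_a Absorption coefficient, per cm.
#' @param mu_s_prime Reduced scattering coefficient, per cm.
#' @param thickness Slab thickness, cm.
#' @param n_tissue Refractive index of the slab (external medium n = 1).
#' @param n_images Number of image-source pairs on each side.
#' @return Transmittance per unit time (arbitrary source normalization),
#'   nonnegative, zero for `t <= 0`.
#' @export
slab_tpsf <- function(t_ns, mu_a, mu_s_prime, thickness,
                      n_tissue = nirs_constants$n_tissue, n_images = 3L) {
  if (mu_a <= 0) stop("'mu_a' must be > 0")
  if (mu_s_prime <= 0 || thickness <= 0) stop("scattering and thickness must be > 0")
  v <- nirs_constants$c_vacuum / n_tissue
  D <- 1 / (3 * mu_s_prime)
  z0 <- 1 / mu_s_prime
  # internal-reflection parameter (Groenhuis/Egan approximation)
  rd <- -1.44 / n_tissue^2 + 0.71 / n_tissue + 0.668 + 0.0636 * n_tissue
  A <- (1 + rd) / (1 - rd)
  ze <- 2 * A * D

  out <- numeric(length(t_ns))
  pos <- t_ns > 0
  tt <- t_ns[pos]
  s <- 0
  for (m in -n_images:n_images) {
    z1 <- thickness * (1 - 2 * m) - 4 * m * ze - z0
    z2 <- thickness * (1 - 2 * m) - (4 * m - 2) * ze + z0
    s <- s + z1 * exp(-z1^2 / (4 * D * v * tt)) -
      z2 * exp(-z2^2 / (4 * D * v * tt))
  }
  out[pos] <- exp(-mu_a * v * tt) * (4 * pi * D * v)^(-0.5) * tt^(-1.5) * s / 2
  pmax(out, 0)
}
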