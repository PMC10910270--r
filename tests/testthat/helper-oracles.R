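# Independent oracles used by the tests only.

# Analytic gradients of real solid harmonics (spherical family, l <= 2), in
# the frame coordinates of the expansion. External solid harmonic
# R_lm = r^l S_lm is a polynomial; internal I_lm = S_lm / r^(l+1) follows as
# I_lm = R_lm / r^(2l+1). Conventions match real_sph_harm (including the
# (-1)^m phase).
solid_harm_R <- function(l, m, p) {
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  if (l == 1) {
    c1 <- sqrt(3 / (4 * pi))
    switch(as.character(m),
           "0" = c1 * z, "1" = -c1 * x, "-1" = -c1 * y)
  } else if (l == 2) {
    c0 <- sqrt(5 / (16 * pi)); c1 <- 3 * sqrt(5 / (12 * pi))
    c2 <- 3 * sqrt(5 / (48 * pi))
    switch(as.character(m),
           "0" = c0 * (2 * z^2 - x^2 - y^2),
           "1" = -c1 * x * z, "-1" = -c1 * y * z,
           "2" = c2 * (x^2 - y^2), "-2" = 2 * c2 * x * y)
  } else stop("oracle implements l <= 2 only")
}

solid_harm_gradR <- function(l, m, p) {
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]; n <- nrow(p); zero <- numeric(n)
  if (l == 1) {
    c1 <- sqrt(3 / (4 * pi))
    switch(as.character(m),
           "0" = cbind(zero, zero, zero + c1),
           "1" = cbind(zero - c1, zero, zero),
           "-1" = cbind(zero, zero - c1, zero))
  } else if (l == 2) {
    c0 <- sqrt(5 / (16 * pi)); c1 <- 3 * sqrt(5 / (12 * pi))
    c2 <- 3 * sqrt(5 / (48 * pi))
    switch(as.character(m),
           "0" = cbind(-2 * c0 * x, -2 * c0 * y, 4 * c0 * z),
           "1" = cbind(-c1 * z, zero, -c1 * x),
           "-1" = cbind(zero, -c1 * z, -c1 * y),
           "2" = cbind(2 * c2 * x, -2 * c2 * y, zero),
           "-2" = cbind(2 * c2 * y, 2 * c2 * x, zero))
  } else stop("oracle implements l <= 2 only")
}

# grad of I_lm = R_lm r^(-2l-1)
solid_harm_gradI <- function(l, m, p) {
  r <- sqrt(rowSums(p^2))
  R <- solid_harm_R(l, m, p)
  gR <- solid_harm_gradR(l, m, p)
  gR / r^(2 * l + 1) - (2 * l + 1) * p * (R / r^(2 * l + 3))
}

# Surface quadrature over the unit sphere: Gauss-Legendre in cos(theta) x
# uniform in phi (exact for trigonometric polynomials of the orders tested).
sphere_quadrature <- function(n_theta = 40, n_phi = 80) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  grid <- expand.grid(x = gl$x, phi = phi)
  list(theta = acos(grid$x), phi = grid$phi,
       w = rep(gl$w, times = n_phi) * (2 * pi / n_phi))
}

# Primary (vacuum) field of a current dipole, Biot-Savart closed form.
primary_dipole_field <- function(pos, src, q) {
  d <- sweep(pos, 2, src)
  dn <- sqrt(rowSums(d^2))
  qxd <- cbind(q[2] * d[, 3] - q[3] * d[, 2],
               q[3] * d[, 1] - q[1] * d[, 3],
               q[1] * d[, 2] - q[2] * d[, 1])
  1e-7 * qxd / dn^3
}
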