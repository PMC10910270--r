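test_that("conducting-sphere lead fields satisfy the exact field identities", {
  arr <- fixture("arr_small")
  src <- c(0.02, 0.03, -0.01)
  q <- c(0, 0.6, 0.8); q <- q / sqrt(sum(q^2))
  # radial component equals the primary dipole field's radial component
  # (volume currents of a spherically symmetric conductor are radially silent)
  pos <- arr$positions
  B <- ammr:::sarvas_field(pos, src, q)
  rhat <- pos / sqrt(rowSums(pos^2))
  Bp <- primary_dipole_field(pos, src, q)
  expect_equal(rowSums(B * rhat), rowSums(Bp * rhat), tolerance = 1e-10)
  # radially oriented dipoles are silent
  l_rad <- single_sphere_leadfield(arr, src, src / sqrt(sum(src^2)))
  qt <- q - sum(q * src) * src / sum(src^2)
  l_tan <- single_sphere_leadfield(arr, src, qt)
  expect_lt(max(abs(l_rad)), 1e-6 * max(abs(l_tan)))
  # field decays monotonically along an outward radial ray
  ray_dir <- c(0.0, 0.3, 0.954); ray_dir <- ray_dir / sqrt(sum(ray_dir^2))
  radii <- seq(0.09, 0.2, by = 0.01)
  ray <- outer(radii, ray_dir)
  mag <- sqrt(rowSums(ammr:::sarvas_field(ray, src, q)^2))
  expect_true(all(diff(mag) < 0))
  # the external field is curl- and divergence-free (finite differences)
  h <- 1e-6
  p0 <- c(0.05, 0.07, 0.06)
  J <- sapply(1:3, function(j) {
    e <- numeric(3); e[j] <- h
    (ammr:::sarvas_field(rbind(p0 + e), src, q) -
       ammr:::sarvas_field(rbind(p0 - e), src, q)) / (2 * h)
  }) # J[i, j] = dB_i / dx_j
  expect_lt(abs(sum(diag(J))), 1e-6 * max(abs(J)))
  expect_lt(max(abs(J - t(J))), 1e-6 * max(abs(J)))
  expect_error(single_sphere_leadfield(arr, c(0, 0, 0), q), "centre")
  expect_error(single_sphere_leadfield(arr, c(0.2, 0, 0), q), "not inside")
})

test_that("cortical source sets are interior, uniform and unit-normal", {
  sph <- fixture("sph")
  src <- cortical_source_set(sph, 200, seed = 3)
  co <- to_prolate_spheroidal(src$positions, sph)
  expect_true(all(co$rmaj < sph$a))
  expect_equal(unname(sqrt(rowSums(src$orientations^2))), rep(1, 200),
               tolerance = 1e-12)
  nn <- apply(as.matrix(dist(src$positions)) + diag(Inf, 200), 1, min)
  expect_lt(stats::sd(nn) / mean(nn), 0.35)
  expect_identical(src, cortical_source_set(sph, 200, seed = 3))
})

test_that("interference topographies realise the field + gradient model", {
  arr_rad <- generate_scalp_array(fixture("sph"), 0.035, axes = 1, seed = 1)
  # homogeneous field along x on a radial-only array: x-component of normals
  v <- interference_topography(arr_rad, c(1, 0, 0, rep(0, 5)))
  expect_equal(v, arr_rad$orientations[, 1], tolerance = 1e-12)
  # every topography lies in the span of the spherical L_out = 2 basis
  bas <- fixture("bas_small")
  Hout <- basis_external(bas)
  Qe <- qr.Q(qr(Hout))
  set.seed(24)
  for (i in 1:5) {
    w <- as.numeric(with_seed_test(24 + i, random_interference(fixture("arr_small"))))
    resid <- w - Qe %*% crossprod(Qe, w)
    expect_lt(sqrt(sum(resid^2)) / sqrt(sum(w^2)), 1e-8)
  }
  # gradient-only model at mirrored positions is antisymmetric
  mir <- sensor_array(c("a", "b"), rbind(c(0.05, 0.02, 0.01),
                                         -c(0.05, 0.02, 0.01)),
                      rbind(c(0, 0, 1), c(0, 0, 1)), 1, c(1, 2))
  g <- interference_topography(mir, c(0, 0, 0, 0.3, -0.2, 0.5, 0.1, 0.4))
  expect_equal(g[1], -g[2], tolerance = 1e-12)
  # unit rms scaling
  w <- with_seed_test(25, random_interference(fixture("arr_small")))
  expect_equal(sqrt(mean(w^2)), 1, tolerance = 1e-12)
})

test_that("nonlinearity corruption scales channels by at most e_max", {
  set.seed(26)
  E <- matrix(rnorm(40), 8)
  n_topo <- rnorm(8)
  expect_identical(apply_nonlinearity(E, n_topo, 0), E)
  out <- apply_nonlinearity(E, n_topo, 0.05)
  rel <- abs(out - E) / abs(E)
  expect_equal(max(rel), 0.05, tolerance = 1e-12)
  expect_error(apply_nonlinearity(E, rep(0, 8), 0.01), "zero")
  # corrupted topography leaks out of span(Hout) linearly in e_max
  bas <- fixture("bas_small")
  arr <- fixture("arr_small")
  Qe <- qr.Q(qr(basis_external(bas)))
  topo <- with_seed_test(27, random_interference(arr))
  ntopo <- with_seed_test(28, random_interference(arr))
  grid <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  leak <- sapply(grid, function(e) {
    x <- apply_nonlinearity(topo, ntopo, e)
    sqrt(sum((x - Qe %*% crossprod(Qe, x))^2))
  })
  expect_true(all(leak > 0))
  expect_gt(stats::cor(leak, grid)^2, 0.99)
})

test_that("worst-case shielding follows the reciprocal nonlinearity law", {
  arr <- fixture("arr_tri")
  Pa <- fixture("P_amm")
  Ps <- fixture("P_sss")
  sphc <- fixture("sph")$centre
  # e_max = 0: interference is fully inside span(Hout), shielding is huge
  w0 <- worst_case_shielding(arr, Pa, n_interf = 5, n_nonlin = 1, e_max = 0,
                             seed = 5, origin = sphc)
  expect_gt(w0$min_linear, 1e8)
  grid <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  mins <- sapply(grid, function(e)
    worst_case_shielding(arr, Pa, n_interf = 15, n_nonlin = 10, e_max = e,
                         seed = 6, origin = sphc)$min_linear)
  slope <- stats::coef(stats::lm(log(mins) ~ log(grid)))[2]
  expect_lt(abs(slope + 1), 0.15)
  # AMM never shields worse than SSS on the same draws
  for (seed in 1:3) {
    wa <- worst_case_shielding(arr, Pa, 10, 5, 0.01, seed = seed, origin = sphc)
    ws <- worst_case_shielding(arr, Ps, 10, 5, 0.01, seed = seed, origin = sphc)
    expect_gte(wa$min_linear, ws$min_linear)
  }
  # deterministic given seed
  expect_identical(
    worst_case_shielding(arr, Pa, 5, 3, 0.01, seed = 9, origin = sphc),
    worst_case_shielding(arr, Pa, 5, 3, 0.01, seed = 9, origin = sphc))
})

test_that("white noise generator is reproducible and white", {
  W <- white_noise(50, 4000, sigma = 2, seed = 7)
  expect_identical(W, white_noise(50, 4000, sigma = 2, seed = 7))
  n <- length(W)
  expect_lt(abs(mean(W)), 4 * 2 / sqrt(n))
  expect_equal(stats::sd(as.numeric(W)), 2, tolerance = 0.02)
  ac <- stats::acf(W[1, ], lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac), 3 / sqrt(4000))
})
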