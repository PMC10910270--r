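test_that("real spherical harmonics match closed forms and are orthonormal", {
  expect_equal(real_sph_harm(0, 0, 0.7, 1.3), 1 / sqrt(4 * pi))
  expect_equal(real_sph_harm(1, 0, 0, 0), sqrt(3 / (4 * pi)))
  expect_error(real_sph_harm(1, 2, 0, 0), "exceed")
  # quadrature orthonormality up to l = 4
  qd <- sphere_quadrature()
  idx <- do.call(rbind, lapply(1:4, function(l)
    data.frame(l = l, m = -l:l)))
  vals <- sapply(seq_len(nrow(idx)), function(i)
    real_sph_harm(idx$l[i], idx$m[i], qd$theta, qd$phi))
  G <- t(vals * qd$w) %*% vals
  expect_lt(max(abs(G - diag(nrow(idx)))), 1e-6)
})

test_that("radial ratios match closed-form Legendre functions", {
  a <- 0.08; cc <- 0.04
  rmaj <- c(0.085, 0.1, 0.2)
  # normalisation at the reference surface
  expect_equal(q_ratio(3, 2, a, cc, a), 1)
  expect_equal(p_ratio(3, 2, a, cc, a), 1)
  # l=0 second kind: Q0(xi) = atanh(1/xi)
  Q0 <- function(xi) 0.5 * log((xi + 1) / (xi - 1))
  expect_equal(q_ratio(0, 0, rmaj, cc, a), Q0(rmaj / cc) / Q0(a / cc),
               tolerance = 1e-10)
  # l=2, m=1 first kind: P21(xi) = 3 xi sqrt(xi^2 - 1)
  P21 <- function(xi) 3 * xi * sqrt(xi^2 - 1)
  expect_equal(p_ratio(2, 1, rmaj, cc, a), P21(rmaj / cc) / P21(a / cc),
               tolerance = 1e-10)
  # spherical limits
  tiny <- 1e-6 * a
  expect_equal(q_ratio(4, 1, rmaj, tiny, a), (a / rmaj)^5, tolerance = 1e-8)
  expect_equal(p_ratio(4, 1, rmaj, tiny, a), (rmaj / a)^4, tolerance = 1e-8)
  expect_error(q_ratio(2, 3, 0.1, cc, a))
  # non-convergence reported with context
  expect_error(q_ratio(5, 0, cc * (1 + 1e-9), cc, a, kmax = 50L),
               "did not converge")
})

test_that("potential values are harmonic and family-consistent", {
  sph <- fixture("sph")
  set.seed(7)
  pts <- sweep(0.12 * ammr:::fibonacci_sphere(12), 2, sph$centre, `+`)
  # 7-point finite-difference Laplacian vanishes (solutions of Laplace's eq.)
  h <- 1e-4 * sph$a
  for (spec in list(c("internal", "spheroidal", 3, 2),
                    c("external", "spheroidal", 2, -1),
                    c("internal", "spherical", 4, 0))) {
    V0 <- potential_value(spec[1], spec[2], as.numeric(spec[3]),
                          as.numeric(spec[4]), pts, sph)
    lap <- -6 * V0
    for (j in 1:3) for (s in c(-1, 1)) {
      ps <- pts; ps[, j] <- ps[, j] + s * h
      lap <- lap + potential_value(spec[1], spec[2], as.numeric(spec[3]),
                                   as.numeric(spec[4]), ps, sph)
    }
    expect_lt(max(abs(lap / h^2) * sph$a^2 / abs(V0)), 1e-4)
  }
  # spheroidal ~ spherical at vanishing focus
  nearly <- reference_spheroid(a = 0.08, b = 0.08 * sqrt(1 - 1e-12))
  vs <- potential_value("internal", "spheroidal", 3, 1, pts, nearly)
  vr <- potential_value("internal", "spherical", 3, 1, pts, nearly)
  expect_lt(max(abs(vs - vr) / abs(vr)), 1e-5)
  # external spherical l=1, m=0 potential is proportional to frame z
  pf <- ammr:::to_frame_coords(pts, sph)
  v <- potential_value("external", "spherical", 1, 0, pts, sph)
  expect_lt(max(abs(v / (sqrt(3 / (4 * pi)) * pf[, 3] / sph$a) - 1)), 1e-12)
})

test_that("basis has the prescribed column structure and counts", {
  bas <- fixture("bas_small")
  expect_equal(sum(bas$meta$kind == "internal"), 99) # l^2 + 2l at l = 9
  expect_equal(sum(bas$meta$kind == "external"), 8)
  expect_false(any(duplicated(bas$meta[, c("kind", "l", "m")])))
  expect_equal(unname(sqrt(colSums(bas$matrix^2))),
               rep(1, ncol(bas$matrix)), tolerance = 1e-12)
  expect_true(all(bas$scales > 0))
  bas11 <- suppressWarnings(build_basis(fixture("arr_small"), fixture("sph"),
                                        L_in = 11, L_out = 1))
  expect_equal(sum(bas11$meta$kind == "internal"), 143)
  expect_equal(sum(bas11$meta$kind == "external"), 3)
})

test_that("finite-difference columns match analytic spherical gradients", {
  arr <- fixture("arr_small")
  sph <- fixture("sph")
  bas <- suppressWarnings(build_basis(arr, sph, family = "spherical",
                                      L_in = 2, L_out = 2))
  R <- ammr:::spheroid_frame(sph)
  pf <- ammr:::to_frame_coords(arr$positions, sph)
  of <- arr$orientations %*% R # orientations in frame coords
  for (j in seq_len(ncol(bas$matrix))) {
    meta <- bas$meta[j, ]
    g <- if (meta$kind == "internal") {
      sph$a^(meta$l + 1) * solid_harm_gradI(meta$l, meta$m, pf)
    } else {
      sph$a^(-meta$l) * solid_harm_gradR(meta$l, meta$m, pf)
    }
    raw <- bas$matrix[, j] * bas$scales[j]
    expect_equal(raw, rowSums(of * g), tolerance = 1e-6)
  }
})

test_that("spheroidal basis equals spherical basis in the sphere limit", {
  arr <- fixture("arr_small")
  nearly <- reference_spheroid(a = 0.08, b = 0.08 * sqrt(1 - 1e-12))
  b_sph <- suppressWarnings(build_basis(arr, nearly, family = "spherical",
                                        L_in = 5))
  b_sfd <- suppressWarnings(build_basis(arr, nearly, family = "spheroidal",
                                        L_in = 5))
  cosd <- 1 - abs(colSums(b_sph$matrix * b_sfd$matrix))
  expect_lt(max(cosd), 1e-5)
})

test_that("basis is invariant under rigid rotation of array and frame", {
  arr <- fixture("arr_small")
  sph <- fixture("sph")
  bas <- suppressWarnings(build_basis(arr, sph, L_in = 4))
  set.seed(8)
  Q <- random_rotation()
  arr_r <- sensor_array(arr$names, arr$positions %*% t(Q),
                        arr$orientations %*% t(Q), arr$axes_per_sensor,
                        arr$sensor_index)
  sph_r <- reference_spheroid(as.numeric(Q %*% sph$centre),
                              as.numeric(Q %*% sph$axis), sph$a, sph$b)
  bas_r <- suppressWarnings(build_basis(arr_r, sph_r, L_in = 4))
  # rotated-basis columns span the same per-(l) subspaces; compare through
  # the projection onto the original column space, per column magnitude
  Q1 <- qr.Q(qr(bas$matrix))
  resid <- bas_r$matrix - Q1 %*% crossprod(Q1, bas_r$matrix)
  expect_lt(max(sqrt(colSums(resid^2))), 1e-6)
})

test_that("external spherical block at l=1 spans the homogeneous fields", {
  arr <- fixture("arr_small")
  sph <- fixture("sph")
  bas <- suppressWarnings(build_basis(arr, sph, L_in = 1, L_out = 1))
  Hext <- basis_external(bas)
  # analytic constant-field topographies
  Hhom <- arr$orientations
  Qe <- qr.Q(qr(Hext))
  resid <- Hhom - Qe %*% crossprod(Qe, Hhom)
  expect_lt(max(sqrt(colSums(resid^2)) / sqrt(colSums(Hhom^2))), 1e-6)
})
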