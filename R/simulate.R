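# Simulation suite: dipolar lead fields in a conducting sphere, quasi-uniform
# cortical source sets, homogeneous-field + first-order-gradient interference,
# spatially structured sensor nonlinearity and white noise.

MU0 <- 4e-7 * pi

#' Lead field of a current dipole in a conducting sphere
#'
#' Closed-form magnetic field of a current dipole inside a homogeneous
#' spherically symmetric conductor, projected on the channel orientations.
#' The field outside such a conductor does not depend on the conductor
#' radius, only on the common centre; validity requires the source to be
#' strictly inside the sensor shell (a separating sphere must exist). Radially
#' oriented dipoles are magnetically silent.
#'
#' @param array A [sensor_array()].
#' @param src_pos Length-3 source position (m).
#' @param src_ori Length-3 dipole moment direction (normalised internally;
#'   the returned field is per unit dipole moment, A·m).
#' @param centre Length-3 conductor centre (m).
#' @return Numeric n_c vector (Tesla per A·m).
#' @export
single_sphere_leadfield <- function(array, src_pos, src_ori,
                                    centre = c(0, 0, 0)) {
  centre <- as.numeric(centre)
  r0 <- as.numeric(src_pos) - centre
  q <- as.numeric(src_ori)
  q <- q / sqrt(sum(q^2))
  r0n <- sqrt(sum(r0^2))
  if (r0n < 1e-12) stop("source lies at the conductor centre")
  pos <- sweep(array$positions, 2, centre)
  rn <- sqrt(rowSums(pos^2))
  if (r0n >= min(rn))
    stop(sprintf("source (%.4g m from centre) is not inside the sensor shell (min sensor radius %.4g m)",
                 r0n, min(rn)))
  B <- sarvas_field(pos, r0, q)
  rowSums(array$orientations * B)
}

# Field (n x 3, Tesla per unit dipole moment) at points `pos` (rows, relative
# to conductor centre) of a unit current dipole q at r0 (relative to centre).
sarvas_field <- function(pos, r0, q) {
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  avec <- sweep(pos, 2, r0)
  an <- sqrt(rowSums(avec^2))
  rn <- sqrt(rowSums(pos^2))
  adotr <- rowSums(avec * pos)
  r0dotr <- as.numeric(pos %*% r0)
  FF <- an * (rn * an + rn^2 - r0dotr)
  c1 <- an^2 / rn + adotr / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + adotr / an
  gradF <- pos * c1 - matrix(r0, nrow(pos), 3, byrow = TRUE) * c2
  num <- matrix(qxr0, nrow(pos), 3, byrow = TRUE) * FF -
    gradF * as.numeric(pos %*% qxr0)
  MU0 / (4 * pi) * num / FF^2
}

#' Quasi-uniform cortical source set on an inner spheroidal surface
#'
#' Sources sit on a spheroid scaled to `scale` (default 0.9) of the scalp
#' semi-axes, with surface-normal orientations — a smooth stand-in for a
#' cortical mesh with normal-oriented dipoles. Deterministic given the seed
#' (which randomises the rotation of the underlying Fibonacci lattice about
#' the spheroid axis).
#'
#' @param spheroid Scalp [reference_spheroid()].
#' @param n_src Number of sources.
#' @param seed Integer seed.
#' @param scale Source-surface scale relative to the scalp semi-axes.
#' @return List with `positions` (n_src x 3), `orientations` (n_src x 3 unit
#'   surface normals) and the source-surface semi-axes.
#' @export
cortical_source_set <- function(spheroid, n_src, seed = 1, scale = 0.9) {
  stopifnot(n_src >= 1)
  a_s <- scale * spheroid$a; b_s <- scale * spheroid$b
  dirs <- fibonacci_sphere(n_src)
  ang <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  dirs <- dirs %*% t(Rz)
  surf <- sphere_to_spheroid_surface(dirs, a_s, b_s)
  R <- spheroid_frame(spheroid)
  list(positions = sweep(surf$points %*% t(R), 2, spheroid$centre, `+`),
       orientations = surf$normals %*% t(R),
       a = a_s, b = b_s)
}

#' Simulate a lead-field set for a source surface
#'
#' One conducting-sphere lead field per source, conductor centred at the
#' spheroid centre.
#'
#' @param array A [sensor_array()].
#' @param spheroid Scalp [reference_spheroid()].
#' @param n_src Number of sources.
#' @param seed Source-placement seed.
#' @param scale Source-surface scale (see [cortical_source_set()]).
#' @return Object of class `lead_field_set`: `matrix` (n_c x n_src, T per
#'   A·m), `src_pos`, `src_ori`.
#' @export
simulate_leadfields <- function(array, spheroid, n_src = 500, seed = 1,
                                scale = 0.9) {
  src <- cortical_source_set(spheroid, n_src, seed, scale)
  L <- vapply(seq_len(n_src), function(j)
    single_sphere_leadfield(array, src$positions[j, ], src$orientations[j, ],
                            centre = spheroid$centre),
    numeric(n_channels(array)))
  structure(list(matrix = matrix(L, nrow = n_channels(array)),
                 src_pos = src$positions, src_ori = src$orientations),
            class = "lead_field_set")
}

#' @export
print.lead_field_set <- function(x, ...) {
  cat(sprintf("<lead_field_set> %d channels x %d sources\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# Basis of symmetric traceless 3x3 gradient tensors (5 degrees of freedom of a
# curl- and divergence-free static field gradient).
gradient_tensor_basis <- function() {
  list(
    diag(c(1, -1, 0)),
    diag(c(0, 1, -1)),
    rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)),
    rbind(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0)),
    rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0))
  )
}

#' Interference topography from field + gradient coefficients
#'
#' Channel response to a static field `B0 + G (r - r0)` with `B0` the three
#' homogeneous components (T) and `G` a symmetric traceless gradient tensor
#' built from five independent components (T/m).
#'
#' @param array A [sensor_array()].
#' @param coeffs Length-8 vector: 3 homogeneous components then 5 gradient
#'   components.
#' @param origin Length-3 expansion origin of the gradient (m).
#' @return Numeric n_c topography vector (T).
#' @export
interference_topography <- function(array, coeffs, origin = c(0, 0, 0)) {
  coeffs <- as.numeric(coeffs)
  stopifnot(length(coeffs) == 8)
  B0 <- coeffs[1:3]
  G <- Reduce(`+`, Map(`*`, gradient_tensor_basis(), coeffs[4:8]))
  rel <- sweep(array$positions, 2, as.numeric(origin))
  B <- sweep(rel %*% G, 2, B0, `+`)
  rowSums(array$orientations * B)
}

#' Random unit-RMS interference topography
#'
#' Coefficients drawn iid standard normal (homogeneous components in T,
#' gradient components in T/m), then the channel topography is scaled to unit
#' root-mean-square amplitude.
#'
#' @param array A [sensor_array()].
#' @param origin Gradient expansion origin.
#' @return Numeric n_c topography with `sqrt(mean(x^2)) = 1`.
#' @export
random_interference <- function(array, origin = c(0, 0, 0)) {
  repeat {
    v <- interference_topography(array, stats::rnorm(8), origin)
    r <- sqrt(mean(v^2))
    if (r > 0) return(v / r)
  }
}

#' Apply a structured multiplicative nonlinearity
#'
#' The nonlinearity topography is rescaled so its largest absolute entry
#' equals `e_max`, then applied channel-wise: `out = (I + diag(n)) E`. This is
#' the diagonal-gain abstraction of calibration/orientation errors
#' (cross-talk, cell heating, drifts): a fractional, spatially structured
#' perturbation of each channel's response.
#'
#' @param E n_c vector or n_c x n_t matrix of interference data.
#' @param n_topo n_c nonlinearity topography (any scale; shape only).
#' @param e_max Maximum fractional error in `[0, 0.2]`.
#' @return Corrupted data, same shape as `E`.
#' @export
apply_nonlinearity <- function(E, n_topo, e_max) {
  stopifnot(e_max >= 0, e_max <= 0.2)
  if (e_max == 0) return(E)
  mx <- max(abs(n_topo))
  if (mx == 0) stop("nonlinearity topography is identically zero")
  n <- n_topo / mx * e_max
  if (is.matrix(E)) E * (1 + n) else as.numeric(E) * (1 + n)
}

#' Worst-case shielding factor under structured nonlinearity
#'
#' For each of `n_interf` random interference topographies and `n_nonlin`
#' random nonlinearity topographies (both random combinations of homogeneous
#' fields and first-order gradients), the corrupted topography
#' `(I + diag(n)) e` is passed through the projector and the shielding factor
#' `rms(before) / rms(after)` recorded; the minimum over all draws is the
#' conservative performance bound.
#'
#' @param array A [sensor_array()].
#' @param P A `field_projector`.
#' @param n_interf Number of interference topographies.
#' @param n_nonlin Nonlinearity draws per topography.
#' @param e_max Maximum fractional nonlinearity.
#' @param seed Integer seed (fully determines all draws).
#' @param origin Gradient expansion origin.
#' @return List with `min_linear`, `min_db` (= 20 log10 of the linear
#'   minimum) and `per_topography` (data.frame of per-topography minima).
#' @export
worst_case_shielding <- function(array, P, n_interf = 50, n_nonlin = 20,
                                 e_max = 0.01, seed = 1, origin = c(0, 0, 0)) {
  stopifnot(n_interf >= 1, n_nonlin >= 1)
  M <- P$matrix
  with_seed(seed, {
    mins <- numeric(n_interf)
    for (i in seq_len(n_interf)) {
      topo <- random_interference(array, origin)
      sf <- numeric(n_nonlin)
      for (j in seq_len(n_nonlin)) {
        ntopo <- random_interference(array, origin)
        x <- apply_nonlinearity(topo, ntopo, e_max)
        px <- as.numeric(M %*% x)
        sf[j] <- sqrt(mean(x^2)) / max(sqrt(mean(px^2)), 1e-300)
      }
      mins[i] <- min(sf)
    }
    list(min_linear = min(mins), min_db = 20 * log10(min(mins)),
         per_topography = data.frame(topography = seq_len(n_interf),
                                     min_shielding = mins))
  })
}

#' Gaussian white noise matrix
#'
#' @param n_c Channels; @param n_t Samples; @param sigma Standard deviation.
#' @param seed Integer seed.
#' @return n_c x n_t matrix of iid N(0, sigma^2) draws.
#' @export
white_noise <- function(n_c, n_t, sigma = 1, seed = 1) {
  with_seed(seed, matrix(stats::rnorm(n_c * n_t, sd = sigma), n_c, n_t))
}
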