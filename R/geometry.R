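# Coordinate systems and sensor-array geometry.
#
# All lengths are in metres, all fields in Tesla. The prolate spheroidal frame
# is defined by a reference spheroid (centre, major-axis direction, semi-axes
# a >= b) whose foci sit at centre +/- c * axis with c = sqrt(a^2 - b^2).

#' Construct a reference spheroid
#'
#' A prolate spheroid of revolution used as the reference surface for the
#' harmonic expansions: semi-major axis `a` along `axis`, semi-minor axis `b`
#' in the two transverse directions, foci at `centre +/- c * axis` with
#' `c = sqrt(a^2 - b^2)`.
#'
#' @param centre Numeric length-3 centre (m).
#' @param axis Numeric length-3 major-axis direction (normalised internally).
#' @param a Semi-major axis (m); must satisfy `a >= b > 0`.
#' @param b Semi-minor axis (m).
#' @return An object of class `reference_spheroid` with fields `centre`,
#'   `axis`, `a`, `b` and the focal distance `c`.
#' @examples
#' sph <- reference_spheroid(a = 0.08, b = 0.07)
#' sph$c
#' @export
reference_spheroid <- function(centre = c(0, 0, 0), axis = c(0, 1, 0),
                               a = 0.08, b = 0.07) {
  centre <- as.numeric(centre)
  axis <- as.numeric(axis)
  stopifnot(length(centre) == 3, length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("axis must be a nonzero vector")
  axis <- axis / nrm
  if (!(a >= b && b > 0)) stop("require a >= b > 0 (got a=", a, ", b=", b, ")")
  structure(
    list(centre = centre, axis = axis, a = a, b = b,
         c = sqrt(max(a^2 - b^2, 0))),
    class = "reference_spheroid"
  )
}

#' @export
print.reference_spheroid <- function(x, ...) {
  cat(sprintf(
    "<reference_spheroid> a=%.4g m, b=%.4g m, c=%.4g m\n  centre (%.4g, %.4g, %.4g), axis (%.3f, %.3f, %.3f)\n",
    x$a, x$b, x$c, x$centre[1], x$centre[2], x$centre[3],
    x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

# Right-handed orthonormal frame (e1, e2, axis) for a spheroid; columns of the
# returned matrix. e1/e2 fix the zero of longitude deterministically.
spheroid_frame <- function(spheroid) {
  ax <- spheroid$axis
  t12 <- complete_axes(ax)
  cbind(t12$tangential1, t12$tangential2, ax)
}

# Points (k x 3) expressed in the spheroid frame, relative to its centre.
to_frame_coords <- function(points, spheroid) {
  points <- rbind_points(points)
  R <- spheroid_frame(spheroid)
  sweep(points, 2, spheroid$centre) %*% R
}

from_frame_coords <- function(pf, spheroid) {
  R <- spheroid_frame(spheroid)
  sweep(pf %*% t(R), 2, spheroid$centre, `+`)
}

rbind_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("points must be k x 3")
  points
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Cartesian to spherical coordinates
#'
#' Radius, co-latitude and longitude about the global z axis of an
#' origin-centred frame. The origin itself maps to `(0, 0, 0)` by convention.
#'
#' @param points k x 3 matrix (or length-3 vector) of Cartesian points (m).
#' @param origin Length-3 origin of the spherical frame.
#' @return data.frame with columns `r`, `theta` (in `[0, pi]`) and
#'   `phi` (in `(-pi, pi]`).
#' @export
to_spherical <- function(points, origin = c(0, 0, 0)) {
  p <- sweep(rbind_points(points), 2, as.numeric(origin))
  r <- sqrt(rowSums(p^2))
  theta <- ifelse(r > 0, acos(clamp1(p[, 3] / pmax(r, .Machine$double.xmin))), 0)
  phi <- ifelse(r > 0 & (p[, 1] != 0 | p[, 2] != 0), atan2(p[, 2], p[, 1]), 0)
  data.frame(r = r, theta = theta, phi = phi)
}

spherical_to_cartesian <- function(coords, origin = c(0, 0, 0)) {
  x <- coords$r * sin(coords$theta) * cos(coords$phi)
  y <- coords$r * sin(coords$theta) * sin(coords$phi)
  z <- coords$r * cos(coords$theta)
  sweep(cbind(x, y, z), 2, as.numeric(origin), `+`)
}

#' Cartesian to prolate spheroidal coordinates
#'
#' The confocal construction: with `d1`, `d2` the distances from a point to the
#' two foci of the reference spheroid, the major-axis coordinate is
#' `rmaj = (d1 + d2) / 2` (the semi-major axis of the confocal spheroid through
#' the point), `cos(theta) = (d1 - d2) / (2c)` and `phi` is the azimuth about
#' the major axis. Points on the reference surface have `rmaj = a`.
#'
#' @param points k x 3 matrix (m).
#' @param spheroid A [reference_spheroid()] with strictly positive focal
#'   distance `c` (use [to_spherical()] for the degenerate sphere).
#' @return data.frame with columns `rmaj` (>= c), `theta`, `phi`.
#' @export
to_prolate_spheroidal <- function(points, spheroid) {
  if (spheroid$c <= 0)
    stop("spheroid is degenerate (c = 0); use to_spherical for a sphere")
  pf <- to_frame_coords(points, spheroid)
  cc <- spheroid$c
  d1 <- sqrt(pf[, 1]^2 + pf[, 2]^2 + (pf[, 3] - cc)^2)
  d2 <- sqrt(pf[, 1]^2 + pf[, 2]^2 + (pf[, 3] + cc)^2)
  rmaj <- (d1 + d2) / 2
  costheta <- clamp1((d2 - d1) / (2 * cc))
  # theta measured from the +axis focus end: point at centre + a*axis has
  # d1 = a - c, d2 = a + c, so (d2 - d1)/(2c) = 1 -> theta = 0.
  theta <- acos(costheta)
  phi <- ifelse(pf[, 1] != 0 | pf[, 2] != 0, atan2(pf[, 2], pf[, 1]), 0)
  data.frame(rmaj = rmaj, theta = theta, phi = phi)
}

#' Prolate spheroidal to Cartesian coordinates
#'
#' Inverse of [to_prolate_spheroidal()] for the same reference spheroid.
#'
#' @param coords data.frame with columns `rmaj`, `theta`, `phi`.
#' @param spheroid A [reference_spheroid()].
#' @return k x 3 matrix of Cartesian points (m).
#' @export
spheroidal_to_cartesian <- function(coords, spheroid) {
  cc <- spheroid$c
  u <- coords$rmaj * cos(coords$theta)
  rho <- sqrt(pmax(coords$rmaj^2 - cc^2, 0)) * sin(coords$theta)
  pf <- cbind(rho * cos(coords$phi), rho * sin(coords$phi), u)
  from_frame_coords(pf, spheroid)
}

#' Fit a reference spheroid to a point cloud
#'
#' The major-axis direction is the leading principal component of the cloud;
#' the semi-axes are then fit in that frame. `least_squares` minimises the mean
#' squared algebraic residual `(u^2/a^2 + rho^2/b^2 - 1)^2`; `enclose` rescales
#' the least-squares shape to the smallest spheroid of that shape containing
#' every point.
#'
#' @param points k x 3 matrix (m), k >= 10, full-rank covariance.
#' @param mode `"least_squares"` (default) or `"enclose"`.
#' @return A [reference_spheroid()].
#' @export
fit_reference_spheroid <- function(points, mode = c("least_squares", "enclose")) {
  mode <- match.arg(mode)
  points <- rbind_points(points)
  if (nrow(points) < 10) stop("need at least 10 points to fit a spheroid")
  centre <- colMeans(points)
  pc <- sweep(points, 2, centre)
  cv <- crossprod(pc) / nrow(pc)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[3] < 1e-12 * ev$values[1])
    stop("degenerate point cloud: covariance rank < 3 (collinear or coplanar points)")
  axis <- ev$vectors[, 1]
  # deterministic sign: largest-magnitude component positive
  axis <- axis * sign(axis[which.max(abs(axis))])
  u <- as.numeric(pc %*% axis)
  rho <- sqrt(pmax(rowSums(pc^2) - u^2, 0))
  a0 <- max(abs(u)); b0 <- max(rho)
  obj <- function(lab) {
    a <- exp(lab[1]); b <- exp(lab[2])
    mean((u^2 / a^2 + rho^2 / b^2 - 1)^2)
  }
  fit <- stats::optim(log(c(a0, b0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  a <- exp(fit$par[1]); b <- exp(fit$par[2])
  if (b > a) b <- a # transverse spread exceeds axial: clamp to a sphere
  if (mode == "enclose") {
    s <- max(sqrt(u^2 / a^2 + rho^2 / b^2)) * (1 + 1e-12)
    a <- a * s; b <- b * s
  }
  reference_spheroid(centre = centre, axis = axis, a = a, b = min(b, a))
}

#' Complete a radial axis to an orthonormal sensor triad
#'
#' Given a unit radial direction `[p, q, r]`, the first tangential axis is the
#' normalised `[-q, p, 0]` (zero the third component, swap the first two and
#' negate the first, so the dot product with the original is exactly zero); the
#' second is the cross product of the radial and the first tangential axis,
#' giving a right-handed orthonormal triad. When the radial axis is `[0, 0,
#' +/-1]` the construction degenerates and `[1, 0, 0]` is used instead.
#'
#' @param radial Unit length-3 vector.
#' @return list with `tangential1` and `tangential2`, both unit length-3.
#' @export
complete_axes <- function(radial) {
  radial <- as.numeric(radial)
  stopifnot(length(radial) == 3)
  if (abs(sqrt(sum(radial^2)) - 1) > 1e-8)
    stop("radial axis must have unit norm")
  t1 <- c(-radial[2], radial[1], 0)
  n1 <- sqrt(sum(t1^2))
  if (n1 < 1e-12) {
    t1 <- c(1, 0, 0) # radial is [0, 0, +/-1]
  } else {
    t1 <- t1 / n1
  }
  t2 <- c(radial[2] * t1[3] - radial[3] * t1[2],
          radial[3] * t1[1] - radial[1] * t1[3],
          radial[1] * t1[2] - radial[2] * t1[1])
  t2 <- t2 / sqrt(sum(t2^2))
  list(tangential1 = t1, tangential2 = t2)
}

#' Construct a sensor array
#'
#' Validates and wraps channel geometry: one row per channel, channels of a
#' multi-axis sensor sharing a position and carrying mutually orthogonal unit
#' orientations.
#'
#' @param names Character channel identifiers.
#' @param positions n_c x 3 matrix (m).
#' @param orientations n_c x 3 matrix of unit vectors.
#' @param axes_per_sensor 1, 2 or 3 measurement axes per physical sensor.
#' @param sensor_index Integer parent-sensor id per channel.
#' @return Object of class `sensor_array`.
#' @export
sensor_array <- function(names, positions, orientations, axes_per_sensor,
                         sensor_index) {
  positions <- rbind_points(positions)
  orientations <- rbind_points(orientations)
  n_c <- nrow(positions)
  stopifnot(length(names) == n_c, nrow(orientations) == n_c,
            length(sensor_index) == n_c, axes_per_sensor %in% 1:3)
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-10))
    stop("orientation rows must have unit norm (max deviation ",
         format(max(abs(nrm - 1))), ")")
  for (s in unique(sensor_index)) {
    idx <- which(sensor_index == s)
    if (length(idx) > 1) {
      if (max(abs(sweep(positions[idx, , drop = FALSE], 2,
                        positions[idx[1], ]))) > 1e-12)
        stop("channels of sensor ", s, " do not share a position")
      G <- orientations[idx, , drop = FALSE] %*% t(orientations[idx, , drop = FALSE])
      if (max(abs(G - diag(length(idx)))) > 1e-10)
        stop("within-sensor orientations of sensor ", s, " are not orthonormal")
    }
  }
  structure(
    list(names = as.character(names), positions = positions,
         orientations = orientations, axes_per_sensor = as.integer(axes_per_sensor),
         sensor_index = as.integer(sensor_index)),
    class = "sensor_array"
  )
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d channels (%d sensors x %d axes)\n",
              n_channels(x), length(unique(x$sensor_index)), x$axes_per_sensor))
  invisible(x)
}

#' Number of channels in a sensor array
#' @param array A `sensor_array`.
#' @return Integer channel count.
#' @export
n_channels <- function(array) nrow(array$positions)

# Evaluate with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Quasi-uniform unit-sphere directions (Fibonacci lattice), n points.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  rho <- sqrt(pmax(1 - z^2, 0))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# Map unit-sphere directions (spheroid-frame coords) onto the spheroid surface
# and return frame coordinates plus outward unit normals (frame coords).
sphere_to_spheroid_surface <- function(dirs, a, b) {
  pf <- cbind(b * dirs[, 1], b * dirs[, 2], a * dirs[, 3])
  nf <- cbind(pf[, 1] / b^2, pf[, 2] / b^2, pf[, 3] / a^2)
  nf <- nf / sqrt(rowSums(nf^2))
  list(points = pf, normals = nf)
}

#' Generate a scalp-conformal OPM sensor array
#'
#' Sensors are packed quasi-uniformly on the reference (scalp) spheroid surface
#' (Fibonacci lattice seeding followed by Poisson-disk thinning at the
#' requested spacing) and then displaced outward along the local surface
#' normal by a stand-off `offset` (default 6.5 mm, a typical OPM cell-to-scalp
#' distance). The first channel of every sensor measures along the outward
#' normal; second and third axes (if requested) are built with
#' [complete_axes()].
#'
#' @param spheroid Scalp [reference_spheroid()].
#' @param spacing Minimum inter-sensor separation (m).
#' @param offset Outward sensor stand-off from the scalp surface (m).
#' @param axes Measurement axes per sensor (1 = radial only, 2 = + first
#'   tangential, 3 = full triaxial).
#' @param seed Integer seed; the packing is deterministic given the seed.
#' @return A [sensor_array()] with `axes * n_sensors` channels.
#' @export
generate_scalp_array <- function(spheroid, spacing, offset = 0.0065,
                                 axes = 1, seed = 1) {
  stopifnot(spacing > 0, offset >= 0, axes %in% 1:3)
  a <- spheroid$a; b <- spheroid$b
  if (spacing > 2 * a)
    stop("spacing ", spacing, " m is larger than the reference surface; no sensors placed")
  # candidate budget: several candidates per final sensor site
  area <- 4 * pi * (a * b^2)^(2 / 3) # sphere of equal volume, adequate scale
  n_cand <- max(800L, min(6000L, as.integer(8 * area / spacing^2)))
  dirs <- fibonacci_sphere(n_cand)
  ord <- with_seed(seed, sample.int(n_cand))
  surf <- sphere_to_spheroid_surface(dirs[ord, , drop = FALSE], a, b)
  pts <- surf$points
  keep <- integer(0)
  sp2 <- spacing^2
  for (i in seq_len(n_cand)) {
    if (length(keep) == 0L) {
      keep <- i
    } else {
      d2 <- (pts[keep, 1] - pts[i, 1])^2 + (pts[keep, 2] - pts[i, 2])^2 +
        (pts[keep, 3] - pts[i, 3])^2
      if (min(d2) >= sp2) keep <- c(keep, i)
    }
  }
  if (length(keep) == 0L)
    stop("spacing ", spacing, " m is larger than the reference surface; no sensors placed")
  pf <- pts[keep, , drop = FALSE]
  nf <- surf$normals[keep, , drop = FALSE]
  pos_sensor <- from_frame_coords(pf + offset * nf, spheroid)
  R <- spheroid_frame(spheroid)
  normals <- nf %*% t(R) # global coords
  n_s <- nrow(pos_sensor)
  suffix <- c("RAD", "TAN1", "TAN2")[seq_len(axes)]
  names <- character(0); positions <- NULL; orientations <- NULL; sensor_index <- integer(0)
  for (s in seq_len(n_s)) {
    rad <- normals[s, ] / sqrt(sum(normals[s, ]^2))
    oris <- rad
    if (axes >= 2) {
      t12 <- complete_axes(rad)
      oris <- rbind(oris, t12$tangential1)
      if (axes == 3) oris <- rbind(oris, t12$tangential2)
    }
    oris <- matrix(oris, ncol = 3)
    k <- nrow(oris)
    names <- c(names, sprintf("S%03d-%s", s, suffix[seq_len(k)]))
    positions <- rbind(positions, matrix(pos_sensor[s, ], k, 3, byrow = TRUE))
    orientations <- rbind(orientations, oris)
    sensor_index <- c(sensor_index, rep(s, k))
  }
  sensor_array(names, positions, orientations, axes_per_sensor = axes,
               sensor_index = sensor_index)
}

#' Generate an array with (approximately) a target channel count
#'
#' Bisects the inter-sensor spacing so that `axes * n_sensors` is as close as
#' possible to `n_channels`.
#'
#' @param spheroid Scalp [reference_spheroid()].
#' @param n_target Desired channel count.
#' @param axes Axes per sensor.
#' @param offset Sensor stand-off (m).
#' @param seed Packing seed.
#' @param tol Accept when within `tol` channels of the target.
#' @return A [sensor_array()].
#' @export
array_with_channel_count <- function(spheroid, n_target, axes = 3,
                                     offset = 0.0065, seed = 1, tol = 2L) {
  lo <- 0.008; hi <- 0.09
  best <- NULL; best_gap <- Inf
  for (it in 1:24) {
    mid <- (lo + hi) / 2
    arr <- generate_scalp_array(spheroid, spacing = mid, offset = offset,
                                axes = axes, seed = seed)
    n <- n_channels(arr)
    gap <- abs(n - n_target)
    if (gap < best_gap) { best <- arr; best_gap <- gap }
    if (gap <= tol) break
    if (n > n_target) lo <- mid else hi <- mid
  }
  best
}
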