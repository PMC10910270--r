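# Real spherical harmonics, prolate spheroidal radial ratios and assembly of
# the channels x harmonics basis matrices.
#
# The magnetic scalar potential is expanded in solid harmonics of an internal
# (decaying with distance from the reference surface; brain) and an external
# (growing; environmental interference) family. Each basis column is the field
# component along a channel's orientation, i.e. the directional derivative of
# the potential at the channel position. The vacuum permeability and overall
# sign are absorbed into the per-column normalisation scales.

# Associated Legendre P_l^m(x) on [-1, 1], vectorised in x, without the
# Condon-Shortley phase (the (-1)^m of the real-harmonic definition is applied
# explicitly by real_sph_harm).
assoc_legendre <- function(l, m, x) {
  stopifnot(m >= 0, m <= l)
  # P_m^m = (2m-1)!! (1-x^2)^{m/2}
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(1 - x^2, 0))
    pmm <- prod(seq(1, 2 * m - 1, by = 2)) * somx2^m
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    pll <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pmmp1
}

#' Real spherical harmonic S_lm
#'
#' Orthonormal real surface harmonics: the `m = 0` zonal term is
#' `sqrt((2l+1)/(4*pi)) P_l(cos(theta))`; positive orders carry
#' `cos(m*phi)` and negative orders `sin(|m|*phi)`, both with the
#' `sqrt((2l+1)/(2*pi) * (l-|m|)!/(l+|m|)!)` normalisation and the `(-1)^m`
#' phase factor.
#'
#' @param l Degree, integer >= 0.
#' @param m Order, integer with |m| <= l.
#' @param theta Co-latitude (rad), vectorised.
#' @param phi Longitude (rad), vectorised.
#' @return Numeric vector of harmonic values.
#' @export
real_sph_harm <- function(l, m, theta, phi) {
  if (abs(m) > l) stop("|m| must not exceed l (got l=", l, ", m=", m, ")")
  am <- abs(m)
  x <- cos(theta)
  P <- assoc_legendre(l, am, x)
  if (m == 0) {
    sqrt((2 * l + 1) / (4 * pi)) * P
  } else {
    norm <- (-1)^am * sqrt((2 * l + 1) / (2 * pi) *
                             exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
    if (m > 0) norm * P * cos(am * phi) else norm * P * sin(am * phi)
  }
}

#' Internal (second-kind) prolate spheroidal radial ratio
#'
#' Ratio of associated Legendre functions of the second kind,
#' `Q_lm(rmaj/c) / Q_lm(a/c)`, evaluated through the hypergeometric-type
#' series in `(c/rmaj)^2`, truncated when the next term's relative
#' contribution drops below `tol`; gamma factors cancel between numerator and
#' denominator series and the remaining prefactor is computed in closed form.
#' Normalised to 1 on the reference surface (`rmaj = a`) and tending to the
#' spherical decay `(a/rmaj)^(l+1)` as the focal distance vanishes.
#'
#' @param l Degree >= 0; @param m Order 0..l.
#' @param rmaj Major-axis coordinate(s), `rmaj > c` (m).
#' @param c Focal distance (m), `c >= 0`; @param a Reference semi-major axis.
#' @param tol Relative truncation tolerance of the series.
#' @param kmax Hard cap on the number of series terms.
#' @return Numeric vector of ratios (1 at `rmaj = a`).
#' @export
q_ratio <- function(l, m, rmaj, c, a, tol = 1e-12, kmax = 200L) {
  stopifnot(m >= 0, m <= l, a > c, c >= 0, all(rmaj > c), tol > 0)
  pref <- (rmaj / a)^(-l - m - 1) *
    ((rmaj^2 - c^2) / (a^2 - c^2))^(m / 2)
  if (c == 0) return(pref) # series is identically 1 term
  s_num <- q_series(l, m, (c / rmaj)^2, tol, kmax)
  s_den <- q_series(l, m, (c / a)^2, tol, kmax)
  pref * s_num / s_den
}

# Sum_k [((l+m+1)/2)_k ((l+m+2)/2)_k / ((l+3/2)_k k!)] t2^k, t2 = (c/r)^2 < 1.
# Leading gamma constants are dropped (they cancel in the ratio).
q_series <- function(l, m, t2, tol, kmax) {
  s <- rep(1, length(t2))
  term <- rep(1, length(t2))
  a1 <- (l + m + 1) / 2; a2 <- (l + m + 2) / 2; b1 <- l + 3 / 2
  for (k in 0:(kmax - 1)) {
    term <- term * ((a1 + k) * (a2 + k)) / ((b1 + k) * (k + 1)) * t2
    s <- s + term
    if (max(abs(term) / abs(s)) < tol) return(s)
  }
  stop(sprintf(
    "q_ratio series did not converge within %d terms (l=%d, m=%d, max c/rmaj=%.4f)",
    kmax, l, m, sqrt(max(t2))))
}

#' External (first-kind) prolate spheroidal radial ratio
#'
#' Ratio of associated Legendre functions of the first kind,
#' `P_lm(rmaj/c) / P_lm(a/c)`, via the finite alternating series with upper
#' index `floor((l - m)/2)`. Normalised to 1 on the reference surface and
#' tending to the spherical growth `(rmaj/a)^l` as the focal distance
#' vanishes.
#'
#' @inheritParams q_ratio
#' @return Numeric vector of ratios (1 at `rmaj = a`).
#' @export
p_ratio <- function(l, m, rmaj, c, a) {
  stopifnot(m >= 0, m <= l, a > c, c >= 0, all(rmaj > c))
  pref <- (rmaj / a)^(l - m) * ((rmaj^2 - c^2) / (a^2 - c^2))^(m / 2)
  if (c == 0) return(pref)
  pref * p_series(l, m, (c / rmaj)^2) / p_series(l, m, (c / a)^2)
}

# Finite sum_k (-1)^k (2l-2k)! / (k! (l-k)! (l-2k-m)!) t2^k, k = 0..floor((l-m)/2).
p_series <- function(l, m, t2) {
  kk <- 0:((l - m) %/% 2)
  coef <- (-1)^kk * exp(lgamma(2 * l - 2 * kk + 1) - lgamma(kk + 1) -
                          lgamma(l - kk + 1) - lgamma(l - 2 * kk - m + 1))
  drop(outer(t2, kk, `^`) %*% coef)
}

#' Scalar-potential value of one solid harmonic
#'
#' Evaluates a single internal or external solid harmonic of either the
#' spherical or the prolate spheroidal family at arbitrary points, in the
#' frame of a reference spheroid. The spherical family uses
#' `(a/r)^(l+1) S_lm` (internal) and `(r/a)^l S_lm` (external) about the
#' spheroid centre with the spheroid axis as pole; the spheroidal family
#' replaces the radial power laws by the Legendre-function ratios of
#' [q_ratio()] and [p_ratio()]. Negative orders use the sine convention of
#' [real_sph_harm()] with radial ratios evaluated at `|m|`. Permeability and
#' overall sign are absorbed into basis column scales.
#'
#' @param kind `"internal"` or `"external"`.
#' @param family `"spherical"` or `"spheroidal"`.
#' @param l Degree >= 1 for field-generating harmonics (l = 0 permitted here).
#' @param m Order, |m| <= l.
#' @param points k x 3 matrix (m), strictly outside the focal segment.
#' @param frame A [reference_spheroid()].
#' @return Numeric vector of potential values (arbitrary scale).
#' @export
potential_value <- function(kind = c("internal", "external"),
                            family = c("spherical", "spheroidal"),
                            l, m, points, frame) {
  kind <- match.arg(kind); family <- match.arg(family)
  if (abs(m) > l) stop("|m| must not exceed l")
  if (family == "spherical" || frame$c <= 0) {
    pf <- to_frame_coords(points, frame)
    co <- to_spherical(pf, origin = c(0, 0, 0))
    radial <- if (kind == "internal") (frame$a / co$r)^(l + 1) else (co$r / frame$a)^l
  } else {
    co <- to_prolate_spheroidal(points, frame)
    radial <- if (kind == "internal")
      q_ratio(l, abs(m), co$rmaj, frame$c, frame$a)
    else
      p_ratio(l, abs(m), co$rmaj, frame$c, frame$a)
  }
  radial * real_sph_harm(l, m, co$theta, co$phi)
}

#' Assemble a channels x harmonics basis matrix
#'
#' For every harmonic (internal degrees `1..L_in`, external degrees
#' `1..L_out`, all orders) the column entry at channel `i` is the directional
#' derivative of the scalar potential along the channel orientation at the
#' channel position, computed by central finite differences with step
#' `grad_step`. Columns are ordered internal-first by `(l, m)` and normalised
#' to unit Euclidean norm with the scales recorded, so that fitted data stay
#' in Tesla.
#'
#' @param array A [sensor_array()].
#' @param frame A [reference_spheroid()] defining the expansion frame.
#' @param family Radial family of the internal block: `"spheroidal"`
#'   (default) or `"spherical"`.
#' @param L_in Internal maximum degree (default 9, giving `9^2 + 2*9 = 99`
#'   internal columns).
#' @param L_out External maximum degree (default 2, giving 8 external
#'   columns spanning homogeneous fields and first-order gradients).
#' @param external_family Radial family of the external block; defaults to
#'   `"spherical"`, whose degree-2 block spans exactly the physical
#'   homogeneous-field + first-order-gradient interference model.
#' @param grad_step Finite-difference step (m); default `1e-6 * a`.
#' @return Object of class `harmonic_basis`: fields `matrix` (n_c x n_h,
#'   unit-norm columns), `meta` (data.frame kind/l/m/family), `scales`
#'   (pre-normalisation column norms), `frame`, `channel_names`.
#' @export
build_basis <- function(array, frame, family = c("spheroidal", "spherical"),
                        L_in = 9, L_out = 2,
                        external_family = c("spherical", "spheroidal"),
                        grad_step = NULL) {
  family <- match.arg(family); external_family <- match.arg(external_family)
  stopifnot(L_in >= 1, L_out >= 1)
  if (is.null(grad_step)) grad_step <- 1e-6 * frame$a
  pos <- array$positions
  n_c <- nrow(pos)
  # interior-sampling warning for the internal block
  if (family == "spheroidal" && frame$c > 0) {
    rm_ <- to_prolate_spheroidal(pos, frame)$rmaj
    if (any(rm_ < frame$a))
      warning(sum(rm_ < frame$a),
              " channel(s) lie inside the reference spheroid; the internal",
              " expansion may converge poorly there")
  } else {
    rr <- to_spherical(to_frame_coords(pos, frame), c(0, 0, 0))$r
    if (any(rr < frame$a))
      warning(sum(rr < frame$a),
              " channel(s) lie inside the reference sphere; the internal",
              " expansion may converge poorly there")
  }
  # 6 shifted point sets for central differences
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)) * grad_step
  shifted <- lapply(seq_len(6), function(j) sweep(pos, 2, shifts[j, ], `+`))
  # precompute coordinates per family actually used
  fams <- unique(c(family, external_family))
  coords <- list()
  for (fm in fams) {
    coords[[fm]] <- lapply(shifted, function(p) {
      if (fm == "spherical" || frame$c <= 0) {
        pf <- to_frame_coords(p, frame)
        to_spherical(pf, c(0, 0, 0))
      } else {
        to_prolate_spheroidal(p, frame)
      }
    })
  }
  eval_col <- function(kind, fm, l, m) {
    V <- matrix(0, n_c, 6)
    for (j in 1:6) {
      co <- coords[[fm]][[j]]
      if (fm == "spherical" || frame$c <= 0) {
        radial <- if (kind == "internal") (frame$a / co$r)^(l + 1) else (co$r / frame$a)^l
      } else {
        radial <- if (kind == "internal")
          q_ratio(l, abs(m), co$rmaj, frame$c, frame$a)
        else
          p_ratio(l, abs(m), co$rmaj, frame$c, frame$a)
      }
      V[, j] <- radial * real_sph_harm(l, m, co$theta, co$phi)
    }
    g <- cbind((V[, 1] - V[, 2]), (V[, 3] - V[, 4]), (V[, 5] - V[, 6])) /
      (2 * grad_step)
    rowSums(array$orientations * g)
  }
  meta <- list(); cols <- list(); k <- 0
  for (l in seq_len(L_in)) for (m in -l:l) {
    k <- k + 1
    cols[[k]] <- eval_col("internal", family, l, m)
    meta[[k]] <- data.frame(kind = "internal", l = l, m = m, family = family)
  }
  for (l in seq_len(L_out)) for (m in -l:l) {
    k <- k + 1
    cols[[k]] <- eval_col("external", external_family, l, m)
    meta[[k]] <- data.frame(kind = "external", l = l, m = m,
                            family = external_family)
  }
  H <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  scales <- sqrt(colSums(H^2))
  if (any(scales == 0)) stop("zero-norm basis column encountered")
  H <- sweep(H, 2, scales, `/`)
  structure(
    list(matrix = H, meta = meta, scales = scales, frame = frame,
         channel_names = array$names),
    class = "harmonic_basis"
  )
}

#' @export
print.harmonic_basis <- function(x, ...) {
  cat(sprintf(
    "<harmonic_basis> %d channels x %d harmonics (%d internal [%s], %d external [%s])\n",
    nrow(x$matrix), ncol(x$matrix),
    sum(x$meta$kind == "internal"), x$meta$family[x$meta$kind == "internal"][1],
    sum(x$meta$kind == "external"), x$meta$family[x$meta$kind == "external"][1]))
  invisible(x)
}

#' Internal and external blocks of a harmonic basis
#' @param basis A `harmonic_basis`.
#' @return Numeric matrix of the requested columns.
#' @export
basis_internal <- function(basis) basis$matrix[, basis$meta$kind == "internal", drop = FALSE]

#' @rdname basis_internal
#' @export
basis_external <- function(basis) basis$matrix[, basis$meta$kind == "external", drop = FALSE]
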