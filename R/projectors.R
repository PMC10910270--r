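# Interference-rejection projectors built from a harmonic basis.
#
# SSS fits the full harmonic model and keeps the internal part: an oblique
# projector that reproduces the internal span exactly but can amplify noise
# when internal and external spans are poorly separated. AMM keeps only the
# internal components orthogonal to the external span: a symmetric idempotent
# (orthogonal) projector that never increases variance.

#' Truncated SVD pseudoinverse
#'
#' Moore-Penrose pseudoinverse discarding singular values below
#' `rtol * sigma_max`.
#'
#' @param M p x q numeric matrix.
#' @param rtol Relative truncation tolerance (default 1e-10).
#' @return q x p matrix. The number of retained singular values is attached as
#'   attribute `"rank"`.
#' @export
regularized_pinv <- function(M, rtol = 1e-10) {
  stopifnot(rtol >= 0)
  sv <- svd(M)
  keep <- sv$d > rtol * max(sv$d, 0)
  r <- sum(keep)
  out <- if (r == 0) {
    matrix(0, ncol(M), nrow(M))
  } else {
    sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  }
  attr(out, "rank") <- r
  out
}

new_projector <- function(matrix, ptype, rank, basis_meta = NULL) {
  structure(list(matrix = matrix, ptype = ptype, rank = as.integer(rank),
                 basis_meta = basis_meta),
            class = "field_projector")
}

#' @export
print.field_projector <- function(x, ...) {
  cat(sprintf("<field_projector> %s, %d x %d, rank %d\n",
              x$ptype, nrow(x$matrix), ncol(x$matrix), x$rank))
  invisible(x)
}

#' Orthogonal rejector of the external space
#'
#' `R_out = I - H_out H_out^+`: the orthogonal projector onto the complement
#' of the external (interference) span. Annihilates every interference
#' topography representable by the external model.
#'
#' @param basis A [build_basis()] result containing an external block.
#' @param rtol Pseudoinverse truncation tolerance.
#' @return A `field_projector` with `ptype = "orthogonal"`.
#' @export
external_rejector <- function(basis, rtol = 1e-10) {
  Hout <- basis_external(basis)
  if (ncol(Hout) == 0) stop("basis has no external block")
  n_c <- nrow(Hout)
  Hp <- regularized_pinv(Hout, rtol)
  R <- diag(n_c) - Hout %*% Hp
  R <- (R + t(R)) / 2
  new_projector(R, "orthogonal", n_c - attr(Hp, "rank"), basis$meta)
}

#' SSS-style oblique projector onto the internal space
#'
#' `P = H_in (R_out H_in)^+` applied to the data reproduces the full-model
#' least-squares internal reconstruction in a single oblique projection
#' (partitioned-coefficient identity): it preserves every internal-span
#' topography exactly (`P H_in = H_in`) and annihilates the external span
#' (`P H_out = 0`), but is not symmetric and can amplify white noise when the
#' combined basis is poorly conditioned.
#'
#' @param basis A [build_basis()] result.
#' @param rtol Pseudoinverse truncation tolerance (no additional
#'   regularisation is applied by default).
#' @param cond_ceiling Combined-basis condition number above which a warning
#'   is issued (the fit proceeds regardless).
#' @return A `field_projector` with `ptype = "oblique"`.
#' @export
sss_projector <- function(basis, rtol = 1e-10, cond_ceiling = 1e8) {
  Hin <- basis_internal(basis)
  Hout <- basis_external(basis)
  n_c <- nrow(Hin)
  if (n_c < ncol(Hin) + ncol(Hout))
    warning("channel count (", n_c, ") below harmonic count (",
            ncol(Hin) + ncol(Hout), "); SSS fit is underdetermined")
  d <- svd(cbind(Hin, Hout), nu = 0, nv = 0)$d
  kappa <- d[1] / d[length(d)]
  if (!is.finite(kappa) || kappa > cond_ceiling)
    warning(sprintf("combined basis condition number %.3g exceeds %.3g; the oblique SSS projection may be unstable",
                    kappa, cond_ceiling))
  Rout <- external_rejector(basis, rtol)$matrix
  Ap <- regularized_pinv(Rout %*% Hin, rtol)
  P <- Hin %*% Ap
  new_projector(P, "oblique", attr(Ap, "rank"), basis$meta)
}

#' AMM orthogonal projector onto the interference-free internal space
#'
#' `P = (R_out H_in)(R_out H_in)^+`: the orthogonal projector onto the part of
#' the internal span orthogonal to the external span. Symmetric, idempotent
#' and norm-non-increasing for every input, hence stable on any array design;
#' the price is that internal topographies spatially correlated with
#' interference are attenuated.
#'
#' @inheritParams sss_projector
#' @return A `field_projector` with `ptype = "orthogonal"`.
#' @export
amm_projector <- function(basis, rtol = 1e-10) {
  Hin <- basis_internal(basis)
  Rout <- external_rejector(basis, rtol)$matrix
  A <- Rout %*% Hin
  Ap <- regularized_pinv(A, rtol)
  P <- A %*% Ap
  P <- (P + t(P)) / 2
  new_projector(P, "orthogonal", attr(Ap, "rank"), basis$meta)
}

#' Apply a projector to a recording or matrix
#'
#' Matrix product preserving metadata: recordings keep channel names and
#' sampling rate (units unchanged, Tesla); lead-field sets keep source
#' metadata; plain matrices are returned as matrices.
#'
#' @param P A `field_projector`.
#' @param X A [recording()], a `lead_field_set` or an n_c x k matrix.
#' @return Same type as `X`.
#' @export
apply_projector <- function(P, X) {
  M <- P$matrix
  if (inherits(X, "opm_recording")) {
    if (nrow(X$data) != ncol(M))
      stop("dimension mismatch: projector is ", nrow(M), " x ", ncol(M),
           ", recording has ", nrow(X$data), " channels")
    out <- X
    out$data <- M %*% X$data
    out
  } else if (inherits(X, "lead_field_set")) {
    if (nrow(X$matrix) != ncol(M))
      stop("dimension mismatch: projector is ", nrow(M), " x ", ncol(M),
           ", lead fields have ", nrow(X$matrix), " channels")
    out <- X
    out$matrix <- M %*% X$matrix
    out
  } else {
    X <- as.matrix(X)
    if (nrow(X) != ncol(M))
      stop("dimension mismatch: projector is ", nrow(M), " x ", ncol(M),
           ", input is ", nrow(X), " x ", ncol(X))
    M %*% X
  }
}

#' Conditioning diagnostics of a harmonic basis
#'
#' Condition numbers of the internal, external and combined blocks, and the
#' principal angles between the internal and external spans. Near-zero minimum
#' principal angles flag array designs on which the oblique SSS fit is
#' unstable.
#'
#' @param basis A [build_basis()] result.
#' @return List with `cond_in`, `cond_out`, `cond_joint` and
#'   `principal_angles` (radians, in `[0, pi/2]`, decreasing).
#' @export
condition_report <- function(basis) {
  Hin <- basis_internal(basis)
  Hout <- basis_external(basis)
  kap <- function(M) {
    d <- svd(M, nu = 0, nv = 0)$d
    if (d[length(d)] <= 1e-300 * d[1]) Inf else d[1] / d[length(d)]
  }
  Qin <- qr.Q(qr(Hin))
  Qout <- qr.Q(qr(Hout))
  sv <- svd(crossprod(Qin, Qout), nu = 0, nv = 0)$d
  list(cond_in = kap(Hin), cond_out = kap(Hout),
       cond_joint = kap(cbind(Hin, Hout)),
       principal_angles = acos(clamp1(sv)))
}

#' Construct a multichannel recording
#'
#' @param data n_c x n_t numeric matrix (Tesla).
#' @param fs Sampling rate (Hz), > 0.
#' @param names Channel identifiers, length n_c.
#' @return Object of class `opm_recording`.
#' @export
recording <- function(data, fs, names = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(fs), fs > 0)
  if (is.null(names)) names <- sprintf("CH%03d", seq_len(nrow(data)))
  if (length(names) != nrow(data))
    stop("names length (", length(names), ") does not match channel count (",
         nrow(data), ")")
  structure(list(data = data, fs = as.numeric(fs), names = as.character(names)),
            class = "opm_recording")
}

#' @export
print.opm_recording <- function(x, ...) {
  cat(sprintf("<opm_recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}
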