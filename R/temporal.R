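# Temporal stage: inner/outer/intermediate decomposition, CCA-based cleaning
# and the correlation-limit heuristic.
#
# Residual interference that leaks past the spatial projector (through sensor
# nonlinearity or model truncation) appears simultaneously in the inner space
# and in the intermediate space (the part of the data neither the internal nor
# the external model explains). Temporal components that are near-perfectly
# correlated between the two are therefore removed, with the correlation limit
# chosen from a closed-form bound on the correlation brain signal alone could
# produce by chance.

#' Decompose a recording into inner, outer and intermediate spaces
#'
#' `inner = P_amm Y` (internal components orthogonal to interference),
#' `outer = H_out H_out^+ Y` (interference and any internal signal spatially
#' correlated with it), `inter = Y - inner - outer` (everything of higher
#' spatial order than either model). The three parts sum to the input by
#' construction and the inner and outer images are mutually orthogonal.
#'
#' @param Y A [recording()] (or n_c x n_t matrix).
#' @param basis A [build_basis()] result with matching channel count.
#' @param rtol Pseudoinverse truncation tolerance.
#' @return List of class `space_decomposition` with `inner`, `outer`, `inter`
#'   matrices and the sampling rate.
#' @export
decompose_spaces <- function(Y, basis, rtol = 1e-10) {
  dat <- if (inherits(Y, "opm_recording")) Y$data else as.matrix(Y)
  fs <- if (inherits(Y, "opm_recording")) Y$fs else NA_real_
  if (nrow(dat) != nrow(basis$matrix))
    stop("dimension mismatch: recording has ", nrow(dat),
         " channels, basis has ", nrow(basis$matrix))
  Pamm <- amm_projector(basis, rtol)$matrix
  Hout <- basis_external(basis)
  Pout <- Hout %*% regularized_pinv(Hout, rtol)
  inner <- Pamm %*% dat
  outer <- Pout %*% dat
  structure(list(inner = inner, outer = outer, inter = dat - inner - outer,
                 fs = fs),
            class = "space_decomposition")
}

# Orthonormal temporal basis (rows of t(v)) of X, dropping directions with
# singular value <= rtol * sigma_max.
temporal_basis <- function(X, rtol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > rtol * max(sv$d, 0)
  sv$v[, keep, drop = FALSE]
}

#' CCA-based temporal cleaning of the inner space
#'
#' Within each window, orthonormal temporal bases of the inner and
#' intermediate spaces are computed by SVD; their canonical correlations are
#' the singular values of the product of the two bases. Every canonical
#' temporal direction whose correlation reaches `limit` is treated as
#' residual interference and projected out of the inner-space data. The
#' returned recording is the cleaned inner space (the spatially and
#' temporally filtered output).
#'
#' @param Y A [recording()].
#' @param basis A [build_basis()] result.
#' @param limit Correlation limit in (0, 1]; default 0.98.
#' @param window_s Window length in seconds; `NULL` (default) uses the whole
#'   recording as a single window.
#' @param rtol Rank-truncation tolerance for the temporal bases.
#' @return List of class `temporal_clean` with `cleaned` (a [recording()])
#'   and `report` (data.frame: window, component, correlation, removed).
#' @export
temporal_clean <- function(Y, basis, limit = 0.98, window_s = NULL,
                           rtol = 1e-10) {
  stopifnot(inherits(Y, "opm_recording"))
  if (!(limit > 0 && limit <= 1)) stop("limit must lie in (0, 1]")
  n_t <- ncol(Y$data)
  win <- if (is.null(window_s) || window_s <= 0) n_t
         else as.integer(round(window_s * Y$fs))
  if (win < 2) stop("window must contain at least 2 samples")
  if (win > n_t) stop("window (", win, " samples) exceeds recording length (",
                      n_t, ")")
  dec <- decompose_spaces(Y, basis)
  starts <- seq(1, n_t, by = win)
  cleaned <- dec$inner
  rep_rows <- list()
  for (w in seq_along(starts)) {
    idx <- starts[w]:min(starts[w] + win - 1, n_t)
    if (length(idx) < 2) next
    Vin <- temporal_basis(dec$inner[, idx, drop = FALSE], rtol)
    Vinter <- temporal_basis(dec$inter[, idx, drop = FALSE], rtol)
    if (ncol(Vin) == 0 || ncol(Vinter) == 0) next
    cc <- svd(crossprod(Vin, Vinter))
    rho <- clamp1(cc$d)
    removed <- rho >= limit
    if (any(removed)) {
      # canonical temporal directions on the inner side
      W <- Vin %*% cc$u[, removed, drop = FALSE] # |idx| x k, orthonormal
      block <- cleaned[, idx, drop = FALSE]
      cleaned[, idx] <- block - (block %*% W) %*% t(W)
    }
    rep_rows[[w]] <- data.frame(window = w, component = seq_along(rho),
                                correlation = rho, removed = removed)
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows)
            else data.frame(window = integer(0), component = integer(0),
                            correlation = numeric(0), removed = logical(0))
  structure(list(cleaned = recording(cleaned, Y$fs, Y$names), report = report),
            class = "temporal_clean")
}

#' Upper bound on the inner-intermediate canonical correlation
#'
#' Closed-form heuristic for the largest temporal correlation brain signal
#' alone can produce between the inner and intermediate spaces:
#' `rho_max = alpha * beta / sqrt((beta^2 + k) (alpha^2 + k))` with
#' `k = T * sigma_e2 / (tau * sigma_x2 * n_c)`. `alpha` and `beta_frac` are
#' the fractions of neural signal amplitude present in the inner and
#' intermediate spaces, `T` the analysis window (s), `tau` the time scale over
#' which neural activity stays correlated (s; 0.25 s is typical of an evoked
#' response), `sigma_x2` / `sigma_e2` the signal and white-noise variances and
#' `n_c` the channel count. Setting the cleaning limit at or above this value
#' minimises the risk of removing brain signal by chance. Monotone decreasing
#' in `k`; equal to 1 in the noiseless limit; 0 when either fraction is 0
#' (and, by continuity convention, when `sigma_x2 = 0`).
#'
#' @param alpha Fraction of neural signal in the inner space (0-1).
#' @param beta_frac Fraction of neural signal in the intermediate space (0-1).
#' @param T_s Window length (s).
#' @param tau Neural correlation time (s), `tau <= T_s`; default 0.25.
#' @param sigma_x2 Signal variance.
#' @param sigma_e2 White-noise variance.
#' @param n_c Channel count.
#' @return Scalar correlation bound in `[0, 1]`.
#' @export
correlation_limit <- function(alpha, beta_frac, T_s, tau = 0.25,
                              sigma_x2 = 1, sigma_e2 = 1, n_c = 100) {
  stopifnot(alpha >= 0, beta_frac >= 0, T_s > 0, tau > 0, tau <= T_s,
            sigma_x2 >= 0, sigma_e2 >= 0, n_c >= 1)
  if (alpha == 0 || beta_frac == 0) return(0)
  if (sigma_x2 == 0) return(0) # continuity convention: k -> Inf
  k <- (T_s * sigma_e2) / (tau * sigma_x2 * n_c)
  alpha * beta_frac / sqrt((beta_frac^2 + k) * (alpha^2 + k))
}
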