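# Quantitative read-outs: lead-field reconstruction correlation, white-noise
# reduction, PSD shielding, band-pass filtering, epoching and t-statistics.

#' Correlation between lead fields and their projected versions
#'
#' `cosine` mode: `|<l, P l>| / (||l|| ||P l||)`. `sqrt_ve` mode: the square
#' root of variance explained, `sqrt(max(0, 1 - ||l - P l||^2 / ||l||^2))`.
#' For an orthogonal projector the two coincide. Values near 1 mean the
#' projector preserves that source's topography; zero-norm lead fields are
#' flagged `NaN` with a warning.
#'
#' @param L A `lead_field_set` (or n_c x n_src matrix).
#' @param P A `field_projector`.
#' @param mode `"cosine"` or `"sqrt_ve"`.
#' @return Numeric n_src vector in `[0, 1]` (or NaN).
#' @export
leadfield_correlation <- function(L, P, mode = c("cosine", "sqrt_ve")) {
  mode <- match.arg(mode)
  M <- if (inherits(L, "lead_field_set")) L$matrix else as.matrix(L)
  if (nrow(M) != ncol(P$matrix))
    stop("dimension mismatch between lead fields and projector")
  PL <- P$matrix %*% M
  nl <- sqrt(colSums(M^2))
  zero <- nl == 0
  if (any(zero)) warning(sum(zero), " zero-norm lead field(s); returning NaN")
  out <- if (mode == "cosine") {
    npl <- sqrt(colSums(PL^2))
    abs(colSums(M * PL)) / (nl * npl)
  } else {
    sqrt(pmax(0, 1 - colSums((M - PL)^2) / nl^2))
  }
  out[zero] <- NaN
  pmin(out, 1)
}

#' White-noise reduction factor of a projector
#'
#' Mean over repeated iid Gaussian noise draws of
#' `20 log10(sigma_noise / sigma_projected)`, with the projected standard
#' deviation pooled over channels and samples. Positive values mean the
#' projector reduces white noise; an oblique projector on a poorly conditioned
#' basis can return negative values (no clamping).
#'
#' @param P A `field_projector`.
#' @param n_t Samples per draw.
#' @param reps Number of noise draws (>= 10).
#' @param sigma Noise standard deviation.
#' @param seed Integer seed.
#' @return Scalar reduction factor (dB).
#' @export
white_noise_reduction <- function(P, n_t = 1000, reps = 50, sigma = 1,
                                  seed = 1) {
  stopifnot(reps >= 10)
  n_c <- nrow(P$matrix)
  vals <- with_seed(seed, vapply(seq_len(reps), function(r) {
    E <- matrix(stats::rnorm(n_c * n_t, sd = sigma), n_c, n_t)
    PE <- P$matrix %*% E
    20 * log10(stats::sd(as.numeric(E)) / stats::sd(as.numeric(PE)))
  }, numeric(1)))
  mean(vals)
}

# Welch power spectral density, one channel. Hann window, 50% overlap,
# one-sided density scaling.
welch_psd <- function(x, fs, nperseg) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  scale <- fs * sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    sp <- abs(stats::fft(seg))^2 / scale
    p <- sp[seq_len(nf)]
    if (nperseg %% 2L == 0L) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    else p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = acc / length(starts))
}

#' Per-frequency shielding factor between two recordings
#'
#' Welch PSD per channel (Hann window, 50% overlap, default 10 s segments),
#' root-mean-square amplitude across channels, and the dB ratio of raw to
#' cleaned amplitude per frequency. Positive values indicate attenuation by
#' the cleaning step; a flat negative curve indicates broadband
#' amplification.
#'
#' @param raw,cleaned [recording()]s with identical shape and sampling rate.
#' @param nperseg_s Welch segment length (s).
#' @return data.frame with `freq` (Hz) and `shielding_db`.
#' @export
psd_shielding <- function(raw, cleaned, nperseg_s = 10) {
  stopifnot(inherits(raw, "opm_recording"), inherits(cleaned, "opm_recording"))
  if (raw$fs != cleaned$fs) stop("sampling rates differ")
  if (!all(dim(raw$data) == dim(cleaned$data))) stop("recording shapes differ")
  nperseg <- max(8L, as.integer(round(nperseg_s * raw$fs)))
  rms_amp <- function(Y) {
    ps <- apply(Y$data, 1, function(ch) welch_psd(ch, Y$fs, nperseg)$psd)
    sqrt(rowMeans(as.matrix(ps)))
  }
  f <- welch_psd(raw$data[1, ], raw$fs, min(nperseg, ncol(raw$data)))$freq
  data.frame(freq = f,
             shielding_db = 20 * log10(rms_amp(raw) / rms_amp(cleaned)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (bi-directional, zero-phase) Butterworth filtering of
#' every channel.
#'
#' @param Y A [recording()].
#' @param low,high Band edges (Hz).
#' @param order Filter order (default 5).
#' @return Filtered [recording()].
#' @export
bandpass_filter <- function(Y, low, high, order = 5) {
  stopifnot(inherits(Y, "opm_recording"), low > 0, high > low,
            high < Y$fs / 2)
  bf <- signal::butter(order, c(low, high) / (Y$fs / 2), type = "pass")
  out <- t(apply(Y$data, 1, function(ch) signal::filtfilt(bf, ch)))
  recording(out, Y$fs, Y$names)
}

#' Epoch a recording and compute across-trial statistics
#'
#' Trials are windows `[-pre_s, +post_s]` around each event sample; the
#' across-trial mean and t-statistic (mean over standard error, per channel
#' and latency) are returned. Events whose window falls outside the recording
#' are dropped (with a message); overlapping windows trigger a warning. A
#' zero standard error (identical trials) yields a guarded large finite
#' t-value of `sign(mean) * 1e12`.
#'
#' @param Y A [recording()].
#' @param events Integer sample indices of the events.
#' @param pre_s Pre-event window (s, >= 0).
#' @param post_s Post-event window (s, > 0).
#' @return List with `mean` and `tstat` (n_c x n_latency matrices),
#'   `latency` (s, relative to event), `n_trials`, `n_dropped`.
#' @export
epoch_tstat <- function(Y, events, pre_s, post_s) {
  stopifnot(inherits(Y, "opm_recording"), pre_s >= 0, post_s > 0)
  n_t <- ncol(Y$data)
  pre <- as.integer(round(pre_s * Y$fs))
  post <- as.integer(round(post_s * Y$fs))
  ok <- events - pre >= 1 & events + post <= n_t
  dropped <- sum(!ok)
  events <- events[ok]
  if (length(events) < 2) stop("need at least 2 in-bounds events")
  if (dropped > 0) message(dropped, " event(s) dropped (window out of bounds)")
  if (any(diff(sort(events)) < pre + post + 1))
    warning("epoch windows overlap")
  n_lat <- pre + post + 1
  n_c <- nrow(Y$data)
  trials <- array(0, c(length(events), n_c, n_lat))
  for (i in seq_along(events))
    trials[i, , ] <- Y$data[, (events[i] - pre):(events[i] + post)]
  mu <- apply(trials, c(2, 3), mean)
  se <- apply(trials, c(2, 3), stats::sd) / sqrt(length(events))
  tstat <- ifelse(se > 0, mu / se, sign(mu) * 1e12)
  list(mean = mu, tstat = tstat,
       latency = (seq_len(n_lat) - 1 - pre) / Y$fs,
       n_trials = length(events), n_dropped = dropped)
}

#' Shielding report for a set of topographies
#'
#' Per-topography shielding factor (linear and dB) of a projector, with the
#' minimum as summary.
#'
#' @param topographies n_c x k matrix, one topography per column.
#' @param P A `field_projector`.
#' @return data.frame (`topography`, `shielding_linear`, `shielding_db`) with
#'   attribute `min_linear`.
#' @export
shielding_report <- function(topographies, P) {
  X <- as.matrix(topographies)
  PX <- P$matrix %*% X
  lin <- sqrt(colMeans(X^2)) / pmax(sqrt(colMeans(PX^2)), 1e-300)
  out <- data.frame(topography = seq_len(ncol(X)), shielding_linear = lin,
                    shielding_db = 20 * log10(lin))
  attr(out, "min_linear") <- min(lin)
  out
}
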