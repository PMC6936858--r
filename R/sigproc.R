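# Band-limited phase analysis: windowed-sinc band-pass, FFT analytic
# signal, phase-locking coherence, Welch spectra, Kuramoto order.

# Linear-phase FIR band-pass (Hamming-windowed sinc difference of two
# low-pass kernels).  Odd tap count so the group delay is an integer number
# of samples; applying the filter once and shifting by the group delay is
# exactly zero-phase.
fir_bandpass <- function(lo, hi, fs, taps = NULL) {
  stopifnot(lo > 0, hi > lo, hi < fs / 2)
  if (is.null(taps)) taps <- ceiling(3.3 * fs / (hi - lo))
  if (taps %% 2 == 0) taps <- taps + 1
  m <- (taps - 1) / 2
  k <- -m:m
  sinc <- function(fc) {
    h <- 2 * fc / fs * rep(1, length(k))
    nz <- k != 0
    h[nz] <- sin(2 * pi * fc / fs * k[nz]) / (pi * k[nz])
    h
  }
  w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming
  h <- (sinc(hi) - sinc(lo)) * w
  # unit gain at the band center
  fc <- (lo + hi) / 2
  h / abs(sum(h * exp(-2i * pi * fc / fs * (k + m))))
}

# FFT convolution, same length as x, group delay removed.
filt_zerophase <- function(x, h) {
  n <- length(x); m <- (length(h) - 1) / 2
  nfft <- stats::nextn(n + length(h) - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                     stats::fft(c(h, rep(0, nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[(m + 1):(m + n)]
}

# Analytic signal via the frequency-domain Hilbert weighting.
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- rep(0, n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

#' Band-limited analytic signal
#'
#' Zero-phase FIR band-pass around `center` followed by the Hilbert
#' transform, yielding instantaneous phase and amplitude per node.  Filter
#' edge transients of `max(1 s, 3 x group delay)` are trimmed from both
#' ends.
#'
#' @param ts A `jr_timeseries` from [simulate()], or a plain matrix
#'   (step x node) with attribute-free columns plus `dt` given.
#' @param center Band center (Hz).
#' @param halfwidth Band half-width (Hz); the pass band is
#'   `center +/- halfwidth`.
#' @param dt Sampling step (s); taken from `ts` when it is a
#'   `jr_timeseries`.
#' @param include_drivers If TRUE and `ts` carries stored driver waveforms,
#'   they are appended as extra (virtual) columns.
#' @return An `analytic_series`: matrices `phase` (rad, in (-pi, pi]) and
#'   `amplitude`, the band description, `dt`, and column labels.
#' @export
bandpass_analytic <- function(ts, center = 10, halfwidth = 2, dt = NULL,
                              include_drivers = FALSE) {
  if (inherits(ts, "jr_timeseries")) {
    V <- ts$V
    if (include_drivers && !is.null(ts$drivers)) V <- cbind(V, ts$drivers)
    dt <- ts$dt
  } else {
    V <- as.matrix(ts)
    if (is.null(dt)) stop("dt required for plain-matrix input")
  }
  stopifnot(center - halfwidth > 0)
  fs <- 1 / dt
  h <- fir_bandpass(center - halfwidth, center + halfwidth, fs)
  gd <- (length(h) - 1) / 2
  trim <- max(round(1 / dt), 3 * gd)
  if (nrow(V) <= 2 * trim)
    stop(sprintf("series too short: %d samples, need > %d for the filter transient",
                 nrow(V), 2 * trim))
  keep <- (trim + 1):(nrow(V) - trim)
  ph <- am <- matrix(NA_real_, length(keep), ncol(V))
  for (j in seq_len(ncol(V))) {
    a <- hilbert_analytic(filt_zerophase(V[, j] - mean(V[, j]), h))[keep]
    ph[, j] <- Arg(a)
    am[, j] <- Mod(a)
  }
  colnames(ph) <- colnames(am) <- colnames(V)
  structure(list(phase = ph, amplitude = am, center = center,
                 halfwidth = halfwidth, dt = dt, labels = colnames(V)),
            class = "analytic_series")
}

#' Pairwise phase coherence
#'
#' Coherence of two band-limited signals, implemented as the phase-locking
#' value `|mean(exp(1i (phi_i - phi_j)))|`: bounded in [0, 1], invariant to
#' a fixed phase offset and to amplitudes.  The amplitude-weighted variant
#' `|mean(a_i a_j exp(1i dphi))| / sqrt(mean(a_i^2) mean(a_j^2))` is
#' available for sensitivity checks.
#'
#' @param phi_i,phi_j Phase series (rad), equal length.
#' @param a_i,a_j Amplitude series for `weighted = TRUE`.
#' @param weighted Use the amplitude-weighted estimator.
#' @return Scalar in [0, 1].
#' @export
coherence <- function(phi_i, phi_j, a_i = NULL, a_j = NULL, weighted = FALSE) {
  stopifnot(length(phi_i) == length(phi_j), length(phi_i) > 0)
  if (!weighted) return(Mod(mean(exp(1i * (phi_i - phi_j)))))
  stopifnot(!is.null(a_i), !is.null(a_j))
  Mod(mean(a_i * a_j * exp(1i * (phi_i - phi_j)))) /
    sqrt(mean(a_i^2) * mean(a_j^2))
}

#' All-pairs coherence matrix
#'
#' @param an An `analytic_series` from [bandpass_analytic()].
#' @param weighted Use the amplitude-weighted estimator (see [coherence()]).
#' @return Symmetric matrix in [0, 1] with unit diagonal, labeled like the
#'   input columns (including any virtual driver columns).
#' @export
coherence_matrix <- function(an, weighted = FALSE) {
  n <- ncol(an$phase)
  z <- exp(1i * an$phase)
  if (!weighted) {
    M <- Mod(crossprod(Conj(z), z)) / nrow(z)
  } else {
    az <- an$amplitude * z
    M <- Mod(crossprod(Conj(az), az)) / nrow(z)
    rms <- sqrt(colMeans(an$amplitude^2))
    M <- M / outer(rms, rms)
  }
  M <- pmin(M, 1)
  diag(M) <- 1
  dimnames(M) <- list(an$labels, an$labels)
  M
}

#' Welch power spectral density and its dominant peak
#'
#' Averaged periodogram over Hann-windowed segments with 50% overlap.
#' `psd_peak` returns the frequency of maximum power inside a search band.
#'
#' @param x Single-node series (numeric vector).
#' @param dt Sampling step (s).
#' @param seg_len Segment length in samples (default 4 s worth).
#' @return `welch_psd`: data.frame with `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, dt, seg_len = round(4 / dt)) {
  n <- length(x)
  if (n < seg_len) stop("series shorter than one Welch segment")
  x <- x - mean(x)
  step <- floor(seg_len / 2)
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))  # Hann
  acc <- 0
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / length(starts) / sum(w^2) * dt
  half <- floor(seg_len / 2)
  data.frame(freq = (seq_len(half) - 1) / (seg_len * dt),
             power = p[seq_len(half)])
}

#' @rdname welch_psd
#' @param band Search band (Hz) for the peak.
#' @return `psd_peak`: list with `freq` (Hz), `power`, and `prominence`
#'   (peak power over median band power; low values flag a peakless
#'   spectrum).
#' @export
psd_peak <- function(x, dt, band = c(2, 45), seg_len = round(4 / dt)) {
  psd <- welch_psd(x, dt, seg_len = seg_len)
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stop("empty search band")
  fb <- psd$freq[sel]; pb <- psd$power[sel]
  k <- which.max(pb)
  list(freq = fb[k], power = pb[k],
       prominence = pb[k] / stats::median(pb))
}

#' Kuramoto order parameter
#'
#' Time-mean of `|mean_j exp(1i phi_j(t))|`: 1 for full synchrony, ~n^-1/2
#' for independent phases.
#'
#' @param phases Matrix (step x node) of phases (rad), or an
#'   `analytic_series`.
#' @return Scalar in [0, 1].
#' @export
kuramoto_order <- function(phases) {
  if (inherits(phases, "analytic_series")) phases <- phases$phase
  stopifnot(ncol(phases) >= 2)
  mean(Mod(rowMeans(exp(1i * phases))))
}
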