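# Per-cycle feature extraction: 10 time-domain statistics, 4 spectral
# features from the cycle periodogram, and 13 MFCCs averaged over short-time
# frames. The canonical order is fixed and used everywhere downstream.

#' Feature extraction configuration
#'
#' @param entropy_bins amplitude-histogram bins for Shannon entropy.
#' @param delta_f_hz half-window around the spectral peak for the energy
#'   ratio (Hz).
#' @param mfcc_n_coeffs number of cepstral coefficients retained (the 0th is
#'   excluded).
#' @param mfcc_preemphasis pre-emphasis coefficient.
#' @param mfcc_n_mel_filters mel filterbank size.
#' @param mfcc_fmin_hz,mfcc_fmax_hz filterbank frequency range (Hz).
#' @param mfcc_frame_s,mfcc_hop_s short-time frame and hop lengths (s).
#' @param mfcc_whole_cycle analyse the whole cycle as a single frame instead
#'   of short-time framing.
#' @return A `feature_config` list.
#' @export
feature_config <- function(entropy_bins = 32L, delta_f_hz = 10,
                           mfcc_n_coeffs = 13L, mfcc_preemphasis = 0.95,
                           mfcc_n_mel_filters = 26L, mfcc_fmin_hz = 20,
                           mfcc_fmax_hz = 600, mfcc_frame_s = 0.025,
                           mfcc_hop_s = 0.010, mfcc_whole_cycle = FALSE) {
  stopifnot(mfcc_n_coeffs <= mfcc_n_mel_filters, delta_f_hz > 0,
            entropy_bins >= 2)
  structure(as.list(environment()), class = "feature_config")
}

#' Canonical feature names
#' @param reduced if `TRUE`, the 15-name reduced preset (kurtosis, f_max and
#'   the 13 MFCCs); otherwise all 27.
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function(reduced = FALSE) {
  full <- c("mean", "median", "std", "mad", "p25", "p75", "iqr",
            "skewness", "kurtosis", "shannon_entropy",
            "spectral_entropy", "f_max", "mag_at_fmax", "energy_ratio",
            paste0("mfcc_", 1:13))
  if (reduced) c("kurtosis", "f_max", paste0("mfcc_", 1:13)) else full
}

cycle_samples <- function(cycle) {
  if (inherits(cycle, "heart_cycle")) cycle$samples else as.numeric(cycle)
}
cycle_rate <- function(cycle, default = 2000L) {
  if (inherits(cycle, "heart_cycle")) cycle$sample_rate_hz else default
}

#' Time-domain statistics of one cycle
#'
#' Mean, median, standard deviation (n-1 denominator), mean absolute
#' deviation, 25th/75th percentiles (linear interpolation between order
#' statistics), interquartile range, skewness
#' \eqn{g_1 = \sum (x_i - \bar x)^3 / (N s^3)}, excess kurtosis
#' \eqn{k = \sum (x_i - \bar x)^4 / (N s^4) - 3}, and Shannon entropy of a
#' fixed-bin amplitude histogram (log base 2). For a constant cycle,
#' skewness, kurtosis and entropy are defined as 0.
#'
#' @param cycle a `heart_cycle` or numeric vector (length >= 4).
#' @param config a [feature_config].
#' @return Named numeric vector of 10 values.
#' @export
time_features <- function(cycle, config = feature_config()) {
  x <- cycle_samples(cycle)
  if (length(x) < 4) stop("cycle must have at least 4 samples")
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  if (s == 0) {
    skew <- 0; kurt <- 0; ent <- 0
  } else {
    skew <- sum((x - m)^3) / (n * s^3)
    kurt <- sum((x - m)^4) / (n * s^4) - 3
    h <- tabulate(pmin(config$entropy_bins,
                       pmax(1L, ceiling((x - min(x)) / (max(x) - min(x)) *
                                          config$entropy_bins))),
                  nbins = config$entropy_bins)
    p <- h / n
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
  }
  c(mean = m, median = stats::median(x), std = s,
    mad = mean(abs(x - m)), p25 = q[1], p75 = q[2], iqr = q[2] - q[1],
    skewness = skew, kurtosis = kurt, shannon_entropy = ent)
}

#' One-sided periodogram of a cycle
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @return List with `freq_hz`, `power` (`|X_k|^2 / N`) and `mag` (`|X_k|`),
#'   DC excluded.
#' @export
cycle_periodogram <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  k <- 2:(n %/% 2 + 1)          # exclude DC; one-sided
  list(freq_hz = (k - 1) * fs / n, power = Mod(X[k])^2 / n, mag = Mod(X[k]))
}

#' Spectral features of one cycle
#'
#' Periodogram-based: normalized spectral entropy
#' \eqn{-\sum p_k \log_2 p_k / \log_2 N} (in \[0, 1\]), peak frequency
#' `f_max` (Hz), magnitude at the peak, and the ratio of spectral energy
#' within `f_max` +/- `delta_f_hz` to total spectral energy.
#'
#' @param cycle a `heart_cycle` or numeric vector (length >= 8).
#' @param config a [feature_config].
#' @param sample_rate_hz rate used when `cycle` is a bare vector.
#' @return Named numeric vector of 4 values.
#' @export
freq_features <- function(cycle, config = feature_config(),
                          sample_rate_hz = 2000L) {
  x <- cycle_samples(cycle)
  fs <- cycle_rate(cycle, sample_rate_hz)
  if (length(x) < 8) stop("cycle must have at least 8 samples")
  if (all(x == 0)) stop("zero cycle has no spectrum")
  pg <- cycle_periodogram(x, fs)
  ptot <- sum(pg$power)
  p <- pg$power / ptot
  nz <- p > 0
  sen <- -sum(p[nz] * log2(p[nz])) / log2(length(p))
  imax <- which.max(pg$power)
  fmax <- pg$freq_hz[imax]
  band <- abs(pg$freq_hz - fmax) <= config$delta_f_hz
  c(spectral_entropy = sen, f_max = fmax, mag_at_fmax = pg$mag[imax],
    energy_ratio = sum(pg$power[band]) / ptot)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_filters, n_fft, fs, fmin, fmax) {
  mels <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2)
  hz <- mel_to_hz(mels)
  bins <- hz * n_fft / fs                     # fractional FFT bin positions
  freqs <- (0:(n_fft %/% 2)) * fs / n_fft
  fb <- matrix(0, n_filters, length(freqs))
  for (j in seq_len(n_filters)) {
    lo <- hz[j]; mid <- hz[j + 1]; hi <- hz[j + 2]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[j, ] <- pmax(0, pmin(up, down))
  }
  fb
}

dct_ii_ortho <- function(v) {
  M <- length(v)
  k <- seq_len(M) - 1
  out <- vapply(k, function(kk) {
    sum(v * cos(pi * kk * (seq_len(M) - 0.5) / M))
  }, numeric(1))
  out * c(sqrt(1 / M), rep(sqrt(2 / M), M - 1))
}

#' MFCCs of one cycle
#'
#' Pre-emphasis `x[n] - 0.95 x[n-1]` (with `x[-1] = 0`), Hamming-windowed
#' short-time frames, power FFT, triangular mel filterbank over
#' \[fmin, fmax\], log energies (floored at machine epsilon), orthonormal
#' DCT-II, coefficients 1..13 (0th excluded) averaged across frames. A cycle
#' shorter than one frame is analysed as a single frame.
#'
#' @param cycle a `heart_cycle` or numeric vector (length >= 32).
#' @param config a [feature_config].
#' @param sample_rate_hz rate used when `cycle` is a bare vector.
#' @return Named numeric vector `mfcc_1` .. `mfcc_13`.
#' @export
mfcc_features <- function(cycle, config = feature_config(),
                          sample_rate_hz = 2000L) {
  x <- cycle_samples(cycle)
  fs <- cycle_rate(cycle, sample_rate_hz)
  if (length(x) < 32) stop("cycle must have at least 32 samples")
  x <- pre_emphasis(x, config$mfcc_preemphasis)
  frame <- round(config$mfcc_frame_s * fs)
  hop <- max(1L, round(config$mfcc_hop_s * fs))
  if (config$mfcc_whole_cycle || length(x) < frame) {
    starts <- 1L
    frame <- length(x)
  } else {
    starts <- seq(1L, length(x) - frame + 1L, by = hop)
  }
  n_fft <- 2^ceiling(log2(frame))
  fb <- mel_filterbank(config$mfcc_n_mel_filters, n_fft, fs,
                       config$mfcc_fmin_hz, config$mfcc_fmax_hz)
  win <- hamming_window(frame)
  coefs <- matrix(0, length(starts), config$mfcc_n_coeffs)
  for (i in seq_along(starts)) {
    fr <- x[starts[i]:(starts[i] + frame - 1L)] * win
    X <- stats::fft(c(fr, numeric(n_fft - frame)))
    pw <- Mod(X[1:(n_fft %/% 2 + 1)])^2 / n_fft
    fe <- as.numeric(fb %*% pw)
    lg <- log(pmax(fe, .Machine$double.eps))
    cc <- dct_ii_ortho(lg)
    coefs[i, ] <- cc[2:(config$mfcc_n_coeffs + 1L)]
  }
  stats::setNames(colMeans(coefs), paste0("mfcc_", seq_len(config$mfcc_n_coeffs)))
}

pre_emphasis <- function(x, alpha = 0.95) {
  x - alpha * c(0, x[-length(x)])
}

hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Extract the full 27-value feature vector of one cycle
#'
#' Concatenates [time_features], [freq_features] and [mfcc_features] in
#' canonical order (see [feature_names]).
#'
#' @param cycle a `heart_cycle` or numeric vector.
#' @param config a [feature_config].
#' @param sample_rate_hz rate used when `cycle` is a bare vector.
#' @return Named numeric vector of length 27, all finite.
#' @export
extract_features <- function(cycle, config = feature_config(),
                             sample_rate_hz = 2000L) {
  v <- c(time_features(cycle, config),
         freq_features(cycle, config, sample_rate_hz),
         mfcc_features(cycle, config, sample_rate_hz))
  stopifnot(identical(names(v), feature_names()))
  if (!all(is.finite(v))) stop("non-finite feature value in cycle")
  v
}

#' Feature matrix for a list of cycles
#' @param cycles list of heart cycles.
#' @param config a [feature_config].
#' @return Matrix with one row per cycle, 27 canonical columns.
#' @export
extract_feature_matrix <- function(cycles, config = feature_config()) {
  if (length(cycles) == 0) {
    return(matrix(numeric(0), 0, 27, dimnames = list(NULL, feature_names())))
  }
  t(vapply(cycles, extract_features, numeric(27), config = config))
}
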