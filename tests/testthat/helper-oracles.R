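# Independent straight-line oracles: explicit summation loops, no shared
# code with the package implementation.

oracle_time_stats <- function(x, bins = 32L) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v
  m <- m / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  s <- sqrt(ss / (n - 1))
  xs <- sort(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  # linear interpolation between order statistics (type-7 rule)
  pct <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
  }
  sk <- 0; ku <- 0; ad <- 0
  for (v in x) {
    sk <- sk + (v - m)^3
    ku <- ku + (v - m)^4
    ad <- ad + abs(v - m)
  }
  sk <- if (s > 0) sk / (n * s^3) else 0
  ku <- if (s > 0) ku / (n * s^4) - 3 else 0
  counts <- integer(bins)
  rng <- max(x) - min(x)
  if (rng > 0) {
    for (v in x) {
      b <- ceiling((v - min(x)) / rng * bins)
      b <- max(1L, min(bins, b))
      counts[b] <- counts[b] + 1L
    }
  }
  ent <- 0
  for (cnt in counts) {
    if (cnt > 0) ent <- ent - (cnt / n) * log2(cnt / n)
  }
  if (rng == 0) ent <- 0
  c(mean = m, median = med, std = s, mad = ad / n,
    p25 = pct(0.25), p75 = pct(0.75), iqr = pct(0.75) - pct(0.25),
    skewness = sk, kurtosis = ku, shannon_entropy = ent)
}

oracle_metrics <- function(tp, fn, fp, tn) {
  p <- tp + fn; n <- fp + tn
  recall <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  precision <- tp / (tp + fp)
  list(sensitivity = recall,
       specificity = specificity,
       fpr = fp / (tn + fp),
       precision = precision,
       f_score = 2 * recall * precision / (recall + precision),
       accuracy = (tp + tn) / (p + n),
       error = 1 - (tp + tn) / (p + n),
       mcc = (tp * tn - fp * fn) / ((tp + fp) * p * n * (tn + fn))^0.5)
}

oracle_spectral_entropy <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  nf <- n %/% 2
  pw <- numeric(nf)
  for (k in seq_len(nf)) pw[k] <- Mod(X[k + 1])^2 / n
  pk <- pw / sum(pw)
  sen <- 0
  for (p in pk) if (p > 0) sen <- sen - p * log2(p)
  sen / log2(nf)
}

# brute-force MFCC: explicit loops over frames, mel filters and cosines
oracle_mfcc <- function(x, fs = 2000, n_coef = 13, alpha = 0.95,
                        n_filters = 26, fmin = 20, fmax = 600,
                        frame_s = 0.025, hop_s = 0.010) {
  n <- length(x)
  xp <- numeric(n)
  xp[1] <- x[1]
  for (i in 2:n) xp[i] <- x[i] - alpha * x[i - 1]
  frame <- round(frame_s * fs)
  hop <- round(hop_s * fs)
  if (n < frame) { frame <- n; starts <- 1 } else {
    starts <- seq(1, n - frame + 1, by = hop)
  }
  n_fft <- 2^ceiling(log2(frame))
  m_of <- function(f) 2595 * log10(1 + f / 700)
  f_of <- function(m) 700 * (10^(m / 2595) - 1)
  mel_pts <- f_of(seq(m_of(fmin), m_of(fmax), length.out = n_filters + 2))
  freqs <- (0:(n_fft / 2)) * fs / n_fft
  acc <- numeric(n_coef)
  for (s0 in starts) {
    fr <- xp[s0:(s0 + frame - 1)]
    win <- numeric(frame)
    for (i in 1:frame) {
      win[i] <- if (frame == 1) 1 else 0.54 - 0.46 * cos(2 * pi * (i - 1) / (frame - 1))
    }
    fr <- fr * win
    X <- stats::fft(c(fr, numeric(n_fft - frame)))
    pw <- numeric(length(freqs))
    for (i in seq_along(freqs)) pw[i] <- Mod(X[i])^2 / n_fft
    le <- numeric(n_filters)
    for (j in 1:n_filters) {
      lo <- mel_pts[j]; mid <- mel_pts[j + 1]; hi <- mel_pts[j + 2]
      e <- 0
      for (i in seq_along(freqs)) {
        f <- freqs[i]
        w <- if (f >= lo && f <= mid) (f - lo) / (mid - lo)
             else if (f > mid && f <= hi) (hi - f) / (hi - mid)
             else 0
        e <- e + w * pw[i]
      }
      le[j] <- log(max(e, .Machine$double.eps))
    }
    for (k in 1:n_coef) {
      ck <- 0
      for (j in 1:n_filters) {
        ck <- ck + le[j] * cos(pi * k * (j - 0.5) / n_filters)
      }
      acc[k] <- acc[k] + ck * sqrt(2 / n_filters)
    }
  }
  acc / length(starts)
}

oracle_knn_neighbors <- function(Xtr, xq, k) {
  d <- numeric(nrow(Xtr))
  for (i in seq_len(nrow(Xtr))) {
    s <- 0
    for (j in seq_len(ncol(Xtr))) s <- s + (Xtr[i, j] - xq[j])^2
    d[i] <- sqrt(s)
  }
  order(d)[seq_len(k)]
}

band_power <- function(x, fs, lo, hi) {
  X <- stats::fft(x)
  n <- length(x)
  k <- 2:(n %/% 2 + 1)
  f <- (k - 1) * fs / n
  sum((Mod(X[k])^2 / n)[f >= lo & f <= hi])
}

make_noise_cycle <- function(seed = 1, n = 800, fs = 2000) {
  set.seed(seed)
  structure(list(samples = stats::rnorm(n), start_index = 0L,
                 end_index = as.integer(n), s1_index = 100L,
                 sample_rate_hz = fs),
            class = "heart_cycle")
}

# two overlapping Gaussian classes with a screening-style imbalance
make_overlap_data <- function(n_abnormal = 60, n_normal = 190, sep = 1.2,
                              seed = 1) {
  set.seed(seed)
  y <- rep(c("abnormal", "normal"), c(n_abnormal, n_normal))
  X <- cbind(f1 = stats::rnorm(length(y), ifelse(y == "abnormal", sep, -sep) / 2),
             f2 = stats::rnorm(length(y)))
  list(X = X, y = y)
}
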