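# S1-anchored heart-cycle segmentation. S1 is the most dominant peak of the
# PCG, so detection works on a normalized average Shannon energy envelope
# with a refractory period; cycles run S1-to-next-S1 with a configurable
# pre-offset so each cycle captures the start of S1 and the end of S2.
# Coordinates: 0-based sample indices, half-open [start, end) intervals.

#' Normalized average Shannon energy envelope
#'
#' Frames of `frame_s` seconds advanced by `hop_s`; per frame the average
#' Shannon energy \eqn{-\frac{1}{N}\sum x^2 \log x^2} of the peak-normalized
#' signal, smoothed by a short moving average and scaled to max 1. The
#' envelope is amplitude-scale invariant.
#'
#' @param record a [pcg_record].
#' @param frame_s frame length in seconds (>= 0.01).
#' @param hop_s hop length in seconds.
#' @return List with `envelope` (non-negative, max 1 unless all-zero),
#'   `hop_samples`, `frame_samples`, and `centers` (0-based sample index of
#'   each frame centre).
#' @export
shannon_energy_envelope <- function(record, frame_s = 0.02, hop_s = 0.005) {
  if (frame_s < 0.01) stop("frame_s must be at least 10 ms")
  fs <- record$sample_rate_hz
  frame <- round(frame_s * fs)
  hop <- max(1L, round(hop_s * fs))
  x <- record$samples
  if (length(x) < frame) stop("record shorter than one frame")
  peak <- max(abs(x))
  # scale to half range: -x^2 log(x^2) is monotone only for |x| < 1/sqrt(e),
  # so mapping the peak to 0.5 keeps larger sounds larger in the envelope
  if (peak > 0) x <- x / (2 * peak)
  starts <- seq(1L, length(x) - frame + 1L, by = hop)
  x2 <- x^2
  se_term <- ifelse(x2 > 0, -x2 * log(x2), 0)
  cum <- c(0, cumsum(se_term))
  env <- (cum[starts + frame] - cum[starts]) / frame
  env[env < 0] <- 0
  # moving-average smoothing over ~3 frames
  k <- max(1L, round(frame / hop))
  if (length(env) > k) {
    kern <- rep(1 / k, k)
    env <- as.numeric(stats::filter(env, kern, sides = 2))
    env[is.na(env)] <- 0
  }
  if (max(env) > 0) env <- env / max(env)
  list(envelope = env, hop_samples = hop, frame_samples = frame,
       centers = (starts - 1L) + as.integer(frame %/% 2L))
}

#' Detect S1 peaks
#'
#' Finds local maxima of the Shannon energy envelope above a relative
#' threshold and keeps, among candidates closer than the refractory spacing
#' `60 / hr_max`, the one with the larger envelope (the S1-dominance
#' assumption). Returns strictly increasing 0-based sample indices.
#'
#' @param record a pre-processed [pcg_record].
#' @param hr_bounds_bpm plausible heart-rate range (bpm).
#' @param min_rel_height candidate threshold relative to the envelope max.
#' @param frame_s,hop_s envelope parameters.
#' @return Integer vector of S1 sample indices (0-based); empty for a
#'   flat/zero record.
#' @export
detect_s1_peaks <- function(record, hr_bounds_bpm = c(40, 180),
                            min_rel_height = 0.2,
                            frame_s = 0.02, hop_s = 0.005) {
  if (max(abs(record$samples)) == 0) return(integer(0))
  env_obj <- shannon_energy_envelope(record, frame_s, hop_s)
  env <- env_obj$envelope
  m <- length(env)
  if (m < 3) return(integer(0))
  refractory_s <- 60 / hr_bounds_bpm[2]
  refractory_hops <- refractory_s * record$sample_rate_hz / env_obj$hop_samples
  is_max <- c(FALSE, env[2:(m - 1)] >= env[1:(m - 2)] &
                     env[2:(m - 1)] >= env[3:m], FALSE)
  cand <- which(is_max & env >= min_rel_height * max(env))
  if (length(cand) == 0) return(integer(0))
  # greedy selection by envelope height under the refractory constraint
  ord <- cand[order(env[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in ord) {
    if (all(abs(p - keep) >= refractory_hops)) keep <- c(keep, p)
  }
  keep <- sort(keep)
  idx <- env_obj$centers[keep]
  if (length(idx) < 2) {
    warning("fewer than 2 S1 peaks detected; no cycles derivable")
  }
  as.integer(idx)
}

#' Cut a record into S1-to-S1 heart cycles
#'
#' Cycle `i` spans `[s1_i - pre_offset, s1_{i+1} - pre_offset)` so that it
#' captures the beginning of its S1 and the end of its S2. Cycles whose
#' duration falls outside `[min_dur_s, max_dur_s]` are dropped with a
#' message; a pre-offset pushing the start below 0 is clamped.
#'
#' @param record a [pcg_record].
#' @param s1_indices 0-based S1 sample indices (>= 2 of them).
#' @param pre_offset_s offset before each S1 (default 50 ms).
#' @param min_dur_s,max_dur_s physiological duration bounds (s).
#' @return List of `heart_cycle` objects (each with `samples`,
#'   `start_index`, `end_index`, `s1_index`, `sample_rate_hz`).
#' @export
segment_cycles <- function(record, s1_indices, pre_offset_s = 0.05,
                           min_dur_s = 0.3, max_dur_s = 2.0) {
  if (length(s1_indices) < 2) stop("need at least 2 S1 indices")
  fs <- record$sample_rate_hz
  off <- round(pre_offset_s * fs)
  cycles <- list()
  dropped <- 0L
  for (i in seq_len(length(s1_indices) - 1L)) {
    start <- s1_indices[i] - off
    if (start < 0) {
      message("cycle ", i, ": pre-offset clamped to record start")
      start <- 0L
    }
    end <- s1_indices[i + 1L] - off
    end <- min(end, length(record$samples))
    dur <- (end - start) / fs
    if (dur < min_dur_s || dur > max_dur_s) {
      dropped <- dropped + 1L
      next
    }
    cycles[[length(cycles) + 1L]] <- structure(
      list(samples = record$samples[(start + 1L):end],
           start_index = as.integer(start), end_index = as.integer(end),
           s1_index = as.integer(s1_indices[i]), sample_rate_hz = fs),
      class = "heart_cycle")
  }
  if (dropped > 0) {
    warning(dropped, " cycle(s) dropped: duration outside [",
            min_dur_s, ", ", max_dur_s, "] s")
  }
  cycles
}

#' @export
print.heart_cycle <- function(x, ...) {
  cat(sprintf("<heart_cycle> [%d, %d) anchored at S1=%d (%.3f s at %d Hz)\n",
              x$start_index, x$end_index, x$s1_index,
              length(x$samples) / x$sample_rate_hz, x$sample_rate_hz))
  invisible(x)
}

#' Average a set of heart cycles
#'
#' Resamples every cycle to the median cycle length by linear interpolation,
#' then takes the pointwise mean.
#'
#' @param cycles non-empty list of `heart_cycle` objects.
#' @return Numeric vector of the median cycle length.
#' @export
average_cycles <- function(cycles) {
  if (length(cycles) == 0) stop("no cycles to average")
  lens <- vapply(cycles, function(cy) length(cy$samples), integer(1))
  target <- as.integer(round(stats::median(lens)))
  mat <- vapply(cycles, function(cy) {
    if (length(cy$samples) == target) cy$samples
    else stats::approx(seq(0, 1, length.out = length(cy$samples)),
                       cy$samples, xout = seq(0, 1, length.out = target))$y
  }, numeric(target))
  rowMeans(matrix(mat, nrow = target))
}

#' Detect and segment in one call
#' @param record a pre-processed [pcg_record].
#' @param ... passed to [detect_s1_peaks] and [segment_cycles].
#' @return List of heart cycles (possibly empty).
#' @export
segment_record <- function(record, ...) {
  args <- list(...)
  det_args <- args[names(args) %in% names(formals(detect_s1_peaks))]
  seg_args <- args[names(args) %in% names(formals(segment_cycles))]
  peaks <- do.call(detect_s1_peaks, c(list(record), det_args))
  if (length(peaks) < 2) return(list())
  do.call(segment_cycles, c(list(record, peaks), seg_args))
}
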