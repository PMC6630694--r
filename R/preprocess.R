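# Digital pre-processing applied before segmentation: MAD-threshold spike
# removal, baseline-drift correction, and the sixth-order 20-600 Hz
# Butterworth band-pass (applied zero-phase so S1/S2 timing is preserved).

#' Band-pass filter specification
#'
#' Defaults to the pipeline's sixth-order Butterworth band-pass with 20 Hz /
#' 600 Hz cutoffs at 2000 Hz. `order` is the total band-pass order (an
#' order-6 band-pass uses order-3 low/high prototypes).
#'
#' @param order total band-pass order (even, >= 2).
#' @param low_cut_hz,high_cut_hz cutoff frequencies (Hz).
#' @param sample_rate_hz sampling rate (Hz).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 6L, low_cut_hz = 20, high_cut_hz = 600,
                        sample_rate_hz = 2000L) {
  if (low_cut_hz >= high_cut_hz) stop("low_cut_hz must be < high_cut_hz")
  if (low_cut_hz <= 0 || high_cut_hz >= sample_rate_hz / 2) {
    stop("cutoffs must satisfy 0 < low < high < Nyquist")
  }
  if (order %% 2 != 0 || order < 2) stop("order must be even and >= 2")
  structure(list(order = as.integer(order), low_cut_hz = low_cut_hz,
                 high_cut_hz = high_cut_hz,
                 sample_rate_hz = as.integer(sample_rate_hz),
                 family = "iir_butterworth"),
            class = "filter_spec")
}

#' Design the Butterworth band-pass
#'
#' Returns transfer-function coefficients (`b`, `a`) and checks stability
#' (all poles strictly inside the unit circle).
#'
#' @param spec a [filter_spec].
#' @return A `signal::Arma`-style list with elements `b` and `a`.
#' @export
design_bandpass <- function(spec = filter_spec()) {
  nyq <- spec$sample_rate_hz / 2
  flt <- signal::butter(spec$order / 2,
                        c(spec$low_cut_hz, spec$high_cut_hz) / nyq,
                        type = "pass")
  poles <- polyroot(rev(flt$a))
  if (any(Mod(poles) >= 1)) {
    stop("unstable filter at order ", spec$order,
         "; consider cascaded second-order sections")
  }
  flt
}

#' Filter magnitude response at given frequencies
#' @param flt coefficients from [design_bandpass].
#' @param freqs_hz frequencies (Hz).
#' @param sample_rate_hz sampling rate (Hz).
#' @return `|H(f)|` for a single forward pass.
#' @export
filter_response <- function(flt, freqs_hz, sample_rate_hz = 2000) {
  w <- 2 * pi * freqs_hz / sample_rate_hz
  ev <- function(coef, w) {
    vapply(w, function(wi) sum(coef * exp(-1i * wi * (seq_along(coef) - 1))),
           complex(1))
  }
  Mod(ev(flt$b, w) / ev(flt$a, w))
}

#' Apply the band-pass to a record (zero-phase)
#'
#' Forward-backward filtering; length-preserving.
#'
#' @param record a [pcg_record].
#' @param spec a [filter_spec]; its rate must match the record's.
#' @return The filtered [pcg_record].
#' @export
bandpass_filter <- function(record, spec = filter_spec()) {
  if (record$sample_rate_hz != spec$sample_rate_hz) {
    stop("record rate ", record$sample_rate_hz, " != filter rate ",
         spec$sample_rate_hz)
  }
  flt <- design_bandpass(spec)
  record$samples <- as.numeric(signal::filtfilt(flt, record$samples))
  record$provenance <- c(record$provenance,
                         sprintf("bandpass %g-%g Hz order %d",
                                 spec$low_cut_hz, spec$high_cut_hz, spec$order))
  record
}

#' Remove spikes by MAD thresholding
#'
#' Samples deviating from the median by more than `threshold_mads` median
#' absolute deviations are replaced by linear interpolation of flanking
#' non-spike samples. Constant records (MAD = 0) pass through unchanged.
#'
#' @param record a [pcg_record].
#' @param threshold_mads detection threshold in MAD units (default 8).
#' @return The despiked [pcg_record].
#' @export
remove_spikes <- function(record, threshold_mads = 8) {
  x <- record$samples
  med <- stats::median(x)
  madv <- stats::mad(x)
  if (madv == 0) return(record)
  spike <- abs(x - med) > threshold_mads * madv
  if (any(spike)) {
    good <- which(!spike)
    if (length(good) >= 2) {
      x[spike] <- stats::approx(good, x[good], xout = which(spike),
                                rule = 2)$y
    } else {
      x[spike] <- med
    }
    record$samples <- x
    record$provenance <- c(record$provenance,
                           sprintf("despiked %d samples", sum(spike)))
  }
  record
}

#' Correct baseline drift
#'
#' Zero-phase Butterworth high-pass below the main analysis band (default
#' 2 Hz); output is approximately zero-mean with content above the cutoff
#' preserved.
#'
#' @param record a [pcg_record].
#' @param cutoff_hz high-pass cutoff (Hz), below the band-pass low edge.
#' @return The corrected [pcg_record].
#' @export
correct_baseline <- function(record, cutoff_hz = 2) {
  nyq <- record$sample_rate_hz / 2
  if (cutoff_hz >= nyq) stop("cutoff must be below the Nyquist frequency")
  flt <- signal::butter(2, cutoff_hz / nyq, type = "high")
  # mean removal first keeps the zero-phase pass free of DC edge transients
  record$samples <- as.numeric(signal::filtfilt(flt,
                                                record$samples - mean(record$samples)))
  record$provenance <- c(record$provenance,
                         sprintf("baseline corrected (%g Hz high-pass)", cutoff_hz))
  record
}

#' Full pre-processing chain
#'
#' Fixed composition: spike removal, then baseline correction, then the
#' band-pass.
#'
#' @param record a [pcg_record].
#' @param spec a [filter_spec].
#' @param threshold_mads spike threshold (MAD units).
#' @param baseline_cutoff_hz drift high-pass cutoff (Hz).
#' @return The pre-processed [pcg_record].
#' @export
preprocess_record <- function(record, spec = filter_spec(), threshold_mads = 8,
                              baseline_cutoff_hz = 2) {
  record <- remove_spikes(record, threshold_mads)
  record <- correct_baseline(record, baseline_cutoff_hz)
  bandpass_filter(record, spec)
}
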