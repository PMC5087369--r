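# Signal averaging, band-pass filtering, vector magnitude, QRS boundary
# detection and the standard time-domain ventricular late potential (VLP)
# parameters fQRSD, RMS40 and LAS40.

#' Beat ensemble container
#'
#' @param beats list of equal-length numeric vectors or [beat_signal()]s from
#'   one lead.
#' @param fs sampling rate, Hz.
#' @return Object of class `beat_ensemble`.
#' @export
beat_ensemble <- function(beats, fs = 2000) {
  beats <- lapply(beats, signal_samples)
  if (length(beats) < 1)
    stop_aiqp("invalid_input", "ensemble needs at least one beat")
  p <- length(beats[[1]])
  if (!all(vapply(beats, length, 1L) == p))
    stop_aiqp("invalid_input", "all beats must have equal length")
  structure(list(beats = beats, fs = fs), class = "beat_ensemble")
}

# Best integer shift aligning `beat` to `template` (argmax of normalized
# cross-correlation over the overlap); positive shift means the beat lags.
best_shift <- function(template, beat, max_lag) {
  p <- length(template)
  lags <- -max_lag:max_lag
  cors <- vapply(lags, function(s) {
    ia <- max(1, 1 + s):min(p, p + s)   # template indices
    ib <- ia - s                        # beat indices
    a <- template[ia]; b <- beat[ib]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) 0 else sum(a * b) / den
  }, numeric(1))
  k <- which.max(cors)
  list(shift = lags[k], cor = cors[k])
}

# Shift a vector by s samples (positive s moves content earlier), repeating
# the edge sample into the vacated region.
shift_fill <- function(x, s) {
  p <- length(x)
  if (s == 0) return(x)
  if (s > 0) c(x[(1 + s):p], rep(x[p], s))
  else c(rep(x[1], -s), x[1:(p + s)])
}

#' Signal averaging of a beat ensemble
#'
#' Averages aligned beats to suppress noise uncorrelated with the beat (RMS
#' noise falls as 1/sqrt(N)). Each beat is optionally aligned to the
#' first-beat template by the integer shift maximizing the normalized
#' cross-correlation; beats whose peak correlation falls below
#' `reject_correlation_below` are excluded from the average.
#'
#' @param ensemble a [beat_ensemble()] (or list of beats).
#' @param align align beats to the first-beat template before averaging.
#' @param reject_correlation_below rejection threshold for the peak
#'   normalized correlation (default 0.98).
#' @param max_lag largest alignment shift searched, samples (default p/4).
#' @return A [beat_signal()]: the pointwise mean of the surviving aligned
#'   beats, with attributes `shifts`, `correlations` and `kept` (logical).
#' @export
signal_average <- function(ensemble, align = TRUE,
                           reject_correlation_below = 0.98,
                           max_lag = NULL) {
  if (!inherits(ensemble, "beat_ensemble")) ensemble <- beat_ensemble(ensemble)
  beats <- ensemble$beats
  p <- length(beats[[1]])
  if (is.null(max_lag)) max_lag <- max(1L, p %/% 4L)
  template <- beats[[1]]
  shifts <- integer(length(beats))
  cors <- rep(1, length(beats))
  aligned <- beats
  if (align && length(beats) > 1) {
    for (i in seq_along(beats)[-1]) {
      bs <- best_shift(template, beats[[i]], max_lag)
      shifts[i] <- bs$shift
      cors[i] <- bs$cor
      aligned[[i]] <- shift_fill(beats[[i]], -bs$shift)
    }
  }
  kept <- cors >= reject_correlation_below
  if (!any(kept))
    stop_aiqp("empty_ensemble", "every beat was rejected by the correlation gate")
  avg <- Reduce(`+`, aligned[kept]) / sum(kept)
  out <- beat_signal(avg, fs = ensemble$fs)
  attr(out, "shifts") <- shifts
  attr(out, "correlations") <- cors
  attr(out, "kept") <- kept
  out
}

#' Butterworth band-pass filtering
#'
#' Band-pass filters a signal with a Butterworth design of analog prototype
#' order `order` (so the realized band-pass transfer function has order
#' `2 * order`, the usual convention of filter-design tools). With
#' `zero_phase = TRUE` the filter is applied forward and backward
#' ("bidirectional"), squaring the magnitude response — band-edge gain 1/2
#' instead of 1/sqrt(2) — and cancelling phase distortion. The signal is
#' extended by odd reflection over three filter lengths at each end before
#' filtering to suppress edge transients, then trimmed.
#'
#' @param x numeric signal or [beat_signal()].
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order analog prototype order (default 4).
#' @param zero_phase apply forward-backward (zero-phase) filtering.
#' @param fs sampling rate, Hz.
#' @return filtered numeric vector, same length as `x`.
#' @export
bandpass_filter <- function(x, low = 40, high = 250, order = 4,
                            zero_phase = TRUE,
                            fs = if (inherits(x, "beat_signal")) x$fs else 2000) {
  xs <- signal_samples(x)
  if (low <= 0 || high <= low || high >= fs / 2)
    stop_aiqp("invalid_parameter", "band must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  p <- length(xs)
  pad <- min(p - 1L, 3L * length(bf$b))
  xp <- c(2 * xs[1] - xs[(pad + 1):2],        # odd reflection, left
          xs,
          2 * xs[p] - xs[(p - 1):(p - pad)])  # odd reflection, right
  yp <- as.numeric(signal::filter(bf, xp))
  if (zero_phase) yp <- rev(as.numeric(signal::filter(bf, rev(yp))))
  yp[(pad + 1):(pad + p)]
}

#' Vector magnitude of the three orthogonal leads
#'
#' Pointwise Euclidean norm `sqrt(x^2 + y^2 + z^2)` of the X, Y and Z lead
#' signals, the standard composite on which QRS boundaries are determined.
#'
#' @param x,y,z equal-length numeric signals (or [beat_signal()]s).
#' @return numeric vector.
#' @export
vector_magnitude <- function(x, y, z) {
  x <- signal_samples(x); y <- signal_samples(y); z <- signal_samples(z)
  if (length(x) != length(y) || length(y) != length(z))
    stop_aiqp("invalid_input", "the three leads must have equal length")
  sqrt(x^2 + y^2 + z^2)
}

#' QRS onset/offset detection on the vector magnitude
#'
#' Thresholds the filtered vector magnitude at `noise mean + k_sigma * noise
#' SD`, estimated on a designated noise window outside the QRS. The onset is
#' the start of the first run that stays above threshold for at least
#' `sustain_ms`; the offset is the end of the last such run.
#'
#' @param vm vector-magnitude signal.
#' @param noise_window length-2 integer vector `(start, end)` of the noise
#'   segment, sample indices.
#' @param k_sigma threshold multiplier (default 3).
#' @param sustain_ms minimum supra-threshold duration (default 5 ms).
#' @param fs sampling rate, Hz.
#' @return list with `onset_idx`, `offset_idx` and `noise_rms` (uV).
#' @export
detect_qrs_bounds <- function(vm, noise_window, k_sigma = 3, sustain_ms = 5,
                              fs = 2000) {
  vm <- signal_samples(vm)
  if (sustain_ms <= 0)
    stop_aiqp("invalid_parameter", "sustain_ms must be > 0")
  nw <- vm[noise_window[1]:noise_window[2]]
  threshold <- mean(nw) + k_sigma * stats::sd(nw)
  sustain_n <- max(1L, round(sustain_ms * fs / 1000))
  r <- rle(vm > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$values & r$lengths >= sustain_n)
  if (length(long) == 0)
    stop_aiqp("no_qrs_detected",
              sprintf("no supra-threshold run of >= %g ms found", sustain_ms))
  list(onset_idx = starts[long[1]],
       offset_idx = ends[long[length(long)]],
       noise_rms = rms(nw))
}

#' Time-domain ventricular late potential parameters
#'
#' Computes the three standard VLP indices from a filtered vector-magnitude
#' signal and its QRS boundaries:
#' * `fqrsd_ms` — filtered QRS duration, onset to offset;
#' * `rms40_uV` — RMS voltage over the terminal 40 ms of the QRS;
#' * `las40_ms` — duration for which the terminal QRS stays below
#'   `las_threshold_uV` (default 40 uV), scanning backward from the offset.
#'
#' @param vm filtered vector-magnitude signal (uV).
#' @param onset_idx,offset_idx QRS boundary sample indices.
#' @param fs sampling rate, Hz.
#' @param las_threshold_uV low-amplitude threshold (default 40 uV).
#' @param noise_rms optional noise RMS (uV) carried through to the output.
#' @return Object of class `vlp_params`: list with `fqrsd_ms`, `rms40_uV`,
#'   `las40_ms`, `onset_idx`, `offset_idx`, `noise_rms_uV`.
#' @export
vlp_params <- function(vm, onset_idx, offset_idx, fs = 2000,
                       las_threshold_uV = 40, noise_rms = NA_real_) {
  vm <- signal_samples(vm)
  if (onset_idx >= offset_idx)
    stop_aiqp("invalid_input", "onset must precede offset")
  n40 <- round(0.040 * fs)
  if (offset_idx < n40)
    stop_aiqp("invalid_input", "fewer than 40 ms of samples before the offset")
  fqrsd <- (offset_idx - onset_idx) / fs * 1000
  rms40 <- rms(vm[(offset_idx - n40 + 1):offset_idx])
  inside <- vm[onset_idx:offset_idx]
  above <- which(inside > las_threshold_uV)
  las40 <- if (length(above) == 0) fqrsd
           else (offset_idx - (onset_idx - 1 + max(above))) / fs * 1000
  structure(list(fqrsd_ms = fqrsd, rms40_uV = rms40, las40_ms = las40,
                 onset_idx = onset_idx, offset_idx = offset_idx,
                 noise_rms_uV = noise_rms),
            class = "vlp_params")
}

#' @export
print.vlp_params <- function(x, ...) {
  cat(sprintf("<vlp_params> fQRSD %.1f ms, RMS40 %.1f uV, LAS40 %.1f ms (noise %.2f uV)\n",
              x$fqrsd_ms, x$rms40_uV, x$las40_ms, x$noise_rms_uV))
  invisible(x)
}
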