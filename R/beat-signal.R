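#' Single-lead QRS window
#'
#' Container for one lead's QRS-window samples: an ordered amplitude series
#' in microvolts at a uniform sampling rate, optionally annotated with QRS
#' onset/offset sample indices.
#'
#' @param samples numeric vector of amplitudes in microvolts (uV); at least
#'   two finite samples.
#' @param fs sampling frequency in Hz (default 2000, i.e. 0.5 ms/sample).
#' @param lead lead label, typically one of `"X"`, `"Y"`, `"Z"`.
#' @param onset,offset optional QRS onset/offset sample indices.
#'
#' @return An object of class `beat_signal`: a list with elements `samples`,
#'   `fs`, `lead`, `onset`, `offset`.
#' @examples
#' b <- beat_signal(sin(seq(0, pi, length.out = 100)) * 500)
#' print(b)
#' @export
beat_signal <- function(samples, fs = 2000, lead = "X",
                        onset = NULL, offset = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2)
    stop_aiqp("invalid_input", "a beat signal needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop_aiqp("invalid_input", "beat signal samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop_aiqp("invalid_parameter", "sampling frequency must be a positive scalar")
  structure(
    list(samples = samples, fs = fs, lead = as.character(lead)[1],
         onset = onset, offset = offset),
    class = "beat_signal"
  )
}

#' @export
print.beat_signal <- function(x, ...) {
  cat(sprintf("<beat_signal> lead %s: %d samples @ %g Hz (%.1f ms), RMS %.1f uV\n",
              x$lead, length(x$samples), x$fs,
              1000 * length(x$samples) / x$fs, rms(x$samples)))
  invisible(x)
}

#' @export
length.beat_signal <- function(x) length(x$samples)

# Accept either a beat_signal or a bare numeric vector; returns the samples.
signal_samples <- function(y) {
  if (inherits(y, "beat_signal")) y$samples
  else if (is.numeric(y)) as.numeric(y)
  else stop_aiqp("invalid_input", "expected a beat_signal or a numeric vector")
}
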