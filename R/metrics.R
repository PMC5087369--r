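#' AIQP amplitude: RMS of the approximation residual
#'
#' The abnormal intra-QRS potential estimate is quantified as the root mean
#' square of the RBF-network approximation error over the QRS window,
#' `sqrt(mean(residual^2))`, in microvolts.
#'
#' @param residual numeric residual sequence in uV (nonempty).
#' @return scalar RMS in uV.
#' @export
aiqp_rms <- function(residual) {
  if (length(residual) == 0)
    stop_aiqp("invalid_input", "residual is empty")
  rms(residual)
}

#' AIQP-to-QRS ratio (AQR)
#'
#' Ratio of the residual RMS (the AIQP estimate) to the RMS of the measured
#' QRS complex. Because the approximation error scales in proportion to the
#' QRS amplitude, this normalization removes the amplitude dependence when
#' comparing subjects. For an orthogonal-projection residual the value lies
#' in `[0, 1]`.
#'
#' @param residual residual sequence (uV).
#' @param y the measured QRS complex (uV), same length, not identically zero.
#' @return dimensionless scalar.
#' @export
aqr <- function(residual, y) {
  y <- signal_samples(y)
  if (length(residual) != length(y))
    stop_aiqp("invalid_input", "residual and signal lengths differ")
  ry <- rms(y)
  if (ry == 0)
    stop_aiqp("degenerate_signal", "QRS complex is identically zero")
  aiqp_rms(residual) / ry
}

#' AQR over a (neuron count, spread) parameter grid
#'
#' Computes `AQR(M, sigma)` for every combination of the requested neuron
#' counts and spread parameters, e.g. the grids `AQR(20, 1:20)` (spread sweep
#' at 20 neurons) and `AQR(seq(2, 40, 2), 10)` (neuron sweep at spread 10)
#' used as discriminant features.
#'
#' Because OLS selection is nested in M, only one selection at `max(m_values)`
#' is run per spread value; smaller neuron counts reuse the leading centers
#' with weights re-solved on the subset, which is identical to a direct fit.
#' Grid cells whose selection degenerates before reaching the requested M are
#' recorded as `NA` (missing, not zero) with a message.
#'
#' @param y QRS complex ([beat_signal] or numeric).
#' @param m_values neuron counts (rows of the grid).
#' @param sigma_values spread parameters in samples (columns).
#' @param lead lead label stored with the grid (taken from `y` when it is a
#'   `beat_signal`).
#' @return Object of class `aqr_grid`: list with `lead`, `m_values`,
#'   `sigma_values` and `values`, a `length(m_values) x length(sigma_values)`
#'   matrix of dimensionless AQR values.
#' @examples
#' qrs <- simulate_qrs()
#' g <- aqr_grid(qrs, m_values = c(10, 20), sigma_values = c(5, 10))
#' g$values
#' @export
aqr_grid <- function(y, m_values, sigma_values,
                     lead = if (inherits(y, "beat_signal")) y$lead else "X") {
  if (length(m_values) == 0 || length(sigma_values) == 0)
    stop_aiqp("invalid_parameter", "m_values and sigma_values must be nonempty")
  ys <- signal_samples(y)
  m_values <- as.integer(m_values)
  vals <- matrix(NA_real_, length(m_values), length(sigma_values),
                 dimnames = list(paste0("M", m_values),
                                 paste0("s", sigma_values)))
  p <- length(ys)
  for (j in seq_along(sigma_values)) {
    # one neuron per sample needs no greedy selection (maximum-number case)
    m_sel <- max(m_values[m_values < p], 1L)
    sel <- tryCatch(
      ols_select_centers(ys, sigma_values[j], m_sel),
      aiqp_partial_selection = function(e) {
        message(sprintf("aqr_grid: sigma = %g placed only %d centers (%s)",
                        sigma_values[j], e$n_placed, conditionMessage(e)))
        e$partial
      })
    centers <- sel$model$centers
    for (i in seq_along(m_values)) {
      m <- m_values[i]
      if (m == p)
        vals[i, j] <- evaluate_centers(ys, seq_len(p), sigma_values[j])$aqr
      else if (m <= length(centers))
        vals[i, j] <- evaluate_centers(ys, centers[seq_len(m)],
                                       sigma_values[j])$aqr
    }
  }
  structure(list(lead = lead, m_values = m_values,
                 sigma_values = sigma_values, values = vals),
            class = "aqr_grid")
}

#' @export
print.aqr_grid <- function(x, ...) {
  cat(sprintf("<aqr_grid> lead %s: %d neuron counts x %d spreads (AQR %%)\n",
              x$lead, length(x$m_values), length(x$sigma_values)))
  print(round(100 * x$values, 3))
  invisible(x)
}

#' Repetition study of AIQP detectability
#'
#' Protocol for quantifying the AIQP estimation error inherent to the network:
#' the clean QRS complex is fitted once (baseline residual RMS), then in each
#' repetition a fresh 40-250 Hz colored-noise AIQP of fixed RMS is added and
#' the complex refitted with the same (M, sigma). The recorded "increase" is
#' the change in residual RMS relative to baseline. Because the inherent
#' approximation error and the added AIQP can be out of phase, some
#' repetitions may show a *negative* increase — a misjudgment, where the
#' presence of an AIQP would be missed.
#'
#' @param qrs clean QRS complex ([beat_signal] or numeric).
#' @param M,sigma network size and spread used for every fit.
#' @param noise_rms RMS of the added colored noise, uV.
#' @param band noise passband in Hz (default 40-250).
#' @param n_reps number of repetitions.
#' @param seed master seed; each repetition uses a derived substream so that
#'   increasing `n_reps` does not reshuffle earlier repetitions.
#' @param fs sampling rate in Hz (taken from `qrs` when it is a `beat_signal`).
#' @return Object of class `repetition_study`: list with `n_reps`,
#'   `baseline_error_rms` (uV), `increases` (uV, one per repetition),
#'   `n_misjudgments` (count of negative increases) and `misjudged`
#'   (repetition indices).
#' @examples
#' study <- repetition_study(simulate_qrs(), M = 20, sigma = 10,
#'                           noise_rms = 5, n_reps = 10, seed = 1)
#' mean(study$increases)
#' @export
repetition_study <- function(qrs, M, sigma, noise_rms, band = c(40, 250),
                             n_reps = 50, seed = 1,
                             fs = if (inherits(qrs, "beat_signal")) qrs$fs else 2000) {
  if (!is.numeric(noise_rms) || noise_rms < 0)
    stop_aiqp("invalid_parameter", "noise_rms must be >= 0")
  if (n_reps < 1)
    stop_aiqp("invalid_parameter", "n_reps must be >= 1")
  ys <- signal_samples(qrs)
  p <- length(ys)
  baseline <- fit_rbfnn(ys, M, sigma)
  increases <- vapply(seq_len(n_reps), function(i) {
    noise <- simulate_aiqp_noise(p, noise_rms, band = band, fs = fs,
                                 seed = derive_seed(seed, i))
    fit_rbfnn(ys + noise, M, sigma)$aiqp - baseline$aiqp
  }, numeric(1))
  structure(
    list(n_reps = as.integer(n_reps),
         baseline_error_rms = baseline$aiqp,
         increases = increases,
         n_misjudgments = sum(increases < 0),
         misjudged = which(increases < 0)),
    class = "repetition_study")
}

#' @export
print.repetition_study <- function(x, ...) {
  cat(sprintf(
    "<repetition_study> %d reps: baseline %.2f uV, increases %.2f..%.2f uV (mean %.2f), %d misjudgment(s)\n",
    x$n_reps, x$baseline_error_rms, min(x$increases), max(x$increases),
    mean(x$increases), x$n_misjudgments))
  invisible(x)
}
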