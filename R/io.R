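# Readers and writers: delimited text for signals, grids and feature tables;
# JSON for reports. CSV dialect: comma separated, mandatory header, UTF-8,
# '.' decimal; microvolt columns carry the suffix `_uV`. Floats are written
# with 15 significant digits so write/read round-trips are lossless at that
# precision and repeated writes are byte identical.

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

write_json_stable <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(15),
                              null = "null", na = "null", pretty = TRUE),
             path)
  invisible(path)
}

#' Read QRS signals from a delimited text file
#'
#' Expects a CSV with a `sample_index` column and one column per lead
#' (e.g. `X`, `Y`, `Z`, optionally suffixed `_uV`), amplitudes in microvolts.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz to attach to the signals.
#' @return named list of [beat_signal()]s, one per lead column.
#' @export
read_signal_csv <- function(path, fs = 2000) {
  if (!file.exists(path))
    stop_aiqp("invalid_input", sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_index" %in% names(df))
    stop_aiqp("invalid_input",
              sprintf("%s: missing required 'sample_index' column (line 1)", path))
  leads <- setdiff(names(df), "sample_index")
  if (length(leads) == 0)
    stop_aiqp("invalid_input", sprintf("%s: no lead columns found", path))
  bad <- which(!stats::complete.cases(df))
  if (length(bad) > 0)
    stop_aiqp("invalid_input",
              sprintf("%s: non-numeric or missing values at data line %d",
                      path, bad[1] + 1L))
  out <- lapply(leads, function(ld)
    beat_signal(df[[ld]], fs = fs, lead = sub("_uV$", "", ld)))
  names(out) <- sub("_uV$", "", leads)
  out
}

#' Write one or more signals as CSV
#'
#' @param signals a [beat_signal()] or named list of them (equal lengths).
#' @param path output CSV path.
#' @export
write_signal_csv <- function(signals, path) {
  if (inherits(signals, "beat_signal")) signals <- stats::setNames(list(signals), signals$lead)
  p <- length(signals[[1]]$samples)
  df <- data.frame(sample_index = seq_len(p))
  for (nm in names(signals))
    df[[paste0(nm, "_uV")]] <- fmt_num(signals[[nm]]$samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an RBF fit report as JSON
#'
#' Stable-keyed JSON with the selected centers, spread, neuron count,
#' weights, SSE, AIQP, AQR and per-step error reduction ratios.
#'
#' @param fit an [fit_rbfnn()] result.
#' @param path output JSON path.
#' @export
write_fit_report <- function(fit, path) {
  write_json_stable(list(
    centers = fit$model$centers,
    sigma = fit$model$sigma,
    M = fit$model$M,
    weights = fit$model$weights,
    sse = fit$sse,
    aiqp_uV = fit$aiqp,
    aqr = fit$aqr,
    err_ratios = fit$trace$err_ratios
  ), path)
}

#' Write / read an AQR grid
#'
#' The grid matrix (rows = neuron counts, columns = spreads) is written as
#' CSV, with a JSON sidecar `<path>.json` holding the lead and axis values.
#'
#' @param grid an [aqr_grid()] result.
#' @param path output CSV path.
#' @export
write_aqr_grid <- function(grid, path) {
  df <- data.frame(M = grid$m_values)
  for (j in seq_along(grid$sigma_values))
    df[[paste0("sigma_", grid$sigma_values[j])]] <- fmt_num(grid$values[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  write_json_stable(list(lead = grid$lead, m_values = grid$m_values,
                         sigma_values = grid$sigma_values), paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_aqr_grid
#' @export
read_aqr_grid <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  df <- utils::read.csv(path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- list(paste0("M", meta$m_values), paste0("s", meta$sigma_values))
  structure(list(lead = meta$lead, m_values = meta$m_values,
                 sigma_values = meta$sigma_values, values = vals),
            class = "aqr_grid")
}

#' Write / read a labelled feature table
#'
#' @param table data frame with `subject_id`, `label` and feature columns.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  num <- vapply(table, is.numeric, TRUE)
  table[num] <- lapply(table[num], fmt_num)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a simulated cohort to a directory
#'
#' One CSV per subject (`sample_index, X_uV, Y_uV, Z_uV`) plus a
#' `manifest.csv` listing subject id, label, file name and the true
#' per-subject AIQP RMS.
#'
#' @param cohort an [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(cohort$subjects, function(su) {
    f <- paste0(su$id, ".csv")
    write_signal_csv(su$signals, file.path(dir, f))
    f
  }, character(1))
  manifest <- cbind(cohort$truth[, c("subject_id", "label")],
                    file = files,
                    cohort$truth[, setdiff(names(cohort$truth),
                                           c("subject_id", "label"))])
  write_feature_table(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @param fs sampling rate, Hz.
#' @return list of subjects (`id`, `label`, `signals`) usable by
#'   [cohort_aqr_features()].
#' @export
read_cohort <- function(dir, fs = 2000) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    list(id = manifest$subject_id[i], label = manifest$label[i],
         signals = read_signal_csv(file.path(dir, manifest$file[i]), fs = fs))
  })
}

#' Write a performance report as JSON
#'
#' @param report a `performance_report`.
#' @param path output JSON path.
#' @export
write_performance_report <- function(report, path) {
  write_json_stable(list(
    sp_pct = report$sp, se_pct = report$se, tpa_pct = report$tpa,
    auc_pct = report$auc, threshold = report$threshold,
    confusion = as.list(report$confusion)
  ), path)
}

#' Write VLP parameters as JSON
#'
#' @param params a [vlp_params()] result.
#' @param path output JSON path.
#' @export
write_vlp_json <- function(params, path) {
  write_json_stable(list(
    fqrsd_ms = params$fqrsd_ms, rms40_uV = params$rms40_uV,
    las40_ms = params$las40_ms, onset_idx = params$onset_idx,
    offset_idx = params$offset_idx, noise_rms_uV = params$noise_rms_uV
  ), path)
}

#' Write a repetition study as CSV
#'
#' @param study a [repetition_study()] result.
#' @param path output CSV path.
#' @export
write_repetition_study <- function(study, path) {
  utils::write.csv(
    data.frame(repetition = seq_len(study$n_reps),
               increase_uV = fmt_num(study$increases),
               misjudged = seq_len(study$n_reps) %in% study$misjudged),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Configuration mirrors the CLI flags: sampling rate, filter band/order,
#' grid axes, VLP thresholds, cohort spec fields, seed, output directory.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_aiqp("invalid_input", sprintf("config file not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}
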