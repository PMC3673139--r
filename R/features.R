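# Wavelet energy features.
#
# For one axis decomposed to level i, the descriptor is the energy
# distribution ratio (EDR) of the approximation vector and of each detail
# vector -- the fraction of total squared-coefficient energy each carries --
# followed by the normalized variances of the same i+1 coefficient vectors.
# Both blocks are dimensionless and sum to one, which makes the features
# invariant to amplitude scaling and hence to device gain. Three axes give
# 6(1+i) features per window.

#' Total coefficient energy of a decomposition
#'
#' `E_T = A_i A_i' + sum_j D_j D_j'`: the sum of squares of every coefficient.
#' For orthogonal wavelets this equals the energy of the (padded) signal.
#'
#' @param coeffs a `dwt_coefficients` object.
#' @return nonnegative scalar.
#' @export
total_energy <- function(coeffs) {
  .validate_coefficients(coeffs)
  sum(coeffs$approximation^2) + sum(unlist(coeffs$details)^2)
}

#' Energy distribution ratios
#'
#' `EDR_A = A_i A_i' / E_T` and `EDR_Dj = D_j D_j' / E_T`; the i+1 ratios sum
#' to one by construction. An all-zero decomposition (possible only for an
#' all-zero window) falls back to `EDR_A = 1`, all `EDR_Dj = 0`, with a
#' warning.
#'
#' @param coeffs a `dwt_coefficients` object.
#' @return list with elements `EDR_A` (scalar) and `EDR_D` (vector, element
#'   `j` for detail level `j`).
#' @export
energy_ratios <- function(coeffs) {
  .validate_coefficients(coeffs)
  ea <- sum(coeffs$approximation^2)
  ed <- vapply(coeffs$details, function(d) sum(d^2), 0)
  et <- ea + sum(ed)
  if (et == 0) {
    warning("zero total energy; falling back to EDR_A = 1", call. = FALSE)
    return(list(EDR_A = 1, EDR_D = rep(0, coeffs$level)))
  }
  list(EDR_A = ea / et, EDR_D = ed / et)
}

.pop_var <- function(v) {
  mean((v - mean(v))^2)
}

#' Normalized coefficient variances
#'
#' Population variance of each of the i+1 coefficient vectors (`A_i`,
#' `D_1..D_i`), normalized so the values sum to one. Population (divide by n)
#' rather than sample variance is used because deep-level vectors can have a
#' single element. If every variance is zero the uniform distribution
#' `1/(i+1)` is returned.
#'
#' @param coeffs a `dwt_coefficients` object.
#' @return numeric vector of length `level + 1`, ordered `A_i, D_1, ..., D_i`.
#' @export
coefficient_variances <- function(coeffs) {
  .validate_coefficients(coeffs)
  v <- c(.pop_var(coeffs$approximation),
         vapply(coeffs$details, .pop_var, 0))
  s <- sum(v)
  if (s == 0) {
    return(rep(1 / length(v), length(v)))
  }
  v / s
}

.axis_feature_names <- function(axis, level) {
  paste(axis,
        c("EDR_A", paste0("EDR_D", seq_len(level)),
          "NVAR_A", paste0("NVAR_D", seq_len(level))),
        sep = "_")
}

#' Names of the 6(1+i) window features, in canonical order
#'
#' The ordering is normative (per axis x, y, z: the EDR block
#' `EDR_A, EDR_D1..EDR_Di` then the normalized-variance block
#' `NVAR_A, NVAR_D1..NVAR_Di`) so that saved feature tables are portable.
#'
#' @param level decomposition level i.
#' @return character vector of length `6 * (1 + level)`.
#' @export
feature_names <- function(level) {
  unlist(lapply(c("x", "y", "z"), .axis_feature_names, level = level))
}

#' Extract the wavelet energy feature vector of one window
#'
#' Decomposes each axis independently with [dwt_decompose()] and assembles
#' the per-axis EDR and normalized-variance blocks.
#'
#' @param window an `activity_window`.
#' @param wavelet wavelet name or spec.
#' @param level decomposition level, 1..7.
#' @return named numeric vector of length `6 * (1 + level)` with attributes
#'   `wavelet`, `level`, `window_length`, `source_rate` and `label`.
#' @export
extract_features <- function(window, wavelet, level) {
  stopifnot(inherits(window, "activity_window"))
  w <- get_wavelet(wavelet)
  axes <- list(x = window$x, y = window$y, z = window$z)
  vals <- unlist(lapply(names(axes), function(ax) {
    coeffs <- dwt_decompose(axes[[ax]], w, level)
    edr <- energy_ratios(coeffs)
    nv <- coefficient_variances(coeffs)
    out <- c(edr$EDR_A, edr$EDR_D, nv)
    names(out) <- .axis_feature_names(ax, level)
    out
  }))
  structure(vals, wavelet = w$name, level = as.integer(level),
            window_length = window$length, source_rate = window$source_rate,
            label = window$label)
}

#' Build a per-window feature table from activity logs
#'
#' Cuts a centred window of `window_length` seconds from every log and
#' extracts its feature vector; the result is the flat table consumed by
#' [sport_classifier()] and the evaluation protocol.
#'
#' @param logs list of `activity_log` objects.
#' @param wavelet wavelet name or spec.
#' @param level decomposition level, 1..7.
#' @param window_length window length in seconds.
#' @return data frame: `window_id`, `label` (factor over A1..A7), `wavelet`,
#'   `level`, `window_length`, then the `6(1+level)` feature columns.
#' @export
feature_table <- function(logs, wavelet, level, window_length) {
  w <- get_wavelet(wavelet)
  rows <- lapply(logs, function(log) {
    extract_features(segment_window(log, window_length), w, level)
  })
  mat <- do.call(rbind, rows)
  data.frame(
    window_id = sprintf("w_%04d", seq_along(logs)),
    label = factor(vapply(logs, function(l) l$label, ""),
                   levels = .activity_labels),
    wavelet = w$name, level = as.integer(level),
    window_length = window_length,
    mat, check.names = FALSE)
}

#' Numeric feature columns of a feature table
#'
#' @param features a data frame from [feature_table()] (or any data frame
#'   whose feature columns are named like `x_EDR_A`).
#' @return data frame holding only the feature columns.
#' @export
feature_matrix <- function(features) {
  keep <- grepl("^[xyz]_(EDR|NVAR)_", names(features))
  if (!any(keep)) {
    stop("no feature columns (x_EDR_* ...) found", call. = FALSE)
  }
  features[, keep, drop = FALSE]
}
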