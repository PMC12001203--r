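#' Quality-control configuration
#'
#' Bundles the thresholds of the LC-MS quality-control pipeline. Defaults
#' target unit-resolution LC-MS as used for reaction monitoring: an absolute
#' m/z tolerance of 0.3 Da, TIC peaks kept when their prominence reaches 5%
#' of the TIC maximum and their base-to-base width spans at least 2 scans,
#' and peak spectra aggregated by summing scans across the peak window
#' (robust to apex jitter).
#'
#' @param mz_tolerance Absolute m/z match tolerance in Da (default 0.3).
#' @param ppm Optional relative tolerance in ppm; when non-`NULL` it replaces
#'   the absolute tolerance (`tol = ppm * 1e-6 * expected_mz`). Off by
#'   default.
#' @param adducts Adduct rule tibble (default `[M+H]+` only; see
#'   [crm_adducts()]).
#' @param min_prominence_fraction TIC-peak prominence threshold as a fraction
#'   of the TIC maximum (default 0.05).
#' @param min_peak_width Minimum base-to-base peak width in scans (default 2).
#' @param spectrum_aggregation `"sum"` (default) or `"apex"`.
#' @return A `crm_qc_config` list.
#' @export
qc_config <- function(mz_tolerance = 0.3,
                      ppm = NULL,
                      adducts = crm_adducts("[M+H]+"),
                      min_prominence_fraction = 0.05,
                      min_peak_width = 2L,
                      spectrum_aggregation = c("sum", "apex")) {
  stopifnot(mz_tolerance > 0,
            min_prominence_fraction > 0, min_prominence_fraction < 1,
            min_peak_width >= 1)
  structure(
    list(mz_tolerance = mz_tolerance,
         ppm = ppm,
         adducts = tibble::as_tibble(adducts),
         min_prominence_fraction = min_prominence_fraction,
         min_peak_width = as.integer(min_peak_width),
         spectrum_aggregation = match.arg(spectrum_aggregation)),
    class = "crm_qc_config"
  )
}

ion_tolerance <- function(config, expected_mz) {
  if (!is.null(config$ppm)) config$ppm * 1e-6 * expected_mz
  else rep_len(config$mz_tolerance, length(expected_mz))
}
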