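#' Match expected product ions in a peak spectrum
#'
#' For every (target, adduct) expected ion, the most intense signal within
#' the m/z tolerance is reported, with its intensity rank against the whole
#' peak spectrum (rank 1 = base peak). Ions with no signal within tolerance
#' produce no row, so widening the tolerance can only add matches.
#'
#' @param spectrum Tibble with `mz` and `intensity` (see [peak_spectrum()]).
#' @param ions Expected-ion table from [expected_ions()] (columns
#'   `target_id`, `adduct`, `expected_mz`), or a product table from
#'   [enumerate_products()], in which case ions are derived using the
#'   config's adducts.
#' @param config A [qc_config()].
#' @return Tibble: `target_id`, `adduct`, `expected_mz`, `observed_mz`,
#'   `intensity`, `rank`, `within_tol`, `most_prominent`.
#' @export
match_expected <- function(spectrum, ions, config = qc_config()) {
  if (!"expected_mz" %in% names(ions)) {
    ions <- expected_ions(ions, adducts = config$adducts)
  }
  empty <- tibble::tibble(target_id = character(), adduct = character(),
                          expected_mz = numeric(), observed_mz = numeric(),
                          intensity = numeric(), rank = integer(),
                          within_tol = logical(), most_prominent = logical())
  if (!nrow(spectrum) || !nrow(ions)) return(empty)
  ranks <- as.integer(rank(-spectrum$intensity, ties.method = "min"))
  tol <- ion_tolerance(config, ions$expected_mz)
  rows <- purrr::map(seq_len(nrow(ions)), function(i) {
    hit <- which(abs(spectrum$mz - ions$expected_mz[i]) <= tol[i])
    if (!length(hit)) return(NULL)
    best <- hit[which.max(spectrum$intensity[hit])]
    tibble::tibble(
      target_id = ions$target_id[i], adduct = ions$adduct[i],
      expected_mz = ions$expected_mz[i], observed_mz = spectrum$mz[best],
      intensity = spectrum$intensity[best], rank = ranks[best],
      within_tol = TRUE, most_prominent = ranks[best] == 1L
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) empty else out
}

#' Assign a success/fail verdict for one sample
#'
#' Success is the identification of an expected product ion in the spectrum
#' of at least one TIC peak. Confidence is `"prominent"` when some match is
#' the base peak of its peak spectrum, `"minor"` otherwise — matched-but-
#' not-most-prominent ions still count as success but are flagged, since
#' manual review tends to reclassify exactly these.
#'
#' @param sample_id Sample identifier.
#' @param peaks Peak table from [find_tic_peaks()].
#' @param matches_per_peak List of [match_expected()] tables, one per peak
#'   row.
#' @return One-row tibble: `sample_id`, `status` (`"success"`/`"fail"`),
#'   `confidence` (`"prominent"`/`"minor"`/`NA`), `n_peaks`, `n_matches`,
#'   `top_target`, `matches` (list-column of per-peak match tables with a
#'   `peak` column).
#' @export
assign_verdict <- function(sample_id, peaks, matches_per_peak) {
  stopifnot(nrow(peaks) == length(matches_per_peak))
  all_matches <- purrr::imap(matches_per_peak, function(m, i) {
    if (is.null(m) || !nrow(m)) return(NULL)
    dplyr::mutate(m, peak = as.integer(i), .before = 1)
  })
  all_matches <- dplyr::bind_rows(all_matches)
  success <- nrow(all_matches) > 0 && any(all_matches$within_tol)
  confidence <- if (!success) NA_character_
                else if (any(all_matches$most_prominent)) "prominent"
                else "minor"
  top <- if (success) {
    all_matches$target_id[which.max(all_matches$intensity)]
  } else NA_character_
  tibble::tibble(
    sample_id = sample_id,
    status = if (success) "success" else "fail",
    confidence = confidence,
    n_peaks = nrow(peaks),
    n_matches = nrow(all_matches),
    top_target = top,
    matches = list(all_matches)
  )
}

#' Run the full QC chain on one run
#'
#' TIC construction, peak finding, per-peak spectrum aggregation, expected-
#' ion matching and verdict assignment, in one call.
#'
#' @param run A `crm_run`.
#' @param targets Product table (or precomputed expected-ion table).
#' @param config A [qc_config()].
#' @return One-row verdict tibble (see [assign_verdict()]).
#' @export
run_qc <- function(run, targets, config = qc_config()) {
  ions <- if ("expected_mz" %in% names(targets)) targets
          else expected_ions(targets, adducts = config$adducts)
  tic <- compute_tic(run)
  peaks <- find_tic_peaks(tic, config)
  matches <- purrr::map(seq_len(nrow(peaks)), function(i) {
    match_expected(peak_spectrum(run, peaks[i, ], config), ions, config)
  })
  assign_verdict(run$sample_id, peaks, matches)
}

#' QC an entire campaign of mzML files
#'
#' @param paths Character vector of mzML paths (or a directory, expanded to
#'   its `*.mzML` files in sorted order).
#' @param targets Product table or expected-ion table. When it carries a
#'   `sample_id` column mapping samples to their intended target, each run is
#'   matched only against its own target's ions; otherwise every run is
#'   searched for all targets.
#' @param config A [qc_config()].
#' @return Verdict tibble, one row per run.
#' @export
qc_campaign <- function(paths, targets, config = qc_config()) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.mzML$", full.names = TRUE,
                             ignore.case = TRUE))
  }
  if (!length(paths)) abort_crm("no mzML files to QC", "crm_mzml_error")
  per_sample <- "sample_id" %in% names(targets) &&
    !"expected_mz" %in% names(targets)
  rows <- purrr::map(paths, function(p) {
    run <- read_run(p)
    tgt <- if (per_sample) {
      dplyr::filter(structure(targets, adducts = attr(targets, "adducts")),
                    .data$sample_id == run$sample_id)
    } else targets
    if (per_sample) attr(tgt, "adducts") <- attr(targets, "adducts")
    run_qc(run, tgt, config)
  })
  dplyr::bind_rows(rows)
}
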