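#' Confusion category of a machine verdict against a human label
#'
#' TP: both call the synthesis successful; TN: both call it failed;
#' FP: machine success, human no; FN: machine fail, human yes.
#'
#' @param status Machine verdicts, `"success"`/`"fail"` (or logical).
#' @param human_label Human labels, `"yes"`/`"no"` (or logical). Missing
#'   labels are an error: unreviewed samples cannot be reconciled.
#' @return Character vector in `c("TP", "TN", "FP", "FN")`.
#' @examples
#' confusion_category(c("success", "fail"), c("yes", "yes"))  # TP, FN
#' @export
confusion_category <- function(status, human_label) {
  m <- if (is.logical(status)) status else status == "success"
  if (is.logical(human_label)) {
    h <- human_label
  } else {
    h <- dplyr::case_match(tolower(as.character(human_label)),
                           "yes" ~ TRUE, "no" ~ FALSE, .default = NA)
  }
  if (any(is.na(h)) || any(is.na(m))) {
    abort_crm("missing or unrecognised human label", "crm_report_error")
  }
  dplyr::case_when(m & h ~ "TP", !m & !h ~ "TN", m & !h ~ "FP",
                   .default = "FN")
}

#' Reconcile machine verdicts with human annotations
#'
#' @param verdicts Verdict tibble from [qc_campaign()]/[run_qc()].
#' @param annotations Tibble with `sample_id`, `human_label` (`yes`/`no`)
#'   and optionally `note` and `iteration`.
#' @return The verdict tibble with `human_label`, `note`, `iteration` (when
#'   provided) and `category` columns appended.
#' @export
reconcile_verdicts <- function(verdicts, annotations) {
  keep <- intersect(c("sample_id", "human_label", "note", "iteration"),
                    names(annotations))
  if (!all(c("sample_id", "human_label") %in% keep)) {
    abort_crm("annotations need sample_id and human_label columns",
              "crm_report_error")
  }
  missing <- setdiff(verdicts$sample_id, annotations$sample_id)
  if (length(missing)) {
    abort_crm(paste0("no human label for sample(s): ",
                     paste(utils::head(missing, 5), collapse = ", ")),
              "crm_report_error")
  }
  out <- dplyr::left_join(verdicts, annotations[keep], by = "sample_id")
  out$category <- confusion_category(out$status, out$human_label)
  out
}

#' Per-iteration quality-control report
#'
#' Aggregates reconciled verdicts into one row per iteration, in the layout
#' of a campaign QC summary table: sample count, % agreement with the human
#' labels, the four confusion counts and the percentage each category
#' represents. Percentages are computed on the unrounded counts and rounded
#' once, half-up, at reporting precision.
#'
#' @param reconciled Output of [reconcile_verdicts()] including an
#'   `iteration` column.
#' @param digits Decimal places for the per-iteration percentages
#'   (default 1).
#' @return Tibble with columns `iteration`, `n_samples`, `match_pct`,
#'   `tp`, `tn`, `fn`, `fp`, `tp_tn_pct`, `fn_pct`, `fp_pct`.
#' @export
iteration_report <- function(reconciled, digits = 1) {
  stopifnot("iteration" %in% names(reconciled),
            "category" %in% names(reconciled))
  reconciled |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      tp = sum(.data$category == "TP"),
      tn = sum(.data$category == "TN"),
      fn = sum(.data$category == "FN"),
      fp = sum(.data$category == "FP"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      match_pct = round_half_up(100 * (.data$tp + .data$tn) / .data$n_samples,
                                digits),
      tp_tn_pct = round_half_up(100 * (.data$tp + .data$tn) / .data$n_samples,
                                digits),
      fn_pct = round_half_up(100 * .data$fn / .data$n_samples, digits),
      fp_pct = round_half_up(100 * .data$fp / .data$n_samples, digits)
    ) |>
    dplyr::select("iteration", "n_samples", "match_pct", "tp", "tn",
                  "fn", "fp", "tp_tn_pct", "fn_pct", "fp_pct")
}

#' Summarise per-iteration QC rows into campaign totals
#'
#' Summary percentage cells are the arithmetic mean of the per-iteration
#' percentages (iterations weigh equally regardless of size), rounded
#' half-up to integers as printed in summary rows; count cells are sums.
#' Iterations with missing percentage cells (not evaluated) are excluded
#' from the means but their counts still sum.
#'
#' @param per_iteration Tibble of per-iteration rows, e.g. from
#'   [iteration_report()]. Columns ending in `_pct` are treated as
#'   percentages; all other numeric columns as counts.
#' @return A `crm_qc_summary`: list with `per_iteration`, `totals` (one-row
#'   tibble, percentage cells rounded to integers) and `totals_raw`
#'   (unrounded means).
#' @export
summarize_iterations <- function(per_iteration) {
  stopifnot(is.data.frame(per_iteration))
  if (!nrow(per_iteration)) {
    abort_crm("no iteration rows to summarise", "crm_report_error")
  }
  num <- names(per_iteration)[vlgl(per_iteration, is.numeric)]
  pct_cols <- grep("_pct$", num, value = TRUE)
  count_cols <- setdiff(num, pct_cols)
  raw <- purrr::map_dbl(per_iteration[pct_cols],
                        function(x) mean(x, na.rm = TRUE))
  totals <- tibble::as_tibble(c(
    purrr::map(per_iteration[count_cols],
               function(x) sum(x, na.rm = TRUE)),
    purrr::map(raw, round_half_up)
  ))[c(count_cols, pct_cols)]
  structure(list(per_iteration = tibble::as_tibble(per_iteration),
                 totals = totals,
                 totals_raw = tibble::as_tibble(as.list(raw))),
            class = "crm_qc_summary")
}

#' @export
print.crm_qc_summary <- function(x, ...) {
  cat("<crm_qc_summary>", nrow(x$per_iteration), "iteration(s)\n")
  print(x$per_iteration)
  cat("totals (percentage cells are means of iteration percentages):\n")
  print(x$totals)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.crm_qc_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$per_iteration,
                  iteration = as.character(.data$iteration)),
    dplyr::mutate(x$totals, iteration = "Total", .before = 1)
  )
}

#' @importFrom generics glance
#' @export
glance.crm_qc_summary <- function(x, ...) x$totals
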