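#' Stage counts of a screening funnel
#'
#' The campaign funnel runs: attempted syntheses -> LC-MS-confirmed
#' products -> usable diffraction datasets -> product-bound structures
#' (with starting-material-bound structures tracked alongside).
#'
#' @param attempted Number of attempted syntheses.
#' @param lcms_success Syntheses whose expected product ion was detected.
#' @param datasets_usable Usable X-ray datasets from soaked CRMs.
#' @param product_bound Structures with a bound reaction product.
#' @param starting_material_bound Structures binding a starting material
#'   (default 0).
#' @return A `crm_stage_counts` list.
#' @export
stage_counts <- function(attempted, lcms_success, datasets_usable,
                         product_bound, starting_material_bound = 0) {
  counts <- c(attempted = attempted, lcms_success = lcms_success,
              datasets_usable = datasets_usable,
              product_bound = product_bound,
              starting_material_bound = starting_material_bound)
  stopifnot(all(counts >= 0))
  if (product_bound > datasets_usable || datasets_usable > attempted) {
    abort_crm("stage counts violate funnel ordering", "crm_triage_error")
  }
  structure(as.list(counts), class = "crm_stage_counts")
}

#' Read funnel counts from a YAML config
#'
#' @param path YAML file with the [stage_counts()] fields.
#' @return A `crm_stage_counts`.
#' @export
read_stage_counts <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(stage_counts, cfg[intersect(names(cfg), names(formals(stage_counts)))])
}

#' Funnel success rates between workflow stages
#'
#' Each rate is the count of successful outcomes of a stage over the
#' successful outcomes of the previous stage. Raw percentages are retained
#' alongside two printed precisions (half-up at one decimal and at integer
#' precision, both of which appear in campaign figures). A zero denominator
#' yields `NA` (undefined), never 0.
#'
#' @param counts A [stage_counts()].
#' @return Tibble: `stage`, `numerator`, `denominator`, `fraction`,
#'   `pct` (raw), `pct_1dp`, `pct_int`.
#' @examples
#' funnel_rates(stage_counts(1876, 1077, 969, 22))
#' @export
funnel_rates <- function(counts) {
  stopifnot(inherits(counts, "crm_stage_counts"))
  tbl <- tibble::tibble(
    stage = c("lcms_success", "datasets_usable", "product_bound"),
    numerator = c(counts$lcms_success, counts$datasets_usable,
                  counts$product_bound),
    denominator = c(counts$attempted, counts$lcms_success,
                    counts$datasets_usable)
  )
  tbl |>
    dplyr::mutate(
      fraction = ifelse(.data$denominator > 0,
                        .data$numerator / .data$denominator, NA_real_),
      pct = 100 * .data$fraction,
      pct_1dp = round_half_up(.data$pct, 1),
      pct_int = round_half_up(.data$pct, 0)
    )
}

#' Resource totals: manual versus automated synthesis
#'
#' Computes campaign-level resource totals from per-iteration rows and the
#' manual-vs-automated savings. Manual figures are per-target and scale
#' with the number of targets; automated time and column figures are
#' per-iteration totals (a robot run handles the whole plate).
#'
#' @param rows Tibble with columns `iteration`, `n_targets`,
#'   `manual_days_per_target`, `auto_days_total`,
#'   `manual_columns_per_target`, `auto_columns_total`,
#'   `manual_solvent_per_target_ml`, `auto_solvent_per_target_ml`.
#' @return A `crm_resource_summary` list: totals for both arms (days,
#'   years at 365 days/year, columns/work-ups, solvent in litres), saving
#'   fractions (automated as % of manual) and the manual/automated solvent
#'   fold reduction. All values unrounded; rounding is applied at render
#'   time only.
#' @export
resource_totals <- function(rows) {
  need <- c("iteration", "n_targets", "manual_days_per_target",
            "auto_days_total", "manual_columns_per_target",
            "auto_columns_total", "manual_solvent_per_target_ml",
            "auto_solvent_per_target_ml")
  missing <- setdiff(need, names(rows))
  if (length(missing)) {
    abort_crm(paste0("resource table lacks column(s): ",
                     paste(missing, collapse = ", ")), "crm_triage_error")
  }
  if (!nrow(rows)) abort_crm("empty resource table", "crm_triage_error")
  stopifnot(all(vlgl(rows[setdiff(need, "iteration")],
                     function(x) all(x >= 0))))
  manual_days <- sum(rows$n_targets * rows$manual_days_per_target)
  manual_columns <- sum(rows$n_targets * rows$manual_columns_per_target)
  manual_solvent <- sum(rows$n_targets * rows$manual_solvent_per_target_ml) / 1000
  auto_days <- sum(rows$auto_days_total)
  auto_columns <- sum(rows$auto_columns_total)
  auto_solvent <- sum(rows$n_targets * rows$auto_solvent_per_target_ml) / 1000
  structure(list(
    n_targets = sum(rows$n_targets),
    manual_total_days = manual_days,
    manual_total_years = manual_days / 365,
    manual_total_columns = manual_columns,
    manual_total_solvent_l = manual_solvent,
    auto_total_days = auto_days,
    auto_total_columns = auto_columns,
    auto_total_solvent_l = auto_solvent,
    saving_fraction_time_pct = 100 * auto_days / manual_days,
    saving_fraction_columns_pct = 100 * auto_columns / manual_columns,
    saving_fraction_solvent_pct = 100 * auto_solvent / manual_solvent,
    fold_reduction_solvent = manual_solvent / auto_solvent,
    rows = tibble::as_tibble(rows)
  ), class = "crm_resource_summary")
}

#' @export
print.crm_resource_summary <- function(x, ...) {
  cat("<crm_resource_summary>", x$n_targets, "targets over",
      nrow(x$rows), "iteration(s)\n")
  cat(sprintf("  time:    %d d manual (%.2f y) vs %d d automated (%.1f%%)\n",
              x$manual_total_days, x$manual_total_years, x$auto_total_days,
              x$saving_fraction_time_pct))
  cat(sprintf("  columns: %d manual vs %d automated (%.1f%%)\n",
              x$manual_total_columns, x$auto_total_columns,
              x$saving_fraction_columns_pct))
  cat(sprintf("  solvent: %.2f L manual vs %.2f L automated (%.0f-fold less)\n",
              x$manual_total_solvent_l, x$auto_total_solvent_l,
              x$fold_reduction_solvent))
  invisible(x)
}

#' @export
tidy.crm_resource_summary <- function(x, ...) {
  vals <- x[setdiff(names(x), "rows")]
  tibble::tibble(quantity = names(vals), value = vnum(vals, identity))
}

#' Render campaign report files
#'
#' Writes a deterministic CSV + Markdown + JSON bundle reproducing the
#' layout of campaign resource and QC summary tables: rounded values in the
#' Markdown, raw unrounded values in the JSON (rounded totals compound
#' error, so machine-readable output always carries the raw numbers).
#' Sections whose input is `NULL` are emitted as headers only.
#'
#' @param dir Output directory (created if needed).
#' @param funnel Optional [funnel_rates()] table.
#' @param resources Optional [resource_totals()] summary.
#' @param qc_summary Optional [summarize_iterations()] summary.
#' @return Tibble of written files, invisibly.
#' @export
render_reports <- function(dir, funnel = NULL, resources = NULL,
                           qc_summary = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- c("# Campaign report", "")
  json <- list()
  files <- character()

  md <- c(md, "## Funnel success rates", "")
  if (!is.null(funnel)) {
    f <- file.path(dir, "funnel.csv")
    readr::write_csv(funnel, f)
    files <- c(files, f)
    md <- c(md, "| stage | n/N | rate |", "|---|---|---|",
            sprintf("| %s | %d/%d | %.1f%% |", funnel$stage,
                    funnel$numerator, funnel$denominator, funnel$pct_1dp),
            "")
    json$funnel <- funnel
  } else {
    md <- c(md, "(not provided)", "")
  }

  md <- c(md, "## Resources: manual vs automated", "")
  if (!is.null(resources)) {
    t_ <- tidy(resources)
    f <- file.path(dir, "resources.csv")
    readr::write_csv(t_, f)
    files <- c(files, f)
    md <- c(md,
      sprintf("- Manual: %d days (%.2f y), %d columns/work-ups, %.2f L solvent",
              resources$manual_total_days, resources$manual_total_years,
              resources$manual_total_columns,
              resources$manual_total_solvent_l),
      sprintf("- Automated: %d days, %d columns/work-ups, %.2f L solvent",
              resources$auto_total_days, resources$auto_total_columns,
              resources$auto_total_solvent_l),
      sprintf(
        "- Saving fractions (auto/manual): time %.1f%%, columns %.1f%%, solvent %.1f%% (%.0f-fold solvent reduction)",
        resources$saving_fraction_time_pct,
        resources$saving_fraction_columns_pct,
        resources$saving_fraction_solvent_pct,
        resources$fold_reduction_solvent),
      "")
    json$resources <- as.list(t_ |> tidyr::pivot_wider(
      names_from = "quantity", values_from = "value"))
  } else {
    md <- c(md, "(not provided)", "")
  }

  md <- c(md, "## LC-MS quality control", "")
  if (!is.null(qc_summary)) {
    f <- file.path(dir, "qc_per_iteration.csv")
    readr::write_csv(qc_summary$per_iteration, f)
    f2 <- file.path(dir, "qc_totals.csv")
    readr::write_csv(qc_summary$totals, f2)
    files <- c(files, f, f2)
    tot <- qc_summary$totals
    md <- c(md, paste0("Totals (percentage cells are means of per-iteration ",
                       "percentages): "),
            paste(sprintf("%s = %s", names(tot), unlist(tot)),
                  collapse = ", "),
            "")
    json$qc <- list(per_iteration = qc_summary$per_iteration,
                    totals = qc_summary$totals,
                    totals_raw = qc_summary$totals_raw)
  } else {
    md <- c(md, "(not provided)", "")
  }

  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, md_path, json_path)
  invisible(tibble::tibble(file = files))
}

#' Plot a screening funnel
#'
#' @param counts A [stage_counts()].
#' @return A ggplot bar chart of stage counts with rate labels.
#' @export
plot_funnel <- function(counts) {
  rates <- funnel_rates(counts)
  df <- tibble::tibble(
    stage = factor(c("attempted", rates$stage),
                   levels = c("attempted", rates$stage)),
    count = c(counts$attempted, rates$numerator)
  )
  lab <- c(NA, sprintf("%.1f%%", rates$pct_1dp))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(lab), "", lab)),
                       vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "samples") +
    ggplot2::theme_minimal()
}
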