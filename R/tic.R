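#' Total ion chromatogram of a run
#'
#' @param run A `crm_run`.
#' @return Tibble with `scan`, `rt` and `tic` (per-scan summed intensity).
#' @export
compute_tic <- function(run) {
  stopifnot(inherits(run, "crm_run"))
  tibble::tibble(
    scan = run$scans$scan,
    rt = run$scans$rt,
    tic = vnum(run$scans$intensity, sum)
  )
}

# Local maxima of a trace with plateau handling: a plateau of equal values
# higher than both flanks yields one apex at its midpoint.
local_maxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  if (k < 3) return(integer())
  keep <- which(seq_len(k) > 1 & seq_len(k) < k &
                r$values > c(-Inf, r$values[-k]) &
                r$values > c(r$values[-1], -Inf))
  as.integer(floor((starts[keep] + ends[keep]) / 2))
}

# Prominence of peak at index i: height minus the higher of the two key
# saddles, where each saddle is the minimum between the peak and the nearest
# strictly higher point (or the trace end) on that side. Returns the saddle
# positions as the peak bases.
peak_prominence <- function(x, apex) {
  h <- x[apex]
  n <- length(x)
  left <- if (apex == 1) integer() else seq_len(apex - 1)
  higher_l <- left[x[left] > h]
  lo <- if (length(higher_l)) max(higher_l) + 1L else 1L
  left_base <- (lo:apex)[which.min(x[lo:apex])]
  right <- if (apex == n) integer() else (apex + 1):n
  higher_r <- right[x[right] > h]
  hi <- if (length(higher_r)) min(higher_r) - 1L else n
  right_base <- (apex:hi)[which.min(x[apex:hi])]
  list(prominence = h - max(x[left_base], x[right_base]),
       left_base = left_base, right_base = right_base)
}

#' Find peaks in a total ion chromatogram
#'
#' Local maxima are kept when their topographic prominence reaches
#' `min_prominence_fraction` of the TIC maximum and their base-to-base width
#' spans at least `min_peak_width` scans. Peak bounds are the prominence
#' bases, returned half-open (`left_index <= apex_index < right_index`). A
#' flat trace has no local maxima and yields an empty table.
#'
#' @param tic TIC tibble from [compute_tic()] (columns `scan`, `rt`, `tic`),
#'   or a bare numeric trace.
#' @param config A [qc_config()].
#' @return Tibble: `apex_index`, `apex_rt`, `height`, `prominence`,
#'   `left_index`, `right_index` — ordered by retention time.
#' @export
find_tic_peaks <- function(tic, config = qc_config()) {
  if (is.numeric(tic)) {
    tic <- tibble::tibble(scan = seq_along(tic), rt = as.numeric(seq_along(tic)),
                          tic = as.numeric(tic))
  }
  x <- tic$tic
  if (length(x) < 3) {
    abort_crm("TIC trace must have at least 3 scans", "crm_tic_error")
  }
  empty <- tibble::tibble(apex_index = integer(), apex_rt = numeric(),
                          height = numeric(), prominence = numeric(),
                          left_index = integer(), right_index = integer())
  apexes <- local_maxima(x)
  if (!length(apexes) || max(x) <= 0) return(empty)
  rows <- purrr::map(apexes, function(a) {
    p <- peak_prominence(x, a)
    tibble::tibble(apex_index = a, apex_rt = tic$rt[a], height = x[a],
                   prominence = p$prominence,
                   left_index = p$left_base,
                   right_index = p$right_base + 1L)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$prominence >= config$min_prominence_fraction * max(x) &
             (out$right_index - out$left_index) >= config$min_peak_width, ,
             drop = FALSE]
  out[order(out$apex_rt), , drop = FALSE]
}

#' Aggregated mass spectrum of a TIC peak
#'
#' Under `"sum"` aggregation, the centroids of every scan in the half-open
#' window `[left_index, right_index)` are pooled, clustered on the m/z axis
#' (gaps larger than half the match tolerance split clusters) and summed per
#' cluster, with intensity-weighted mean m/z. Under `"apex"` the apex scan's
#' spectrum is returned unchanged.
#'
#' @param run A `crm_run`.
#' @param peak One row of [find_tic_peaks()] output (or a list with
#'   `left_index`, `right_index`, `apex_index`).
#' @param config A [qc_config()].
#' @return Tibble with `mz` (ascending) and `intensity`.
#' @export
peak_spectrum <- function(run, peak, config = qc_config()) {
  stopifnot(inherits(run, "crm_run"))
  n <- nrow(run$scans)
  li <- peak$left_index; ri <- peak$right_index
  if (is.null(li) || is.null(ri) || li < 1 || ri > n + 1 || li > peak$apex_index ||
      peak$apex_index >= ri) {
    abort_crm("peak bounds outside run", "crm_tic_error")
  }
  idx <- if (config$spectrum_aggregation == "apex") peak$apex_index
         else seq.int(li, ri - 1L)
  mz <- unlist(run$scans$mz[idx], use.names = FALSE)
  it <- unlist(run$scans$intensity[idx], use.names = FALSE)
  if (!length(mz)) return(tibble::tibble(mz = numeric(), intensity = numeric()))
  o <- order(mz)
  mz <- mz[o]; it <- it[o]
  gap <- config$mz_tolerance / 2
  cl <- cumsum(c(1, as.integer(diff(mz) > gap)))
  tibble::tibble(
    mz = as.numeric(tapply(mz * it, cl, sum) / tapply(it, cl, sum)),
    intensity = as.numeric(tapply(it, cl, sum))
  )
}

#' Plot a TIC with detected peaks
#'
#' @param run A `crm_run`.
#' @param config A [qc_config()]; peaks are recomputed for display.
#' @return A ggplot object.
#' @export
plot_tic <- function(run, config = qc_config()) {
  tic <- compute_tic(run)
  pks <- find_tic_peaks(tic, config)
  p <- ggplot2::ggplot(tic, ggplot2::aes(x = .data$rt, y = .data$tic)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (s)", y = "TIC (counts)",
                  title = run$sample_id) +
    ggplot2::theme_minimal()
  if (nrow(pks)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(rt = pks$apex_rt, tic = pks$height),
      colour = "red"
    )
  }
  p
}
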