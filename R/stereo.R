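#' One-sided paired t-test on replicate differences
#'
#' For paired observations `(r_i, s_i)` over k replicate structures, tests
#' whether the first member systematically exceeds the second:
#' `d_i = r_i - s_i`, `t = mean(d) / (sd(d) / sqrt(k))` with the sample
#' (k-1 denominator) standard deviation, `df = k - 1`, and the one-sided
#' upper-tail Student-t p-value. Degenerate inputs are flagged rather than
#' erroring: identical non-zero differences give an infinite t with p = 0
#' (or p = 1 for the opposite direction); all-zero differences give t = 0,
#' p = 0.5.
#'
#' @param r,s Numeric vectors of equal length k >= 2.
#' @return One-row tibble: `t_stat`, `df`, `p_value`, `degenerate`.
#' @examples
#' paired_t(c(3, 2, 4), c(1, 1, 1))  # differences 2, 1, 3: t = 2*sqrt(3)
#' @export
paired_t <- function(r, s) {
  stopifnot(is.numeric(r), is.numeric(s), length(r) == length(s))
  k <- length(r)
  if (k < 2) {
    abort_crm(paste0(
      "paired test needs at least two replicate structures: a single ",
      "structure cannot support a stereochemistry call"), "crm_stereo_error")
  }
  d <- r - s
  m <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (m == 0) {
      return(tibble::tibble(t_stat = 0, df = k - 1L, p_value = 0.5,
                            degenerate = TRUE))
    }
    return(tibble::tibble(t_stat = sign(m) * Inf, df = k - 1L,
                          p_value = if (m > 0) 0 else 1, degenerate = TRUE))
  }
  t_stat <- m / (sdd / sqrt(k))
  tibble::tibble(t_stat = t_stat, df = k - 1L,
                 p_value = stats::pt(t_stat, df = k - 1, lower.tail = FALSE),
                 degenerate = FALSE)
}

#' Call the enantiomer from replicate density observations
#'
#' Each replicate structure contributes a pair of mean-positive-density
#' values, one per candidate enantiomer hypothesis. The paired t-test is run
#' on R - S; when the upper-tail p-value falls below `alpha` the call is R,
#' when the mirror test falls below `alpha` the call is S, otherwise the
#' stereochemistry is left inconclusive. The default is one-sided testing
#' at the 1% level (the two directional tests are mirror images, so one
#' computation suffices); `sided = "two"` instead calls the direction of the
#' observed difference when the two-sided p-value clears `alpha`.
#'
#' @param pairs Data frame with columns `r` and `s` (mean positive density
#'   under the R and S hypothesis, one row per replicate), e.g. built from
#'   [probe_mean_positive()] across maps. k >= 2 rows required: single
#'   structures cannot be unambiguously assigned.
#' @param alpha Significance level (default 0.01).
#' @param sided `"one"` (default) or `"two"`.
#' @return A `crm_stereo_call`: list with `call` (`"R"`, `"S"` or
#'   `"inconclusive"`), `t_stat`, `df`, `p_value` (one-sided, in the
#'   direction of the observed difference), `alpha`, `sided`, `k`,
#'   `degenerate` and the input `pairs`.
#' @export
call_enantiomer <- function(pairs, alpha = 0.01, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(is.data.frame(pairs), all(c("r", "s") %in% names(pairs)),
            alpha > 0, alpha < 1)
  if (nrow(pairs) < 2) {
    abort_crm(paste0(
      "stereochemistry cannot be called from a single structure; ",
      "provide k >= 2 replicate observations"), "crm_stereo_error")
  }
  tt <- paired_t(pairs$r, pairs$s)
  p_r <- tt$p_value                      # H1: R density exceeds S
  p_s <- if (tt$degenerate && tt$t_stat == 0) 0.5 else 1 - p_r
  p_dir <- min(p_r, p_s)
  call <- if (sided == "one") {
    if (p_r < alpha) "R" else if (p_s < alpha) "S" else "inconclusive"
  } else {
    p2 <- min(2 * p_dir, 1)
    if (p2 < alpha) (if (tt$t_stat > 0) "R" else "S") else "inconclusive"
  }
  structure(
    list(call = call, t_stat = tt$t_stat, df = tt$df, p_value = p_dir,
         alpha = alpha, sided = sided, k = nrow(pairs),
         degenerate = tt$degenerate, pairs = tibble::as_tibble(pairs)),
    class = "crm_stereo_call"
  )
}

#' @export
print.crm_stereo_call <- function(x, ...) {
  cat("<crm_stereo_call>", x$call,
      sprintf("(t = %.3f, df = %d, one-sided p = %.4g, alpha = %g, k = %d%s)\n",
              x$t_stat, x$df, x$p_value, x$alpha, x$k,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @export
tidy.crm_stereo_call <- function(x, ...) {
  dplyr::mutate(x$pairs, replicate = dplyr::row_number(),
                difference = .data$r - .data$s, .before = 1)
}

#' @export
glance.crm_stereo_call <- function(x, ...) {
  tibble::tibble(call = x$call, t_stat = x$t_stat, df = x$df,
                 p_value = x$p_value, alpha = x$alpha, sided = x$sided,
                 k = x$k, degenerate = x$degenerate)
}

#' Stereochemistry call across replicate maps
#'
#' Convenience wrapper: profiles both candidate bonds in every replicate
#' map, assembles the paired mean-positive-density table and calls the
#' enantiomer.
#'
#' @param grids List of `crm_density_grid` replicates.
#' @param probes Probe tibble with `hypothesis` values `"R"` and `"S"`
#'   (see [simulate_density_pair()]), shared across replicates, or a list of
#'   per-replicate probe tibbles.
#' @param n_samples Samples per bond (default 21).
#' @param alpha Significance level (default 0.01).
#' @param sided Test sidedness (default `"one"`).
#' @return A `crm_stereo_call`.
#' @export
call_from_maps <- function(grids, probes, n_samples = 21L, alpha = 0.01,
                           sided = c("one", "two")) {
  if (!is.data.frame(probes)) {
    stopifnot(length(probes) == length(grids))
  }
  pairs <- purrr::map_dfr(seq_along(grids), function(i) {
    pr <- if (is.data.frame(probes)) probes else probes[[i]]
    mp <- probe_mean_positive(grids[[i]], pr, n_samples)
    tibble::tibble(r = mp$mean_positive[mp$hypothesis == "R"],
                   s = mp$mean_positive[mp$hypothesis == "S"])
  })
  call_enantiomer(pairs, alpha = alpha, sided = match.arg(sided))
}
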