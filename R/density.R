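#' Trilinear interpolation of a density grid
#'
#' @param grid A `crm_density_grid`.
#' @param xyz Matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @return Numeric vector of interpolated densities.
#' @export
interpolate_density <- function(grid, xyz) {
  stopifnot(inherits(grid, "crm_density_grid"))
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  d <- dim(grid$values)
  sp <- grid_spacing(grid)
  # fractional voxel coordinates, 0-based: voxel centres at 0, 1, ..., d-1
  f <- sweep(sweep(xyz, 2, grid$origin), 2, sp, `/`)
  out_of <- f < 0 | f > matrix(rep(d - 1, each = nrow(f)), ncol = 3) + 1e-9
  if (any(out_of)) {
    bad <- which(apply(out_of, 1, any))[1]
    abort_crm(sprintf(
      "probe point %d (%.2f, %.2f, %.2f A) lies outside the grid extent",
      bad, xyz[bad, 1], xyz[bad, 2], xyz[bad, 3]), "crm_map_error")
  }
  f <- pmin(pmax(f, 0), matrix(rep(d - 1, each = nrow(f)), ncol = 3))
  i0 <- pmin(floor(f), matrix(rep(d - 2, each = nrow(f)), ncol = 3))
  t <- f - i0
  v <- grid$values
  vnum(seq_len(nrow(f)), function(r) {
    i <- i0[r, ] + 1  # 1-based corner
    tx <- t[r, 1]; ty <- t[r, 2]; tz <- t[r, 3]
    c00 <- v[i[1], i[2], i[3]] * (1 - tx) + v[i[1] + 1, i[2], i[3]] * tx
    c10 <- v[i[1], i[2] + 1, i[3]] * (1 - tx) + v[i[1] + 1, i[2] + 1, i[3]] * tx
    c01 <- v[i[1], i[2], i[3] + 1] * (1 - tx) + v[i[1] + 1, i[2], i[3] + 1] * tx
    c11 <- v[i[1], i[2] + 1, i[3] + 1] * (1 - tx) +
      v[i[1] + 1, i[2] + 1, i[3] + 1] * tx
    c0 <- c00 * (1 - ty) + c10 * ty
    c1 <- c01 * (1 - ty) + c11 * ty
    c0 * (1 - tz) + c1 * tz
  })
}

#' Density profile along a bond
#'
#' Samples the map by trilinear interpolation at `n_samples` evenly spaced
#' points on the segment from `a` to `b` (endpoints included) and computes
#' the mean positive density: the mean over samples strictly greater than
#' zero, or 0 when no sample is positive. For stereochemistry assignment,
#' `a` is the ring carbon and `b` a candidate methyl-carbon position.
#'
#' @param grid A `crm_density_grid`.
#' @param a,b Cartesian endpoints (length-3, Angstrom).
#' @param n_samples Number of sample points (default 21, matching the voxel pitch of the default fixture grid so the profile uses the independent information along the bond; >= 2).
#' @return Tibble with `t` (0..1 position along the bond), `x`, `y`, `z`
#'   and `density`; the `mean_positive` attribute carries the summary
#'   scalar (see [mean_positive()]).
#' @export
sample_bond_density <- function(grid, a, b, n_samples = 21L) {
  stopifnot(length(a) == 3, length(b) == 3, n_samples >= 2)
  if (all(a == b)) {
    abort_crm("bond endpoints coincide", "crm_map_error")
  }
  tt <- seq(0, 1, length.out = n_samples)
  xyz <- outer(tt, as.numeric(b) - as.numeric(a)) +
    matrix(rep(as.numeric(a), each = n_samples), ncol = 3)
  dens <- interpolate_density(grid, xyz)
  out <- tibble::tibble(t = tt, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        density = dens)
  attr(out, "mean_positive") <- if (any(dens > 0)) mean(dens[dens > 0]) else 0
  out
}

#' Mean positive density of a profile
#'
#' @param profile Output of [sample_bond_density()] (or any data frame with
#'   a `density` column).
#' @return Mean of the positive samples, 0 if none are positive.
#' @export
mean_positive <- function(profile) {
  mp <- attr(profile, "mean_positive")
  if (!is.null(mp)) return(mp)
  d <- profile$density
  if (any(d > 0)) mean(d[d > 0]) else 0
}

#' Simulate a replicate event-map fixture for stereochemistry assignment
#'
#' Builds a density grid containing a Gaussian signal blob centred on the
#' methyl-carbon position of one of two candidate enantiomer geometries,
#' plus white noise, together with the bond probes for both hypotheses.
#' Geometry emulates a methyl-substituted ring carbon: both candidate methyl
#' positions sit one C-C bond length (1.54 A) from the shared ring carbon,
#' pointing to opposite sides, and the blob width (sd 0.8 A) approximates a
#' methyl group's density footprint in a well-resolved event map.
#'
#' @param true_site `"R"` or `"S"`: which candidate carries the density.
#' @param effect Peak height of the signal blob, map units (>= 0; 0 gives a
#'   pure-noise map).
#' @param noise_sd White-noise standard deviation, map units.
#' @param n Grid points per axis (default 64).
#' @param spacing Voxel spacing, Angstrom (default 0.075, an oversampled
#'   event-map grid; see the methods vignette for why the fixture is
#'   generated fine-grained).
#' @param seed Integer seed for the noise field.
#' @return List: `grid` (a `crm_density_grid`) and `probes`, a tibble with
#'   one row per hypothesis (`hypothesis`, `ax, ay, az`, `bx, by, bz`).
#' @export
simulate_density_pair <- function(true_site = c("R", "S"), effect, noise_sd,
                                  n = 64L, spacing = 0.075, seed = 1L) {
  true_site <- match.arg(true_site)
  stopifnot(effect >= 0, noise_sd >= 0, n >= 8)
  side <- n * spacing
  centre <- rep(side / 2, 3)
  bond <- 1.54
  # tetrahedral-ish split: the two candidate methyl directions from the ring
  # carbon, one per enantiomer, separated by ~109.5 degrees. The directions
  # are mirror images across a lattice plane so that both probe bonds have
  # identical geometry relative to the voxel grid (no hypothesis is favoured
  # by interpolation artifacts).
  half <- 109.5 / 2 * pi / 180
  u_r <- c(sin(half), 0, cos(half))
  u_s <- c(-sin(half), 0, cos(half))
  a <- centre
  b_r <- a + bond * u_r
  b_s <- a + bond * u_s
  blob_centre <- if (true_site == "R") b_r else b_s
  ax <- (seq_len(n) - 1) * spacing
  rng <- local_rng(seed)
  vals <- array(0, dim = c(n, n, n))
  if (effect > 0) {
    sigma <- 0.8
    dx2 <- (ax - blob_centre[1])^2
    dy2 <- (ax - blob_centre[2])^2
    dz2 <- (ax - blob_centre[3])^2
    vals <- effect * exp(-(outer(outer(dx2, dy2, `+`), dz2, `+`)) /
                           (2 * sigma^2))
  }
  if (noise_sd > 0) {
    vals <- vals + array(rng(stats::rnorm(n^3, sd = noise_sd)),
                         dim = c(n, n, n))
  }
  probes <- tibble::tibble(
    hypothesis = c("R", "S"),
    ax = a[1], ay = a[2], az = a[3],
    bx = c(b_r[1], b_s[1]), by = c(b_r[2], b_s[2]), bz = c(b_r[3], b_s[3])
  )
  list(grid = density_grid(vals, cell = rep(side, 3)), probes = probes)
}

#' Mean positive density for both hypotheses of a probe table
#'
#' @param grid A `crm_density_grid`.
#' @param probes Probe tibble as produced by [simulate_density_pair()] (or
#'   read from a probe JSON).
#' @param n_samples Samples per bond (default 21).
#' @return Tibble `hypothesis`, `mean_positive`.
#' @export
probe_mean_positive <- function(grid, probes, n_samples = 21L) {
  purrr::map_dfr(seq_len(nrow(probes)), function(i) {
    p <- probes[i, ]
    prof <- sample_bond_density(grid, c(p$ax, p$ay, p$az),
                                c(p$bx, p$by, p$bz), n_samples)
    tibble::tibble(hypothesis = p$hypothesis,
                   mean_positive = mean_positive(prof))
  })
}

#' Plot bond-density profiles
#'
#' @param profiles Named list of profiles from [sample_bond_density()]
#'   (names become the legend, e.g. `R`/`S`).
#' @return A ggplot object.
#' @export
plot_density_profile <- function(profiles) {
  df <- dplyr::bind_rows(purrr::imap(profiles, function(p, nm) {
    dplyr::mutate(p, hypothesis = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$density,
                                   colour = .data$hypothesis)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "position along bond (fraction)",
                  y = "density (map units)") +
    ggplot2::theme_minimal()
}
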