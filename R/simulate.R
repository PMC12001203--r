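#' @title Synthetic LC-MS campaigns
#' @description Generates labelled centroided MS1 runs that emulate a crude
#'   reaction mixture sample: the spiked product contributes a Gaussian
#'   chromatographic profile whose per-scan spectrum carries the adduct's
#'   carbon isotopologue envelope, on top of a Poisson field of decoy
#'   signals at random m/z. Carbon-13 is the only heavy isotope modelled
#'   (per-carbon probability 0.0107, isotopologue spacing 1.00336 Da), which
#'   is adequate to exercise +/-0.3 Da ion matching.
#' @name synth-lcms
NULL

C13_ABUNDANCE <- 0.0107
C13_SPACING <- 1.00336

#' Species specification for a simulated run
#'
#' @param target_id Identifier of the product the species represents.
#' @param neutral_mass Neutral monoisotopic mass M, Da.
#' @param rt_apex Chromatographic apex, seconds.
#' @param rt_sigma Gaussian peak width (sd), seconds (default 4).
#' @param abundance Apex total abundance, counts (default 1e4).
#' @param n_carbons Carbon count for the isotopologue envelope (default 20).
#' @param adducts Adduct rules for the ions this species produces
#'   (default `[M+H]+`).
#' @return One-row tibble (rows can be bound to form a species table).
#' @export
species_spec <- function(target_id, neutral_mass, rt_apex, rt_sigma = 4,
                         abundance = 1e4, n_carbons = 20L,
                         adducts = crm_adducts("[M+H]+")) {
  stopifnot(neutral_mass > 0, rt_sigma > 0, abundance > 0, n_carbons >= 0)
  tibble::tibble(target_id = target_id, neutral_mass = neutral_mass,
                 rt_apex = rt_apex, rt_sigma = rt_sigma,
                 abundance = abundance, n_carbons = as.integer(n_carbons),
                 adducts = list(tibble::as_tibble(adducts)))
}

#' Noise model for simulated runs
#'
#' @param baseline Intensity scale of decoy signals, counts (default 500).
#' @param jitter_sd Additive Gaussian intensity noise, counts (default 50).
#' @param decoy_density Expected decoy signals per spectrum, Poisson mean
#'   (default 0.5). Together with `mz_range` this sets the run-level chance
#'   that noise lands within match tolerance of a product ion; the default
#'   reproduces the few-percent noise-match rate seen in real campaign QC.
#' @param mz_range m/z interval decoys are drawn from (default 50-1050).
#' @return A `crm_noise_model` list.
#' @export
noise_model <- function(baseline = 500, jitter_sd = 50, decoy_density = 0.5,
                        mz_range = c(50, 1050)) {
  stopifnot(baseline >= 0, jitter_sd >= 0, decoy_density >= 0,
            length(mz_range) == 2, mz_range[1] < mz_range[2])
  structure(list(baseline = baseline, jitter_sd = jitter_sd,
                 decoy_density = decoy_density, mz_range = mz_range),
            class = "crm_noise_model")
}

# isotopologue envelope of one adduct ion: m/z and relative abundance
isotopologue_envelope <- function(neutral_mass, n_carbons, delta, charge,
                                  pmin = 1e-12) {
  j <- 0:n_carbons
  p <- stats::dbinom(j, n_carbons, C13_ABUNDANCE)
  keep <- p > pmin
  tibble::tibble(
    mz = (neutral_mass + j[keep] * C13_SPACING + delta) / abs(charge),
    frac = p[keep]
  )
}

#' Closed-form TIC of a species table
#'
#' The noiseless total ion current contributed by the species at each grid
#' retention time: `sum_species abundance * exp(-(rt - apex)^2 / (2 sigma^2))`
#' times the retained envelope fraction. Used as the analytic reference for
#' round-trip tests.
#'
#' @param species Species table ([species_spec()] rows).
#' @param rt_grid Retention-time grid, seconds.
#' @return Numeric vector of TIC values on `rt_grid`.
#' @export
analytic_tic <- function(species, rt_grid) {
  out <- numeric(length(rt_grid))
  for (i in seq_len(nrow(species))) {
    s <- species[i, ]
    envs <- purrr::map(seq_len(nrow(s$adducts[[1]])), function(k) {
      a <- s$adducts[[1]][k, ]
      isotopologue_envelope(s$neutral_mass, s$n_carbons, a$delta_mass,
                            a$charge)
    })
    frac <- sum(vnum(envs, function(e) sum(e$frac)))
    out <- out + s$abundance * frac *
      exp(-(rt_grid - s$rt_apex)^2 / (2 * s$rt_sigma^2))
  }
  out
}

#' Simulate one centroided MS1 run
#'
#' @param species Species table ([species_spec()] rows); may have zero rows
#'   for a blank (negative-control) run.
#' @param noise A [noise_model()].
#' @param rt_grid Retention-time grid, seconds; must cover every species
#'   apex +/- 4 sigma.
#' @param seed Integer seed; the run is fully reproducible given
#'   (species, noise, rt_grid, seed).
#' @param sample_id Sample identifier (default `"sim"`).
#' @return A `crm_run`.
#' @export
simulate_run <- function(species, noise = noise_model(),
                         rt_grid = seq(0, 180, by = 2), seed = 1L,
                         sample_id = "sim") {
  stopifnot(inherits(noise, "crm_noise_model"))
  if (nrow(species)) {
    lo <- species$rt_apex - 4 * species$rt_sigma
    hi <- species$rt_apex + 4 * species$rt_sigma
    if (any(lo < min(rt_grid)) || any(hi > max(rt_grid))) {
      abort_crm("rt_grid does not cover all species apexes +/- 4 sigma",
                "crm_sim_error")
    }
  }
  rng <- local_rng(seed)
  ions <- if (nrow(species)) {
    dplyr::bind_rows(purrr::map(seq_len(nrow(species)), function(i) {
      s <- species[i, ]
      dplyr::bind_rows(purrr::map(seq_len(nrow(s$adducts[[1]])), function(k) {
        a <- s$adducts[[1]][k, ]
        env <- isotopologue_envelope(s$neutral_mass, s$n_carbons,
                                     a$delta_mass, a$charge)
        tibble::tibble(mz = env$mz, frac = env$frac, abundance = s$abundance,
                       rt_apex = s$rt_apex, rt_sigma = s$rt_sigma)
      }))
    }))
  } else NULL
  scans <- purrr::map(seq_along(rt_grid), function(si) {
    rt <- rt_grid[si]
    mz <- numeric(); it <- numeric()
    if (!is.null(ions)) {
      g <- exp(-(rt - ions$rt_apex)^2 / (2 * ions$rt_sigma^2))
      inten <- ions$abundance * ions$frac * g
      keep <- inten > 1e-6
      mz <- ions$mz[keep]; it <- inten[keep]
    }
    n_decoy <- rng(stats::rpois(1, noise$decoy_density))
    if (n_decoy > 0) {
      mz <- c(mz, rng(stats::runif(n_decoy, noise$mz_range[1],
                                   noise$mz_range[2])))
      it <- c(it, noise$baseline * rng(stats::rexp(n_decoy)))
    }
    if (noise$jitter_sd > 0 && length(it)) {
      it <- it + rng(stats::rnorm(length(it), sd = noise$jitter_sd))
    }
    keep <- it > 0
    o <- order(mz[keep])
    list(mz = mz[keep][o], intensity = it[keep][o])
  })
  new_crm_run(
    sample_id,
    tibble::tibble(
      scan = seq_along(rt_grid), rt = as.numeric(rt_grid),
      mz = purrr::map(scans, "mz"),
      intensity = purrr::map(scans, "intensity")
    ),
    metadata = c(source = "crmscreen simulate_run", seed = as.character(seed))
  )
}

# Evaluate an expression under a private RNG stream, leaving the caller's
# random state untouched (seeds are explicit everywhere, no global state).
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  function(expr) {
    outer <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(outer)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", outer, globalenv())
      }
    })
    expr
  }
}

#' Simulate a labelled LC-MS campaign
#'
#' Writes `n_samples` mzML runs to `dir`. The first
#' `ceiling(n_samples * spike_fraction)` samples of a seed-determined random
#' order are spiked with their assigned target's `[M+H]+` species (apex
#' position drawn per run); every run receives decoy noise. A truth table
#' accompanies the files.
#'
#' @param n_samples Number of runs.
#' @param spike_fraction Fraction of runs containing their product, in
#'   `[0, 1]`.
#' @param targets Product table (`target_id`, `mono_mass`, optionally
#'   `formula` from which carbon counts are taken); targets are assigned to
#'   samples in rotation.
#' @param noise A [noise_model()].
#' @param seed Integer seed controlling every random choice.
#' @param dir Output directory (created if needed).
#' @param rt_grid Retention-time grid, seconds.
#' @param rt_sigma Chromatographic peak width of spiked species, seconds
#'   (default 4); apexes are drawn at least 4 sigma inside the grid.
#' @param abundance Apex abundance of spiked species, counts (default 1e4;
#'   signal-to-baseline = `abundance / noise$baseline`).
#' @return List with `truth` (tibble `sample_id`, `target_id`, `spiked`,
#'   `path`) and `dir`.
#' @export
make_campaign <- function(n_samples, spike_fraction, targets,
                          noise = noise_model(), seed = 1L,
                          dir = tempfile("campaign"),
                          rt_grid = seq(0, 180, by = 2), rt_sigma = 4,
                          abundance = 1e4) {
  stopifnot(n_samples >= 1, spike_fraction >= 0, spike_fraction <= 1,
            nrow(targets) >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- local_rng(seed)
  n_spiked <- ceiling(n_samples * spike_fraction)
  spiked <- logical(n_samples)
  spiked[rng(sample.int(n_samples, n_spiked))] <- TRUE
  target_idx <- rep_len(seq_len(nrow(targets)), n_samples)
  n_carbons <- if ("formula" %in% names(targets)) {
    vnum(targets$formula, function(f) {
      counts <- parse_formula(f)
      if ("C" %in% names(counts)) counts[["C"]] else 0
    })
  } else rep(20, nrow(targets))
  rt_lo <- min(rt_grid) + 4 * rt_sigma
  rt_hi <- max(rt_grid) - 4 * rt_sigma
  if (rt_lo >= rt_hi) {
    abort_crm("rt_grid too short for the species peak width", "crm_sim_error")
  }
  truth <- purrr::map(seq_len(n_samples), function(i) {
    sid <- sprintf("S%04d", i)
    ti <- target_idx[i]
    sp <- if (spiked[i]) {
      apex <- rng(stats::runif(1, rt_lo, rt_hi))
      species_spec(targets$target_id[ti], targets$mono_mass[ti],
                   rt_apex = apex, rt_sigma = rt_sigma,
                   abundance = abundance, n_carbons = n_carbons[ti])
    } else species_spec("none", 1, rt_apex = mean(rt_grid))[0, ]
    run <- simulate_run(sp, noise, rt_grid,
                        seed = rng(sample.int(.Machine$integer.max, 1)),
                        sample_id = sid)
    path <- file.path(dir, paste0(sid, ".mzML"))
    write_mzml(run, path)
    tibble::tibble(sample_id = sid, target_id = targets$target_id[ti],
                   spiked = spiked[i], path = path)
  })
  list(truth = dplyr::bind_rows(truth), dir = dir)
}

#' Score verdicts against simulation truth
#'
#' Applies the campaign confusion framework with the truth table playing the
#' human-label role: recall = TP / (TP + FN), precision = TP / (TP + FP),
#' false-positive rate = FP / (FP + TN).
#'
#' @param verdicts Verdict tibble from [qc_campaign()].
#' @param truth Truth tibble from [make_campaign()].
#' @return One-row tibble: `tp`, `tn`, `fp`, `fn`, `recall`, `precision`,
#'   `fp_rate`.
#' @export
evaluate_verdicts <- function(verdicts, truth) {
  if (!setequal(verdicts$sample_id, truth$sample_id)) {
    abort_crm("verdict and truth sample ids do not match", "crm_sim_error")
  }
  joined <- dplyr::inner_join(verdicts, truth, by = "sample_id")
  cat_ <- confusion_category(joined$status, joined$spiked)
  tp <- sum(cat_ == "TP"); tn <- sum(cat_ == "TN")
  fp <- sum(cat_ == "FP"); fn <- sum(cat_ == "FN")
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    fp_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_
  )
}
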