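# The synthetic LC-MS generator: analytic ground truth, isotope envelope,
# determinism, and scoring against truth.

test_that("a noiseless species gives the closed-form Gaussian TIC", {
  rt <- seq(0, 120, by = 2)
  sp <- species_spec("T", 300, rt_apex = 60, rt_sigma = 5, abundance = 5000)
  quiet <- noise_model(baseline = 0, jitter_sd = 0, decoy_density = 0)
  run <- simulate_run(sp, quiet, rt, seed = 1)
  tic <- compute_tic(run)
  expect_equal(tic$tic, analytic_tic(sp, rt), tolerance = 1e-9)
  expect_equal(tic$rt[which.max(tic$tic)], 60)
  # and it survives an mzML round trip within float tolerance
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, path)
  tic2 <- compute_tic(read_run(path))
  expect_equal(tic2$tic, tic$tic, tolerance = 1e-6)
})

test_that("the isotopologue envelope follows the carbon binomial model", {
  rt <- seq(0, 120, by = 2)
  sp <- species_spec("T", 300, rt_apex = 60, n_carbons = 20, abundance = 1e4)
  quiet <- noise_model(baseline = 0, jitter_sd = 0, decoy_density = 0)
  run <- simulate_run(sp, quiet, rt, seed = 1)
  apex <- run$scans[run$scans$rt == 60, ]
  it <- apex$intensity[[1]]
  # envelope sums to the species abundance at the apex scan
  expect_equal(sum(it), 1e4, tolerance = 1e-6)
  # M+1 / M ratio equals the exact binomial pmf ratio:
  # dbinom(1)/dbinom(0) = 20 * 0.0107 / (1 - 0.0107)
  expect_equal(it[2] / it[1], 20 * 0.0107 / (1 - 0.0107), tolerance = 1e-9)
  # spacing of 13C isotopologues
  expect_equal(diff(apex$mz[[1]])[1], 1.00336, tolerance = 1e-9)
})

test_that("a baseline-only run fails QC (negative control)", {
  rt <- seq(0, 120, by = 2)
  run <- simulate_run(species_spec("x", 1, rt_apex = 60)[0, ],
                      noise_model(), rt, seed = 9, sample_id = "blank")
  v <- run_qc(run, tibble::tibble(target_id = "T", mono_mass = 300))
  expect_equal(v$status, "fail")
})

test_that("spike fractions hit their boundaries and campaigns are byte-deterministic", {
  tg <- tibble::tibble(target_id = c("A", "B"), mono_mass = c(250, 300))
  d0 <- withr::local_tempdir()
  c0 <- make_campaign(10, 0, tg, seed = 3, dir = file.path(d0, "none"),
                      rt_grid = seq(0, 60, 2))
  expect_false(any(c0$truth$spiked))
  c1 <- make_campaign(10, 1, tg, seed = 3, dir = file.path(d0, "all"),
                      rt_grid = seq(0, 60, 2))
  expect_true(all(c1$truth$spiked))
  ca <- make_campaign(6, 0.5, tg, seed = 7, dir = file.path(d0, "a"),
                      rt_grid = seq(0, 60, 2))
  cb <- make_campaign(6, 0.5, tg, seed = 7, dir = file.path(d0, "b"),
                      rt_grid = seq(0, 60, 2))
  expect_equal(sum(ca$truth$spiked), 3L)
  for (i in seq_len(6)) {
    fa <- ca$truth$path[i]; fb <- cb$truth$path[i]
    expect_identical(readBin(fa, "raw", file.size(fa)),
                     readBin(fb, "raw", file.size(fb)))
  }
})

test_that("with zero noise, QC recall on spiked runs is exactly 1", {
  tg <- tibble::tibble(target_id = sprintf("T%d", 1:3),
                       mono_mass = c(250.1, 310.2, 402.3))
  quiet <- noise_model(baseline = 0, jitter_sd = 0, decoy_density = 0)
  camp <- make_campaign(6, 1, tg, noise = quiet, seed = 11,
                        dir = withr::local_tempdir(),
                        rt_grid = seq(0, 120, 2))
  tmap <- dplyr::mutate(camp$truth,
                        mono_mass = tg$mono_mass[match(target_id,
                                                       tg$target_id)])
  verdicts <- qc_campaign(camp$dir, tmap)
  scores <- evaluate_verdicts(verdicts, camp$truth)
  expect_equal(scores$recall, 1.0)
})

test_that("verdict scoring reproduces count arithmetic", {
  verdicts <- tibble::tibble(
    sample_id = sprintf("s%d", 1:5),
    status = c("success", "success", "success", "fail", "success"))
  truth <- tibble::tibble(
    sample_id = sprintf("s%d", 1:5),
    spiked = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  sc <- evaluate_verdicts(verdicts, truth)
  expect_equal(sc$tp, 3L); expect_equal(sc$fn, 1L); expect_equal(sc$fp, 1L)
  expect_equal(sc$recall, 0.75)
  expect_equal(sc$precision, 0.75)
  # degenerate: all-fail verdicts give recall 0
  vf <- dplyr::mutate(verdicts, status = "fail")
  expect_equal(evaluate_verdicts(vf, truth)$recall, 0)
  # id mismatch is an error
  expect_error(evaluate_verdicts(verdicts[1:4, ], truth),
               class = "crm_sim_error")
})

test_that("rt grids must cover species apexes", {
  sp <- species_spec("T", 300, rt_apex = 110, rt_sigma = 5)
  expect_error(simulate_run(sp, noise_model(), seq(0, 120, 2), seed = 1),
               class = "crm_sim_error")
})
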