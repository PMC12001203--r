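# TIC construction, peak finding, spectrum aggregation, ion matching and
# verdict/report logic.

test_that("mzML round-trips preserve scans, rt and TIC", {
  run <- manual_run(list(
    list(mz = c(100, 200), intensity = c(10, 20)),
    list(mz = c(100, 200, 300), intensity = c(5, 1, 2)),
    list(mz = 150, intensity = 7)
  ), rt = c(1.5, 2.5, 3.5))
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, path)
  back <- read_run(path)
  expect_equal(nrow(back$scans), 3L)
  expect_equal(back$scans$rt, run$scans$rt)
  expect_equal(compute_tic(back)$tic, compute_tic(run)$tic)
  expect_equal(back$scans$mz, run$scans$mz)
})

test_that("missing files and malformed mzML raise typed errors", {
  expect_error(read_run("no/such/file.mzML"), class = "crm_mzml_error")
  bad <- withr::local_tempfile(fileext = ".mzML")
  writeLines("<not-mzml/>", bad)
  expect_error(read_run(bad), class = "crm_mzml_error")
})

test_that("TIC sums per-scan intensities and conserves total signal", {
  run <- manual_run(list(list(mz = c(1, 2, 3), intensity = c(10, 20, 30)),
                         list(mz = 1, intensity = 0)))
  tic <- compute_tic(run)
  expect_equal(tic$tic, c(60, 0))
  # conservation: sum over scans of summed intensities == sum of trace
  run2 <- simulate_run(species_spec("t", 250, rt_apex = 60),
                       noise_model(), rt_grid = seq(0, 120, 2), seed = 5)
  expect_identical(sum(unlist(run2$scans$intensity)),
                   sum(compute_tic(run2)$tic))
})

test_that("peak finding: flat traces give no peaks, a noiseless Gaussian exactly one", {
  expect_equal(nrow(find_tic_peaks(rep(5, 50))), 0L)
  rt <- seq(0, 120, 2)
  trace <- 1000 * exp(-(rt - 60)^2 / (2 * 16))
  pks <- find_tic_peaks(tibble::tibble(scan = seq_along(rt), rt = rt,
                                       tic = trace))
  expect_equal(nrow(pks), 1L)
  expect_equal(pks$apex_rt, 60)
  expect_equal(pks$apex_index, which.max(trace))
  expect_true(pks$left_index <= pks$apex_index &&
              pks$apex_index < pks$right_index)
})

test_that("prominence threshold is monotone: lowering it never removes a peak", {
  rt <- seq(0, 200, 2)
  trace <- 1000 * exp(-(rt - 50)^2 / 32) + 1000 * exp(-(rt - 150)^2 / 32) +
    50 * sin(rt / 3)^2
  tic <- tibble::tibble(scan = seq_along(rt), rt = rt, tic = trace)
  fracs <- c(0.5, 0.2, 0.1, 0.05, 0.02, 0.01)
  found <- purrr::map(fracs, function(f) {
    find_tic_peaks(tic, qc_config(min_prominence_fraction = f))$apex_index
  })
  expect_true(all(found[[1]] %in% found[[length(found)]]))
  for (i in seq_along(fracs)[-1]) {
    expect_true(all(found[[i - 1]] %in% found[[i]]))
  }
  # the two well-separated equal Gaussians survive every threshold
  for (f in found) expect_true(length(intersect(f, which(trace > 900))) >= 2)
})

test_that("peak spectra aggregate by summation within m/z tolerance bins", {
  run <- manual_run(list(
    list(mz = c(100.0, 200.0), intensity = c(10, 5)),
    list(mz = c(100.1, 200.0), intensity = c(20, 5)),
    list(mz = c(400.0), intensity = c(1))
  ))
  peak <- list(left_index = 1L, right_index = 3L, apex_index = 2L)
  sp <- peak_spectrum(run, peak, qc_config(mz_tolerance = 0.3))
  # 100.0 and 100.1 merge (gap < tol/2); intensity-weighted mz
  expect_equal(sp$intensity, c(30, 10))
  expect_equal(sp$mz[1], (100.0 * 10 + 100.1 * 20) / 30)
  # single-scan window returns the scan unchanged
  sp1 <- peak_spectrum(run, list(left_index = 3L, right_index = 4L,
                                 apex_index = 3L), qc_config())
  expect_equal(sp1$mz, 400)
  # apex aggregation returns the apex scan
  spa <- peak_spectrum(run, peak,
                       qc_config(spectrum_aggregation = "apex"))
  expect_equal(spa$intensity, c(20, 5))
})

test_that("expected-ion matching respects tolerance and ranks against the spectrum", {
  ions <- tibble::tibble(target_id = "T", adduct = "[M+H]+",
                         expected_mz = 101.007276)
  sp <- tibble::tibble(mz = 101.0073, intensity = 1000)
  m <- match_expected(sp, ions, qc_config(mz_tolerance = 0.3))
  expect_equal(nrow(m), 1L)
  expect_equal(m$rank, 1L)
  expect_true(m$most_prominent)
  # outside a tight tolerance: no match
  sp2 <- tibble::tibble(mz = 101.10, intensity = 1000)
  expect_equal(nrow(match_expected(sp2, ions,
                                   qc_config(mz_tolerance = 1e-4))), 0L)
  # decoy base peak twice the product ion: match at rank 2, not prominent
  sp3 <- tibble::tibble(mz = c(101.0073, 353.2), intensity = c(1000, 2000))
  m3 <- match_expected(sp3, ions, qc_config(mz_tolerance = 0.3))
  expect_equal(m3$rank, 2L)
  expect_false(m3$most_prominent)
})

test_that("tolerance widening only ever adds matches", {
  set.seed(21)
  ions <- tibble::tibble(target_id = sprintf("T%d", 1:5), adduct = "[M+H]+",
                         expected_mz = stats::runif(5, 100, 500))
  sp <- tibble::tibble(mz = sort(stats::runif(80, 100, 500)),
                       intensity = stats::rexp(80, 1 / 100))
  tols <- c(0.01, 0.05, 0.1, 0.3, 0.5, 1)
  got <- purrr::map(tols, function(tl) {
    m <- match_expected(sp, ions, qc_config(mz_tolerance = tl))
    paste(m$target_id, round(m$observed_mz, 6))
  })
  for (i in seq_along(tols)[-1]) {
    expect_true(all(got[[i - 1]] %in% got[[i]]))
  }
})

test_that("verdicts follow the expected-ion definition of synthesis success", {
  # no peaks: fail
  v0 <- assign_verdict("s", find_tic_peaks(rep(1, 10)), list())
  expect_equal(v0$status, "fail")
  m_hit <- tibble::tibble(target_id = "T", adduct = "[M+H]+",
                          expected_mz = 101, observed_mz = 101,
                          intensity = 10, rank = 1L, within_tol = TRUE,
                          most_prominent = TRUE)
  pks <- tibble::tibble(apex_index = 5L, apex_rt = 10, height = 1,
                        prominence = 1, left_index = 4L, right_index = 7L)
  v1 <- assign_verdict("s", pks, list(m_hit))
  expect_equal(v1$status, "success")
  expect_equal(v1$confidence, "prominent")
  # only a low-rank match: still success, flagged minor
  m_minor <- dplyr::mutate(m_hit, rank = 3L, most_prominent = FALSE)
  v2 <- assign_verdict("s", pks, list(m_minor))
  expect_equal(v2$status, "success")
  expect_equal(v2$confidence, "minor")
})

test_that("confusion categories follow the machine/human contingency", {
  expect_equal(confusion_category(c("success", "fail", "success", "fail"),
                                  c("yes", "yes", "no", "no")),
               c("TP", "FN", "FP", "TN"))
  expect_error(confusion_category("success", NA), class = "crm_report_error")
  expect_error(confusion_category("success", "maybe"),
               class = "crm_report_error")
})

test_that("reconciliation attaches labels and fails on unlabelled samples", {
  verdicts <- tibble::tibble(sample_id = c("a", "b"),
                             status = c("success", "fail"))
  ann <- tibble::tibble(sample_id = c("a", "b"), human_label = c("yes", "no"),
                        iteration = "1")
  rec <- reconcile_verdicts(verdicts, ann)
  expect_equal(rec$category, c("TP", "TN"))
  expect_error(reconcile_verdicts(verdicts, ann[1, ]),
               class = "crm_report_error")
})

test_that("campaign totals are means of iteration percentages and sums of counts", {
  s <- summarize_iterations(qc_rows())
  expect_equal(s$totals$match_pct, 83)
  expect_equal(s$totals$tp_tn_pct, 91)
  expect_equal(s$totals$fn_pct, 6)
  expect_equal(s$totals$fp_pct, 3)
  expect_equal(s$totals$tp, 243)
  expect_equal(s$totals$fn, 67)
  expect_equal(s$totals$fp, 83)
  expect_equal(s$totals$n_samples, 1876)
  # single iteration: totals equal the row
  s1 <- summarize_iterations(qc_rows()[1, ])
  expect_equal(s1$totals$match_pct, 81)
  expect_error(summarize_iterations(qc_rows()[0, ]),
               class = "crm_report_error")
  # tidy/glance accessors
  expect_equal(nrow(tidy(s)), nrow(qc_rows()) + 1)
  expect_equal(glance(s), s$totals)
})

test_that("identical run and config give identical verdicts", {
  run <- simulate_run(species_spec("T", 321.1, rt_apex = 60),
                      noise_model(), rt_grid = seq(0, 120, 2), seed = 3)
  tg <- tibble::tibble(target_id = "T", mono_mass = 321.1)
  expect_identical(run_qc(run, tg), run_qc(run, tg))
})
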