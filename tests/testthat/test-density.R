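# Density grids: trilinear sampling, mean positive density, CCP4 round trips.

test_that("constant fields interpolate exactly and set mean positive density", {
  g <- density_grid(array(2.5, dim = c(8, 8, 8)), cell = c(4, 4, 4))
  prof <- sample_bond_density(g, c(0.5, 0.5, 0.5), c(3, 3, 3), n_samples = 7)
  expect_equal(prof$density, rep(2.5, 7))
  expect_equal(mean_positive(prof), 2.5)
  gneg <- density_grid(array(-1, dim = c(8, 8, 8)), cell = c(4, 4, 4))
  pneg <- sample_bond_density(gneg, c(0.5, 0.5, 0.5), c(3, 3, 3))
  expect_equal(mean_positive(pneg), 0)
})

test_that("a linear field sampled along its axis matches the closed form", {
  # f(x, y, z) = x on a grid with 1 A spacing: voxel centres at x = 0..7
  n <- 8
  vals <- array(rep((0:(n - 1)), n * n), dim = c(n, n, n))
  g <- density_grid(vals, cell = c(n, n, n))  # spacing 1
  prof <- sample_bond_density(g, c(0, 2, 2), c(1, 2, 2), n_samples = 5)
  expect_equal(prof$density, c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-12)
  # mean positive excludes the zero sample: (.25+.5+.75+1)/4
  expect_equal(mean_positive(prof), 0.625, tolerance = 1e-12)
})

test_that("probes outside the grid extent raise an error naming the point", {
  g <- density_grid(array(1, dim = c(8, 8, 8)), cell = c(4, 4, 4))
  expect_error(sample_bond_density(g, c(0.5, 0.5, 0.5), c(9, 0.5, 0.5)),
               class = "crm_map_error")
  expect_error(sample_bond_density(g, c(1, 1, 1), c(1, 1, 1)),
               class = "crm_map_error")
})

test_that("mean positive density is monotone under pointwise grid increase", {
  set.seed(31)
  vals <- array(stats::rnorm(10^3), dim = c(10, 10, 10))
  g1 <- density_grid(vals, cell = c(5, 5, 5))
  a <- c(1, 1, 1); b <- c(4, 4, 4)
  base <- mean_positive(sample_bond_density(g1, a, b))
  for (shift in c(0.1, 0.5, 2)) {
    g2 <- density_grid(vals + shift, cell = c(5, 5, 5))
    expect_gte(mean_positive(sample_bond_density(g2, a, b)), base)
  }
})

test_that("CCP4 maps round-trip bit-faithfully at float32 precision", {
  sim <- simulate_density_pair("R", effect = 1, noise_sd = 0.2,
                               n = 16, spacing = 0.3, seed = 2)
  path <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4(sim$grid, path)
  back <- read_ccp4(path)
  expect_equal(back$values, sim$grid$values, tolerance = 1e-6)
  expect_equal(back$cell, sim$grid$cell, tolerance = 1e-6)
  expect_equal(dim(back$values), dim(sim$grid$values))
  # and the profile statistics survive the round trip
  mp1 <- probe_mean_positive(sim$grid, sim$probes)
  mp2 <- probe_mean_positive(back, sim$probes)
  expect_equal(mp2$mean_positive, mp1$mean_positive, tolerance = 1e-5)
})

test_that("written maps are readable by an independent CCP4 implementation", {
  # gemmi (python) as format oracle: values, cell and axis order must agree
  sim <- simulate_density_pair("R", effect = 1, noise_sd = 0.1,
                               n = 12, spacing = 0.4, seed = 4)
  path <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4(sim$grid, path)
  script <- paste0(
    "import gemmi, numpy as np;",
    "g = gemmi.read_ccp4_map('", path, "').grid;",
    "a = np.array(g, copy=False);",
    "print(a.shape[0], a.shape[1], a.shape[2]);",
    "print(repr(g.unit_cell.a));",
    "print(repr(float(a.mean())));",
    "print(repr(float(g.get_value(2, 3, 4))))")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  expect_equal(as.numeric(strsplit(out[1], " ")[[1]]), dim(sim$grid$values))
  expect_equal(as.numeric(out[2]), sim$grid$cell[1], tolerance = 1e-6)
  expect_equal(as.numeric(out[3]), mean(sim$grid$values), tolerance = 1e-6)
  expect_equal(as.numeric(out[4]), sim$grid$values[3, 4, 5],
               tolerance = 1e-6)
})

test_that("map reading rejects wrong modes and missing signatures", {
  path <- withr::local_tempfile(fileext = ".ccp4")
  writeBin(raw(2048), path)
  expect_error(read_ccp4(path), class = "crm_map_error")
  expect_error(read_ccp4("no/such.map"), class = "crm_map_error")
})

test_that("the simulated pair puts signal on the true bond only", {
  # noiseless construction: mean positive density along the true-site bond
  # strictly exceeds the false-site bond
  for (site in c("R", "S")) {
    sim <- simulate_density_pair(site, effect = 1, noise_sd = 0,
                                 n = 32, spacing = 0.15, seed = 1)
    mp <- probe_mean_positive(sim$grid, sim$probes)
    expect_gt(mp$mean_positive[mp$hypothesis == site],
              mp$mean_positive[mp$hypothesis != site])
  }
  # effect 0, noise 0: both profiles identically zero
  sim0 <- simulate_density_pair("R", effect = 0, noise_sd = 0,
                                n = 16, spacing = 0.3, seed = 1)
  mp0 <- probe_mean_positive(sim0$grid, sim0$probes)
  expect_equal(mp0$mean_positive, c(0, 0))
})
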