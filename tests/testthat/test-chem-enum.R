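# Reaction-array enumeration: applicability, mass bookkeeping, determinism.

test_that("canonicalization is idempotent", {
  smis <- c("C1CNCCN1", "OC(=O)c1ccco1", "N1CCNCC1C")
  once <- canonicalize_smiles(smis)$canonical
  twice <- canonicalize_smiles(once)$canonical
  expect_equal(once, twice)
})

test_that("a single applicable combination yields one product with summed formula", {
  route <- crm_route("u", list(list(id = "s1", rxn = UREA_RXN,
                                    roles = c("amine", "isocyanate"),
                                    leaving = "")))
  blocks <- tibble::tibble(id = c("a", "i"),
                           smiles = c("CCN", "O=C=NC"),
                           role = c("amine", "isocyanate"), iteration = "u")
  tg <- enumerate_products(blocks, route)
  expect_equal(nrow(tg), 1L)
  # urea formation adds with no leaving group
  expect_equal(tg$formula, formula_add("C2H7N", "C2H3NO"))
  expect_equal(tg$mono_mass,
               formula_mass("C2H7N")[["mono"]] + formula_mass("C2H3NO")[["mono"]],
               tolerance = 1e-9)
})

test_that("2 amines x 3 acids give 6 amides with bookkept masses", {
  tg <- enumerate_products(small_blocks(), amide_route())
  expect_equal(nrow(tg), 6L)
  # brute-force pairing oracle: mass = amine + acid - water, per combination
  b <- compute_formula_mass(small_blocks()$smiles)
  water <- formula_mass("H2O")[["mono"]]
  expected <- outer(b$mono_mass[1:2], b$mono_mass[3:5], `+`) - water
  key <- outer(small_blocks()$id[1:2], small_blocks()$id[3:5], paste, sep = "+")
  expect_equal(tg$mono_mass[match(as.vector(key), tg$blocks)],
               as.vector(expected), tolerance = 1e-9)
  # and the structures RDKit produced close the same mass balance
  prod <- compute_formula_mass(tg$smiles)
  expect_equal(prod$mono_mass, tg$mono_mass, tolerance = 1e-6)
})

test_that("enumeration is deterministic and ordered by block ids", {
  tg1 <- enumerate_products(small_blocks(), amide_route())
  tg2 <- enumerate_products(small_blocks(), amide_route())
  expect_identical(tg1, tg2)
  expect_equal(tg1$blocks, sort(tg1$blocks))
})

test_that("unparseable blocks are dropped with a per-record warning, enumeration continues", {
  blocks <- dplyr::bind_rows(small_blocks(),
                             tibble::tibble(id = "bad", smiles = "xx(",
                                            role = "acid", iteration = "t"))
  expect_warning(tg <- enumerate_products(blocks, amide_route()),
                 regexp = "bad")
  expect_equal(nrow(tg), 6L)
  expect_equal(attr(tg, "errors")$id, "bad")
})

test_that("unsatisfiable roles raise a route-level error", {
  blocks <- small_blocks()[small_blocks()$role == "amine", ]
  expect_error(enumerate_products(blocks, amide_route()),
               class = "crm_route_error", regexp = "acid")
})

test_that("inapplicable combinations are excluded and reported", {
  blocks <- dplyr::bind_rows(
    small_blocks(),
    tibble::tibble(id = "inert", smiles = "CCCC", role = "amine",
                   iteration = "t")  # no amine group: rule cannot apply
  )
  tg <- enumerate_products(blocks, amide_route())
  expect_equal(nrow(tg), 6L)
  inap <- attr(tg, "inapplicable")
  expect_equal(nrow(inap), 3L)
  expect_true(all(grepl("^inert", inap$combination)))
})

test_that("racemic building blocks collapse to one target with an enantiomer list", {
  blocks <- tibble::tibble(
    id = c("mpz", "ac"), smiles = c("C[C@H]1CNCCN1", "CC(=O)O"),
    role = c("amine", "acid"), iteration = "t")
  tg <- enumerate_products(blocks, amide_route())
  expect_equal(nrow(tg), 1L)
  expect_equal(tg$n_enantiomers, 2L)
  # both enantiomer structures carry the same formula
  both <- compute_formula_mass(tg$enantiomers[[1]])
  expect_equal(both$formula[1], both$formula[2])
})

test_that("the two-step methylpiperazine iteration enumerates 1024 targets", {
  route <- read_route(extdata("route_iter3_5.yaml"))
  blocks <- read_building_blocks(extdata("blocks_iter3_5.csv"))
  tg <- enumerate_products(blocks, route)
  expect_equal(nrow(tg), 1024L)
  # full factorial: 32 acids x 32 sulfonyl chlorides, none inapplicable
  expect_equal(nrow(attr(tg, "inapplicable")), 0L)
  # mass closure along the two steps, spot-checked on a sample
  idx <- seq(1, 1024, by = 128)
  prod <- compute_formula_mass(tg$smiles[idx])
  expect_equal(prod$mono_mass, tg$mono_mass[idx], tolerance = 1e-6)
})

test_that("expected ion m/z follows the adduct rule", {
  expect_equal(expected_ion_mz(100, 1.007276, 1L), 101.007276)
  expect_equal(expected_ion_mz(100, -1.007276, -1L), 98.992724)
  expect_equal(expected_ion_mz(200, 2.014552, 2L), 101.007276)
  expect_error(expected_ion_mz(-1, 1.007276, 1L))
})

test_that("product tables round-trip through CSV with expected ions", {
  tg <- enumerate_products(small_blocks(), amide_route())
  path <- withr::local_tempfile(fileext = ".csv")
  write_targets(tg, path)
  back <- read_targets(path)
  expect_equal(back$target_id, tg$target_id)
  expect_equal(back$`mz_[M+H]+`, tg$mono_mass + 1.007276, tolerance = 1e-9)
  expect_equal(attr(back, "adducts")$adduct, "[M+H]+")
})
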