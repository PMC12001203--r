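#' Formula and exact mass from structure
#'
#' Canonicalizes each SMILES, derives its Hill-order molecular formula, and
#' computes monoisotopic (most-abundant-isotope) and average masses from the
#' package's isotope table.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Tibble with columns `smiles`, `canonical`, `formula`,
#'   `mono_mass`, `avg_mass` (Da).
#' @examples
#' \dontrun{compute_formula_mass("C1CNCCN1")  # piperazine, C4H10N2}
#' @export
compute_formula_mass <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  canon <- canonicalize_smiles(smiles)
  if (any(!canon$valid)) {
    bad <- smiles[!canon$valid]
    abort_crm(paste0("unparseable structure(s): ",
                     paste(sprintf("'%s'", bad), collapse = ", ")),
              "crm_parse_error")
  }
  masses <- purrr::map(canon$formula, formula_mass)
  tibble::tibble(
    smiles = smiles,
    canonical = canon$canonical,
    formula = canon$formula,
    mono_mass = vnum(masses, `[[`, "mono"),
    avg_mass = vnum(masses, `[[`, "avg")
  )
}

#' Expected ion m/z under an adduct rule
#'
#' `mz = (M + delta_mass) / abs(charge)` for neutral monoisotopic mass M.
#'
#' @param mono_mass Neutral monoisotopic mass(es), Da.
#' @param delta_mass Adduct mass shift, Da (e.g. +1.007276 for `[M+H]+`).
#' @param charge Signed integer charge (non-zero).
#' @return Numeric m/z values.
#' @examples
#' expected_ion_mz(100, 1.007276, 1L)    # [M+H]+
#' expected_ion_mz(200, 2.014552, 2L)    # [M+2H]2+
#' @export
expected_ion_mz <- function(mono_mass, delta_mass, charge) {
  stopifnot(all(mono_mass > 0), all(charge != 0))
  (mono_mass + delta_mass) / abs(charge)
}

#' Expected ions for a product table
#'
#' @param targets Product table from [enumerate_products()] (or any tibble
#'   with `target_id` and `mono_mass`).
#' @param adducts Adduct rule tibble (see [crm_adducts()]); defaults to the
#'   adducts the route declared.
#' @return Long tibble: one row per target x adduct with `expected_mz`.
#' @export
expected_ions <- function(targets, adducts = NULL) {
  adducts <- adducts %||% attr(targets, "adducts") %||% crm_adducts("[M+H]+")
  tidyr::crossing(
    targets[, c("target_id", "mono_mass")],
    adducts[, c("adduct", "delta_mass", "charge")]
  ) |>
    dplyr::mutate(
      expected_mz = expected_ion_mz(.data$mono_mass, .data$delta_mass,
                                    .data$charge)
    ) |>
    dplyr::arrange(.data$target_id, .data$adduct)
}

# Input set for one stage: either prior-stage products ("@<step_id>") or the
# building blocks carrying a role label. Items are (id, variants, formula).
stage_inputs <- function(ref, blocks, produced, step_id) {
  if (startsWith(ref, "@")) {
    items <- produced[[sub("^@", "", ref)]]
    if (is.null(items) || !nrow(items)) {
      abort_crm(paste0("step '", step_id, "': no products available from '",
                       ref, "'"), "crm_route_error")
    }
    return(items)
  }
  b <- blocks[blocks$role == ref, , drop = FALSE]
  if (!nrow(b)) {
    abort_crm(paste0("step '", step_id, "': no building blocks with role '",
                     ref, "'"), "crm_route_error")
  }
  tibble::tibble(
    id = b$id,
    variants = purrr::map(b$canonical, enantiomer_variants),
    formula = b$formula
  )
}

#' Enumerate a reaction array into expected products
#'
#' Runs each route step over the full factorial of its two input sets,
#' applying the step's reaction-SMARTS rule to every combination. Product
#' formulas are book-kept exactly: formula(product) = sum of input formulas
#' minus the step's leaving-group formula (the structure produced by the rule
#' is checked against this in the test-suite, not trusted for mass).
#' Racemic building blocks written with an explicit stereocentre are expanded
#' to both enantiomers and collapse to a single product target of identical
#' mass, with the enantiomer structures retained in `enantiomers`.
#'
#' Combinations the rule does not apply to are dropped from the product table
#' and reported in the `inapplicable` attribute; building blocks whose SMILES
#' fails to parse are dropped with a per-record entry in the `errors`
#' attribute (enumeration continues).
#'
#' @param blocks Building-block table (`id, smiles, role, iteration`); may be
#'   raw or already validated by [validate_building_blocks()].
#' @param route A `crm_route` from [read_route()]/[crm_route()].
#' @return Tibble of product targets ordered lexicographically by combined
#'   block ids: `target_id`, `blocks`, `steps`, `smiles`, `formula`,
#'   `mono_mass`, `avg_mass`, `n_enantiomers`, `enantiomers` (list-column).
#'   Attributes: `adducts` (the route's adduct table), `inapplicable`,
#'   `errors`.
#' @export
enumerate_products <- function(blocks, route) {
  stopifnot(inherits(route, "crm_route"))
  blocks <- tibble::as_tibble(blocks)
  if (!"canonical" %in% names(blocks)) {
    canon <- canonicalize_smiles(blocks$smiles)
    errors <- tibble::tibble(
      id = blocks$id[!canon$valid],
      smiles = blocks$smiles[!canon$valid]
    )
    blocks$canonical <- canon$canonical
    blocks$formula <- canon$formula
    if (nrow(errors)) {
      warning(sprintf("dropping %d unparseable building block(s): %s",
                      nrow(errors), paste(errors$id, collapse = ", ")),
              call. = FALSE)
      blocks <- blocks[canon$valid, , drop = FALSE]
    }
  } else {
    errors <- tibble::tibble(id = character(), smiles = character())
  }
  dup <- blocks$id[duplicated(blocks$id)]
  if (length(dup)) {
    abort_crm(paste0("duplicate building-block id(s): ",
                     paste(unique(dup), collapse = ", ")), "crm_blocks_error")
  }

  produced <- list()
  inapplicable <- list()
  for (step in route$steps) {
    left <- stage_inputs(step$roles[1], blocks, produced, step$id)
    right <- stage_inputs(step$roles[2], blocks, produced, step$id)
    combos <- tidyr::crossing(i = seq_len(nrow(left)), j = seq_len(nrow(right)))
    combos$key <- paste(left$id[combos$i], right$id[combos$j], sep = "+")
    combos <- combos[order(combos$key), , drop = FALSE]

    # batch every variant pair of every combination into one backend call
    vp <- purrr::map2(combos$i, combos$j, function(i, j) {
      expand.grid(a = left$variants[[i]], b = right$variants[[j]],
                  stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    })
    counts <- vnum(vp, nrow)
    flat <- dplyr::bind_rows(vp)
    prods <- apply_reaction(step$rxn, purrr::map2(flat$a, flat$b, c))
    idx <- rep(seq_len(nrow(combos)), counts)

    items <- purrr::map(seq_len(nrow(combos)), function(k) {
      # one representative product per variant pair (sorted first), then the
      # distinct variants across enantiomer pairings
      pk <- prods[idx == k]
      smis <- unique(unlist(purrr::map(pk, function(p) {
        if (is.null(p)) NULL else p[[1]]
      })))
      if (is.null(smis) || !length(smis)) return(NULL)
      i <- combos$i[k]; j <- combos$j[k]
      fml <- formula_subtract(formula_add(left$formula[i], right$formula[j]),
                              step$leaving)
      tibble::tibble(id = combos$key[k], variants = list(sort(smis)),
                     formula = fml)
    })
    ok <- !vlgl(items, is.null)
    if (any(!ok)) {
      inapplicable[[step$id]] <- tibble::tibble(step = step$id,
                                                combination = combos$key[!ok])
    }
    out <- dplyr::bind_rows(items[ok])
    if (!nrow(out)) {
      abort_crm(paste0("step '", step$id, "' applied to no combination"),
                "crm_route_error")
    }
    produced[[step$id]] <- out
  }

  final <- produced[[route$steps[[length(route$steps)]]$id]]
  final <- final[order(final$id), , drop = FALSE]
  masses <- purrr::map(final$formula, formula_mass)
  targets <- tibble::tibble(
    target_id = paste0(route$id, ":", final$id),
    blocks = final$id,
    steps = paste(vchr(route$steps, `[[`, "id"), collapse = ">"),
    smiles = vchr(final$variants, function(v) v[[1]]),
    formula = final$formula,
    mono_mass = vnum(masses, `[[`, "mono"),
    avg_mass = vnum(masses, `[[`, "avg"),
    n_enantiomers = lengths(final$variants),
    enantiomers = final$variants
  )
  attr(targets, "adducts") <- route$adducts
  attr(targets, "inapplicable") <- dplyr::bind_rows(inapplicable)
  attr(targets, "errors") <- errors
  targets
}

#' Write / read a product-target table as CSV
#'
#' The CSV flattens the enantiomer list-column to a `;`-separated field and
#' appends one `mz_<adduct>` column per adduct, which is the interface the
#' LC-MS quality-control layer consumes.
#'
#' @param targets Product table from [enumerate_products()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  ions <- expected_ions(targets) |>
    dplyr::mutate(col = paste0("mz_", .data$adduct)) |>
    dplyr::select("target_id", "col", "expected_mz") |>
    tidyr::pivot_wider(names_from = "col", values_from = "expected_mz")
  flat <- targets |>
    dplyr::mutate(enantiomers = vchr(.data$enantiomers, paste,
                                     collapse = ";")) |>
    dplyr::left_join(ions, by = "target_id")
  readr::write_csv(flat, path)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols())
  tbl$enantiomers <- strsplit(tbl$enantiomers, ";", fixed = TRUE)
  mzcols <- grep("^mz_", names(tbl), value = TRUE)
  adduct <- sub("^mz_", "", mzcols)
  attr(tbl, "adducts") <- crm_adducts(adduct)
  tbl
}
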