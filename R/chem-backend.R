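# Bridge to the RDKit-based chemistry helper (inst/python/chem_backend.py).
# One subprocess call per batch; requests and responses are JSON on
# stdin/stdout so no temporary state is shared.

chem_backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "crmscreen")
  if (!nzchar(path) || !file.exists(path)) {
    # during development (pkgload) system.file resolves inside inst/
    abort_crm("chem_backend.py not found in installed package",
              "crm_backend_error")
  }
  path
}

chem_python <- function() {
  py <- getOption("crmscreen.python", Sys.getenv("CRMSCREEN_PYTHON", "python"))
  if (!nzchar(Sys.which(py))) {
    abort_crm(paste0("python interpreter '", py, "' not found; set ",
                     "options(crmscreen.python=) or CRMSCREEN_PYTHON"),
              "crm_backend_error")
  }
  py
}

chem_backend_call <- function(request) {
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  jsonlite::write_json(request, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  out <- suppressWarnings(
    system2(chem_python(), shQuote(chem_backend_script()),
            stdin = infile, stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    abort_crm(paste0("chemistry backend failed: ",
                     paste(utils::tail(out, 5), collapse = "\n")),
              "crm_backend_error")
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Returns the RDKit canonical SMILES and Hill-order molecular formula for
#' each input structure. Unparseable inputs yield `NA` rows rather than an
#' error so that enumeration can report per-record failures.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A tibble with columns `smiles` (input), `canonical`, `formula`,
#'   and `valid`.
#' @examples
#' \dontrun{canonicalize_smiles(c("C1CNCCN1", "not-a-molecule"))}
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) {
    return(tibble::tibble(smiles = character(), canonical = character(),
                          formula = character(), valid = logical()))
  }
  res <- chem_backend_call(list(op = "canon", smiles = as.list(unname(smiles))))
  rows <- purrr::map(res$results, function(r) {
    tibble::tibble(canonical = r$smiles %||% NA_character_,
                   formula = r$formula %||% NA_character_,
                   valid = isTRUE(r$ok))
  })
  dplyr::bind_cols(tibble::tibble(smiles = smiles), dplyr::bind_rows(rows))
}

# Apply a two-component reaction SMARTS to pairs of reactant SMILES.
# Returns a list parallel to `pairs`: character vector of distinct sanitized
# product SMILES, or NULL where the rule does not apply.
apply_reaction <- function(rxn_smarts, pairs) {
  stopifnot(is.character(rxn_smarts), length(rxn_smarts) == 1)
  if (!length(pairs)) return(list())
  res <- chem_backend_call(list(
    op = "react", rxn = rxn_smarts,
    pairs = purrr::map(unname(pairs), function(p) as.list(unname(p)))
  ))
  purrr::map(res$results, function(r) {
    if (is.null(r)) NULL else unlist(r)
  })
}

#' Morgan (circular) fingerprints as bit-index sets
#'
#' Computes circular fingerprints for each structure. Defaults are radius 2
#' and 2048 bits (ECFP4-like, the de-facto standard for similarity work);
#' the generation parameters travel with the result as attributes so that
#' [tanimoto()] can refuse to compare incompatible fingerprints.
#'
#' @param smiles Character vector of SMILES.
#' @param radius Circular fingerprint radius (default 2).
#' @param nbits Folded length in bits (default 2048).
#' @return Named list of sorted 0-based on-bit integer vectors with
#'   attributes `radius` and `nbits`; unparseable structures give `NULL`.
#' @export
morgan_fingerprints <- function(smiles, radius = 2, nbits = 2048) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  res <- chem_backend_call(list(op = "morgan",
                                smiles = as.list(unname(smiles)),
                                radius = radius, nbits = nbits))
  fps <- purrr::map(res$results, function(r) {
    if (is.null(r)) NULL else as.integer(unlist(r))
  })
  names(fps) <- names(smiles) %||% smiles
  structure(fps, radius = as.integer(res$radius), nbits = as.integer(res$nbits))
}
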