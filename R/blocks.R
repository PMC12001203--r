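#' Read a building-block table
#'
#' Building blocks are the array inputs of a campaign: one row per reagent
#' with a unique `id`, a SMILES structure, a `role` label that reaction steps
#' refer to (e.g. `"amine"`, `"acid"`, `"isocyanate"`) and an `iteration` tag.
#' Structures are canonicalized on read; rows that fail to parse raise an
#' error naming the offending ids.
#'
#' @param path CSV file with columns `id, smiles, role, iteration`.
#' @return Tibble with the input columns plus `canonical` and `formula`.
#' @export
read_building_blocks <- function(path) {
  blocks <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  validate_building_blocks(blocks)
}

#' @rdname read_building_blocks
#' @param blocks A data frame with columns `id, smiles, role, iteration`
#'   (e.g. assembled in code rather than read from disk).
#' @export
validate_building_blocks <- function(blocks) {
  need <- c("id", "smiles", "role", "iteration")
  missing <- setdiff(need, names(blocks))
  if (length(missing)) {
    abort_crm(paste0("building-block table lacks column(s): ",
                     paste(missing, collapse = ", ")), "crm_blocks_error")
  }
  blocks <- tibble::as_tibble(blocks)[need]
  dup <- blocks$id[duplicated(blocks$id)]
  if (length(dup)) {
    abort_crm(paste0("duplicate building-block id(s): ",
                     paste(unique(dup), collapse = ", ")), "crm_blocks_error")
  }
  canon <- canonicalize_smiles(blocks$smiles)
  if (any(!canon$valid)) {
    abort_crm(paste0("unparseable SMILES for block(s): ",
                     paste(blocks$id[!canon$valid], collapse = ", ")),
              "crm_blocks_error")
  }
  blocks$canonical <- canon$canonical
  blocks$formula <- canon$formula
  blocks
}

# Expand a SMILES into its enantiomer variants: racemic blocks are written
# with one explicit stereocentre and enumerated as both mirror images, which
# later collapse to a single product target of identical mass.
enantiomer_variants <- function(smiles) {
  if (!grepl("@", smiles, fixed = TRUE)) return(smiles)
  flipped <- gsub("@@", "\001", smiles, fixed = TRUE)
  flipped <- gsub("@", "@@", flipped, fixed = TRUE)
  flipped <- gsub("\001", "@", flipped, fixed = TRUE)
  unique(c(smiles, flipped))
}

# Strip stereo annotations so enantiomeric products collapse to one key.
achiral_key <- function(smiles) {
  s <- gsub("@", "", smiles, fixed = TRUE)
  gsub("[\\\\/]", "-", s)
}
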