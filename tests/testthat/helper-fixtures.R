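# Shared fixture builders: everything is generated in code at test time.

AMIDE_RXN <- "[NX3;H2,H1;!$(N[C,S]=O):1].[CX3:2](=[OX1:3])[OX2H1]>>[N:1][C:2]=[O:3]"
UREA_RXN <- "[NX3;H2,H1;!$(N[C,S]=O):1].[NX2:2]=[CX2:3]=[OX1:4]>>[N:1][C:3](=[O:4])[N:2]"

amide_route <- function(id = "t") {
  crm_route(id, list(list(id = "s1", rxn = AMIDE_RXN,
                          roles = c("amine", "acid"), leaving = "H2O")))
}

small_blocks <- function() {
  tibble::tibble(
    id = c("am1", "am2", "ac1", "ac2", "ac3"),
    smiles = c("C1CNCCN1", "CCN", "CC(=O)O", "CCC(=O)O", "OC(=O)c1ccco1"),
    role = c("amine", "amine", "acid", "acid", "acid"),
    iteration = "t"
  )
}

# A run built directly from scan lists (no simulation, no file)
manual_run <- function(spectra, rt = NULL, sample_id = "manual") {
  if (is.null(rt)) rt <- seq_along(spectra)
  crmscreen:::new_crm_run(
    sample_id,
    tibble::tibble(
      scan = seq_along(spectra), rt = as.numeric(rt),
      mz = purrr::map(spectra, function(s) as.numeric(s$mz)),
      intensity = purrr::map(spectra, function(s) as.numeric(s$intensity))
    )
  )
}

extdata <- function(...) system.file("extdata", ..., package = "crmscreen")

# printed per-iteration QC rows of the campaign summary table
qc_rows <- function() {
  readr::read_csv(extdata("qc_iterations.csv"), show_col_types = FALSE)
}

resource_rows <- function() {
  readr::read_csv(extdata("campaign_resources.csv"), show_col_types = FALSE)
}
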