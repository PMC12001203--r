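#' Adduct rules
#'
#' An adduct rule converts a neutral monoisotopic mass M into an expected ion
#' m/z: `mz = (M + delta_mass) / abs(charge)`. The built-in table covers the
#' common positive/negative electrospray species; campaigns can extend it in
#' the route configuration.
#'
#' @param names Optional character vector selecting rows by adduct name.
#' @return Tibble with columns `adduct`, `delta_mass` (Da), `charge`.
#' @examples
#' crm_adducts()
#' crm_adducts("[M+H]+")
#' @export
crm_adducts <- function(names = NULL) {
  tbl <- tibble::tibble(
    adduct = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M+2H]2+", "[M-H]-"),
    delta_mass = c(1.007276, 22.989218, 18.033823, 2.014552, -1.007276),
    charge = c(1L, 1L, 1L, 2L, -1L)
  )
  if (is.null(names)) return(tbl)
  missing <- setdiff(names, tbl$adduct)
  if (length(missing)) {
    abort_crm(paste0("unknown adduct(s): ", paste(missing, collapse = ", ")),
              "crm_route_error")
  }
  tbl[match(names, tbl$adduct), ]
}

#' Read a reaction-route configuration
#'
#' A route is an ordered list of reaction steps. Each step names a
#' two-component reaction-SMARTS rule, the two input sets it combines
#' (building-block `role` labels, or `"@<step_id>"` to consume the products
#' of an earlier step — which is how branched routes merge), and the
#' molecular formula of the leaving group removed by the step (possibly
#' empty). Steps must form an acyclic chain: a step may only reference steps
#' defined before it.
#'
#' @param path YAML route file with fields `id`, optional `adducts`,
#'   and `steps` (each with `id`, `rxn`, `roles` (length 2), optional
#'   `leaving`).
#' @return A `crm_route` object.
#' @export
read_route <- function(path) {
  cfg <- yaml::read_yaml(path)
  crm_route(id = cfg$id, steps = cfg$steps, adducts = cfg$adducts)
}

#' @rdname read_route
#' @param id Route identifier.
#' @param steps List of step definitions (see above).
#' @param adducts Character vector of adduct names (default `"[M+H]+"`),
#'   or a data frame with `adduct`, `delta_mass`, `charge` columns.
#' @export
crm_route <- function(id, steps, adducts = NULL) {
  if (is.null(id) || !nzchar(id)) {
    abort_crm("route must have a non-empty id", "crm_route_error")
  }
  if (!length(steps)) abort_crm("route has no steps", "crm_route_error")
  seen <- character()
  steps <- purrr::map(steps, function(s) {
    for (f in c("id", "rxn", "roles")) {
      if (is.null(s[[f]])) {
        abort_crm(paste0("route step missing field '", f, "'"),
                  "crm_route_error")
      }
    }
    s$roles <- as.character(unlist(s$roles))
    if (length(s$roles) != 2) {
      abort_crm(paste0("step '", s$id, "' must combine exactly two input ",
                       "sets"), "crm_route_error")
    }
    refs <- sub("^@", "", s$roles[startsWith(s$roles, "@")])
    bad <- setdiff(refs, seen)
    if (length(bad)) {
      abort_crm(paste0("step '", s$id, "' references undefined or later ",
                       "step(s): ", paste(bad, collapse = ", ")),
                "crm_route_error")
    }
    seen <<- c(seen, s$id)
    s$leaving <- s$leaving %||% ""
    if (nzchar(s$leaving)) parse_formula(s$leaving)  # fail fast
    s[c("id", "rxn", "roles", "leaving")]
  })
  if (anyDuplicated(vchr(steps, `[[`, "id"))) {
    abort_crm("duplicate step ids in route", "crm_route_error")
  }
  adducts <- adducts %||% "[M+H]+"
  if (is.character(adducts)) adducts <- crm_adducts(adducts)
  adducts <- tibble::as_tibble(adducts)
  stopifnot(all(c("adduct", "delta_mass", "charge") %in% names(adducts)),
            all(adducts$charge != 0))
  structure(list(id = id, steps = steps, adducts = adducts),
            class = "crm_route")
}

#' @export
print.crm_route <- function(x, ...) {
  cat("<crm_route>", x$id, "-", length(x$steps), "step(s)\n")
  for (s in x$steps) {
    cat("  ", s$id, ": ", paste(s$roles, collapse = " + "),
        if (nzchar(s$leaving)) paste0(" (- ", s$leaving, ")") else "",
        "\n", sep = "")
  }
  cat("  adducts:", paste(x$adducts$adduct, collapse = ", "), "\n")
  invisible(x)
}
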