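#' @title Molecular formula arithmetic and exact masses
#'
#' @description
#' Expected-ion matching hinges on the neutral monoisotopic mass M of each
#' enumerated product. Masses are computed from a fixed isotope table versioned
#' with the package: monoisotopic masses are those of the most abundant isotope
#' of each element, average masses are the standard atomic weights.
#' @name formula-tools
NULL

# Most-abundant-isotope masses (Da) and standard atomic weights, IUPAC 2021.
# Restricted to elements that occur in small-molecule array chemistry.
.iso_table <- data.frame(
  element = c("H",  "B",  "C",  "N",  "O",  "F",  "Na", "Mg", "Si", "P",
              "S",  "Cl", "K",  "Ca", "Fe", "Br", "I"),
  mono = c(1.00782503207, 11.0093054, 12.0, 14.0030740048, 15.9949146196,
           18.99840322, 22.9897692809, 23.985041700, 27.9769265325,
           30.97376163, 31.97207100, 34.96885268, 38.96370668,
           39.96259098, 55.9349375, 78.9183371, 126.904473),
  avg = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
          28.085, 30.974, 32.06, 35.45, 39.098, 40.078, 55.845, 79.904,
          126.904),
  stringsAsFactors = FALSE
)

#' Mass of the proton in Da, used for protonated/deprotonated adducts
#' @export
PROTON_MASS <- 1.007276

#' Parse a molecular formula into element counts
#'
#' @param formula A Hill-order molecular formula string, e.g. `"C4H10N2"`.
#'   Parenthesised groups are not supported (Hill formulas never contain them).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C4H10N2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (is.na(formula) || !nzchar(formula)) {
    abort_crm("empty molecular formula", "crm_formula_error")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    abort_crm(paste0("cannot parse formula: '", formula, "'"),
              "crm_formula_error")
  }
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(ifelse(grepl("[0-9]+$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  bad <- setdiff(el, .iso_table$element)
  if (length(bad)) {
    abort_crm(paste0("element(s) not in isotope table: ",
                     paste(bad, collapse = ", ")), "crm_formula_error")
  }
  counts <- c(tapply(n, el, sum))  # c() drops the 1-d array shape
  storage.mode(counts) <- "integer"
  counts[counts > 0]
}

#' Write element counts as a Hill-order formula
#'
#' Hill order: carbon first, hydrogen second, then the remaining elements
#' alphabetically (all alphabetical when no carbon is present).
#'
#' @param counts Named integer vector of element counts.
#' @return Formula string.
#' @export
hill_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return("")
  el <- names(counts)
  ord <- if ("C" %in% el) {
    c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  } else {
    sort(el)
  }
  paste0(ord, ifelse(counts[ord] > 1, counts[ord], ""), collapse = "")
}

#' Add or subtract molecular formulas
#'
#' Used for step-level mass bookkeeping: the product formula of a reaction
#' step is the sum of the input formulas minus the leaving-group formula.
#'
#' @param a,b Formula strings (`b` may be `""` for no leaving group).
#' @return Hill-order formula string.
#' @examples
#' formula_add("C2H7N", "C2H4O2")        # amine + acetic acid
#' formula_subtract("C4H11NO2", "H2O")   # condensation
#' @export
formula_add <- function(a, b) {
  ca <- parse_formula(a)
  cb <- parse_formula(b)
  el <- union(names(ca), names(cb))
  out <- stats::setNames(integer(length(el)), el)
  out[names(ca)] <- out[names(ca)] + ca
  out[names(cb)] <- out[names(cb)] + cb
  hill_formula(out)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  if (is.na(b) || !nzchar(b)) return(hill_formula(parse_formula(a)))
  ca <- parse_formula(a)
  cb <- parse_formula(b)
  el <- union(names(ca), names(cb))
  out <- stats::setNames(integer(length(el)), el)
  out[names(ca)] <- out[names(ca)] + ca
  out[names(cb)] <- out[names(cb)] - cb
  if (any(out < 0)) {
    abort_crm(paste0("leaving group ", b, " not contained in ", a),
              "crm_formula_error")
  }
  hill_formula(out)
}

#' Monoisotopic and average mass of a molecular formula
#'
#' @param formula Formula string.
#' @return Named numeric vector with elements `mono` and `avg` (Da).
#' @examples
#' formula_mass("C4H10N2")
#' @export
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  i <- match(names(counts), .iso_table$element)
  c(mono = sum(counts * .iso_table$mono[i]),
    avg = sum(counts * .iso_table$avg[i]))
}
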