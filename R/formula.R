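# Elemental formula handling. Formulas are flat element->count strings
# ("C6H12O6"); "" denotes a massless species (e.g. a photon); NA means the
# composition is unknown.

#' Parse an elemental formula
#'
#' @param formula a formula string such as "C6H12O6". An empty string is a
#'   valid massless formula and parses to an empty vector.
#' @return named integer vector of element counts.
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(formula) {
  if (is.na(formula)) stop("cannot parse a missing (NA) formula")
  if (!nzchar(formula)) return(setNames(integer(0), character(0)))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula) || length(toks) == 0L)
    stop("malformed formula: '", formula, "'")
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  ct[is.na(ct)] <- 1L
  tapply(ct, el, sum)[unique(el)]
}

# net elemental composition of a stoichiometry (named coefficients over
# metabolite ids); met_formula: named formula strings
formulaBalance <- function(coefs, met_formula) {
  tot <- numeric(0)
  for (i in seq_along(coefs)) {
    f <- met_formula[[names(coefs)[i]]]
    if (is.null(f) || is.na(f))
      stop("metabolite '", names(coefs)[i], "' has no formula")
    counts <- parseFormula(f)
    for (e in names(counts)) {
      tot[e] <- (if (e %in% names(tot)) tot[e] else 0) + coefs[i] * counts[e]
    }
  }
  tot[abs(tot) < 1e-9] <- 0
  tot
}
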