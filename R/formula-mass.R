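# Monoisotopic masses of the most abundant isotope (IUPAC/CODATA), Da.
# Electron mass is NOT subtracted for cations: fragment annotations in
# screening tables quote the neutral-formula monoisotopic mass.
.MONOISOTOPIC <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473
)

#' Parse an elemental formula string
#'
#' Turns a Hill-style formula such as `"C17H14N"` into a named integer
#' vector of element counts.  Supported elements: C, H, N, O, S, P, F,
#' Cl, Br, I.
#'
#' @param formula character scalar, e.g. `"C17H14N"`.
#' @return named integer vector of element counts.
#' @examples
#' parse_formula("C17H14N")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("malformed formula: ", sQuote(formula))
  }
  elems <- sub("[0-9]+$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elems, names(.MONOISOTOPIC))
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 1L)) stop("element counts must be positive integers")
  out <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  storage.mode(out) <- "integer"
  c(out)
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of count times monoisotopic atomic mass over the elements of the
#' formula.  No electron-mass correction is applied, so the value for a
#' fragment cation formula is the neutral monoisotopic mass (the
#' convention used in screening feature tables).
#'
#' @param formula a formula string (see [parse_formula()]) or a named
#'   count vector as returned by it.
#' @return monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C17H14N")  # indole-alkyl fragment shared by
#'                               # several synthetic cannabinoids
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (is.null(names(counts)) || !all(names(counts) %in% names(.MONOISOTOPIC))) {
    stop("formula must be a string or a named vector of supported elements")
  }
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("element counts must be positive integers")
  }
  sum(.MONOISOTOPIC[names(counts)] * as.numeric(counts))
}
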