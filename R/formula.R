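#' Parse a chemical formula string into an element-count table
#'
#' Formulas follow the usual Hill-style convention used by BiGG and SBML
#' FBC models: element symbols (capital letter, optional lowercase
#' letter) each followed by an optional integer count, e.g. `"C3H8O3"`
#' for glycerol.  No parentheses, charges or isotopes — genome-scale
#' models do not use them.
#'
#' @param formula_string a single formula string; `""` and `NA` give an
#'   empty count table (metabolite of unknown composition).
#' @return named integer vector of element counts.
#' @examples
#' parse_formula("C3H8O3")
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula_string) {
  if (length(formula_string) != 1L) stop("parse_formula() takes one string")
  if (is.na(formula_string) || !nzchar(formula_string)) {
    return(stats::setNames(integer(0), character(0)))
  }
  s <- formula_string
  toks <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  if (toks[1] == -1L) {
    stop("malformed formula '", s, "': no element token at offset 1")
  }
  lens <- attr(toks, "match.length")
  ## every character must be covered by some token, in order
  covered <- unlist(mapply(function(st, le) seq(st, st + le - 1L), toks, lens,
                           SIMPLIFY = FALSE))
  gap <- setdiff(seq_len(nchar(s)), covered)
  if (length(gap)) {
    stop("malformed formula '", s, "': unexpected character '",
         substr(s, gap[1], gap[1]), "' at offset ", gap[1])
  }
  out <- integer(0)
  for (i in seq_along(toks)) {
    tok <- substr(s, toks[i], toks[i] + lens[i] - 1L)
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    out[sym] <- (if (sym %in% names(out)) out[[sym]] else 0L) + n
  }
  out
}

#' Number of atoms of one element in a formula string
#'
#' @param formula_string formula as in [parse_formula()].
#' @param element element symbol, default `"C"`.
#' @return integer count (0 when absent or formula empty).
#' @export
element_count <- function(formula_string, element = "C") {
  f <- parse_formula(formula_string)
  if (element %in% names(f)) unname(f[[element]]) else 0L
}

#' Carbon counts for a set of metabolites
#'
#' @param model an [fba_model].
#' @param ids metabolite ids; default all.
#' @return named integer vector, carbons per metabolite.
#' @export
carbon_counts <- function(model, ids = NULL) {
  stopifnot(inherits(model, "fba_model"))
  met <- model$metabolites
  if (!is.null(ids)) met <- met[match(ids, met$id), , drop = FALSE]
  stats::setNames(vapply(met$formula, element_count, integer(1), element = "C",
                         USE.NAMES = FALSE), met$id)
}
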