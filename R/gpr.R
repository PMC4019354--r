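#' Evaluate a gene-protein-reaction rule under a gene deletion
#'
#' GPR rules are boolean expressions over gene identifiers using `and`
#' (complex subunits — all required) and `or` (isozymes — any suffices),
#' with parentheses; the syntax is the one found in BiGG JSON
#' `gene_reaction_rule` fields.  A reaction with an empty rule has no
#' known genetic basis and is treated as non-deletable: the rule
#' evaluates to `TRUE` whatever is deleted.
#'
#' @param gpr rule string, e.g. `"(b1234 and b1235) or b2222"`; `""` or
#'   `NA` means no rule.
#' @param deleted character vector of deleted gene ids.
#' @return `TRUE` if the reaction retains enzymatic support, else `FALSE`.
#' @examples
#' evaluate_gpr("g1 and g2", "g1")   # FALSE: complex loses a subunit
#' evaluate_gpr("g1 or g2",  "g1")   # TRUE:  isozyme survives
#' @export
evaluate_gpr <- function(gpr, deleted = character(0)) {
  if (length(gpr) != 1L) stop("evaluate_gpr() takes one rule")
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(TRUE)
  toks <- gpr_tokens(gpr)
  expr <- vapply(toks, function(tk) {
    lw <- tolower(tk)
    if (lw == "and") "&"
    else if (lw == "or") "|"
    else if (tk %in% c("(", ")")) tk
    else if (tk %in% deleted) "FALSE"
    else "TRUE"
  }, character(1))
  e <- tryCatch(parse(text = paste(expr, collapse = " "))[[1]],
                error = function(err) stop("unparsable GPR rule: '", gpr, "'"))
  isTRUE(eval(e, envir = baseenv()))
}

#' Gene identifiers appearing in a GPR rule
#'
#' @param gpr rule string.
#' @return character vector of distinct gene ids (empty for empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (length(gpr) != 1L || is.na(gpr) || !nzchar(trimws(gpr))) {
    return(character(0))
  }
  toks <- gpr_tokens(gpr)
  unique(toks[!tolower(toks) %in% c("and", "or") & !toks %in% c("(", ")")])
}

## Tokenizer shared by the evaluator and the gene extractor: parentheses
## are their own tokens, everything else splits on whitespace.
gpr_tokens <- function(gpr) {
  s <- gsub("([()])", " \\1 ", gpr)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}
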