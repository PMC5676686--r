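#' @keywords internal
# IUPAC element symbols (periods 1-7, incl. lanthanides/actinides).
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu")

# Residue markers used by metabolic models for variable acyl chains etc.
.GENERIC_MARKERS <- c("R", "X", "*")

#' Parse an elemental formula
#'
#' Parses Hill-notation or simply concatenated molecular formulas
#' (`"C16H32O2"`, `"H2O"`) into element counts by a single left-to-right
#' character walk: an uppercase letter starts a token, an optional lowercase
#' letter completes a two-letter symbol, and following digits give the count
#' (default 1). Generic residue markers (`R`, `X`, `*`, optionally digit-
#' suffixed like `R1`), used by metabolic models for unspecified acyl chains,
#' do not contribute counts but mark the formula as generic.
#'
#' @param text a single formula string.
#' @return an object of class `tdl_formula`: a named integer vector of element
#'   counts with attribute `generic` (logical).
#' @examples
#' parse_formula("C16H32O2")
#' attr(parse_formula("C40H77NO8R"), "generic")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  counts <- integer()
  generic <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "*") {
      generic <- TRUE
      i <- i + 1L
      # optional digits after a residue marker
      while (i <= n && grepl("[0-9]", chars[i])) i <- i + 1L
      next
    }
    if (!grepl("[A-Z]", ch)) {
      stop(sprintf("unparseable token at position %d in formula '%s': '%s'",
                   i, text, ch))
    }
    sym <- ch
    if (i + 1L <= n && grepl("[a-z]", chars[i + 1L])) {
      sym <- paste0(ch, chars[i + 1L])
      i <- i + 1L
    }
    i <- i + 1L
    digits <- character()
    while (i <= n && grepl("[0-9]", chars[i])) {
      digits <- c(digits, chars[i])
      i <- i + 1L
    }
    cnt <- if (length(digits)) as.integer(paste(digits, collapse = "")) else 1L
    if (sym %in% .GENERIC_MARKERS) {
      generic <- TRUE
      next
    }
    if (!(sym %in% .ELEMENTS)) {
      # one-letter residue fallback: unknown single uppercase letters that are
      # not elements are rejected rather than silently treated as generic
      stop(sprintf("unparseable element symbol '%s' in formula '%s'", sym, text))
    }
    if (cnt < 1L) stop(sprintf("element count < 1 for '%s' in '%s'", sym, text))
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + cnt else cnt
  }
  structure(counts, generic = generic, class = "tdl_formula")
}

#' Test a formula against minimum element counts
#'
#' The lipid composition gate: a formula passes when it has at least the
#' required number of atoms of every thresholded element. The threshold
#' applies only to the listed elements (C, H, O by default); other elements
#' (N, P, S, ...) neither help nor disqualify, which keeps phospholipids and
#' sphingolipids in scope.
#'
#' @param formula a `tdl_formula`, a formula string, or `NA`.
#' @param min_counts named integer vector of per-element minimum counts.
#' @return `TRUE`/`FALSE`, or `NA` when the formula is missing or generic
#'   (caller decides how to treat unfilterable formulas).
#' @examples
#' formula_passes("C16H32O2")          # palmitate: TRUE
#' formula_passes("C3H8O3")            # glycerol: FALSE
#' @export
formula_passes <- function(formula, min_counts = c(C = 4L, H = 8L, O = 2L)) {
  if (length(formula) == 1L && (is.na(formula)[1] || identical(formula, ""))) {
    return(NA)
  }
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "tdl_formula"))
  if (isTRUE(attr(formula, "generic"))) return(NA)
  cnt <- unclass(formula)
  all(vapply(names(min_counts), function(e) {
    !is.na(cnt[e]) && cnt[e] >= min_counts[[e]]
  }, logical(1)))
}

#' @export
print.tdl_formula <- function(x, ...) {
  cat(paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = ""))
  if (isTRUE(attr(x, "generic"))) cat(" [generic residue]")
  cat("\n")
  invisible(x)
}
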