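# Monoisotopic atomic masses in Da (IUPAC 2021 / AME2020 values, >= 7 decimals).
ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069
)

ELEMENTS <- names(ATOMIC_MASS)

#' Monoisotopic mass from CHNOPS element counts
#'
#' Computes the neutral monoisotopic mass of a molecular formula from its
#' element counts, using IUPAC monoisotopic atomic masses. All arguments are
#' vectorized and recycled.
#'
#' @param C,H,N,O,P,S Non-negative integer element counts.
#' @return Numeric vector of masses in Da.
#' @examples
#' formula_mass(C = 6, H = 12, O = 6) # glucose, 180.0634
#' @export
formula_mass <- function(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0) {
  C * ATOMIC_MASS[["C"]] + H * ATOMIC_MASS[["H"]] + N * ATOMIC_MASS[["N"]] +
    O * ATOMIC_MASS[["O"]] + P * ATOMIC_MASS[["P"]] + S * ATOMIC_MASS[["S"]]
}

#' Parse a CHNOPS molecular formula string
#'
#' @param formula A formula string such as `"C6H12O6"` or `"H2O"`. Only the
#'   elements C, H, N, O, P and S are supported.
#' @return Named integer vector with components C, H, N, O, P, S.
#' @examples
#' parse_formula("C2H3NO") # glycine residue
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  counts <- setNames(integer(length(ELEMENTS)), ELEMENTS)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!nzchar(formula) || sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% ELEMENTS) {
      stop("unsupported element '", el, "' in formula ", formula, call. = FALSE)
    }
    counts[[el]] <- counts[[el]] + n
  }
  counts
}
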