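#' @keywords internal
"_PACKAGE"

# Monoisotopic atomic masses (Da), IUPAC/CODATA values.
ELEMENTS <- c("C", "H", "N", "O", "S", "P")

ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

ELECTRON_MASS <- 0.00054857990946

#' Coerce input to a formula table
#'
#' Internal canonicalisation: accepts a data frame with (a subset of) the
#' element-count columns `C,H,N,O,S,P`, or a character vector of Hill-notation
#' strings, and returns a data frame with all six integer columns.
#'
#' @param x data frame of element counts or character vector of formulas.
#' @return data frame with integer columns `C,H,N,O,S,P`.
#' @keywords internal
as_formula_df <- function(x) {
  if (is.character(x)) {
    return(parse_formula(x))
  }
  if (!is.data.frame(x)) {
    stop("formulas must be a data frame of element counts or a character vector")
  }
  out <- x
  for (el in ELEMENTS) {
    if (is.null(out[[el]])) out[[el]] <- 0L
    if (any(is.na(out[[el]])) || any(out[[el]] < 0) ||
        any(out[[el]] != round(out[[el]]))) {
      stop("element counts must be non-negative integers (column ", el, ")")
    }
  }
  out[ELEMENTS] <- lapply(out[ELEMENTS], as.integer)
  out
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of element counts times standard monoisotopic atomic masses.
#'
#' @param formula data frame with element-count columns `C,H,N,O,S` (optionally
#'   `P`), or a character vector of Hill-notation formulas such as `"C6H12O6"`.
#' @return numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("C6H12O6")  # 180.063388
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_formula_df(formula)
  m <- rep(0, nrow(f))
  for (el in ELEMENTS) m <- m + f[[el]] * ELEMENT_MASS[[el]]
  m
}

#' m/z of the singly charged deprotonated ion
#'
#' Negative-mode DOM spectra are acquired as singly charged \[M-H\]- ions:
#' the ion m/z is the neutral mass minus one hydrogen atom plus one electron.
#'
#' @param formula formula table or Hill strings (see [monoisotopic_mass()]),
#'   or a numeric vector of neutral monoisotopic masses.
#' @return numeric vector of ion m/z values (Th).
#' @export
deprotonated_mz <- function(formula) {
  m <- if (is.numeric(formula)) formula else monoisotopic_mass(formula)
  m - ELEMENT_MASS[["H"]] + ELECTRON_MASS
}

#' Hill-notation string for formulas
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; elements
#' with zero count are omitted, unit counts are written without a number.
#'
#' @param formula formula table (see [as_formula_df()]).
#' @return character vector, e.g. `"C6H12O6"`.
#' @export
formula_string <- function(formula) {
  f <- as_formula_df(formula)
  hill <- c("C", "H", "N", "O", "P", "S")  # N,O,P,S already alphabetical
  out <- rep("", nrow(f))
  for (el in hill) {
    n <- f[[el]]
    part <- ifelse(n == 0L, "", ifelse(n == 1L, el, paste0(el, n)))
    out <- paste0(out, part)
  }
  out
}

#' Parse Hill-notation formulas
#'
#' @param x character vector such as `"C6H12O6"` or `"C5H9NO4"`.
#' @return data frame with integer columns `C,H,N,O,S,P`.
#' @export
parse_formula <- function(x) {
  out <- matrix(0L, nrow = length(x), ncol = length(ELEMENTS),
                dimnames = list(NULL, ELEMENTS))
  for (i in seq_along(x)) {
    s <- x[[i]]
    matches <- gregexpr("([CHNOSP])([0-9]*)", s)[[1]]
    if (matches[1] == -1 ||
        sum(attr(matches, "match.length")) != nchar(s)) {
      stop("cannot parse formula string: ", s)
    }
    parts <- regmatches(s, gregexpr("([CHNOSP])([0-9]*)", s))[[1]]
    for (p in parts) {
      el <- substr(p, 1, 1)
      n <- substr(p, 2, nchar(p))
      out[i, el] <- out[i, el] + if (nzchar(n)) as.integer(n) else 1L
    }
  }
  as.data.frame(out)
}

# Fast composite key used for set operations on formulas.
formula_key <- function(formula) {
  f <- as_formula_df(formula)
  paste(f$C, f$H, f$N, f$O, f$S, f$P, sep = ".")
}
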