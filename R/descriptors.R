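#' Default Van Krevelen compound-class boundary table
#'
#' Rectangles in (O/C, H/C) space mapping formulas onto the biochemical
#' compound classes commonly used for DOM.  Intervals are half-open
#' `[low, high)` on both axes; the protein/amino-sugar rectangle additionally
#' requires at least one nitrogen (otherwise the molecule falls through to
#' `"other"`).  Points covered by no rectangle are labelled `"other"`.
#'
#' @return data frame with columns `class`, `oc_min`, `oc_max`, `hc_min`,
#'   `hc_max`, `requires_n`.
#' @export
vk_class_table <- function() {
  data.frame(
    class = c("lipids", "proteins/amino sugars", "carbohydrates",
              "unsaturated hydrocarbons", "lignin/CRAM-like", "tannins",
              "condensed aromatics"),
    oc_min = c(0,    0.3,  0.67, 0,   0.1,  0.67, 0),
    oc_max = c(0.3,  0.67, 1.2,  0.1, 0.67, 1.2,  0.67),
    hc_min = c(1.5,  1.5,  1.5,  0.7, 0.7,  0.5,  0.2),
    hc_max = c(2.2,  2.2,  2.2,  1.5, 1.5,  1.5,  0.7),
    requires_n = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Validate a compound-class boundary table
#'
#' Checks that no two rectangles overlap (half-open interval semantics), so
#' every Van Krevelen point maps to at most one class.
#'
#' @param table a boundary table shaped like [vk_class_table()].
#' @return the table, invisibly; errors on overlap or malformed input.
#' @export
validate_class_table <- function(table) {
  need <- c("class", "oc_min", "oc_max", "hc_min", "hc_max")
  if (!all(need %in% names(table))) {
    stop("class table must have columns ", paste(need, collapse = ", "))
  }
  if (is.null(table$requires_n)) table$requires_n <- FALSE
  if (any(table$oc_min >= table$oc_max) || any(table$hc_min >= table$hc_max)) {
    stop("class table rectangles must have positive extent")
  }
  n <- nrow(table)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        oc_olap <- table$oc_min[i] < table$oc_max[j] &&
          table$oc_min[j] < table$oc_max[i]
        hc_olap <- table$hc_min[i] < table$hc_max[j] &&
          table$hc_min[j] < table$hc_max[i]
        if (oc_olap && hc_olap) {
          stop("overlapping class rectangles: ", table$class[i], " and ",
               table$class[j])
        }
      }
    }
  }
  invisible(table)
}

#' Van Krevelen compound class of molecules
#'
#' @param o_c,h_c atomic O/C and H/C ratios.
#' @param n nitrogen counts (needed for the protein/amino-sugar rule);
#'   defaults to 0.
#' @param table boundary table, validated at load; see [vk_class_table()].
#' @return character vector of class labels (`"other"` when no rectangle
#'   matches or a nitrogen-requiring rectangle matches an N-free formula).
#' @export
assign_compound_class <- function(o_c, h_c, n = 0L, table = vk_class_table()) {
  validate_class_table(table)
  if (is.null(table$requires_n)) table$requires_n <- FALSE
  n <- rep_len(n, length(o_c))
  out <- rep("other", length(o_c))
  for (i in seq_len(nrow(table))) {
    hit <- o_c >= table$oc_min[i] & o_c < table$oc_max[i] &
      h_c >= table$hc_min[i] & h_c < table$hc_max[i]
    if (table$requires_n[i]) hit <- hit & n > 0L
    out[hit] <- table$class[i]
  }
  out
}

#' Redox quadrant in (DBE-O)/C versus NOSC space
#'
#' Molecules are called oxidized when NOSC exceeds `nosc_cut` (strict) and
#' saturated when (DBE-O)/C falls below `sat_cut` (strict); the four
#' combinations partition the plane.  The "saturated & oxidized" quadrant is
#' the population preferentially degraded by hydroxyl radicals.
#'
#' @param nosc nominal oxidation state of carbon.
#' @param dbe_o_c (DBE-O)/C values.
#' @param nosc_cut,sat_cut quadrant thresholds (defaults 0 and 0.3).
#' @return character vector in `{"saturated & oxidized",
#'   "saturated & reduced", "unsaturated & oxidized", "unsaturated & reduced"}`.
#' @export
classify_redox_quadrant <- function(nosc, dbe_o_c, nosc_cut = 0,
                                    sat_cut = 0.3) {
  ox <- ifelse(nosc > nosc_cut, "oxidized", "reduced")
  sat <- ifelse(dbe_o_c < sat_cut, "saturated", "unsaturated")
  paste(sat, "&", ox)
}

#' Heteroatom class label
#'
#' Concatenates the heteroelements present among N, S, P (in that fixed
#' order) onto `"CHO"`: `CHO`, `CHON`, `CHOS`, `CHONS`, `CHOP`, ...
#'
#' @param formula formula table or Hill strings.
#' @return character vector of heteroatom-class labels.
#' @export
heteroatom_class <- function(formula) {
  f <- as_formula_df(formula)
  paste0("CHO",
         ifelse(f$N > 0L, "N", ""),
         ifelse(f$S > 0L, "S", ""),
         ifelse(f$P > 0L, "P", ""))
}

#' Molecular descriptors for assigned formulas
#'
#' Appends the descriptor block used throughout the DOM fate analysis to a
#' table of element counts: atomic ratios, double-bond equivalents
#' `DBE = 1 + C - H/2 + (N+P)/2`, nominal oxidation state of carbon
#' `NOSC = 4 - (4C + H - 3N - 2O + 5P - 2S)/C`, the modified aromaticity
#' index `AImod = (1 + C - 0.5 O - S - 0.5 H)/(C - 0.5 O - S - N - P)`
#' (set to 0 when the denominator is non-positive or the ratio is negative),
#' the theoretical deprotonated ion m/z, and the categorical heteroatom
#' class, Van Krevelen compound class and redox quadrant.
#'
#' @param formula formula table (e.g. the `assignments` element of a
#'   [assign_peaklist()] result) or a character vector of Hill strings.
#' @param class_table Van Krevelen boundary table.
#' @param nosc_cut,sat_cut redox-quadrant thresholds,
#'   see [classify_redox_quadrant()].
#' @return the input (as a data frame) with descriptor columns `o_c`, `h_c`,
#'   `n_c`, `s_c`, `dbe`, `dbe_o`, `dbe_o_c`, `nosc`, `ai_mod`, `mz_theor`,
#'   `heteroatom_class`, `compound_class`, `redox_quadrant` appended.
#' @examples
#' compute_descriptors("C6H12O6")[, c("dbe", "nosc", "o_c", "h_c")]
#' @export
compute_descriptors <- function(formula, class_table = vk_class_table(),
                                nosc_cut = 0, sat_cut = 0.3) {
  f <- as_formula_df(formula)
  if (any(f$C < 1L)) stop("descriptors require at least one carbon")
  if (is.null(f$formula)) f$formula <- formula_string(f)
  f$o_c <- f$O / f$C
  f$h_c <- f$H / f$C
  f$n_c <- f$N / f$C
  f$s_c <- f$S / f$C
  f$dbe <- dbe_of(f)
  f$dbe_o <- f$dbe - f$O
  f$dbe_o_c <- f$dbe_o / f$C
  f$nosc <- 4 - (4 * f$C + f$H - 3 * f$N - 2 * f$O + 5 * f$P - 2 * f$S) / f$C
  num <- 1 + f$C - 0.5 * f$O - f$S - 0.5 * f$H
  den <- f$C - 0.5 * f$O - f$S - f$N - f$P
  ai <- ifelse(den <= 0, 0, num / den)
  f$ai_mod <- pmax(ai, 0)
  f$mz_theor <- deprotonated_mz(f[ELEMENTS])
  f$heteroatom_class <- heteroatom_class(f[ELEMENTS])
  f$compound_class <- assign_compound_class(f$o_c, f$h_c, f$N, class_table)
  f$redox_quadrant <- classify_redox_quadrant(f$nosc, f$dbe_o_c,
                                              nosc_cut, sat_cut)
  f
}
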