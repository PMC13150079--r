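#' Default one-step reaction library for paired-mass-distance matching
#'
#' Elemental deltas are signed counts with the convention
#' `delta = product - reactant`.  The default library covers the common DOM
#' transformation reactions: dealkylation (-CH2), decarboxylation (-CO2),
#' oxygen addition (+O), hydrogenation (+H2), dehydrogenation (-H2),
#' hydration (+H2O), dehydration (-H2O), deamination (-NH3), sulfonation
#' (+SO3) and desulfurization (-S).
#'
#' @param reactions optional data frame with columns `name`, `dC`, `dH`,
#'   `dN`, `dO`, `dS`, `dP` to replace the default library.
#' @return validated reaction-library data frame.
#' @export
reaction_library <- function(reactions = NULL) {
  lib <- reactions
  if (is.null(lib)) {
    lib <- data.frame(
      name = c("dealkylation", "decarboxylation", "oxygen addition",
               "hydrogenation", "dehydrogenation", "hydration",
               "dehydration", "deamination", "sulfonation",
               "desulfurization"),
      dC = c(-1L, -1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      dH = c(-2L, 0L, 0L, 2L, -2L, 2L, -2L, -3L, 0L, 0L),
      dN = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, -1L, 0L, 0L),
      dO = c(0L, -2L, 1L, 0L, 0L, 1L, -1L, 0L, 3L, 0L),
      dS = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, -1L),
      dP = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
    )
  }
  need <- c("name", "dC", "dH", "dN", "dO", "dS", "dP")
  if (!all(need %in% names(lib))) {
    stop("reaction library must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(lib$name)) stop("reaction names must be unique")
  if (any(rowSums(abs(lib[, c("dC", "dH", "dN", "dO", "dS", "dP")])) == 0)) {
    stop("reaction deltas must be non-zero")
  }
  lib
}

#' Match Disappeared-to-Product pairs against a reaction library
#'
#' Emits every (Disappeared reactant, Product) pair whose exact elemental
#' difference (product minus reactant) equals a library delta.  Matching is
#' in formula space: formulas are already assigned, so no mass tolerance is
#' involved.  A formula may participate in several pairs; each qualifying
#' pair is counted.
#'
#' @param partition a [classify_fate()] result (or any list with character
#'   vectors `disappeared` and `product` of Hill-notation formulas).
#' @param library a [reaction_library()].
#' @return data frame of matches: `reactant`, `product`, `reaction`,
#'   `class_combo` (e.g. `"CHO-CHO"`).
#' @export
match_transformations <- function(partition, library = reaction_library()) {
  library <- reaction_library(library)
  d_keys <- partition$disappeared
  p_keys <- partition$product
  out <- list()
  if (length(d_keys) && length(p_keys)) {
    d <- parse_formula(d_keys)
    p_lookup <- stats::setNames(seq_along(p_keys), formula_key(p_keys))
    d_class <- heteroatom_class(d)
    p_class <- heteroatom_class(p_keys)
    for (i in seq_len(nrow(library))) {
      shifted <- data.frame(C = d$C + library$dC[i], H = d$H + library$dH[i],
                            N = d$N + library$dN[i], O = d$O + library$dO[i],
                            S = d$S + library$dS[i], P = d$P + library$dP[i])
      ok <- shifted$C >= 0 & shifted$H >= 0 & shifted$N >= 0 &
        shifted$O >= 0 & shifted$S >= 0 & shifted$P >= 0
      key <- rep(NA_character_, nrow(shifted))
      key[ok] <- paste(shifted$C[ok], shifted$H[ok], shifted$N[ok],
                       shifted$O[ok], shifted$S[ok], shifted$P[ok],
                       sep = ".")
      hit <- p_lookup[key]
      found <- which(!is.na(hit))
      if (length(found)) {
        out[[length(out) + 1L]] <- data.frame(
          reactant = d_keys[found],
          product = p_keys[hit[found]],
          reaction = library$name[i],
          class_combo = paste0(d_class[found], "-", p_class[hit[found]])
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(reactant = character(), product = character(),
                      reaction = character(), class_combo = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize paired-mass-distance matches
#'
#' @param matches a [match_transformations()] result.
#' @return object of class `"reaction_summary"`: list with `by_reaction`
#'   (all-pairs and unique-reactant counts per reaction), `by_class_combo`
#'   (counts per heteroatom-class combination) and `total`.
#' @export
summarize_reactions <- function(matches) {
  if (nrow(matches) == 0L) {
    by_reaction <- data.frame(reaction = character(), n_pairs = integer(),
                              n_unique_reactants = integer())
    by_combo <- data.frame(class_combo = character(), n_pairs = integer())
  } else {
    by_reaction <- as.data.frame(table(reaction = matches$reaction),
                                 stringsAsFactors = FALSE)
    names(by_reaction)[2] <- "n_pairs"
    uniq <- unique(matches[, c("reactant", "reaction")])
    nu <- table(uniq$reaction)
    by_reaction$n_unique_reactants <-
      as.integer(nu[by_reaction$reaction])
    by_combo <- as.data.frame(table(class_combo = matches$class_combo),
                              stringsAsFactors = FALSE)
    names(by_combo)[2] <- "n_pairs"
  }
  structure(list(by_reaction = by_reaction, by_class_combo = by_combo,
                 total = nrow(matches)),
            class = "reaction_summary")
}

#' @export
print.reaction_summary <- function(x, ...) {
  cat("Reaction summary:", x$total, "matched pairs\n")
  if (nrow(x$by_reaction)) {
    print(x$by_reaction[order(-x$by_reaction$n_pairs), ], row.names = FALSE)
  }
  invisible(x)
}
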