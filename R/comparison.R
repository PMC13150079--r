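#' Partition paired samples into molecular fates
#'
#' Classifies every neutral formula observed in a paired (Before, After)
#' experiment as `"Disappeared"` (Before only), `"Resistant"` (both) or
#' `"Product"` (After only).  Identity is the neutral formula (element
#' counts), not the observed m/z.  Duplicate formulas within one sample have
#' their intensities summed with a warning.
#'
#' @param before,after assigned samples: data frames with element-count
#'   columns (or a `formula` Hill-string column) and an `intensity` or
#'   `relative_abundance` column, e.g. the `assignments` element of
#'   [assign_peaklist()], or a `"dom_assignment"` object directly.
#' @return object of class `"fate_partition"`: list with `fates` (data frame
#'   `formula`, `fate`, `rel_before`, `rel_after`), the formula vectors
#'   `disappeared`, `resistant`, `product`, and `counts`
#'   (`n_before`, `n_after`, `n_common`, `n_disappeared`, `n_resistant`,
#'   `n_product`).
#' @export
classify_fate <- function(before, after) {
  b <- sample_abundance(before, "before")
  a <- sample_abundance(after, "after")
  all_f <- union(b$formula, a$formula)
  rel_b <- b$rel[match(all_f, b$formula)]
  rel_a <- a$rel[match(all_f, a$formula)]
  fate <- ifelse(is.na(rel_a), "Disappeared",
                 ifelse(is.na(rel_b), "Product", "Resistant"))
  fates <- data.frame(formula = all_f, fate = fate,
                      rel_before = rel_b, rel_after = rel_a)
  structure(
    list(fates = fates,
         disappeared = all_f[fate == "Disappeared"],
         resistant = all_f[fate == "Resistant"],
         product = all_f[fate == "Product"],
         counts = c(n_before = nrow(b), n_after = nrow(a),
                    n_common = sum(fate == "Resistant"),
                    n_disappeared = sum(fate == "Disappeared"),
                    n_resistant = sum(fate == "Resistant"),
                    n_product = sum(fate == "Product"))),
    class = "fate_partition"
  )
}

# Collapse an assigned sample to one relative abundance per neutral formula.
sample_abundance <- function(x, label) {
  if (inherits(x, "dom_assignment")) x <- x$assignments
  if (!is.data.frame(x) || nrow(x) == 0L) {
    stop("sample `", label, "` must be a non-empty data frame")
  }
  key <- if (!is.null(x$formula)) x$formula else formula_string(x)
  val <- if (!is.null(x$intensity)) x$intensity else x$relative_abundance
  if (is.null(val)) {
    stop("sample `", label,
         "` needs an `intensity` or `relative_abundance` column")
  }
  if (anyDuplicated(key)) {
    warning("duplicate formulas in sample `", label,
            "`; intensities summed")
    val <- tapply(val, key, sum)
    key <- names(val)
    val <- as.numeric(val)
  }
  data.frame(formula = key, rel = val / sum(val))
}

#' @export
print.fate_partition <- function(x, ...) {
  cat("Molecular fate partition:\n")
  print(x$counts)
  invisible(x)
}

#' Abundance variation of resistant (common) formulas
#'
#' For each formula present in both samples, computes the log2 ratio of
#' relative abundances `r = log2(rel_after / rel_before)` and labels the
#' molecule `"enriched"` if `r >= log2(fold_cut)`, `"depleted"` if
#' `r <= -log2(fold_cut)`, else `"stable"`.  A zero relative abundance on
#' either side is treated as absence: the formula is re-routed to
#' Disappeared/Product with a warning.
#'
#' @param partition a [classify_fate()] result.
#' @param fold_cut fold-change threshold, must be > 1 (default 2).
#' @return the partition with an `abundance_change` data frame
#'   (`formula`, `log2_ratio`, `label`) attached and counts extended by
#'   `n_enriched`, `n_depleted`, `n_stable`.
#' @export
abundance_variation <- function(partition, fold_cut = 2) {
  stopifnot(inherits(partition, "fate_partition"))
  if (fold_cut <= 1) stop("fold_cut must be > 1")
  f <- partition$fates
  res <- f[f$fate == "Resistant", , drop = FALSE]
  zero_b <- res$rel_before == 0
  zero_a <- res$rel_after == 0
  if (any(zero_b | zero_a)) {
    warning(sum(zero_b | zero_a),
            " common formulas with zero abundance re-routed to ",
            "Product/Disappeared")
    move_p <- res$formula[zero_b & !zero_a]
    move_d <- res$formula[zero_a & !zero_b]
    drop <- res$formula[zero_a & zero_b]
    f$fate[f$formula %in% move_p] <- "Product"
    f$fate[f$formula %in% move_d] <- "Disappeared"
    f <- f[!f$formula %in% drop, , drop = FALSE]
    partition$fates <- f
    partition$disappeared <- f$formula[f$fate == "Disappeared"]
    partition$resistant <- f$formula[f$fate == "Resistant"]
    partition$product <- f$formula[f$fate == "Product"]
    res <- f[f$fate == "Resistant", , drop = FALSE]
  }
  r <- log2(res$rel_after / res$rel_before)
  cut <- log2(fold_cut)
  label <- ifelse(r >= cut, "enriched", ifelse(r <= -cut, "depleted",
                                               "stable"))
  partition$abundance_change <- data.frame(formula = res$formula,
                                           log2_ratio = r, label = label)
  partition$counts <- c(partition$counts,
                        n_enriched = sum(label == "enriched"),
                        n_depleted = sum(label == "depleted"),
                        n_stable = sum(label == "stable"))
  partition
}
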