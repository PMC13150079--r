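#' Read and write centroided peak lists
#'
#' Peak lists are exchanged as comma-delimited text with the header
#' `mz,intensity,sn`.  `write_peaklist()` drops any auxiliary columns (such
#' as the generator's `true_formula`); `read_peaklist()` validates the
#' header and basic sanity of the values.
#'
#' @param x data frame with at least `mz` and `intensity` (and usually `sn`).
#' @param path file path.
#' @return `read_peaklist()` returns a data frame `mz`, `intensity`, `sn`;
#'   `write_peaklist()` returns `path` invisibly.
#' @export
write_peaklist <- function(x, path) {
  if (is.null(x$sn)) x$sn <- NA_real_
  utils::write.csv(x[c("mz", "intensity", "sn")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("mz", "intensity") %in% names(x))) {
    stop("peak list must have header mz,intensity,sn: ", path)
  }
  if (any(x$mz <= 0) || any(x$intensity <= 0)) {
    stop("peak m/z and intensity must be positive: ", path)
  }
  x
}

#' Read and write ground-truth sidecar tables
#'
#' The synthetic generator's ground truth travels as delimited text with
#' header `formula,fate,reaction,partner`.
#'
#' @param truth the `truth$fates` data frame of a [generate_sample_pair()]
#'   result (or a compatible data frame).
#' @param path file path.
#' @return `read_ground_truth()` returns the data frame;
#'   `write_ground_truth()` returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth[c("formula", "fate", "reaction", "partner")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- utils::read.csv(path)
  need <- c("formula", "fate", "reaction", "partner")
  if (!all(need %in% names(x))) {
    stop("ground truth must have header formula,fate,reaction,partner: ",
         path)
  }
  x
}

#' Export an assignment table as delimited text
#'
#' Writes the assigned peaks (m/z, Hill formula, mass error, relative
#' abundance, element counts and any descriptor columns present) as CSV.
#'
#' @param assignment a [assign_peaklist()] result or its `assignments`
#'   data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  x <- if (inherits(assignment, "dom_assignment")) assignment$assignments
       else assignment
  lead <- intersect(c("mz", "formula", "error_ppm", "relative_abundance"),
                    names(x))
  utils::write.csv(x[c(lead, setdiff(names(x), lead))], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
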