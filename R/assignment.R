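#' Configuration for molecular formula assignment
#'
#' Holds the constrained-enumeration settings used to assign a unique neutral
#' CHNOS(P) formula to each negative-mode peak: mass tolerance, per-element
#' count ranges, elemental-ratio plausibility bounds and the allowed range of
#' double-bond equivalents.  All inputs are treated as singly charged
#' deprotonated ions.
#'
#' Defaults follow common practice for natural dissolved organic matter:
#' C 1-60, H 1-120, N 0-5, O 0-30, S 0-2, P 0; 0.3 <= H/C <= 2.25,
#' O/C <= 1.2, N/C <= 0.5, S/C <= 0.2; integer DBE in 0-40; 1 ppm tolerance.
#'
#' @param tolerance_ppm maximum absolute mass error of an accepted candidate,
#'   in parts per million of the observed m/z. Must be > 0 (a value of 0 is
#'   allowed and accepts only numerically exact matches).
#' @param elements named list of `c(min, max)` integer ranges per element.
#' @param hc_bounds,oc_max,nc_max,sc_max elemental-ratio plausibility bounds.
#' @param dbe_range allowed (integer) range of double-bond equivalents.
#' @return object of class `"assignment_config"`.
#' @export
assignment_config <- function(tolerance_ppm = 1.0,
                              elements = list(
                                C = c(1L, 60L), H = c(1L, 120L),
                                N = c(0L, 5L), O = c(0L, 30L),
                                S = c(0L, 2L), P = c(0L, 0L)
                              ),
                              hc_bounds = c(0.3, 2.25),
                              oc_max = 1.2,
                              nc_max = 0.5,
                              sc_max = 0.2,
                              dbe_range = c(0L, 40L)) {
  if (tolerance_ppm < 0) stop("tolerance_ppm must be >= 0")
  for (el in ELEMENTS) {
    r <- elements[[el]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2] || r[1] < 0) {
      stop("invalid element range for ", el)
    }
  }
  if (elements$C[1] < 1L) stop("at least one carbon is required (C min >= 1)")
  if (elements$H[1] < 1L) stop("at least one hydrogen is required (H min >= 1)")
  if (dbe_range[1] > dbe_range[2]) stop("invalid DBE range")
  structure(
    list(tolerance_ppm = tolerance_ppm, elements = elements,
         hc_bounds = hc_bounds, oc_max = oc_max, nc_max = nc_max,
         sc_max = sc_max, dbe_range = dbe_range),
    class = "assignment_config"
  )
}

# Double-bond equivalents; trivalent N and P contribute +1/2 each.
dbe_of <- function(f) {
  1 + f$C - f$H / 2 + (f$N + f$P) / 2
}

#' Chemical validity filter for candidate formulas
#'
#' Applies the element-range, elemental-ratio and DBE filters of an
#' [assignment_config()].  DBE must be a non-negative integer within range,
#' which also enforces electron-parity consistency for a singly deprotonated
#' even-electron ion.
#'
#' @param formula formula table or Hill strings.
#' @param config an [assignment_config()].
#' @return logical vector, `TRUE` where the formula passes all filters.
#' @export
is_valid_formula <- function(formula, config = assignment_config()) {
  f <- as_formula_df(formula)
  ok <- rep(TRUE, nrow(f))
  for (el in ELEMENTS) {
    r <- config$elements[[el]]
    ok <- ok & f[[el]] >= r[1] & f[[el]] <= r[2]
  }
  hc <- f$H / f$C
  ok <- ok & hc >= config$hc_bounds[1] & hc <= config$hc_bounds[2]
  ok <- ok & f$O / f$C <= config$oc_max
  ok <- ok & f$N / f$C <= config$nc_max
  ok <- ok & f$S / f$C <= config$sc_max
  dbe <- dbe_of(f)
  ok <- ok & dbe >= config$dbe_range[1] & dbe <= config$dbe_range[2] &
    abs(dbe - round(dbe)) < 1e-9
  ok
}

# Pre-computed heteroatom lattice (all element combinations except H), sorted
# by base mass so per-peak lookups can use a binary-searched mass window.
candidate_grid <- function(config) {
  e <- config$elements
  g <- expand.grid(
    C = seq.int(e$C[1], e$C[2]),
    N = seq.int(e$N[1], e$N[2]),
    O = seq.int(e$O[1], e$O[2]),
    S = seq.int(e$S[1], e$S[2]),
    P = seq.int(e$P[1], e$P[2]),
    KEEP.OUT.ATTRS = FALSE
  )
  base <- g$C * ELEMENT_MASS[["C"]] + g$N * ELEMENT_MASS[["N"]] +
    g$O * ELEMENT_MASS[["O"]] + g$S * ELEMENT_MASS[["S"]] +
    g$P * ELEMENT_MASS[["P"]]
  ord <- order(base)
  g <- g[ord, , drop = FALSE]
  g$base_mass <- base[ord]
  g
}

enumerate_on_grid <- function(mz, config, grid) {
  m_h <- ELEMENT_MASS[["H"]]
  target <- mz + m_h - ELECTRON_MASS  # neutral mass implied by [M-H]-
  tol_da <- config$tolerance_ppm * 1e-6 * mz
  h_rng <- config$elements$H
  # window of base masses that can reach `target` with an allowed H count
  lo <- target - h_rng[2] * m_h - tol_da - m_h
  hi <- target - h_rng[1] * m_h + tol_da + m_h
  i0 <- findInterval(lo, grid$base_mass) + 1L
  i1 <- findInterval(hi, grid$base_mass)
  empty <- data.frame(C = integer(), H = integer(), N = integer(),
                      O = integer(), S = integer(), P = integer(),
                      formula = character(), mass = numeric(),
                      mz_theor = numeric(), error_ppm = numeric())
  if (i1 < i0) return(empty)
  g <- grid[i0:i1, , drop = FALSE]
  resid <- target - g$base_mass
  h0 <- round(resid / m_h)
  # a tolerance wider than half a hydrogen mass can admit adjacent H counts
  span <- max(1L, ceiling(tol_da / m_h))
  out <- vector("list", 2L * span + 1L)
  for (k in seq.int(-span, span)) {
    h <- h0 + k
    mass <- g$base_mass + h * m_h
    mz_theor <- mass - m_h + ELECTRON_MASS
    err <- (mz_theor - mz) / mz * 1e6
    keep <- h >= h_rng[1] & h <= h_rng[2] & abs(err) <= config$tolerance_ppm
    if (!any(keep)) next
    cand <- data.frame(C = g$C[keep], H = as.integer(h[keep]), N = g$N[keep],
                       O = g$O[keep], S = g$S[keep], P = g$P[keep],
                       mass = mass[keep], mz_theor = mz_theor[keep],
                       error_ppm = err[keep])
    out[[k + span + 1L]] <- cand[is_valid_formula(cand, config), , drop = FALSE]
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[!duplicated(paste(out$C, out$H, out$N, out$O, out$S, out$P)), ,
             drop = FALSE]
  out$formula <- formula_string(out)
  out <- out[order(abs(out$error_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out[c("C", "H", "N", "O", "S", "P", "formula", "mass", "mz_theor",
        "error_ppm")]
}

#' Enumerate candidate formulas for one m/z
#'
#' Returns every formula in the configured element lattice whose singly
#' charged deprotonated ion lies within `tolerance_ppm` of the observed m/z
#' and that passes the chemical validity filters, sorted by absolute mass
#' error.  An empty data frame is a valid result.
#'
#' @param mz observed ion m/z (Th).
#' @param config an [assignment_config()].
#' @return data frame with element counts, `formula` (Hill string), neutral
#'   `mass`, theoretical ion `mz_theor` and signed `error_ppm`.
#' @examples
#' enumerate_candidates(179.056112, assignment_config())
#' @export
enumerate_candidates <- function(mz, config = assignment_config()) {
  stopifnot(length(mz) == 1L, mz > 0)
  enumerate_on_grid(mz, config, candidate_grid(config))
}

# min |error_ppm| -> fewest heteroatoms (N+S+P) -> fewest N -> lowest mass
pick_candidate <- function(cand) {
  ord <- order(abs(cand$error_ppm), cand$N + cand$S + cand$P, cand$N,
               cand$mass)
  cand[ord[1L], , drop = FALSE]
}

#' Assign formulas to a peak list
#'
#' Gives each centroided peak at most one neutral formula by constrained
#' exact-mass enumeration.  Ties are broken by smallest absolute mass error,
#' then fewest heteroatoms (N+S+P), then fewest N, then lowest mass
#' (parsimony heuristics standard for CHNOS assignment).  Peaks with no
#' candidate within tolerance are reported separately with a reason rather
#' than raising an error; relative abundance is computed over assigned peaks
#' only and sums to 1 per sample.
#'
#' @param peaks data frame with columns `mz`, `intensity` and optionally `sn`.
#' @param config an [assignment_config()].
#' @return object of class `"dom_assignment"`: a list with `assignments`
#'   (one row per assigned peak: peak columns, element counts, `formula`,
#'   `error_ppm`, `relative_abundance`), `unassigned` (peak + `reason`) and
#'   the `config` used.
#' @export
assign_peaklist <- function(peaks, config = assignment_config()) {
  if (!is.data.frame(peaks) || nrow(peaks) == 0L) {
    stop("`peaks` must be a non-empty data frame")
  }
  if (is.null(peaks$mz) || is.null(peaks$intensity)) {
    stop("`peaks` must have columns `mz` and `intensity`")
  }
  if (any(peaks$mz <= 0) || any(peaks$intensity <= 0)) {
    stop("peak m/z and intensity must be positive")
  }
  grid <- candidate_grid(config)
  n <- nrow(peaks)
  hits <- vector("list", n)
  reason <- character(n)
  for (i in seq_len(n)) {
    cand <- enumerate_on_grid(peaks$mz[[i]], config, grid)
    if (nrow(cand) == 0L) {
      reason[[i]] <- "no candidate"
    } else {
      hits[[i]] <- pick_candidate(cand)
    }
  }
  assigned_idx <- which(reason == "")
  unassigned <- cbind(peaks[reason != "", , drop = FALSE],
                      reason = reason[reason != ""])
  rownames(unassigned) <- NULL
  if (length(assigned_idx) == 0L) {
    warning("no peak could be assigned a formula")
    assignments <- cbind(peaks[0, , drop = FALSE],
                         do.call(rbind, hits))
  } else {
    assignments <- cbind(peaks[assigned_idx, , drop = FALSE],
                         do.call(rbind, hits[assigned_idx]))
    assignments$relative_abundance <-
      assignments$intensity / sum(assignments$intensity)
  }
  rownames(assignments) <- NULL
  structure(list(assignments = assignments, unassigned = unassigned,
                 config = config),
            class = "dom_assignment")
}

#' @export
print.dom_assignment <- function(x, ...) {
  cat("Formula assignment:", nrow(x$assignments), "assigned,",
      nrow(x$unassigned), "unassigned peaks",
      sprintf("(tolerance %.3g ppm)\n", x$config$tolerance_ppm))
  invisible(x)
}
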