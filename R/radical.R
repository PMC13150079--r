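#' Hydroxyl-radical yield per unit of p-hydroxybenzoic acid probe
#'
#' Benzoic acid competes for hydroxyl radicals; its hydroxylation product
#' p-HBA is quantified by HPLC and converted to the apparent accumulated
#' radical concentration captured by the probe under competition kinetics
#' (not a steady-state concentration).  One micromolar of p-HBA corresponds
#' to 5.87 micromolar of accumulated hydroxyl radical.
#'
#' @format a single numeric constant.
#' @export
OH_PER_PHBA <- 5.87

#' Convert p-HBA probe concentration to accumulated hydroxyl radical
#'
#' @param p_hba p-hydroxybenzoic acid concentration(s), uM; must be >= 0.
#' @return accumulated hydroxyl-radical concentration, uM
#'   (`OH_PER_PHBA * p_hba`).
#' @examples
#' phba_to_oh(1.00)   # 5.87
#' @export
phba_to_oh <- function(p_hba) {
  if (any(p_hba < 0)) stop("p-HBA concentration must be non-negative")
  OH_PER_PHBA * p_hba
}

#' Normalize a suspension concentration to soil-mass basis
#'
#' Converts a concentration measured in the soil suspension (uM, i.e.
#' umol/l) to umol per kg of dry soil: `conc * volume_ml / soil_g`.
#'
#' @param conc concentration in the suspension, uM.
#' @param volume_ml suspension volume, ml; must be > 0.
#' @param soil_g dry-soil mass, g; must be > 0.
#' @return umol per kg soil.
#' @examples
#' to_soil_mass_basis(142.30, volume_ml = 50, soil_g = 20)  # 355.75
#' @export
to_soil_mass_basis <- function(conc, volume_ml, soil_g) {
  if (volume_ml <= 0) stop("suspension volume must be positive")
  if (soil_g <= 0) stop("soil mass must be positive")
  conc * volume_ml / soil_g
}

#' Ordinary least-squares line fit
#'
#' Linear regression with intercept, used e.g. for accumulated hydroxyl
#' radical versus initial 0.5 M HCl-extracted Fe(II).
#'
#' @param x,y numeric vectors of equal length, n >= 3; `x` must not be
#'   constant.
#' @return list of class `"dom_regression"` with `slope`, `intercept` and
#'   `r_squared`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 points are required")
  if (stats::sd(x) == 0) stop("x is constant; slope is undefined")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "dom_regression")
}

#' @export
print.dom_regression <- function(x, ...) {
  cat(sprintf("slope %.4f, intercept %.4f, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Percent contribution of a scavenged pathway
#'
#' Fractional decrease of accumulated hydroxyl radical when a scavenger
#' (e.g. 2,2'-dipyridyl for Fe(II), catalase for H2O2) is added:
#' `100 * (oh_control - oh_scavenged) / oh_control`.
#'
#' @param oh_control accumulated radical without scavenger, uM; must be > 0.
#' @param oh_scavenged accumulated radical with scavenger, uM; values above
#'   the control trigger a warning (negative contribution).
#' @return percent decrease.
#' @export
scavenger_contribution <- function(oh_control, oh_scavenged) {
  if (any(oh_control <= 0)) stop("control concentration must be positive")
  if (any(oh_scavenged < 0)) stop("scavenged concentration must be >= 0")
  if (any(oh_scavenged > oh_control)) {
    warning("scavenged concentration exceeds control; negative contribution")
  }
  100 * (oh_control - oh_scavenged) / oh_control
}

#' Contaminant removal rate
#'
#' Percent of the initial contaminant concentration removed during the
#' oxygen-exposure treatment: `100 * (c0 - ct) / c0`.
#'
#' @param c0 initial concentration, uM; must be > 0.
#' @param ct concentration after treatment, uM.
#' @return percent removal.
#' @export
removal_rate <- function(c0, ct) {
  if (any(c0 <= 0)) stop("initial concentration must be positive")
  if (any(ct < 0)) stop("final concentration must be >= 0")
  100 * (c0 - ct) / c0
}
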