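#' Default compound-class sampling weights
#'
#' Natural DOM is dominated by lignin/CRAM-like material, with smaller
#' tannin, protein, lipid, aromatic and carbohydrate fractions.
#'
#' @return named probability vector over Van Krevelen classes (sums to 1).
#' @export
default_class_weights <- function() {
  c("lignin/CRAM-like" = 0.45,
    "tannins" = 0.12,
    "proteins/amino sugars" = 0.12,
    "lipids" = 0.08,
    "condensed aromatics" = 0.08,
    "carbohydrates" = 0.05,
    "unsaturated hydrocarbons" = 0.05,
    "other" = 0.05)
}

#' Default heteroatom-class sampling weights
#'
#' CHO and CHON dominate; sulfur-bearing formulas (CHOS) are a small
#' minority of the molecular composition.
#'
#' @return named probability vector over heteroatom classes (sums to 1).
#' @export
default_heteroatom_weights <- function() {
  c(CHO = 0.40, CHON = 0.40, CHOS = 0.06, CHONS = 0.14)
}

#' Configuration for the synthetic DOM generator
#'
#' Defines the statistical structure of generated peak lists and paired
#' before/after samples: how many formulas, how they spread over Van
#' Krevelen compound classes and heteroatom classes, the (log-normal)
#' intensity distribution, the mass-accuracy noise, which one-step reactions
#' are planted linking Disappeared reactants to Products, and the logistic
#' disappearance model that ties molecular fate to descriptors.
#'
#' The default fate model is logistic in the standardized descriptors N/C,
#' m/z, S/C and O/C with coefficients +3.0, -2.5, +2.0 and +1.5: nitrogen-
#' rich, lighter, sulfur-bearing and oxygen-rich molecules are more
#' susceptible to removal.  The default reaction plan plants 30 dealkylation,
#' 20 decarboxylation and 10 oxygen-addition edges.
#'
#' @param n_formulas number of formulas in the pool.
#' @param class_weights named probabilities over compound classes (must sum
#'   to 1 within 1e-9); names must match [vk_class_table()] classes or
#'   `"other"`.
#' @param heteroatom_weights named probabilities over
#'   `{CHO, CHON, CHOS, CHONS}` (must sum to 1 within 1e-9).
#' @param intensity_log_mean,intensity_log_sd parameters of the log-normal
#'   peak-intensity distribution (unitless; intensities are analysed as
#'   relative abundances).
#' @param mz_error_sd_ppm Gaussian mass-accuracy noise, ppm (0.2 ppm default,
#'   typical of a 15 T instrument).
#' @param reaction_plan named counts of planted reaction edges; names must
#'   exist in [reaction_library()].
#' @param fate_coefficients named coefficients `intercept`, `n_c`, `mz`,
#'   `s_c`, `o_c` of the logistic disappearance model (applied to
#'   pool-standardized descriptors).
#' @param n_denovo_products number of additional Product formulas not linked
#'   to any planted reaction (flagged `"de-novo"` in the ground truth).
#' @param c_range carbon-count sampling range.
#' @param mz_range acceptance window for the deprotonated ion m/z, Th.
#' @param seed integer seed fixing all randomness end-to-end; stage sub-seeds
#'   are derived deterministically from it.
#' @param max_attempts rejection-sampling attempts allowed per molecule
#'   before an infeasible class/heteroatom combination is reported.
#' @param assignment the [assignment_config()] whose validity filters every
#'   generated formula must pass.
#' @return object of class `"generator_config"`.
#' @export
generator_config <- function(n_formulas = 3000,
                             class_weights = default_class_weights(),
                             heteroatom_weights = default_heteroatom_weights(),
                             intensity_log_mean = 0,
                             intensity_log_sd = 1.0,
                             mz_error_sd_ppm = 0.2,
                             reaction_plan = c("dealkylation" = 30,
                                               "decarboxylation" = 20,
                                               "oxygen addition" = 10),
                             fate_coefficients = c(intercept = 0, n_c = 3.0,
                                                   mz = -2.5, s_c = 2.0,
                                                   o_c = 1.5),
                             n_denovo_products = 0,
                             c_range = c(8L, 36L),
                             mz_range = c(150, 800),
                             seed = 0L,
                             max_attempts = 2000L,
                             assignment = assignment_config()) {
  if (n_formulas < 1) stop("n_formulas must be >= 1")
  if (abs(sum(class_weights) - 1) > 1e-9) {
    stop("class_weights must sum to 1")
  }
  if (abs(sum(heteroatom_weights) - 1) > 1e-9) {
    stop("heteroatom_weights must sum to 1")
  }
  if (any(class_weights < 0) || any(heteroatom_weights < 0)) {
    stop("weights must be non-negative")
  }
  known <- c(vk_class_table()$class, "other")
  if (!all(names(class_weights) %in% known)) {
    stop("unknown compound class in class_weights: ",
         paste(setdiff(names(class_weights), known), collapse = ", "))
  }
  if (!all(names(heteroatom_weights) %in%
           c("CHO", "CHON", "CHOS", "CHONS"))) {
    stop("heteroatom_weights must be over CHO/CHON/CHOS/CHONS")
  }
  if (length(reaction_plan) && is.null(names(reaction_plan))) {
    stop("reaction_plan must be a named count vector")
  }
  if (any(reaction_plan < 0) || any(reaction_plan != round(reaction_plan))) {
    stop("reaction_plan counts must be non-negative integers")
  }
  lib_names <- reaction_library()$name
  if (!all(names(reaction_plan) %in% lib_names)) {
    stop("unknown reaction in reaction_plan: ",
         paste(setdiff(names(reaction_plan), lib_names), collapse = ", "))
  }
  need <- c("intercept", "n_c", "mz", "s_c", "o_c")
  if (!all(need %in% names(fate_coefficients))) {
    stop("fate_coefficients needs names ", paste(need, collapse = ", "))
  }
  if (n_denovo_products < 0) stop("n_denovo_products must be >= 0")
  out <- structure(
    list(n_formulas = as.integer(n_formulas), class_weights = class_weights,
         heteroatom_weights = heteroatom_weights,
         intensity_log_mean = intensity_log_mean,
         intensity_log_sd = intensity_log_sd,
         mz_error_sd_ppm = mz_error_sd_ppm, reaction_plan = reaction_plan,
         fate_coefficients = fate_coefficients,
         n_denovo_products = as.integer(n_denovo_products),
         c_range = as.integer(c_range), mz_range = mz_range,
         seed = as.integer(seed), max_attempts = as.integer(max_attempts),
         assignment = assignment),
    class = "generator_config"
  )
  conditional_het_weights(out)  # fail fast on infeasible combinations
  out
}

# Sampling rectangles: the Van Krevelen class table intersected with the
# validity ratio bounds.  The "other" label covers the areas no class
# rectangle claims: the saturated band above H/C 2.2, the protein rectangle
# when nitrogen is absent, and the oxygen-rich low-H/C corner below the
# tannin rectangle.  `forbids_n` marks sub-regions only reachable by N-free
# formulas (an N-bearing draw there would classify as protein).
class_regions <- function(config) {
  tab <- vk_class_table()
  tab$forbids_n <- FALSE
  other <- data.frame(
    class = "other",
    oc_min = c(0, 0.3, 0.67), oc_max = c(1.2, 0.67, 1.2),
    hc_min = c(2.2, 1.5, 0.2), hc_max = c(2.25, 2.2, 0.5),
    requires_n = FALSE,
    forbids_n = c(FALSE, TRUE, FALSE)
  )
  tab <- rbind(tab, other)
  tab$hc_min <- pmax(tab$hc_min, config$assignment$hc_bounds[1])
  tab$hc_max <- pmin(tab$hc_max, config$assignment$hc_bounds[2])
  tab$oc_max <- pmin(tab$oc_max, config$assignment$oc_max)
  tab$area <- (tab$oc_max - tab$oc_min) * (tab$hc_max - tab$hc_min)
  tab
}

# Heteroatom weights conditioned on whether the compound class requires N,
# chosen so that BOTH the class and heteroatom marginals are preserved.
conditional_het_weights <- function(config) {
  regions <- class_regions(config)
  w_class <- config$class_weights
  w_het <- config$heteroatom_weights
  req_n <- regions$class[regions$requires_n]
  p_req <- sum(w_class[names(w_class) %in% req_n])
  has_n <- grepl("N", names(w_het))
  r <- ifelse(has_n, w_het, 0)
  if (p_req > 0 && sum(r) == 0) {
    stop("infeasible combination: class '", req_n[1],
         "' requires nitrogen but no N-containing heteroatom class has ",
         "positive weight")
  }
  if (p_req > 0) r <- r / sum(r)
  if (p_req >= 1 - 1e-12) {
    if (any(w_het[!has_n] > 0)) {
      stop("infeasible combination: all class weight is on ",
           "nitrogen-requiring classes but heteroatom_weights puts mass ",
           "on N-free classes")
    }
    comp <- r
  } else {
    comp <- (w_het - p_req * r) / (1 - p_req)
    if (any(comp < -1e-9)) {
      stop("infeasible combination: heteroatom_weights cannot support the ",
           "weight of nitrogen-requiring class '", req_n[1], "'")
    }
    comp <- pmax(comp, 0)
    comp <- comp / sum(comp)
  }
  list(restricted = r, complementary = comp)
}

# Pick a sampling rectangle for each slot: classes map to one row, "other"
# to one of its sub-regions (area-weighted, excluding N-forbidding rows for
# nitrogen-bearing draws).
draw_region_rows <- function(class_lab, has_n, regions) {
  ri <- integer(length(class_lab))
  for (cl in unique(class_lab)) {
    rows <- which(regions$class == cl)
    rows_nfree <- rows
    rows_n <- rows[!regions$forbids_n[rows]]
    for (variant in list(list(sel = class_lab == cl & has_n, rows = rows_n),
                         list(sel = class_lab == cl & !has_n,
                              rows = rows_nfree))) {
      if (!any(variant$sel)) next
      rr <- variant$rows
      ri[variant$sel] <- rr[sample.int(length(rr), sum(variant$sel),
                                       replace = TRUE,
                                       prob = regions$area[rr])]
    }
  }
  ri
}

# One candidate formula per pending slot, vectorized.
draw_candidates <- function(class_lab, het_lab, regions, config) {
  n <- length(class_lab)
  ri <- draw_region_rows(class_lab, grepl("N", het_lab), regions)
  c_count <- sample(seq.int(config$c_range[1], config$c_range[2]), n,
                    replace = TRUE)
  oc <- stats::runif(n, regions$oc_min[ri], regions$oc_max[ri])
  hc <- stats::runif(n, regions$hc_min[ri], regions$hc_max[ri])
  has_n <- grepl("N", het_lab)
  has_s <- grepl("S", het_lab)
  n_count <- ifelse(has_n,
                    sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                    0L)
  s_count <- ifelse(has_s & !has_n,
                    sample(1:2, n, replace = TRUE, prob = c(0.85, 0.15)),
                    ifelse(has_s, 1L, 0L))
  o_count <- pmax(1L, as.integer(round(oc * c_count)))
  h_count <- as.integer(round(hc * c_count))
  # even (H + N) keeps DBE integral; nudge H down when adding one hydrogen
  # would push H/C past the class rectangle (tight for saturated classes)
  odd <- (h_count + n_count) %% 2L == 1L
  up_ok <- (h_count + 1L) / c_count < regions$hc_max[ri]
  h_count[odd & up_ok] <- h_count[odd & up_ok] + 1L
  h_count[odd & !up_ok] <- h_count[odd & !up_ok] - 1L
  data.frame(C = c_count, H = h_count, N = as.integer(n_count),
             O = o_count, S = as.integer(s_count), P = 0L)
}

#' Generate a pool of DOM-like molecular formulas
#'
#' Draws `n_formulas` unique CHNOS formulas by rejection sampling inside the
#' configured Van Krevelen class rectangles, honouring the compound-class
#' and heteroatom-class weights and guaranteeing that every formula passes
#' the chemical validity filters of the assignment module.
#'
#' @param config a [generator_config()].
#' @return data frame with element counts, `formula`, `mass`, `mz_theor`,
#'   `compound_class` and `heteroatom_class`; exactly
#'   `config$n_formulas` rows.
#' @export
generate_formula_pool <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  sample_formula_batch(config$n_formulas, config, exclude_keys = character())
}

# Shared by the pool generator and the de-novo product draw.
sample_formula_batch <- function(n, config, exclude_keys) {
  regions <- class_regions(config)
  hw <- conditional_het_weights(config)
  w_class <- config$class_weights
  class_lab <- sample(names(w_class), n, replace = TRUE, prob = w_class)
  req_n <- regions$class[regions$requires_n]
  het_lab <- character(n)
  is_req <- class_lab %in% req_n
  het_names <- names(config$heteroatom_weights)
  if (any(is_req)) {
    het_lab[is_req] <- sample(het_names, sum(is_req), replace = TRUE,
                              prob = hw$restricted)
  }
  if (any(!is_req)) {
    het_lab[!is_req] <- sample(het_names, sum(!is_req), replace = TRUE,
                               prob = hw$complementary)
  }
  accepted <- vector("list", 64L)
  n_acc <- 0L
  keys <- exclude_keys
  pending <- seq_len(n)
  attempts <- 0L
  while (length(pending)) {
    attempts <- attempts + 1L
    if (attempts > config$max_attempts) {
      stop("could not generate a valid formula for class '",
           class_lab[pending[1]], "' (heteroatom class ",
           het_lab[pending[1]], ") after ", config$max_attempts,
           " attempts")
    }
    cand <- draw_candidates(class_lab[pending], het_lab[pending], regions,
                            config)
    ok <- is_valid_formula(cand, config$assignment)
    mz <- deprotonated_mz(cand)
    ok <- ok & mz >= config$mz_range[1] & mz <= config$mz_range[2]
    lab <- assign_compound_class(cand$O / cand$C, cand$H / cand$C, cand$N)
    ok <- ok & lab == class_lab[pending]
    ok <- ok & heteroatom_class(cand) == het_lab[pending]
    key <- formula_key(cand)
    ok <- ok & !key %in% keys & !duplicated(key)
    if (any(ok)) {
      hit <- cand[ok, , drop = FALSE]
      hit$formula <- formula_string(hit)
      hit$mass <- monoisotopic_mass(hit)
      hit$mz_theor <- mz[ok]
      hit$compound_class <- class_lab[pending][ok]
      hit$heteroatom_class <- het_lab[pending][ok]
      n_acc <- n_acc + 1L
      accepted[[n_acc]] <- hit
      keys <- c(keys, key[ok])
      pending <- pending[!ok]
    }
  }
  out <- do.call(rbind, accepted[seq_len(n_acc)])
  out <- out[order(out$mz_theor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a paired before/after sample with planted ground truth
#'
#' Assigns each pool formula a fate by the logistic disappearance model
#' (Disappeared molecules occur only in the Before sample, Resistant in
#' both), plants the configured one-step reaction edges from Disappeared
#' reactants to new Product formulas (Products occur only in the After
#' sample, and satisfy the exact elemental delta of their reaction), then
#' renders both samples as centroided peak lists with log-normal intensities
#' and Gaussian ppm mass noise.
#'
#' @param pool a [generate_formula_pool()] result (regenerated from `config`
#'   when omitted).
#' @param config a [generator_config()].
#' @return list with `before` and `after` peak lists (`mz`, `intensity`,
#'   `sn`), and `truth`: a list holding `fates` (data frame `formula`,
#'   `fate`, `reaction`, `partner`) and `edges` (planted reaction edges
#'   `reactant`, `product`, `reaction`).
#' @export
generate_sample_pair <- function(pool = NULL, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(pool)) pool <- generate_formula_pool(config)
  set.seed(config$seed + 1L)
  desc <- compute_descriptors(pool)
  b <- config$fate_coefficients
  lin <- b[["intercept"]] +
    b[["n_c"]] * standardize(desc$n_c) +
    b[["mz"]] * standardize(desc$mz_theor) +
    b[["s_c"]] * standardize(desc$s_c) +
    b[["o_c"]] * standardize(desc$o_c)
  p_dis <- stats::plogis(lin)
  fate <- ifelse(stats::runif(nrow(pool)) < p_dis, "Disappeared",
                 "Resistant")
  planted <- plant_reactions(pool, fate, config)
  products <- planted$products
  fates <- data.frame(formula = pool$formula, fate = fate,
                      reaction = NA_character_, partner = NA_character_)
  if (nrow(products)) {
    fates <- rbind(fates,
                   data.frame(formula = products$formula, fate = "Product",
                              reaction = products$reaction,
                              partner = products$partner))
  }
  before_f <- pool
  after_f <- rbind(pool[fate == "Resistant",
                        c(ELEMENTS, "formula", "mz_theor")],
                   products[c(ELEMENTS, "formula", "mz_theor")])
  list(
    before = render_peaklist(before_f, config),
    after = render_peaklist(after_f, config),
    truth = list(fates = fates, edges = planted$edges)
  )
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

plant_reactions <- function(pool, fate, config) {
  lib <- reaction_library()
  plan <- config$reaction_plan
  pool_keys <- formula_key(pool)
  dis_idx <- which(fate == "Disappeared")
  if (sum(plan) > length(dis_idx)) {
    stop("reaction_plan plants ", sum(plan), " edges but only ",
         length(dis_idx), " Disappeared formulas are available")
  }
  used <- integer()
  prod_keys <- character()
  products <- list()
  edges <- list()
  for (rn in names(plan)) {
    k <- plan[[rn]]
    if (k == 0) next
    delta <- lib[lib$name == rn, c("dC", "dH", "dN", "dO", "dS", "dP")]
    cand <- sample(setdiff(dis_idx, used))
    got <- 0L
    for (i in cand) {
      prod <- data.frame(C = pool$C[i] + delta$dC, H = pool$H[i] + delta$dH,
                         N = pool$N[i] + delta$dN, O = pool$O[i] + delta$dO,
                         S = pool$S[i] + delta$dS, P = pool$P[i] + delta$dP)
      if (any(prod < 0) || prod$C < 1 || prod$H < 1) next
      if (!is_valid_formula(prod, config$assignment)) next
      pmz <- deprotonated_mz(prod)
      if (pmz < config$mz_range[1] || pmz > config$mz_range[2]) next
      pkey <- formula_key(prod)
      if (pkey %in% pool_keys || pkey %in% prod_keys) next
      prod$formula <- formula_string(prod)
      prod$mz_theor <- pmz
      prod$reaction <- rn
      prod$partner <- pool$formula[i]
      products[[length(products) + 1L]] <- prod
      edges[[length(edges) + 1L]] <-
        data.frame(reactant = pool$formula[i], product = prod$formula,
                   reaction = rn)
      prod_keys <- c(prod_keys, pkey)
      used <- c(used, i)
      got <- got + 1L
      if (got == k) break
    }
    if (got < k) {
      stop("could not plant ", k, " '", rn, "' edges: only ", got,
           " Disappeared formulas yield a valid, unique product")
    }
  }
  if (config$n_denovo_products > 0) {
    extra <- sample_formula_batch(config$n_denovo_products, config,
                                  exclude_keys = c(pool_keys, prod_keys))
    extra <- extra[c(ELEMENTS, "formula", "mz_theor")]
    extra$reaction <- "de-novo"
    extra$partner <- NA_character_
    products <- c(products, list(extra))
  }
  empty_prod <- data.frame(C = integer(), H = integer(), N = integer(),
                           O = integer(), S = integer(), P = integer(),
                           formula = character(), mz_theor = numeric(),
                           reaction = character(), partner = character())
  empty_edge <- data.frame(reactant = character(), product = character(),
                           reaction = character())
  list(
    products = if (length(products)) do.call(rbind, products) else empty_prod,
    edges = if (length(edges)) do.call(rbind, edges) else empty_edge
  )
}

# Render formulas as a centroided negative-mode peak list.  The generating
# formula is carried along in `true_formula` (dropped by write_peaklist) so
# assignment recovery can be audited against the ground truth.
render_peaklist <- function(formulas, config) {
  n <- nrow(formulas)
  mz <- formulas$mz_theor *
    (1 + stats::rnorm(n, 0, config$mz_error_sd_ppm) * 1e-6)
  intensity <- stats::rlnorm(n, config$intensity_log_mean,
                             config$intensity_log_sd)
  sn <- pmax(4, stats::rlnorm(n, log(30), 0.8))
  out <- data.frame(mz = mz, intensity = intensity, sn = sn,
                    true_formula = formulas$formula)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic oxygenation time series
#'
#' Emulates the radical and iron dynamics observed when an anaerobically
#' incubated soil suspension is exposed to oxygen: accumulated hydroxyl
#' radical rises as a saturating exponential
#' `oh(t) = plateau * (1 - exp(-k_oh * t))`, the HCl-extractable Fe(II)
#' fraction decays as `fe2(t) = fe2_final + (fe2_initial - fe2_final) *
#' exp(-k_fe * t)`, and the p-HBA probe reads `oh / 5.87`.  Optional
#' Gaussian noise is added and concentrations are floored at zero.
#'
#' @param plateau asymptotic accumulated hydroxyl radical, uM.
#' @param k_oh radical accumulation rate constant, 1/h; must be >= 0.
#' @param fe2_initial,fe2_final initial and residual 0.5 M HCl-extracted
#'   Fe(II), mg/g soil.
#' @param k_fe Fe(II) oxidation rate constant, 1/h; must be >= 0.
#' @param times sampling times, h (strictly increasing).
#' @param noise_sd Gaussian noise standard deviation applied to the radical
#'   (uM) and Fe(II) (same units scaled by `fe2_initial/plateau`) curves.
#' @param volume_ml,soil_g suspension volume and dry-soil mass, carried as
#'   attributes for soil-mass normalization.
#' @param seed integer seed.
#' @return data frame of class `"radical_series"` with columns `time`,
#'   `p_hba`, `oh`, `fe2_hcl` and attributes `volume_ml`, `soil_g`.
#' @export
generate_incubation_series <- function(plateau = 142.30, k_oh = 1.8,
                                       fe2_initial = 3.13, fe2_final = 0.61,
                                       k_fe = 1.5,
                                       times = seq(0, 12, by = 0.5),
                                       noise_sd = 0, volume_ml = 50,
                                       soil_g = 20, seed = 0L) {
  if (k_oh < 0 || k_fe < 0) stop("rate constants must be non-negative")
  if (plateau < 0 || fe2_initial < 0 || fe2_final < 0 || noise_sd < 0) {
    stop("concentrations and noise sd must be non-negative")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  set.seed(as.integer(seed))
  n <- length(times)
  oh <- plateau * (1 - exp(-k_oh * times)) + stats::rnorm(n, 0, noise_sd)
  oh <- pmax(oh, 0)
  fe_noise_sd <- if (plateau > 0) noise_sd * fe2_initial / plateau else 0
  fe2 <- fe2_final + (fe2_initial - fe2_final) * exp(-k_fe * times) +
    stats::rnorm(n, 0, fe_noise_sd)
  fe2 <- pmax(fe2, 0)
  out <- data.frame(time = times, p_hba = oh / OH_PER_PHBA, oh = oh,
                    fe2_hcl = fe2)
  attr(out, "volume_ml") <- volume_ml
  attr(out, "soil_g") <- soil_g
  class(out) <- c("radical_series", "data.frame")
  out
}
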