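# Shared fixture builders.  Everything is generated in code at test time.

# Small noiseless paired experiment with planted reactions, assigned at the
# default 1 ppm tolerance.  Cached per (n, seed) within a test run.
.fixture_cache <- new.env(parent = emptyenv())

noiseless_pair <- function(n = 400, seed = 0) {
  key <- paste0("pair_", n, "_", seed)
  if (!is.null(.fixture_cache[[key]])) {
    return(.fixture_cache[[key]])
  }
  cfg <- generator_config(n_formulas = n, seed = seed, mz_error_sd_ppm = 0)
  pair <- generate_sample_pair(config = cfg)
  before <- assign_peaklist(pair$before)
  after <- assign_peaklist(pair$after)
  out <- list(config = cfg, pair = pair, before = before, after = after,
              partition = classify_fate(before$assignments,
                                        after$assignments))
  .fixture_cache[[key]] <- out
  out
}

# Feature matrix labelled directly from the generator's ground truth
# (bypasses assignment noise; used for the ML planted-structure checks).
truth_features <- function(pair) {
  tr <- pair$truth$fates
  desc <- compute_descriptors(parse_formula(tr$formula))
  desc$formula <- tr$formula
  part <- structure(
    list(fates = data.frame(formula = tr$formula, fate = tr$fate)),
    class = "fate_partition"
  )
  build_feature_matrix(desc, desc, part)
}

# Hand-built three-class feature table (no generator): `sep` carries the
# class perfectly, `noise` carries nothing.
separable_features <- function(n_per_class = 100, seed = 1) {
  set.seed(seed)
  fate <- factor(rep(c("Disappeared", "Resistant", "Product"),
                     each = n_per_class))
  out <- data.frame(
    formula = paste0("F", seq_along(fate)),
    fate = fate,
    sep = as.integer(fate) + stats::runif(length(fate), -0.2, 0.2),
    noise = stats::rnorm(length(fate))
  )
  attr(out, "feature_cols") <- c("sep", "noise")
  out
}
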