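test_that("the generator is deterministic end-to-end", {
  cfg <- generator_config(n_formulas = 200, seed = 42)
  pool1 <- generate_formula_pool(cfg)
  pool2 <- generate_formula_pool(cfg)
  expect_identical(pool1, pool2)
  pair1 <- generate_sample_pair(pool1, cfg)
  pair2 <- generate_sample_pair(pool2, cfg)
  expect_identical(pair1, pair2)
  # a different seed changes the draw
  pool3 <- generate_formula_pool(generator_config(n_formulas = 200,
                                                  seed = 43))
  expect_false(identical(pool1$formula, pool3$formula))
})

test_that("degenerate class weights confine the pool to one region", {
  cfg <- generator_config(
    n_formulas = 50, seed = 1,
    class_weights = c(carbohydrates = 1),
    reaction_plan = c(dealkylation = 0)
  )
  pool <- generate_formula_pool(cfg)
  expect_identical(nrow(pool), 50L)
  expect_true(all(pool$compound_class == "carbohydrates"))
  expect_true(all(pool$O / pool$C >= 0.67 & pool$O / pool$C < 1.2))
  expect_true(all(pool$H / pool$C >= 1.5 & pool$H / pool$C < 2.2))
})

test_that("heteroatom proportions track their weights", {
  pool <- generate_formula_pool(generator_config(n_formulas = 5000,
                                                 seed = 0))
  chos <- mean(pool$heteroatom_class == "CHOS")
  expect_gte(chos, 0.045)
  expect_lte(chos, 0.075)
  # compound-class marginals also stay within binomial error (~4 sd)
  w <- default_class_weights()
  obs <- table(factor(pool$compound_class, levels = names(w))) / nrow(pool)
  expect_true(all(abs(obs - w) < 4 * sqrt(w * (1 - w) / nrow(pool)) + 1e-9))
})

test_that("every generated formula passes the assignment validity filters", {
  pool <- generate_formula_pool(generator_config(n_formulas = 800,
                                                 seed = 3))
  expect_true(all(is_valid_formula(pool)))
  expect_false(anyDuplicated(pool$formula) > 0)
  mz <- deprotonated_mz(pool[c("C", "H", "N", "O", "S", "P")])
  expect_true(all(mz >= 150 & mz <= 800))
})

test_that("planted reactions satisfy their exact elemental deltas", {
  cfg <- generator_config(n_formulas = 400, seed = 5,
                          reaction_plan = c("oxygen addition" = 10))
  pair <- generate_sample_pair(config = cfg)
  edges <- pair$truth$edges
  expect_identical(nrow(edges), 10L)
  r <- parse_formula(edges$reactant)
  p <- parse_formula(edges$product)
  expect_true(all(p$O - r$O == 1L))
  expect_true(all(p$C == r$C & p$H == r$H & p$N == r$N & p$S == r$S))
  # fate labels partition the union of both samples
  tr <- pair$truth$fates
  expect_identical(anyDuplicated(tr$formula), 0L)
  expect_setequal(unique(tr$fate), c("Disappeared", "Resistant", "Product"))
})

test_that("samples respect the planted fate structure", {
  fx <- noiseless_pair(n = 400, seed = 0)
  tr <- fx$pair$truth$fates
  before_f <- fx$pair$before$true_formula
  after_f <- fx$pair$after$true_formula
  dis <- tr$formula[tr$fate == "Disappeared"]
  res <- tr$formula[tr$fate == "Resistant"]
  pro <- tr$formula[tr$fate == "Product"]
  expect_true(all(dis %in% before_f) && !any(dis %in% after_f))
  expect_true(all(res %in% before_f) && all(res %in% after_f))
  expect_true(all(pro %in% after_f) && !any(pro %in% before_f))
})

test_that("descriptor-coupled disappearance is detectable by a rank test", {
  cfg <- generator_config(
    n_formulas = 1000, seed = 0,
    fate_coefficients = c(intercept = 0, n_c = 8, mz = 0, s_c = 0, o_c = 0)
  )
  pair <- generate_sample_pair(config = cfg)
  tr <- pair$truth$fates
  d <- compute_descriptors(parse_formula(tr$formula))
  w <- wilcox.test(d$n_c[tr$fate == "Disappeared"],
                   d$n_c[tr$fate == "Resistant"],
                   alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("invalid generator configurations fail loudly", {
  expect_error(generator_config(class_weights = c(lipids = 0.5)), "sum to 1")
  expect_error(generator_config(reaction_plan = c(pyrolysis = 3)),
               "unknown reaction")
  expect_error(
    generator_config(n_formulas = 10,
                     reaction_plan = c(dealkylation = -1)),
    "non-negative"
  )
  # plan larger than the Disappeared set
  cfg <- generator_config(n_formulas = 30, seed = 1,
                          reaction_plan = c(dealkylation = 30))
  expect_error(generate_sample_pair(config = cfg), "Disappeared")
  # nitrogen-requiring classes need N-bearing heteroatom weight
  expect_error(
    generator_config(class_weights = c("proteins/amino sugars" = 1),
                     heteroatom_weights = c(CHO = 1)),
    "nitrogen"
  )
})

test_that("de-novo products are flagged in the ground truth", {
  cfg <- generator_config(n_formulas = 200, seed = 9,
                          reaction_plan = c(dealkylation = 5),
                          n_denovo_products = 7)
  pair <- generate_sample_pair(config = cfg)
  tr <- pair$truth$fates
  expect_identical(sum(tr$reaction == "de-novo", na.rm = TRUE), 7L)
  expect_identical(sum(tr$fate == "Product"), 12L)
  expect_identical(nrow(pair$truth$edges), 5L)
})

test_that("incubation series follow the saturating and decaying forms", {
  s <- generate_incubation_series(times = c(0, 1, 2, 6, 200), noise_sd = 0)
  expect_identical(s$oh[1], 0)
  expect_equal(s$oh[5], 142.30, tolerance = 1e-9)
  expect_equal(s$oh, 5.87 * s$p_hba, tolerance = 1e-12)
  expect_equal(s$fe2_hcl[1], 3.13)
  expect_equal(s$fe2_hcl[5], 0.61, tolerance = 1e-6)
  expect_true(all(diff(s$oh) >= 0))
  # soil-mass normalization of the plateau
  expect_equal(
    to_soil_mass_basis(s$oh[5], attr(s, "volume_ml"), attr(s, "soil_g")),
    355.75, tolerance = 1e-6
  )
  expect_error(generate_incubation_series(k_oh = -1), "non-negative")
  expect_error(generate_incubation_series(times = c(0, 0, 1)),
               "strictly increasing")
  # noisy series stay non-negative and reproducible under a fixed seed
  n1 <- generate_incubation_series(noise_sd = 5, seed = 2)
  n2 <- generate_incubation_series(noise_sd = 5, seed = 2)
  expect_identical(n1, n2)
  expect_true(all(n1$oh >= 0) && all(n1$fe2_hcl >= 0))
})
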