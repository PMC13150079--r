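test_that("enumeration finds glucose at its deprotonated mass", {
  cand <- enumerate_candidates(179.056112, assignment_config())
  expect_true("C6H12O6" %in% cand$formula)
  # exact-mass input: glucose is the closest candidate
  expect_identical(cand$formula[1], "C6H12O6")
  # degenerate tolerance admits nothing at a perturbed mass
  none <- enumerate_candidates(179.0569,
                               assignment_config(tolerance_ppm = 0))
  expect_identical(nrow(none), 0L)
})

test_that("every candidate re-checks within tolerance (round trip)", {
  cfg <- assignment_config(tolerance_ppm = 3)
  for (mz in c(179.056112, 301.1, 455.21, 620.37)) {
    cand <- enumerate_candidates(mz, cfg)
    if (nrow(cand) == 0L) next
    mz_rt <- deprotonated_mz(monoisotopic_mass(cand[c("C", "H", "N", "O",
                                                      "S", "P")]))
    expect_true(all(abs(mz_rt - mz) / mz * 1e6 <= cfg$tolerance_ppm + 1e-9))
    expect_true(all(is_valid_formula(cand, cfg)))
  }
})

test_that("widening the tolerance never removes a candidate", {
  set.seed(42)
  for (mz in runif(6, 150, 700)) {
    narrow <- enumerate_candidates(mz, assignment_config(tolerance_ppm = 1))
    wide <- enumerate_candidates(mz, assignment_config(tolerance_ppm = 4))
    expect_true(all(narrow$formula %in% wide$formula))
  }
})

test_that("enumeration agrees with the exhaustive lattice oracle", {
  set.seed(7)
  mzs <- c(runif(10, 150, 800), deprotonated_mz(c("C15H18N2O8S",
                                                  "C20H24O13",
                                                  "C27H32O5")) + 1e-4)
  for (mz in mzs) {
    for (tol in c(1, 5)) {
      cand <- enumerate_candidates(mz, assignment_config(tolerance_ppm = tol))
      got <- sort(paste(cand$C, cand$H, cand$N, cand$O, cand$S, cand$P,
                        sep = "."))
      expect_identical(got, oracle_candidates(mz, tol))
    }
  }
})

test_that("assignment tie-breaking prefers parsimony then low mass", {
  tied <- data.frame(
    C = c(10L, 12L, 10L, 9L), H = c(12L, 14L, 13L, 10L),
    N = c(0L, 2L, 1L, 0L), O = c(5L, 2L, 4L, 6L), S = c(1L, 0L, 0L, 0L),
    P = c(0L, 0L, 0L, 0L),
    mass = c(240.05, 230.11, 211.08, 198.05),
    error_ppm = c(0.2, -0.2, 0.2, -0.2)
  )
  # equal |error|: fewest N+S+P wins (rows 3 and 4 tie at 1 vs 0 -> row 4)
  expect_identical(domfate:::pick_candidate(tied)$C, 9L)
  # among equal heteroatom counts, fewest N, then lowest mass
  tied2 <- tied[tied$N + tied$S == 1, ]
  expect_identical(domfate:::pick_candidate(tied2)$N, 0L)
})

test_that("unassignable peaks are reported with a reason, not an error", {
  peaks <- data.frame(mz = c(5.0, 179.056112), intensity = c(10, 20),
                      sn = c(8, 9))
  res <- assign_peaklist(peaks, assignment_config())
  expect_identical(nrow(res$assignments), 1L)
  expect_identical(res$unassigned$reason, "no candidate")
  expect_equal(sum(res$assignments$relative_abundance), 1, tolerance = 1e-9)
  expect_warning(
    assign_peaklist(data.frame(mz = 5, intensity = 1, sn = 5)),
    "no peak"
  )
})

test_that("true formulas are recovered perfectly without mass noise", {
  fx <- noiseless_pair(n = 400, seed = 0)
  a <- fx$before$assignments
  expect_identical(nrow(fx$before$unassigned), 0L)
  expect_true(all(a$formula == a$true_formula))
})
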