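fake_partition <- function(disappeared, product) {
  structure(list(disappeared = disappeared, product = product),
            class = "fate_partition")
}

test_that("exact elemental differences match library reactions", {
  p <- fake_partition(c("C10H12O7", "C10H12O5"),
                      c("C9H12O5", "C10H12O6"))
  m <- match_transformations(p)
  expect_identical(nrow(m), 2L)
  dec <- m[m$reaction == "decarboxylation", ]
  expect_identical(dec$reactant, "C10H12O7")
  expect_identical(dec$product, "C9H12O5")
  oxa <- m[m$reaction == "oxygen addition", ]
  expect_identical(oxa$reactant, "C10H12O5")
  expect_identical(oxa$product, "C10H12O6")
  expect_identical(unique(m$class_combo), "CHO-CHO")
})

test_that("summaries count pairs and class combinations exactly", {
  empty <- summarize_reactions(match_transformations(
    fake_partition(character(), character())
  ))
  expect_identical(empty$total, 0L)
  expect_identical(nrow(empty$by_reaction), 0L)

  p <- fake_partition(c("C10H12O5", "C12H16O6", "C14H20O7"),
                      c("C10H12O6", "C12H16O7", "C14H20O8"))
  m <- match_transformations(p)
  s <- summarize_reactions(m)
  expect_identical(s$total, nrow(m))
  expect_identical(
    s$by_reaction$n_pairs[s$by_reaction$reaction == "oxygen addition"], 3L)
  expect_identical(
    s$by_class_combo$n_pairs[s$by_class_combo$class_combo == "CHO-CHO"], 3L)
  # permuting the match list leaves the summary unchanged
  s2 <- summarize_reactions(m[rev(seq_len(nrow(m))), ])
  expect_identical(s$by_reaction, s2$by_reaction)
  expect_identical(s$by_class_combo, s2$by_class_combo)
})

test_that("reversing the samples maps reactions to negated deltas", {
  p <- fake_partition(c("C10H12O7", "C10H12O5"),
                      c("C9H12O5", "C10H12O6"))
  lib <- reaction_library()
  neg <- lib
  neg[c("dC", "dH", "dN", "dO", "dS", "dP")] <-
    -lib[c("dC", "dH", "dN", "dO", "dS", "dP")]
  rev_p <- fake_partition(p$product, p$disappeared)
  fwd <- match_transformations(p, lib)
  bwd <- match_transformations(rev_p, neg)
  expect_identical(nrow(bwd), nrow(fwd))
  key_fwd <- sort(paste(fwd$reactant, fwd$product, fwd$reaction))
  key_bwd <- sort(paste(bwd$product, bwd$reactant, bwd$reaction))
  expect_identical(key_bwd, key_fwd)
})

test_that("planted reaction edges are recalled completely without noise", {
  fx <- noiseless_pair(n = 400, seed = 0)
  m <- match_transformations(fx$partition)
  edges <- fx$pair$truth$edges
  got <- paste(m$reactant, m$product, m$reaction)
  want <- paste(edges$reactant, edges$product, edges$reaction)
  expect_true(all(want %in% got))
  # per-reaction counts are at least the planted counts; extras are the
  # expected incidental pairs and are visible in the summary
  s <- summarize_reactions(m)
  plan <- fx$config$reaction_plan
  for (rn in names(plan)) {
    expect_gte(s$by_reaction$n_pairs[s$by_reaction$reaction == rn],
               plan[[rn]])
  }
  expect_identical(s$total, nrow(m))
})

test_that("malformed reaction libraries are rejected", {
  lib <- reaction_library()
  lib$name[2] <- lib$name[1]
  expect_error(reaction_library(lib), "unique")
  lib2 <- reaction_library()
  lib2[1, c("dC", "dH", "dN", "dO", "dS", "dP")] <- 0L
  expect_error(reaction_library(lib2), "non-zero")
})
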