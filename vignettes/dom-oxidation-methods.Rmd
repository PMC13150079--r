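---
title: "Molecular fate analysis of DOM under hydroxyl-radical oxidation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular fate analysis of DOM under hydroxyl-radical oxidation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`domfate` analyses paired ultrahigh-resolution mass spectra of dissolved
organic matter (DOM) taken before and after an oxidative treatment — the
setting in which anaerobically accumulated Fe(II) reacts with oxygen to
generate hydroxyl radicals that selectively transform the DOM pool. This
vignette is the package's account of its models: what is computed, under
which assumptions, which knobs matter, and what the synthetic-data tests do
and do not demonstrate.

## Formula assignment

Negative-mode FT-ICR spectra of DOM are acquired as singly charged
deprotonated ions, so a peak at observed m/z implies a neutral monoisotopic
mass of `mz + m(H) − m(e)`. `enumerate_candidates()` searches the full
element lattice for neutral formulas whose deprotonated ion falls within a
ppm tolerance of the observation. The search solves for the hydrogen count
along each (C, N, O, S, P) combination rather than looping over it: within
any tolerance much smaller than half a hydrogen mass, at most a handful of
H values can reconcile the residual, which reduces the lattice from millions
of points to tens of thousands. The test suite checks this optimised path
against a literal brute-force lattice scan (set equality over random m/z).

Candidates must pass chemical plausibility filters standard for natural
DOM: element ranges C 1–60, H 1–120, N 0–5, O 0–30, S 0–2, P 0;
0.3 ≤ H/C ≤ 2.25; O/C ≤ 1.2; N/C ≤ 0.5; S/C ≤ 0.2; and an integer DBE in
0–40, which simultaneously enforces electron parity for an even-electron
[M−H]⁻ ion. All of these are configurable through `assignment_config()` so
that laboratory-specific settings can be substituted. When several
candidates survive, `assign_peaklist()` takes the smallest |mass error|,
breaking exact ties by fewest heteroatoms (N+S+P), fewest N, then lowest
mass — parsimony heuristics; unassignable peaks are reported with a reason
rather than discarded silently.

**Known limitation.** Exact mass alone cannot resolve every CHNOS doublet.
The lattice contains parity-valid composite substitutions — the smallest is
twice (+7C −2H +N −8O +S), a net +14C −4H +2N −16O +2S at ≈ 0.26 mDa — that
bring a second valid formula within ~0.3–0.6 ppm of oxygen-rich formulas
(O ≥ 11). With Gaussian 0.2 ppm mass noise such a neighbour is occasionally
the closer candidate, which bounds single-peak recovery at roughly 97% on
the default synthetic pool; on noiseless data recovery is exactly 100%.
Real pipelines break these ties with ¹³C isotopologue checks, which operate
on isotopic fine structure that monoisotopic peak lists do not carry; the
package deliberately leaves this out of scope and reports the ambiguity
rather than hiding it.

## Descriptors and classification

`compute_descriptors()` evaluates, per formula: atomic ratios; double-bond
equivalents `DBE = 1 + C − H/2 + (N+P)/2`; the nominal oxidation state of
carbon `NOSC = 4 − (4C + H − 3N − 2O + 5P − 2S)/C`, which runs from −4
(methane) to +4 (CO₂) and increases by exactly 2/C per added oxygen; and
the modified aromaticity index
`AImod = (1 + C − 0.5·O − S − 0.5·H) / (C − 0.5·O − S − N − P)`, set to 0
when the denominator is non-positive or the ratio negative (the standard
non-aromatic convention).

Compound classes are rectangles in (O/C, H/C) space, half-open on both
axes, validated for non-overlap at load: lipids, proteins/amino sugars
(requires N ≥ 1), carbohydrates, unsaturated hydrocarbons,
lignin/CRAM-like, tannins, condensed aromatics; points outside every
rectangle are "other". These are the common literature boundaries; exact
boundaries differ between laboratories, so the table is a plain data frame
argument. Redox quadrants combine NOSC (oxidized ⇔ NOSC > 0, strictly) with
saturation ((DBE−O)/C < 0.3, strictly). NOSC = 0 is the natural oxidation
midpoint; 0.3 on (DBE−O)/C separates aliphatic-dominated from
unsaturated/aromatic-dominated compositions. Both cuts are arguments.

## Fate partition and PMD matching

Molecular identity across samples is the neutral formula, not the observed
m/z: after assignment, set algebra on formulas partitions Before ∪ After
into Disappeared / Resistant / Product, and the three counts always sum to
the union size. Common formulas are labelled enriched/depleted/stable by
log₂ ratio of relative abundances against a fold-change threshold (default
2, configurable); relative abundances make the labels invariant to uniform
intensity rescaling.

Paired-mass-distance matching explains Disappeared→Product pairs by exact
elemental difference against a reaction library (delta = product −
reactant). Because formulas are already assigned, matching uses integer
element deltas, not mass windows — more specific and tolerance-free. A
formula may participate in several pairs; summaries therefore report both
all-pairs counts and unique-reactant counts per reaction. The default
library (dealkylation, decarboxylation, oxygen addition, (de)hydrogenation,
(de)hydration, deamination, sulfonation, desulfurization) is a data frame
the user can replace.

## Susceptibility modelling

`build_feature_matrix()` assembles one row per unique formula with features
m/z, O/C, H/C, N/C, S/C, DBE, (DBE−O)/C, NOSC, AImod and one indicator per
heteroatom class, labelled by fate. `train_and_evaluate()` runs stratified
k-fold cross-validation (default 5 folds) of a gradient-boosted tree
ensemble (`xgboost`, exact greedy splits, depth 5, learning rate 0.1, 200
rounds, single thread — deterministic for a fixed seed) with balanced
instance weights so that each class contributes equal total weight. A
random-forest backend (`ranger`) is available as a plug-in.

Two accuracy notions are reported. *Overall* accuracy is the fraction of
correct CV predictions. *Balanced* accuracy (mean per-class recall) is the
chance-calibrated statistic under class weighting: for any classifier whose
predictions are independent of the labels its expectation is exactly
1/(number of classes), whatever the class imbalance. The shuffled-label
null checks therefore assert balanced accuracy ≈ 1/3; overall accuracy
under a permuted-label null approaches 1/3 only for balanced designs, which
the test suite exercises separately.

Attribution uses exact additive tree (SHAP) contributions from the boosted
model — per prediction and class they sum to the margin deviation from the
model bias, which the tests verify to 1e−6 — summarized as mean absolute
attribution per feature and class. Backends without an exact tree method
fall back to permutation importance with a warning, never silently; a
constant feature scores exactly zero there.

One caveat the package makes explicit: several descriptors are
deterministic functions of others (NOSC is algebraically
−H/C + 3·N/C + 2·O/C + 2·S/C). When a generative process drives fate
through a subset of descriptors, algebraically entangled descriptors
legitimately absorb some attribution. In the validation experiments the
four generative drivers still out-rank all passive features once
attributions are averaged over five generator/model seeds, but users should
expect correlated descriptors to share credit on real data.

## The synthetic-data generator

The generator exists so that every downstream module can be tested against
a planted truth. It emulates:

* a formula pool drawn from the Van Krevelen class mixture (dominated by
  lignin/CRAM-like material at weight 0.45, with tannins and
  proteins/amino sugars at 0.12 each, lipids and condensed aromatics at
  0.08, carbohydrates, unsaturated hydrocarbons and "other" making up the
  rest) crossed with heteroatom classes CHO 0.40 / CHON 0.40 / CHOS 0.06 /
  CHONS 0.14 — sulfur-bearing CHOS formulas are a ~6% minority, as in
  natural DOM. Because the protein rectangle requires nitrogen, heteroatom
  draws are conditioned on the class and the complementary conditional
  weights are solved in closed form so that **both** marginals are
  preserved; infeasible weight combinations fail at configuration time
  naming the class. The "other" label is sampled from the three regions no
  class rectangle claims (the saturated band above H/C 2.2, the protein
  rectangle without nitrogen, the O-rich low-H/C corner), area-weighted.
  Every generated formula passes the assignment validity filters, lies in
  the 150–800 Th working range (carbon counts 8–36), and is unique.
* log-normal peak intensities (sdlog 1.0) normalised downstream to relative
  abundances — FT-ICR DOM intensities are heavy-tailed, and all analyses
  are on relative abundance. The true intensity distribution of such
  spectra is not established; log-normal is a stand-in, not an instrument
  claim.
* Gaussian m/z noise of 0.2 ppm (1 s.d.), the mass accuracy of a modern
  high-field instrument; configurable.
* fates from a logistic disappearance model on pool-standardized N/C, m/z,
  S/C and O/C with default coefficients +3.0, −2.5, +2.0, +1.5 (intercept
  0): nitrogen-rich, lighter, sulfur-bearing and oxygen-rich molecules are
  preferentially removed, mirroring the reactivity pattern of
  radical-driven DOM oxidation; the magnitude order follows the importance
  order of those descriptors in fate modelling. This plants exactly the
  structure the ML stage must recover.
* planted one-step reactions (default 30 dealkylation, 20 decarboxylation,
  10 oxygen addition) from Disappeared reactants to fresh Product formulas
  satisfying the exact elemental delta, each validity-checked; optional
  "de-novo" products not linked to any reactant are flagged as such in the
  ground truth.
* incubation kinetics: •OH(t) = plateau·(1 − e^(−k·t)) with default plateau
  142.30 µM and k = 1.8 h⁻¹ (≈ 97% of plateau within 2 h, matching the
  observation that accumulation stabilises after the first two hours);
  Fe(II)(t) decaying from 3.13 to 0.61 mg/g at k′ = 1.5 h⁻¹; the p-HBA
  probe channel is •OH/5.87 identically.

A single integer seed fixes every draw; stage sub-seeds are derived
deterministically (the sample-pair stage uses seed + 1 so that pool and
pair draws are independent but jointly reproducible). Identical
configuration and seed give byte-identical output.

**What passing tests show — and what they do not.** The synthetic pool has
independent class/heteroatom draws, rectangular class occupancy, and
exactly one-step reaction connectivity. Real DOM has correlated descriptor
structure (mass–class coupling, homologous series), multi-step
transformation cascades, isotopologues and adduct peaks. Recovery and
accuracy figures on synthetic data therefore validate the *machinery*
(set logic, exact deltas, learnable planted structure), not instrument-level
performance on field samples.

## Radical chemistry arithmetic

The benzoic-acid probe quantifies •OH through its hydroxylation product
p-HBA; the conversion •OH = 5.87 × p-HBA is an apparent accumulated
concentration under competition kinetics (not a steady state) and is kept
as a single named constant. Suspension concentrations (µM) convert to a
soil basis as conc × volume/mass (µmol/kg); •OH–Fe(II) relations use
ordinary least squares with intercept (R² computed from residual sums, so
perfect fits are exact); scavenger contributions and contaminant removal
are plain percent decreases with guardrails (positive controls, warnings
when a scavenged value exceeds its control). All are homogeneous of degree
one in their concentration argument, which the property tests exercise.

## Validation scales

The test suite validates at sizes chosen to exercise every code path while
staying desk-sized: oracle equivalence over 100 random m/z against a
~4-million-point lattice; recovery and fate/PMD audits on pools of
400–2000 formulas; classification at 3000 formulas with 5-fold CV; the
attribution ranking averaged over five seeds at 1500 formulas. At those
sizes the pipeline recovers planted fates exactly (noiseless), recalls
100% of planted reaction edges, classifies fate at ≈ 79% cross-validated
accuracy against a ≈ 1/3 chance level, and ranks the four generative
descriptors above all passive ones.
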