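# domfate

Molecular-level analysis of dissolved organic matter (DOM) transformation in
redox-fluctuating soils, as probed by ultrahigh-resolution (FT-ICR) mass
spectrometry. When an anaerobically incubated paddy-soil suspension is
exposed to oxygen, surface-bound Fe(II) reduces O₂ to H₂O₂ and then to
hydroxyl radicals (•OH), which selectively oxidize the DOM pool. `domfate`
implements the complete desk-side analysis chain for such paired
before/after oxygenation experiments:

* **Formula assignment** — constrained exact-mass enumeration of neutral
  CHNOS(P) formulas for negative-mode ([M−H]⁻) centroided peak lists, with
  configurable element ranges, elemental-ratio plausibility bounds
  (0.3 ≤ H/C ≤ 2.25, O/C ≤ 1.2, N/C ≤ 0.5, S/C ≤ 0.2), integer-DBE
  filtering and parsimony tie-breaking.
* **Molecular descriptors** — atomic ratios, double-bond equivalents
  DBE = 1 + C − H/2 + (N+P)/2, nominal oxidation state of carbon
  NOSC = 4 − (4C + H − 3N − 2O + 5P − 2S)/C, the modified aromaticity index
  AImod, Van Krevelen compound classes (lipids … condensed aromatics) and
  redox quadrants in (DBE−O)/C–NOSC space.
* **Fate partitioning** — every formula in a paired experiment is classified
  *Disappeared* (before only), *Resistant* (both) or *Product* (after only),
  and common formulas are scored enriched/depleted/stable by log₂ relative
  abundance ratio.
* **Paired-mass-distance (PMD) matching** — Disappeared→Product pairs are
  explained by exact elemental differences against a configurable one-step
  reaction library (dealkylation −CH₂, decarboxylation −CO₂, oxygen addition
  +O, …) and summarized by reaction type and heteroatom-class combination
  (CHO–CHO, CHON–CHON, …).
* **Susceptibility modelling** — gradient-boosted trees (xgboost) predict
  molecular fate from the descriptor block under stratified cross-validation
  with balanced class weights, and exact additive tree (SHAP) attributions
  rank the descriptors that drive reactivity.
* **Radical chemistry arithmetic** — the benzoic-acid probe conversion
  (•OH = 5.87 × p-HBA), suspension-to-soil-mass normalization, •OH–Fe(II)
  regressions, scavenger contributions and contaminant removal rates.
* **Synthetic data** — a generator that emulates the statistical structure
  of such experiments (Van Krevelen class mixture, log-normal intensities,
  ppm mass noise, planted reaction edges, a logistic descriptor-dependent
  disappearance model, saturating •OH / decaying Fe(II) kinetics) with
  planted ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(domfate)

cfg   <- generator_config(n_formulas = 1000, seed = 1)
pair  <- generate_sample_pair(config = cfg)              # planted truth
before <- compute_descriptors(assign_peaklist(pair$before)$assignments)
after  <- compute_descriptors(assign_peaklist(pair$after)$assignments)

part <- abundance_variation(classify_fate(before, after))
part
#> Molecular fate partition:
#>      n_before       n_after      n_common n_disappeared   n_resistant
#>          1000           636           550           450           550
#>     n_product    n_enriched    n_depleted      n_stable
#>            86           243           121           186

summarize_reactions(match_transformations(part))
#> Reaction summary: 66 matched pairs
#>         reaction n_pairs n_unique_reactants
#>     dealkylation      31                 31
#>  decarboxylation      19                 19
#>  oxygen addition      11                 11
#>      dehydration       2                  2
#>        hydration       2                  2
#>      deamination       1                  1

fit <- train_and_evaluate(build_feature_matrix(before, after, part),
                          folds = 5, seed = 1)
fit
#> 5-fold CV accuracy (gbt backend): 0.730 (balanced 0.553)
feature_attribution(fit)
#> Feature attribution (shap), mean |attribution|:
#>    n_c     mz    s_c    o_c   nosc    h_c  ...
#> 0.7060 0.6234 0.3671 0.3128 0.2861 0.2180 ...
```

The partition recovers the planted fates, the reaction summary contains the
planted 30/20/10 dealkylation/decarboxylation/oxygen-addition edges (plus a
few incidental pairs; one planted decarboxylation edge is lost here to a
0.2 ppm mass-noise misassignment), and the attribution ranking recovers the
four descriptors the generator's disappearance model actually uses (N/C,
m/z, S/C, O/C) ahead of all passive descriptors. At the validation scale
(n = 3000 formulas) the cross-validated accuracy is ≈ 79%.

Probe arithmetic works on plain numbers:

```r
phba_to_oh(24.24)                                  # 142.2888 uM  •OH
to_soil_mass_basis(142.30, volume_ml = 50, soil_g = 20)  # 355.75 umol/kg
```

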