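# moltevol

Phylogenetic comparative tools for reconstructing the evolution of wing
flight-feather molt strategy in first-year birds — and, more generally,
for any 3-state life-history character on a time-calibrated phylogeny.

Most birds replace all, some, or none of their wing flight feathers
during their first year of life ("complete", "partial", "absent" molt).
Whether complete first-year molt is ancestral or derived in modern birds
(Neornithes), and how body mass and latitudinal distribution shaped its
evolution, are comparative questions that require explicit phylogenetic
models. This package implements the full analysis chain:

- **Mk models** — maximum-likelihood fitting of k-state continuous-time
  Markov models of discrete character evolution via the pruning
  algorithm, in the equal-rates (ER), symmetric (SYM) and
  all-rates-different (ARD) parameterizations, with small-sample AICc
  selection (a model is preferred only when its AICc advantage exceeds
  2.0).
- **Marginal ancestral state reconstruction** — exact empirical-Bayes
  posteriors P(state | data) at every node by a single up-down sweep,
  identical to re-rooting at every node but O(n).
- **Brownian-motion reconstruction** of a continuous trait (body mass):
  GLS root estimate `μ̂ = (1'V⁻¹1)⁻¹1'V⁻¹x` and ML rate
  `σ̂² = (x−μ̂1)'V⁻¹(x−μ̂1)/n` computed by a linear-time contrast
  recursion, plus per-node conditional estimates by Gaussian message
  passing.
- **Phylogenetic logistic regression** (two-state Markov switching
  model): a binary strategy with tip mean `logit⁻¹(xᵢ'β)` and residual
  correlation `exp(−α d_ij)` decaying with patristic distance;
  estimation by iterated quasi-Fisher scoring with a profiled switching
  rate α, Wald statistics per coefficient, and a small-sample
  efficient-score test per slope.
- **Family-level robustness analysis** — assign each family the argmax
  posterior state at its MRCA, build one-tip-per-family trees, and
  compare reconstructions across alternative backbone topologies.
- **Seeded simulators** for birth-death trees and for every trait model
  above, including a study-like generator (1,808 species, 146 families,
  27 orders, strategy counts 532/217/1,059) so the entire pipeline is
  testable without downloading any tree.

Trees are ape `"phylo"` objects; branch lengths are interpreted as
millions of years.

## Worked example

```r
library(moltevol)

ds <- make_study_like_dataset(seed = 1)       # tree + trait table
res <- run_full_analysis(ds$tree, ds$table,
                         output_dir = "results/bundle", seed = 1)
print(res)
```

```
Molt-strategy analysis: 1808 species (1591 in regression subset)
Mk model selection: ARD (decisive, threshold 2.00)
 model k_free      logL     aicc delta_aicc
   ARD      6 -1583.451 3178.949      0.000
   SYM      3 -1663.689 3333.392    154.442
    ER      1 -1693.459 3388.920    209.971
root posterior:
  absent  partial complete 
  0.3373   0.3411   0.3216 
BM mass: root 226.7, sigma2 5.859e+04
        parameter    alpha     estimate           se          z            p
      body_mass_g 923.4971 -0.004971164 0.0006133074  -8.105501 5.252864e-16
 mid_latitude_deg 238.0216 -0.052331559 0.0044457021 -11.771270 5.489196e-32
```

Reading this output: the all-rates-different model wins the AICc
comparison decisively (ΔAICc 154 over SYM); the root posterior is the
probability vector over (absent, partial, complete) molt at the root of
this synthetic tree; the regression rows show that heavier species
(negative mass slope, logit units per gram) and higher-latitude species
(negative latitude slope, per degree) are less likely to show complete
first-year molt — the direction built into the generator, mirroring the
empirical pattern. The bundle directory
additionally receives the node-posterior CSV, an annotated Newick with
per-node posteriors, the BM node estimates, descriptive summaries,
order-level regressions, and a run manifest; reruns with the same seed
are byte-identical.

To analyze real data instead, pass a Newick tree and a CSV with columns
`species, order, family, molt_strategy, body_mass_g, mid_latitude_deg,
bdpr_flag` (see `?load_species_table`); `inst/exec/molt-pipeline.R` is
a thin command-line wrapper (`simulate`, `run-all`, `family-compare`).

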