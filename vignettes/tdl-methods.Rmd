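---
title: "Transcriptomics-driven lipidomics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomics-driven lipidomics: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdl)
```

## The problem

Untargeted lipidomics cannot measure everything: on the order of 10^5 lipid
species are known, and any one platform annotates a few hundred. The usual way
out — measuring the lipids legacy knowledge says should matter — is biased
toward what is already known. `tdl` implements the alternative this package is
built around: let condition-specific transcriptomics *predict* which lipids are
worth measuring, then score the predictions against what was actually measured.

A two-group comparison (for instance germ-free mice versus mice monocolonized
with a bacterial strain) yields differentially expressed (DE) genes. Three
independent branches translate that gene list into candidate lipids:

* **Lipid-gene database branch (L).** A table of genes annotated to lipid
  classes or specific species, in the style of the LIPID MAPS Proteome
  Database. DE genes found in the table predict their annotated lipids.
* **Pathway database branch (R).** A Reactome-style per-gene pathway table,
  restricted to pathways relevant to lipid metabolism. DE genes in a
  lipid-relevant pathway predict the pathway's lipid class.
* **Metabolic model branch (G).** A genome-scale metabolic model (GEM). DE
  genes present in the model's gene universe are propagated through the binary
  gene–reaction incidence to the impacted reactions, and through the
  stoichiometric matrix to the participating metabolites. An elemental
  composition gate (at least C4, H8, O2) keeps lipid-like metabolites;
  compartment duplicates are collapsed; an optional stop-list removes
  cofactors (ATP, NADP, ...) that pass the gate on raw composition.

The branch predictions are merged into a **consensus predicted lipidome**
(deduplicated entities with a per-branch support mask), extended with
**negative-control classes** — classes no branch predicted, measured to test
specificity — and shipped as the measurement panel.

## Evaluation model

Each measured species is tested for a group difference with the two-sample
Kolmogorov–Smirnov test; Benjamini–Hochberg adjustment runs across all tested
species in the table (not per class — the correction scope is a package
choice, since "FDR correction" alone does not fix one). A species is
significant at q < 0.05. A class shows *observed change* when at least one
member species is significant or is detected in only one group
(differential by presence). This "at least one" rule is deliberate: a class
where 1 of 12 species responds counts as a correctly predicted change, which
matches how partial-class signals behave in real intestinal lipidomes.

Each class is then scored on a six-category grid of branch support versus
observation:

| support | observed | category |
|--------:|:--------:|---------:|
| 3       | yes      | 1 |
| 1–2     | yes      | 2 |
| 0       | no       | 3 |
| 1–2     | no       | 4 |
| 3       | no       | 5 |
| 0       | yes      | 6 |

The grid is total: every (support, observed) cell maps to exactly one
category. The published verbal description of the last two categories is
ambiguous (two near-identical sentences with different examples); the grid
above is the consistent resolution this package adopts — category 5 is a
unanimous prediction that failed, category 6 an unpredicted change.

### Kolmogorov–Smirnov details

D is the supremum of the ECDF difference evaluated at every pooled observed
value, so ties are handled exactly. The p-value is the exact conditional
probability over all label assignments of the pooled sample whenever
`length(a) * length(b) <= 10000` (computed by the exact Smirnov distribution
with the pooled data supplied, which is identical to full enumeration — the
test suite verifies this against literal enumeration for n_a + n_b ≤ 12), and
the asymptotic Kolmogorov tail otherwise. With n = 8 versus 7 samples the
smallest achievable exact p is about 1.5e-4, so single species can survive BH
across a few hundred species — but with 3 versus 3 samples no species can
reach q < 0.05 at all. Group sizes below ~5 make the whole evaluation
insensitive by construction; the package does not warn about this, it is
inherent to the test.

### Absence handling

Measured tables keep "absent" (`NA`) distinct from zero. Three rules apply:

* absent in *every* sample → the species is dropped with a warning;
* absent in one entire group → not testable by KS; flagged
  `differential_by_presence` and counted as observed change;
* absent in *some* samples of a group → the absence value (0.0001, the
  conventional substitution for ratio computation) is substituted per sample
  before testing, so partial presence contributes signal. Substituting before
  the KS test (rather than only for plotting ratios) is a package decision:
  the alternative — dropping absent samples — silently reduces n and biases D.

`log_ratio()` applies the same substitution to group means for plotting
(log10 scale; a species present at 1.0 in one group and absent in the other
plots at ±4).

## Differential expression model

The default per-gene test is classical one-way ANOVA, which for two groups is
exactly the squared pooled-variance t test (the equivalence is verified
numerically in the tests). Welch's t and KS are available alternatives.
Fold change is a *signed linear ratio of group means on the natural scale*:
log-scale values are unlogged per sample (default base 2), group means are
taken, and ratios below 1 are reported as −1/ratio so gates read symmetrically
(">1.5 or <−1.5"). The published analysis does not define its fold-change
algebra; this convention reproduces its volcano-plot description. The DE
gates are q < 0.05 (BH) and |FC| > 1.5.

Degenerate genes (zero within-group variance in both groups) get p = 1 when
means are equal and p = 0 otherwise, by convention.

## Metabolic model handling

Gene identifiers are matched case-insensitively (uppercased, trimmed):
microarray symbols like *Acsl6* must meet model symbols like *ACSL6*, and no
common identifier scheme can be assumed. Boolean gene–protein–reaction rules
are flattened to plain gene sets — propagation only needs the binary
incidence, not rule evaluation, so AND/OR structure is discarded on read.
Substrates and products are both "impacted" (unsigned stoichiometry): a
perturbed reaction can move the levels of everything it touches, in either
direction, and the method predicts *what to measure*, not the direction of
change.

The composition gate applies only to C, H and O counts. Other elements never
disqualify a metabolite: a reading of the cutoff under which nitrogen- and
phosphorus-bearing phospholipids — plainly intended targets — stay in scope.
Metabolites whose formula is missing or contains generic acyl-residue markers
(R, X, *) cannot be gated on composition; they are retained, flagged
`unfiltered`, and treated as class-level predictions (pools), resolved through
the class vocabulary. Pool names that resolve to no vocabulary class are
dropped from the prediction rather than invented.

Two model dialects are read: SBML Level 3 with the FBC package (species,
compartments, chemical formulas, flattened gene-product associations), and a
four-file tabular dialect (`genes.tsv`, `metabolites.tsv`, `reactions.tsv`,
`stoich.tsv`) that also serves as the lossless round-trip format. Metabolite
ids follow the `name[compartment]` convention.

## What the synthetic generators emulate

All generators are seeded and bit-reproducible, and every generated dataset
carries its ground truth.

* `gen_expression()`: Gaussian log2 expression (baselines uniform on 6–12,
  within-group SD 0.5 by default — typical microarray-like dispersion), two
  groups of 8 (matching the in vivo design scale of 8 versus 7), planted genes
  shifted by a chosen log2 effect in group B. The default planted effect in
  the linked study is 4 log2 units with SD 0.5 — a strong, unambiguous signal
  chosen so that recovery failures indicate pipeline defects, not test noise.
* `gen_lipidome()`: log-normal intensities (SD 0.25 on log10 scale); in each
  planted class a fraction (default 0.4) of species is shifted by 4 pooled
  SDs, mimicking partial-class signals (real classes respond with a handful
  of species, e.g. 5 of 18); optional group-exclusive species exercise the
  presence/absence logic.
* `gen_toy_gem()`: random bipartite incidences with formulas drawn from
  lipid-like, small-molecule and generic pools so the composition gate sees
  passes, failures and unfilterables; base names recur across compartments so
  deduplication is exercised.
* `gen_tdl_study()`: one causal story wiring all of the above together —
  planted classes, two causal genes each, present in all three annotation
  sources, decoy DE genes with no lipid links, inert background genes and
  annotation noise, and negative controls drawn from non-planted classes.

What the generators do **not** emulate: probe-level microarray noise and
normalization artifacts, mass-spectral annotation ambiguity, correlated
species within a class, heavy-tailed intensity distributions, and incomplete
or wrong database annotations (the synthetic annotations are perfectly
consistent with the causal truth). Passing the recovery tests therefore shows
the pipeline machinery is correct, not that real databases and models are
complete enough for any particular tissue — the published application itself
found classes (PE) where model resolution was too coarse.

## Numerical and degenerate-input choices

* BH adjustment is the standard step-up; empty input returns empty output.
* `venn_counts()` computes all seven regions from set memberships, so
  inclusion–exclusion holds by construction; derived counts (union,
  exactly-one, exactly-two, per-branch unique) are recomputed from the same
  memberships, never from the identity.
* Merging branches is order-invariant; entities are deduplicated by
  (level, name). A species-level prediction marks its class as
  *implied* support, kept separate from direct class predictions; class
  evaluation defaults to strict (direct only) because counting implications
  double-counts a single gene's evidence — permissive mode is available where
  the model predicts only species.
* A negative-control class with any branch support (direct or implied) is an
  error, not a silent drop.
* Pipeline inputs are order-normalized (sorted by gene/species) before
  processing, so row order never changes any output; reruns on identical
  inputs are byte-identical.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
null calibration on 2000 genes (8 per group), planted-recovery on 1000 genes
with 25 planted, lipid recovery on 6 classes × 8 species over 10 replicates,
and 20 linked end-to-end replicates (10 classes, 4 planted, ~210 genes).
These sizes give stable recovery statistics in seconds while exercising every
stage at realistic group sizes.

## Known limitations

* Transcript abundance is a proxy for enzyme activity; the method inherits
  that gap and predicts *candidates*, not effect directions or magnitudes.
* Class resolution depends on the model's granularity: a model that carries
  only a generic PE pool cannot support species-level PE predictions.
* The KS test needs ≥ ~5 samples per group to be able to reject at q < 0.05.
* The SBML reader covers Level 3 + FBC documents of the usual
  constraint-based-model shape; exotic SBML constructs (species references by
  id-less rules, initial assignments) are out of scope.
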