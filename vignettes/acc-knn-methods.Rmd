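---
title: "Alignment-free allergen prediction: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free allergen prediction: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allerknn)
```

## The model

`allerknn` treats allergenicity as a property of a protein's
physicochemical profile rather than of its literal sequence. Each residue
is mapped to the three Hellberg z-scales — principal-component summaries
of 29 measured amino-acid properties, dominated by hydrophobicity (z1),
molecular size (z2) and polarity (z3) — giving an n × 3 descriptor matrix
Z for a protein of n residues. The auto-/cross-covariance (ACC)
transformation of Wold and colleagues then collapses this variable-length
matrix into a fixed-length vector of lagged covariances:

$$A_{jj}(l) = \sum_{i=1}^{n-l} \frac{Z_{j,i}\,Z_{j,i+l}}{n-l},\qquad
  C_{jk}(l) = \sum_{i=1}^{n-l} \frac{Z_{j,i}\,Z_{k,i+l}}{n-l}\ (j \neq k)$$

for descriptor indices $j,k \in \{1,2,3\}$ and lags $l = 1..L$. The
products pair each position with the position $l$ steps downstream, so
the terms measure how strongly a property at one site co-varies with a
property a short distance along the chain — local neighbour effects that
position-independent composition statistics miss. Both orders of each
cross pair are kept ($C_{12} \neq C_{21}$ in general) because the
sequence is directional; with $L = 5$ this gives
$(3 + 6) \times 5 = 3^2 \times 5 = 45$ features per protein.

Classification is deliberately simple: a memory-based k-nearest-neighbour
rule over the 45-dimensional feature space. The score of a query is the
fraction of its $k$ nearest training vectors labelled allergen; a score
at or above the decision threshold yields the verdict
"Probable Allergen". Because the neighbours themselves are reported, a
prediction is directly inspectable — and the route tags of the allergen
neighbours supply a most-probable route of exposure (food, inhalant or
toxin) for predicted allergens.

Assumptions worth keeping in mind: the z-scales treat every occurrence of
a residue identically (no context-dependent conformation), the ACC terms
capture only pairwise, short-range (≤ L positions) interactions, and the
kNN rule assumes the training set densely samples the relevant sequence
space. None of these hold perfectly for real proteomes; they are the
price of an alignment-free, assumption-light method.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `L` (maximum lag) | 5 | positions | short lags restrict the covariances to close residue proximity; 9·L = 45 features |
| `k` (neighbours) | 3 | instances | the small odd neighbourhood that performs best in k-scans on this feature space; odd k forces a strict majority |
| `threshold` | 0.5 | score fraction | simple majority at k = 3; exposed so ROC curves can be traced |
| `distance` | euclidean | — | the standard metric for ACC/QSAR descriptor spaces; `manhattan` available to make the choice explicit |
| `scale` | off | — | raw ACC values are already on a common scale (descriptor products); optional z-score standardisation is fitted on training folds only |
| residue mode | strict | — | non-standard residues are errors by default; permissive mode substitutes B/Z/J by the mean of their pair and X/U/O by the 20-residue mean, with a warning |

The minimum sequence length is $L + 1 = 6$ residues — the mathematical
floor at which every lag has at least one summand.

The k-scan (`k_scan()`) is restricted to odd k. At threshold 0.5 an even
k admits 2–2 ties in which the "≥" rule silently favours the allergen
class; restricting to odd k removes that asymmetry, and the scan over
k ∈ {1, 3, 5, 7, 9} uses identical folds for every k so comparisons are
paired.

## What the synthetic generator emulates — and what it does not

No curated allergen compilation is bundled; every stage of the pipeline
is instead exercised on synthetic data with a *planted*, recoverable
class structure. `synthetic_spec()` draws sequences with i.i.d. residues:
non-allergens from the average composition of natural proteins, allergens
from that background with the aliphatic/aromatic hydrophobics I, L, V, F
enriched 2.5-fold (renormalised). The enrichment axis mirrors the
documented surface-hydrophobicity signature of allergenic proteins and
moves the class mean of the z1 auto-covariances; the factor was fixed
once, at the value that places 5-fold cross-validated performance in the
low-to-mid 90% sensitivity/specificity regime reported for ACC–kNN
allergen models on real data, and is not tuned thereafter. Route tags
follow the rough proportions of curated collections (29% food,
48% inhalant, 23% toxin) with an 8% chance of a second route, so
multi-route allergens exist. Default problem sizes — 300 sequences per
class of length 50–300 for the main recovery check, 150 per route for the
cross-comparative design — are large enough for stable fold metrics while
keeping a full test run fast on a laptop.

For the cross-comparative analysis, `synthetic_route_sets()` plants
*route-specific* biases: food = I/L/V/F, inhalant = K/R/H, toxin = C/K/R.
Food and inhalant biases are disjoint, emulating the clinical observation
that food allergens rarely cause respiratory reactions and vice versa, so
a model trained on one route should transfer poorly to the other; the
toxin bias shares K/R with the inhalant bias (and adds the cysteine
richness typical of venom toxins), emulating the strong inhalant–toxin
overlap in curated sets. The evaluation harness must recover exactly this
pattern: off-diagonal sensitivity collapses between disjoint routes and
survives between overlapping ones.

What the generator does **not** emulate: domain architecture, repeats,
conserved motifs, phylogenetic correlation between sequences, length–class
dependence, and label noise. Sequences are i.i.d. draws, so class
information lives entirely in composition — which ACC features capture
through their lag-independent component. Passing the recovery tests
therefore demonstrates that the pipeline is correctly wired and that the
feature space separates composition-biased classes; it does not
demonstrate field performance on real allergens, which is a property of
real training data, not of this code.

## Evaluation choices

- **Specificity** is computed as TN/(TN + FP), the true-negative rate.
  (Some descriptions of this metric misprint it as FP/(TN + FP), which is
  the false-positive rate; the implemented form is the one consistent
  with "high specificity = few false positives".)
- **AUC** uses the Mann–Whitney rank formulation with half-credit for
  ties. kNN scores are coarse — multiples of 1/k — so tie handling is not
  a corner case but the common case, and the rank form makes the tie
  convention explicit. Tests pin it to an $O(n^2)$ pair-count oracle.
- **Aggregation over folds** is pooled confusion counts (micro average),
  with the mean of per-fold metrics (macro) reported alongside; for
  stratified folds of near-equal size the two differ little, but the
  pooled form is the primary number.
- **Undefined metrics** (single-class fold, empty prediction column) are
  reported as `NA` with a warning, never silently as 0.

## Numerical and degenerate-input choices

- Distance ties are broken by training-set insertion order via a stable
  sort key `(distance, index)`, making predictions — including the
  reported neighbour order — exactly reproducible.
- Route-count ties are broken by the route of the nearest allergen
  neighbour carrying a tied route, then by the fixed order
  food < inhalant < toxin.
- Zero-variance features under standardisation are excluded with a
  warning rather than producing division by zero.
- The homopolymer identities $A_{jj}(l) = z_j^2$, $C_{jk}(l) = z_j z_k$
  hold to machine rounding (the implementation averages $n-l$ identical
  products, so the last bit may differ from the single product).
- Model files are JSON with doubles written at 17 significant digits, so
  a save/load round trip reproduces the stored vectors exactly and
  re-training on identical input yields a byte-identical file.

## Mirror-set construction

Negative sets mirror the allergen set: for each allergen one same-species
protein with no detectable similarity to *any* allergen, relaxing to the
genus and finally to a designated fallback pool (standing in for a random
background proteome). The default similarity screen is an exact shared
k-mer test with k = 8, motivated by the FAO/WHO guideline that flags
identity of 6–8 contiguous residues; it is deterministic and has no
external dependencies. An adapter that shells out to BLAST
(`makeblastdb`/`blastp`, E-value 0.001) is provided for users who want
the classical protocol; note that the original protocol's exact BLAST
parameterisation (program, matrix, word size) is not recoverable, which
is a recorded limitation of any reconstruction. Both screens are
config-selectable and logged in the dataset provenance.

## Known limitations

- The 94%-range figures quoted for ACC–kNN allergen prediction on curated
  compilations are not reproducible here without those compilations; the
  synthetic recovery bounds are engineering contracts, not benchmark
  claims.
- The kNN score is not a calibrated probability; no calibration is
  attempted.
- Only the three-component Hellberg scale is implemented; alternative
  descriptor sets (five-component z-scales, VHSE, ProtFP) are an
  extension point, and nucleotide input is out of scope.
- Neighbour voting and route assignment are unweighted; distance-weighted
  variants were considered and rejected to keep the score quantised and
  the decision rule transparent.
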