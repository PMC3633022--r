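# allerknn

Alignment-free prediction of protein allergenicity and route of exposure.

## The problem

Allergens are proteins that provoke IgE-mediated hypersensitivity. Most
computational screens for allergenicity rely on sequence similarity to
known allergens (FAO/WHO-style identity rules, motif libraries), which
assumes allergenicity is linearly encoded in the sequence and struggles
with structurally novel allergens. `allerknn` takes the alignment-free
route: it classifies proteins purely from the statistics of their
physicochemical profile, so sequences of any length become comparable
without alignment. It is aimed at researchers screening novel proteins —
e.g. from transgenic crops or biologic drug candidates — and at anyone
building or evaluating allergenicity predictors.

## The method

1. **z-descriptor encoding.** Each residue is replaced by the Hellberg
   z-scales (z1, z2, z3): principal-component scores summarising
   hydrophobicity, molecular size and polarity. A protein of *n* residues
   becomes an *n* × 3 matrix *Z*.

2. **Auto-/cross-covariance (ACC) transformation.** For descriptors
   *j*, *k* ∈ {1, 2, 3} and lags *l* = 1…*L* (default *L* = 5):

   A<sub>jj</sub>(l) = Σ<sub>i=1</sub><sup>n−l</sup> Z<sub>j,i</sub> · Z<sub>j,i+l</sub> / (n − l)

   C<sub>jk</sub>(l) = Σ<sub>i=1</sub><sup>n−l</sup> Z<sub>j,i</sub> · Z<sub>k,i+l</sub> / (n − l),  j ≠ k

   Three auto terms and six ordered cross terms over five lags give a
   fixed 45-component vector (3² × 5) per protein, capturing local
   neighbour effects along the chain.

3. **k-nearest-neighbour classification.** A query is labelled by its
   *k* = 3 nearest training vectors (Euclidean distance by default). The
   score is the allergen fraction among the neighbours; at the default
   threshold 0.5 the verdict is "Probable Allergen" or "Probable
   Non-allergen". For predicted allergens the most probable **route of
   exposure** (food, inhalant or toxin) is the majority route tag of the
   allergen neighbours.

The package also ships the surrounding study machinery: labelled
FASTA/TSV datasets, mirror non-allergen set construction with a
similarity screen (exact k-mer by default, BLAST adapter optional), a
seeded synthetic-data generator, stratified 5-fold cross-validation, a
k-scan, a cross-comparative route analysis and naive Bayes / logistic
regression / decision tree baselines.

## Worked example

```r
library(allerknn)

ds  <- generate_synthetic(synthetic_spec())   # 300 allergens + 300 non-allergens
fit <- allerknn(ds, k = 3)
fit
#> k-nearest-neighbour allergen classifier on ACC z-descriptor features
#>   training instances: 600 (300 allergen / 300 non-allergen)
#>   k = 3, distance = euclidean, features = 45 (acc-z3-L5/pairmajor-v1)

predict(fit, c(novel = "MKVILFLAVAVVSATTYAHA"))
#> novel: Probable Allergen (score 1.000, route of exposure: food)
#>     1. allergen_0097  d=4.9809  allergen [food,inhalant]
#>     2. allergen_0083  d=5.2013  allergen [food,inhalant]
#>     3. allergen_0041  d=5.6278  allergen [food]

cross_validate(ds, k = 3, seed = 42)
#> 5-fold cross-validation, kNN k = 3 (euclidean distance)
#> Pooled (micro) metrics:
#> Performance at threshold 0.50 (n = 600)
#>   TP=277 FN=23 TN=288 FP=12
#>   sensitivity=0.9233 specificity=0.9600 ppv=0.9585 F1=0.9406 AUC=0.9650
#> Macro (mean per-fold): sensitivity=0.9233 specificity=0.9600 ppv=0.9592 f1=0.9399 auc=0.9654
```

All three neighbours of the query are allergens (score 3/3 = 1.0), so the
verdict is "Probable Allergen"; two of the three carry the food tag, so
food is the assigned route. The cross-validation block reports pooled
confusion counts over the five held-out folds: with the generator's
default hydrophobic composition bias the classifier recovers the planted
class structure with ~92% sensitivity and ~96% specificity.

The same workflow is available from a shell via the installed
`exec/allerknn` script (`synth`, `train`, `predict`, `evaluate`
subcommands), e.g.

```sh
allerknn synth --n-per-class 300 --seed 42 --out-fasta d.fasta --out-labels d.tsv
allerknn train --fasta d.fasta --labels d.tsv --out model.json
allerknn predict --model model.json --query query.fasta --out-json pred.json
allerknn evaluate --mode cv --fasta d.fasta --labels d.tsv --seed 42 --out cv.json
```

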