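# saflex

Characterization and prediction of protein backbone flexibility from
structural-alphabet conformational entropy.

Proteins are dynamic: some residues keep one local backbone conformation
across the conformational ensemble, others switch between several. `saflex`
quantifies this by encoding each conformation of a protein as a string over
a **structural alphabet** (SA) — a finite set of recurring local backbone
states — and measuring, per residue, the Shannon entropy of the letters
observed across the ensemble:

    H(i) = - sum_{j=1..m} a_ij * ln(a_ij)

where `a_ij` is the frequency of letter *j* at position *i* across the
conformations and *m* is the alphabet size. High `H(i)` marks a residue
whose local structure varies (flexible); `H(i) = 0` marks a residue locked
into one letter (rigid). The entropy profile is compared against
crystallographic B-factors through the Pearson correlation

    cc = sum_i (H_i - mean(H)) (B_i - mean(B)) /
         sqrt( sum_i (H_i - mean(H))^2 * sum_i (B_i - mean(B))^2 )

and residues are classified as flexible when their entropy exceeds a
threshold `T` (by default the pooled mean entropy of the reference data),
with sensitivity / specificity / precision and a tie-aware ROC score for
evaluation.

Four alphabets are supported, in increasing resolution:

| alphabet   | letters | assignment                                             |
|------------|---------|--------------------------------------------------------|
| Sec3       | 3       | hydrogen-bond pattern (Kabsch–Sander-style), collapsed |
| Sec8       | 8       | hydrogen-bond pattern, full 8 classes                  |
| PB         | 16      | dihedral RMSD to the bundled Protein Blocks prototypes |
| FragmentSA | 28      | superposed CA RMSD to trainable 7-residue fragments    |

Flexibility can also be **predicted from sequence alone**: a dual-layer
classifier (multinomial ridge logistic regression on sliding PSSM windows,
refined by a second layer over neighboring first-layer class
distributions) emits a per-residue distribution over the alphabet letters,
whose entropy `H = -sum_j Y_j ln Y_j` is used as the flexibility score.

A synthetic-data module generates backbone ensembles with *known*
per-position letter distributions, matched B-factors and sequence profiles
carrying a learnable signal, so the whole pipeline is testable end to end
without external datasets.

## Worked example

```r
library(saflex)

# a synthetic 24-residue protein whose loop positions swap conformation
spec <- generator_spec(strrep("HEC", 8),
                       variability = rep(c(0, 0.15, 0.4), 8),
                       n_members = 200, seed = 1)
gen <- make_decoy_ensemble(spec)

# encode every conformation, build letter frequencies, entropy
encs <- lapply(gen$ensemble$members, encode_rama)
h <- conformational_entropy(letter_matrix(encs))
round(h$values[2:7], 3)
#> [1] 0.456 0.656 0.000 0.456 0.679 0.000

# compare with (synthetic, noise-free) B-factors
b <- make_synthetic_bfactors(gen$truth$true_entropy, noise_sd = 0)
bfactor_correlation(h, b)
#> [1] 0.9953238

# label and evaluate flexible residues
truth <- ifelse(gen$truth$flexible, "flexible", "rigid")
pred <- classify_by_threshold(h, mean_entropy_threshold(h))
flex_metrics(confusion(pred, truth))
#> sensitivity specificity   precision
#>           1           1           1
roc_score(h$values, truth)$auc
#> [1] 1
```

The entropies at variability 0.15 estimate the generating value
`-(0.15 ln 0.15 + 0.85 ln 0.85) = 0.423` nats and those at 0.4 the value
`0.673` nats (the 200-member sample wobbles around them); positions with
zero variability score exactly 0. On this
noise-free example every flexible residue separates perfectly from every
rigid one, so all Eq-style metrics are 1.

A command-line wrapper over the same functions is installed at
`system.file("cli", "saflex.R", package = "saflex")` with subcommands
`encode`, `train-alphabet`, `characterize`, `train-predictor`,
`predict-flex` and `simulate`.

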