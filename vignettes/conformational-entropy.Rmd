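---
title: "Conformational entropy over structural alphabets: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational entropy over structural alphabets: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saflex)
```

## The model

`saflex` treats protein flexibility as variability of *local* backbone
structure. Every conformation of a protein is reduced to a string over a
structural alphabet — a finite set of recurring local backbone states —
and flexibility at position $i$ is the Shannon entropy of the letters seen
there across the ensemble:

$$H(i) = -\sum_{j=1}^{m} a_{ij}\,\ln a_{ij},$$

with $a_{ij}$ the across-conformation frequency of letter $j$ at position
$i$ and $m$ the alphabet size. Two readings of $a_{ij}$ are possible from
its verbal definition (per-conformation probability versus per-letter
frequency); only the per-letter frequency makes the sum over $m$ letters a
well-defined entropy of conformational variability, so that is what the
package computes. Entropies are in nats (natural log) and are deliberately
*not* normalized by $\ln m$: thresholds are alphabet-specific by design,
because alphabets of different resolution see different amounts of
variability.

The same functional is applied to a *predicted* per-residue class
distribution $Y_1,\dots,Y_m$ emitted by the sequence-based predictor:
$H = -\sum_j Y_j \ln Y_j$, high meaning "the sequence is compatible with
several local structures here".

Downstream, the entropy profile is (a) correlated with per-residue
B-factors by the Pearson coefficient over jointly unmasked positions, and
(b) thresholded to call flexible residues: a residue is *predicted*
flexible iff $H(i) > T$ strictly, with the boundary case rigid; the
default $T$ is the mean entropy over all unmasked residues of the
reference dataset, pooled at the residue level (a protein with 300
residues contributes 300 terms, not one). Reference ("true") labels from
an ensemble follow the letter-change rule: flexible iff at least two
distinct non-mask letters occur at the position, rigid iff exactly one,
masked iff none.

## The alphabets

* **Sec3 / Sec8** — rule-based secondary structure. The package implements
  a simplified Kabsch–Sander assigner: amide hydrogens are placed
  geometrically ($1.01\,\mathrm{\AA}$ from N along the direction opposite
  the bisector of the two adjacent backbone bonds), hydrogen bonds are
  detected with the electrostatic energy
  $E = 27.888\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$ kcal/mol and
  threshold $E < -0.5$, n-turns at $i \to i{+}3/4/5$ give G/H/I helices
  (two consecutive turns required), bridge patterns give E/B, remaining
  turn residues T, bends S, else C, with priority H > E > G > I > B > T >
  S > C. Pairs closer than $|i-j| = 3$ are not evaluated since no
  assignment pattern uses them. Exact DSSP edge cases (termini, π-helix
  preference) vary between DSSP versions, so `read_dssp()` accepts
  precomputed DSSP files as an override; byte-identical DSSP output is a
  non-goal.
* **PB** — the 16-letter Protein Blocks alphabet. The bundled plain-text
  table carries the canonical 16 × 8 prototype dihedrals (letters a–p).
  Assignment minimizes the dihedral RMSD
  $\mathrm{RMSDA} = \sqrt{\tfrac{1}{8}\sum_k d_k^2}$,
  $d_k = \min(|\Delta\theta_k|, 360-|\Delta\theta_k|)$, over the window
  vector $(\psi_{i-2},\phi_{i-1},\psi_{i-1},\phi_i,\psi_i,
  \phi_{i+1},\psi_{i+1},\phi_{i+2})$ — the canonical Protein Blocks window
  convention. Two residues at each terminus are mask.
* **FragmentSA** — a trainable 28-letter Cartesian alphabet of 7-residue
  CA fragments, the same geometry space and size as published
  Cartesian fragment libraries ("DW-style"). Because the original
  prototype coordinates are not published, the package trains its own:
  centered CA windows are clustered by Lloyd iteration under superposed
  (Kabsch) RMSD, prototypes being the superposed means of their members.
  Initialization is a seeded random draw of $m$ fragments; empty clusters
  are refilled with the worst-fit fragments; iteration stops when
  memberships are stable and prototypes have converged (shift
  $< 10^{-7}\,\mathrm{\AA}$). Everything is deterministic given the seed,
  and ties in assignment always break to the lowest prototype index.
  During development a more elaborate refill rule (protecting singleton
  clusters) and farthest-point seeding were both evaluated and discarded:
  each let the library degenerate on mixtures dominated by one
  conformation class, which destroys the resolution advantage a 28-letter
  alphabet should have.
* **Rama3** — a per-residue nearest-center classifier over the three
  canonical $(\phi,\psi)$ basins (helical $(-57,-47)$, extended
  $(-119,113)$, left-handed $(60,45)$) under wrapped Euclidean distance.
  It exists because it is the exact inverse of the synthetic generator:
  per-residue assignment has no window leakage, so generating letter
  distributions are recoverable position by position, which the recovery
  tests exploit.

## Geometry and numerical choices

Angles are degrees in $(-180, 180]$; torsions follow the IUPAC sign
convention (validated against an independent implementation). Backbones
are built by natural-extension (NeRF) placement with standard internal
coordinates (N–CA 1.46 Å, CA–C 1.52 Å, C–N 1.33 Å, $\omega = 180^\circ$);
an ideal helix built this way shows $i \to i{+}4$ O–N distances of
3.06 Å, inside the hydrogen-bonding range, which is what makes the
built-in secondary-structure assigner label it H. Superposition RMSD uses
the SVD form of the Kabsch algorithm with the proper-rotation (reflection)
correction; the fragment-encoder evaluates the whole fragment × prototype
grid with a closed-form symmetric 3×3 eigensolve, which is
exactly equivalent (tested against per-pair SVD) but runs as nine matrix
products.

Missing atoms and chain breaks are masked, not dropped: a residue is
invalid when any of N/CA/C/O is absent or when the CA–CA distance to its
predecessor reaches 4.5 Å (a generous bound above the trans value of
~3.8 Å), and the mask propagates through dihedrals, encodings, frequency
rows, entropies, labels and metrics. Per-residue B-factors are taken from
the CA atom, the standard per-residue flexibility proxy. Alternate
locations resolve to highest occupancy, then first seen; only one chain
is used per call (the first, unless requested).

In every frequency or probability row, $0\ln 0 := 0$. Predicted
distributions must sum to 1 within $10^{-6}$ or are rejected. The ROC
sweep groups tied scores into single steps and uses trapezoidal area;
with this convention the normalized area *equals* the Mann–Whitney
statistic (probability a random flexible residue outscores a random rigid
one, ties counting half), which the tests assert to $10^{-12}$.

## The predictor

Layer 1 is an L2-regularized multinomial logistic regression (single
fixed penalty $\lambda = 0.01$, hence deterministic) on sliding windows
of PSSM features squashed through the logistic $x \mapsto 1/(1+e^{-x})$;
layer 2 is the same estimator on windows of neighboring layer-1 class
distributions, exploiting the strong correlation between adjacent local
structures. Window sizes default to $W_1 = 15$ and $W_2 = 9$ residues
(typical profile-window scales; both configurable). Layer 2 is trained on
*cross-fitted* layer-1 outputs with protein-level folds, so its training
inputs have held-out quality and the stacking is not optimistically
biased. The original work used SVMs; the package fixes the interface (a
probabilistic multiclass classifier), not the estimator, and the ridge
model keeps training fast and reproducible. Running the profile search
itself (PSI-BLAST) is out of scope — profiles are ingested from ASCII
PSSM files or synthesized.

## What the synthetic generator emulates — and what it does not

`make_decoy_ensemble()` perturbs local conformation classes, not
Cartesian coordinates: position $i$ keeps its base class with probability
$1-v_i$ or swaps to a fixed alternative, independently across positions
and members. The alternative is either a different basin (helix ↔
extended; visible to every alphabet) or a "subtle" within-basin variant
(e.g. $(-57,-47) \to (-70,-30)$; invisible at secondary-structure
resolution but resolvable by finer alphabets). This is a deliberate
idealization: the generating per-position letter distribution is then
*exact*, so entropy recovery, the B-factor link ($B_i = 20 H_i + 10$ Å²
plus Gaussian noise), the labeling rule and the ROC machinery can be
tested against closed-form ground truth. Default study sizes used by the
test suite: 1000-member ensembles over ~30 residues for recovery
(estimated-vs-generating entropy MAE < 0.05 nats over 20 seeds), 60-member
ensembles of 48 residues with three distinct-swap and six subtle-swap
flexible positions at $v = 0.3$ for the alphabet-resolution comparison,
and 20 proteins × 100 residues with Markov letter chains (self-transition
0.85) and profile signal strength 0.5 for the predictor.

What the generator does **not** emulate: energetically realistic decoys
(no physics, no Rosetta-like sampling), correlated segment motions
(swaps are independent per position), within-class dihedral jitter,
side chains, or real evolutionary profiles. Consequently, passing tests
demonstrate that the estimators and the pipeline are correct and that the
qualitative trends (finer alphabets detect more flexibility; the second
predictor layer helps; entropy tracks B-factors when the link exists) are
reproduced under controlled conditions — they do not certify performance
numbers on real decoy sets or real crystallographic B-factors, which are
noisier in ways the generator intentionally omits.

## Degenerate inputs and error policy

Structures shorter than an encoding window yield all-mask encodings
(PB needs 5 residues; FragmentSA needs $L$). Correlation requires at
least 3 jointly unmasked positions and non-zero variance on both sides;
ROC requires both classes present; metrics with a zero denominator return
`NA` for that metric only. Flexibility labeling requires at least two
conformations. All such conditions raise classed errors
(`saflex_*`) so callers can distinguish contract violations from bugs.

## Known limitations

* The secondary-structure assigner is a simplified Kabsch–Sander scheme;
  on real, irregular structures it will disagree with DSSP at edge cases
  (π-helix preference, chain termini, bifurcated bonds). Use
  `read_dssp()` where fidelity to a specific DSSP version matters.
* The trained 28-letter fragment alphabet is a stand-in of the same
  family as published Cartesian libraries, not a reproduction of any
  specific one; letters are not comparable across retrainings.
* Entropy from finite ensembles is biased slightly downward (plug-in
  estimator); at the 60–1000 member scales used here the bias is well
  below the 0.05-nat recovery tolerance.
* Window-based alphabets smear entropy over up to $(L-1)/2$ neighboring
  positions (a letter change at $i$ alters the windows of its neighbors),
  which costs precision near flexible segments; the per-residue Rama3
  encoder avoids this but cannot see subtle variability.
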