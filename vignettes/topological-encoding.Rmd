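---
title: "Topological encoding of lysine environments for sumoylation-site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological encoding of lysine environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TopoSumo)
```

# The model

A candidate sumoylation site is a lysine K in a protein of known 3D
structure. TopoSumo represents its context as the heavy-atom point cloud
of the 41-residue window K ± 20 (hydrogens are dropped — they only add
short redundant bars) and summarizes the cloud's shape with persistent
homology: as a scale parameter grows, simplicial complexes built on the
atoms gain simplices, and homology classes — components (dim 0), loops
(dim 1), voids (dim 2) — are born and die. The multiset of
(dimension, birth, death) intervals, the barcode, is a
coordinate-free, rigid-motion-invariant shape summary. At covalent-bond
scales (1.2–1.6 Å) the dim-0 bars fingerprint bonding patterns; at 2–7 Å
the dim-1/2 bars capture packing, rings and voids of the fold.

Two filtrations are used, deliberately different in character:

* **Vietoris–Rips (VR)**: a simplex enters when all pairwise distances
  among its vertices are below the filtration value. We report values on
  the *pairwise-distance* scale (a pair connects at its distance). The
  alternative radius-scale convention would place covalent bonds at
  0.6–1.0, inconsistent with the 1.2–2.0 Å dim-0 bin edges the feature
  definitions use; the distance scale makes those edges exactly the
  covalent-bond range, which is why it is the package convention.
* **Alpha**: the nerve of Voronoi-restricted balls of radius δ, a
  subcomplex of the Delaunay triangulation, reported on the radius scale
  in Å. Its persistence coincides with the Čech filtration (a simplex
  enters when its vertices fit in a common ball), but the complex stays
  small, so no filtration cap is needed.

## The feature blocks

Barcodes are vectorized by **binning** — the number of bars of one
dimension whose *death* time falls in a half-open bin (lo, hi] — and by
**barcode statistics** — maximum, minimum, mean, sum and population
standard deviation of the birth times, death times and bar lengths of
one dimension (15 values). Essential (infinite) bars are excluded from
all statistics; a VR class still alive at the filtration cap r_f is
treated as dying at r_f and flagged as censored.

* **TF1 (48)** — whole-window VR, dims 0–2: dim-0 death counts over
  edges [1.2, 1.3, 1.4, 1.5, 1.6, 2.0] Å, dim-1 over
  [1.5, 2.7, 3.5, 4.5, 5, 6.7], dim-2 over [2.4, 2.9, 5.5, 6.7]; the
  second- and third-longest dim-0 bar lengths; the sum and mean of dim-0
  bar lengths; the birth of the longest dim-1 bar; dim-1 and dim-2
  statistics.
* **TF2 (30)** — whole-window Alpha: dim-1 and dim-2 statistics.
* **TF3 (240)** — each of the 40 flanking residues alone, VR: counts in
  (1.25, 1.5] and (1.5, 1.75] Å (which bonds a residue type has), the
  number of 0-bars (the heavy-atom count), and dim-0/1/2 bar-length
  sums; a dummy-code X position contributes six zeros.
* **TF4 (38)** — the local region K ± 2 residues, VR: all-atom dim-0
  counts over (1.2, 1.6] in 0.1 Å steps plus dim-1 statistics;
  carbon-only (element-specific PH) dim-0 counts over (1.5, 3.0] in
  0.5 Å steps plus dim-1 statistics; and the number of nitrogen-only
  finite 0-bars dying below 10 Å.

Total: 356 features, concatenated in that order with stable names
(`topoFeatureNames()`).

Two readings of the written feature definitions were genuinely open and
are resolved as follows. All bins count bars by death time in half-open
(lo, hi] intervals — the one place the source conventions are explicit
uses exactly that form, and a both-endpoints-inside reading would make
several bins structurally empty. The TF4 covalent-scale bins count
*dim-0* deaths: at 1.2–3 Å essentially no dim-1 class dies (the earliest
dim-1 deaths in TF1's design sit at 2.4 Å and above), so a 1-bar reading
would zero those features. "Longest" bars are ranked by length with ties
broken by earlier birth and then input order; fewer than the required
number of bars yields zeros.

## Downstream protocol

The published modelling protocol around the encoding is implemented as:
F-score ranking (between-class squared deviation of class means from the
grand mean over the sum of within-class sample variances, zero
denominator ⇒ score 0), incremental selection by cross-validated MCC
(smallest prefix attaining the maximum), NearMiss version-1
undersampling (keep the majority samples with the smallest mean
Euclidean distance to their 3 nearest minority neighbours, on raw
feature values, deterministic index tie-break), and three classifiers:
gradient boosting (500 rounds, learning rate 0.1, depth 3, exact
splits), random forest (370 trees, square-root feature subsampling) and
an RBF SVM (kernel width 1/d, internally standardized, probability
outputs). Folds and train/test splits are stratified and seeded;
pooled out-of-fold probabilities give one ROC/AUC per run, matching the
one-curve-per-run reporting style. Metrics are Sp, Sn, Acc, MCC (any
zero factor in the denominator ⇒ 0) and the rank-formulation AUC (ties
count one half).

# Numerical choices

* **Persistence computation.** The VR clique filtration enumerates
  simplices to dimension 3 (so homology to dim 2 is exact) and reduces
  the boundary matrix over GF(2) with the standard
  high-dimensions-first twist and clearing. Ties in simplex order break
  by (value, dimension, lexicographic vertices), making the reduction
  deterministic.
* **Filtration caps.** r_f = 7 Å for whole-window VR (covers the
  largest feature bin edge, 6.7 Å, and bounds the dim-3 clique
  enumeration), 6 Å for the per-residue TF3 runs, 7 Å for the TF4
  all-atom and carbon runs, and 12 Å for the TF4 nitrogen run (its
  feature needs deaths up to 10 Å). These are the smallest values that
  leave every defined feature uncensored.
* **Delaunay/Alpha.** An incremental Bowyer–Watson triangulation with an
  infinite vertex; predicates accumulate in extended precision and
  compare against a term-magnitude error bound, flagging
  near-degenerate input. Flagged inputs are retried under a
  deterministic Gaussian jitter of 1e-6 Å (escalating tenfold up to two
  more times) — far below any feature bin width. Exactly collinear
  clouds are triangulated directly as the path along the line. Alpha
  values are squared circumradii with Gabriel propagation
  (non-Gabriel faces inherit their cofaces' values), reported as radii.
* **Zero-length pairs** (birth = death) carry no topology and are
  discarded, using a relative tolerance of 1e-5 so that the huge,
  mutually cancelling circumradii of near-degenerate Alpha slivers
  cannot leak into features.
* **Population standard deviation** (divide by n) is used in barcode
  statistics so a single bar contributes 0 rather than NA.
* **Window identity** for de-redundancy is positionwise over the fixed
  41 positions (windows are pre-aligned by their central lysine); X
  matches only X, so terminal padding does not create spurious
  redundancy. The greedy keep-first pass runs in (proteinId, center)
  order, which makes "only one of them is retained" reproducible.
* **Gaps.** Residues missing from a structure inside a requested window
  are an error, never silently skipped; positions beyond the sequence
  termini are the dummy code X and contribute no atoms.

# The synthetic test bed

`synthStructure()` builds idealized peptides: CA atoms along a trace
with exact 3.8 Å steps — a helical turn of 100°/residue ("compact") or a
straight strand ("extended") — dressed with the true heavy-atom
composition of each residue type (glycine 4 atoms … tryptophan 14) at
idealized bond lengths (N–CA 1.46, CA–C 1.52, C–O 1.23, C–N(next) 1.33,
side-chain bonds 1.43–1.55 Å, all inside the 1.2–1.6 Å range probed by
the dim-0 bins). Side chains grow as zigzag chains: atom counts and bond
scales are faithful; ring closures and rotamer geometry are not. Seeded
Gaussian coordinate noise (default 0.05 Å for datasets) controls the
effect size.

`synthDataset()` labels compact windows positive and extended windows
negative, with random flanking sequences drawn identically for both
classes — the class signal is purely conformational, mirroring the view
that sumoylation propensity reflects local structure. On 50 + 50 windows
the pipeline (featurize → NearMiss → F-score ranking → gradient
boosting, 5-fold CV) separates the classes essentially perfectly, and
permuting labels collapses the AUC to chance — evidence that the
features carry the geometric signal and not a bookkeeping artifact.

What this does **not** show: real positive and negative lysine
environments differ far more subtly than a helix-versus-strand
dichotomy, real side chains have rotameric variety the generator lacks,
and AlphaFold models carry their own error structure. Synthetic
separability validates the plumbing and the discriminative geometry of
the encoding, not the biological effect size; the published performance
on curated datasets requires the original structures.

# Problem sizes and costs

A 41-residue window has ≈ 320 heavy atoms; its TF1 run enumerates on
the order of 10⁵–10⁶ simplices and takes ~1 s, the Alpha run ~0.02 s,
and a full 356-feature vector ~2.5 s on one core. The shipped tests and
the acceptance script therefore use 100-window synthetic datasets and
50 random oracle clouds of ≤ 8 points — sizes chosen so the whole suite
runs in minutes while still exercising every code path; the encoding
scales linearly in windows for real datasets.

# Known limitations

* Homology is computed to dimension 2; no cubical complexes, landscapes
  or persistence images.
* The VR engine targets windows of a few hundred atoms; it enumerates
  cliques explicitly and is not meant for whole proteins at large r_f.
* The identity filter is center-anchored positionwise identity, not an
  alignment; it is the deterministic reading of a 41-mer comparison,
  not a CD-HIT replacement.
* NearMiss is version 1 with 3 neighbours on raw features; other
  versions can be emulated by pre-selecting indices.
* Whether undersampling precedes or follows feature computation is a
  genuine protocol ambiguity; the package computes features first and
  undersamples the feature matrix, which keeps the feature values
  independent of the balancing step.
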