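---
title: "Classifying missense variants from MD trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying missense variants from MD trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdvar)
```

## The idea

Sequence-conservation predictors (SIFT, FATHMM, MutationTaster, PROVEAN)
disagree substantially on which missense variants of a protein impair its
function, and they tend to overpredict damage. For an enzyme whose
catalytic mechanism is structurally understood, molecular dynamics offers
an orthogonal signal: simulate the wild type and each mutant under
identical conditions and ask whether the mutant's trajectory explores a
different region of the conformational space that matters for catalysis.

`mdvar` implements everything around the MD engine: mapping database
variants onto a reference structure and emitting per-variant starting
models, extracting per-frame features from trajectories, reducing them by
principal component analysis, clustering whole trajectories by histogram
overlap, and converting the resulting tree into binary affected /
unaffected calls that can be benchmarked against experiments with Cohen's
κ. The running example throughout is the human 8-oxoguanine DNA
glycosylase OGG1 bound to damaged DNA, whose catalytic lysine/aspartate
dyad and everted 8-oxo-2′-deoxyguanosine (oxodG) define the geometry of a
productive active site.

The pipeline makes three assumptions worth stating explicitly:

* trajectories are **comparable**: same system preparation, same length,
  and the same analysis window for every variant (the bookkeeping helper
  `trajectory_plan()` encodes the default 40 ns / 8 ps / 5000-frame run
  with the final 2500 frames analysed);
* functional impairment manifests as a **shift in occupancy** of the
  active-site conformational landscape, not merely as faster dynamics;
* the wild type is part of the analysed set, since all calls are defined
  *relative to it*.

## Feature extraction

**Active site.** All residues (protein or nucleic) with at least one
heavy atom within `cutoff` (default 5 Å) of the ligand in the reference
frame. Hydrogens are excluded by default because the crystallographic
reference typically lacks them; both toggles are exposed. The ligand for
the OGG1 case is the oxodG *nucleoside* (base + sugar, no phosphate),
matching its chemical definition.

**Torsions.** For amino acids: φ, ψ and the standard side-chain χ ladder
(χ₁–χ₅ for Arg, χ₁–χ₄ for Lys, and so on). ω is excluded by default — it
is near-constant at 180° and only inflates dimensionality. For
nucleotides: backbone α, β, γ, δ, ε, ζ and the glycosidic χ; sugar
pseudorotation is not included. Torsions whose first or last atom lies in
a neighbouring residue belong to the residue owning the central bond and
are kept even when the neighbour is outside the selection; torsions with
missing atoms (termini, truncated side chains) are dropped with a log
message. Dihedrals follow the IUPAC sign convention (verified against
`bio3d::torsion.xyz`), reported in degrees in (−180, 180]; frames where
the three central atoms become collinear yield `NA` for that frame.

**Catalytic geometry.** Three scalars per frame: d₁ = Nζ(Lys)–C1′(oxodG)
in Å, d₂ = min over the two carboxylate oxygens of Asp of the distance to
O4′(oxodG) in Å, and a₁ = the Nζ–C1′–N9 angle in degrees. The min
resolves the Oδ1/Oδ2 labelling ambiguity per frame — either oxygen may
engage the sugar.

**Solvent stripping.** A water is retained iff it has an atom within 5 Å
of the ligand in at least `min_fraction` (default 0.10) of frames;
everything else, including counter-ions, is removed. The operation keeps
the frame count, hence is idempotent.

## Dimensionality reduction

Raw torsion angles are discontinuous at ±180°, so the dihedral feature
matrix uses the standard dihedral-PCA construction: each angle θ
contributes the column pair (cos θ, sin θ). In geometric mode the three
parameters mix Å and degrees, so each column is z-scored over the pooled
frames of all variants (configurable off). One PCA is fitted to the
pooled rows of *all* trajectories — per-variant fits would give
incomparable projections. Loadings are sign-fixed so that each loading's
largest-magnitude element is positive, making projections reproducible
across platforms.

The optional torsion screen keeps a torsion if at least one mutant's
circular mean differs from the wild type's by more than `threshold`
(default 36°) *and* the difference is significant under a two-sample
permutation test (statistic: absolute circular-mean difference; default
10⁴ permutations, level 0.001, seeded). The test we chose is
distribution-free; because consecutive MD frames are autocorrelated, the
series are thinned (default stride 10) before permutation, which makes
the test conservative rather than anti-conservative. Frame-label
permutation of autocorrelated data without thinning would overstate
significance.

NA-containing frames are dropped per variant before assembly; if that
leaves unequal frame counts, every variant is truncated to the common
minimum (keeping the latest frames) so that all occupancy histograms
share one total — a requirement of the overlap distance below.

## Trajectory clustering

The PC1–PC2 plane is partitioned into a 10 × 10 equidistant grid whose
bounds are the pooled min/max over all variants; bins are half-open with
the top/right edge closed so each point lands in exactly one bin. Shared
bounds are essential: per-variant bounds would make the histograms
incomparable. A degenerate axis (max = min) is widened by a
machine-scale epsilon with a warning.

For two occupancy-count grids *p*, *q* with equal totals *N* the package
uses the Bhattacharyya coefficient

$$BC = \sum_i \sqrt{p_i q_i}, \qquad 0 \le BC \le N,$$

and the distance *N* − BC. The radical is essential: without it the
coefficient is bounded by *N*², not *N*, and the identity BC = *N* for
identical histograms fails. Counts (not frequencies) are used, so the
distance scales with *N* and equal totals are enforced. *N* − BC is not a
metric — the triangle inequality can fail — which is acceptable because
it is consumed only by average-linkage clustering, not by any embedding.

UPGMA merges the closest pair of clusters, with inter-cluster distance
the unweighted arithmetic mean over all original cross pairs and node
height half the merge distance, giving an ultrametric tree. Ties are
broken lexicographically on the smallest member label of each cluster so
results are deterministic under label permutation. The implementation is
validated against `stats::hclust(method = "average")` merge heights and
cophenetic structure on random matrices, and trees export to Newick
parseable by `ape`.

## Branch classification

The tree's root splits the leaves into the wild-type-side subtree and the
far subtree; the far subtree's own root splits once more — three branches
meeting at the *three-branch point*. The **distal** branch is the branch
whose members have the largest mean cophenetic distance to the wild type.
On an exactly ultrametric tree the two far branches are equidistant from
the wild type by construction, so branches tied at the maximum are
pooled: the distal set is then the whole far subtree. This convention is
deliberate — a remote outlier that merges with the impaired cluster only
near the root (such as an isolated singleton branch) is counted distal
together with that cluster, which matches how the published OGG1 distal
set pooled the impaired trio with the isolated P291Q branch, at the cost
of one false positive. For imported non-ultrametric trees the rule
degenerates gracefully to "the single farthest branch".

Two rules convert branches into calls: `distal_affected` (distal branch
affected, everything else unaffected — fewer false positives) and
`proximal_unaffected` (wild-type branch unaffected, everything else
affected — more sensitive, more overcalls). A far subtree consisting of a
single leaf is handled with a warning.

## Agreement benchmarking

Cohen's κ = (p₀ − pₑ)/(1 − pₑ) on the 2 × 2 confusion counts, items with
ties or missing calls excluded pairwise; κ is undefined (and flagged, not
silently 0) when fewer than two items remain or pₑ = 1. Summaries round
half away from zero to 3 decimals.

The benchmark harness encodes three conventions required for
comparability with the reference layout: (i) the wild type enters as an
extra item, experimentally unaffected and predicted unaffected by every
method; (ii) the combined ±1 score over the four predictors excludes
score-0 ties from that method's κ (policies "count as affected /
unaffected" are selectable); (iii) ambiguous experimental labels are
resolved per scenario (e.g. the mild variants counted as neutral vs.
affected), and every scenario must resolve all of them. MD augmentation
adds ±1 to the combined score by membership in the MD-derived affected
set, after which no ties are possible.

The packaged OGG1 fixture ships the four predictor calls for the 20
sampled somatic variants plus experimental labels (three affected, two
ambiguous, eight unaffected); the test suite reproduces all fourteen
benchmark κ values from it at 3 decimals.

## Synthetic data: what it emulates, and what it does not

The generators are statistical stand-ins for the MD engine, not physical
simulators. `gen_torsion_set()` draws each torsion from a von Mises
distribution whose mean depends on a hidden metastable state following a
Markov switch chain — reproducing multi-modal, temporally clustered
angular populations. `gen_geometry_set()` draws (d₁, d₂, a₁) from a
Gaussian mixture; wild-type-like variants put weight 0.9 on the
catalytically "optimal" cluster and impaired variants 0.05. The preset
conditions (fixed once, as study conditions): optimal cluster at
d₁ = 3.1 Å, d₂ = 2.7 Å, a₁ = 155°, sd (0.25 Å, 0.25 Å, 6°) — a typical
near-attack H-bond/contact geometry; two mild excursion clusters around
4.6–5.2 Å to give the wild-type-like population two families, as seen in
real trees; an impaired cluster at d₁ = 7.5 Å, d₂ = 6.0 Å, a₁ = 95°,
more than 3σ from the optimal center on every coordinate; 21 variants ×
2500 frames; 3 impaired, fixed by position. Deterministic per-variant
center offsets individualize variants.

What passing these tests shows: the pipeline's bookkeeping, the overlap
distance, the tree construction and the branch rule correctly recover
population-level occupancy differences of the planted size. What it does
not show: robustness to force-field artifacts, incomplete equilibration,
slow conformational exchange (states longer-lived than the analysis
window), or impairment mechanisms that do not alter active-site
occupancy (e.g. pure binding-affinity or stability effects) — on real
systems those remain the user's responsibility.

`gen_toy_complex()` builds a small protein–DNA–ligand complex by exact
internal-coordinate (NeRF) placement, so every scripted dihedral is
recovered by measurement to machine precision, active-site membership and
water contact fractions are planted, and rigid-motion invariance can be
asserted without tolerance games.

## Numerical choices and edge cases

* Angles live in (−180, 180]; the wrap maps −180 to +180 so the interval
  is half-open exactly as stated.
* The circular mean is flagged undefined (NA with a warning) when the
  resultant length is below 1e−8 — e.g. two antipodal angles.
* Permutation p-values use the add-one estimator (hits + 1)/(n + 1), so
  with the default 10⁴ permutations the smallest attainable p is
  1/10001 < 0.001; callers reducing `n_perm` below 1000 cannot reach the
  default α.
* UPGMA tie-breaks and the PCA loading sign convention are the only two
  places where arbitrary choices could leak into results; both are fixed
  deterministically (lexicographic; largest element positive).
* Kabsch superposition corrects a reflection optimum by flipping the
  smallest singular direction, never returning determinant −1; genuinely
  collinear point sets (rank < 2) are warned about.
* Mutated models truncate side chains at Cβ rather than building
  rotamers: rebuilding is the job of the downstream modelling step, and
  truncation is the standard hand-off convention.
* Sampling of variants order-normalizes records first, so the seed alone
  (Mersenne–Twister) determines the selection regardless of input order.

Problem sizes in the shipped tests were chosen to exercise the study
conditions where it matters and stay small elsewhere: the full 21 × 2500
preset for single-run recovery and a 100-seed recovery study, 3–7-label
matrices for the clustering oracle (where exhaustive comparison is
strongest), and a few hundred frames for the permutation-test checks.

## Known limitations

* The three-branch decomposition presumes the root separates wild-type
  from non-wild-type behaviour; if the wild type itself is an outlier,
  both rules degrade (a warning covers the single-leaf case only).
* κ is reported without confidence intervals; with 13–14 items the
  sampling error is substantial, and comparing two methods by κ alone is
  fragile.
* The divergent-torsion screen tests mean shifts only; a variant that
  changes dispersion or state populations without moving circular means
  passes unflagged into the full-torsion mode.
* Binary trajectory formats are not parsed; trajectories enter as
  multi-model PDB through `read_models()`, and any other reader can be
  plugged in as long as it produces the same atom-table + frame-matrix
  contract.
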