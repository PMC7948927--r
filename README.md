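# mdvar

Classify protein missense variants as functionally **affected** or
**unaffected** from molecular dynamics (MD) trajectories.

Most variant-effect predictors score sequence conservation; they disagree
with each other and overcall deleterious changes. `mdvar` implements the
complementary, structure-dynamics route for enzymes with a known
mechanism, developed around the DNA repair glycosylase OGG1 (which excises
8-oxoguanine from DNA): if a mutation matters, the mutant's trajectory
should *look different* from the wild type's in the coordinates that
matter for catalysis. The package covers the full desk-side pipeline —
everything around the MD engine itself:

1. **Variant mapping** — parse missense records from a database snapshot
   (COSMIC-style TSV), map them through a Needleman–Wunsch isoform
   alignment (BLOSUM62, gap 10/0.5) onto the reference structure with
   residue-identity verification, sample *k* variants with a recorded
   seed, and emit one single-mutation PDB per variant (side chains
   truncated at Cβ for downstream rebuilding), plus Kabsch superposition
   for patching reference models.
2. **Feature extraction** — read multi-model PDB trajectories, define the
   active site as every residue within 5 Å of the damaged nucleoside,
   enumerate standard torsions (φ, ψ, χ₁…χₙ; nucleic α…ζ, χ), compute
   per-frame dihedrals and the catalytic-dyad geometry
   (d₁ = Nζ(Lys)–C1′, d₂ = min(Oδ1/Oδ2(Asp))–O4′, a₁ = Nζ–C1′–N9), and
   strip bulk solvent (a water is kept iff near the ligand in ≥ 10 % of
   frames).
3. **Dimensionality reduction** — dihedral PCA on sin/cos-transformed
   torsions (or z-scored geometry), one pooled fit over all trajectories;
   optional restriction to torsions whose circular mean diverges > 36°
   from wild type with a seeded permutation test (p < 0.001).
4. **Trajectory clustering** — 10 × 10 occupancy histograms in the
   PC1–PC2 plane on shared bounds; for two count grids *p*, *q* with
   equal totals *N*, the Bhattacharyya coefficient is

   > BC = Σᵢ √(pᵢ qᵢ),  0 ≤ BC ≤ N

   and *N* − BC is the inter-trajectory distance. UPGMA turns the
   distance matrix into an ultrametric tree (Newick export included).
5. **Branch classification** — the tree's root separates the wild-type
   branch from two far branches (the *three-branch point*); the
   *distal-affected* rule calls the branch farthest from the wild type
   affected, the *proximal-unaffected* rule calls everything off the
   wild-type branch affected.
6. **Agreement benchmarking** — Cohen's κ = (p₀ − pₑ)/(1 − pₑ) between
   any two binary raters, rater-vs-rater κ matrices, the ±1 combined
   score over four sequence predictors, and κ benchmarking against
   experimental labels under ambiguity scenarios, with optional MD
   augmentation of the combined score.

A seeded synthetic-data module (von Mises torsion mixtures over a hidden
metastable-state chain; Gaussian-mixture catalytic geometry with a dense
"optimal" cluster; a fully scripted toy protein–DNA–ligand complex built
from internal coordinates) provides planted ground truth for every stage.

## Worked example

Simulate the default study layout — a wild type plus 20 mutants with
2500-frame geometric trajectories, 3 of them impaired (barely visiting
the catalytically optimal cluster) — then run the geometric pipeline:

```r
library(mdvar)

pre <- synthetic_geometry_preset(n_variants = 21, n_impaired = 3)
geo <- gen_geometry_set(pre, n_frames = 2500, seed = 42)
res <- classify_variant_trajectories(geo, "WT", mode = "geometric",
                                     rule = "distal_affected")
res$tree
#> <ClusterTree> 21 leaves, root height 991.202
names(res$calls)[res$calls == "affected"]
#> [1] "M10" "M19" "M02"
attr(pre, "impaired")
#> [1] "M02" "M10" "M19"
```

The root height is in N − BC units (out of N = 2500): the impaired
variants' occupancy grids barely overlap anything else, so they split off
near the maximal distance, and the distal branch recovers exactly the
planted set. The closest mutants to the wild type sit at single-digit
distances (`sort(res$distance["WT", ])[2:3]` → `M12` 8.43, `M06` 11.58).

Benchmarking the packaged OGG1 predictor calls against the experimental
labels (wild type included as a 14th item; the mild R161W/S292N variants
counted as neutral; combined-score ties excluded; the MD distal set
{I145M, G202C, V267M, P291Q} used for augmentation):

```r
bm <- benchmark(ogg1_call_table()[, c("variant", "SIFT", "FATHMM",
                                      "MutationTaster", "PROVEAN")],
                ogg1_experimental_labels(),
                scenarios = list(mild_neutral = c(R161W = "unaffected",
                                                  S292N = "unaffected")),
                md_affected = c("I145M", "G202C", "V267M", "P291Q"))
bm[, c("method", "kappa3", "a", "b", "c", "d", "n")]
#>           method kappa3 a b c  d  n
#> 1           SIFT  0.340 3 5 0  6 14
#> 2         FATHMM  0.152 1 2 2  9 14
#> 3 MutationTaster  0.263 3 6 0  5 14
#> 4        PROVEAN  0.533 3 3 0  8 14
#> 5       combined  0.519 3 3 0  7 13
#> 6    combined+md  0.533 3 3 0  8 14
#> 7      md_distal  0.811 3 1 0 10 14
```

`a, b, c, d` are the confusion counts (both affected / prediction only /
experiment only / both unaffected); `kappa3` is κ rounded half-up to
3 decimals. The MD distal rule is the strongest single predictor here
(κ = 0.811, a single false positive), and adding it to the combined
sequence score lifts κ from 0.519 to 0.533.

A command-line front end over the same functions is in
`inst/cli/mdvar.R` (`simulate`, `classify`, `features`, `map-variants`,
`kappa`, `benchmark`).

## Vignette

`vignettes/trajectory-classification.Rmd` describes the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic generators do and do not emulate, and the numerical and design
choices (tie-breaking, tolerances, degenerate inputs).
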