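# morphotraj

Geometric-morphometric comparison of ontogenetic trajectories in 3D landmark
data.

`morphotraj` is for evolutionary morphologists who ask whether related
species — including fossils with incomplete material — share a common growth
trajectory of skull shape, how their adult shapes differ once size is
accounted for, and whether shape similarity tracks phylogenetic relatedness.
It implements the full inference chain as composable R functions plus a
config-driven runner, and ships a synthetic-data generator with known ground
truth shaped like a four-species, two-age-class bear cranium/mandible study
(36 bilaterally symmetric cranial landmarks, 9 one-sided mandibular
landmarks).

## What it computes

* **Superimposition.** Generalized Procrustes analysis (partial Procrustes:
  translation, unit-centroid-size scaling, proper rotations), with the
  reflect-and-relabel **object symmetry** decomposition for paired
  templates: the symmetric component `(x + reflected(x))/2` of each aligned
  specimen feeds all covariance analyses.
* **Missing landmarks.** Thin-plate-spline interpolation (3D kernel
  `U(r) = r`, full affine term) warping a reference shape onto each
  incomplete specimen's observed landmarks.
* **Morphospace.** Covariance PCA of shape coordinates; scores, percent
  variance, 95% equal-frequency ellipses, extreme-shape models
  `mean + s · axis`.
* **Allometry.** Multivariate regression of shape on log centroid size:
  `shape_i = intercept + β · log CS_i + ε_i`, with predicted-SS permutation
  test, the residual ("non-allometric") shape track, and trajectory
  comparison via the angle `θ = arccos(β̂₁·β̂₂ / |β̂₁||β̂₂|)` tested against
  the uniform-random-directions null, whose cosine obeys
  `(cos θ + 1)/2 ~ Beta((d−1)/2, (d−1)/2)` in `d` dimensions.
* **Group comparison.** Procrustes distances between group mean shapes with
  pairwise label-permutation tests (raw and size-corrected tracks), CVA with
  Mahalanobis distances, Kruskal–Wallis rank tests with mean-rank post-hoc
  comparisons.
* **Phylogenetic signal.** Squared-change parsimony tree length
  `Σ_b ||child_b − parent_b||²/w_b` minimized over ancestral states, tested
  by permuting tip values (exhaustively enumerated for ≤ 8 tips; with 4
  species there are only 24 assignments).

## Worked example

Simulate a study-shaped cranial dataset, complete the fossil specimens,
superimpose with object symmetry, and compare the brown-bear and cave-bear
growth trajectories:

```r
library(morphotraj)

params <- scenario_params("bear_like", "cranium", seed = 42)
ds <- simulate_ontogeny(params)
ds
#> Landmark dataset: 253 specimens x 36 landmarks (cranium)
#>              adult juvenile
#>   americanus    28        0
#>   arctos        56       27
#>   maritimus     42        0
#>   spelaeus      97        3
#> 163 missing landmark(s) across 79 specimen(s)

ds <- estimate_missing(ds)            # TPS completion of fossil crania
sym <- gpa_with_object_symmetry(ds)
sym$gpa
#> GPA of 506 configurations (36 landmarks): 4 iterations, converged, final SS = 5.73462

pca <- shape_pca(flatten_shapes(sym$symmetric))
pca
#> Shape PCA: 253 specimens, 55 non-zero components
#>   % variance (PC1..): 11.79, 7.21, 5.00, 3.89, 2.94

reg <- regress_shape_on_size(flatten_shapes(sym$symmetric),
                             sym$gpa$log_centroid_sizes,
                             n_permutations = 999, seed = 1)
reg
#> Shape ~ log(CS): 4.36% of variation predicted, permutation p = 0.001 (999 rounds)

keep <- ds$meta$species %in% c("arctos", "spelaeus")
tr <- ontogenetic_trajectories(flatten_shapes(sym$symmetric)[keep, ],
                               sym$gpa$log_centroid_sizes[keep],
                               ds$meta$species[keep],
                               n_permutations = 999, seed = 1)
tr$angles
#>   group_a  group_b angle_degrees      p_value
#> 1  arctos spelaeus      50.79437 8.702825e-08
```

Reading the output: the 36-landmark configurations of all 253 crania (and
their mirrored copies — hence 506) converge in 4 GPA iterations; symmetric
shape variation spans 55 numerically non-zero components; log centroid size
predicts a significant 4.4% of shape variation; and the two species' growth
directions sit 50.8° apart — far closer than random directions in a
~55-dimensional shape space, hence the tiny p-value: the simulated
trajectories are truly similar by construction (the generator draws them 29°
from a shared axis), and the test recovers that.

The whole chain — including group Procrustes distances on both tracks, rank
tests by dietary category, and the phylogenetic-signal test on the packaged
four-species tree — runs end to end from one configuration:

```r
res <- run_study(default_config(scenario = "bear_like", seed = 1,
                                out_dir = "results_demo"))
```

which writes PC scores, distance tables with bracketed p-values, wireframe
extreme shapes, morphospace SVGs and a JSON manifest recording every seed.

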