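---
title: "Comparing ontogenetic trajectories in 3D landmark data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ontogenetic trajectories in 3D landmark data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphotraj)
```

# The analysis chain

`morphotraj` implements the inference chain used in comparative studies of
skull growth: several species, each sampled across an ontogenetic size range,
digitized as homologous 3D landmarks, and compared in a common shape space.
The stages are

1. **Validation and completion.** Landmark files (TPS or CSV dialects) are
   checked against a packaged template; landmarks missing from fossil
   material are estimated by thin-plate-spline (TPS) warping of a reference
   shape onto each incomplete specimen.
2. **Superimposition.** Generalized Procrustes analysis (GPA): all
   configurations are centered, scaled to unit centroid size, and iteratively
   rotated onto the consensus. For structures digitized on both body sides
   (the 36-landmark cranium template), each specimen is superimposed together
   with its reflected-and-relabeled copy and only the *symmetric component* —
   the average of the two aligned copies — enters the covariance analyses.
3. **Morphospace.** Principal component analysis of the covariance matrix of
   the superimposed coordinates, with equal-frequency confidence ellipses per
   group and linear "extreme shape" models along each axis.
4. **Allometry.** Multivariate linear regression of shape coordinates on log
   centroid size, pooled and within groups. The fitted coefficient vector is
   the ontogenetic trajectory direction; trajectory pairs are compared by the
   angle between their vectors against a null of independent uniformly random
   directions. The regression residuals (plus consensus) form the
   "non-allometric" (size-corrected) track.
5. **Group comparison.** Procrustes distances between group mean shapes with
   pairwise label-permutation tests, run on both the raw and the
   non-allometric track; canonical variates ordination and Mahalanobis
   distances as auxiliary output; Kruskal–Wallis rank tests with a mean-rank
   post-hoc rule across ecological (dietary) categories.
6. **Phylogenetic signal.** Per-species mean scores (adults only,
   size-corrected) are mapped onto a phylogeny by squared-change parsimony;
   the total squared change is compared against random reassignments of the
   species values to the tips.

# Statistical model and conventions

**Centroid size** is `sqrt(sum((x_i - centroid)^2))`; sizes are kept in the
units of digitization (mm) and their natural logarithm is the allometric
predictor. All statistics downstream of the regression are invariant to the
logarithm base, which only rescales the predictor.

**Partial Procrustes.** Scaling is fixed at unit centroid size (no
residual-minimizing size regression), reflections are disallowed in all
alignments, and the Procrustes distance between two shapes is the root
residual sum of squares after optimal rotation of unit-size shapes. GPA
convergence is declared when the relative change in total Procrustes sum of
squares falls below `1e-10` (cap: 100 iterations); the total is provably
non-increasing across iterations and convergence takes well under 20
iterations in all scenarios we generate.

**Permutation p-values** always use the add-one convention
`p = (b + 1) / (N + 1)`, so a p-value is never exactly zero and a zero
exceedance count reads as `p <= 1/(N+1)`. All permutation streams derive
from one master seed via named substreams, making every stage independently
reproducible. The phylogenetic test is special: with up to 8 tips it
enumerates every distinct assignment instead of sampling — with 4 species
only 24 assignments exist, so the attainable p-values are coarse (the
smallest is 1/24, or 2/24 when two tips share a branch length and tie), and
enumeration makes this exact rather than approximate.

**Trajectory-angle null.** Under the null the two directions are independent
and uniform on the unit sphere in a `d`-dimensional space; the cosine of
their angle satisfies `(cos θ + 1)/2 ~ Beta((d-1)/2, (d-1)/2)`, which is the
closed form of the integrated `sin^(d-2)` density and is evaluated directly
(`method = "analytic"`); a Monte-Carlo method is kept as a cross-check. The
p-value is one-sided toward similarity, `P(null angle <= observed)`, and
depends strongly on `d`. The default `d` is the numerical rank of the pooled
superimposed data: superimposition removes 7 degrees of freedom (3
translations, 3 rotations, scale) and the symmetry decomposition removes
more (for the 36-landmark cranium the symmetric subspace has
`14*3 + 8*2 - 4 = 54` dimensions), so using the raw coordinate count would
overstate the dimension and anti-conservatively shrink p.

**Kruskal–Wallis and post-hoc.** The H statistic with tie correction comes
from `stats::kruskal.test`; a fully tied response returns `H = 0` rather
than the indeterminate 0/0. The post-hoc rule is the normal-approximation
critical difference of mean ranks,
`|R_i - R_j| > z_{1-α/(g(g-1))} sqrt(N(N+1)/12 (1/n_i + 1/n_j))`,
the standard multiple-comparison rule for mean ranks.

**Squared-change parsimony.** Internal node values minimize
`sum_b ||child_b - parent_b||^2 / w_b` with `w_b` the branch length
(`given_lengths`) or 1 (`unit_lengths`); the minimizer solves a weighted
graph-Laplacian system, zero-length branches are contracted into hard
equality constraints, and the criterion is additive over trait dimensions
and invariant to rotations of the multivariate tip data. Both branch-length
schemes are computed and reported side by side, since either convention is
defensible for divergence-time trees.

# The synthetic-data generator

No raw landmark data accompany the study design we emulate, so the generator
is a first-class module with known ground truth rather than a test fixture.
Its latent model for a specimen of species *s* with drawn centroid size CS is

```
shape = mean_s + strength * v_s * (log CS - log CS_ref_s) + noise,
```

built in the unit-size shape space and then randomly rotated, translated and
scaled to CS. Species means are a shared symmetric base shape plus
tangent-space offsets; by default (`scenario_params("bear_like")`) the
offsets evolve by Brownian motion on the packaged four-species phylogeny, so
species differences carry phylogenetic structure. Defaults and their
rationale:

* **Group sizes** mirror the packaged study design table (253 crania, 183
  mandibles over four species and two age classes).
* **Centroid sizes** are log-uniform per age class: crania 150–300 mm
  (juvenile) and 300–450 mm (adult), mandibles 80–150 / 150–250 mm —
  plausible spans for medium-to-large ursids with roughly a 1.5-fold adult
  size range. Age classes are labelled by the generating group; since the
  class ranges do not overlap this is exactly a size threshold.
* **Landmark noise** `noise_sd = 0.01` Procrustes units per coordinate,
  applied in shape space *before* the rigid motion so the isotropy and
  small-variation assumptions of Procrustes statistics hold by construction;
  an optional post-rigid noise mode stresses that assumption deliberately.
  An optional `asymmetry_sd` perturbs only the left side of paired
  templates.
* **Allometry** `strength = 0.08` shape units per log size, i.e. about 0.09
  Procrustes distance across a juvenile-to-adult size span — a realistic
  magnitude for strong cranial ontogenetic allometry.
* **Trajectory spread** 29 degrees of each species' direction from the
  shared axis, which puts species pairs at roughly 40 degrees of each other —
  similar directions that are still distinguishable, matching the regime the
  trajectory-angle test is designed for.
* **Missing data**: 5% of landmarks masked in the fossil species' crania
  (at least 8 landmarks always retained).

What the generator does *not* emulate: realistic skull geometry (the base
shape is a smooth random symmetric configuration, not a bear), sexual
dimorphism, measurement structure beyond isotropic noise (no digitizer
drift, no landmark-specific error variance), and integration/modularity
among landmarks. Passing tests therefore demonstrate correctness of the
statistical machinery under its own assumptions, not robustness to every
pathology of real archaeological material.

# Exactness on the pre-shape sphere

One geometric subtlety deserves a note, because it determines how parameter
recovery is tested. GPA scales every configuration to unit centroid size, so
aligned shapes live on a sphere; a latent trajectory that is a straight line
in configuration space maps onto a *curve* on that sphere — a line can meet
the sphere in at most two points. Regression on the unit-size coordinates
therefore recovers a noiseless generating direction only approximately
(the bend contributes an angular error of order the squared trajectory
length; about 0.03 degrees at default settings).

The package's tangent-projection options resolve this exactly. The *central*
(gnomonic) projection divides each aligned shape by its inner product with
the consensus, mapping shapes onto the tangent hyperplane; a projective map
sends lines to lines, so the latent trajectory becomes exactly straight
again. Two further facts make noiseless recovery exact rather than merely
close: (i) generating directions are drawn orthogonal to the similarity
transformations at the mean (`tangent_direction()`), which makes every GPA
rotation exactly the identity in the latent frame; (ii) the recovered vector
is compared with the generating one *within the fitted tangent space*
(projecting the truth off the consensus direction, after rotating frames
with `transfer_frame()`), because the component along the consensus is not
part of shape variation. Under these conventions the noiseless recovery test
demands — and achieves — an angular error below `1e-6` radians, and with the
generator's balanced size design (`size_mode = "balanced"`, antithetic
log-size pairs) the regression predicts exactly 100% of the noiseless
variation. Routine analyses do not need any of this machinery and use the
raw Procrustes coordinates, the standard small-variation treatment; the
orthogonal projection variant is also available and makes the
`3k - 7` rank bound of superimposed data exact.

# Numerical choices

* **TPS kernel**: `U(r) = r`, the 3D biharmonic kernel, with a full affine
  term; the interpolation system is solved directly and re-solved with a
  ridge of `1e-10 x trace` on the kernel block if nearly singular (flagged on
  the result); exactly coplanar or coincident sources error. The
  missing-landmark reference defaults to the Procrustes consensus of all
  complete specimens, and incomplete specimens are aligned to the reference
  on their observed landmarks before warping, making estimation equivariant
  under rigid motion of the input.
* **PCA**: covariance (not correlation) matrix, divisor `n - 1`; components
  with eigenvalues below `1e-12` of the leading one are dropped; axis signs
  are fixed by making each axis' largest-magnitude loading positive, so
  scores are deterministic across platforms (PC signs carry no meaning).
* **Ellipses** are equal-frequency data ellipses (chi-square quantile, 2 df)
  — they enclose specimen scatter, not the standard error of the mean.
* **Group means** for distance tests are arithmetic means of aligned
  coordinates re-standardized to unit centroid size, consistent with the
  tangent-space linearity used throughout; pairwise tests permute only the
  two groups' labels, and no multiple-testing correction is applied across
  the pairwise table by default (a Holm/Bonferroni option exists in
  `stats::p.adjust` form downstream of the returned matrices).
* **CVA** retains the leading PCs explaining 95% of variance (capped at
  `n - groups - 1`) so the pooled within-group covariance is invertible;
  Mahalanobis distances are invariant to any invertible linear transform of
  the retained scores, which the tests verify.

# Open design points, resolved

* Whether left/right averaging happens before or within the reflection
  procedure is ambiguous in verbal descriptions of object symmetry; we
  implement the standard reflect–relabel–average procedure (the two readings
  agree up to the alignment of the reflected copies).
* The reference shape for missing-landmark estimation is exposed as a
  parameter (`grand_mean_complete` default, or any explicit shape), since
  TPS-based completion is well defined for either choice.
* Per-species regressions are computed on the joint superimposition (a
  shared shape space) rather than per-species GPAs; this keeps trajectory
  vectors directly comparable and is the default in comparable software.
* Branch lengths for the packaged example tree are approximate divergence
  times (millions of years) supplied as data, not estimates; the
  unit-branch-length mode needs no external information.
* Dietary categories used by the rank-test stage are configuration data
  (`diet_map`), not code.

# Problem sizes

The test suite exercises the chain at sizes chosen to make every statistical
property measurable while keeping the default run fast: full study-shaped
runs (253 crania / 183 mandibles) for the end-to-end checks with 499
permutations; 500 replicate null simulations at n = 20 specimens and 99
permutations for type-I-error calibration; 100-150 replicates for the
distance- and signal-test calibrations; Monte-Carlo cross-checks of the
angle null at 1e5 samples in dimensions 3–101. The acceptance script runs
the full scenario with 10,000 permutations, the count conventional for
permutation tests of this kind.

# Known limitations

* Semilandmarks, sliding, and resistant-fit superimposition are out of
  scope; so are MANCOVA-style common-slope tests and growth-curve models
  over chronological age.
* The trajectory-angle null treats the two directions as fully random; it
  does not condition on the estimation error of the regression vectors, so
  with very noisy vectors the angle itself is inflated (the test remains
  valid, only conservative for similarity).
* With four species the phylogenetic permutation test cannot produce
  p-values below 1/24 regardless of effect size.
* The CVA stage is ordination output only; classification rates are not
  computed.
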