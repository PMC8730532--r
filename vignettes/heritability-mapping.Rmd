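---
title: "Voxelwise heritability mapping and region extraction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelwise heritability mapping and region extraction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model, the numerical choices, and
the design decisions behind `herimap`, at the level a user needs to judge
what the package does and does not establish.

## The variance-component model

Each quantitative trait (a voxel's intensity, or a region average) is
modelled as

$$y = X\beta + g + \varepsilon, \qquad
g \sim N(0, \sigma_g^2 A), \quad \varepsilon \sim N(0, \sigma_e^2 I),$$

with $A = WW'/M$ the genetic relationship matrix (GRM) over $M$ standardized
dosages, $w_{ij} = (x_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$. Allele frequencies
are estimated from the sample itself (the usual default when no reference
panel is given); missing dosages pass through QC untouched and are
mean-imputed — standardized value 0 — only here. SNP heritability is
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$.

Covariates (intercept, age, sex, and the top 10 eigenvectors of the GRM as
population-structure proxies) are projected out *inside* the REML
likelihood, not pre-residualized, so fixed-effect uncertainty is handled by
the restricted likelihood itself. The PCs come from the GRM
eigendecomposition rather than a genotype SVD; with the same standardized
$W$ the two differ only by eigenvalue scaling.

## REML: likelihood, optimizer, inference

The restricted log-likelihood is
$-\tfrac12(\log|V| + \log|X'V^{-1}X| + y'Py)$ with
$V = \sigma_g^2 A + \sigma_e^2 I$; the additive constant
$-\tfrac{n-c}{2}\log 2\pi$ is dropped. The convention cancels in every
likelihood *difference*, which is all the package reports. Two
implementations coexist deliberately: a dense reference (`restricted_loglik`,
Cholesky-based) and the production path that rotates everything once into
the eigenbasis of $A$, where $V$ is diagonal. The rotation is what makes
voxelwise mapping cheap: `fit_reml_batch` eigendecomposes $A$ once and fits
thousands of traits at $O(NC^2)$ per iteration each. A test asserts the two
paths agree to $10^{-8}$.

Optimization: each component is constrained to at least
$10^{-6}\,\mathrm{Var}(y)$ (the conventional GREML floor; fits of
non-heritable traits report $h^2 \approx 10^{-6}$). Three EM-REML warm-up
iterations precede average-information updates; any proposal is step-halved
toward the current point until the likelihood does not decrease, and if no
fraction of the step improves it the fit falls back to an EM step, then
declares a (possibly boundary) optimum. Convergence is
$|\Delta \ell| < 10^{-8}$, at most 100 iterations.

Inference: the null model fixes $\sigma_g^2 = 0$ and has the closed form
$\hat\sigma_e^2 = \mathrm{RSS}/(n-c)$. Because the null lies on the boundary
of the parameter space, the LRT is referred to the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$: $p = \tfrac12 P(\chi^2_1 \ge
\mathrm{LRT})$, hence $p = 0.5$ exactly for a fit on the floor. An LRT below
the convergence tolerance is reported as 0, since differences smaller than
the optimizer's own resolution are not meaningful. The standard error of
$\hat h^2$ comes from the delta method on the inverse AI matrix; when a
component is constrained the SE is still reported but unreliable (the
`constrained` flag says so).

Two properties of boundary REML are worth knowing when reading results.
First, under a truly non-heritable trait the unconstrained optimum is
interior with probability about one half (the $\chi^2$ mixture), so roughly
half of null fits report a small positive $h^2$ rather than the floor — the
package's replicate tests measure about 60 % of null fits on the floor at
$N = 400$. Second, $\hat h^2$ of a null trait is therefore positively biased
even though the *test* retains its nominal behaviour.

## Spatial stage

The per-voxel p-values are mapped into the 3D grid (background fill 1, so
smoothing near mask edges dilutes toward insignificance rather than creating
spurious borders), smoothed with a separable Gaussian kernel of σ = 0.5
voxels, truncated at 4σ (radius $\lfloor 4\sigma + 0.5\rfloor$ voxels),
reflect boundary (edge value repeated). Smoothing runs over the *full*
array, background included. The smoothed map is thresholded at α = 0.05;
candidates are ranked by smoothed p (ascending for the significant arm,
descending for the insignificant arm), the top
$\lceil f \cdot |\mathrm{candidates}|\rceil$ kept for each fraction
$f \in \{0.1, 0.2, 0.3, 1\}$ (significant) or $\{0.1, 0.2, 0.3\}$
(insignificant), ties at the cut broken by lexicographic coordinate.
Smoothing precedes selection, and ranking uses smoothed p-values — the
pipeline's single ordering of operations; raw-p ranking exists behind a
flag. Connected components use 26-connectivity by default (6 and 18
available), labels assigned in lexicographic first-encounter order. No
minimum region size is imposed by default (`min_voxels` exists for practical
use). Region QTs are unweighted member-voxel means; atlas labels are
intersected with the analysis mask, and voxels outside the mask never enter
an atlas average.

One numerical caveat the tests quantify: the discrete sampled kernel at
σ = 0.5 is coarse, so the Gaussian semigroup identity (twice σ equals once
σ√2) holds only to a few percent at that width; the identity is verified to
$10^{-3}$ at σ = 2, where sampling error drops below truncation error.

## The synthetic study and what it shows

The generator's defaults define the study conditions used everywhere:

* **Genotypes** — $N = 400$ subjects in 50 family blocks of 8 full siblings,
  $M = 2000$ independent biallelic variants, MAF uniform on $[0.05, 0.5]$.
  Within a block, dosages are drawn from two shared parental haplotype pairs,
  giving expected within-block relatedness 0.5. Family structure widens the
  GRM spectrum so that desk-scale variance-component estimation is well
  conditioned — a test-design choice, not a claim about any real cohort;
  population cohorts are closer to the unrelated limit, where sampling
  variance of $\hat h^2$ is far larger at this $N$.
* **Phenotypes** — a 16³ grid with a centred spherical mask of radius 7.5
  voxels (voxels outside it are exactly 0 for all subjects, exercising
  background filtering). Two spherical blobs of radius 3 (123 voxels each,
  centres (5,5,5) and (10,10,10), comfortably inside the mask and apart)
  carry true $h^2 = 0.8$ and $0.6$; the background is non-heritable. Each
  voxel follows $y_v = \beta_a\,\mathrm{age} + \beta_s\,\mathrm{sex} +
  \sqrt{h^2_v}\,g + \sqrt{1-h^2_v}\,e_v$ with $g = Lz$ ($LL' = A$, eigenvalues
  clipped at 0 if numerically negative), $z$ shared within a blob, and both
  parts rescaled to unit sample variance. Sharing $z$ makes the blob-average
  QT strictly more heritable than its member voxels — the aggregation
  behaviour region extraction is meant to exploit. Ages are
  $N(76.9, 7.5^2)$, sex balanced, with small fixed effects (0.01/yr, 0.1),
  emulating an elderly imaging cohort. Blob radius 3 was chosen as the
  smallest sphere that remains clearly super-voxel against a 16³ grid while
  two of them fit disjointly inside the mask.
* **Atlas** — a seeded Voronoi partition of the mask into contiguous labels.

All simulators consume randomness only through their design seed and restore
the caller's RNG stream, so reruns are byte-identical and the pipeline
itself is fully deterministic.

What passing tests show — and what they do not. The end-to-end tests show
the pipeline separates heritable from non-heritable tissue sharply: every
significant-arm region estimate exceeds every insignificant-arm estimate,
and the summary reproduces the all-or-nothing contrast between the two arms.
They do not show robustness to LD structure, population stratification
beyond PC-adjustable block effects, registration error, or PET noise
physics, none of which the generator emulates.

Two measured behaviours sit at the edge of their nominal targets and are
reported as such rather than hidden. (1) Smoothing a p-value map before
thresholding erodes the surface of small clusters: for radius-3 blobs about
40 % of surface voxels lose significance, so the Dice overlap between the
recovered region and the true blob plateaus around 0.67–0.74 across seeds —
occasionally under a 0.7 target. Larger structures erode proportionally
less. (2) As noted above, only ~60 % of true-null fits land on the variance
floor; this is intrinsic to boundary REML, not an optimizer failure (the
grid-search oracle test pins the optimizer itself to within one grid step).

## Problem sizes

The default test and acceptance runs use the design above (≈ 1 790 in-mask
voxels, 400 subjects), 50 replicate fits for recovery, 25 random volumes for
the component-labeling oracle, and 5 fixtures of $N = 40$ for the
grid-search oracle — sizes chosen so the whole suite completes in a few
minutes on one CPU while keeping every estimate's Monte-Carlo error well
inside the asserted tolerances.

## Known limitations

* Single genetic variance component: no partitioned or bivariate models,
  no GxE.
* Mean imputation only; multi-allelic variants and VCF input are out of
  scope (PLINK triples and dosage tables are the interfaces).
* Relatedness pruning is a simplified greedy GRM rule (off by default), not
  full identity-by-descent estimation; heterozygosity outlier removal is a
  plain 3-SD rule (off by default).
* The world-space affine of NIfTI inputs is carried through untouched;
  all computation is in voxel coordinates.
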