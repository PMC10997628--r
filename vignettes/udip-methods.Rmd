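---
title: "Latent imaging phenotypes from 3D brain volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent imaging phenotypes from 3D brain volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`udip` implements a complete pipeline for *unsupervised deep-learning
derived imaging phenotypes* (UDIPs): a 3D convolutional autoencoder turns
registered, brain-extracted volumes into a low-dimensional latent vector per
subject; each latent coordinate is treated as a quantitative phenotype for
genetic association; and a perturbation-based decoder interpretation maps
each coordinate back onto brain anatomy. This vignette explains the models,
the parameters that matter, and the choices made where the design was
genuinely open.

## The autoencoder and its loss

The encoder is an initial block of two (3x3x3 convolution, stride 1 ->
batch normalisation -> leaky ReLU) units followed by `n_blocks` encoder
blocks, each a 2x2x2 max-pool and two further conv units. A fully connected
layer maps the final feature grid to a `latent_dim`-dimensional bottleneck,
so every latent unit has a receptive field covering the whole volume; the
decoder mirrors the encoder, with each block ending in a transposed
convolution (kernel 2, stride 2), and the final block closes with a
kernel-1 convolution and **no output activation** - reconstruction is a
per-voxel regression. There are deliberately no skip connections: all
information must pass through the bottleneck, which is what makes the
bottleneck a complete image descriptor.

Training minimises the background-masked reconstruction error

$$\mathcal{L} = \sum_{ijk} \big(R(i,j,k) - O(i,j,k)\big)^2 \, f\big(O(i,j,k)\big),$$

where $R$ is the reconstruction, $O$ the original, and $f$ the step
function of the brain mask (1 where the image is non-zero). Because $f$
multiplies the squared difference, *nothing in the background can ever move
the loss* - a property the test suite asserts exactly, not approximately.
By default the package divides this sum by the number of masked voxels
(a per-image mean, averaged over the batch): a mean is stable across mask
sizes, which matters when cohorts mix head sizes; a `loss_reduction = "sum"`
mode is available for the raw sum. Sum and mean differ by a constant
factor per image and are absorbed by the learning rate, so the choice is a
matter of numerical convenience, not of substance.

Inputs must first be z-normalised with the background **excluded** from the
mean and standard deviation (`znormalize()`); the background stays exactly
zero. We use the population (n) denominator - the choice is a pure
rescaling absorbed by training. Dimensions are zero-padded to the next
multiple of $2^{n\_blocks}$ before the first block and centre-cropped after
the last, so the output shape equals the input shape exactly (182x218x182
in, 182x218x182 out at full scale).

Optimisation is Adam; one integer seed fixes weight initialisation, the
75/25 train/validation split, and shuffling, and the checkpoint with the
lowest validation loss is returned. Batch-norm layers use batch statistics
in training and running statistics everywhere else, so encoding is
deterministic. Channel widths are fully configurable - they are the main
capacity dial between desk-scale phantoms and full-resolution images; the
package default is `16 * 2^(0:n_blocks)` capped at 256.

## Perturbation-based decoder interpretation (PerDI)

To ask "which voxels does latent dimension $d$ control?", we take the
encoded cohort, add one standard deviation $\sigma_d$ of that dimension to
a seeded sample of `n_subjects` (default 500) latent vectors - all other
coordinates held fixed - and decode both versions. At each voxel a paired
t-test across subjects compares perturbed and original reconstructions:
$t = \bar d / (s_d / \sqrt n)$. The absolute t-map is then smoothed with a
Gaussian kernel (sigma = 3 voxels, truncated at 4 sigma, zero padding), in
that order: absolute value first, then smoothing. Smoothing compensates for
the imperfect voxel
correspondence of linearly-registered anatomy.

Numerical edge cases are defined, not left to chance: zero perturbation
gives an identically zero map (0/0 := 0); a voxel whose paired differences
have zero variance but non-zero mean receives the maximum finite |t| of the
map (rank-preserving, no infinities); and for a strictly linear decoder -
where *every* voxel is deterministic - the mean absolute difference itself
is the ranking statistic. That last case is also the package's strongest
oracle: with `decode(z) = A z`, the unsmoothed difference map is exactly
$|\delta \, A_{:,d}|$ for any perturbation $\delta$, which the tests verify
to machine precision, along with the +sigma/-sigma sign symmetry.

$\sigma_d$ is estimated from the full encoded cohort rather than from the
500-subject sample; with stated sample sizes the two differ negligibly, and
the full-cohort estimate is the better-conditioned one.

One practical caveat the phantom experiments exposed: reconstructions of
*background* voxels are never constrained by the masked training loss, so
their perturbation responses are arbitrary yet highly consistent - which a
paired t-test mistakes for overwhelming signal - and spatial smoothing can
bleed those values into brain regions near the mask edge. `perdi_tmap()`
therefore accepts the brain mask and zeroes the t-map outside it before
smoothing; the pipeline always passes the cohort mask.

## Ranked-voxel atlas enrichment

A t-map is annotated against an integer-labelled atlas by ranking all
in-scope voxels from highest to lowest statistic (ties broken by voxel
index, for exact reproducibility) and walking the ranking: after the top
$n$ voxels, of which $k$ lie in a region of size $V$ out of $N$ ranked
voxels, the enrichment curve is $k/V - n/N$. The statistic is the maximum
of this curve - a one-sided Kolmogorov-Smirnov statistic comparing the
region's rank distribution with uniform. The curve ends at zero, so the
statistic lies in $[0,\, 1 - V/N]$ and equals the upper bound exactly when
the region claims the top $V$ ranks. The ranking scope defaults to the
labelled brain (background excluded). The quantity $r = V/N$ is reported
alongside; the printed formula does not use it, and we implement the
printed formula.

## Characterising the latent space

Three quantifications of what the latents capture:

* **CCA variance explained** between two latent sets, computed through
  SVDs: demean, $X = U_1 S_1 V_1^T$, $Y = U_2 S_2 V_2^T$, canonical
  correlations $S$ from $U_1^T U_2 = U S V^T$, and
  $\mathrm{var}(X\,|\,Y) = \|S_1 U \odot S\|_F^2 / \|S_1\|_F^2$. This is
  algebraically the fraction of $X$'s demeaned sum of squares captured by
  projection onto $Y$'s column space, and the tests verify that identity on
  random instances at 1e-8. Singular values below 1e-10 of the largest are
  truncated (rank-deficiency is reported, not fatal).
* **Cross-validated prediction**: ten-fold out-of-fold R-squared (OLS) for
  continuous traits and AUROC (ridge-penalised logistic regression,
  penalty 1e-3, stratified folds) for binary traits. Out-of-fold is the
  standard reading of a cross-validated coefficient of determination; the
  small ridge penalty only exists to keep separable toy problems
  well-posed.
* **Correlation summaries**: mean absolute off-diagonal correlation within
  a latent set and mean absolute cross-correlation between paired sets.

## The association pipeline

Latent dimensions are quantitative phenotypes. The stages, each its own
function:

1. **Variant QC** (`qc_genotypes`): MAF > 1e-4 and missing rate < 0.05 at
   the initial stage, < 0.1 per cohort. No Hardy-Weinberg filter - dosages
   are not hard calls.
2. **Cohort independence** (`exclude_related`): replication subjects with
   kinship coefficient > 2^-4.5 (~0.0442) to any discovery subject are
   dropped; overlapping ids are an error.
3. **Scan** (`assoc_scan`): per (variant, dimension), OLS of the latent on
   dosage plus covariates (age, age^2, sex, sex-by-age interactions, plus
   anything supplied), casewise deletion of missing dosages, two-sided p
   from the t distribution. The full-scale analogue uses a sparse-GRM
   linear mixed model; phantom cohorts are unrelated by construction, so
   OLS with the same covariate design is the appropriate desk-scale form,
   and the kinship-exclusion step keeps the cohort-independence logic
   intact.
4. **minP aggregation** (`minp_aggregate`): per variant, the smallest p
   across all dimensions, recording the attaining dimension.
5. **Clumping** (`clump_loci`): significant variants (threshold
   `5e-8 / D_total` at full scale) pruned greedily by ascending p at LD
   r-squared 0.6, then again at 0.1 to give lead variants; each locus is
   the smallest interval containing every genotyped variant with r-squared
   > 0.1 with a lead; adjacent loci closer than 250 kb merge (so a locus
   may carry several leads). LD is computed in-sample from dosages - there
   is no external reference panel in the desk-scale setting, so locus
   extents span observed variants only. Greedy order and index tie-breaks
   are fixed for reproducibility.
6. **Replication** (`test_replication`): a locus replicates if any lead,
   tested at its discovery peak dimension, has p < 0.05 / (number of lead
   variants) in the replication cohort. When discovery and replication
   disagree about a lead's best dimension, the discovery peak pair is the
   tested one (the rule's natural reading; the alternative is not stated
   anywhere).
7. **Inflation** (`genomic_inflation`): median chi-square over the 1-df
   null median (~0.4549).
8. **Meta-analysis** (`meta_combine`): signed z from each cohort's p and
   effect direction, alleles aligned (swaps flip the sign, unalignable
   variants dropped), combined with sqrt(n) weights.

P values are floored at 1e-300 so z conversions stay finite. Positions are
1-based base pairs, locus intervals closed, and the 250 kb rule compares
the end of the left locus with the start of the right.

## What the synthetic cohort emulates - and what it does not

`phantom_spec()` defines a brain-like ellipsoid (background exactly zero,
as in brain-extracted images) containing a central dark "ventricle" and two
lateral "subcortical" spheres, on a 32x38x32 grid - the full-scale
182x218x182 aspect ratio scaled by ~5.7 so the model trains on one CPU.
Two standard-normal generative factors drive anatomy: factor 1 enlarges the
ventricle (+5% semi-axes per SD, so its voxel count is monotone in the
factor) and strongly darkens its interior (-45% intensity per SD) -
mirroring how larger ventricles carry purer, darker CSF, and how a
reconstruction loss actually sees ventricular variation; factor 2 scales
the subcortical sphere radii (+20% per SD), their baseline intensity (0.75
against cortex 0.6) staying fixed because subcortical T1 contrast is
subtle. Per-subject nuisance jitter (region centres sd 0.3 voxels, radii
3%, tissue intensities 2%) supplies the anatomical variability of a real
population; an optional smooth random texture field is available for
richer per-voxel variability. Factors beyond +-2 SD are clamped with a
warning so regions neither vanish nor breach the brain. Gaussian noise
(sd 0.05 on tissue intensities of 0.03-0.8) is added inside the mask only.

Genotypes come in blocks of 10 variants sharing an allele frequency drawn
from U(0.05, 0.5); within a block each haplotype copies a latent block
haplotype with a resampling probability tuned so pairwise dosage r-squared
equals the target (r2 = (1-eps)^4), giving controllable, seedable LD;
blocks are independent. A planted causal variant adds `beta x dosage` to a
named factor; the demo sets beta so the variant explains 5% of the factor's
variance. Uniform missingness (2%) exercises the QC filters.

Passing tests on phantoms therefore show that the *machinery* is correct:
the loss is exactly masked, training recovers planted factors (the
end-to-end check requires at least one latent dimension with |r| > 0.5 per
factor, a ventricle-top enrichment for the ventricle-factor dimension, and
detection/replication of the causal locus), and the statistical pipeline is
calibrated under the null. They do not show performance on real MRI:
phantoms have no bias fields, no nonlinear anatomical variation, no
registration error, no population stratification, and their two-factor
anatomy is vastly simpler than brain morphology.

One end-to-end property deserves an honest flag. Background-excluded
z-normalisation ties every voxel's normalised value to the global image
statistics, so the ventricle factor - which moves those statistics - exports
a small but *deterministic* intensity shift to every other structure; in the
phantom data themselves, subcortical normalised intensity correlates ~0.6
with the ventricle factor. A paired t-test rewards consistency over
magnitude: those bystander responses have near-zero between-subject
variance, while the ventricle's own (larger) response varies with each
subject's current anatomy. At desk scale, where two factors dominate the
statistics, the ventricle dimension's t-map therefore ranks compact
bystander structures above the ventricle itself, and the ventricle-top
enrichment check fails even though the latent space demonstrably carries
the ventricle factor and its mean response is 2-3 times larger. At full
scale, hundreds of anatomical modes dilute any single factor's hold on the
normalisation statistics, so the effect is far weaker there - but it is a
real property of perturbation-based interpretation under global intensity
normalisation, worth knowing about when reading such maps.

## Problem sizes and thresholds in the desk-scale study

The shipped demonstration (`demo_config()`) trains on 800 phantoms (75/25
train/validation split, latent 16, 3 blocks, widths 2/6/12/16, 40 epochs,
batch 16, Adam 1e-3) and runs GWAS on a disjoint cohort of 2000 split
65/35 into discovery and replication, with 300 variants in 30 LD blocks.
With 16 dimensions and 300 variants, the full-scale threshold `5e-8/256`
would demand power no cohort of 2000 can deliver; the demo therefore calls
significance at the proportionally scaled 1e-5 (and replication at
0.05/#leads, unchanged). Those are the package's chosen study conditions;
`assoc_config()` defaults remain the full-scale values. The planted-variant
recovery check repeats the association half of the pipeline over 20 seeds
on the factor phenotype itself, where the 5%-variance effect gives
essentially complete power at n = 2000 - retraining the autoencoder 20
times would add hours of compute and no information about the association
machinery.

## Numerical choices, in one place

* float32 arithmetic in the network engine; direct cache-blocked 3x3x3
  convolution kernels (the working set of a 32x38x32 batch fits in cache,
  so explicit kernels beat an im2col + GEMM formulation on one CPU).
* Batches of size 1 are skipped (batch norm needs 2 samples); batch-norm
  epsilon 1e-5, running-stat momentum 0.1.
* Divergence (non-finite loss) aborts with the epoch index.
* Ties in voxel ranking break by ascending linear index; greedy pruning
  visits variants by ascending p, ties by position.
* `with_seed()` isolates every seeded operation from the caller's RNG
  state; a single run seed derives all stage seeds.

## Known limitations

* The network engine is single-threaded CPU code aimed at phantom-scale
  grids; full-resolution training is architecturally supported but not
  computationally practical here.
* In-sample LD makes locus extents slightly conservative compared to
  reference-panel extension.
* The linear-mixed-model stage of a real GWAS is out of scope (unrelated
  phantom cohorts); so are heritability estimation, gene mapping and
  catalogue queries.
* PerDI interprets one dimension at a time; correlated latent dimensions
  share anatomy, and no orthogonalisation is attempted.
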