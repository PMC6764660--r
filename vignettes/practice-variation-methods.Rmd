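---
title: "Voxelwise statistics for practice variation in brain tumor surgery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelwise statistics for practice variation in brain tumor surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectvox)
```

## The problem

When two neurosurgical teams resect glioblastomas, they may
systematically differ in *where* they stop: one team may routinely spare
a region that the other resects. Resection probability maps make such
practice variation visible by registering every patient's pre-operative
tumor mask and post-operative residue mask to a common atlas and
aggregating, per voxel, how often tumor at that location was left behind.

The statistical difficulty is that the data are doubly discrete: at a
voxel, the residue outcome is only observed for patients whose tumor
covered that voxel, so the number of "trials" varies from voxel to voxel
and is often very small. Voxelwise tests must therefore be discrete-data
tests, and any false-discovery-rate (FDR) machinery has to cope with a
different null distribution at every voxel.

`resectvox` implements three approaches to this problem, together with a
synthetic generative model for benchmarking them against a known ground
truth.

## Data model

For cohorts A and B, each voxel has the 2x2 contingency data

|            | A             | B             | total     |
|------------|---------------|---------------|-----------|
| residue    | $r_A$         | $r_B$         | $r$       |
| no residue | $t_A - r_A$   | $t_B - r_B$   | $t - r$   |
| tumors     | $t_A$         | $t_B$         | $t$       |

built by `aggregate_counts()` from per-patient binary masks
(`load_clinical_cohort()` for NIfTI cohorts, `simulate_cohorts()` for
synthetic ones). `downsample_mask()` sub-samples masks by an integer
factor; a coarse voxel is set when at least 50% of its fine voxels are
set (a `"majority"` rule, chosen so mask volume is preserved in
expectation; an `"any"` rule is available). Masks are sub-sampled per
patient *before* aggregation, because all three statistics are defined on
per-patient binary events.

## Method 1: permutation test on risk-minus values

The statistic is the absolute difference of residue proportions,
$|r_A/t_A - r_B/t_B|$, kept as an exact rational so that, e.g., $1/2$
arising at a two-tumor voxel and $2/4$ at a four-tumor voxel pool into
the same histogram bin. Only voxels with $t_A + t_B \ge 6$ are tested
(`min_tumors`, after the original analyses), and a voxel needs both
cohorts observed for the statistic to exist.

Patients are relabeled between cohorts (1000 random relabelings
preserving cohort sizes, sampled with replacement rather than
enumerated), counts re-aggregated, and the statistic pooled over all
tested voxels and relabelings into one null histogram. Voxel-relabeling
pairs where a shuffled cohort has no tumors at the voxel contribute no
mass, mirroring the statistic's domain. The p-value is the cumulative
tail $\Pr(\text{null} \ge \text{observed})$ with ties counted in the
tail (the conservative reading of a cumulative lookup). q-values divide
the expected false declarations $p \cdot N$ by the number of voxels
declared at that p, are clamped to $[0,1]$ and made monotone in $p$ by a
running minimum from the largest p downward — without that
regularization the raw ratios are not usable as a thresholding function.

## Method 2: Fisher's exact test with an exact pooled null

Conditioning on a voxel's marginals $(t_A, t_B, r)$, the cohort-A
residue count follows the hypergeometric distribution under the null.
The two-sided p-value doubles the smaller (inclusive) tail in the
following precise sense: probabilities on the opposing side that are
*strictly smaller* than the observed one are added walking inward from
the opposing extreme, stopping just before the total would exceed twice
the one-sided p. Strictness matters and differs from the more common
minimum-likelihood convention; floating-point comparisons treat values
within a relative $10^{-12}$ as equal (hence not smaller), so that exact
rational ties are honored. Tail sums use `dhyper` and the budget
comparison carries a relative $10^{-9}$ slack, adequate for the voxel
counts encountered here (tables of at most a few hundred patients).

The multiplicity correction is an *exact null histogram*: every
attainable $r_A$ at every tested voxel contributes its hypergeometric
probability as mass at the p-value it would produce
(`exact_null_histogram()`; keys pooled after rounding to 12 significant
digits). With $F_0(p)$ the expected null count at threshold $p$,
$f_0 = F_0(p)/N$, $i$ the observed number of declared voxels and $N$ the
number of tested voxels, the FDR estimate solves to

$$q = \frac{f_0}{1 - f_0}\cdot\frac{N - i}{i},$$

clamped to $[0,1]$ (with $f_0 = 1$ giving $q = 1$) and monotonized as
above.

Voxels whose hypergeometric support is a single point ($r = 0$, $r = t$,
or a cohort with no tumors) carry no information under fixed marginals.
The pipeline reports them with $p = q = 1$ but keeps them out of the
null histogram and out of $N$: with that convention their inclusion or
exclusion leaves every other voxel's q-value exactly unchanged, which is
the behavior one wants from non-informative voxels. (The
`exact_null_histogram()` *function* itself processes whatever tables it
is given — a degenerate voxel contributes unit mass at $p = 1$ — so the
choice lives in the fitting pipeline, not in the primitive.)

By default the Fisher method tests every voxel with $t_A + t_B \ge 1$;
the 6-tumor filter of the permutation method is available through
`min_tumors` but is not applied, since the exact conditioning already
accounts for small counts.

## Method 3: hierarchical Bayesian partial pooling

`fit_bayes_pooling()` treats the per-voxel resection outcome of each
cohort as a binomial trial with success rate $\theta_{k,v}$ (success =
resection, i.e. $t - r$ successes out of $t$), and pools voxels through
a cohort-level population on the logit scale:

$$\mathrm{logit}\,\theta_{k,v} = \mu_k + \sigma_k\,\eta_{k,v},\qquad
  \eta_{k,v}\sim N(0,1),\ \mu_k \sim N(0,1),\ \sigma_k \sim N^+(0,1).$$

The non-centered parameterization of the voxel effects aids sampler
convergence. The location prior is the vague $N(0,1)$; the scale prior
family is not pinned down by the source description, and the half-normal
$N^+(0,1)$ is used as the standard weakly-informative choice. Whether
the population parameters are shared between cohorts is likewise open;
they are cohort-specific by default (the statistic contrasts the
cohorts), with `shared_population = TRUE` available.

Sampling runs 4 chains of 500 MCMC iterations, discarding the first half
as burn-in, retaining 1000 posterior draws, via JAGS (with a short
adaptation phase before burn-in, a sampler-tuning detail). Split R-hat
for $\mu$ and $\sigma$ is reported and a warning raised above 1.05.
Every voxel with $t_A + t_B \ge 1$ enters the model; voxels observed in
only one cohort still draw a $\theta$ for the other cohort from the
population. Non-informative voxels are deliberately *included*: unlike
in the Fisher method they inform $\mu$ and $\sigma$ and improve the
model.

The per-voxel evidence score is the probability level of the largest
credible interval of $\delta_v = \theta_{A,v} - \theta_{B,v}$, centered
within the posterior, that excludes zero. On sample ranks this is
$1 - 2\min(\Pr(\delta<0), \Pr(\delta>0))$, with draws exactly at zero
split evenly — the equal-tailed reading of a centered interval. For
skewed posteriors a highest-density variant is available
(`hdi = "highest-density"`); for the roughly symmetric posteriors seen
here the two agree closely.

## The synthetic generative model

`simulate_cohorts()` implements the spheres model: a spherical brain of
radius 74 mm (at 1 mm resolution, about 1.7 million voxel centers — the
size of a standard atlas brain mask; a voxel belongs to a sphere iff its
center does, and the grid origin is the brain center); per patient a
spherical tumor (default 8 cm diameter) centered uniformly over
brain-interior voxel centers; a spherical resection cavity centered
uniformly over the (brain-cropped) tumor's voxel centers, with radius
chosen so the cavity covers the target extent of resection (default 60%)
of the realized tumor volume — leaving a crescent residue; tumor and
residue cropped to the brain. The cavity radius is computed exactly as
the $k$-th smallest voxel-center distance with
$k = \lceil \mathrm{EOR}\cdot n_\mathrm{tumor}\rceil$, i.e. the smallest
radius covering at least the target fraction (a closed-form equivalent
of a bisection search, exact on the voxel grid).

A spherical surgical-avoidance region (default 4 cm diameter), fixed in
atlas space and identical across patients, models the practice
difference: with per-patient probability $\Pr(\mathrm{avoid}_k)$
(defaults 0 for A, 1 for B) the region is subtracted from the *planned*
cavity before it is applied, so all tumor inside it is left behind for
that patient. Avoidance is a per-patient Bernoulli draw — the whole
region is either spared or not — matching the mechanic of removing the
region from the cavity sphere. The region's position is not prescribed
by the source description; it is placed 30 mm from the brain center
along $+x$ (well inside the brain, frequently overlapped by tumors) and
is configurable.

Cohort repetition $j$ of a benchmark uses seed $\mathrm{base} + j$, so
individual repetitions are independently reproducible.

### Generation grid versus analysis grid

The reference model is defined on the 1 mm grid, while benchmarking
statistics are computed on a 4 mm grid. These two resolutions are
coupled by per-patient majority-rule sub-sampling, and the distinction
is *not* cosmetic: a 4 mm voxel straddling the avoidance-region boundary
mixes avoided and resected 1 mm voxels, and the majority rule turns that
mixture into label noise at exactly the voxels that decide detection
performance. Generating directly on the 4 mm grid removes this
partial-volume noise and measurably inflates benchmark AUCs (the effect
is strongest in hard settings, e.g. small cohorts). `sim_config()`
therefore separates `voxel_size_mm` (generation) from
`analysis_voxel_size_mm`, and the benchmarking conditions used
throughout the package's tests and reproduction script are generation at
1 mm with analysis at 4 mm.

## Benchmark harness

`run_benchmark()` repeats simulate → aggregate → fit → score. Ground
truth is the avoidance sphere on the analysis grid restricted to tested
voxels; untested voxels never enter any curve. Scores are q-values
(small = detection) or HDI levels (large = detection); ROC and
precision-recall curves group tied scores and the AUC is the trapezoid
area, identical under score negation with flipped direction. The
observed FDR at a cut-off is the fraction of declared voxels outside the
truth, undefined when nothing is declared. Cut-off grids use the unique
observed scores for per-fit curves and a fixed grid (step 0.02) for
cross-repetition aggregation; AUC is aggregated as the mean of
per-repetition AUCs (a pooled-over-repetitions AUC is also reported),
with 2.5/50/97.5 percentile bands across repetitions.

Problem sizes used by the shipped tests and the reproduction script:
50 repetitions for Fisher benchmarks and parameter variations, 20–50
repetitions at 1000 permutations for the permutation method. The
per-repetition AUC distribution is strongly left-skewed — most
repetitions score near 0.99 while occasional unlucky tumor
configurations score near 0.5 — so mean AUCs carry a sampling standard
error of roughly 0.02 at 50 repetitions; tolerances in the tests account
for that. The full-brain Bayesian benchmark at 4 mm (about 26k voxels
per fit, times many repetitions) is beyond a sensible single-machine
budget; the Bayesian method is instead validated by exact unit tests of
the HDI statistic, posterior recovery on model-simulated data, and a
half-scale smoke benchmark (37 mm brain, 4 cm tumors, 2 cm avoidance
region, 6 mm analysis voxels) that must show AUC above 0.8 and the
characteristic declining FDR-versus-HDI-cut-off curve.

```{r smoke, eval = FALSE}
smoke <- sim_config(brain_radius_mm = 37, voxel_size_mm = 1,
                    analysis_voxel_size_mm = 6, tumor_diameter_mm = 40,
                    effect_region_diameter_mm = 20,
                    effect_region_center = c(15, 0, 0))
bm <- run_benchmark(smoke, method = "bayes", n_repetitions = 3, seed = 1)
bm$auc
```

## What the simulator does and does not emulate

The spheres model reproduces the features that drive the statistics:
per-voxel trial counts that vary across space, crescent-shaped residues,
a localized region of differential practice, and cohorts that are
exchangeable outside it. It does not emulate anatomically shaped brains
or tumors, infiltrative growth, segmentation or registration error, or
spatial correlation beyond what the spherical shapes induce. Passing
benchmarks therefore demonstrate the statistical machinery under
idealized geometry, not clinical performance; in clinical data the
avoidance contrast is unknown and q-values should be read
conservatively.

## Numerical choices, degenerate inputs, tie-breaks

* Risk-minus values are exact rationals; pooled histogram keys are the
  correctly rounded doubles of reduced fractions, which are collision-free
  at the denominators reachable here (at most the product of the cohort
  sizes).
* When the two hypergeometric tails are equal, the lower tail is taken
  as the one-sided side; for symmetric supports the two choices give the
  same two-sided p.
* `q_from_exact_null()` skips thresholds with no declared voxels; f0 = 1
  maps to q = 1 before the ratio would degenerate.
* Empty case lists aggregate to an all-zero map only when a grid is
  given; mixed grids are an error. Residue voxels outside the tumor in
  clinical masks warn and are clipped.
* The cavity radius equals an order statistic of squared distances; ties
  at the boundary can make the covered fraction exceed the target by the
  tie multiplicity, which on integer-squared-distance lattices is a few
  voxels at most.
* MCMC seeds derive per-chain RNGs from the user seed; fixed seeds give
  bit-identical posterior draws on a fixed JAGS version.

## Known limitations

Permutation and Bayesian methods are substantially slower than Fisher's
method (minutes versus seconds per cohort at 4 mm). The permutation
q-values are structurally coarse — they rarely fall below ~0.35 and
never below 0.25 in the nominal benchmark — which is precisely the
liberality the benchmark quantifies. The Fisher q-map is exact per voxel
but ignores spatial clustering; spatially aware statistics are out of
scope. Only two cohorts are supported.
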