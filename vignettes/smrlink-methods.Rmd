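---
title: "Methods: mass response testing and biophysics-transcriptome association"
author: "smrlink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass response testing and biophysics-transcriptome association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrlink)
```

## The measurement setting

A suspended microchannel resonator (SMR) weighs single cells in suspension:
each cell passing through the vibrating cantilever shifts its resonance
frequency in proportion to the cell's *buoyant mass* — the mass in excess of
the displaced fluid, measured in picograms. The same device reports an
acoustic-scattering signal that, after size normalization, serves as a
per-cell *stiffness* readout (arbitrary units). Two analyses are built on
these measurements:

1. **Ex vivo drug sensitivity.** Aliquots of a tumor sample are treated for
   ~24 h with a drug or with vehicle (DMSO), and the single-cell mass
   distributions are compared. A sensitive sample shows a multiplicative
   mass reduction in the drug arm; a resistant sample does not.
2. **Gene-biophysics association.** Cells measured on the SMR are deposited
   one-per-well for Smart-seq2 RNA sequencing, linking each expression
   profile to that cell's mass and stiffness. Genes whose expression tracks
   a biophysical covariate across cells are nominated by rank correlation.

## Buoyant mass, volume and density

With volume $V$ (µm³) and fluid density $\rho_{fluid}$ (g/cm³), buoyant
mass obeys
$$m_b = V(\rho - \rho_{fluid}) = m\left(1 - \frac{\rho_{fluid}}{\rho}\right),$$
so `cell_density()` returns $\rho = \rho_{fluid} + m_b/V$, using the unit
identity 1 pg/µm³ = 1 g/cm³, and `total_mass()` returns $m = \rho V$. The
default $\rho_{fluid} = 1.005$ g/cm³ is the density of the
dextran-supplemented measurement buffer; a neutrally buoyant cell
($m_b = 0$) therefore has exactly the buffer density. The round trip
$\rho \to (m, m_b) \to \rho$ is exact to $10^{-12}$ relative tolerance,
which the test suite asserts over random inputs.

Distribution summaries (`summarize_masses()`) report median and IQR with
quartiles by linear interpolation between order statistics (the type-7
convention, R's default). No convention is stated for the instrument
software, so the choice is recorded in every summary object.

## The mass response statistic

For equal-size samples $X$ (drug) and $Z$ (reference), the Earth Mover's
Distance in one dimension with uniform weights is attained by pairing order
statistics:
$$\mathrm{EMD}(X, Z) = \sum_{i=1}^N |X_{(i)} - Z_{(i)}|,$$
and the *mass response* normalizes by the total reference mass:
$$\mathrm{MR}(X) = \frac{\mathrm{EMD}(X, Z)}{\sum_i Z_i}.$$
The sorted pairing is the unique reading under which the summed absolute
difference *is* the 1D optimal-transport cost; an acquisition-order pairing
would depend on arbitrary run order. The test suite checks the sorted
pairing against a brute-force assignment enumeration (the extreme points of
the transportation polytope) on all instances up to $n = 8$.

The mass response is dimensionless, non-negative and invariant to a common
rescaling of all masses. For a pure shift $\delta$ it equals
$\delta/\bar Z$.

Because thousands of cells are measured per arm, tiny distributional
deviations (sampling error, instrument drift) are statistically visible
without being biologically meaningful. The test statistic therefore
contrasts the drug arm with a second, independently measured vehicle
replicate $Y$ against the same reference $Z$ (itself vehicle-treated):
$$\theta(X, Y, Z) = \mathrm{MR}(X) - \mathrm{MR}(Y).$$
$\theta$ is antisymmetric in $(X, Y)$ and zero when the drug arm behaves
like a vehicle replicate.

### Harmonizing unequal sample sizes

The formula presumes equal $N$; real runs differ by arm. `harmonize_masses()`
reconciles sizes at $N = \min(n_A, n_B)$ with two policies:

* **quantile** (default, deterministic): the larger sample's empirical
  quantile function (type-7 interpolation) is evaluated at the midpoint
  grid $(i - 0.5)/N$; a sample already of length $N$ passes through
  sorted but unchanged, so equal-size inputs reproduce the classic
  equal-$N$ formula exactly.
* **subsample**: a seeded draw of $N$ values without replacement from the
  larger sample, preserving equal-$N$ semantics at the cost of randomness.

Within `theta_statistic()` both mass-response terms use the same target
length $N = \min(n_X, n_Y, n_Z)$.

### The bootstrap decision rule

`bootstrap_t_test()` compares $\theta_{obs}$ to a resampled null
distribution and reports an add-one p-value
$$p = \frac{1 + \#\{\theta^*_b - \bar\theta^* \ge \theta_{obs}\}}{B + 1}$$
for the one-sided "greater" alternative (the biological claim is a drug
induced mass reduction, i.e. extra divergence of $X$ from $Z$), with a
doubled smaller tail for the two-sided variant. Replicates are studentized
by their bootstrap standard deviation; the reported `t_obs` is
$\theta_{obs}$ over that standard error.

The null construction was a genuinely open design point. Resampling each
arm from its own empirical distribution — the textbook percentile-t recipe
for smooth statistics — is badly behaved here: the Earth Mover's Distance
is not differentiable at coinciding distributions, so per-arm resampling
centers each EMD term away from zero and inflates the replicate variance
relative to the true null sampling variance of $\theta$ (in our
simulations, bootstrap SE ≈ 0.014 against a true null SD ≈ 0.010 at
300 cells/arm), and a common-SD studentization cannot repair the rank
comparison — a nested inner bootstrap would be needed, at quadratic cost.
The default `null_resampling = "pooled"` instead draws all three arms,
at their original sizes, from the pooled vehicle + reference masses — the
two arms that are exchangeable replicates by design. This enforces the
null hypothesis inside the resampling scheme, a standard construction for
bootstrap hypothesis tests, and calibrates well: with 300 cells/arm and
2000 replicates, the simulated type-I error at $\alpha = 0.05$ sits inside
the exact binomial 99% band over 1000 repeats and the null p-value
distribution passes a Kolmogorov-Smirnov uniformity check (distance
< 0.05); both checks are run by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`. The per-arm scheme is retained as
`null_resampling = "per_arm"` for comparison; expect it to be strongly
conservative. Whether the duplicate-DMSO design implies a paired
resampling constraint is unknowable from the data layout; arms are
resampled independently.

Defaults: `n_boot = 10000` (the same order as the permutation convention
used elsewhere in the pipeline; 2000 suffices for the calibration studies
and is used there to keep runtimes in minutes), `alpha = 0.05`,
one-sided "greater". When the event table carries a `viable` flag,
`mass_response_from_events()` gates on it before testing, so only viable
cells enter the mass analysis.

## Gene-biophysics association

`correlate_biophysics()` chains the following stages, each exported on its
own:

1. **Cell QC** (`qc_filter_cells()`): remove cells with fewer than 1000
   total reads or more than 20% mitochondrial reads. Both are strict
   removal inequalities — a cell at exactly 1000 reads or exactly 20%
   mito is retained. Mitochondrial genes are identified by symbol prefix
   (default `MT-`), configurable because no fixed gene list is implied by
   an annotation choice. The filter is idempotent.
2. **Model-specific gene exclusion**
   (`exclude_model_specific_genes()`): drop genes expressed (raw count
   > 0) in less than 10% of cells in *any* model, so cross-model
   correlations are not driven by model-restricted programs (sex,
   immunoglobulin clonotype). Again strict: exactly 10% everywhere is
   retained. No CPM threshold defines "expressed"; a positive raw count
   does.
3. **Log-normalization** (`log_normalize()`): counts per 10,000 per cell,
   then $\ln(1 + x)$ — the default of the standard single-cell toolkits,
   with the scale configurable.
4. **Spearman correlation** (`spearman_vs_biophys()`): per-gene rank
   correlation (average-rank ties) of normalized expression with the
   biophysical covariate. Constant genes yield `NA` and are excluded
   downstream. The statistic is invariant under strictly monotone
   transforms of either side.
5. **z-scoring and selection** (`rho_to_z()`, `select_top()`): the
   per-gene coefficients are standardized *across genes*,
   $z_g = (\rho_g - \bar\rho)/s_\rho$, and genes with $z > 2.5$ (strict)
   are selected. Cross-gene standardization — rather than the Fisher
   transform — is the default because mass- and stiffness-derived
   coefficient distributions differ, and only a common standardization
   makes one 2.5 cutoff comparable across the two correlates; the Fisher
   variant (`method = "fisher"`) is available. No multiple-testing
   correction is applied at this gate; the z-threshold is the contract.
6. **Combined ranking** (`combined_rank()`): descending average of the
   mass and stiffness z-scores, ties broken lexicographically by gene
   symbol so the ranking is deterministic.
7. **Permutation null bounds** (`permutation_ci()`): expression profiles
   are randomly re-paired with biophysical profiles (the covariate is
   permuted over cells); after each of `n_iter` permutations every gene's
   Spearman rho is recomputed, and the per-gene 95th percentile of the
   signed null distribution is reported. The signed upper bound is the
   default (an `absolute = TRUE` variant exists); mass and stiffness
   nulls are generated independently. 10,000 iterations is the
   convention mirrored by the default; the validation studies use 1000,
   which bounds the Monte-Carlo error of a 95th percentile well below
   the effect sizes of interest. Internally each iteration is one
   matrix-vector product on pre-standardized gene ranks; a test verifies
   bit-equality of the result against a direct `stats::cor` replay of
   the same seeded permutations.

## The synthetic-data generator

No patient or PDX measurements are distributed with the package, so
`simulate_linked()` and `simulate_drug_triplet()` generate datasets with
the statistical structure the pipeline assumes, plus ground-truth records:

* **Mass**: lognormal within cell-cycle phase (right-skewed unimodal, the
  minimal emulation of observed mass histograms), with model-specific
  G0-G1 medians (defaults 55/62/80 pg, consistent with median cell
  volumes near 800-1100 µm³ at densities a few percent above buffer) and
  phase multipliers (1, 1.15, 1.35) reflecting the ~30-45% G2-M mass
  excess seen in synchronized lymphoma lines. Model cell-cycle mixes
  differ, so between-model mass differences arise partly, but not only,
  from cycle composition.
* **Stiffness**: lognormal, drawn independently of mass; the empirical
  mass-stiffness $R^2$ at 500 cells is ~0.002 on average, emulating the
  reported decorrelation of the two readouts.
* **Counts**: per-gene negative binomial with dispersion
  $\alpha$ ($\mathrm{var} = \mu + \alpha\mu^2$, default 0.4). Designated
  disjoint gene subsets are coupled to mass, stiffness or both through
  the log-mean, linearly in the standardized log covariate — the
  simplest mechanism yielding a tunable rank association. The default
  effect size 0.26 log-units/SD was calibrated once to an injected
  Spearman rho of ≈ 0.3 at ~500 cells. Library sizes are lognormal
  (median 50,000 — scaled down from full Smart-seq2 depth in proportion
  to the reduced gene panel) and a Beta-distributed mitochondrial
  fraction (mean 5%) is allocated to 13 `MT-` genes.
* **Low-quality cells**: injected explicitly (5% of cells get either a
  100-900-read library or a 25-50% mito fraction) rather than emergent,
  so QC tests have exact ground truth.
* **Drug triplets**: reference and vehicle arms are iid lognormal
  (vehicle's median jittered by ±1% to model treatment-independent
  drift between duplicate DMSO measurements); a *sensitive* drug arm has
  its median multiplied by $1 - r$ (default $r = 0.2$); a *resistant*
  arm is untouched. The calibration studies set the jitter to zero so
  the three arms are exactly exchangeable.

The default linked problem size is 3 × 167 cells by 2000 genes, chosen so
the full validation suite runs in minutes; `preset = "full_scale"`
switches to the platform-scale 500 cells × 9442 genes. What passing tests
on these data do **not** show: robustness to transcriptome covariance
structure, batch effects, doublets, empty wells, or mass-stiffness
coupling in real tumors — none of which the generator attempts to
emulate.

## Numerical and degenerate-input conventions

* Quantiles everywhere are type 7; ties in ranks are averaged.
* Masses must be finite and positive; `emd_sorted()` insists on sorted
  inputs rather than silently re-sorting.
* A fully constant triplet yields a degenerate bootstrap (`se = 0`) and
  p-value 1, not an error; a constant biophysical covariate makes the
  permutation null undefined and is an error naming the input.
* `n_boot < 200` and `n_iter < 100` are rejected as too unstable for
  tail estimates.
* All stochastic stages consume an explicit integer seed and are
  bit-reproducible; result tables embed the package version, seed and a
  configuration digest in `#` header lines.

## Validation problem sizes

The statistical validation (in `tests/testthat/test-acceptance.R` and
re-run by `scripts/acceptance.R`) uses: 100 random instances up to
$n = 8$ for the transport oracle; 1000 null triplets at 300 cells/arm and
2000 bootstrap replicates for calibration; 200 repeats at 1000 cells/arm
and 500 replicates for power (detection rate > 0.9 at a 20% mass
reduction; resistant rate within the binomial band around
$\alpha = 0.05$); 20 seeds of the 500-cell × 2000-gene generator for gene
recovery (sensitivity ≥ 0.8 at ≤ 10 false discoveries among 1970
background genes); and 1000 permutations for the null-exceedance check
(~5% of genes above their 95th-percentile bound).

## Known limitations

* The bootstrap null treats the three arms as independent; paired designs
  are not modelled.
* The permutation bound is marginal per gene; no joint error control
  across genes is attempted, matching the z-threshold contract.
* Stiffness is consumed as a measured covariate; the acoustic-scattering
  signal processing that produces it is out of scope.
* The generator draws genes independently given the covariates, so
  pathway-level co-expression structure is absent by construction.
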