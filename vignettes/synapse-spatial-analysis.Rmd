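---
title: "Replicated 3D point-pattern analysis of cortical synapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicated 3D point-pattern analysis of cortical synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsa3d)
```

## The problem

Volume electron microscopy (FIB/SEM) yields, for each tissue sample, a cloud
of synaptic-junction centroids inside a rectangular imaging window, each
centroid carrying a Feret diameter — the diameter of the smallest sphere
circumscribing the reconstructed junction. Two questions drive the analysis
of such data across cortical layers:

1. Do synaptic densities differ between layers?
2. Is the *spatial arrangement* of synapses anything more structured than
   "random, except that synapses cannot overlap"?

`rsa3d` implements the full workflow: per-sample descriptive statistics,
second-order summary functions, hard-sphere (RSA) null models, global
Monte-Carlo envelope tests with leave-one-out parameterisation, aggregation
and comparison of replicated patterns, and a thinning cross-validation of a
common dense model.

## Data model and units

A sample is a `pp3_pattern`: centroid coordinates and Feret diameters in
nanometres inside a `box3d` window, with layer, animal and sample
identifiers. Intensities are reported in synapses/µm³ with the single
conversion 1 µm³ = 10⁹ nm³. Box membership is half-open
(`origin <= coord < origin + side`) so subsampling windows never
double-count points. Tissue shrinks during processing; `shrinkage_correct()`
divides all lengths by the linear shrinkage factor (default 0.90, hence
volumes by 0.729).

A `study_collection` groups samples by layer and animal. The bundled
reference table (`cortex_samples()`) records volumes, counts and densities
for 25 samples across layers I–VI of P14 rat somatosensory cortex from
three animals; the raw centroid clouds are not distributed, so simulated
studies (below) stand in for them wherever coordinates are needed.

## Second-order summaries

The central tool is Ripley's K in 3D with the
Miles–Lantuéjoul–Stoyan–Hanisch translation edge correction,

$$\hat K(d) = \frac{vol(B)^2}{N^2} \sum_{k}\sum_{l \neq k}
  \frac{\mathbf{1}\{\lVert x_k - x_l\rVert \le d\}}{\gamma_B(x_k - x_l)},$$

where $\gamma_B$ is the set covariance of the box (a product of clipped
side lengths). Two conventions are deliberate: the $N^2$ normalisation is
used exactly as printed above (not $N(N-1)$), and pairs enter with the
closed inequality $\le d$. Complete spatial randomness has
$K_{CSR}(d) = \tfrac{4}{3}\pi d^3$; Besag's transform
$L(d) = (3K(d)/4\pi)^{1/3}$ maps it to the diagonal and approximately
stabilises the variance. A hard-core pattern shows $L(d) < d$ at short
distances — the empty space around each synapse.

**Distance grid.** The default grid is 128 equally spaced points from 0 to
a quarter of the shortest box side. The upper limit is a policy, not a
theorem: the translation correction becomes unstable as $\gamma_B \to 0$
when $d$ approaches the box dimensions. `r_max_frac` can be raised
explicitly when needed.

```{r k-demo}
p <- simulate_rsa(box3d(c(7600, 5700, 4600)),
                  rsa_params(1.0, cortex_global_size()), seed = 1)
L <- l_from_k(k3_translation(p))
range(L$values[L$grid > 150 & L$grid < 350] -
        L$grid[L$grid > 150 & L$grid < 350])  # below the diagonal
```

## The RSA null model

A random sequential adsorption process adds spheres one at a time at
uniform locations; a candidate whose sphere intersects any accepted sphere
is discarded and a *fresh location and diameter* are drawn. Placement stops
at the target count `round(intensity * volume)`. Diameters follow a
lognormal law; the maximum-likelihood fit (`fit_lognormal()`) is the mean
and population standard deviation of log diameters. The reference global
fit is $\mu = 5.911$, $\sigma = 0.404$ (log-nm), mean diameter ≈ 400 nm.

**Radius convention.** A synapse is modelled as the sphere circumscribing
it, so the exclusion distance between two synapses is
$(D_k + D_l)/2$ (`half_feret`, default). Because "radii following the
fitted law" could also be read literally, `full_feret` (exclusion
$D_k + D_l$) is available and the convention is recorded in the parameter
object.

**Jamming.** At study densities (~1.4 synapses/µm³ with ~400 nm spheres)
the sphere packing fraction is only ≈ 5–8%, far from the RSA saturation
limit; a guard nevertheless aborts with a typed error after
`max_consecutive_rejections` (default 10 000) failed candidates, reporting
the achieved count. Note that the *exclusion-volume* fraction is eight
times the packing fraction, which has a visible consequence: rejection
preferentially discards large candidates, so the diameters actually placed
average ≈ 3–6% below $e^{\mu + \sigma^2/2}$ at study densities. This is a
property of the process, not an implementation artefact; the size law is
therefore validated on large low-packing simulations, and placed-size
summaries at full density should be interpreted accordingly.

## Envelope goodness-of-fit tests

The null distribution of $L$ under RSA is analytically unknown, so testing
is Monte Carlo: 99 simulations give the central curve $\bar L$ (pointwise
mean), a *separate* 99 give the half-width $w_{max}$ — the furthest
deviation of any of their $L$ functions from $\bar L$ at any grid distance.
The envelope is the constant-width band $\bar L \pm w_{max}$, and the null
is rejected when the observed $L$ leaves the band at any distance (both
sides trigger; the deviation distances are reported). Monte-Carlo tests are
conservative when the null parameters are estimated from the tested data,
so hypothesis tests estimate them leave-one-out: `loo_intensity()` is the
volume-weighted aggregate density of the *other* samples of the layer and
`loo_size()` the lognormal fit of their pooled diameters. $w_{max}$ is
maximised over the same grid on which $L$ is evaluated.

## Replicated patterns and the group test

Per-group K functions are aggregated with count weights,
$\bar K_i(d) = \sum_j n_{ij} \hat K_{ij}(d) / \sum_j n_{ij}$ — K does not
depend on intensity, so samples with different densities are legitimately
pooled. Groups are compared with a bootstrap (Diggle) test on

$$D = \sum_i W_i \int \left(\sqrt{\bar K_i(d)} - \sqrt{\bar K(d)}\right)^2
  \mathrm{d}d, \qquad W_i = \sum_j n_{ij},$$

with the integral evaluated by the trapezoid rule on the common grid.
The null distribution resamples residual curves
$r_{ij} = \sqrt{\hat K_{ij}} - \sqrt{\bar K_i}$ with replacement from the
pool across groups (each residual carrying its weight), reattaches them to
the overall mean and recomputes $D$; the p-value is
$(1 + \#\{D^* \ge D\})/(1 + n_{boot})$ with 5000 iterations by default.

One calibration detail matters: residuals about a group mean of $m_i$
curves carry only $(m_i - 1)/m_i$ of the curve variance, so the raw recipe
is anti-conservative (measured type-I error ≈ 0.15 at nominal 0.05 with two
groups of five replicates). Each residual is therefore rescaled by
$\sqrt{m_i/(m_i - 1)}$ before pooling (measured type-I ≈ 0.08; the option
`rescale_residuals = FALSE` restores the raw recipe). The weight exponent
(weights $n_{ij}$ or $n_{ij}^2$) is likewise exposed and recorded.
One-vs-rest comparisons are the same test after regrouping.

## Thinning cross-validation of a common dense model

To test whether layers II–VI are thinned versions of one underlying
process, a dense global model is fitted: $\mu_{global}, \sigma_{global}$
from the pooled diameters of all member samples, and
$\lambda_{global} = 1.01 \times \max_{ij} \lambda_{ij}$, rounded to one
decimal (the rounding is dropped if it would not exceed the maximum; with
the reference table this gives 1.4 synapses/µm³). 198 dense RSA simulations
are generated once in a 300 µm³ window (7.6 × 5.7 µm field of view) — 420
synapses each at the reference intensity — and reused for every held-out
sample: they are randomly thinned to the sample's leave-one-out intensity
(uniform subsets keep coordinates and diameters, so the hard core is
inherited), the first 99 thinned sets give $\bar L$, the second 99 give
$w_{max}$, and the held-out sample's $L$ is checked against the band.

Two structural facts make this test slightly harsher than the per-sample
fit: the observed window (≈ 124–280 µm³) is smaller than the dense window,
so the observed $L$ is noisier than the simulated ones; and a directly
simulated RSA pattern at a layer's intensity is only approximately a
thinned draw of the denser process (thinning preserves the dense process's
correlation structure). Both effects push occasional true-null samples just
outside the band, which is worth remembering when reading sweep tables.

## Density comparisons across layers

`min_box()` gives the largest box fitting inside every sample window;
`subsample_densities()` places it uniformly at random inside a uniformly
chosen sample of a layer and records count/volume, 50 repetitions per layer
by default (samples drawn with replacement across repetitions). Layers are
compared with the Kruskal–Wallis test and pairwise two-sided Mann–Whitney
tests with Bonferroni adjustment (exact enumeration for untied groups of at
most 8, the tie-corrected normal approximation otherwise). A Levene check
(`levene_check()`) reports whether ANOVA's equal-variance assumption would
have held; the pipeline proceeds rank-based regardless. The degenerate
all-tied case is reported as $H = 0$, $p = 1$.

A caveat: the 50 draws per layer are pseudo-replicates of a handful of
underlying samples. When layers have only two or three samples, the
between-sample realisation noise is invisible to the rank tests and
spurious "differences" between identically generated layers are common.
The comparison is trustworthy when within-draw counting noise dominates —
many samples per layer and/or a small subsampling window.

## The synthetic-study generator

`default_study_spec()` encodes the reference study conditions: six layers
with intensities (0.794, 1.098, 0.940, 1.222, 0.828, 0.466) synapses/µm³,
sample counts (2, 3, 10, 3, 3, 4), the shared size law (5.911, 0.404), and
windows with the 7.6 × 5.7 µm field of view whose depth is a whole number
of 20 nm sections chosen so each layer's window volume matches its
reference mean sample volume (expected study total ≈ 3954 synapses).
`generate_study()` simulates each sample as an independent RSA draw at its
layer's parameters, assigning animals round-robin. A `core_scale`
multiplier on the diameters of a contrast layer emulates the slightly
stronger repulsion seen in layer I; its size is a free parameter. Scales
must respect sphere-packing feasibility: the exclusion fraction grows with
the cube of the scale, and a ×3 scale at cortical intensities is physically
unplaceable, so contrast experiments here use ×1.5.

What the generator deliberately omits: FIB/SEM imaging noise, segmentation
error, anisotropic z-resolution, the unbiased-counting-frame geometry, and
any within-window inhomogeneity. Passing tests on generated studies
validate the statistical machinery under the stated model, not those
acquisition effects.

## Numerical choices and problem sizes

* Pairwise loops (K estimator, RSA insertion, nearest neighbours) are
  compiled (Rcpp); all randomness flows through R's RNG, so a single seed
  reproduces any run, and master seeds spawn per-stage sub-seeds
  deterministically.
* `thin_to_intensity()` and the simulators use `round(lambda * volume)`
  as the target count.
* K values are accumulated by binning pair weights and taking a cumulative
  sum, preserving the closed-inequality step-function convention.
* The test suite calibrates the Monte-Carlo machinery at reduced sizes:
  envelope type-I error with 39 + 39 simulations over 200 replicates,
  Diggle calibration with groups of five replicates of ≈ 150-point
  patterns over 100 replicates with 199 bootstrap iterations, and pipeline
  sweeps at the full 99 + 99 on one generated study. These sizes are the
  package's validation conditions; production analyses default to
  99 + 99 envelopes and 5000 bootstrap iterations.

## Known limitations

* The RSA size-selection bias (above) means placed diameters are not an
  unbiased sample of the fitted law at study densities.
* The subsampling density comparison is anti-conservative for layers with
  few samples.
* The thinning cross-validation compares windows of different volumes by
  construction; its per-sample false-rejection rate is a few percent above
  the envelope test's.
* No inhomogeneous or Gibbs/Strauss alternatives are provided: the package
  tests CSR and RSA nulls only, and periodic boundary conditions are not
  supported.
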