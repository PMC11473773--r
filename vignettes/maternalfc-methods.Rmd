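---
title: "Models and methods behind maternalfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind maternalfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maternalfc)
```

`maternalfc` implements a complete analysis stack for studying how brain
function changes after childbirth with resting-state fMRI: postpartum women
scanned in the first week after delivery (a large cross-sectional group plus
a smaller subgroup followed over roughly six months) are compared with
once-scanned nulliparous controls on three voxel-level metrics, group
differences are localized with non-parametric cluster inference, their
spatial layout is related to hormone- and neurotransmitter-receptor
distributions, and their temporal evolution is modeled with mixed models.
Because individual neuroimaging data of this kind cannot be shared openly,
the package ships a synthetic-data generator that reproduces the
*statistical* structure of such a study, so that every stage of the pipeline
can be validated against known ground truth.

## Resting-state metrics

Three voxel-level metrics summarize local activity, local connectivity and
global connectivity:

* **fALFF** (fractional amplitude of low-frequency fluctuations): the ratio
  of summed spectral amplitudes in the 0.01–0.08 Hz band to the summed
  amplitude over the whole positive spectrum,
  $\mathrm{fALFF}_v = \sum_{f \in B} a_v(f) \, / \sum_{f \le f_{Nyq}} a_v(f)$
  with $a_v(f)$ the square root of the periodogram power.
* **LCOR** (local correlation): the Gaussian-kernel-weighted average of
  Pearson correlations between a voxel's time series and all other in-mask
  voxels, $\mathrm{LCOR}_v = \sum_{u \ne v} w_{uv} r_{uv} / \sum_{u \ne v} w_{uv}$,
  with weights $w_{uv} = \exp(-d_{uv}^2 / 2\sigma^2)$ from inter-voxel
  distance. The kernel FWHM defaults to 25 mm, the common toolbox default;
  it is an exposed parameter because published analyses rarely restate it.
* **GCOR** (global correlation): the signed mean correlation of a voxel with
  all other in-mask voxels, $\mathrm{GCOR}_v = \frac{1}{V-1}\sum_{u \ne v} r_{uv}$.
  The signed (not absolute) mean is used so that *decreases* are
  interpretable as reduced connectivity.

The preprocessing contract is: confound regression (Friston-24 motion
expansion plus mean white-matter and CSF signals, 26 regressors and an
intercept) and linear detrending for all metrics; bandpass filtering
(0.01–0.08 Hz) only for LCOR and GCOR. fALFF must see the full spectrum
because the band fraction *is* the statistic — bandpassing first would force
it towards 1.

### Numerical choices

* The bandpass is an ideal zero-phase FFT mask after linear detrending:
  frequency bins outside the band are zeroed and the series inverted back.
  Its response is exactly testable (a 0.2 Hz sinusoid at TR = 2 s retains
  < 1% variance; a 0.04 Hz sinusoid ≥ 95%).
* The fALFF spectrum is estimated from the demeaned, **Hann-tapered**
  series. With a rectangular window, a narrow-band signal whose frequency
  falls between DFT bins (e.g. 0.04 Hz with 160 volumes at TR = 2 s) leaks
  roughly 17% of its summed *amplitude* across the rest of the spectrum,
  biasing fALFF to ~0.83 for a pure in-band oscillation; the Hann taper
  confines leakage to neighboring bins (fALFF ≈ 0.99) while leaving the
  white-noise expectation at the band-bin fraction (≈ 0.28 at these
  settings). fALFF is invariant to positive rescaling of the series by
  construction.
* GCOR is computed through the row-standardized data matrix
  ($\mathrm{GCOR} = (Z Z^\top \mathbf{1} - (T-1)) / ((V-1)(T-1))$ without
  materializing the correlation matrix), which is algebraically identical to
  the brute-force pairwise mean; tests enforce agreement to 1e-10.
* Zero-variance voxels are dropped from the mask (with a warning) before
  any correlation metric.
* Parcel averaging flags parcels without in-mask voxels as missing (`NA`)
  rather than zero.

## Cluster-mass permutation inference

Group contrasts (postpartum vs nulliparous, both directions separately) are
fit per voxel by OLS with covariates (age by default). Voxels exceeding the
one-sided $p < 0.01$ threshold are grouped into connected components
(26-neighbor connectivity by default; 6 and 18 available) and each cluster's
**mass** — the sum of $|t|$ over member voxels — is referred to a null
distribution of *maximum* cluster masses under permutation, giving
family-wise-error-corrected p values
$p_{FWE} = (1 + \#\{M^{null} \ge m\}) / (1 + B)$.

With covariates present, plain label permutation is not exchangeable, so the
**Freedman–Lane** scheme is used: residuals from the covariates-only model
are row-permuted, the covariate fit is added back, and the full model is
refit. With no covariates and few subjects, all distinct group assignments
are enumerated exhaustively (with a message) and p values become exact
proportions; exhaustive enumeration is restricted to covariate-free designs
because Freedman–Lane permutes residual orderings, for which group-split
enumeration is not the correct exhaustive set.

The +1 correction guarantees $p_{FWE} \ge 1/(B+1)$ and validity at any $B$;
calibration is verified empirically (family-wise error within the 95%
binomial interval of 0.05 over 200 null datasets).

## Spatial colocalization

Each postpartum subject's parcel map is converted to a deviation map against
the control reference, $z_p = (x_p - \bar{x}^{NP}_p) / s^{NP}_p$ (sample SD,
parcels with zero reference SD flagged missing), and correlated across the
116 parcels with each receptor distribution map (progesterone PGR, estrogen
ESR1/ESR2, cortisol NR3C1/NR3C2, oxytocin OXTR, GABA-A, mGluR5) using
Spearman's $\rho$ with average-rank ties. Per-subject coefficients are
Fisher-transformed ($z_\rho = \mathrm{atanh}\,\rho$, clipped away from
$\pm 1$), and the group statistic is their mean.

Inference shuffles the group labels and **recomputes the Z maps against each
permuted reference** — necessary for exchangeability because the Z transform
itself depends on group membership. Two p values are reported:

* `p_exact`: the two-sided permutation rank of
  $|\text{statistic} - \text{null mean}|$ with the +1 correction (exact
  enumeration when the number of label splits does not exceed the requested
  permutations; in that regime the Gaussian `p_norm` is reported as `NA`
  when fewer than 100 null values exist);
* `p_norm`: the two-sided tail of a Gaussian fitted to the null by its
  mean and SD. This supports rank-based FDR at a resolution finer than
  $1/(B+1)$.

FDR (Benjamini–Hochberg) is applied per analysis family — all
metric-receptor combinations of the baseline analysis form one family,
mirroring the convention of correcting each post-GLM analysis step
separately.

Multivariate explanation is quantified per subject as the $R^2$ of an OLS
fit of the rank-transformed Z map on the rank-transformed receptor subset
(consistent with the Spearman univariate analyses; a raw-scale option
exists), with the group mean $R^2$ tested by the same label permutation.
Under independence the expected per-subject $R^2$ is approximately
$R/(P-1)$, which the tests verify. Receptor–receptor Spearman matrices aid
interpretation when receptor maps are mutually correlated.

`compare_stat_maps()` correlates two parcel-level statistic maps with a
parcel-label permutation null. This null does not preserve spatial
autocorrelation — a documented simplification: at a resolution of 116
parcels, autocorrelation-preserving (spin/variogram) nulls are out of scope,
and results should be read accordingly.

## Longitudinal statistics

* **Per-timepoint ANCOVAs** compare the postpartum scans of each session
  against the once-measured controls, adjusted for age; the once-scanned
  controls re-enter every comparison unchanged. Hedges' g is the adjusted
  group difference over the model residual SD times the small-sample factor
  $J = 1 - 3/(4\,df - 1)$.
* **Mixed models** (`lme4`) fit `response ~ week (+ week²) + (1 | subject)`
  on the longitudinal postpartum panel, by maximum likelihood (so nested
  model comparisons remain valid; REML is available). Fixed-effect p values
  use the Wald normal approximation and are documented as approximate —
  no degrees-of-freedom correction is applied. Singular and non-converged
  fits are flagged, never silently dropped. Controls never enter the
  trajectory models (they have no postpartum week). Unbalanced panels are
  handled by available-case analysis.
* **Paired t tests** between all session pairs use complete pairs only, with
  the paired-variant Hedges' g.
* **Interaction models** fit `response ~ predictor × week + (1 | subject)`
  after z-standardizing the predictor within subjects (removing
  between-subject level differences so the interaction captures temporal
  covariation) and scaling the response to unit SD, making the interaction
  coefficient a standardized effect size. Hormone predictors are
  log-transformed (natural log) before standardization.
* **FDR correction** is applied within analysis families: one family per
  analysis step (baseline colocalization; session ANCOVAs; trajectory LMMs;
  interaction LMMs).
* The **regression-toward-the-mean diagnostic** asks whether an apparent
  normalization could arise with no true change: it estimates the
  between/within-subject variance split by method of moments (robust to
  degenerate model fits, e.g. zero measurement noise), simulates the
  observed panel layout under zero true trajectory, and compares the
  observed week slope and the baseline-to-change correlation against their
  simulation bands.

## The synthetic-data generator

`generate_study()` emulates the target study design: 23 nulliparous
controls (one scan), 56 cross-sectional postpartum women (first-week scan
only), 19 longitudinal postpartum women at sessions ~0.5, 3.2, 6.2, 9.2,
12.1 and 24.8 weeks postpartum, and 116 parcels (100 cortical + 16
subcortical, subcortical last). Parcel values follow

$$x_{isp} = u_{i} + s\,\delta\,\sigma_\epsilon\, m(w_{is})\,[p \in
\mathcal{P}] + \sigma_\epsilon\, m_c(w_{is}) \textstyle\sum_r c_r
\tilde{R}_{pr} + \epsilon_{isp},$$

a per-subject, per-metric random intercept $u_i \sim N(0, \sigma_u^2)$, an
additive group effect of sign $s$ and magnitude $\delta$ (in residual-SD
units) on a parcel set $\mathcal{P}$ with a trajectory multiplier $m(w)$, a
receptor-coupled spatial component with coefficients $c_r$ on standardized
receptor maps $\tilde{R}$ (the generative pattern that the colocalization
statistic is designed to detect), and Gaussian noise. Trajectories are
either **persistent** ($m \equiv 1$) or **quadratically normalizing**
($m(w) = 1 + \beta_1 w + \beta_2 w^2$, floored at zero from the first root
onward so normalized effects do not rebound; the default roots at week 7,
the middle of the 6–9-week window in which global-connectivity differences
are expected to resolve).

Defaults are the study conditions, chosen once:

* effect magnitude 2.5 residual-SD units — the baseline group effects being
  emulated are very strong cluster-level findings;
* `noise_sd` 0.5 and `subject_sd` 0.35, i.e. an intraclass correlation of
  ~0.33. The within-subject stability of parcel-wise rsfMRI metrics over
  weeks is a genuinely open parameter; test-retest literature for
  connectivity metrics puts ICCs broadly in the 0.2–0.5 range, and the value
  is exposed in the configuration;
* dropout probability 0.03 per follow-up session, matching per-session
  counts of roughly 19/19/18/19/18/17;
* log-progesterone with a steep post-delivery fall and quadratic recovery,
  log-estradiol nearly flat, and depression/attachment scores with small
  linear + quadratic week trends on their native scales (ranges clipped).

Parcel maps live on a pseudo-standardized scale (grand mean 0): the
generator emulates the *statistical* structure of parcel-wise metric maps,
not the metric's native range. All randomness flows from one root seed
through named substreams (`substream_seed()`), so components can be
regenerated independently; the substream derivation passes through the
generator itself because arithmetic seed combination leaves related seeds on
an arithmetic progression with measurably correlated streams (this showed up
as inflated family-wise error in early calibration runs).

`generate_voxel_timeseries()` produces small 4D fixtures (shared sinusoids,
a shared global noise component with a known variance fraction, white
noise, plus a 26-column confound table) whose spectra and correlation
structure are analytically known. `make_receptor_atlas()` builds receptor
maps either as structured random maps (a shared latent gradient plus a
subcortical elevation for PGR/OXTR) or by rank-mixing to hit target Spearman
correlations with a supplied pattern within ±0.1 (bisection over the mixing
weight, fresh-noise retries, bounded attempts).

What the generator does *not* emulate — scanner artifacts, physiological
noise, realistic anatomy or spatial autocorrelation of parcels — bounds what
passing tests show: they validate the statistical machinery under the
generating model, not robustness to real-data nuisance structure.

## The qualitative dissociation pattern

The headline scientific pattern the pipeline must be able to detect is a
temporal dissociation: local-metric effects that persist across six months
versus a global-connectivity effect that normalizes by roughly weeks 6–9.
The package operationalizes "reproducing the dissociation" on a synthetic
study with the paper-style significance convention (BH-FDR q < 0.05 per
analysis family) as:

1. the normalizing measure differs between groups at the first session and
   *not* at the 9-week session (the first session after the trajectory's
   zero-crossing);
2. its quadratic mixed model shows significant linear *and* quadratic week
   terms;
3. the persistent measure differs at *every* session;
4. the persistent measure does **not** show both week terms significant.

A stricter reading — requiring non-significance at every session from
6 weeks on plus two additional null checks — stacks six 5%-level null
requirements per replicate; even a perfect implementation would then meet
the pattern in only ~85% of replicates, so the operationalization above
keeps one decisive null check per claim. With the default study conditions
the pattern is met in ~93% of replicates.

## Problem sizes used in validation

The test-suite and acceptance-script simulations are sized to be decisive
yet quick: FWE calibration uses 10×10×10 null volumes (10 vs 10 scans,
300–500 permutations, 100–200 datasets); colocalization sign recovery uses
50 postpartum subjects × 116 parcels with couplings of ±0.3; null
calibration uses ~100–200 replicates at ~200 permutations; mixed-model
recovery uses the longitudinal panel size (19 subjects × 6 sessions, 100–200
replicates); the dissociation pattern uses the full default design (98
subjects) over 120–150 replicates. These sizes are the package's validation
choices and are stated here so they can be scaled up by users who want
tighter Monte-Carlo error.

## Known limitations

* Parcel-label permutation nulls ignore spatial autocorrelation; map-to-map
  and map-to-receptor p values are liberal to the extent that parcel-level
  autocorrelation exists.
* Wald normal approximation for mixed-model fixed effects is slightly
  anticonservative at 19 subjects.
* The multivariate $R^2$ is computed per subject with ~116 observations and
  6–8 predictors and is therefore upward-biased as an estimate of
  population variance explained; the permutation test accounts for this
  under the null.
* Receptor maps are consumed as parcel-level inputs; their construction
  (and its considerable uncertainty) is out of scope.
* In real mode the pipeline starts at confound regression; upstream
  preprocessing (realignment, normalization, QC) must be done elsewhere.
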