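---
title: "Quantifying genuine higher-order functional connectivity with multivariate cumulants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genuine higher-order functional connectivity with multivariate cumulants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hofc)
```

## The problem

Functional connectivity is the statistical dependence between signals
recorded at different brain regions.  Pairwise (second-order) dependence is
routinely measured with the Pearson correlation, but dependence can involve
three or more regions at once.  The difficulty is that the obvious
higher-order statistics are *redundant*: a fourth-order moment
$m_{ijkl} = E[X_iX_jX_kX_l]$, or the edge functional connectivity built
from products of region pairs, is generally nonzero for purely Gaussian
signals, in which case it carries no information beyond the pairwise
correlations.  A measure of *genuine* higher-order connectivity must vanish
for Gaussian signals of arbitrary correlation structure.

Multivariate cumulants have exactly this property.  For zero-mean signals,
cumulants up to order three equal the corresponding moments, while the
fourth-order cumulant subtracts the pairwise part:

$$c_{ijkl} = m_{ijkl} - m_{ij}m_{kl} - m_{ik}m_{jl} - m_{il}m_{jk}.$$

Normalizing by the signal standard deviations gives dimensionless measures:
the **coskewness** $r^c_{ijk}$ (a multivariate generalization of skewness;
sign-reversing under joint sign flip of the three signals, so it
distinguishes coherent extreme activations from deactivations) and the
**cokurtosis** $r^c_{ijkl}$ (a multivariate excess kurtosis; invariant
under joint sign flips of any two signals).  Orders above four are out of
scope: the number of tuples and the sampling variance both explode.

The **edge connectivity** between region pairs $(i,j)$ and $(k,l)$ is the
normalized uncentered fourth moment
$\varepsilon_{ij,kl} = m_{ijkl} / (m_{iijj}\,m_{kkll})^{1/2} \in [-1, 1]$.
Expressing it through cumulants and setting the fourth-order cumulants to
zero yields its **redundant part**

$$\varepsilon^r_{ij,kl} =
\frac{m_{ij}m_{kl} + m_{ik}m_{jl} + m_{il}m_{jk}}
{\left[(2m_{ij}^2 + m_{ii}m_{jj})(2m_{kl}^2 + m_{kk}m_{ll})\right]^{1/2}},$$

the value expected under Gaussianity; the **corrected** edge connectivity
is their difference and is the package's non-redundant version of edge
functional connectivity.

## Estimation conventions

All estimators are plug-in: expectations are replaced by temporal averages
$(1/T)\sum_t$.  Inputs are z-scored per region with sample mean computed
with $1/T$ and sample variance with $1/(T-1)$.  These two conventions are
deliberately kept exactly as stated even though they interact: the plug-in
self-moment of a standardized row is $(T-1)/T$ rather than 1, and the
second-order "correlation" is the Pearson correlation times $(T-1)/T$.
This is documented behaviour, not a defect; `correlation2()` warns when
called on a self-pair.  Because the signals are standardized, the
$\sigma_i$ normalizers are unity and the estimators skip the division.
Estimators require the `standardized` flag and otherwise z-score
automatically with a notice.  Public measures demand distinct regions
(a repeated region makes the "higher-order" reading meaningless), while
internal moments with repeated indices remain available because the edge
normalizers need $m_{iijj}$-type terms.  Invariance tests (permutation
symmetry, sign symmetries, equality with brute-force summation loops) are
asserted at an absolute tolerance of 1e-10 or tighter.

## The generative model

Synthetic signals with known higher-order structure come from a first-order
vector-autoregressive process driven by Gaussian and non-Gaussian noise:

$$X_i(t+1) = \varphi X_i(t) + Z_i(t) + \psi U(t), \qquad i = 1,\dots,n,$$

with $Z(t)$ an equicorrelated (pairwise $\rho$) unit-variance Gaussian
vector and the *same* zero-mean unit-variance non-Gaussian innovation
$U(t)$ added to every region — the shared innovation is what produces
genuine third- and fourth-order dependence.  Parameters, with defaults used
throughout the simulation studies:

| parameter | meaning | default / range |
|---|---|---|
| $\tau$ | autocorrelation time-scale in samples, $\varphi = e^{-1/\tau}$ | 2 (least-squares fit of $e^{-k/\tau}$ to group-level BOLD autocorrelation) |
| $\psi$ | strength of the shared non-Gaussian innovation | $[0, 1]$; 1 means equal strength with the Gaussian part |
| $r$ | common pairwise signal correlation; $\rho = r + (r-1)\psi^2$ | 0.4 (realistic, though at the high end, for parcel-averaged BOLD) |
| $\alpha$ | skew-normal shape, $\delta = \alpha/\sqrt{1+\alpha^2}$ | swept 0–6; negative values (left skew) allowed, flipping the coskewness sign |
| $\nu$ | t degrees of freedom, $U = \sqrt{(\nu-2)/\nu}\,t_\nu$ | 5–20; $\nu \ge 5$ required for a finite fourth cumulant $6/(\nu-4)$ |

Two printed conventions for $\varphi$ are inconsistent in the source
literature ($e^{-\tau}$ versus lag-$k$ autocorrelation $e^{-k/\tau}$); the
package adopts $\varphi = e^{-1/\tau}$, the only reading consistent with
the stated autocorrelation form, with the block-length rationale below, and
with the reported coskewness ceiling of about 0.2.

Positive-definiteness of the Gaussian innovation covariance requires
$\rho > -1/(n-1)$; for $\psi \in [0,1]$ a sufficient condition is
$r > 1/2 - 1/(2(n-1))$, i.e. $r > 1/4$ for $n=3$ and $r > 1/3$ for $n=4$
(`validate_model()` reports both).  The stationary process admits closed
forms.  With $c_3^U, c_4^U$ the innovation cumulants,
$\kappa_4 = \psi^4 c_4^U/(1-\varphi^4)$,
$c = (\rho+\psi^2)/(1-\varphi^2)$ and $v = (1+\psi^2)/(1-\varphi^2)$:

$$r^c_{ij} = \frac{\rho + \psi^2}{1 + \psi^2},\qquad
r^c_{ijk} = \frac{(1-\varphi^2)^{3/2}\,\psi^3}
{(1-\varphi^3)(1+\psi^2)^{3/2}}\,c_3^U,\qquad
r^c_{ijkl} = \frac{(1-\varphi^2)^2\,\psi^4}
{(1-\varphi^4)(1+\psi^2)^2}\,c_4^U,$$

$$\varepsilon_{ij,kl} = \frac{\kappa_4 + 3c^2}{\kappa_4 + v^2 + 2c^2},
\qquad \varepsilon^r_{ij,kl} = \frac{3c^2}{v^2 + 2c^2}.$$

The edge expressions are derived here from the process's cumulant structure
(each lag contributes multilinearly, and only the shared innovation carries
cumulants beyond order two); they reproduce the pairwise-correlation and
cumulant formulas by the same route and are verified against long plug-in
simulations in the test suite.  Coskewness and cokurtosis do not depend on
$\rho$; the edge connectivity does.  At $\tau = 2$, $\psi = 1$ the
coskewness ceiling over $\alpha$ is

```{r ceiling}
true_coskewness(hofc_model(n = 3, tau = 2, r = 0.4, psi = 1,
                           innovation = skew_normal_innovation(6)))
```

**Sampling.**  The skew-normal uses the half-normal representation
$U = \sigma_U(\delta |Z_1| + \sqrt{1-\delta^2} Z_2) - \sigma_U\delta\sqrt{2/\pi}$
with $\sigma_U = \sqrt{\pi/(\pi - 2\delta^2)}$.  Simulation starts at
$X(0) = 0$ and discards a burn-in of $20\tau$ samples by default
(configurable); with $\varphi^{20\tau} = e^{-20} \approx 2\cdot10^{-9}$ the
retained stretch is stationary for all practical purposes.  The
equicorrelated $Z$ is produced through the symmetric square root of the
correlation matrix, and each `simulate()` call uses one seeded RNG stream,
recorded in the result's attributes.

## Statistical inference

The estimators are asymptotically normal but their variance depends on the
autocorrelation structure, so independent resampling of time points is
mis-calibrated on fMRI-like signals.  The package's primary tool is the
**non-overlapping block bootstrap**: the $T$ columns are cut into
$B = \lfloor T/L \rfloor$ blocks of $L$ consecutive time points (a
trailing remainder is dropped — the wrap-around alternative buys little and
complicates the spectral interpretation), $B$ blocks are drawn with
replacement and concatenated, and all regions are resampled jointly so
cross-region alignment is never broken.  The default $L = 10$ follows from
$\tau \approx 2$: the autocorrelation has essentially decayed within ten
samples.  Each replicate re-applies the full estimator (including
re-standardization of the resampled matrix).  From $B_{rep}$ replicates
(default 1000) come the bootstrap SE, the normal-approximation confidence
interval $\hat\theta \pm z_{\beta/2}\,\mathrm{se}$ (a percentile interval
is available but non-default) and a two-sided z-test of
$H_0{:}\ \theta = 0$ using $\hat\theta/\mathrm{se}$.  Two-sided testing is
used throughout.

**Coherent phase randomization** provides the complementary null: every
row's discrete Fourier transform is rotated by the *same* uniformly random
Hermitian-symmetric phases (DC and Nyquist untouched), which preserves each
amplitude spectrum exactly and all cross-spectral phase differences, while
destroying higher-order structure — the surrogate ensemble realizes a
linear Gaussian process with the observed second-order structure.  The
empirical two-sided p-value uses the $+1$ correction,
$p = (1 + \#\{|T_{surr}| \ge |T_{obs}|\})/(n_{surr}+1)$, so it can never be
exactly zero.  Circular-shift nulls (which destroy cross-correlations and
therefore test the wrong hypothesis) and autoregressive surrogates are
deliberately not provided; the stationary bootstrap is omitted because it
behaves like the block bootstrap here.

For the coskewness statistic the block bootstrap is also implemented
through an algebraically identical additive kernel: the statistic of any
resample is a function of ten per-block column sums, so one replicate is a
ten-number reduction.  The test suite verifies exact equality with the
generic resample loop under a shared RNG stream; the calibration harnesses
use the fast path to afford $10^6$ replicates.

## Simulation harnesses and what they show

`ground_truth_curves()` tabulates the closed forms over $(\psi, \alpha)$ or
$(\psi, \nu)$ grids (defaults $\psi \in \{0, 0.1, \dots, 1\}$, $\alpha$ in
steps of 0.5 up to 6, $\nu$ from 5 to 20).  `sampling_study()` simulates
`n_datasets` series per grid point (scan length default $T = 1200$,
matching a 14.4-minute session at TR 0.72 s), and reports bias, ensemble
SE, and the detection probability: the fraction of datasets with
$|\hat\theta|/\sigma_{MC} > z_{.975}$, where $\sigma_{MC}$ is the ensemble
SD at that grid point.  Using the Monte-Carlo $\sigma$ matches a setting
where the sampling distribution is available by construction; per-dataset
bootstrap SEs are the practical field alternative and are exposed through
`bootstrap()`.  Key reproducible findings: the coskewness estimator is
unbiased at $T = 1200$ with detection probability rising to roughly 87% at
$\psi = 1, \alpha = 3$ and collapsing to the 5% test size at the Gaussian
corner; the fourth-order estimators (`fourth_order_feasibility()`) are
negatively biased for $\psi > 0$ and their central 95% sampling intervals
exclude zero only in the strongly heavy-tailed corner ($\nu = 5$), making
single-dataset fourth-order detection essentially infeasible at this scan
length.  `bootstrap_calibration()` reproduces the bootstrap's known finite-
sample defect: the block-bootstrap SE *under*-estimates the true SE, with
the gap shrinking as $T$ grows, so the null rejection rate is inflated —
about 9% at $T = 300$, settling near 6% for long scans — while independent
resampling of these autocorrelated series rejects at about 12%.
`fit_ar_timescale()` performs the least-squares fit of $e^{-k/\tau}$ that
motivates $\tau = 2$ (over lags 1–20 by default; an all-non-positive
autocorrelation is an error and a boundary fit is flagged as white noise).

Problem sizes: the shipped test suite runs these studies at reduced
ensemble sizes (hundreds of datasets per point) chosen so that three-sigma
Monte-Carlo bands still separate the expected values; `scripts/acceptance.R`
runs the fuller versions (up to $10^4$ datasets, $10^6$ bootstrap
replicates per rate).

## Group-level mapping

`subject_ensemble()` bundles per-subject region×time matrices sharing one
region set.  Each subject is standardized separately before estimation
(the alternative — pooled standardization — would let between-subject
variance differences leak into the dimensionless estimates; per-subject
z-scoring matches how individual scans are preprocessed).  A coskewness map
fixes two seed regions and varies a target region; fourth-order maps
(cokurtosis or corrected edge connectivity, with the seed pair as one edge)
vary a target *pair* over user-supplied homologous region pairs, keeping
the test count linear in regions; correlation maps average over the two
seeds.  Map values are exactly the per-tuple estimator outputs — there is
no separate code path, which the tests verify by explicit loops.
`group_threshold()` bootstraps subjects (10,000 resamples by default),
forms a two-sided normal-approximation p-value from the bootstrap SE of the
group mean, and Bonferroni-corrects over the number of tested targets.
`random_ktuple_distribution()` estimates group-level distributions of the
measures over random region tuples, with independent re-selections as a
stability check and phase-randomized companions as a null overlay.
`interpret_sign()` disambiguates a significant coskewness using the signs
of the pairwise correlations (coherent extreme activations vs.
deactivations vs. the two-against-one pattern); its "no structure"
threshold defaults to the approximate 5% critical value
$1.96\sqrt{6/T}$ of the estimator under an independent Gaussian null.

## Numerical and design notes

* Degenerate inputs: constant rows are refused by name; an edge with a
  zero fourth-moment normalizer raises a degenerate-edge error; a
  single-subject ensemble cannot be bootstrapped.
* All map/bootstrap randomness uses R's global RNG; top-level entry points
  (`simulate()`, the CLI, the acceptance script) accept seeds, and
  identical seeds give byte-identical outputs.
* Result tables are TSV with a fixed column schema, 10 significant digits
  and lexicographic row order; configurations are flat YAML; simulation
  metadata (parameters, seed, full ground truth) goes to a JSON sidecar.
* The CLI (`inst/cli/hofc.R`) is a thin wrapper over the exported
  functions with subcommands `simulate`, `estimate`, `bootstrap`,
  `surrogate`, `map`, `experiment`; every numeric knob of the simulation
  studies is reachable from flags or config.

## What the synthetic data does and does not show

The generative model reproduces three properties that matter for the
estimators: non-Gaussianity with tunable third/fourth cumulants, exact
ground truths, and fMRI-like exponential autocorrelation.  It does *not*
emulate non-stationarity, region-heterogeneous innovation strengths,
hemodynamic filtering, measurement noise structure, or realistic network
topology (all regions are exchangeable).  Passing tests therefore certify
the estimators and the inference machinery under a stationary, linear,
exchangeable model of the right correlation scale — not performance on any
particular empirical dataset.  Real-data magnitudes (e.g. relative sizes of
third- versus second-order correlations in group data) are outside what
desk-scale simulation can reproduce and are not asserted anywhere in the
package.

Known limitations: cumulant orders above four are unsupported by design;
single-subject fourth-order inference is underpowered at realistic scan
lengths (a finding, not a bug); the block bootstrap's residual ~1
percentage-point size inflation at long scans is inherent to the method and
documented rather than corrected; and at $\nu = 5$ the fourth-order
estimators' sampling distributions are heavy-tailed enough that
moment-based summaries of simulation output (Pearson correlations, sample
variances) need robust alternatives, which the tests use.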