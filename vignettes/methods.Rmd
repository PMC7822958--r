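---
title: "Directed-coherence gradients from multichannel fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed-coherence gradients from multichannel fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcgradient)
```

## The scientific problem

The lateral prefrontal cortex is thought to be organized hierarchically
along its rostro-caudal axis, with rostral regions exerting a predominant
directed influence on caudal ones. Multichannel fNIRS sampled at 10 Hz can
resolve this axis spatially (rostral, middle, caudal prefrontal cortex) and
temporally (the 0.06–0.12 Hz band of low-frequency hemodynamic
oscillations, below respiratory and cardiac noise). `dcgradient`
implements the full analysis chain that turns such recordings into a
statistical statement about the rostro-caudal gradient of directed
functional connectivity and its modulation by deep-brain stimulation state
and patient covariates — together with a synthetic-data generator with
known directed coupling, so that every stage can be validated against
ground truth.

## Preprocessing model

**Modified Beer–Lambert law.** Optical-density changes are
$\Delta OD(\lambda, t) = -\log_{10} I(t)/I_0$ with $I_0$ the temporal mean
intensity of the recording, and concentration changes solve the 2×2 system
$\Delta OD = \varepsilon \,\Delta c\, d\, \mathrm{DPF}$ per sample.
Defaults: wavelengths 695/830 nm, extinction coefficients from standard
hemoglobin absorption tabulations, source–detector distance 3 cm, DPF 6.0
at both wavelengths; all overridable in `optics_config()`. Because $I_0$
is the temporal mean, concentration changes are defined only up to a
per-channel additive constant: every conversion output satisfies
$\mathrm{mean}_t\, 10^{-\Delta OD} = 1$. The inverse operation
(`generate_raw_intensities()`) therefore recovers an arbitrary series only
up to that constant; `mbll_gauge()` projects a series onto the
mean-referenced gauge, on which the round trip is exact. The shift is
second-order in signal amplitude and irrelevant after standardization.

**Bad-channel interpolation.** Channels without signal (hair occlusion,
detector saturation) are repaired sample-wise by 2-D spatial interpolation
over the good channels at the grid coordinates. We use an
inverse-distance-weighted local-plane (weighted least squares) interpolant.
Its testable contract is *linear precision*: any field linear in the grid
coordinates is reproduced exactly, and a neighborhood carrying one common
trace yields that trace. We chose this over triangulation-based barycentric
interpolation because it needs no triangulation machinery, behaves
gracefully at the convex-hull boundary, and satisfies the same contract.

**CBSI motion correction.** Head motion moves HbO and HbR in the *same*
direction while hemodynamics move them oppositely. Per channel, with
$x = \Delta HbO$, $y = \Delta HbR$, $\alpha = \mathrm{sd}(x)/\mathrm{sd}(y)$:
$x' = (x - \alpha y)/2$, $y' = -x'/\alpha$. The output is exactly
anticorrelated (Pearson $r = -1$), the common-mode artifact is cancelled
exactly in the symmetric case, and the transform is idempotent.

**Standardization, and nothing else.** Each channel is standardized to
zero mean and unit variance before model fitting. No filtering, detrending
or resampling is applied anywhere: such preprocessing is known to induce
spurious Granger-causal structure, which is why the analysis band is
selected in the frequency domain instead.

The fixed order is interpolate → CBSI → standardize (after optional MBLL).
Whether standardization precedes or follows interpolation is immaterial
for the contract tested here; the package fixes interpolate-first.

## Connectivity model

A vector autoregressive model
$x_t = \sum_{k=1}^{p} A_k x_{t-k} + \epsilon_t$ is fitted by per-equation
ordinary least squares, with order $p = 20$: at 10 Hz this spans the past
2 s of the series and gives a native spectral resolution of
$f_s/p = 0.5$ Hz. For the spectral estimate the coefficient sequence is
zero-padded to the length of the fitted series (7200 samples for a 12-min
recording, grid spacing ≈ 0.0014 Hz), which smooths the estimate without
adding information. The transfer function is
$H(f) = [I - \sum_k A_k e^{-i 2\pi f k / f_s}]^{-1}$, and the
noise-weighted directed coherence from source $j$ to sink $i$ is

$$\gamma_{ij}(f) = \frac{\sigma_j H_{ij}(f)}
{\sqrt{\sum_m \sigma_m^2 |H_{im}(f)|^2}}, \qquad
\sigma_m = \sqrt{\Sigma_{mm}},$$

which lies in $[0, 1]$ and satisfies $\sum_j |\gamma_{ij}(f)|^2 = 1$ per
sink and frequency. The reported connectivity value is the *magnitude*
$|\gamma_{ij}(f)|$, maximized over the grid frequencies inside the
(inclusive) 0.06–0.12 Hz band. Design choices worth flagging:

* **Magnitude, not squared magnitude.** "Maximum DC value" is ambiguous;
  the magnitude preserves $[0,1]$ and the ordering is identical. This is a
  single point of configuration should the squared convention be wanted.
* **Noise-weighted normalization** is the default; the unweighted variant
  (the directed transfer function) is available via `weighted = FALSE`.
* **One joint VAR over all analyzed channels** is the default
  (`scope = "joint"`; 7200 samples comfortably support 32 × 20 regressors
  per equation). Per-hemisphere and per-stream fits are available by
  configuration and are used in the package's own large replicate studies,
  where coupling is confined to streams by construction.
* **Unstable fitted VARs are a warning, not an error** — empirical fits on
  short records can be borderline; the companion spectral radius is always
  recorded. Generative models, by contrast, *refuse* to simulate from an
  unstable configuration.

## Network extraction and statistics

The analyzed grid is 2 hemispheres × 4 rostro-caudal streams × 4 levels
(level 1 most rostral); the 6 midline channels of the full 38-channel
probe are excluded from the stream analysis. Only directly neighboring
level pairs enter the connection table: 3 pairs × 4 streams = 12
connections per hemisphere, each read in both directions, 48 rows per
measurement. Hemispheres are labeled ipsi-/contralateral with respect to
the hemisphere of disease onset; since the recorded onset side is the
*symptomatic body side*, the ipsilateral hemisphere is by default the one
contralateral to it (`onset_is_body_side = TRUE`, configurable).

Connection tables are analyzed with linear mixed-effects models (lme4/
lmerTest, maximum likelihood), with random intercepts for participant ×
stream and participant × level pair — never reduced — and sum-to-zero
factor contrasts so that Type III marginal F tests (Satterthwaite
denominator degrees of freedom) are meaningful. The maximal fixed
structure crosses direction × hemisphere × stimulation state with each
covariate (age at onset, disease duration before implantation, time since
implantation, LEDD, VAT) in its own block; the replication model uses
direction × state × pre-implant duration. Reduction is top-down: among the
currently maximal interaction terms, the least significant one with
$p > 0.05$ is removed, the model refitted, and the procedure repeated;
main effects are never removed and marginality is never violated. Should
the Satterthwaite computation fail, likelihood-ratio tests are substituted
and flagged in the output — the in/out decision contract at
$\alpha = 0.05$, not the df recipe, is the tested surface. Post-hoc cell
means and simple slopes with Tukey-adjusted pairwise comparisons come from
`emmeans`. Multicollinearity is screened by variance inflation factors
computed from the fixed-effects design (flag threshold 5 by default).
Covariates enter untransformed (no centering) by default, with a switch,
since interaction interpretation depends on it. Tercile splits of
covariates are a projection device for summaries and figures only; the
models always use continuous covariates.

## The synthetic-data generator

The generator defines the study conditions: 24 participants; sessions ON
(n = 24), steady-state OFF (n = 22) and ON2, immediately after stimulation
is switched back on (n = 18), dropout emulated by truncating each
participant's session list; 12-min recordings at 10 Hz on the analyzed
grid. Covariates are truncated-at-zero normals — age at onset 50 ± 9 y,
pre-implant duration 9 ± 4 y, time since implantation 3.5 ± 2.5 y, LEDD
900 ± 350 mg/day, VAT 150 ± 60 mm³ — values a movement-disorders cohort of
this kind would plausibly show; the three time covariates sum to the
chronological age by construction, and the correlation between pre-implant
and overall disease duration is set to 0.79 by solving for the required
component correlation.

Signals come from a stable generative VAR: each channel has mild
first-order self-dynamics, a band-limited Gaussian drive (0.06–0.12 Hz —
band-limited noise rather than a sinusoid, to avoid degenerate spectra)
enters the most rostral channel of each stream, and lagged linear coupling
(lag 0.5 s) propagates activity along the stream in both directions. The
generative model class is thus contained in the analysis model class,
making parameter recovery well-posed. HbR is exactly −HbO until motion
artifacts (same-signed spikes on both chromophores, Poisson event times)
are injected. Every emitted configuration is checked for stability
(companion spectral radius < 1) and refused otherwise.

Effect sizes modulate the coupling gains, covariates entering as z-scores:
baseline 0.10 both directions, +0.08 rostro-caudal (the gradient), +0.02
when stimulated, −0.04 per SD of pre-implant duration when stimulated (the
key negative three-way), +0.03 per SD of VAT and +0.025 per SD of LEDD.
Interaction effects are injected *antisymmetrically* (+m rostro-caudal,
−m caudo-rostral). This is deliberate: after channel-wise
standardization the two directions' coefficient estimates are coupled
through the channel variances, so a modulation applied to one direction
alone partially leaks into the other and cancels in the direction
contrast; the push–pull injection makes the injected effect express itself
in the contrast the statistics test — and it is also the empirical
signature the covariate effects it emulates are described to have
(stronger rostro-caudal together with weaker caudo-rostral influences).
Baseline gains sit below the saturation knee of the band-max DC response
(which compresses above gains of roughly 0.3), so that effect-size
monotonicity holds over the tested range. Since no numerical DC magnitudes
are available to anchor them, the gains are free parameters of the
generator, fixed here once.

What the generator does *not* emulate: systemic physiology (Mayer waves,
respiration, cardiac pulsation), optical photon transport, spatially
correlated noise between neighboring channels, and any hemispheric
asymmetry. Passing recovery tests therefore demonstrates the estimator
chain is correct *for data of this class*, not that real recordings meet
its assumptions.

## Numerical choices and degenerate inputs

* Band edges are inclusive; a grid frequency exactly at 0.06 Hz
  participates in the band maximum.
* OLS VAR fits refuse rank-deficient regressor matrices; zero-variance
  channels are refused by name in CBSI and standardization; non-positive
  intensities and singular extinction matrices are configuration/data
  errors.
* The normalization identity ($\sum_j |\gamma_{ij}|^2 = 1$) is enforced to
  1e−10 in tests; the closed-form oracle agreement to 1e−8; CBSI
  anticorrelation to 1e−12.
* In the reduction, ties among removable terms are broken by removing the
  largest p first, one term per iteration, refitting before the next
  decision.
* lme4's post-estimation gradient check can flag borderline convergence on
  small simulated fits; genuine optimizer failure is an error, the
  post-hoc check a recorded warning.
* Mixed models are fitted by maximum likelihood (the analysis convention);
  REML is available and is used when comparing balanced designs against
  classical ANOVA, where the equivalence of the Satterthwaite Type III F
  with the blocked-ANOVA F is exact.

## Problem sizes used in the validation suite

The package's own studies are sized to run on a single CPU in minutes:
oracle sweeps use 50 two- and three-channel VAR(1) systems; detection uses
100 seeded 12-min two-channel runs; cohort-scale recovery uses 20
replicates of the full 24/22/18 cohort on the 32-channel grid with
per-stream VAR fits (coupling is stream-confined by construction, so the
per-stream scope estimates the same connections at a fraction of the
cost); the null-generator calibration uses 500 replicates of a reduced
cohort (n = 8, one hemisphere, 2 streams × 3 levels, 2-min recordings) and
the Type-I calibration of the Type III test 500 small balanced fits. These
are the package's choices of simulation size; all are configurable
upward.

## Known limitations

* The channel layout is a faithful schematic of the probe geometry
  (staggered lattice with the correct diagonal neighbor distance), not a
  coordinate-exact reconstruction of any particular montage; layouts are
  user-suppliable.
* Directed coherence quantifies directed *linear* dependence in the chosen
  band; it does not threshold individual edges statistically, and partial/
  time-varying variants are out of scope.
* The mixed models include random intercepts only (no random slopes), as
  in the analysis convention they implement.
* Reported F statistics on synthetic cohorts characterize the pipeline,
  not any empirical dataset: patient-level results are not reproducible
  without the original recordings, which is precisely why the generator
  exists.
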