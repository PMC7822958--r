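# dcgradient

Directed-coherence gradients from multichannel fNIRS.

## What this package is for

The lateral prefrontal cortex (PFC) is organized hierarchically along its
rostro-caudal axis: rostral regions exert a predominant directed influence
on caudal ones. `dcgradient` estimates this gradient from multichannel
fNIRS recordings and tests how it is modulated by deep-brain-stimulation
state and patient covariates. It is written for researchers analyzing
resting-state or passive-viewing fNIRS in clinical cohorts (e.g.
Parkinson's disease with subthalamic stimulation), and for methodologists
who want a fully synthetic, ground-truth-controlled test bed for
frequency-domain Granger-causality pipelines.

The chain, end to end:

1. **Preprocessing** — modified Beer–Lambert conversion of raw
   dual-wavelength intensities, spatial interpolation of signal-free
   channels, correlation-based signal improvement (CBSI) for motion
   artifacts, channel-wise standardization. No filtering or resampling
   anywhere (it induces spurious Granger causality).
2. **Connectivity** — a VAR(p) model (default p = 20, i.e. 2 s at 10 Hz)
   fitted by OLS; transfer function H(f) = [I − Σₖ Aₖ e^(−i2πfk/fs)]⁻¹ on a
   zero-padded frequency grid; noise-weighted directed coherence

   γᵢⱼ(f) = σⱼ Hᵢⱼ(f) / √(Σₘ σₘ² |Hᵢₘ(f)|²),  σₘ = √Σₘₘ,

   with Σⱼ|γᵢⱼ(f)|² = 1 per sink; the band maximum of |γ| over 0.06–0.12 Hz
   is the connectivity value per ordered channel pair.
3. **Network extraction** — on the analyzed 2 × 4 × 4 grid (hemisphere ×
   stream × level), the directly neighboring level pairs give 12
   connections per hemisphere, read in both directions (rostro-caudal vs
   caudo-rostral); hemispheres are labeled ipsi/contra w.r.t. the
   hemisphere of disease onset.
4. **Statistics** — linear mixed models (ML) of the connection table with
   random intercepts participant × stream and participant × level pair,
   Type III F tests with Satterthwaite df, top-down reduction of
   non-significant maximal interactions at α = 0.05, VIF screening,
   Tukey-adjusted post-hoc means and simple slopes, and control refits
   with substituted time covariates.
5. **Synthetic data** — a generative VAR with a narrowband 0.06–0.12 Hz
   drive entering rostral channels and propagating caudally, known
   directed coupling gains modulated by state and covariates, motion
   artifacts with the CBSI-detectable signature, and a 24-participant
   cohort with ON/OFF/ON2 sessions (24/22/18, dropout by truncation).

## Worked example

```r
library(dcgradient)

grid  <- make_grid()                 # 32 analyzed channels, 2 x 4 x 4
spec  <- cohort_spec(seed = 3)       # study conditions + effect sizes
study <- simulate_study(spec, grid)  # 64 measurements (24 ON, 22 OFF, 18 ON2)

dc <- estimate_connectivity(study$measurements[[1]], grid = grid)
print(dc)
#> Directed-coherence matrix: 32 channels, band 0.06-0.12 Hz (43 grid frequencies)
#>   off-diagonal DC: median 0.076, max 0.898

dc_list <- lapply(study$measurements, estimate_connectivity,
                  scope = "stream", grid = grid)
tab <- build_connection_table(dc_list, grid, study$cohort)
m2  <- reduce_model(tab, lmm_spec_model2())
print(m2)
#> Linear mixed model of directed coherence (reduced)
#>   fixed terms: 7 | random intercepts: participant:stream, participant:level_pair
#>
#> Type III tests (satterthwaite df):
#>                                     term      F num_df den_df         p
#>                                direction 921.21      1 2999.9 1.07e-176
#>                                    state   3.39      2 3013.9  3.37e-02
#>                  duration_before_implant   0.14      1   71.9  7.11e-01
#>                          direction:state  19.84      2 2999.9  2.75e-09
#>        direction:duration_before_implant  53.79      1 2999.9  2.85e-13
#>            state:duration_before_implant   2.19      2 3009.6  1.12e-01
#>  direction:state:duration_before_implant  12.62      2 2999.9  3.48e-06
```

Reading the output: the `direction` main effect is the rostro-caudal
gradient itself (rostro-caudal DC ≈ 0.56 vs caudo-rostral ≈ 0.21 in this
simulation); the retained `direction:state:duration_before_implant`
interaction is the injected clinical signal — ON-stimulation rostro-caudal
influences decline with disease duration before implantation. The simple
slopes confirm its sign:

```r
posthoc_contrasts(m2, specs = c("direction", "state"),
                  var = "duration_before_implant")
#> rostro_caudal OFF - rostro_caudal ON    0.0113   p = 0.0001   (ON slope more negative)
#> rostro_caudal ON  - rostro_caudal ON2   0.0014   p = 0.997    (ON and ON2 agree)
```

`run_pipeline(run_config(...))` executes the same chain end to end and
writes all intermediates plus a JSON manifest with checksums and warnings.

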