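# ammr — Adaptive Multipole Models for OPM-MEG interference rejection

Wearable optically-pumped-magnetometer (OPM) MEG systems sample the brain's
magnetic field on the scalp, on arrays of wildly varying design (radial,
dual-axis or triaxial sensors; tens to hundreds of channels), in the presence
of environmental interference orders of magnitude above the signal. `ammr`
implements multipole-model interference rejection for such arrays, for
methods developers and OPM users who need a cleaning stage that is stable on
*any* array geometry:

* real **spherical and prolate spheroidal harmonic bases** on arbitrary
  sensor arrays — the spheroidal radial dependence uses ratios of associated
  Legendre functions, `Q_l^m(r_maj/c) / Q_l^m(a/c)` (internal) and
  `P_l^m(r_maj/c) / P_l^m(a/c)` (external), normalised to 1 on a reference
  spheroid fit to the head, and reduces to the spherical laws `(a/r)^(l+1)`,
  `(r/a)^l` as the focal distance `c → 0`;
* two projectors built from the basis `H = [H_in H_out]`, with
  `R_out = I − H_out H_out⁺`:
  - **SSS-style (oblique)** `P = H_in (R_out H_in)⁺` — reproduces the
    internal span exactly, but can amplify noise on poorly conditioned
    arrays;
  - **AMM (orthogonal)** `P = (R_out H_in)(R_out H_in)⁺` — symmetric and
    idempotent, never increases variance, reduces iid sensor noise by
    `10·log10(n_c / rank P)` dB;
* **temporal CCA cleaning** between the inner and intermediate spaces, with
  a closed-form **correlation-limit heuristic**
  `ρ_max = αβ / sqrt((β² + k)(α² + k))`, `k = T·σ_ε² / (τ·σ_X²·n_c)`;
* a full **simulation suite**: scalp-conformal array generation,
  current-dipole lead fields in a conducting sphere, homogeneous-field +
  first-order-gradient interference, spatially structured multiplicative
  nonlinearity, white noise; plus metrics (shielding factors, lead-field
  reconstruction correlation, white-noise reduction, Welch PSD shielding,
  epoch t-statistics).

## Worked example

```r
library(ammr)
sph  <- reference_spheroid()          # head-sized: a = 8 cm, b = 7 cm
arr  <- generate_scalp_array(sph, spacing = 0.025, axes = 3, seed = 1)
arr
#> <sensor_array> 195 channels (65 sensors x 3 axes)

bas <- build_basis(arr, sph, family = "spheroidal", L_in = 9, L_out = 2)
bas
#> <harmonic_basis> 195 channels x 107 harmonics (99 internal [spheroidal], 8 external [spherical])

P_amm <- amm_projector(bas)           # orthogonal, rank 99
P_sss <- sss_projector(bas)

white_noise_reduction(P_amm, seed = 1)            # 2.94 dB  (law: 10*log10(195/99) = 2.94)
worst_case_shielding(arr, P_amm, n_interf = 50, n_nonlin = 20,
                     e_max = 0.01, seed = 1, origin = sph$centre)$min_linear
#> 203  (46.2 dB at 1% structured nonlinearity)

lf <- simulate_leadfields(arr, sph, n_src = 300, seed = 2)
min(leadfield_correlation(lf, P_amm, "cosine"))   # 0.923 worst source
```

Read: on this 195-channel triaxial array the orthogonal AMM projector keeps
99 of 195 spatial degrees of freedom, shaving 2.9 dB off the white-noise
floor; even when every channel's gain is corrupted by a structured 1%
nonlinearity, the worst of 1000 simulated interference patterns is still
attenuated 203-fold; and the worst-case simulated source keeps 92% of its
lead-field topography after projection. Cleaning a recording is then
`apply_projector(P_amm, rec)` or, with the temporal stage,
`temporal_clean(rec, bas, limit = 0.98)`.

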