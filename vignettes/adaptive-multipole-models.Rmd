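---
title: "Adaptive multipole models for OPM-MEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive multipole models for OPM-MEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ammr)
```

## The problem

Optically pumped magnetometers (OPMs) sample the neuromagnetic field a few
millimetres above the scalp, on arrays whose geometry varies widely between
laboratories: single-axis (radial), dual-axis or triaxial sensors, anywhere
from tens to hundreds of channels. Environmental magnetic interference is
orders of magnitude larger than brain signal, and because the sensors move
with the head, reference-array and empty-room methods that assume a fixed
sensor-to-environment geometry do not carry over. Multipole (harmonic) models
separate the measured field into a part generated inside the array (brain)
and a part generated outside it (interference) using only the sensor
geometry. This package implements two such projectors on either spherical or
prolate spheroidal harmonic bases, a temporal canonical-correlation cleaning
stage, and a complete simulation suite for characterising their behaviour on
arbitrary array designs.

## Field model

In a current-free region the field derives from a scalar potential,
$\mathbf B = -\mu_0 \nabla V$, and $V$ solves Laplace's equation. In
spherical coordinates $(r, \theta, \varphi)$ about a reference sphere of
radius $a$,

$$V = \sum_{l,m} \alpha_{lm} \left(\frac{a}{r}\right)^{l+1} S_{lm}(\theta,\varphi)
    + \sum_{l,m} \beta_{lm} \left(\frac{r}{a}\right)^{l} S_{lm}(\theta,\varphi),$$

with $S_{lm}$ the orthonormal real surface harmonics. The first (internal)
series converges outside the reference surface and models sources inside it;
the second (external) series models distant sources. On-scalp sampling
breaks the spherical premise: no sphere containing the brain keeps all
sensors outside it, and convergence suffers at the front and back of the
head. The brain is, however, well enclosed by a prolate spheroid (longer in
the anterior–posterior direction). In prolate spheroidal coordinates
$(r_{maj}, \theta, \varphi)$ — where $r_{maj}$ is the semi-major axis of the
confocal spheroid through a point, equal to $(d_1+d_2)/2$ with $d_{1,2}$ the
distances to the two foci — the radial power laws are replaced by ratios of
associated Legendre functions of the second and first kind,

$$\frac{Q_l^m(r_{maj}/c)}{Q_l^m(a/c)} \quad\text{(internal)}, \qquad
  \frac{P_l^m(r_{maj}/c)}{P_l^m(a/c)} \quad\text{(external)},$$

normalised to 1 on the reference surface ($r_{maj} = a$, focal distance
$c = \sqrt{a^2 - b^2}$). Both ratios reduce to the spherical laws
$(a/r)^{l+1}$ and $(r/a)^l$ as $c \to 0$; the property suite asserts this
limit numerically. The internal $Q$-ratio is evaluated through a
hypergeometric-type series in $(c/r_{maj})^2$ whose leading gamma constants
cancel in the ratio; terms are added until the next term contributes less
than `tol` (default `1e-12`, hard cap 200 terms, error with $(l, m, c/r_{maj})$
context on non-convergence). The external $P$-ratio is a finite alternating
sum with upper index $\lfloor (l-m)/2 \rfloor$ (the reciprocal-gamma
convention makes any larger upper bound equivalent, since
$1/\Gamma(\text{non-positive integer}) = 0$). Negative orders use the sine
convention of the real harmonics with ratios evaluated at $|m|$.

A basis column for channel $i$ and harmonic $(l, m)$ is the directional
derivative $\mathbf o_i \cdot \nabla V_{lm}(\mathbf r_i)$ along the channel
orientation. Gradients are computed by central finite differences (step
$10^{-6} a$); for the spherical family the suite checks them against
analytic solid-harmonic gradients at $10^{-6}$ relative accuracy, which
validates the scheme for the spheroidal family too (same code path).
Degree $l = 0$ is excluded from both blocks — its gradient carries no
magnetic field information here, and the internal column count is then
$L^2 + 2L$ (99 at order 9, 143 at order 11). Columns are normalised to unit
Euclidean norm (the permeability and overall sign are absorbed into the
recorded scales), standard practice for conditioning; projected data remain
in Tesla because projectors are built from the normalised columns only.

## The two projectors

With $H = [H_{in}\; H_{out}]$ the channels × harmonics basis and
$R_{out} = I - H_{out} H_{out}^{+}$ the orthogonal rejector of the external
span, the partitioned-coefficient identity gives the internal least-squares
reconstruction in a single product:

* **SSS-style (oblique)**: $P_{sss} = H_{in} (R_{out} H_{in})^{+}$.
  Reproduces every internal topography exactly ($P H_{in} = H_{in}$) and
  annihilates the external span, but is asymmetric; on arrays that separate
  the two spans poorly (radial or dual-axis designs) the pseudoinverse
  amplifies model residuals and white noise.
* **AMM (orthogonal)**: $P_{amm} = (R_{out} H_{in}) (R_{out} H_{in})^{+}$,
  the orthogonal projector onto the part of the internal span orthogonal to
  interference. Symmetric and idempotent, hence norm-non-increasing for
  every input: white noise is always reduced, by
  $10 \log_{10}(n_c / \mathrm{rank}\,P)$ dB for iid noise. The price is that
  internal signal spatially correlated with interference is attenuated.

Pseudoinverses are SVD-truncated at `rtol = 1e-10` relative; no further
regularisation is applied by default (an explicit choice: the oblique
projector's instability on poorly conditioned arrays is a finding, not a
nuisance to be hidden), though the truncation threshold is exposed. The
partitioned form is used rather than inverting $[H_{in}\,H_{out}]$ wholesale
so that any instability is isolated in $(R_{out} H_{in})^{+}$. Both
projectors are stored densely; arrays up to roughly a thousand channels are
the intended scale. SSS and AMM coincide when the two spans are exactly
orthogonal, and the suite verifies this on synthetic orthogonal blocks.

The external family defaults to *spherical* even when the internal family is
spheroidal: at external order 2 the spherical block spans exactly the
physical interference model used throughout — three homogeneous field
components plus the five independent components of a symmetric traceless
first-order gradient tensor. A spheroidal external block is available as an
option.

## Temporal cleaning and the correlation limit

Interference that the spatial model cannot represent (sensor nonlinearity,
truncation) leaks into both the inner space $P_{amm} Y$ and the intermediate
space $Y - P_{amm} Y - H_{out} H_{out}^{+} Y$. The cleaning stage
orthonormalises the temporal bases of both spaces by SVD (dropping
directions below $10^{-10} \sigma_{max}$), takes the singular values of their
product as canonical correlations — numerically stabler than
covariance-inversion CCA — and projects out of the inner space every
canonical temporal direction whose correlation reaches the limit (default
0.98). The intermediate rather than the outer space is used because it has
many more degrees of freedom. The default window is the whole recording;
windowed operation is available for long sessions. Removal is an orthogonal
temporal projection, so total power never increases.

How high can that correlation be by chance, from brain signal alone? If
fractions $\alpha$ and $\beta$ of a neural signal of variance $\sigma_X^2$
appear in the inner and intermediate spaces, the white-noise variance is
$\sigma_\varepsilon^2$, the window is $T$ seconds, neural activity stays
correlated over at most $\tau$ seconds (0.25 s is typical of an evoked
response) and matched combinations over $n_c$ channels are formed, then

$$\rho_{max} = \frac{\alpha\beta}{\sqrt{(\beta^2 + k)(\alpha^2 + k)}},
\qquad k = \frac{T \sigma_\varepsilon^2}{\tau \sigma_X^2 n_c}.$$

Setting the limit at or above $\rho_{max}$ protects brain signal. The bound
is 1 in the noiseless limit, 0 when either fraction vanishes (and, by a
continuity convention, when $\sigma_X^2 = 0$), increasing in
$\sigma_X^2, n_c, \tau$ and decreasing in $T, \sigma_\varepsilon^2$. The
test suite validates it against a Monte-Carlo construction — a shared
sinusoid active for $\tau$ of $T$ seconds, split across two noisy
$n_c$-channel groups and recovered by matched filters. For that construction
the bound is *tight* (the population correlation equals it), so replicates
scatter symmetrically around it within sampling error; the suite asserts
exactly that, rather than strict one-sided exceedance. The fractions
$\alpha$ and $\beta$ are not observable directly; defaults of
$\alpha = 0.95$ (the "sufficiently modelled" reconstruction criterion) and
$\beta = \sqrt{1 - \alpha^2}$ are documented choices for users who want an
adaptive limit.

## What the simulation suite emulates — and what it does not

* **Arrays.** Sensors are packed quasi-uniformly (Fibonacci lattice seeding,
  Poisson-disk thinning at the requested spacing) on a head-sized reference
  spheroid — semi-axes 8 cm anterior–posterior and 7 cm transverse, a
  child-to-small-adult head — then displaced 6.5 mm outward along the
  surface normal, a typical OPM cell stand-off. The first axis is the
  outward normal; tangential axes zero the third component of the normal
  $[p, q, r]$, swap and negate to get $[-q, p, 0]$ (with $[1, 0, 0]$ as the
  documented fallback at the poles), and complete the right-handed triad by
  a cross product.
* **Lead fields.** A current dipole in a homogeneous conducting sphere
  (closed form; the external field is independent of the conductor radius).
  Sources sit on a spheroidal shell at 0.9× the scalp semi-axes with
  surface-normal orientations. This is a deliberate, documented substitute
  for a boundary-element or single-shell model on a cortical mesh, and it
  changes the *reconstruction* statistics materially: shell sources are
  uniformly shallow (7–8 mm below the scalp), so their topographies are more
  focal than real cortex — worst-case reconstruction correlations come out
  *higher* for radial and dual-axis arrays (no deep, spatially smooth
  sources overlapping the external span) and slightly *lower* for triaxial
  arrays at a given order (larger truncation residuals). The white-noise and
  interference-rejection results do not depend on the forward model and
  transfer directly.
* **Interference.** Random combinations of homogeneous fields and symmetric
  traceless first-order gradients, scaled to unit channel RMS. These lie
  exactly in the order-2 spherical external span, so shielding is
  numerically infinite absent nonlinearity.
* **Nonlinearity.** Channel-wise multiplicative corruption
  $(I + \mathrm{diag}(n))\,e$, with the perturbation topography itself a
  random field+gradient pattern rescaled so its largest entry is the target
  fractional error (0.5%–10%). This is the diagonal-gain abstraction of
  cross-talk and calibration drift, chosen adversarially rather than
  realistically: the reported worst case over 50 interference × 20
  nonlinearity draws is a conservative performance floor, and its
  log–log slope against the error magnitude is $-1$ (shielding is the
  reciprocal of the fractional nonlinearity).
* **White noise.** iid Gaussian draws behind explicit seeds; every
  stochastic function takes a seed and is reproducible.

Problem sizes in the shipped tests and the acceptance script are desk-scale
by design: arrays of roughly 100–420 channels, 300–500 sources, 50 × 20
nonlinearity draws, 50 noise repetitions. These sizes put the Monte-Carlo
error well below the tolerances asserted.

## Numerical choices and degenerate inputs

* $\cos\theta$ from focal distances is clamped to $[-1, 1]$ (focal-line
  safety); the exact origin maps to $(0, 0, 0)$ in spherical coordinates.
* A spheroid with $c = 0$ is rejected by the spheroidal transform with a
  pointer to the spherical path; basis construction switches automatically.
* Spheroid fitting takes the axis from the leading principal component
  (sign fixed deterministically), then optimises $(a, b)$ on the algebraic
  residual; `enclose` mode rescales the fitted shape to contain every point.
  Clouds with rank-deficient covariance are rejected by name.
* Channels sampling inside the reference surface trigger a warning, not an
  error: on-scalp arrays can violate the spherical convergence region, which
  is precisely when the spheroidal frame should be preferred.
* Sources at the conductor centre, or not strictly inside the sensor shell,
  are rejected (no separating sphere exists).
* A zero standard error in epoch t-statistics yields a guarded
  $\pm 10^{12}$ rather than infinity.

## Known limitations

* The forward model is a conducting sphere on a shell source space:
  reconstruction metrics should be read as characterising the projectors on
  *this* geometry, not as per-vertex predictions for a real head (see
  above).
* No MaxFilter-compatible SSS dialects (fine calibration, component
  selection, regularised variants), no movement simulation, no anatomical
  meshes or co-registration.
* The oblique SSS projector is deliberately left unregularised; on radial
  and dual-axis arrays its reconstruction and noise behaviour is unstable,
  which the diagnostics (`condition_report()`) surface as a joint condition
  number orders of magnitude above the triaxial case.
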