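---
title: "Methods: depth-resolved stiffness tomography of corneocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-resolved stiffness tomography of corneocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneomech)
```

## Scope and model

`corneomech` estimates the apparent elastic modulus of stratum corneum
corneocytes from AFM force-volume data, resolved by indentation depth.
The contact model is the Hertz–Sneddon law for a sharp pyramidal
indenter,

$$F(\delta) = C\,\tan\theta\,\frac{E_a}{1-\nu^2}\,\delta^2,$$

with fixed units nm / nN / MPa (the conversion constant
$1\,\mathrm{MPa\,nm^2} = 10^{-3}\,\mathrm{nN}$ is handled internally).
Its assumptions — elastic half-space, sharp rigid tip, small strain, no
adhesion — are idealizations for a layered, finite, viscoelastic cell;
the estimate is therefore an *apparent* modulus, meaningful for
comparisons made with a fixed geometry and fit range, which is exactly
how the package uses it.

Three genuinely open choices were settled as follows:

* **Geometry prefactor $C$.** The quadratic law is standard but its
  prefactor is convention-dependent. Default $C = 2/\pi$ (Sneddon cone
  of equivalent half-angle); $C = 0.7453$ (four-sided pyramid) is one
  argument away. Because $C$ multiplies every fitted modulus equally,
  any fixed choice leaves all within-study comparisons unchanged.
* **Poisson ratio.** $\nu = 0.5$, the incompressible limit customary
  for hydrated biological material; configurable, and $1-\nu^2 > 0$ is
  enforced.
* **Tip radius.** Stored as metadata only (nominal 8–12 nm for the
  probes this analysis targets); no blunting correction, since a single
  quadratic law is fitted throughout.

## Estimator chain

Per curve: (1) a straight line fitted to the first 30% of samples
(pre-contact) is subtracted — offset and drift removal; (2) contact is
the last sample within one noise SD of zero before the first run of
three consecutive samples above $3\sigma$ ($\sigma$ estimated from the
detrended baseline window unless supplied); (3) depth is re-referenced,
$\delta = (z - z_0) - F/k$ when a spring constant $k$ is given,
$\delta = z - z_0$ otherwise (data pre-converted to tip–sample
distance); (4) least squares of

$$F = F_0 + C\tan\theta\,\frac{E_a}{1-\nu^2}\,(\delta^2-\delta_{lo}^2)$$

on each window $[\delta_{lo}, \delta_{hi}]$ — ten 5 nm segments over
0–50 nm and one full-range window. The free offset $F_0$ absorbs force
accumulated above the window, so each segment estimates a *local*
apparent modulus; subtracting $\delta_{lo}^2$ keeps the regressor
anchored at the window entry. The fit is linear in
$\delta^2-\delta_{lo}^2$, hence exact on noiseless model curves (the
round-trip tests assert $10^{-6}$ relative recovery).

Numerical contracts: windows with fewer than 3 samples (6 for the
full range) raise a classed underfill error; non-positive fitted moduli
raise a classed fit failure carrying diagnostics; curves ending
shallower than 50 nm are fitted over their available range, recorded in
`depth_effective`. Whether the study's headline $E_a$ was a full-range
fit or an aggregate of segment fits is not determinable from published
descriptions; both are computed and the full-range fit is the default
headline.

At cell level, pixels (not curves) are the unit of failure: any pixel
whose chain fails at any stage is masked with its reason recorded,
never imputed, and a cell is reported whenever at least one pixel
survives. The cell aggregate is the **median** over unmasked full-range
pixels (robust to debris/edge pixels; the outlier test puts 5% of
pixels at 10× and requires ≤ 2% shift), the subject aggregate the
**mean** over cells (each cell an equally weighted acquisition); both
are switchable, and the choice is recorded in the outputs.

### Contact detection caveats

The threshold-crossing detector is deterministic and testable, but at
finite noise it localizes contact where the force *emerges from* the
noise floor, i.e. late by roughly the depth at which
$F \approx \sigma$. At the default instrument noise (0.1 nN) this is
~2 nm for a 100 MPa surface; the Monte-Carlo test requires ≤ 3 samples
error in ≥ 95% of draws at 1 nm sampling. Two knock-on effects are
visible in tomograms and are physical consequences, not bugs: shallow
segments read a few percent high (the compressed depth axis steepens
the apparent quadratic), and at 2% -of-setpoint noise (3 nN) contact is
only localizable to ~5 nm, which is why ground-truth-contact recovery
is the meaningful test of the *fitting* stage at that noise level (the
generator emits true contact positions for exactly this purpose).

## What the generator emulates — and what it does not

`generate_force_volume()` builds curves from a three-zone depth profile
(defaults: boundaries 10 and 20 nm; moduli 100/200/400 MPa — ordered
soft surface / intermediate envelope / stiff interior; the ordering is
the only published constraint, the magnitudes are order-of-magnitude
choices in the hundreds-of-MPa range typical of corneocyte
indentation). Within each zone the local stiffness acts through
$\mathrm{d}F = 2C\tan\theta\,\frac{E(\delta)}{1-\nu^2}\,\delta\,
\mathrm{d}\delta$, integrated across boundaries; $F$ is continuous with
the stated within-zone slope (the slope itself necessarily steps where
$E(\delta)$ steps). Embedded artifacts: per-pixel lognormal modulus
scaling ($\sigma = 0.1$), Gaussian force noise (0.1 nN), linear
baseline tilt (0.002 nN/nm), contact-position jitter (2 nm SD), 0.1 nm
sampling (~1000 samples over a ~100 nm ramp, as captured
high-resolution force curves provide), 40 nm approach, and truncation
where the *noisy* force first reaches the 150 nN setpoint, as a
force-triggered controller would stop. Every artifact carries its full
parameterization and seed; regeneration is bit-identical.

Not emulated: adhesion and retract hysteresis, viscoelastic rate
dependence, substrate (finite-thickness) stiffening, tip blunting and
contamination, piezo creep/hysteresis, and spatially correlated
(non-lognormal) heterogeneity such as corneodesmosomes. Passing tests
therefore demonstrate that the estimator chain is correct and robust
under the stated noise model — not that real tape-stripped corneocytes
satisfy that model. A deliberately simple consequence worth knowing:
pixels stiffer than ~200 MPa (after scaling) reach the setpoint before
50 nm, so the deepest segments are populated only by the softest
pixels. Aggregates over sparsely populated deep segments are
selection-biased low, which is why across-pixel ordering checks exclude
segments reached by fewer than half the pixels.

`generate_cohort()` draws subjects with the study design: 20 patients
(FLG wild-type/heterozygous/homozygous-or-compound = 5/10/5) and 7
controls (5/2/0). NMF is the single latent driver — the simplest
structure consistent with the observed correlation pattern: genotype
lowers the NMF mean with allele dose (WT > het > hom) and the patient
group carries an additional NMF deficit independent of genotype; then
$E_a = 400\,\mathrm{NMF} + \varepsilon$ (SD 40 MPa),
$\mathrm{TEWL} = 37.8 - 29.9\,\mathrm{NMF} + \varepsilon$ (SD 3), and
SCORAD $\sim N(47.2, 15)$ truncated to $[0, 103]$, independent of
$E_a$. The TEWL intercept/slope were calibrated once so that the
default design reproduces group mean TEWL of 24.7 (patients) and 9.6
(controls) g·m⁻²·h⁻¹, and SCORAD is centred on 47.2 — published
cohort descriptives used as design targets. NMF (0.25–1.0 mmol/g
protein) and $E_a$ scales are realistic orders of magnitude only; every
test asserts relative recovery or signs, never absolute values of those
two. TEWL and NMF are truncated at physical floors (1 g·m⁻²·h⁻¹ and 0),
which very slightly compresses the extreme tails.

`generate_topography()` (rendering/fixtures only) adds
Poisson-scattered dome protrusions to a correlated-noise base surface
for the AD group; protrusion morphology is never analysed
quantitatively here.

## Statistics module

* **Variance gate.** "Welch in the case of non-equal variance" needs an
  operational gate: a two-sided F-test at $\alpha = 0.05$ by default
  (Brown–Forsythe Levene as the config alternative, for its robustness
  to non-normality). Shapiro–Wilk normality p-values are *reported*
  with every comparison, never used to switch tests. The acceptance
  suite checks the composite procedure's type-I error on null normal
  data over 2000 replicates against 0.05 ± 0.01.
* **Spearman p-values.** Exact permutation for $n \le 10$, computed by
  a subset-sum dynamic program over the linear rank statistic
  $S=\sum a_i b_{\pi(i)}$ (ties handled by average ranks scaled to an
  integer lattice; the full null distribution over all $n!$
  permutations, no sampling). The t-approximation is used beyond.
  Cohorts of 7–27 straddle the small-$n$ regime, hence the split.
* **Missing data.** Pairwise complete cases with the used $n$ reported
  per cell; fewer than 4 pairs flags the cell missing. SCORAD pairs are
  restricted to patients. Nothing is imputed anywhere.
* **Multiplicity.** No correction by default, matching common reporting
  of such cohorts; Benjamini–Hochberg is available
  (`p_adjust = "BH"`) and off by default.

## Pipeline and problem sizes

`run_pipeline()` composes simulate (or read) → fit → aggregate → stats
→ report; everything derives from one seed, and identical config + seed
give byte-identical tables. The default configuration measures each
subject's $E_a$ through the force-volume route on 3 cells of 4×4
curves — a deliberately reduced acquisition density chosen so that the
×50-cohort pattern-recovery run (1350 subjects, ~65 000 curves)
completes in a couple of minutes on one CPU while still exercising
every stage; the per-cell analyses in the unit tests use the full
10×10 grids. Acceptance checks run at: 100 pixels for zone recovery
and depth ordering, 500 curves for noise robustness, 2000 replicates
for the type-I rate, ×50 for the cohort pattern.

## Known limitations

* The apparent modulus conflates layer properties within the fit range;
  no deconvolution of true layer moduli is attempted.
* Threshold contact detection is biased late at low surface stiffness
  relative to noise; a ratio-of-variances detector would trade
  determinism for less bias and was noted but not implemented.
* The HDF5 variant of the force-volume container is not provided; the
  equivalent long-format CSV (+ YAML sidecar) is the interchange
  format.
* Cohort simulation treats subjects as exchangeable within stratum;
  age, body-site and seasonal effects on TEWL/NMF are not modelled.
* Retract curves, adhesion work, and spring-constant calibration are
  out of scope by design.
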