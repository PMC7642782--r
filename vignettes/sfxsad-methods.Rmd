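---
title: "Models and methods behind sfxsad"
author: "sfxsad authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sfxsad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Serial femtosecond crystallography (SFX) records one still diffraction
pattern per microcrystal.  Because the crystal neither rotates nor survives
the pulse, every Bragg observation is *partial* — only the fraction of the
reflection's reciprocal-space volume that intersects the Ewald sphere is
recorded — and every pattern carries its own unknown scale factor,
temperature-factor offset and orientation.  Native-SAD phasing on top of
this measures a signal (the Bijvoet intensity difference from sulfur
anomalous scattering, a few percent of the mean intensity) that is far
below the noise of any single observation.  Whether phasing succeeds is
therefore a question about *aggregate* data quality: how many patterns
must be merged before the anomalous signal stands clear of the noise, and
how much do better geometry calibration and better partiality modelling
reduce that number.

`sfxsad` implements this entire measurement chain at desk scale: a
synthetic still simulator with exact ground truth, Monte Carlo merging
with per-crystal scaling and partiality post-refinement,
detector-distance optimization, and the anomalous data-quality
indicators (S_ano, CC_ano, CC_ano model-versus-data, R_split, CC_1/2)
used to compare processing strategies.

# Crystallographic core

Structure factors are computed by direct summation,

$$F(\mathbf h) = \sum_{s}\sum_{j} o_j\, f_j(s_{\theta\lambda})\,
  e^{-B_j s_{\theta\lambda}^2} e^{2\pi i\,\mathbf h\cdot(R_s\mathbf x_j + \mathbf t_s)},$$

with $f_j = f_0(s_{\theta\lambda}) + f' + i f''$ and
$s_{\theta\lambda}=1/(2d)$.  $F(-\mathbf h)$ is evaluated with the *same*
complex $f_j$; this sign convention is what makes $|F^+| \ne |F^-|$ when
$f'' > 0$.  $f_0$ uses the standard 4-Gaussian-plus-constant
parameterization, bundled for H, C, N, O and S only — enough for a protein
with a native sulfur substructure; other elements raise an error rather
than silently extrapolate.

Three space groups are hard-coded as explicit operator lists: P1,
P4~1~2~1~2 (no. 92, the tetragonal thaumatin-like form) and C222~1~
(no. 20, the orthorhombic A2A-like form).  The reciprocal asymmetric unit
is defined canonically as the lexicographic maximum over the Laue images
of both $\mathbf h$ and $-\mathbf h$; the Friedel flag records whether the
inversion was used.  Any consistent convention works; this one is chosen
because idempotence and mate-collapse are trivially testable.  Reflections
whose Friedel mate lies in their own Laue orbit are flagged centric and
merge to a single record.

# The still simulator

Each pattern draws a crystal with

* a uniform random orientation (random unit quaternions),
* cell lengths jittered by independent Gaussian factors (default 0.2%
  fractional spread, matching the per-dataset cell-length spreads of
  roughly 0.1–0.4 Å reported for real serial datasets on these crystal
  forms),
* a log-normal linear scale (default sd(log) = 0.3) and a Gaussian
  B-factor offset (default sd 5 Å²), emulating crystal-size and disorder
  variation,
* a log-normal profile radius around $R = 2\times10^{-3}$ Å⁻¹.  The beam
  bandwidth (~0.7–0.9% FWHM at these photon energies) is *not* modelled
  explicitly; it is absorbed into this effective reflection size, keeping
  partiality one-dimensional.

A reflection is recorded when its excitation error — the signed distance
from the Ewald sphere, $r = |\mathbf k_0 + \mathbf q| - 1/\lambda$ —
satisfies $|r| < R$, its resolution is within the cutoff, and its spot
(the intersection of the diffracted ray with the detector plane)
falls on the detector.  The recorded fraction is the spherical-cap
volume fraction

$$p(t) = \tfrac{1}{4}(2 - 3t + t^3), \qquad t = \mathrm{clamp}(r/R, -1, 1),$$

i.e. the volume of a sphere of radius $R$ cut off by a plane at signed
distance $r$: $p(-R)=1$, $p(0)=\tfrac12$, $p(R)=0$.  Intensities are

$$I = k\, s_j\, e^{-2B_j s_{\theta\lambda}^2}\, p\, |F|^2 + \varepsilon,
  \qquad \varepsilon \sim \mathcal N(0,\; I_0 + \sigma_{bg}^2),$$

a Gaussian approximation to counting noise plus a background floor, with
$\sigma$ stored from the *true* intensity so that negative recorded
intensities are possible, as in real SFX data.  Patterns with fewer than
10 observations are discarded ("crystal hit" threshold).

**Noise calibration.**  The defaults $k = 0.01$ (photon scale) and
$\sigma_{bg} = 15$ counts put the median per-observation I/σ near 2.3 —
deliberately weak-signal conditions typical of still data measured with
low beam transmission — and give merged datasets whose overall ⟨I/σ⟩,
R_split and CC_1/2 at a few thousand patterns resemble the values
reported for real serial datasets.  Because the toy model is small (100
atoms with 10 sulfurs, Bijvoet ratio ≈ 11%, versus 1558 atoms with 17
sulfurs ≈ 3.3% for thaumatin), the anomalous signal per reflection is
several times larger than in the real experiment, and S_ano threshold
crossings occur at hundreds rather than tens of thousands of images.
The *ratios* between processing strategies and photon energies — the
quantities of scientific interest — are preserved.

**What the simulator does not emulate:** pixel-level images and spot
profiles, detector gain/pedestal artefacts, jet background scattering,
multi-crystal hits, spectral jitter between pulses, and absorption by
window materials.  Consequently, passing tests demonstrate the internal
consistency and statistical behaviour of the analysis chain under its
own assumptions, not performance on raw detector frames.

# Detector-distance optimization

A wrong sample-to-detector distance distorts every derived |q|
nonlinearly with scattering angle, so per-pattern unit-cell estimates
scatter more (and indexing residuals grow) the further the assumed
distance is from the truth.  `distanceScan()` refits every pattern's cell
lengths at each candidate distance on a uniform grid (default 20 µm
increments) by linear least squares on

$$d^{*2} = \frac{h^2+k^2}{a^2} + \frac{l^2}{c^2}
  \quad\text{(tetragonal; analogously orthorhombic)},$$

and reports the standard deviation of each fitted length over indexed
patterns plus the indexed fraction.  The optimum is the argmin of the
c-length spread (ties break to the smaller distance); a- and c-based
optima agree on default simulations.

Two numerical points matter here:

* **Off-sphere correction.**  The elastic unprojection of a spot assumes
  the reflection sits exactly on the Ewald sphere, but it sits at
  excitation error $r$, and exactly
  $\hat q^2 = (q^2 - r^2)/(1 + \lambda r)$.  The fit therefore inverts
  this relation using the per-reflection excitation error carried in the
  stream record (index assignment and $r$ come from the simulator's
  stored indexing solution — the package's "oracle indexer" — mirroring
  how stream files from real pipelines carry predicted reflection
  geometry).  Without the correction the recovered optimum is
  systematically offset by ~100 µm at default conditions; with it,
  noise-free scans recover the distance to machine precision and the
  spread at the true distance is below 10⁻⁴ Å.
* **Indexing gate.**  A pattern counts as indexed when the rms relative
  residual of the fit is below 10⁻³.  At the true distance essentially
  all patterns pass; at ±0.2 mm most fail, so the indexing-rate curve
  peaks (as a plateau) around the optimum.

The distance-recovery benchmark runs with cell jitter disabled.  With the
default 0.2% jitter the cell spread at the true distance (~0.3 Å) buries
the 20 µm-scale distance signal for any desk-scale pattern count — the
standard error of a standard deviation over 500 patterns is two orders of
magnitude larger than the curve's change per grid step — so the
calibration experiment isolates geometry, which is what a distance scan
measures in practice when the crystal form is well known.

# Monte Carlo merging

`runMerge()` implements the pipeline: initial unscaled Monte Carlo merge
as reference → (per iteration, default 1) per-crystal scaling, then under
the `xsphere` model partiality post-refinement, then a re-merge → a
per-crystal resolution push → robust outlier rejection → final merge.

* **Models.**  `unity` sets $p \equiv 1$ (plain Monte Carlo averaging);
  `xsphere` divides each observation by its spherical-cap partiality
  evaluated from the stored excitation error and the crystal's current
  profile radius.  Corrected observations with $p < 0.05$ are excluded —
  dividing by a tiny partiality amplifies noise without bound.
* **Scaling.**  Per crystal, ordinary regression of
  $\log(I_{obs}/(p\,I_{ref}))$ on $s_{\theta\lambda}^2$: the intercept is
  the log scale, the slope $-2B$.  Crystals with fewer than 3 usable
  reflections keep scale 1, B 0 and are flagged.  Log scales are centered
  to mean zero (the global scale is unobservable).
* **Post-refinement.**  One-dimensional least-squares refinement of each
  crystal's profile radius over a bounded bracket (×0.25–×4 around the
  current value) with `stats::optimize`; a refined value is accepted only
  if it does not increase the residual, so the step is a descent by
  construction.
* **Averaging.**  Unweighted mean of corrected intensities per
  (ASU, Friedel side).  Sigma is the sample standard deviation over
  $\sqrt n$, floored by the propagated estimate, for $n \ge 2$; the
  propagated single-observation error for $n = 1$.  The unweighted mean
  is the Monte Carlo convention; the sample-standard-deviation sigma is
  robust against mis-modelled observation errors, and the floor protects
  reflections whose few measurements happen to agree closely.
* **Resolution push.**  Each crystal's diffraction limit is the largest
  |q| among its observations with I/σ ≥ 1; observations beyond
  limit + 0.5 nm⁻¹ (the parameter is given in nm⁻¹, converted internally)
  are dropped.  This implements per-crystal resolution cut-offs that
  suppress pure-noise observations from weakly diffracting crystals.
* **Outliers.**  Within each merged reflection, measurements with
  |I − median| > 4 × 1.4826 × MAD are rejected, two passes.  The
  reference pipeline delegates this step to an external program without
  documenting its rule; median/MAD at 4σ is the package's own robust
  choice.
* Per-crystal ΔCC½ rejection is deliberately **not** implemented,
  matching the processing convention the package reproduces.

On noise-free data the xsphere merge inverts the simulation exactly
(recovering |F|² to 10⁻⁶ relative); on the default partial-intensity
simulation it yields strictly higher S_ano and CC_ano and lower R_split
than unity merging — the package's reproduction of the benefit of
partiality correction and post-refinement.

# Quality and anomalous metrics

Half-dataset statistics split *by pattern* (all SFX half-set statistics
are defined over crystal splits): a seeded shuffle assigns patterns
alternately to two halves, each merged independently.

* $R_{split} = 100 \cdot 2^{-1/2} \sum|I_1-I_2| \,/\, \tfrac12\sum(I_1+I_2)$,
  pooled over common records (the overall value pools sums, never
  averages shells).
* CC_1/2 is the Pearson correlation of half intensities;
  $CC^* = \sqrt{2CC/(1+CC)}$, reported missing when the transform is
  undefined.
* CC_ano correlates the Bijvoet differences $(I^+ - I^-)$ between halves
  over acentric reflections with both mates in both halves.  Intensity
  (not amplitude) differences are used; the choice is documented here
  because conventions differ between programs.
* Completeness counts observed unique (ASU, side) records against the
  enumerated theoretical set (centric reflections count once, acentric
  twice); redundancy is measurements per observed unique.
* Shells are equal-volume in $d^{*3}$, 10 by default.

Anomalous amplitudes use the simplest defensible convention:
$F = \sqrt{\max(I, 0)}$ per side (no French–Wilson treatment), with
first-order error propagation and an inflated placeholder sigma for
truncated sides.  The phased anomalous difference Fourier synthesis uses
coefficients $\Delta F \, e^{i(\varphi - \pi/2)}$ with $\varphi$ the
Bijvoet-averaged phase from the noise-free model (the role played by the
refined-model phases in a real study), expanded to the full sphere by the
space-group operators and Friedel completion, and evaluated by FFT on a
grid no coarser than $d_{min}/3$.  S_ano is the mean map height at the
anomalous sites *by direct Fourier summation at the exact coordinates*
(not grid interpolation), in units of the map rms computed from the
coefficients by Parseval's identity (identical to the grid rms on an
alias-free grid).  All model anomalous sites enter the average.  An
S_ano of 10 is used as the phasing-feasibility threshold; the constant is
configurable.

`subsampleStudy()` merges nested seeded subsets of increasing size and
linearly interpolates the image count at which S_ano crosses the
threshold.  Comparing two otherwise identical simulations with
$f'' = 1.51$ and $0.95$ e⁻ reproduces the expected
$(1.51/0.95)^2 = 2.5$-fold reduction in required images within the
tolerance of a desk-scale experiment.

# Problem sizes

The test-suite and acceptance computations use: 30–400 patterns of a
small tetragonal toy cell (30 × 30 × 40 Å, 3 Å cutoff) where mechanics
are under test; 400–2000 patterns of the default thaumatin-like
conditions (58.5 × 58.5 × 151.25 Å, 2.65 Å) for statistical behaviour;
500 patterns for the distance scan; and 2000-pattern simulations with
subsets from 100 to 1500 images for the threshold-crossing study.  These
sizes are the package's desk-scale choices: large enough that the
statistics of interest are resolved, small enough to run interactively.

# Known limitations

* The partiality model and its inversion share the same functional form;
  the package validates the pipeline's self-consistency, not the physical
  accuracy of any particular partiality model against real stills.
* Scaling assumes a single isotropic B offset per crystal and no
  radiation damage (appropriate for femtosecond exposures).
* The oracle indexer sidesteps indexing failures and indexing ambiguity;
  indexing-rate curves measure a residual gate, not an autoindexing
  algorithm.
* Sigma estimates for reflections with very few measurements are noisy;
  consistency statements (e.g. Friedel mates agreeing within combined
  sigmas) hold at the stated rates only at adequate multiplicity.
* The CCP4 map writer emits a P1 full-cell grid regardless of symmetry;
  consumers that require symmetry-encoded maps should expand from the
  reflection data instead.
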