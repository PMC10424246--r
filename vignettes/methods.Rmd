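---
title: "Methods: quantifying droplet-bioprinted airway epithelial cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying droplet-bioprinted airway epithelial cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aliprint)
```

aliprint implements the quantitative analyses used to characterize
droplet-based bioprinting (DBB) of airway epithelial progenitor cells and
the air–liquid-interface (ALI) cultures they form: printability physics of
the cell-laden bioink, ciliary beat frequency (CBF), tight-junction
spacing, marker areas, viability and infection gating, barrier function,
and the pass-number dosing plan. Because the raw microscopy behind such
studies is rarely shareable, every analysis is paired with a seeded
synthetic generator carrying ground truth, so the whole pipeline is
validated by parameter recovery.

## Printability of the bioink

A droplet-jetting configuration is summarized by dimensionless numbers
built from the fluid's viscosity $\eta$, surface tension $\gamma$, density
$\rho$, the nozzle orifice diameter $L$, droplet velocity $U$ and gravity
$g$:

$$\mathrm{Oh} = \frac{\sqrt{\mathrm{We}}}{\mathrm{Re}} =
  \frac{\eta}{\sqrt{\gamma\rho L}} = \frac{1}{Z}, \qquad
  \mathrm{We} = \frac{\rho U^2 L}{\gamma}, \qquad
  \mathrm{Re} = \frac{\rho U L}{\eta}, \qquad
  \mathrm{Fr} = \frac{U}{\sqrt{gL}},$$

$$\mathrm{Bo} = \frac{\rho g L^2}{\gamma}, \qquad
  K_{sp} = \sqrt{\mathrm{We}\sqrt{\mathrm{Re}}}.$$

Two regime flags matter for deposition quality: gravity is negligible when
$\mathrm{Bo} < 1$ (spreading is inertial/capillary-driven), and droplet
impact does not splash significantly when $K_{sp} < 57.7$. The splashing
boundary is implemented exactly at 57.7 with the splashing side closed
($K_{sp} \ge 57.7$), and the Bond test strictly below 1, matching how the
thresholds are conventionally quoted. The Froude number is reported
without a flag — no threshold on it enters any deposition criterion here.

Culture media are dilute aqueous solutions whose properties are rarely
measured and published; the package therefore ships a documented
water-like default (`water_like_medium()`: 1.0 mPa·s, 72.8 mN/m,
998 kg/m³) with a 250 µm nozzle and 2 m/s droplets for examples and
tests. Published $K_{sp}$ values for such systems (e.g. 5.1) are treated
as classification inputs, not reproducible outputs, since the underlying
$\eta,\gamma,\rho,U$ are unpublished. Internally everything is SI;
`read_fluid_spec()` accepts the lab units (mPa·s, mN/m, g/ml, µm) a
configuration file would use. Droplet velocity from tracked frames is
defined as the least-squares displacement slope, robust to frame jitter.

## Ciliary beat frequency

Beating cilia modulate local image intensity quasi-periodically; CBF is
the dominant frequency of an ROI-mean intensity trace. `cbf_fft()`:

1. removes the mean and a linear trend (photobleaching drift),
2. applies a Hann window (sidelobe suppression),
3. takes the magnitude spectrum and locates the maximum bin inside the
   analysis band (default 1–20 Hz, covering both the 6–9 Hz of cultured
   epithelium and the 11–16 Hz healthy in-vivo range),
4. refines the peak by a three-point quadratic fit on the log magnitude.

The refinement is essential at the standard recording geometry (100
frames/s, 1024 frames → ~0.098 Hz bins) to resolve group medians a few
hundredths of a hertz apart. A significance floor guards against
reporting noise: the dominant bin's power must exceed 3× the median band
bin power, otherwise the estimate fails with an error. The cycle-counting
route (`cbf_cycle_count()`) is the physically consistent reading
`n_cycles × frame_rate / frames_elapsed`; on noiseless tones both routes
agree within one spectral bin. Estimates are invariant to intensity gain
and offset, and the three ROIs per insert are pooled (not averaged)
before group medians — both behaviors are tested.

Measured recovery: for simulated traces at 4–12 Hz, SNR ≥ 2, the FFT
estimate lands within max(0.1, bin width) Hz of the generating frequency
in well over 95% of seeded replicates.

## Tight-junction spacing

Junction (ZO-1) fluorescence outlines cell borders; spacing is measured
the way an analyst would in ImageJ: draw a line, read the intensity
profile, find peaks, convert peak-to-peak distances to µm.
`extract_line_profile()` samples by bilinear interpolation at 1-pixel
arc-length steps (1-based coordinates, pixel centers at integers).
`junction_spacings()` smooths the profile with a 1 µm Gaussian (narrower
than a boundary ridge, so peak positions are preserved while per-pixel
noise is suppressed), keeps local maxima with topographic prominence
above 15% of the dynamic range, and enforces a 2 µm minimum separation;
plateau ties keep the leftmost sample. The 15% prominence default was
chosen because, at realistic SNR, weaker thresholds let smoothed noise
excursions split boundary peaks and bias chords low; at 15% the detected
chord statistics match the noiseless geometry.

A random line samples *chords* of the cells it crosses, and the mean
chord of a convex cell is systematically shorter than the cell diameter
(mean intercept = $\pi A / P$; for hexagonal cells of across-flats $d$,
$\pi d/4 \approx 0.785\,d$). `sample_junction_spacings()` therefore
reports, besides the raw chord statistics, the standard line-intercept
stereology estimator of cell diameter, $4/\pi \times$ mean chord, which
recovers the generator's mean cell diameter within 15% across seeds.

## Areas, viability, counting, gating

* `area_fraction()` thresholds (Otsu by default) and reports both field
  conventions: percent-of-field (mucin convention) and absolute positive
  area per $10^5\ \mu m^2$ of field (cilia convention). The reference
  area is $10^5\ \mu m^2$ — a $10^5$ mm² region would exceed any
  microscope field by orders of magnitude.
* `count_cells()` is blob counting: threshold, label connected
  components (EBImage), filter by size. The default threshold is
  background-based (median + 6×MAD) because Otsu fails when bright
  objects cover a tiny fraction of the field, as in sparse dead-cell
  channels. Viability is simply 100·live/(live+dead).
* `histocytometry_gate()` mirrors flow-style gating of per-cell mean
  intensities exported from segmented scans: gate first on the nuclear
  channel (DAPI-positive = a real cell, excluding segmentation debris),
  then on the reporter (GFP), and report double positives as a
  percentage of DAPI-positive rows. Default thresholds are Otsu cuts on
  log-transformed intensities, since fluorescence intensities are
  positive and right-skewed; Otsu presumes genuine bimodality, so fixed
  thresholds are available where a channel is unimodal. The gated
  percentage is monotone non-increasing in the GFP threshold.

## Barrier function

TEER readings are blank-subtracted and area-normalized:
$(R_{raw} - R_{blank}) \times A$, with $A = 0.33$ cm² the nominal area
of a 6.5 mm Transwell insert (configurable). Negative values (raw below
blank) are returned with a warning, never clipped — they flag electrode
problems. Aggregation into a condition-by-day time course refuses mixed
membrane areas within a group, where mean TEER would be meaningless.

Dextran permeability is quantified as the least-squares slope of
cumulative basal tracer amount versus time (hourly samples over 3 h),
optionally normalized by the apical load to a fraction-per-hour. No
apparent-permeability coefficient is reported: the comparisons of
interest are relative (cell-free membrane vs cultured epithelium, and
between dose groups), for which the regression slope is the direct
statistic; a $P_{app}$ layer is a documented extension point. Conversion
from plate-reader signal to concentration is a user-supplied linear
calibration.

## Seeding plan

One printed pass deposits 2200 cells per insert; the dose is exactly
linear in pass count, so 10–50 passes deliver 0.22–1.1 × 10⁵
cells/insert, one-tenth to one-half of the 2.2 × 10⁵ manual-seeding
benchmark, at ~0.2 min per pass. The suspension-density figure sometimes
quoted alongside such protocols (0.022 × 10⁵ cells/ml) is not consistent
with the per-insert doses as a volumetric density; the per-insert-per-pass
constant is the operative quantity here, and print time is a planning
estimate only.

## Synthetic data: what it emulates, and what it does not

Each generator is seeded, restores the caller's RNG state, and attaches
its ground truth (generator, parameters, seed); identical seeds are
byte-identical, including written TIFF/CSV/JSON artifacts.

* `gen_cilia_stack()`: per-pixel baseline + sinusoid at $f_0$ with a
  linear spatial phase gradient (a crude metachronal wave), a 0.2-relative
  second harmonic (beat asymmetry), and Gaussian noise; SNR is amplitude
  over noise sd. Defaults (100 fps, 1024 frames, SNR 5) are the recording
  geometry of a standard high-speed CBF acquisition.
* `gen_junction_image()`: cell centers on a hexagonal lattice at the
  stated spacing, Gaussian-jittered under a hard-core minimum separation
  (0.6 d) — a Poisson-disc-like process whose spacing is controlled
  exactly, and which degenerates to the exact lattice at jitter 0 so that
  boundary spacings along lattice rows equal the stated diameter.
  Boundaries are Voronoi ridges rendered with a Gaussian profile.
* `gen_livedead()`: minimum-separation point spots per channel; the live
  count is deterministic (`round`), so counted viability is exactly
  recoverable up to detection error.
* `gen_infection_table()`: log-normal DAPI/GFP mixtures with a small
  (5%) low-DAPI debris population — real segmentations contain
  non-nuclear objects, and the debris keeps the DAPI channel genuinely
  bimodal for Otsu gating. Infected counts are deterministic.
* `gen_dextran_series()` and `gen_teer_course()`: linear accumulation and
  a gamma-shaped rise-then-decline template (peak ~1000 Ω·cm² around day
  7 falling to ~275 by day 28, the shape typical of differentiating
  airway epithelium), plus Gaussian replicate noise.

These generators emulate the *statistical* structure the analyses rely
on — oscillation frequencies, boundary spacings, class mixtures, slopes,
templates — not the optics or biology: there is no point-spread function,
no mucus or debris texture, no metachronal hydrodynamics, no virus
spread. Passing recovery tests therefore demonstrates that the analysis
code measures what it claims to measure on data of known structure; it
does not certify performance on degraded real microscopy.

## Numerical choices and problem sizes

Tolerances asserted in the test suite: the two Ohnesorge routes agree to
1e-9 relative over 1000 random configurations; the splashing boundary is
sharp to ±1e-6; CBF recovery to ±0.1 Hz (95% over 200 replicates per
frequency); gating to ±1.5 / ±1.0 percentage points at 10.6% / 2.8%
infected over 50 seeds; junction diameter to 15% over 20 seeds; dextran
slope to ±0.05/h; viability to ±2 points. Synthetic fields are sized for
desk-scale validation (256 px junction fields, 512 px spot fields,
1024-frame traces) — large enough that estimator error, not field size,
dominates the tolerance, and small enough that the full suite runs in
well under a minute of compute per module.

Degenerate inputs fail loudly rather than silently: flat traces, bands
beyond Nyquist, coincident line endpoints, constant profiles, empty
tables, zero-cell counts, and raw-below-blank TEER all raise typed
errors or warnings tested in the suite.
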