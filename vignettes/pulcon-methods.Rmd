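---
title: "Quantifying mineral oil hydrocarbons by external-calibration qNMR: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pulcon methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pulcon)
```

## The measurement model

Mineral hydrocarbons split into a saturated fraction (MOSH) and an aromatic
fraction (MOAH). In a ¹H spectrum of a product dissolved in CDCl₃ these
fractions appear as broad envelopes of thousands of unresolved resonances
("humps"): saturates between 0.2 and 3.0 ppm, aromatics between 6.5 and
9.2 ppm. Because no individual compound can be resolved, both fractions are
*sum parameters*: each is defined operationally as everything that
integrates inside its window, expressed as equivalents of a single
representative compound — decalin (MW 138.25, N = 18) for the saturates,
naphthalene (MW 128.17, N = 8) for the aromatics, glycerol (MW 92.09,
N = 5) for the "other compounds" window between 3.0 and 6.5 ppm that
captures non-mineral-oil ingredients.

Quantification uses the PULCON principle: with acquisition parameters held
constant, absolute integrals are comparable across spectra, so one external
calibration sample per series (the *quantref*: tetrachloronitrobenzene and
ethylbenzene, 5.0 g/L each, i.e. 50 mg + 50 mg in 10 mL CDCl₃) fixes the
proportionality between integral-per-proton and molar concentration. Each
of its four signals yields `ERETIC_i = I_i · MW / (C · N_i)`; the series
factor is their mean, and their relative spread is a health check (default
tolerance 10 %; a larger spread invalidates the factor and blocks
quantification). Analytes then follow `C = I · MW / (ERETIC · N)` and the
dilution arithmetic `w = C · V / m · 100` (g/100 g for C in g/L, V in mL,
m in mg — a fully dissolved pure hydrocarbon at 50 mg / 1.5 mL reads
100 g/100 g). Because calibration and quantification are mutual inverses,
any overall intensity scale cancels; the package's property suite asserts
the round trip to 1e-9 and scale invariance explicitly.

Two conventions matter for reproducibility:

* **Integrals are Riemann sums** (intensity × ppm step) over the region's
  grid points. Any consistent convention cancels in PULCON; the Riemann sum
  is additive over sub-windows, which the aromatic region (four windows
  with three solvent cut-outs) relies on.
* **Window membership is half-open**, `low < ppm ≤ high`, so the saturates
  (3.0–0.2), "other" (6.5–3.0) and aromatics regions partition the axis
  without double-counting a grid point.

The aromatic cut-outs at 7.55–7.50, 7.30–7.22 and 7.00–6.97 ppm remove
residual CHCl₃ (7.26 ppm) and its ¹³C satellites. The satellite offset
follows from the one-bond ¹H–¹³C coupling of ≈209 Hz: ±0.261 ppm at
400 MHz, which places them at 7.52 and 7.00 ppm — inside the cut-outs.
The residual-water exclusion inside the saturates window defaults to
1.58–1.50 ppm (configurable; the printed description of the artifact is
only "around 1.53 ppm"). The cyclohexane control window (1.53–1.36 ppm)
never carries the water exclusion: the control is a clean solution and its
gate must not depend on a matrix-artifact setting.

PAH4 target windows (benz[a]anthracene 9.20–9.12 N=1, benzo[a]pyrene
9.06–8.98 N=2, chrysene 8.76–8.70 N=2, benzo[b]fluoranthene 7.45–7.38 N=2)
overlap the aromatic span; MOAH is reported *inclusive* of them, matching
the practice of reporting both independently. In aromatic-rich matrices the
PAH4 windows necessarily include hump background — a genuine property of
the method, visible in the README example where a 0.55 g/100 g chrysene
spike on a 0.6 g/100 g aromatic hump reads 0.60.

## Series protocol and QC

A series is quantref → samples → control. The control (cyclohexane,
2500 mg/L, N = 12, MW 84.16 — standard chemistry, not printed in the
source tables) is quantified against the series factor; its recovery must
lie in the closed interval [95 %, 105 %] ("100 ± 5 %" read inclusively; the
implementation adds a 1e-9 relative epsilon so an exactly-boundary recovery
passes regardless of floating-point rounding). A failed gate still produces
a report, but marked INVALID and with a nonzero process exit status.
Validation statistics are the usual ones: sample-SD/mean coefficient of
variation and per-level spike recoveries, always computed from unrounded
values (printed tables round concentrations and recoveries independently,
so recomputing recoveries from rounded concentrations does not reproduce
them exactly).

## Detection limits

The manual practice of estimating the LOD from "a small but still
integratable signal" is automated as a height criterion: the LOD is the
mass fraction of a synthetic Lorentzian reference line whose peak height
equals 3× the spectral noise SD. A Lorentzian of height h and HWHM γ has
area πhγ, so `I_LOD = 3σπγ` converts through the ERETIC factor and the
dilution arithmetic. The reference HWHM defaults to 0.002 ppm (0.8 Hz at
400 MHz), the linewidth used for the simulated PAH multiplet lines; the
noise window is 10.5–9.5 ppm, where no quantified region or standard has
signal. Consequences worth knowing:

* LOD scales inversely with sample mass (halving the mass doubles the
  LOD), reproducing per-sample LOD variation.
* Detection is `max(window intensity) ≥ 3σ`, boundary inclusive — a
  deterministic stand-in for a manual judgment that is not reproducible.
* For *wide* windows the height-based LOD is optimistic: the SD of the
  2.54-ppm aromatic integral over pure noise is ≈ 0.9× the LOD itself, so
  a blank exceeds its LOD with ~13 % probability. The blank test is
  therefore statistical (a majority of fixed-seed blanks below the LOD)
  rather than per-spectrum. Height-based LODs should be quoted for the
  narrow PAH4 windows, not for the sum parameters.

## Processing pipeline

FIDs are exponentially apodized (default 0.3 Hz, typical for 400 MHz 1D
work), first-point-halved (removes the DC offset so spectra need no
baseline pedestal), zero-filled (default factor 2, padded to a power of
two) and Fourier transformed with a dwell-time scaling under which the
discrete integral of an absorptive line equals the closed-form value A/2
for a one-sided decay of initial amplitude A — the property the FT tests
assert against the analytic Lorentzian.

**Phasing** minimizes the summed negative intensity after median-offset
removal over zero- and first-order phases (grid search on ph0, then
Nelder-Mead). This simple objective is exact for predominantly positive
absorptive spectra, which is what this method processes; on degenerate
input with no signal above 5×MAD the tie is broken toward 0°. A
non-converged simplex falls back to a ph0-only grid search with a warning.

**Baseline correction** must satisfy two opposing demands: signal-free
regions should end up at zero mean (unbiased noise), while humps several
ppm wide must be *bridged*, not flattened. The default
("masked-whittaker") works on a block-mean decimated grid (the baseline is
smooth by definition; decimation to ≈8192 points keeps the pentadiagonal
system small and well conditioned):

1. a robust noise estimate from first differences (`mad(diff)/√2`, floored
   for noise-free input);
2. a running median over half the axis as the initial zero reference —
   signal occupies less than half of the 14-ppm axis, so the wide median
   tracks the baseline robustly;
3. a two-scale signal mask: running means of the residual over 0.1 ppm
   (peaks) and 0.5 ppm (faint broad humps) against 4σ thresholds, plus a
   6σ point criterion, dilated by 0.25 ppm;
4. a stiff weighted Whittaker smoother (second-difference penalty,
   λ = 1e12 on the decimated grid) through the unmasked points; masked
   spans are bridged by the penalty's natural-spline behaviour. Linear
   baselines are in the penalty's null space, so ramps and offsets are
   removed exactly.

The asymmetric-least-squares default suggested by the original design was
implemented and rejected as the default: ALS settles on the *lower noise
envelope* (≈2–3σ below zero), which is harmless for strong peaks but
biases weak narrow windows (a chrysene window integral at the calibrated
noise level by tens of percent), and its tiny asymmetric weights are lost
numerically against the stiffness needed to bridge 3-ppm humps. ALS and an
iterative-polynomial fit remain available through the configuration; the
ALS test asserts its documented envelope behaviour rather than exact zero.

**Referencing** finds the TMS singlet within ±0.3 ppm of the target shift,
interpolates the apex parabolically and translates the axis — a pure
translation, so peak distances are preserved exactly. If no peak rises 3σ
above the local median the spectrum is returned unchanged with an
`unreferenced` flag.

Processing is deterministic: identical input and configuration give
bitwise-identical output and processing logs, and series reruns produce
byte-identical JSON reports.

## The synthetic-data generator

The simulator is the package's ground truth: every signal's area, *as
integrated by the quantification convention*, equals
`response · C · n/MW` with one proportionality constant shared by all
components, so PULCON holds by construction and the ledger attached to
each spectrum (true g/L and g/100 g per component) is recoverable by the
pipeline. Its stated world:

* grid 12 to −2 ppm, 131072 points (the real-spectrum size of the emulated
  acquisition), 400.13 MHz, 32 scans;
* humps as mixtures of 60–80 Lorentzians with HWHM 0.02–0.2 ppm, positions
  drawn from weighted sub-regions (saturates: CH₃ 0.80–1.05, CH₂
  1.10–1.45, CH/branched 1.45–2.20; aromatics weighted toward
  6.8–7.2 ppm) — a morphological stand-in, not a chemical model;
* solvent artifacts: CHCl₃ at 7.26 ppm (area 0.01·response, matching
  ≈99.9 atom-% D solvent), ¹³C satellites at ±0.261 ppm (0.55 % of the
  parent each), water at 1.53 ppm, TMS at 0; the quantref simulation uses
  artifact-free solvent so its four signals agree by construction;
* additive white noise from a seeded generator; the **calibrated preset**
  fixes the noise SD by inverting the LOD formula so that the chrysene LOD
  of a standard 50 mg / 1.5 mL measurement is 0.05 g/100 g — chosen once,
  before any acceptance quantity was measured, and consistent with the
  emulated method's sub-0.1 g/100 g limits.

Two idealizations are deliberate and documented rather than physical:

* **Compact-support lines.** Rendered lines are clipped at
  max(0.25 ppm, 10·HWHM) from their center (hump sub-lines at 2·width),
  and narrow signals bound to a region are confined to that region's grid
  mask. True Lorentzian tails decay like 1/x² and smear percent-level area
  across neighbouring windows and into the baseline; with them, no
  generator can satisfy "four quantref signals imply the same factor to
  1e-6" or "noise-free end-to-end recovery to 0.5 %" — both of which are
  the construction guarantees this module exists to provide. The clipped
  tails are exactly the ambiguous intensity a manual integrator would
  assign to the baseline anyway.
* **In-window normalization.** A hump's ledger value is defined by its
  area inside the quantification window (exclusions removed), mirroring
  the sum-parameter definition itself. Hump intensity inside the solvent
  cut-outs exists but is, by definition, not part of the analyte.

What a green test therefore establishes: the calibration algebra, the
integration conventions, the QC gates, the LOD arithmetic and the
processing chain recover a known ground truth under realistic morphology,
noise and artifacts. What it does not establish: lineshape physics
(J-coupling, relaxation, shimming artifacts), the behaviour of manual
phasing/baseline judgment on real instrument data, or chemical
hump sub-structure. Reprocessing real deposited spectra is expected to
agree with manually processed results within a few percent, not exactly.

## Numerical choices and degenerate inputs

* Whittaker systems are solved by sparse Cholesky (Matrix); λ = 1e12
  against unit weights retains ~3 significant digits of headroom in double
  precision, validated by the ramp/offset/idempotence tests. ALS uses
  λ = 1e8 because its p = 1e-3 weights would vanish against 1e12.
* Noise-free inputs: noise estimates are floored (1e-9 of the maximum
  intensity) so masking still works; zero-noise LODs report 0 with a
  warning; a zero FID transforms to a zero spectrum.
* A baseline mask covering > 95 % of points falls back to the running
  median reference; > 50 % triggers a warning (expected for noise-free
  simulated spectra, where everything nonzero is signal).
* Negative region integrals (blank windows under noise) clamp the reported
  concentration at 0; the raw value is retained.
* JCAMP-DX: AFFN and SQZ/DIF/DUP are read (DUP counts include the original
  occurrence; DIF continuation lines carry a y-check value that is
  verified and dropped); AFFN only is written, at 9 significant digits
  (round trips hold to 1e-6 easily). A line containing unambiguous
  pseudo-digits is decoded as ASDF, in which case `E`/`e` are SQZ digits —
  exponential AFFN inside ASDF lines is not representable, per the format.
  Absent scans/receiver-gain metadata defaults to 1 with a warning, since
  external calibration presumes constant acquisition; integrals can
  optionally be normalized by scans × receiver gain for mixed series.

## Known limitations

* Wide-window LODs are optimistic (see above); sum-parameter non-detects
  are gated on the same LOD for want of a better printed rule.
* PAH4 results in aromatic-rich matrices include hump background; no
  background subtraction is attempted (none is defined for the method).
* The spike-recovery band (84–112 %) at the lowest validation level is
  inherited from the emulated method's imprecision at the edge of its
  working range; the simulator reproduces the noise-limited part of that
  imprecision only.
* MOSH values above 100 g/100 g are possible and reported as computed —
  a property of the decalin-equivalents convention, not an error.
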