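---
title: "Detecting and quantifying small microplastics in Raman hyperspectral maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying small microplastics in Raman hyperspectral maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanmp)
```

## The measurement problem

Microplastic monitoring in food matrices such as milk pushes particle
detection below the ~10 µm limit of visual µFTIR workflows. The approach
this package implements maps a digested, filtered sample point by point
with a Raman microscope: the sample is filtered over a restricted area of
about 14 mm² on a silicon filter, two sub-areas covering about half of that
surface are scanned on a 5 µm lattice, and one Raman spectrum is recorded
per lattice position (on the order of 250,000 spectra per sample). Every
pixel is then classified chemically, same-polymer pixels are grouped into
particles, and particle counts are turned into per-100-mL concentrations.
Because one pixel is 5 µm, the method's lower particle size bound is a
single pixel, i.e. ≥ 5 µm (25 µm² of mapped surface).

The pipeline has four computational stages, each a module of this package:

1. **Preprocessing** (`preprocess_spectrum()` and friends) — put every
   spectrum on a common wavenumber grid and into a scale-free
   representation.
2. **Classification** (`train_classifier()`, `predict()`) — a random
   forest assigns each pixel one of 11 classes: nine polymers (PA, PE,
   PES, PLA, PMMA, PP, PS, PTFE, PU), a stearate decoy class, and NMP
   (non-microplastic: digestion residue, cellulose, silicon background).
3. **Particle detection** (`cluster_particles()`) — gap-tolerant connected
   components group same-class pixels into particles.
4. **Quantification** (`quantify_particles()`) — extrapolation to the whole
   filter, blank subtraction, per-100-mL conversion, size fractions, QC
   verdicts and a rough mass estimate.

A synthetic-data module (`generate_spectrum()`, `generate_map()`,
`generate_training_library()`) simulates all of the inputs with known
ground truth, so the whole chain is testable without an instrument.

## Spectral preprocessing

Raw spectra arrive on slightly varying acquisition axes covering roughly
550–2000 cm⁻¹. Four steps, applied in a fixed order:

1. **Grid refit.** Cubic-spline interpolation (`stats::splinefun`, natural
   boundary conditions) onto the common grid 559, 562, …, 1990 cm⁻¹ —
   478 points every 3 cm⁻¹. The input axis must cover the grid; the spline
   is never extrapolated. Machine-learning classifiers need a fixed,
   consistent feature vector, which is exactly what this grid provides.
2. **Baseline correction.** Fluorescence from organic residue sits under
   the Raman bands as a broad, smooth background. We estimate it by
   asymmetric least squares: minimise
   $\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2$
   where points above the running estimate ($y_i > z_i$) get the small
   weight $p$ and points below get $1-p$, iterated to convergence. The
   baseline hugs the lower envelope of the spectrum and narrow bands do
   not drag it up. One "universal" default parameter set
   ($\lambda = 10^5$, $p = 0.01$, 10 iterations) is used for every
   spectrum in a run; both knobs are exposed in `preprocess_params()`.
   $\lambda$ controls stiffness (larger = smoother baseline; $10^5$ over a
   478-point grid passes broad fluorescence but not 5–10 cm⁻¹ bands), and
   $p$ the asymmetry. The solver is a banded Cholesky in C++ — the normal
   matrix is pentadiagonal, so each iteration is $O(n)$ — and the
   estimated baseline is kept alongside the corrected spectrum for audit.
3. **Smoothing.** A smoothing spline (`stats::smooth.spline`) with every
   data point as a knot and a deliberately small smoothing parameter
   (`spar = 0.25`). The contract is signal preservation: on a noiseless
   spectrum the output deviates by well under 1% of the signal range,
   while high-frequency noise is attenuated. The default was chosen as
   the largest round value for which the noiseless-identity property holds
   on the shipped synthetic polymer spectra.
4. **SD scaling.** Each spectrum is divided by its own standard deviation
   (population convention, divide by $n$; at $n = 478$ the distinction
   from the $n-1$ convention is numerically immaterial but the choice is
   fixed and documented). This removes overall intensity differences from
   laser focus and particle size, leaving band *shape* as the feature.

A constant spectrum — which a desynchronised acquisition produces — has
zero spread and cannot be scaled. It is flagged *degenerate*, skips the
classifier, and is reported as NMP with confidence 0 and a review flag.

## Random-forest classification

The classifier is a probability random forest (`ranger`) with 1500 trees,
trained directly on the 478 scaled intensities; no derived features are
used. Accuracy is controlled by the out-of-bag (OOB) error — each training
spectrum is predicted by the trees that did not see it — and the OOB
confusion matrix is stored on the model (`report_confusion()`). Forest
defaults (√478 ≈ 21 features tried per split, unweighted classes) are
kept and recorded in the model object.

A pixel's **confidence** is the fraction of trees voting for the winning
class. Pixels below a review threshold (default 0.5) are flagged for
operator inspection; they are still counted unless `drop_review` is set,
because the manual review loop has no automatable acceptance rule — the
package flags and exports, a person decides.

Stearate is kept as a separate class by default: fatty-acid salts from
gloves share polyethylene's aliphatic backbone signal, and an explicit
decoy class makes PE/stearate cross-talk visible in the confusion matrix
instead of silently inflating PE counts. A `merge_stearate_nmp` option
folds it into the non-particle classes for reporting. Silicon-filter
background spectra belong to NMP.

## Gap-tolerant particle detection

Classified pixels are grouped per class: two pixels of the same polymer
join the same particle when their lattice distance is at most 2 steps.
This "gap 2" rule lets a particle jump over a single missed or
misclassified pixel — missed signals occur when the spectrometer clock
desynchronises from the stage — without merging genuinely separate
particles. We interpret the distance as **Chebyshev** distance in lattice
units (diagonal neighbours at distance 1), the natural generalisation of
8-connectivity that makes the gap symmetric in all directions; a
Euclidean-in-steps alternative is available (`metric = "euclidean"`).
Components are computed per class, so particle class purity holds by
construction; mixed-class blobs become one particle per class rather than
being merged by majority vote.

Particle metrics: area $= n_{\text{pixels}} \times \text{step}^2$;
the reported size is the square-equivalent side $\sqrt{A}$, so the
"small" flag (area strictly < 50 µm²) corresponds to size below about
7 µm; a circular-equivalent diameter $\sqrt{4A/\pi}$ is also emitted for
comparability with optical sizing. Each particle carries its
highest-confidence member spectrum into the analytical report, so every
reported particle can be audited spectrally.

## Quantification and QC

* **Extrapolation** from the analyzed fraction $f$ of the filter:
  whole-filter count $= \text{observed}/f$, rounded to the nearest
  integer. For the standard $f = 0.5$ this is the factor-2 rule; its
  validity for uniformly deposited particles is checked by simulation
  (`extrapolation_factor_sim()`): 200 points uniform on a disc, counted on
  the full disc and a randomly oriented half-disc, averaged over 100
  replicates, give a ratio within [1.9, 2.1].
* **Blank subtraction**, per class, clamped at zero: laboratory
  contamination is measured in a procedural blank and removed class by
  class; negative counts are meaningless and never reported.
* **Per-100-mL conversion** from the filtered volume (default 25 mL), then
  the total over classes.
* **Size fraction**: percent of particles with area < 50 µm²; undefined
  (NA, not 0) when no particles were found.
* **QC verdicts** on residual load: a blank passes with strictly fewer
  than 300 retained particles/mm² and at most 5% surface covered; a
  digested sample passes with at most 600/mm² and at most 30% coverage
  (an overloaded filter hides particles). The strict-vs-inclusive
  boundaries follow the wording of the method's validation criteria.
* **Mass estimate**: treating all particles as 10 µm spheres of density
  1 g/cm³, mass $= n \cdot (\pi/6) d^3 \rho$; 1000 particles per 100 mL
  serving ≈ 5.24 µg/kg of product (serving density taken as 1 g/mL; milk
  is ≈ 1.03, well inside the "rough estimate" label this number carries).
* **Acquisition cost**: `scan_point_factor()` gives the lattice-point
  ratio $(s_a/s_b)^2$ — refining 5 µm → 1 µm costs a factor 25 in
  mapping time.

## What the synthetic generator emulates — and what it does not

`generate_spectrum()` builds a class spectrum as a sum of Gaussian bands
from a per-class peak table, plus a polynomial fluorescence baseline, plus
shot-like noise (variance proportional to local intensity) scaled so the
strongest band's peak signal-to-noise equals `snr`. The shipped band
tables use canonical polymer Raman positions (polystyrene's 1001 cm⁻¹
ring breathing, polyethylene's 1296/1440 cm⁻¹ CH₂ pair, PTFE's 732 cm⁻¹
CF₂ stretch, …); they are a documented design choice, user-overridable,
and not a reproduction of any instrument library. The stearate table is
derived from the PE table — slightly shifted bands plus a carboxylate
band near 1100 cm⁻¹ — to preserve the PE/stearate confusability that
motivates the decoy class. NMP is broad humps emulating fluorescent
organic residue.

`generate_map()` rasterises disc-shaped particles onto the lattice (a
pixel belongs to a disc iff its center lies inside — the simplest rule an
independent oracle can check), adds fiber-shaped and blob-shaped NMP
objects and a silicon/NMP background, and replaces dropped-out pixels
with constant spectra (a desynchronised acquisition still records a
frame, so dropout is a degenerate spectrum, not a missing row). Random
particle centers are snapped to lattice points so that, with diameter ≥
step, every ground-truth particle owns at least one pixel; a minimum
pairwise separation keeps distinct particles distinct under the gap-2
rule; overlapping particles of different classes are rejected because
their ground truth would be ambiguous. Dropout is constrained so that no
ground-truth particle is erased or split under gap 2 — the generator
models the nuisance the gap rule is designed to absorb, not pathological
acquisition failure.

What passing tests on this generator do **not** show about real data:
real polymer spectra vary in band ratio and position with crystallinity,
pigments and photobleaching far beyond per-draw noise; real residue is
spectrally diverse (the NMP class here is a single family of broad
humps); real particle shapes are not discs; and real class frequencies
are heavily imbalanced where the generator's library is balanced. The
synthetic OOB errors (< 5% at snr ≥ 15) are therefore a check of the
pipeline's mechanics, not a claim about instrument-data accuracy.

## Numerical and design choices

* Non-finite intensities are rejected at read time rather than imputed —
  downstream SD scaling divides by the spread, and silent imputation
  would corrupt it.
* Lattice tolerance is 10⁻⁶·step; positions are absolute µm with the
  origin at the map corner. The map reader accepts arbitrarily masked
  lattices (real scans mask the filter's unfiltered margin, so a full
  rectangle is never guaranteed).
* Counts round half away from zero (reported counts are integers).
* Ties in the forest vote (`max.col`) resolve to the first class in
  sorted order; with 1500 trees exact ties are rare, and determinism
  under a fixed seed is preserved by single-threaded prediction.
* The text-format dialects (csv with an `x,y,<wavenumber...>` header;
  tab-separated LabSpec-style with an axis header row) are fixed by this
  package and documented in the README, since point-map exports vary by
  instrument software version.
* Training uses the forest's default feature subsampling and no class
  weights; both are recorded in the stored model so a report's provenance
  identifies them.

## Problem sizes used in the shipped checks

The test-suite simulations are desk-scale versions of the instrument
geometry: training libraries of 20–50 spectra per class (the full method
uses thousands per class), scenes of 100 × 100 µm to 500 × 500 µm at the
real 5 µm step (the instrument maps ~7 mm²), 1500 trees as in production.
These sizes were chosen so the statistical properties under test —
separability, OOB error, exact particle recovery, the factor-2
extrapolation — are already stable; they are stated here so that a user
scaling up to instrument-sized maps knows the defaults were validated at
desk scale.

## Known limitations

* The operator review loop is flag-and-export only; no automatic
  acceptance of low-confidence pixels.
* Polymers outside the 11-class inventory (e.g. PSU, PVA) are reported as
  their nearest class with low confidence plus a review flag — the closed
  world is deliberate, and unknowns surface through the review channel.
* The mass estimate is an order-of-magnitude convention (monodisperse
  spheres), not a measurement.
* Recovery rates, digestion efficiency and other wet-lab figures are
  outside the software's scope; the report format carries them, the code
  cannot reproduce them.
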