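---
title: "Models and methods behind smfoci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smfoci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(smfoci)
```

# Scope

`smfoci` quantifies single-molecule live-cell fluorescence movies of
rod-shaped bacteria expressing a DNA-damage-inducible, fluorescently tagged
DNA polymerase (a translesion polymerase such as pol IV carrying a YPet
tag) together with a red-labelled replisome marker. It covers three
measurements and the synthetic data needed to validate them end to end:

1. **Copy number and concentration per cell** from photobleaching decays of
   rapid acquisitions (300 × 34 ms frames under continuous excitation),
   with a single-molecule intensity calibration from return events.
2. **Molecules per focus** from change-point analysis of background-ring
   corrected 5 × 5 px ROI trajectories.
3. **Two-colour colocalisation** between polymerase and replisome foci:
   nearest-neighbour distances, equal-area shell histograms, bidirectional
   200-nm-threshold fractions, and chance levels from disc-union area
   fractions.

Because no raw movies are deposited with the study this package models,
every quantitative claim is validated on the package's own synthetic-movie
generator, which carries full ground truth.

# The photobleaching model

Under continuous excitation the mean pixel intensity inside a cell outline
decays as

$$f(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2},$$

where the fast component is fluorophore photobleaching
($\tau_1 = 6\,\mathrm{s}$, measured independently from the decay of the
number of detected foci) and the slow component is cellular
autofluorescence ($\tau_2 \approx 60\,\mathrm{s}$, the single-exponential
lifetime of cells carrying no fluorophore). $A_1$ is the fluorophore
signal per pixel at $t = 0$; multiplied by the cell area in pixels and
divided by the single-molecule intensity $I_{sm}$ it gives the copy
number, and dividing by the spherocylinder volume
$V = \pi (w/2)^2 (L - w) + \tfrac43 \pi (w/2)^3$ gives the concentration
$c = N / (N_A V)$ in nM.

Numerical choices that matter:

* `fit_two_exponential()` profiles the amplitudes out by non-negative
  least squares for each candidate $\tau_2$ and optimises $\tau_2$ by a
  multi-start search (30, 60, 120 s plus a log grid) with the constraint
  $\tau_2 \ge 2\tau_1$. On noiseless curves it recovers parameters to
  $10^{-4}$ relative.
* Over a 10.2 s movie, $\tau_2$ is *weakly identified per cell*: for dim
  cells the free-$\tau_2$ fit collapses onto its bounds and silently
  absorbs part of $A_1$. `quantify_copy_numbers()` therefore estimates
  $\tau_2$ once from the population-mean decay (restricted to
  $\tau_2 \ge 5\tau_1$, since autofluorescence is an order of magnitude
  slower than bleaching) or accepts a fixed value measured from
  fluorophore-free cells — the workflow the 60 s constant comes from.
  Per-cell fits then reduce to a two-parameter non-negative linear solve.
* **Aperture correction.** A fluorophore inside a 1-µm-wide cell is imaged
  through a PSF of σ ≈ 130 nm, so 8–15 % of its flux lands outside the
  cell outline and is missed by mask-restricted photometry. The expected
  captured fraction for emitters uniform over the mask equals the in-mask
  integral of the mask convolved with the PSF over the mask area
  (`mask_capture_fraction()`, typically 0.86 for these cells);
  `quantify_copy_numbers()` divides each copy number by it. Without the
  correction, recovered copy numbers are biased ~12 % low at every
  expression level.

## Single-molecule calibration

After three or more bleaching lifetimes most fluorophores are dark and
transient single-frame focus appearances are individual molecules
returning to the bright state. `calibrate_from_movie()` accepts a
candidate only if (i) no focus was detected within 300 nm in the adjacent
frames and (ii) the ROI photometry in both adjacent frames is below half
the event's — without the photometric check, persistent foci flickering
around the detection threshold contaminate the event set in either
direction. Each event is then fitted on the temporally
background-subtracted frame ($F_k - \tfrac12(F_{k-1}+F_{k+1})$), which
cancels all static cell structure (autofluorescence, unbound haze) that a
constant-background Gaussian fit would otherwise partially absorb. On the
default calibration scenario this recovers $I_{sm}$ within 1 % of the
configured 1850 a.u. from ~160 events. Intensities scale linearly with
exposure; 34 ms (the rapid-acquisition frame time) is the reference
exposure at which $I_{sm}$ is quoted, a convention the package fixes
because the source measurements do not state one.

## Step counting

`changepoint_steps()` fits a piecewise-constant model minimising the
residual sum of squares plus a per-change-point penalty
$\beta = p\,\hat\sigma^2 \log n$, solved *exactly* by optimal-partitioning
dynamic programming, so the result provably matches exhaustive search
(binary segmentation, the commonly named alternative, is greedy and does
not). $\hat\sigma$ is the median absolute successive difference scaled to
a Gaussian SD. The penalty factor $p = 4$ was frozen by a null
calibration: the smallest integer giving zero change points in at least
99 % of 1000 pure-noise traces at both n = 60 and n = 300. At that value,
97.6 % of simulated two-molecule traces at SNR 5 get the correct step
count. Initial levels divided by $I_{sm}$ (rounded, minimum one) give
molecules per focus.

# Focus detection and fitting

Candidates are local maxima of a difference-of-Gaussians band-pass
(σ and 2σ, σ = 1.3 px) exceeding a per-cell robust threshold
(median + 5 × MAD within the mask). Three details proved essential on
realistic images and are worth knowing when tuning:

* A 1-µm rod is narrow enough that its own uniform haze (unbound
  molecules, autofluorescence) passes the band-pass; each cell's median
  intensity is therefore subtracted inside its mask *before* filtering.
* The intensity step at a bright cell's outline produces spurious
  band-pass maxima along the rim. For focus *counting*
  (`count_foci_per_frame()`) candidates are restricted 2 px inside the
  outline — a uniform detection loss that cannot change a decay rate —
  and the threshold is computed once on the first (noisiest) frame and
  held fixed, so the detection criterion does not drift as the background
  bleaches.
* Candidate foci are fitted with a **pixel-integrated** elliptical
  Gaussian plus constant background (each model pixel is the Gaussian
  mass inside it), avoiding the $\sigma^2 + 1/12$ bias of point-sampled
  fits; fits are rejected for σ outside [0.5, 4] px or amplitudes within
  2 residual SDs of zero. Integrated intensity is
  $2\pi A \sigma_x \sigma_y$. Centroid accuracy on simulated molecules at
  SNR ≥ 10 is below 30 nm RMS, which is what makes a 200 nm
  colocalisation radius meaningful.

# Colocalisation statistics

Distances are nearest-neighbour within the same cell; a focus is
colocalised if at least one partner-channel focus lies within 200 nm
(2 px), and each direction (polymerase→replisome, replisome→polymerase)
is reported with its standard error of proportion, or the SEM across
technical replicates when several are available. Distance histograms use
annular shells of equal area (default 3 × 10⁴ nm² per shell, making
218 nm — cumulative area 15 × 10⁴ nm² — a shell boundary), so complete
spatial randomness fills shells uniformly; a distance exactly on a
boundary belongs to the inner shell. Chance levels are the area of the
*union* (not sum) of search discs around partner foci intersected with
the cell mask, over the cell area, evaluated on a 10 nm rasterisation
(< 1 % error at 200 nm radius); a summed-area variant exists behind a
flag for sensitivity analysis.

# The synthetic-movie generator

The generator states one world and the tests measure it; none of its
parameters were moved to make a test pass.

* **Cells** are spherocylinders, width 1 µm, undamaged tip-to-tip length
  2.5 ± 0.4 µm, placed without overlap by rejection sampling. After
  damage, length grows exponentially from 20 min so that cell *volume*
  reaches 2.5 × its undamaged value at 120 min, then caps.
* **Expression** rises from 20 molecules per cell (baseline) to 280 at
  the plateau along a logistic between the 20 min onset and the 90 min
  plateau, rescaled to hit both endpoints exactly; per-cell counts are
  Poisson.
* **Binding classes**: tight (exactly at a replisome site), loose (site
  plus isotropic 2D Gaussian offset, σ = 300 nm per axis), dispersed
  (uniform in the cell), free (remainder; D = 10² µm²/s — the text value
  is used where the source material is internally inconsistent about this
  constant). After a configurable switch (default 100 min) the tight and
  loose weights are scaled down (default to zero) with the difference
  moved to dispersed, emulating the late-stage loss of replisome-proximal
  binding. Replisome counts per cell stay constant as cells filament
  (damage blocks replication initiation), which is what makes the chance
  colocalisation level fall from ~5 % to ~3 % over a damage time-lapse.
* **Optics/detector**: pixel-integrated Gaussian PSF (σ 1.3 px, chosen
  for a 1.49-NA objective at ~540 nm with 100 nm pixels — no PSF width is
  stated in the source measurements), one fluorophore integrating to
  1850 a.u. at 34 ms, linear in exposure; uniform in-cell
  autofluorescence (τ = 60 s in illuminated time) and the unbound haze
  are PSF-blurred so their flux spills past the outline like any other
  emission; 16-bit detector with constant offset, Poisson shot noise and
  Gaussian read noise.
* **Free molecules** are rendered as 20-sub-step Brownian smears
  (RMS extent ≈ √(4Dt) ≈ 3.7 µm per 34 ms frame, far wider than a cell),
  or — for large ensembles, where it is indistinguishable on the cell
  scale — as a uniform PSF-blurred haze over the mask. Bound-site motion
  (D = 10⁻⁵ µm²/s; ~1 nm per frame, far below pixel size and
  localisation error) is available as ground-truth tracks
  (`diffusion_track()`) but not rendered.
* **Bleaching** is exponential in illuminated time (τ = 6 s) with rare
  single-frame returns (10⁻³ s⁻¹ per bleached molecule). Time-lapse
  series (bright-field 34 ms / yellow 50 ms / red 100 ms every 5 min for
  3 h, fluorescence channels 2 s apart) resample the molecule population
  per time point from the expression curve: synthesis and exchange
  between points dwarf the ~50 ms of illumination per point, so no
  cumulative bleaching is applied across the series.
* **Bright-field** is an inverted soft-edged mask image — sufficient for
  the threshold segmenter; real bright-field optics are out of scope.

What a green test does *not* establish: the generator has no 3D optics,
chromatic aberration, nucleoid structure, cell curvature or lineage;
cells neither divide nor die; autofluorescence is spatially uniform; and
the bright-field channel is synthetic, so segmentation performance on
real transmitted-light images is not demonstrated.

## The tuned colocalisation scenario

The late-stage-switch scenario uses focus-class weights chosen a priori,
by closed form, to sit near the observed 10 % pre-switch colocalisation:
with $f_{tight} = 0.04$, $f_{loose} = 0.12$, dispersed $0.84$, two
replisomes per cell and a chance level $q \approx 0.05$,

$$P(\mathrm{coloc}) \approx f_{tight} + f_{loose} \, P(R_{300} \le 200) +
f_{disp}\, q \approx 0.04 + 0.12 \times 0.199 + 0.84 \times 0.05 \approx
0.10,$$

where $P(R_{300} \le 200) = 1 - e^{-200^2 / (2 \cdot 300^2)}$ is the
Rayleigh mass of the loose offset inside the threshold. After the switch
all foci are dispersed and the measured fraction collapses onto the
chance level (~3–5 %), reproducing the shape of the published
time-resolved curves.

# Segmentation and geometry

The segmenter thresholds the bright-field image (Otsu), labels
4-connected components, fills holes, and discards components that touch
the border, are smaller than 40 px, or fill less than 72 % of their
oriented bounding box — the rod-shape heuristic that flags merged cell
pairs. Length is the extent along the mask's principal axis (simulated
cells are straight rods, so this equals a medial-axis length without the
machinery); width is the minor-axis extent. Imported label masks or
polygon outlines take precedence over internal segmentation, mirroring
manually curated outlines. On the generator's fields it recovers ≥ 95 %
of cells at IoU ≥ 0.8 with areas within 10 %.

# Limitations

* Copy-number recovery carries a residual −3 to −9 % bias (tight/loose
  molecules sit nearer the axis than the uniform-emitter aperture model
  assumes, and segmentation is not pixel-perfect); the acceptance gate is
  ±15 % at 10–300 molecules per cell.
* τ₂ cannot be measured accurately from a single 10.2 s movie; the
  package's population/fixed-τ₂ strategies are the supported routes.
* No single-particle tracking, MSD analysis, Bayesian step models or
  pixel-based (cross-correlation) colocalisation.
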