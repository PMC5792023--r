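# smfoci

Single-molecule quantification of fluorescent-protein foci in live
bacteria: copy numbers from photobleaching decays, molecules per focus
from change-point step counting, and two-colour focus colocalisation —
together with a ground-truth synthetic-movie generator that makes every
step testable.

## The scientific problem

During the bacterial SOS response, error-prone translesion DNA
polymerases such as *E. coli* pol IV (DinB) are up-regulated and bind DNA
at discrete sites. In live-cell fluorescence movies a DNA-bound,
fluorescently tagged polymerase appears as a diffraction-limited *focus*
(unbound molecules diffuse at D ≈ 10² µm²/s and blur over the cell),
so three questions become measurable:

* **How many molecules does a cell contain?** Under continuous
  excitation, the mean pixel intensity in a cell decays as
  `f(t) = A1·exp(−t/τ1) + A2·exp(−t/τ2)`, with τ1 = 6 s (fluorophore
  photobleaching, measured from the decay of detected focus counts) and
  τ2 ≈ 60 s (autofluorescence, measured in fluorophore-free cells). The
  fluorophore amplitude A1 × cell area, divided by the single-molecule
  intensity (calibrated from transient return events of bleached
  fluorophores), gives the copy number N; the concentration is
  c = N / (N_A · V) with V the spherocylinder cell volume.
* **How many molecules sit in one focus?** Intensity trajectories of
  5 × 5 px ROIs (2-px background ring subtracted) are fitted by exact
  penalised change-point segmentation; the initial level over the
  single-molecule intensity counts the molecules.
* **Does the polymerase act at replisomes?** Foci in the polymerase and
  replisome channels are matched by same-cell nearest neighbours;
  fractions within 200 nm (2 px) are reported in both directions,
  distance histograms use equal-area shells (radial measurements are
  otherwise biased toward large radii), and the chance level is the
  disc-union area fraction around partner foci.

Because the study this models deposits no raw movies, the package ships a
two-colour movie simulator (rapid acquisitions of 300 × 34 ms frames;
bright-field/yellow/red time-lapse every 5 min for 3 h) with full ground
truth: cell geometry with damage-induced filamentation, a 20 → 280
molecules/cell expression time course, tight / loose / dispersed / free
binding classes, τ = 6 s bleaching with return events, τ = 60 s
autofluorescence, PSF rendering and camera noise.

## Worked example

```r
library(smfoci)

cfg <- sim_config(seed = 42, field_px = 160)       # undamaged world, N ~ 20
sim <- generate_rapid_acquisition(cfg, "undamaged", n_cells = 12)
seg <- segment_cells(sim$brightfield$data[, , 1], pixel_size_nm = 100)
q   <- quantify_copy_numbers(sim, seg,
                             cal = calibrate_single_molecule(rep(1850, 40)),
                             tau2_fixed_s = 60)
s <- summarise_values(q$table$N_molecules)
```

prints (abridged):

```
<cell_set> 12 cells on a 160 x 160 px field (100 nm/px)
  cell_id        A1 volume_fL N_molecules  conc_nM
1       1  88.29772  2.121072    12.92510 10.11876
2       2 135.50591  1.915680    18.35174 15.90756
3       3 116.75518  1.973648    16.32089 13.73167
copy number: 18.0 +/- 1.7 molecules per cell (SD 5.7, n = 12)
```

The configured truth is 20 molecules per cell (Poisson across cells), so
the pipeline — segmentation, per-cell decay fits with τ1 fixed at 6 s,
calibration algebra, aperture correction — lands within its ±15 %
acceptance band on just 12 cells.

A doubly-labelled-replisome control shows what "tight" colocalisation
looks like:

```r
cfg2  <- sim_config(seed = 7, f_tight = 1, f_loose = 0, f_dispersed = 0)
set.seed(7)
cells <- simulate_cells(cfg2, 20, field_px = 192)
tc    <- simulate_two_colour_foci(cfg2, cells, double_label = TRUE)
colocalised_fractions(tc$fociA, tc$fociB, radius_nm = 200)
#   n_A n_B frac_A_with_B frac_B_with_A
# 1  69  69             1             1
equal_area_histogram(nn_distances(tc$fociA, tc$fociB), n_shells = 6)
#   shell inner_radius_nm outer_radius_nm count
# 1     1          0.0000         97.7205    65
# 2     2         97.7205        138.1977     4
# 3     3        138.1977        169.2569     0
# ...
```

All 69 focus pairs colocalise at 200 nm and the distance mass sits in the
innermost equal-area shells — the signature of two labels on the same
structure, limited only by 30 nm localisation noise and the 2 s channel
lag. A loose population (σ = 300 nm offsets) spreads mass across many
shells instead.

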