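---
title: "Methods: phase-resolved proton ventilation mapping and its comparison with gas ventilation MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-resolved proton ventilation mapping and its comparison with gas ventilation MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hyperpolarized-gas (e.g. ^129^Xe) MRI depicts ventilated airspaces directly
during a breath-hold, but needs polarizer hardware, dedicated coils and an
inhaled gas dose. Free-breathing proton MRI offers an indirect alternative:
because parenchymal proton signal is approximately proportional to tissue
density, and density falls as a lung region inflates, the respiratory
modulation of the proton signal carries a regional ventilation signal.
Phase-resolved functional lung (PREFUL) post-processing turns a dynamic
proton acquisition into respiratory-phase-resolved images and derives
per-voxel ventilation markers from them.

`lungvent` implements both quantification chains and their comparison:

1. **Proton chain** — respiratory-signal estimation, axial registration,
   phase sorting, the static regional-ventilation map (RVent), the dynamic
   flow-volume-loop cross-correlation map (FVL-CM), defect thresholding
   and the ventilation defect percentage (VDP).
2. **Gas chain** — thoracic-cavity segmentation by seeded region growing,
   bias-field correction, linear-binning classification and VDP.
3. **Comparison** — slab-thickness matching, label coregistration, spatial
   overlap, Sørensen–Dice agreement, and cohort statistics (Spearman,
   Bland–Altman, Wilcoxon tests, median/IQR tables).

No public dynamic lung MRI dataset accompanies these methods, so the
package ships a synthetic 4D breathing-lung phantom with exact ground
truth; every stage is validated against it.

## The proton ventilation model

All proton analysis rests on the density–inflation signal model: if a
voxel's local fractional inflation at time $t$ is $e(t)$, its parenchymal
signal is

$$S(t) = \frac{S_0}{1 + e(t)},$$

so signal is maximal at end-expiration ($e = 0$) and falls with
inflation.

**RVent.** For each voxel the two respiratory phases with maximal
ventilation amplitude are its own signal extrema over the phase bins:

$$\mathrm{RVent} = \frac{S_{\max} - S_{\min}}{S_{\max}}.$$

Under the signal model a healthy voxel with inflation amplitude $a$ has
$\mathrm{RVent} = a/(1+a)$, which the phantom tests confirm to within the
phase-binning attenuation. Using each voxel's *own* extremal phases (rather
than one global end-expiration/end-inspiration pair) matters for regions
that ventilate with a phase lag: their amplitude — and hence RVent — is
unchanged, so purely temporal abnormalities are left to the dynamic
marker. This is the mechanism behind the complementarity of the two
markers: amplitude defects are caught by RVent, timing defects by FVL-CM.

**FVL-CM.** Each voxel's ventilation-volume trajectory is
$V(p) = (S(p_E) - S(p))/S(p_E)$ with $p_E$ the global end-expiratory bin,
and its flow channel $F(p)$ is the cyclic central difference of $V$ over
the phase grid. The FVL-CM is the normalized inner product of the
mean-centred, concatenated $(V, F)$ channels of the voxel and of a healthy
reference loop. It is amplitude-invariant and bounded in $[-1, 1]$; a
quarter-cycle phase lag drives it to zero (quadrature orthogonality). The
reference loop is the phase-wise median of $(V, F)$ over the
well-ventilated subset (voxels with RVent at or above the in-mask median);
the median keeps the reference anchored to the healthy majority even when
a third of the lung is delayed. No circular-shift search is performed: the
metric is deliberately sensitive to timing.

**Defect thresholds.** RVent defects fall strictly below
$0.4 \times P_{90}$ of the in-mask RVent distribution ($P_{90}$ by linear
interpolation between order statistics); FVL-CM defects fall strictly
below the fixed threshold 0.9. Boundary values count as healthy — a fixed,
testable convention. The combined map is the voxel-wise logical OR of the
two defect sets, so $\mathrm{VDP}_{\mathrm{Combined}} \ge
\max(\mathrm{VDP}_{\mathrm{RVent}}, \mathrm{VDP}_{\mathrm{FVL\text{-}CM}})$
by construction. VDP is the defect share of evaluable (non-excluded)
in-mask voxels, in percent.

**Exclusions.** Voxels with non-positive end-expiratory signal are
excluded, as are voxels whose peak phase signal exceeds 1.5 times the
in-mask median peak signal. The latter is a simple intensity rule standing
in for vessel exclusion: within a lung mask, bright voxels are
non-parenchymal (vessels, or mask-edge voxels contaminated by chest-wall
or abdominal signal) and do not follow the density model. On the phantom
this removes roughly 2% of mask voxels, all at the diaphragm face.

## Pipeline numerics

**Respiratory signal.** Mean in-mask intensity per frame, sign-flipped and
rescaled to $[0, 1]$; offset- and scale-invariant by construction.

**Registration.** Breathing motion is corrected per frame with an axial
translation + scale about the lung apex, found by minimising the
sum-of-squared-differences to the reference frame over the lung mask
dilated twice — the dilation includes the high-contrast lung boundary,
without which near-uniform parenchyma would leave the transform
under-determined. The transform is bounded (±8 voxels translation, scale
0.7–1.4, i.e. beyond any physiological diaphragm excursion) and optimised
with L-BFGS-B from a warm start at the previous frame's solution. The
similarity metric uses linear interpolation (smooth objective), but the
transform is *applied* with nearest-neighbour sampling: resampled values
are then always observed voxel values, and lung/soft-tissue boundaries are
never blended into the parenchymal time series — interpolation blending at
the diaphragm otherwise manufactures spurious loop distortions in the
bottom voxel layer.

**Phase sorting.** End-expiratory troughs of the respiratory signal
delimit cycles; within a cycle the phase rises linearly from 0 to 1
between troughs. Frames before the first (after the last) trough are
phased by cyclic extrapolation with the adjacent cycle's period, so no
frame is discarded. Frames are averaged into `n_phases = 8` equal-width
bins (configurable); empty bins are filled by cyclic linear interpolation
of their nearest occupied neighbours and per-bin occupancy is recorded.

**Median smoothing.** The RVent map is smoothed with an in-mask 3×3×3
median before thresholding (kernel configurable; 1 disables). Neighbours
outside the grid or the mask are replicate-padded with the centre voxel's
own value, keeping the vote a full 27-sample median everywhere; without
this, voxels on the apex and diaphragm faces of the mask lose half their
neighbourhood and their label is decided by in-plane neighbours alone,
which jitters defect boundaries by a voxel along entire mask faces.

**Percentiles and quartiles.** All percentiles (RVent threshold, gas
normalization anchor) and the summary-table quartiles use linear
interpolation between order statistics, and the unit tests check them
against an independently coded order-statistic oracle.

## The gas chain

**Segmentation.** Region growing from per-lung seed voxels on the
anatomical image, 26-connectivity, with the intensity window
$|I - \mu| \le k \cdot \max(\sigma, 0.2\,\mu)$ where $\mu, \sigma$
summarise the 3×3×3 seed neighbourhoods and $k = 2.5$. The relative floor
keeps the window defined for perfectly homogeneous seed regions (where
$\sigma = 0$) and admits slab partial-volume voxels that are majority
lung. A runaway guard aborts if the region exceeds 60% of the volume
(background seed). Interior cavities of the grown mask are filled; a
box-kernel morphological closing is deliberately not used because it
deposits a staircase shell on digitised convex boundaries.

**Bias correction.** The corrector's contract is
`corrected = image / field` with a smooth, strictly positive field of
in-mask geometric mean 1. The default implementation fits an order-2
polynomial (all cross terms) to log-intensity; voxels below 20% of the
in-mask median are left out (near-zero defect intensities carry no field
information), and the fit is iteratively trimmed — voxels falling more
than 0.2 log units below the current prediction are dropped and the
polynomial refitted — so contiguous ventilation defects are not mistaken
for coil shading. Any external corrector honouring the contract can be
swapped in.

**Linear binning.** In-mask intensities are normalized by their in-mask
99th percentile (clipped at 1) and classified into six bins with upper
edges 0.16, 0.34, 0.52, 0.70, 0.88, 1; bin 1 is the defect class and
$\mathrm{VDP}_{Xe}$ is its share of the mask. The normalization makes the
chain invariant to global intensity scaling. The edges follow the linear
binning convention established for hyperpolarized-gas ventilation
analysis; a healthy-cohort rescaling of the anchor is not reproducible
here, so results are always relative to the configured edges.

## Regional comparison

Proton defect maps (3.9 mm axial) are matched to the gas slab thickness
(15 mm) by overlap-weighted voting: a slab voxel is in-mask if the
weighted in-mask fraction of its thin slices reaches 0.5, excluded if the
weighted excluded fraction reaches 0.5, and defect if the weighted defect
fraction among evaluable contributions reaches 0.5 (the majority level is
configurable). Labels are then coregistered onto the gas grid through the
affine relation with nearest-neighbour sampling — labels are never
interpolated as continuous values.

Agreement is quantified exactly as in the study design this package
follows: *spatial overlap* is the percentage of evaluable voxels
(healthy-or-defect in both maps) on which the maps agree; the
Sørensen–Dice coefficient is reported separately for the healthy and
defect classes, with the empty-set conventions Dice = 1 when both sets are
empty and 0 when exactly one is. Voxels excluded in either map are removed
from the evaluable set — the documented resolution of what "within the
lung parenchyma mask" means when the two masks differ slightly.

## Cohort statistics

The statistics layer always takes the nonparametric branch. Spearman
correlation uses midranks; the paired comparison of VDP scales is a
Bland–Altman analysis (mean bias, limits of agreement
$\mathrm{bias} \pm 1.96\,\mathrm{SD}$ with the sample SD) with a paired
Wilcoxon signed-rank p-value; group comparisons use the Wilcoxon rank-sum
test. Exact p-values are computed for samples of at most 25 without ties,
the normal approximation with tie/continuity correction otherwise; the
switch point is a pinned convention, logged per call in the sense that the
rule is deterministic in the data. Correlation tables flag significance at
family-specific Bonferroni levels: 0.0167 for the three VDP-vs-VDP
comparisons and 0.0125 for the spirometry correlations. Summary tables
report median and IQR with the same linear-interpolation quartile
convention as everywhere else.

## The phantom: what it emulates, and what it does not

The generator builds a torso with two lungs on a 32×26×40 grid at 3.9 mm
isotropic spacing (proton grid) and derives the matched gas pair on a
15 mm slab grid. Design choices:

* **Breathing**: sinusoidal inflation
  $e(t) = a\,(1 - \cos 2\pi t/T)/2$ with tidal amplitude $a = 0.3$ and
  period 4 s, sampled every 0.25 s for 44 frames (2.75 cycles). A
  cycle-to-cycle amplitude jitter knob exists (default 0) — real breathing
  is irregular, and the regular default is a deliberate simplification
  with no claim of physiological fidelity.
* **Motion**: each lung is a vertical elliptic column with a flat apex
  plane and a domed diaphragm; inflation scales the axial coordinate about
  the apex, so the dome descends (deeper columns travel further — the
  diaphragm-dominated pattern) while the apex and the vertical side walls
  stay fixed. Content is advected by the same scaling, which makes the
  motion exactly recoverable by the registration family and keeps every
  end-expiratory lung voxel inside the lung at all inflation states — the
  property the fixed-mask signal-conservation check relies on. There is no
  lateral deformation and no cardiac motion.
* **Signal**: $S = S_0/(1 + e_{\mathrm{local}})$ with $S_0 = 0.4$ against
  soft tissue at 1.0; additive Gaussian noise at a configurable SNR
  (default 30; the distinction from Rician noise is negligible at
  magnitude SNRs this high and Gaussian keeps closed-form checks).
* **Defects**: grown as contiguous wedges over the 2D graph of lung
  columns from seeded germ columns, each accepted column defective over
  its full craniocaudal extent (the final column part-filled from the lung
  base so the defect count matches the configured fraction exactly). The
  wedge shape mirrors the segmental-to-lobar, craniocaudally extended
  defects of obstructive disease and keeps the defect pattern resolvable
  on the 15 mm slab grid. Static defects scale the local amplitude (0 by
  default); dynamic defects keep full amplitude but lag by a quarter cycle
  (default).
* **Gas image**: proportional to the per-voxel fractional ventilation,
  slab-averaged, multiplied by a smooth bias field (peak-to-trough ratio
  1.4 by default, log-field representable by an order-2 polynomial) plus
  noise. Dynamic defects are additionally scaled by a gas-delivery
  efficiency of 0.1: a region that fills a quarter-cycle late receives
  little fresh gas during a single breath-hold wash-in, so timing defects
  are dark in the gas image even though their proton amplitude is intact.
  This one number encodes the wash-in physiology and is set once, as a
  generator property.

What passing the phantom tests does **not** show: performance under
cardiac pulsation, B0/susceptibility artefacts, radial streaking,
irregular breathing, deformable (non-axial) motion, inter-scan volume
differences between free breathing and breath-hold, or real coil-array
bias fields. Cross-modality agreement on the phantom (overlap ≥ 95%,
defect Dice ≥ 0.9 at high SNR) is an *upper bound* — both modalities are
generated from one ground truth in one geometry, with none of the
physiology that separates the two examinations in patients, so cohort
agreement in real data is expected to be far lower.

## Problem sizes and determinism

The shipped defaults are sized for a laptop-class analysis: a phantom
subject (44 frames of 32×26×40) runs the full two-modality pipeline in a
few seconds, and the simulated 20-subject cohort used by the package's
acceptance checks completes in under two minutes. Every stochastic step —
defect growth, noise, cohort composition, spirometry draws — derives from
the configured seed through a scoped RNG, so identical configurations
reproduce results bit for bit and the global RNG stream of the calling
session is never disturbed.

## Known limitations

* The registration family is axial translation + scale only; it cannot
  correct in-plane or deformable motion (none is generated).
* The bias corrector is a low-order polynomial, adequate for smooth coil
  shading but not for sharp sensitivity transitions; the contract allows a
  stronger corrector to be swapped in.
* The FVL-CM reference loop assumes at least half the lung is reasonably
  ventilated; in a lung with a defect majority the reference itself
  degrades.
* Linear-binning results depend on the configured edges; no
  healthy-cohort calibration of the intensity anchor is performed.
* VDP confidence intervals, lobar parcellation and deformable
  registration are out of scope.
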