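---
title: "Concurrent tumor metabolism and vascular morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concurrent tumor metabolism and vascular morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascumet)
```

`vascumet` quantifies, on one shared voxel grid, two faces of a tumor that
are usually imaged separately: its glucose metabolism (dynamic FDG-PET) and
its vascular architecture (ultrafast power-Doppler ultrasound). Because no
public dataset accompanies the protocol it implements, the package ships a
synthetic-phantom generator with exact ground truth; every processing stage
is validated against that truth, and the `analysis/` scripts re-run the full
study workflow on the synthetic world.

## The kinetic model

FDG kinetics follow the irreversible two-tissue-compartment model. With
plasma activity $C_p(t)$, free tracer $C_1$ and phosphorylated tracer $C_2$:

$$\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3)\,C_1, \qquad
  \frac{dC_2}{dt} = k_3 C_1, \qquad C_T = C_1 + C_2,$$

with $k_4 = 0$ (FDG-6-P does not leave the cell on the time scale of the
acquisition). The net influx constant is $K_i = K_1 k_3/(k_2+k_3)$ and the
metabolic rate of glucose is

$$\mathrm{MRGlu} = K_i \cdot PG / LC,$$

with the lumped constant fixed at $LC = 0.69$. `forward_2tc()` evaluates the
analytic exponential-convolution solution exactly for a piecewise-linear
$C_p$ (the recursion per linear segment is closed-form, so the only model
error is the piecewise-linear representation of the input); the test suite
checks it against an independent Runge-Kutta integration to better than
$10^{-4}$ relative.

Conventions worth stating explicitly:

* **Units.** Rate constants are per minute (the field convention); all
  curves are sampled in seconds; conversions happen inside the functions.
  Plasma glucose units are the caller's choice and MRGlu inherits them — the
  package never guesses between mM and mg/dL.
* **Fitting.** `fit_2tc()` minimizes the frame-duration-weighted squared
  residual of frame-averaged model predictions, with box bounds
  $[0, 2]\ \mathrm{min^{-1}}$, the default start $(0.1, 0.1, 0.05)$ and two
  fixed alternate starts (best objective wins). On noiseless synthetic data
  it recovers the rates to better than 1% from any admissible start.
* **Patlak.** `patlak()` regresses $C_T/C_p$ on $\int_0^t C_p\,d\tau / C_p$
  for frame midpoints past $t^* = 10$ min. The start of the linear range is
  not specified by the protocol; 10 min is comfortably past the transient
  for the rate ranges simulated here and is exposed as an argument.
* **SUV** is normalized by body weight (the rodent standard), so a uniform
  distribution of the dose over body mass gives SUV 1.
* **Tumor VOI.** The hottest voxel inside the user's search region defines
  the peak; the VOI is the connected component containing it among voxels
  strictly above 30% of that peak.
* **Input function.** The image-derived input is the mean TAC over the
  five-voxel connected cluster with maximal summed early-frame uptake
  (first 60 s by default). Exhaustive search over 5-voxel clusters is
  combinatorial, so the cluster is grown greedily from every candidate seed
  (ties broken at the lowest linear voxel index) — deterministic, and exact
  whenever one cluster clearly dominates, which is the regime the rule is
  meant for.
* The caliper enrollment volume $\tfrac12 \ell w^2 \ge 140$ mm$^3$ treats
  the boundary as inclusive.

## Ultrafast Doppler processing

Each imaging plane is a stack of frames. Writing the stack as its Casorati
matrix $C$ (space $\times$ time), `svd_clutter_filter()` removes the
`n_cut` leading singular components — the slowly varying, spatially coherent
tissue clutter — and keeps the residual blood signal. No rank-selection rule
is prescribed by the protocol; the default is a fixed `n_cut = 2`, with an
energy-based suggestion (`select_clutter_rank()`, components carrying 95% of
cumulative energy) available and logged when used. Re-applying the filter
with the returned `clutter_basis` is an exact orthogonal projection
(idempotent); re-estimating the subspace on filtered data is not, by
construction. `power_doppler()` integrates $|s|^2$ over frames, and
`assemble_power_volume()` stacks planes at their 0.1 mm elevation spacing.

The elevational point-spread function is wider than the in-plane one.
`estimate_blur_kernel()` runs alternating (blind) Richardson-Lucy updates of
scene and kernel on a bead/wire phantom volume, and `richardson_lucy()`
applies the standard multiplicative update with the estimated kernel. The
iteration preserves non-negativity and total intensity (to within 1% for
content away from the volume faces, where zero padding loses flux —
deliberately, since a normalized-boundary variant would not conserve the
kernel's shift-invariance).

Vessels are then enhanced with multi-scale Hessian (Frangi) vesselness
($\alpha = \beta = 0.5$, structureness scale $c$ set to half the maximum
Hessian norm per scale, scales 0.1–0.4 mm spanning the expected radii),
thresholded by the isodata fixed point
$\tau = (\mu_{\le\tau} + \mu_{>\tau})/2$, cleaned of small components, and
skeletonized.

## Skeletons and graphs

`skeletonize_3d()` is an iterative ordered thinning: six directional
subiterations peel border voxels that are *simple points* — deletion
preserves both the foreground 26-topology and the background 6-topology
(topology numbers $T_{26} = T_6 = 1$) — and are not curve endpoints. The
result is a one-voxel-wide medial set homotopic to the mask.

`skeleton_to_graph()` takes nodes at skeleton voxels of 26-neighborhood
degree $\neq 2$, merges 26-adjacent junction voxels into one node, traces
maximal degree-2 paths as edges, and reports per edge: length (summed
Euclidean inter-voxel steps), chord (endpoint distance), radius (mean of the
Euclidean distance transform of the mask along the path) and tortuosity.

Two clean-up steps matter in practice and are on by default:

* **Junction consolidation.** Inside a junction the medial axis of crossing
  tubes is not resolvable below the local vessel diameter; thinning can
  split one anatomical junction into a cage of nearby nodes and short
  internal edges. `consolidate_junctions()` contracts junction-junction
  edges shorter than the local resolvable scale ($2r + 2$ voxels) and drops
  the sub-scale self-loops this leaves. The scale is physical (the tube
  diameter), not tuned per dataset.
* **Spur pruning.** Terminal branches shorter than two voxels are thinning
  artifacts and are removed, with pass-through nodes re-merged.

**Tortuosity convention.** Tortuosity is chord/length: 1 is straight and
values decrease with winding — the inverse of the more common
length-over-chord ratio. The convention is applied verbatim throughout
(every reported tortuosity is in $(0, 1]$), and the common inverse is
available as the separate `length_over_chord` column, never silently
substituted.

Genuine loops are legal: edges between the same node pair are kept as
distinct edges, and a node-free cycle is traced from an artificial node at
its lowest-index voxel.

## Multimodal bands and histology

The PET tumor VOI crops the power-Doppler volume (`crop_uui_to_pet_voi()`;
a grid mismatch is an error — co-registration is by construction, and
silent resampling would corrupt voxel counts). The VOI is partitioned into
SUV bands $[1,2)$, $[2,3)$, $[3,\infty)$ (closed-left, per the stated
legend; exactly 2.0 is intermediate); VOI voxels below SUV 1 stay explicitly
*unassigned* rather than being folded into the low band. Regional vessel
density is band vessel volume over band region volume; a band with zero
region volume is undefined (NA), never 0.

Immunofluorescence fields are quantified as: isodata threshold + connected
components for the vessel count (touching objects merge — the counter sees
connected CD31-positive regions), pixel share of the field for the CD31
surface fraction, and the fraction of CD31 objects overlapped by thresholded
alpha-SMA for pericyte coverage. "Covered" means any overlapping pixel by
default; a stricter minimum overlap fraction is a parameter. The capillary
subset keeps objects of equivalent diameter $2\sqrt{A/\pi} < 10\ \mu$m.

## Cohort statistics

`delta_endpoint_correlation()` computes, per parameter pair, the squared
Pearson correlation across subjects between the early change
(W1 $-$ W0) and the endpoint value (W6), complete-case per cell with the
per-cell $n$ reported. Two significance rules are always computed and never
merged: the fixed cut $R^2 \ge 0.61$, and the analytic two-sided Pearson
critical value $R^2_c = t_c^2/(t_c^2 + n - 2)$. At $n = 12$ and
$\alpha = 0.01$ the analytic cut is $R^2_c \approx 0.50$, which does not
match the fixed 0.61 — the discrepancy is surfaced, not resolved. "Vessel
length dispersion" is not defined in the source protocol and is implemented
as the standard deviation of per-edge lengths. Group comparisons use two-way
ANOVA (group $\times$ week) with Bonferroni-adjusted per-week contrasts
($p_{adj} = \min(1, m\,p)$) and a Wilcoxon alternative; missing sessions are
never imputed.

## The synthetic world

Generator defaults are fixed once, on physical grounds, and not revisited:

* **Grid**: 0.1 mm isotropic, the stated ultrafast Doppler resolution scale.
* **Plasma input**: gamma-variate rise peaking at 30 s and a bi-exponential
  washout; peak 2500 kBq/mL, the scale of a 10 MBq bolus transiting the
  ~2 mL blood pool of a 30 g mouse. A constant-input mode exists for
  closed-form Patlak tests.
* **PET noise**: zero-mean Gaussian with variance proportional to the frame
  mean and inversely proportional to frame duration — a Poisson surrogate;
  the real reconstruction noise of an OSEM scanner is not modeled.
* **Vessel tree**: branches grow as gently curved polylines with opposed
  child azimuths and explicit collision avoidance (tube surfaces of
  non-adjacent branches keep a >1-voxel clearance), so the rasterized mask
  provably has the tree topology of the truth. Without that guarantee the
  ground-truth node count would be ill-defined.
* **Ultrafast scene**: tissue is an exact low-rank sum of orthonormal smooth
  spatial fields times slow temporal profiles with a steeply decaying
  component spectrum (dominant bulk-motion clutter); blood is temporally
  white on vessel pixels. This makes SVD separation exact by construction —
  a best case, deliberately.

A green test therefore establishes correctness of the computations under
ideal registration, known kernels and idealized noise. It does not establish
robustness to beamforming artifacts, speckle, motion, attenuation errors or
partial-volume effects, none of which are simulated.

## Numerical choices and degenerate inputs

Isodata iterates to an absolute tolerance of $10^{-6}$; constant images are
an error (no threshold exists). Empty vessel masks, empty graphs, zero CD31
objects and zero-variance correlation cells all produce explicitly flagged
NA records rather than zeros, so downstream tables distinguish "measured 0"
from "not measurable". FFT-based convolutions may leave $\sim 10^{-16}$
negative residue; deconvolution routines clamp it and reject anything
genuinely negative.

## Known limitations

Beamforming, CT reconstruction and inter-modality registration are out of
scope (inputs are assumed co-registered on one grid). The 2TC model has no
blood-volume fraction term and no $k_4$; decay correction is assumed already
applied. Skeleton edge lengths are summed voxel steps and therefore inflate
slightly on oblique or curved vessels (digitization bias) and extend into
tube end caps; the tree-phantom tests quantify the size of this effect
(node counts exact; mean length within 10%).
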