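# vascumet

Concurrent quantification of tumor glucose metabolism and vascular
architecture on a shared voxel grid — dynamic FDG-PET kinetics, ultrafast
power-Doppler vessel morphometry, cross-modal SUV-band vessel density,
immunofluorescence quantification, and longitudinal cohort statistics.

It is written for preclinical imaging studies (e.g., antiangiogenic
treatment monitoring in mouse tumor models) where PET and ultrafast
ultrasound volumes are acquired simultaneously and co-registered by
construction. No public dataset accompanies the protocol, so the package
includes a synthetic-phantom generator with exact ground truth; the whole
pipeline is exercised and validated on that synthetic world.

## The models at the core

**Metabolism.** Dynamic PET is quantified with the irreversible
two-tissue-compartment model

    dC1/dt = K1*Cp - (k2 + k3)*C1,   dC2/dt = k3*C1,   CT = C1 + C2

(k4 = 0), fit by weighted least squares on frame-averaged predictions, and
cross-checked by Patlak linearization, whose asymptotic slope estimates the
net influx constant `Ki = K1*k3/(k2 + k3)`. Glucose consumption is
`MRGlu = Ki * PG / LC` with the lumped constant LC = 0.69. The tumor VOI is
the connected component above 30% of the peak SUV; the input function is the
mean TAC of the five-hottest-voxel cluster in a vessel search region; TLG is
mean SUV × metabolic volume.

**Vasculature.** Per-plane ultrafast frame stacks are clutter-filtered by
truncating the leading singular components of the space × time Casorati
matrix, squared and integrated over frames into power-Doppler images, and
stacked into a 3D volume. After blind kernel estimation and Richardson-Lucy
deconvolution, vessels are enhanced with multi-scale Hessian (Frangi)
vesselness, segmented by the isodata threshold, thinned to a
topology-preserving skeleton, and converted to a node/edge graph. Reported
morphometrics: mean/min/max vessel length and radius, tortuosity
(chord/length, 1 = straight), node count, and vessel volume (mask voxels ×
voxel volume).

**Cross-modal.** The PET VOI crops the Doppler volume; the VOI is split into
SUV bands [1,2), [2,3), [3,∞); each band reports its vessel volume and
regional vessel density (vessel volume / band volume).

**Cohort.** Baseline-normalized longitudinal series, two-way ANOVA with
Bonferroni-corrected per-week contrasts, and the early-change (W1−W0) versus
endpoint (W6) R² heatmap with both the fixed (R² ≥ 0.61) and analytic
(t-based) significance masks.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Step 2
simulates a heterogeneous tumor phantom (rim/mid/core shells with known
kinetics, plus a synthetic vena cava), extracts the image-derived input
function, and recovers the kinetics per region:

```
$ Rscript analysis/02_pet_kinetics.R
simulated 31 frames over 60.5 min
IDIF peak 2472 kBq/mL at 28 s
peak SUV 4.62, VOI 0.034 mL, TLG 0.065
max |Ki_2tc - Ki_true|/Ki_true = 0.03%
  region     Ki_true      Ki_2tc   Ki_patlak      MRGlu
1    rim 0.007272727 0.007275053 0.007233637 0.08962022
2    mid 0.029032258 0.029037398 0.028945665 0.35770708
3   core 0.093750000 0.093767574 0.093587241 1.15510780
```

The fitted `Ki` (min⁻¹) matches the simulated truth to 0.03% on the 2%-noise
phantom, and the Patlak slope agrees with the compartmental estimate; MRGlu
is `Ki × PG / 0.69` at the configured plasma glucose (8.5 mM here).

Step 3 runs the Doppler chain on the default vascular tree phantom (seed 0,
0.1 mm voxels) and scores it against ground truth:

```
$ Rscript analysis/03_vasculature.R
power volume 80x80x80; vessel/background power ratio 7248x
blind kernel vs truth correlation: 1.000
isodata threshold 0.189; Dice vs truth mask 0.84
             metric recovered truth
1           n_nodes     8.000 8.000
2           n_edges     7.000 7.000
3    mean_length_mm     2.433 2.283
...
7 vessel_volume_mm3     2.242 2.190
```

Node and edge counts are exact; vessel volume and mean branch length land
within the voxelization error budget (15% / 10%). Steps 4–6 produce the
SUV-band density table, the per-field histology table, and the cohort
heatmap with both significance masks, all under `results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the main pipeline from scratch against the installed package —
phantom simulation, kinetic fitting, clutter filtering and power-volume
assembly, graph morphometry, band densities, and the null-cohort heatmap —
logging each stage's summary, and writes the JSON report to `--out`.
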