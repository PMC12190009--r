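---
title: "Quantifying ER mechanics and organelle contacts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ER mechanics and organelle contacts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ermechquant quantifies how mechanical strain remodels the endoplasmic
reticulum (ER) and its contacts with other organelles, from fluorescence
microscopy and companion assays. The package covers five measurement
families — fluorescence-lifetime (FLIM) readouts of membrane tension,
ER sheet/tubule morphometry, F-actin orientation statistics,
organelle-interaction quantification (colocalization, contact-site extent,
puncta counting), and tabular assay normalizations — plus a synthetic-data
module that generates every input modality with known ground truth. This
vignette records the models, the tunable parameters, and the design
decisions, so that results are interpretable and reproducible.

## Membrane tension from TCSPC lifetime fitting

Mechanosensitive "flipper" probes report membrane tension through their
fluorescence lifetime: higher tension planarizes the probe and lengthens the
excited-state decay. Time-correlated single-photon counting (TCSPC) yields a
histogram of photon arrival times per region of interest or pixel, modeled
here as a two-component decay

$$\mu(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2} + b,$$

with the package-wide convention that $\tau_1 \ge \tau_2$ (the longer
lifetime is always component 1). `fit_biexponential()` minimizes the Poisson
negative log-likelihood by default (`loss = "poisson_mle"`), the correct
noise model for photon counts; Poisson-weighted least squares
(`loss = "weighted_lsq"`, weights $1/\max(c_i, 1)$) is retained for parity
with vendor software. The reported tension statistic,
`report_tension_lifetime()`, is $\tau_1$; when the longer lifetime does not
carry the larger amplitude the value is flagged
`"amplitude_order_violated"` rather than silently reassigned, since the
convention ties the readout to the dominant long component.

Numerical choices that matter:

- **Initialization and multi-start.** A log-linear regression on the final
  third of the histogram seeds $\tau_1$; $\tau_2$ starts at $\tau_1/3$.
  Five multiplicatively jittered starts guard against local minima; the best
  final likelihood wins. Parameters are optimized on the log scale, which
  enforces positivity without constraints.
- **Acquisition window.** The default synthetic window is 25 ns
  (500 bins of 0.05 ns, i.e. a 40 MHz sync rate). This is an acquisition
  choice, not a biological one: with a free background term, a window much
  shorter than four long lifetimes cannot distinguish a slow exponential
  tail from a constant background — on a 12.5 ns window the
  background-absorbing solution has strictly better likelihood than the
  truth for a 6 ns probe. A 25 ns window restores identifiability.
- **Photon gating.** Fits are refused below `min_photons = 1000` per ROI
  (100 per binned pixel in `fit_lifetime_map()`), below which the
  biexponential is practically unidentifiable.
- **Degenerate components.** If the fitted $\tau_1/\tau_2 < 1.2$ or either
  amplitude falls under 1% of the total, the two components have collapsed;
  the fit is replaced by a one-component fit (reported with
  $\tau_1 = \tau_2$, $A_2 = 0$) and flagged
  `"effectively monoexponential"`. This keeps the reported lifetime
  accurate for genuinely single-exponential decays instead of returning an
  arbitrary split of one component into two.
- **No IRF deconvolution by default.** An optional Gaussian instrument
  response can be included in the model (`irf_sigma_ns`), using the
  exponentially-modified-Gaussian closed form; synthetic decays default to a
  negligible IRF.

`summarize_groups()` provides the descriptive per-group layer (n, mean,
SEM); hypothesis testing is deliberately out of scope.

## ER morphometry: Rényi thresholding, sheets and tubules

Images are first converted to 8-bit (`to_8bit()`: linear min–max rescale to
0–255, round-half-to-even). Automatic thresholds come from Rényi entropy:
for a threshold $t$, the background and foreground normalized histograms
$p_i/P_b$ and $p_i/P_f$ each have a Rényi entropy of order $\alpha$,

$$H_\alpha = \frac{1}{1-\alpha}\,\log \sum_i q_i^\alpha,$$

and the threshold maximizes $H_\alpha^{(b)} + H_\alpha^{(f)}$ over all 256
candidate levels ($\alpha \to 1$ recovers the Shannon maximum-entropy
threshold). The default mode is the three-alpha combination used by the
common ImageJ implementation: thresholds at $\alpha \in \{0.5, 1, 2\}$ are
sorted and blended with weights that depend on how far apart they fall.
Ties in the entropy maximization break toward the lower level; a pixel is
foreground when strictly above the threshold.

`segment_er()` labels each pixel background/tubule/sheet:

- `double_renyi` (default): a first threshold separates ER from background;
  a second Rényi threshold, computed within the ER mask's intensity
  histogram, separates sheet ($\ge$) from tubule ($<$). Sheets image
  brighter and denser than tubules under the ER-GFP labeling this pipeline
  targets. A **bimodality guard** drops the sheet class when the two
  intensity classes inside the ER mask are separated by less than twice the
  sum of their within-class standard deviations: without it, a cell with no
  sheets would have its unimodal tubule mode split in half by the second
  threshold. (A split Gaussian yields separation ≈ 1.3× the summed spreads,
  a split uniform ≈ 1.7×, while genuinely bimodal sheet/tubule histograms
  sit far above 2.)
- `renyi_plus_thickness`: the alternative morphological reading — ER
  regions whose local structure width (twice the distance-transform radius)
  exceeds `width_cutoff_px` become sheet.

The radial statistic follows the 56-pixel convention:
`sample_line_segments()` draws three 56 px-wide rectangles from the nuclear
envelope toward the cell periphery and reports per segment
$100 \cdot \text{sheet px} / \text{ER px}$ (the denominator is the ER
pixels *of that segment*). With `directions = "auto"` the segments sit at
120° spacing starting from the cell's long axis (second-moment principal
axis); the segment width stays in pixels, with the physical width derivable
from `pixel_size_nm`. `er_area_fraction()` is the ER share of the examined
cytoplasm mask.

## F-actin organization

Cyclic strain aligns stress fibers; the package quantifies this with the
structure tensor. After rotating the cell so its long axis is vertical
(`align_long_axis()`; masks with axis ratio < 1.05 are rejected as
isotropic), `orientation_field()` computes per pixel the dominant local
orientation from the Gaussian-smoothed tensor of image gradients
(pre-smoothing σ = 1 px, tensor σ = 2 px by default) and a coherence score
$(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2) \in [0,1]$. Angles follow the
axial convention **0° = vertical, 90° = horizontal**; the display map folds
to $[0°, 90°]$ via $\min(\varphi, 180° - \varphi)$, while circular
statistics use the unfolded axial angle in $[0°, 180°)$.

Fibers are orientations, not directions, so all statistics double the
angles first. With mean resultant length $R$ of the doubled angles,
`fiber_dispersion()` reports the angular deviation

$$s = \tfrac{1}{2}\sqrt{2(1-R)} \quad \text{(radians, axial scale)},$$

which is 0 for perfectly parallel fields and reaches its closed-form
maximum $\sqrt{2}/2$ rad ≈ 40.51° for a uniform axial distribution. (The
alternative $\sqrt{-2\log R}$ is unbounded as $R \to 0$ and therefore
unusable as a bounded dispersion score.) Weighting is by coherence by
default — pixels with no oriented texture contribute little — with
intensity weighting and unweighted variants available. The circular
variance $1 - R$ is returned alongside. `intensity_density()` is total
masked fluorescence divided by mask area, per pixel and per µm².

## Organelle interactions

- **Manders colocalization** (`manders()`): thresholded form; $M_1$ is the
  fraction of channel-1 signal over the thresholded channel-2 mask and
  conversely for $M_2$. Per-channel Otsu thresholds by default; `"zero"`
  reproduces the classic unthresholded coefficients.
- **ER-on-mitochondria mapping** (`er_on_mito_map()`): mitochondria are
  segmented by thresholding their own channel; ER intensity is normalized
  to its per-image maximum and averaged over the mitochondrial mask,
  giving a [0, 1] summary of how much ER decorates the mitochondria.
- **Contact-site extent** (`contact_extent()`): membranes arrive as
  digitized polylines in nm (densified to ≤ 1 nm spacing). The gap at each
  point of trace A is its minimum Euclidean distance to trace B; maximal
  runs with gap ≤ `max_gap_nm` (default 30 nm, the reciprocal-distance
  convention for ER–mitochondria and PM–ER contacts in sections) of arc
  length ≥ `min_run_nm` (default 10 nm, suppressing single-point grazes)
  become contact sites whose extent is the run's arc length. "Reciprocal"
  is enforced by requiring each contact point on A to lie within the cutoff
  of B's own contact region, which prevents one-sided overhangs from
  inflating extent; a one-sided mode exists for sensitivity checks. Runs
  separated by a super-cutoff gap are distinct sites.
- **Cortical ER classes** (`classify_cortical_er()`): lumen widths below
  `thin_cutoff_nm` (default 30 nm) are thin, at or above it wide (the
  boundary is wide by convention).
- **SPLICS puncta** (`count_splics_puncta()`): the split-GFP contact-site
  sensor produces discrete puncta in a z-stack; the stack is thresholded
  (global Otsu by default), components smaller than `min_voxels = 4` are
  removed, and the remainder counted under 26-connectivity (6-connectivity
  available). Labeling is an exact union-find pass; a blank stack counts 0.

## Assay normalizations

- `soce_normalized_max()`: store-operated calcium entry traces follow the
  re-addition protocol (5 min Ca²⁺-free wash, 30 min store depletion,
  re-addition; sampled every 5 s). $F_0$ is the mean over the final 60 s
  before re-addition (the paper-silent window is a package default); the
  statistic is $\max F_{\text{post}} / F_0$, with $\Delta F/F_0$ as an
  option and an optional 3-point running median for noisy traces. The raw
  global maximum is positively biased on noisy data (selection over ~120
  samples), which the median filter largely removes.
- `normalize_by_dna()`: elementwise division of OCR/ECAR/ATP readouts by
  per-sample DNA content.
- `xbp1_splicing_ratio()`: spliced over total XBP1, $s/(u+s)$, the ER-stress
  splicing readout (205 bp unspliced, 179 bp spliced products).

## The synthetic-data module

Every generator returns its fixture plus a `synthetic_truth` record (name,
full parameter set with units in the names, seed); regeneration with the
same parameters and seed is bit-for-bit identical, and all randomness flows
through one seeded generator (`withr::with_seed`) without touching the
caller's RNG. What each generator emulates, and deliberately does not:

- `gen_decay_histogram()`: photon arrivals from the exponential mixture
  with Poisson total counts, optional uniform background and Gaussian IRF
  jitter, truncated to the acquisition window (the discarded fraction is
  recorded). No pile-up, dead-time or afterpulsing effects.
- `gen_er_cell_image()`: an elliptical cell (~110 px semi-axis at
  100 nm/px), disk nucleus (30 px), ~60 radiating curvilinear tubules
  1–3 px wide, and compact sheet blobs added until the target sheet
  fraction (default 0.3) is realized — within ±0.05 by construction.
  Sheets sit near the nucleus by default (`"perinuclear"`, the usual
  biology) or spread radially uniformly (`"uniform"`, used by the
  sampling-bias tests). Intensities are three levels (20/100/220) plus
  additive Gaussian noise (σ = 10) — roughly 8σ between class means, the
  regime where Rényi segmentation should and does reach Dice ≥ 0.9. No
  point-spread-function simulation beyond optional blur, no photobleaching
  or shot noise.
- `gen_fiber_image()`: straight fibers with axial angles from a von Mises
  distribution on doubled angles (Best–Fisher sampler; κ = 0 is the uniform
  axial limit), rendered at 0° = vertical and lightly blurred (σ = 1 px) so
  gradients are smooth. No fiber curvature, crossing ambiguity or bundling.
- `gen_membrane_pair()`: a straight reference membrane and a partner offset
  by a constant, linear-ramp or sinusoidal gap profile, with the arc length
  where the gap ≤ cutoff computed in closed form (sinusoid crossings are
  enumerated analytically). For gently modulated profiles (slope ≪ 1) the
  pointwise profile gap equals the true inter-membrane distance to well
  under the 2 nm test tolerance; steep profiles would decouple the two.
- `gen_puncta_volume()`: spheres rejection-sampled with a minimum centre
  separation (default 4 radii); infeasible packings fail after a bounded
  number of attempts with an error naming the constraint.
- `gen_soce_trace()`: the three protocol phases on the 5 s grid with a
  double-exponential re-addition transient normalized so its sampled
  maximum equals `peak_F` exactly; depletion-phase store-release transients
  are not modeled.

Because the generators idealize real data (no optics, simple noise, known
masks), passing recovery tests demonstrates correctness of the estimators
and their implementations — not robustness to the full messiness of real
microscopy (out-of-focus light, bleaching, segmentation of irregular
nuclei), which the package does not claim.

## Pipeline, determinism and problem sizes

`run_config()` collects all stage parameters (defaulting to the conventions
above: 56 px segments, 30 nm gap cutoff, Otsu/26-connectivity/4-voxel
puncta, 5 s SOCE sampling) and validates them all at once;
`run_pipeline()` executes the stages over a seeded synthetic cohort (or
supplied TIFFs for the ER stage), writes `report.csv`/`report.json` with a
provenance block (package version, seed, config hash — the hash excludes
the output directory so relocated reruns stay byte-identical), and aborts
naming the failing cell on error.

Test and acceptance runs use deliberately modest problem sizes — 256²
images, 48³ stacks, 10⁵-photon decays, cohorts of 5 cells, 10–200 seeds
per Monte-Carlo check — chosen so the whole suite exercises every module
at meaningful statistical power while remaining quick on a laptop. The
statistical tolerances in the tests follow from these sizes (e.g. the
median recovered τ₁ over 200 decays at 10⁵ photons sits within 2% of
truth; the ±2·noise_sd SOCE band is asserted as ~95% coverage because the
baseline error is amplified by the peak ratio).

## Known limitations

- Lifetimes are reported as-is; no conversion to absolute tension is
  attempted (probe calibration is outside the package's scope).
- Sheet/tubule separation assumes sheets image brighter or thicker;
  labelings that invert this need the thickness strategy with a suitable
  cutoff.
- Contact extent is a planar arc length, as in sectioned electron
  micrographs; no 3D surface-contact area is estimated.
- Per-pixel lifetime fits at low photon counts carry finite-count bias
  (~2% at 5 × 10⁴ photons with a free background); pooled-ROI fits are
  preferable when spatial resolution is not needed.
- The orientation estimator is pixel-based; it does not trace individual
  filaments.
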