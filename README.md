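# ermechquant

Quantification of ER mechanics, morphology and organelle contacts from
fluorescence microscopy.

Mechanical strain raises membrane tension in the plasma membrane and the
endoplasmic reticulum (ER), flattens ER tubules into sheets, aligns the
actin cytoskeleton, and remodels the ER's contacts with mitochondria and
the plasma membrane. Measuring any of this from microscopy requires a chain
of small, well-defined computations: fitting photon-decay histograms from
mechanosensitive lifetime probes, auto-thresholding and classifying ER
structures, measuring fiber orientation, gating membrane-to-membrane
distances, counting sensor puncta, and normalizing assay traces.
ermechquant implements that chain as a tested R package for cell biologists
and image analysts, together with a synthetic-data module that generates
every input modality with known ground truth so each stage is verifiable
end to end.

## What it computes

| Readout | Function(s) | Core quantity |
|---|---|---|
| Membrane tension (FLIM/TCSPC) | `fit_biexponential()`, `report_tension_lifetime()`, `fit_lifetime_map()` | longer lifetime τ₁ of `A₁e^{−t/τ₁} + A₂e^{−t/τ₂} + b` (Poisson MLE), per ROI or per pixel |
| ER morphometry | `to_8bit()`, `renyi_threshold()`, `segment_er()`, `sample_line_segments()`, `er_area_fraction()` | Rényi-entropy sheet/tubule labels; sheet % per 56-px radial segment; ER / cytoplasm area |
| F-actin organization | `align_long_axis()`, `orientation_field()`, `fiber_dispersion()`, `intensity_density()` | structure-tensor axial angles (0° = vertical), circular dispersion, intensity density |
| Organelle interactions | `manders()`, `er_on_mito_map()`, `contact_extent()`, `classify_cortical_er()`, `count_splics_puncta()` | thresholded Manders M1/M2; contact-site extent at a 30 nm reciprocal gap; thin/wide cortical ER; 3D puncta counts |
| Assays | `soce_normalized_max()`, `normalize_by_dna()`, `xbp1_splicing_ratio()` | SOCE max F/F₀; per-DNA normalization; s/(u+s) splicing ratio |
| Synthetic truth | `gen_decay_histogram()`, `gen_er_cell_image()`, `gen_fiber_image()`, `gen_membrane_pair()`, `gen_puncta_volume()`, `gen_soce_trace()` | every fixture with a `synthetic_truth` oracle |
| Batch runs | `run_config()`, `run_pipeline()` | deterministic per-cell report (CSV + JSON with provenance) |

Results come back as tibbles (or S3 objects with `tidy()`, `glance()` and
`autoplot()` methods), so they compose with dplyr/ggplot2 workflows.

## Worked example

```r
library(ermechquant)

# --- membrane tension from a simulated TCSPC decay -----------------------
g <- gen_decay_histogram(tau1_ns = 6, tau2_ns = 2, frac1 = 0.85,
                         n_photons = 1e5, seed = 42)
fit <- fit_biexponential(g$hist)
fit
#> <biexp_fit> tau1 = 5.983 ns, tau2 = 2.057 ns (poisson_mle)
#>   amplitudes 706.2 / 385.9, background 8.085e-05, reduced chi2 0.9764
#>   converged: TRUE; flag: ok
report_tension_lifetime(fit)
#> # A tibble: 1 × 2
#>   tau_report_ns flag
#>           <dbl> <chr>
#> 1          5.98 ok

# --- ER sheet/tubule morphometry on a synthetic cell ---------------------
cell <- gen_er_cell_image(seed = 42)     # truth sheet fraction ~0.30
seg <- segment_er(cell$image)
seg
#> <er_segmentation> 256 x 256 px; thresholds ER > 50, sheet > 113 (double_renyi)
#>   background 54123 px, tubule 7365 px, sheet 4048 px
sample_line_segments(seg, cell$image$masks$nucleus, cell$image$masks$cell)
#> # A tibble: 3 × 6
#>   segment_index angle_deg width_px sheet_pixels er_pixels sheet_percentage
#>           <int>     <dbl>    <dbl>        <int>     <int>            <dbl>
#> 1             1         0       56          560      1444             38.8
#> 2             2       120       56          759      1794             42.3
#> 3             3       240       56          965      1723             56.0
er_area_fraction(seg, cell$image$masks$cytoplasm)
#> [1] 0.2749731

# --- ER-mitochondria contact extent from membrane traces -----------------
pair <- gen_membrane_pair(span_nm = 500,
                          profile = list(name = "constant", gap_nm = 20))
contact_extent(pair$trace_a, pair$trace_b, max_gap_nm = 30)
#> # A tibble: 1 × 8
#>   site_id partner_a partner_b     start_nm end_nm extent_nm mean_gap_nm ...
#> 1       1 ER        mitochondrion        0    500       500          20
```

The fitted lifetimes recover the simulated 6 ns / 2 ns pair; the reported
tension statistic is the longer lifetime with its amplitude-order flag. The
three radial segments report the percentage of ER pixels that are sheet
(here elevated relative to the whole-cell 30% because sheets concentrate
near the nucleus, where the segments start), and the two parallel membranes
20 nm apart register one contact site covering their full 500 nm span at
the 30 nm reciprocal-distance cutoff.

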