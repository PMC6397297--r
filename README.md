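# fibreDRC

Single-cell quantification of how a fluorescently tagged probe reshapes
the actin cytoskeleton, and dose-response analysis of those changes
against the probe's expression level.

Live-cell actin probes (GFP-tagged actin-binding peptides delivered by
viral transduction) reach wildly different levels in different cells —
vector copy number spans several decades — and at high doses the probe
perturbs the cytoskeleton it is meant to report. fibreDRC is built for
experiments that exploit that spread: every cell becomes one point on a
dose-response curve, with its total background-subtracted GFP intensity

```
total_gfp = sum over cell pixels of max(I - background, 0)
```

as the expression surrogate, and stress-fibre morphometrics measured
from the same field of view.

## What it computes

**Morphometrics** (`segment_cell`, `segment_fibres`,
`compute_descriptors`, `quantify_cell`): cell and nucleus segmentation;
a three-step fibre pipeline (multi-scale Hessian ridge filter →
half-maximum refinement and skeleton-length pruning → background
estimation by grayscale opening and subtraction) yielding per-pixel
fibre masks, brightness and structure-tensor orientation; per-cell
spread area, aspect ratio, stellate factor, fibre amount, fibre
thickness and length, orientation coherence, radiality, and nucleus
size/shape.

**Dose-response regimes** (`build_drc`, `rov_series`,
`detect_thresholds`, `global_thresholds`, `assign_regimes`): cells are
pooled into equal-count expression bins (geometric mean / mean /
median with matching dispersion); along the binned curve the ratio of
variances

```
RoV_i = var(d[i+1..i+N]) / var(d[i-N..i-1])
```

spikes where the curve enters a region of raised variability. Its
significant extrema mark the transitions between the three regimes —
no effect, dose-response, saturation — and candidates pooled across
descriptors (geometric mean) give two global expression thresholds G1
< G2 used to sort cells.

**Time-lapse dynamics** (`track_centroids`, `total_distance`,
`directionality`, `interframe_change`, `disassembly`): migration
directionality `MD = |P_T - P_0| / sum_i |P_{i+1} - P_i|`, F-actin
interframe change `IFC_i = 100 (FA_{i+1} - FA_i) / FA_i`, and
drug-induced disassembly `100 (FA(0) - FA(30 min)) / FA(0)`.

**Nucleus-referenced statistics** (`build_annulus`, `nuc_cyto_ratio`,
`fibre_colocalized_intensity`, `nucleus_descriptors`): the
nuclear-to-cytosolic stain ratio over an equal-area adjacent annulus,
and the mean stain intensity colocalized to fibre pixels.

**Synthetic data** (`population_config`, `generate_population`,
`simulate_cell`, `generate_tracks`, `generate_decay_series`,
`simulate_protein_stain`): a seeded generator of ground-truth-annotated
multi-channel images (lognormal expression, piecewise
flat/log-linear/flat transfer functions, star-convex cells,
constant-width anti-aliased fibre capsules with von Mises orientations,
realistic noise), persistent-random-walk tracks, and exponential decay
series — so every stage of the analysis is testable without microscopy
data. See the vignette (`vignettes/fibre-dose-response.Rmd`) for the
model and its limits.

## Worked example

```r
library(fibreDRC)

# a synthetic population whose morphometrics respond to expression
# between 1e5 and 1e6 GFP counts
cfg <- population_config(n_cells = 300, gfp_log_mean = 5, gfp_log_sd = 1.2,
                         transfer = default_transfer_set(1e5, 1e6),
                         seed = 42)
records <- NULL
invisible(generate_population(cfg, sink = function(cs, i)
  records <<- rbind(records, quantify_cell(cs))))

curve <- build_drc(records, "area", n_min = 10, pooling = "gmean")
detect_thresholds(rov_series(curve), curve)
#>   index expression   log_rov  type
#> 1    16   104876.8  4.709915 lower
#> 2    24   723154.0 -4.862891 upper
```

The detector recovers the generating breakpoints (1e5 and 1e6) from
the measured curve: the positive RoV extremum marks the onset of the
dose-response regime (variance rises ahead of bin 16, at 1.05e5
counts, 0.02 decades from truth), the negative one the entry into
saturation (variance settles past bin 24, at 7.2e5 counts, 0.14
decades from truth). Labelling cells at these thresholds:

```r
thr <- global_thresholds(detect_thresholds(rov_series(curve), curve))
table(assign_regimes(records, thr["G1"], thr["G2"])$regime)
#>     no_effect dose_response    saturation
#>           155            82            63
```

Formula-level metrics work directly on tables:

```r
directionality(data.frame(x = c(0, 3, 3), y = c(0, 0, 4)))   # 5/7
fa <- generate_decay_series(100, rate = log(4) / 30)          # LatA-style
disassembly(fa)                                               # 75
```

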