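# ttfplan

Simulation and comparison of Tumor Treating Fields (TTFields) transducer
array montages for posterior fossa tumors, on voxelized head phantoms.

TTFields are ~200 kHz alternating electric fields applied to the scalp
through two orthogonal pairs of 3×3 transducer-disc arrays. Their
antimitotic effect grows with local field intensity, so *where the arrays
sit* is a treatment-planning decision. The standard montage targets the
supratentorial brain; for a cerebellar tumor it leaves every array far
from the target. `ttfplan` quantifies what is gained by the
posterior-fossa alternatives — dropping the posteroanterior (PA) array to
the lower occiput/upper neck (horizontal, laterally shifted ±2 cm, or
vertical at two heights), pulling the lateral arrays backward, and
rotating the anterior array.

The package provides, end to end:

* **phantom** — synthetic voxel head phantoms (nested scalp/skull/CSF/brain
  ellipsoids, cerebellum, brainstem, neck, a dorsal midline cerebellar
  tumor with necrotic core), label→conductivity mapping, and NIfTI I/O for
  real label volumes;
* **layout** — the seven named montages realized as scalp-conforming
  electrode patches by ray casting;
* **solver** — the quasi-static volume-conductor problem
  ∇·(σ∇φ) = 0 per channel, discretized by voxel finite volumes with
  harmonic-mean face conductances and solved by preconditioned conjugate
  gradients; fields are current-normalized (default 0.9 A per channel);
* **metrics** — electric-field and current-density volume histograms
  (EVH/CDVH) and the derived plan-quality metrics: the histogram area
  `E_AUC`/`CD_AUC` (equal to the ROI mean by the layer-cake identity),
  percentile intensities `E_75%`, `E_50%` (median), `E_5%` (hotspot), and
  volumes at fixed thresholds `V_E75/50/25`, `V_CD15/10/5`;
* **report** — percent changes vs the baseline montage, means over the
  alternatives, rankings, and calibrated anatomy/field overlay PNGs.

## Worked example

Aggregation arithmetic on the bundled worked-example PQM table
(`reference_pqm()`, seven montages × GTV/cerebellum):

```r
library(ttfplan)
rep <- build_report(reference_pqm(), baseline = "SUPRATENTORIAL")
print(rep)
#> comparison_report (baseline SUPRATENTORIAL)
#>   GTV: best e_auc montage PA_HORIZONTAL
#>   CEREBELLUM: best e_auc montage PA_HORIZONTAL
#>   mean over alternatives:
#>         roi     configuration e_auc v_e75 v_e50 v_e25 e_75 e_50   e_5 cd_auc
#>         GTV MEAN_ALTERNATIVES  39.1   7.4  26.6  72.3 23.4 38.1  86.2     11
#>  CEREBELLUM MEAN_ALTERNATIVES  60.8  31.7  55.5  78.4 31.1 55.6 137.1     10
#>  ...
```

The six posterior-fossa montages average a cerebellar `E_AUC` of
60.8 V/m against the supratentorial baseline's 20.5 V/m, a GTV hotspot
intensity `E_5%` of 86.2 V/m against 44.1 V/m, and the PA-horizontal
montage ranks first for both ROIs.

A physics run from scratch — build a phantom, place montages, solve both
channels, summarize the GTV:

```r
res <- run_pipeline(run_config(phantom = mini_phantom_spec(),
                               configurations = c("SUPRATENTORIAL",
                                                  "PA_HORIZONTAL")))
sapply(res$runs, function(r) round(r$gtv_mean_E, 1))
#> SUPRATENTORIAL  PA_HORIZONTAL
#>          123.0          135.1
```

i.e. moving the PA array down to the occiput raises the tumor's mean
field even on this small test phantom; on the default 4 mm phantom every
one of the six alternatives beats the baseline (the study's headline
comparison). Absolute magnitudes depend on the configured drive current
and grid spacing — see the methods vignette
(`vignettes/montage-planning.Rmd`) for the convergence analysis and all
modelling assumptions.

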