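# contourvar

Inter-observer contour variability, dosimetry and radiobiological
prognosis for radiotherapy structure sets.

When several physicians delineate the same tumour target and organs at
risk (OARs) on the same planning images, their contours disagree. Because
an IMRT plan conforms dose tightly to the target it was built on, these
disagreements propagate into under-coverage of the reference anatomy and
extra dose to normal tissue. `contourvar` implements the full analysis
chain for quantifying that propagation, for medical-physics and
radiation-oncology researchers studying delineation quality:

* **Geometric variability** on voxelized masks: signed volume difference
  ΔV = V_M − V_S, max-to-min volume ratio MMR, coefficient of variation
  CV, Dice similarity coefficient DSC = 2|A∩B|/(|A|+|B|), symmetric
  95th-percentile Hausdorff distance HD95 (exact anisotropic Euclidean
  distance transforms), and a STAPLE consensus (EM estimation of a hidden
  true segmentation plus per-observer sensitivity/specificity).
* **Dosimetric mapping** of each observer's dose grid onto the
  gold-standard structures: cumulative DVHs, prescription dose coverage
  PDC = 100 · |{v ∈ PTV : D(v) ≥ rx}| / |PTV|, Dmax/Dmean/D1cc summaries
  by serial/parallel organ class, and relative differences
  ΔD_diff = 100 · (D_M − D_S)/D_S against the standard plan.
* **Radiobiological endpoints**: equivalent uniform dose
  EUD = (Σ v_i d_i^a)^{1/a} (cold-spot-sensitive a = −8 for targets),
  logistic tumour control probability
  TCP = 1/(1 + (TCD50/EUD)^{4γ50}) with TCD50 = 61.69 Gy, γ50 = 3.38,
  and a modified linear-quadratic
  NTCP = exp[−N0 · V^{−k} · exp(−α·D·Γ)], Γ = 1 + d_f/(α/β).
* **Predictor selection**: Spearman correlations of geometric metrics
  against ΔPDC and ΔTCP pooled over all (patient, observer) pairs; a
  metric is designated a delineation-risk predictor when p < 0.05 and
  |r| > 0.4.
* **A synthetic cohort generator** (phantom anatomy, biased/noisy
  simulated observers, conformal dose surrogates) so the whole pipeline
  is testable and demonstrable without clinical data.

## Worked example

Four simulated observers with systematic biases from −4 mm
(under-contouring) to +3 mm (over-contouring) delineate four phantom
patients; each observer's plan is conformal to their own expanded target
and is then evaluated on the gold standard:

```r
library(contourvar)

observers <- list(observer_model("A", volume_bias_mm = -4),
                  observer_model("B", volume_bias_mm = -2),
                  observer_model("C", volume_bias_mm =  1),
                  observer_model("D", volume_bias_mm =  3))

res <- run_study(4, observers, dose_model(penumbra_sigma_mm = 3),
                 seed = 7, grid = voxel_grid(c(64, 64, 48), c(2, 2, 5)))

res$correlations
#>           x_name          y_name  n      r        p selected
#> 1   dV_cc(GTVnx) dPDC_pct(PTVnx) 16  0.962 2.90e-09     TRUE
#> 2   dV_cc(GTVnx)     dTCP(PTVnx) 16  0.947 2.72e-08     TRUE
#> 3     DSC(GTVnx) dPDC_pct(PTVnx) 16  0.488 5.50e-02    FALSE
#> 4     DSC(GTVnx)     dTCP(PTVnx) 16  0.482 5.85e-02    FALSE
#> 5 HD95_mm(GTVnx) dPDC_pct(PTVnx) 16 -0.314 2.36e-01    FALSE
#> 6 HD95_mm(GTVnx)     dTCP(PTVnx) 16 -0.293 2.70e-01    FALSE
```

The signed volume difference of the target — not Dice, not HD95 — passes
the predictor gate for both coverage loss (ΔPDC) and control loss (ΔTCP).
The per-observer summary shows why:

```r
subset(cohort_report(res),
       metric_name %in% c("dV_cc", "dPDC_pct", "dTCP") &
         observer_id %in% c("A", "D"))
#>     structure_label metric_name observer_id    mean       sd n
#>               GTVnx       dV_cc           A -14.540 1.40e+00 4
#>               GTVnx       dV_cc           D  15.485 2.69e+00 4
#>               PTVnx    dPDC_pct           A -43.528 4.32e+00 4
#>               PTVnx    dPDC_pct           D  -0.178 1.69e-01 4
#>               PTVnx        dTCP           A -84.665 3.20e-08 4
#>               PTVnx        dTCP           D  -0.356 4.98e-01 4
```

Observer A under-contours by ~14.5 cc, leaving the standard target 43.5
percentage points short of prescription coverage and collapsing TCP;
observer D over-contours by a similar volume and loses essentially
nothing — over-coverage spills dose outward but keeps the standard target
covered. (Synthetic effect sizes are deliberately larger than clinical
ones; see the methods vignette.)

Single-metric calls work on plain objects:

```r
g   <- voxel_grid(c(20, 20, 20), c(1, 1, 2.5))
ptv <- structure_mask(array(TRUE, g$shape), g, "PTVnx")
d   <- dose_grid(array(61.69, g$shape), g)
e   <- eud(compute_dvh(d, ptv)$voxel_doses_gy, a_exponent = -8)
tcp(e)   # 0.5: a uniform dose at TCD50 gives 50% control by construction
```

Masks and dose grids read/write NIfTI (`read_mask`, `write_dose`, ...);
`generate_cohort(..., dir = ...)` writes a full cohort bundle plus a JSON
manifest of every derived seed, and `write_results()` exports the metric,
correlation and predictor tables as CSV.

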