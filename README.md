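# mwiseg — tissue-type segmentation and quality metrics for microwave breast images

Microwave tomography reconstructs the complex permittivity
ε(**r**) of the breast from scattered electromagnetic fields. Because
skin, adipose (fatty), transition, fibroglandular and malignant tissues
occupy ordered ranges of dielectric properties, a reconstructed
permittivity image can be partitioned into tissue types — but the inverse
problem is severely ill-posed, so the images carry blurred interfaces,
heterogeneous tissue values and peripheral artefacts, and the mapping from
reconstructed values to true tissue properties shifts from algorithm to
algorithm. Fixed-threshold segmentation is therefore unreliable, and its
threshold choice trades sensitivity against specificity.

`mwiseg` is for researchers evaluating image-reconstruction algorithms. It
provides:

* **an unsupervised segmentation** that needs no assumed property values
  and no pre-selected cluster count: k-means clustering (k-means++
  seeding, Lloyd refinement, multiple restarts) applied iteratively with
  k = 3, 4, …, where the highest-valued cluster is the running tumor
  estimate T̂ and the rest of the region of interest its complement T̂ᶜ.
  Two two-sample Kolmogorov–Smirnov tests compare the value samples over
  T̂ and T̂ᶜ with the previous iteration's; the refinement stops at
  significance α = 0.01 once neither rejects. Final clusters map to
  tissues by rank: c₁ background, c₂ fatty, c₃–c₄ transition,
  c₅…c₍max k₋1₎ fibroglandular, c₍max k₎ malignant.
* **six quality metrics** comparing reference and reconstructed masks:
  Fidelity (normalized mask cross-correlation), xcorrDiel (the same on
  masked dielectric values), Dice, ratio of tumor detected (RD), artefact
  rejection (AR, negative when false positives exceed the reference
  area), and the average Hausdorff distance H_A between centroid-aligned
  interface contours, with per-tumor component matching.
* **a threshold-based baseline** (mask = elements ≥ p% of the interior
  maximum) whose sweep demonstrates the sensitivity/specificity
  trade-off.
* **a synthetic phantom generator** with controllable degradations (blur,
  noise, bias, peripheral artefacts), so the whole framework runs and is
  validated without an inversion solver.

## Worked example

Generate a ground-truth phantom, emulate a mid-quality reconstruction,
segment both, and score the reconstruction against the reference:

```r
library(mwiseg)

truth <- generate_phantom(phantom_spec(seed = 7))
recon <- degrade(truth, degradation_spec(blur_sigma_mm = 1, noise_sd = 0.5,
                                         artefact_count = 2, seed = 1007))

ref_fit <- mwiseg(truth$image, domain = truth$domain_mask, seed = 7)
rec_fit <- mwiseg(recon,      domain = truth$domain_mask, seed = 7)
rec_fit
#> Unsupervised tissue segmentation of a microwave breast image
#> Call: mwiseg(image = recon, domain = truth$domain_mask, seed = 7)
#>   real       final k = 7 after 4 refinement iteration(s)
#>   imaginary  final k = 8 after 5 refinement iteration(s)
#>   magnitude  final k = 7 after 4 refinement iteration(s)
```

The fitted object carries the refinement history — per-iteration cluster
count, tumor/complement sample sizes, and both KS tests. Refinement stops
the first time neither test rejects (here at k = 7, where the tumor-sample
test reaches p = 0.98):

```r
as.data.frame(rec_fit$components$real$history)
#>   k n_tumor n_comp ks_tumor_D ks_tumor_p  ks_comp_D ks_comp_p
#> 1 3    3084   2261         NA         NA         NA        NA
#> 2 4    1664   3681 0.46044099  0.0000000 0.38576474         0
#> 3 5    1222   4123 0.26562500  0.0000000 0.10720349         0
#> 4 6     106   5239 0.91325696  0.0000000 0.21301775         0
#> 5 7      99   5246 0.06603774  0.9788825 0.00133435         1
```

Scoring the reconstructed segmentation against the reference yields the
per-region metric rows (real component shown):

```r
report <- evaluate_report(ref_fit, rec_fit)
report[report$component == "real", ]
#>     region component fidelity xcorr_diel  dice    rd    ar hausdorff_mm
#>  glandular      real    0.857      0.908 0.848 0.743 0.992         4.39
#>    tumor_1      real    0.726      0.732 0.722 0.802 0.580        16.16
```

Read: the glandular structure is reconstructed with good geometric and
dielectric agreement (Fidelity 0.86, xcorrDiel 0.91). The tumor is largely
detected (RD 0.80: 80% of the true tumor area lies inside the
reconstructed malignant mask) but at a specificity cost (AR 0.58: false
positives amounting to 42% of the tumor area), and the inflated average
Hausdorff distance (16 mm) flags that the reconstructed malignant mask
includes a residual peripheral artefact far from the tumor. `plot(rec_fit)`
shows the tissue map; `write_report_json()` and `write_contours_csv()`
export results.

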