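# nestseg

Tumor-nest/stroma tissue segmentation and region-stratified immune
cytometry for multiplex immunohistochemistry (mIHC), with the survival
statistics used to test prognostic value of compartment-specific immune
cell densities.

## What it does, and for whom

Intratumoral tissue is a mosaic of **tumor cell nests** (contiguous
neoplastic clusters) and the **intratumoral stroma** between them.
Immune infiltrates — helper T cells, CD8 T cells, TREG, B cells,
granulocytes, tumor-associated macrophages (TAM) — distribute unevenly
across these compartments, and their compartment-specific densities
(e.g. PD-1+ helper T cells inside nests) can carry prognostic
information that whole-region averages hide. `nestseg` is for
computational pathology / tumor-immunology analysts who have
coregistered single-marker grayscale images (signal-high after
inversion) and want a reproducible, fully tested chain from pixels to
hazard ratios:

- **Segmentation** — tissue/blank classification, nest extraction by
  **Huang fuzzy minimum-fuzziness thresholding** of the tumor-marker
  channel inside the ROI, morphological cleaning
  (closing → fill holes → opening → small-object removal), stroma as
  the exact set difference `ROI \ nest`.
- **Image cytometry** — nucleus detection (Otsu + distance-transform
  watershed), per-cell mean marker intensities, hierarchical
  first-match-wins gating (CD45/CD3/CD8/Foxp3/Tbet/GATA3/... or the
  CD4-based validation panel), PD-1 flagged orthogonally, region
  assignment by centroid.
- **Region metrics** — densities in cells/mm², percent of CD45+ cells,
  TH1/TH2 ratios, polarization classes (nest-polarized > 2.0,
  stroma-polarized < 0.5, balanced otherwise).
- **Cohort statistics** — Kaplan–Meier, log-rank, Cox proportional
  hazards (Efron ties, Wald CIs), Spearman matrices, Wilcoxon
  signed-rank / Kruskal–Wallis, and high/low stratification by mean,
  median, fixed (e.g. 43.1 cells/mm²) or ROC-Youden cutoffs.
- **Synthetic data** — slide and cohort generators with known ground
  truth (nest masks, cell lineages, true hazard ratios) so the entire
  chain is verifiable offline.

The core selector minimizes the Huang–Wang fuzziness
E(t) = Σ_g h(g)·S(μ_t(g)) with μ_t(g) = 1/(1 + |g − m(g,t)|/C), where
m(g,t) is the mean of the class containing g, C the dynamic range and
S the binary entropy; the smallest minimizing t wins and pixels > t are
foreground.

## Worked example

```r
library(nestseg)

# one synthetic slide with known ground truth
spec <- image_sim_spec(seed = 11)
sim  <- generate_image_stack(spec)
seg  <- segment_slide(sim$stack)
seg
#> segmentation_result: roi 6.545 mm2 = nest 0.627 + stroma 5.918; nest threshold 93

cells <- detect_cells(gray_image(sim$stack$channels$hematoxylin, 4), seg$roi)
tab   <- assign_region(classify_cells(quantify_markers(cells, sim$stack),
                                      gating_config("discovery")), seg)
st    <- compute_region_stats(tab, seg)
st$by_lineage[st$by_lineage$lineage %in% c("th1", "th2", "cd8_t"), ]
#>  region lineage count density pct_of_cd45
#>    nest   cd8_t    23   36.67       22.12
#>    nest     th1    19   30.29       18.27
#>    nest     th2     2    3.19        1.92
#>  stroma   cd8_t   256   43.26       17.22
#>  stroma     th1    97   16.39        6.52
#>  stroma     th2   145   24.50        9.75

th1_th2_ratio(st, "nest")$ratio    # 9.5: TH1-skewed inside nests
```

The per-region table reads directly against the generator's truth: the
nest is TH1-skewed (TH1/TH2 ratio 9.5 from densities 30.3 vs 3.2
cells/mm²) while the stroma is TH2-leaning, and CD8 T cell densities are
similar in both compartments — the configured study conditions.

Survival side, on a simulated 51-patient cohort with a true hazard
ratio of 3 for high nest density of PD-1+ helper T cells:

```r
coh <- generate_cohort(cohort_sim_spec(n_patients = 51,
                                       log_hazard_beta = log(3), seed = 11))
d   <- dichotomize(coh$pd1_helper_nest, cutoff_rule("mean"))
logrank_test(coh$time_months, coh$event, d$high)
#> cutoff 43.5 cells/mm2; chi-square 24.31, p < 1e-4
coh$group_high <- d$high
cox_fit(coh, c("group_high", "hpv_negative", "male",
               "smoking_history", "stage_3_4"))
#>        covariate    hr ci_low ci_high        p
#>       group_high 7.700  3.085   19.22 1.22e-05
#>     hpv_negative 1.341  0.593    3.03 4.80e-01
#>     ...
```

The density covariate is flagged strongly while the non-informative
clinical covariates are not; at n = 51 the point estimate of a true
HR = 3 is noisy (here 7.7, CI 3.1–19.2), which is why calibration is
checked at n = 2000 (see below).

A full run (simulate → segment → quantify → gate → region stats →
survival analysis → Markdown report with KM panels and composition
figures) is one call:

```r
cfg <- run_config(out_dir = "run1", seed = 1,
                  image_sim = image_sim_spec(), n_specimens = 3,
                  cohort_sim = cohort_sim_spec(n_patients = 51),
                  cutoff_rules = list(mean  = cutoff_rule("mean"),
                                      fixed = cutoff_rule("fixed", 43.1)))
manifest <- run_pipeline(cfg)   # every artifact + parameters in manifest.json
make_report("run1")             # run1/report.md + figure PNGs
```

or from a shell via the thin CLI:
`Rscript inst/cli/nestseg.R run --seed 1 --out run1 --n-specimens 3 --cohort 51`.

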