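# plaquefusion

Quantitative analysis of carotid atherosclerotic plaque composition and its
relation to plaque inflammation, for researchers working with combined
quantitative MRI (qMRI) and ^18^F-FDG PET imaging of the vessel wall.

Two high-risk features of carotid plaque — the lipid-rich necrotic core and
intraplaque hemorrhage — can be mapped voxel-by-voxel with a 4-point Dixon
acquisition: the **fat fraction** FF = F/(W+F) is a proxy for lipid-rich
necrotic core, and the effective transverse relaxation rate **R2\*** (s⁻¹)
is elevated by iron from hemorrhage. Plaque inflammation is measured on PET
as the **standardized uptake value** (SUV) and the **target-to-blood-pool
ratio** TBR = plaque SUV_mean / venous blood-pool SUV_mean. This package
implements the full analysis chain connecting the two, together with a
ground-truth digital phantom so that every stage is testable without any
patient data.

## The models

**Dixon signal model.** The magnitude signal of a voxel with water signal
*W*, fat signal *F* and relaxation rate *R2\** at echo time *T*<sub>e</sub>
(ms) is

S(T_e) = | (W + F·cos(2π·T_e / 2.4)) · exp(−R2*·T_e) |

with the water–fat chemical-shift period of 2.4 ms and *T*<sub>e</sub>
converted to seconds in the decay term. Echoes at 3.6, 7.2, 10.8 and
14.4 ms form an out-of-phase / in-phase / out-of-phase / in-phase scheme.
`fit_voxel()` / `fit_volume()` invert this model per voxel (closed-form
initialization, then bounded nonlinear least squares) into W, F, FF and R2*
maps under the water-dominant convention (FF ≤ 0.5).

**SUV and TBR.** SUV = activity [kBq/mL] / (injected dose [MBq] / body
weight [kg]), under the 1 g/mL tissue-density convention. Whole-plaque
SUV_mean is the mean of the per-slice ROI means (slices first, then the
plaque); the blood pool is the mean SUV at six venous sample points; TBR is
the ratio of the two.

**Registration.** Manual plaque masks are carried between scanner sessions
by a nonreflective similarity transform (translation, rotation, isotropic
scale) found by maximizing Mattes-style mutual information with a (1+1)
evolutionary optimizer; the two T1-weighted sessions are aligned slice-wise
using the carotid bifurcation as a landmark.

**Statistics.** Per-slice and whole-plaque FF/R2* means are correlated with
TBR using the Pearson coefficient with two-sided t-based p-values (and a
permutation cross-check), simple linear regression and mean ± SD group
summaries.

## Worked example

```r
library(plaquefusion)

# a ground-truth plaque phantom and one full subject analysis
ph  <- make_phantom(phantom_config(), seed = 1)
res <- analyze_subject(ph, subject = "P1", seed = 5)
res$summary
#> # A tibble: 1 x 8
#>   subject n_slices ff_mean r2star_mean suv_mean_plaque suv_max_plaque suv_mean_blood   tbr
#>   <chr>      <int>   <dbl>       <dbl>           <dbl>          <dbl>          <dbl> <dbl>
#> 1 P1            14   0.171        54.6            1.31           1.67          0.994  1.32
```

The subject's plaque spans 14 Dixon slices; its whole-plaque mean fat
fraction (0.171) sits between the wall baseline (0.05) and the lipid-core
level (0.40) because the core occupies part of the mask, and the mean R2*
(54.6 s⁻¹) is pulled above the plaque baseline (45 s⁻¹) by the hemorrhagic
region (90 s⁻¹). The PET side reports a plaque SUV_mean of 1.31 against a
blood pool of 0.99, giving TBR = 1.32 — in the range typical of stable,
statin-treated carotid disease. (The blood pool reads below its true SUV of
1.3 because the 3 mm PET point spread dilutes the 4 mm vein — the
partial-volume effect the method reports rather than corrects.)

```r
# a 12-subject synthetic cohort with uptake independent of composition
coh <- simulate_cohort(12, seed = 41)
correlate_group(coh$summary)
#> # A tibble: 2 x 8
#>   measure           r r_squared statistic p_value     n    slope intercept
#>   <chr>         <dbl>     <dbl>     <dbl>   <dbl> <int>    <dbl>     <dbl>
#> 1 ff_mean     -0.464    0.215      -1.66    0.129    12 -3.71         1.73
#> 2 r2star_mean -0.0637   0.00406    -0.202   0.844    12 -0.00453      1.44
```

Because plaque tracer uptake is drawn independently of composition, the
group-level correlations stay inside the n = 12 null band (|r| < 0.576 at
the 5% level) — the pipeline does not manufacture a composition–inflammation
association that is not in the data.

A reference table of measured uptake values from a 12-patient pilot cohort
ships with the package (`fdg_uptake_cohort()`) for desk-checking the TBR
arithmetic and group statistics.

## Package layout

| Area | Functions |
| --- | --- |
| Phantom | `phantom_config()`, `make_phantom()`, `render_dixon()`, `render_t1w()`, `render_pet()` |
| Dixon inversion | `forward_signal()`, `fit_voxel()`, `fit_volume()` |
| Registration | `mattes_mi()`, `register_similarity()`, `apply_to_mask()`, `align_slices()`, transforms |
| ROI sampling | `neighborhood_average()`, `slice_means()`, `whole_mask_mean()`, `roi_table()` |
| PET quantification | `suv_map()`, `plaque_suv()`, `blood_pool_suv()`, `tbr()` |
| Statistics | `pearson()`, `permutation_pvalue()`, `group_summary()`, `slice_profiles()`, `correlate_group()` |
| Pipeline | `analyze_subject()`, `simulate_cohort()` |
| I/O | NIfTI volumes + JSON sidecars: `read_volume()`, `write_dixon_series()`, `read_pet_study()`, ... |

The methods vignette (`vignettes/plaque-composition-and-inflammation.Rmd`)
documents the models, the phantom's design choices and the package's
numerical decisions in detail.
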