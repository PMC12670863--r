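# cmrqa — multilevel reader comparison for cardiovascular MR contours

Readers of cardiovascular MR images — human experts, AI segmentation
models, trainees — disagree on contours, and those disagreements propagate
into the clinical parameters that drive decisions. `cmrqa` compares two
readers' contour annotations on three linked levels:

1. **Segmentation metrics** per slice: Dice similarity
   `2|A∩B|/(|A|+|B|)` on exact polygon intersection areas, boundary
   Hausdorff distance in mm, and the milliliter impact
   `|A₁−A₂|·D/1000` of each area difference (`D` = slice thickness + gap).
2. **Clinical parameters** per case: Simpson slice-summation ventricular
   volumes (ESV, EDV), stroke volume `SV = EDV − ESV` and ejection
   fraction `EF = 100·SV/EDV`, myocardial and papillary mass
   (ring volume × 1.05 g/ml), scar mass/fraction on LGE, global and
   6-segment T1/T2 mapping values, and monoplane area–length atrial
   volumes `V = 8A²/(3πL)`.
3. **Study statistics**: per-parameter bias with the 95% CI
   `mean ± 1.96·SD/√n`, judged **acceptable** iff the CI lies entirely
   within a tolerance range `±hw` derived from intrareader variability
   (`hw = 1.96·SD` of an expert's repeat-annotation differences, or a
   Howe k-factor tolerance interval); per-case **outliers** are
   differences exceeding `hw`.

Its distinguishing feature is **error tracing**: any volume or mass
difference decomposes exactly into signed per-slice contour
contributions, so a flagged case points straight at the causal slice.
Segmentation quality is additionally aggregated by cardiac position
(basal / midventricular / apical, relative to a reference reader) under
two Dice inclusion rules (all slices annotated by ≥ 1 reader vs slices
annotated by both). A synthetic phantom-cohort generator with analytic
ground truth stands in for patient data.

## Worked example

```r
library(cmrqa)

# a 3-case two-reader phantom study: reader 2 systematically dilates the
# LV endocardium by 1 mm and adds 0.8 mm contour noise
coh <- generate_cohort(3, phantom_params(),
                       perturbation(radial_sigma = 0.8,
                                    dilation_mm = c(lv_endo = 1)),
                       seed = 7)

tol <- tibble::tibble(parameter = c("LVEDV", "LVESV", "LVSV"),
                      half_width = c(10.8, 7.3, 4.5))
study <- compare_study(coh$case_r1, coh$case_r2, tolerances = tol)
tidy(study)[1:4, c("parameter", "mean_diff", "ci_low", "ci_high", "acceptable")]
#> # A tibble: 4 × 5
#>   parameter mean_diff ci_low ci_high acceptable
#>   <chr>         <dbl>  <dbl>   <dbl> <lgl>
#> 1 LVEDV        -10.5  -10.8   -10.1  FALSE
#> 2 LVEF           2.04   1.73    2.34 NA
#> 3 LVESV         -6.96  -7.55   -6.37 FALSE
#> 4 LVM           11.0   10.8    11.1  NA
```

The systematic 1 mm endocardial dilation inflates reader 2's cavity by
about 10.5 ml at ED, so the reader-1 − reader-2 bias is negative and its
CI crosses the −10.8 ml tolerance edge: the verdict is unacceptable
(parameters without a supplied tolerance get `NA`). Tracing the
largest-impact slices of the first case shows the difference spread over
the large basal slices, each with high Dice — a systematic border shift,
not a gross error:

```r
trace_parameter(study$pairs[[1]], "LVEDV")[1:3, ]
#> # A tibble: 3 × 6
#>   slice_index phase ctype   contribution  dice hd_mm
#>         <int> <chr> <chr>          <dbl> <dbl> <dbl>
#> 1           3 ED    lv_endo        -1.77 0.955  2.78
#> 2           2 ED    lv_endo        -1.71 0.964  2.95
#> 3           1 ED    lv_endo        -1.68 0.970  2.61
#> # contributions sum exactly to the LVEDV difference
```

and a report bundle (HTML + CSVs + figures):

```r
build_report(study, style = "extensive", outdir = "out")
```

A command-line wrapper with `compare`, `tolerance`, `simulate` and
`report` subcommands ships in `inst/cli/cmrqa.R`.

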