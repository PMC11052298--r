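# transelect

Cross-species signatures of selection on bacterial translation machinery.

Bacterial generation times range from ~10 minutes (*Vibrio natriegens*) to
about a week (*Mycobacterium leprae*). Short-generation species must
duplicate their proteome fast, so selection to optimise translation —
initiation, elongation, termination, and the machinery itself — should be
strongest in them, and strongest of all in their highly expressed genes
(HEGs). `transelect` is for molecular evolutionists who want to extract
those signatures from annotated genomes and model them across species.

From GenBank flat files it computes, per genome:

- **machinery counts** — rrn operons (16S copy number, `N_rrn`) and tRNA
  genes (`N_tRNA`);
- **initiation** — AUG start-codon usage (AUG%), upstream nucleotide and
  PWM profiles around the Shine–Dalgarno (SD) region, a likelihood-ratio
  G-test of C-vs-U avoidance, and the aSD match distance `D_toStart`;
- **elongation** — the index of translation efficiency
  (I\_TE, a mutation-background-corrected CAI), its HEG-minus-REST
  difference `DITE`, and the effective number of anticodons `N_AC` of the
  tRNA gene pool;
- **termination** — UAA stop-codon usage (UAA%);
- **structure** — 40-nt sliding-window minimum-folding-energy (MFE)
  profiles anchored at the start/stop codons, summarised as `MeanMFE` over
  the SD-plus-start window.

The statistical layer fits the cross-species models in the field's
standard form: class-contrast OLS
(`AUG% ~ RankGT + GC% + GE`, GE = 0 for HEG, 1 for REST; with a `GC%:GE`
interaction for MeanMFE), midrank transforms and rank regressions for
`DITE` and `N_AC`, and floor-exponential least squares
`N = floor + a·e^(−b·RankGT)` for the machinery counts. A synthetic-panel
generator (`generate_panel()` / `null_panel()`) emits annotated genomes
with a ground-truth manifest so the entire pipeline is testable without
downloads. A nine-species reference panel (machinery counts, codon-usage
tables, DITE, N\_AC, MeanMFE) ships as in-code tibbles (`panel_*()`) to
drive the regression layer directly.

## Worked example

Fit the start-codon model on the packaged reference panel and derive the
per-class equations:

```r
library(transelect)

aug <- fit_start_model(panel_aug())
aug
#> <ols_fit> aug_percent ~ rank_gt + gc + ge
#>          term   estimate std_error statistic     p_value
#> 1 (Intercept) 125.855279  8.602725  14.62970 7.08115e-10
#> 2     rank_gt  -2.538630  0.764121  -3.32229 5.03404e-03
#> 3          gc  -0.520691  0.194908  -2.67147 1.82475e-02
#> 4          ge  -9.176739  2.944351  -3.11673 7.57641e-03
#> R-squared: 0.8195  n = 18
```

AUG% falls by 2.54 points per rank of generation time after controlling
for genomic GC%, and HEGs sit 9.18 points above REST genes — both in the
direction stronger selection predicts. `derive_class_equations(aug)`
substitutes the dummy: AUG% = 125.86 − 2.54·RankGT − 0.52·GC% for HEGs,
intercept 116.68 for REST.

The tRNA gene count decays to a floor of ~30 genes — a minimal decoding
set — as generation time grows:

```r
fit_floor_exponential(panel_machinery()$rank_gt, panel_machinery()$n_trna)
#> <floor_exp_fit> y = c=29.86 + 129.8 * exp(-0.2737 x)  RSS = 271.1
```

Ranked codon adaptation tracks ranked generation time, and the worked
G-test shows C avoided relative to U in the SD window of HEGs:

```r
rr <- rank_regression(rank_transform(panel_dite()$dite),
                      panel_dite()$rank_gt)
rr$r_squared
#> 0.8784

c_vs_u_test(36, 129, 2952, 7069)
#> # A tibble: 1 × 5
#>   statistic    df p_value percent_c_group1 percent_c_group2
#>       4.84      1  0.0278             21.8             29.5
```

End-to-end on genomes (here a synthetic panel; point `x` at your own
GenBank files for real ones):

```r
cfg <- panel_config(seed = 42)
panel <- generate_panel(cfg, "panel_dir")
res <- run_pipeline(panel$files, rank_gt = 1:9, mfe = FALSE)
res$summary      # one row per species x expression class
res$models       # start/stop (and structure, when mfe = TRUE) ols_fit objects
```

See `vignette("translation-selection")` for the models, parameter
defaults, and the generator's assumptions.

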