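# ischemiaqc

Cold ischemia time — the minutes between surgical resection of a tissue
specimen and its final freezing — silently degrades the molecular signal a
tumor registry is built to capture. The damage is modality-graded: genomic
DNA is essentially stable, mRNA decays slowly, proteins faster, and
phosphorylation sites fastest of all. For target discovery the quantity at
stake is the per-patient *differential* expression, the tumor-minus-normal
contrast on the log2 scale, tested pairwise per biomolecule.

`ischemiaqc` is an R package for quantifying that degradation and deciding
how much ischemia time a collection protocol can tolerate. It provides:

* paired Wilcoxon differential-biomolecule selection with BH adjustment at
  α_fdr = 0.01 and a 5th/95th effect-percentile boundary;
* the Scheirer–Ray–Hare two-factor rank test (tissue × time group,
  `H = SS_effect / MS_total` with tie correction, chi-square reference) and
  Kruskal–Wallis / Fisher screens for DNA submodalities;
* extreme-expression loss: for extreme sets δ(T) outside the (Q2.5, Q97.5)
  quantile interval, the loss `L = 100·|δ(T1)\δ(T)|/|δ(T1)|`, and the same
  set-difference loss applied to per-group differential sets;
* hierarchical (Euclidean, complete-linkage) and Dirichlet-process
  Gaussian-process mixture clustering of pseudo-time fold-change
  trajectories (α = 0.1, m = 12 auxiliary clusters, inverse-gamma(4, 2)
  noise prior, squared-exponential kernel, Gibbs sampling with MAP
  partition selection);
* per-biomolecule OLS confounder regression of fold changes on age, gender,
  alcohol, meat consumption, grade, stage and refined time group, with
  signed-coefficient summaries;
* an explicit ischemia time cut-off rule (differential loss ≤ 25% and
  ischemia coefficients below the stage-IV coefficient, per modality);
* a seeded synthetic paired-cohort generator with known ground truth
  (differential set, modality-ordered decay, confounder effects,
  time-increasing missingness) so everything above is testable without
  patient data.

Results are tibbles throughout; fitted objects have `tidy()` / `glance()`
methods and `autoplot()` / `plot_*()` companions.

## Worked example

```r
library(ischemiaqc)

cfg <- pipeline_config(simulate = sim_config(seed = 1),
                       dpgp = dpgp_config(iterations = 100, burn_in = 50),
                       seed = 1)
res <- run_pipeline(cfg)

tidyr::pivot_wider(res$de_loss, names_from = group, values_from = loss_pct)
#> # A tibble: 3 × 5
#>   modality       T2    T3    T4    T5
#>   <chr>       <dbl> <dbl> <dbl> <dbl>
#> 1 mRNA         2.54  8.47  43.2  61.0
#> 2 protein      0     5.93  47.5  78.0
#> 3 phosphosite  0    12.1   47.4  79.3

res$cutoff
#> Recommended ischemia time cut-off: 12 min (group T2)
#> Rule: loss <= 25.0% and mean |ischemia coef| < mean |stage-IV coef|
#>       for every modality, contiguously from T2
```

The loss table reads: of the biomolecules differentially expressed in the
shortest-time reference group T1 (t < 10 min), 61–79% are no longer
detected in T5 (19–20 min), and the erosion is ordered mRNA < protein <
phosphosite — the modality-graded decay the simulated cohort plants and
the pipeline is designed to expose. The cut-off report shows which
criterion binds in each group: here phosphosite ischemia coefficients
overtake the stage-IV coefficient from T3 (13–15 min) on, so the
recommendation is the T2 bound, 12 minutes.

`run_pipeline(cfg, out_dir = "out")` additionally writes every stage table
as TSV plus a JSON run summary; identical config and seed give
byte-identical outputs (the timing log aside). A thin command-line wrapper
lives at `inst/scripts/ischemia-pipeline.R`.

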