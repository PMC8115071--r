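# oxphosimc

Single-neuron profiling of mitochondrial oxidative-phosphorylation (OxPhos)
deficiency from imaging mass cytometry (IMC) data, for researchers
quantifying respiratory-chain protein expression in post-mortem brain
tissue (e.g. Parkinson's disease and mitochondrial disease cohorts versus
controls).

## What it does

IMC produces one intensity channel per metal-tagged antibody at ~1 µm² per
pixel. Starting from multichannel images plus manually outlined neuron
polygons (or directly from a per-neuron intensity table), the package:

1. **Quantifies**: rasterizes each outline, removes nucleus/neuromelanin
   pixels (intensity > 5 on the Histone H3 and Ir channels), and takes the
   mean cytoplasmic intensity per target per neuron.
2. **Normalizes**: fits the pooled-control regression
   ln I_k = a_k + b_k · ln V + ε per OxPhos subunit k on the mass marker
   VDAC1 (V), and scores every neuron with the perpendicular-distance
   z-score z = [(y − a − bx)/√(1+b²)] / SD(d_control) and a mass z-score
   (ln V − m)/s.
3. **Calls deficiency**: a subunit is "decreased" when the neuron falls
   strictly below the lower limit of the 80% prediction interval of the
   control regression; complex-level calls use representative subunits
   (NDUFA13, SDHA, UqCRC2, MTCO1, ATP5B) and each neuron gets a severity
   category 0–5 (number of decreased complexes).
4. **Compares groups**: robust Bayesian two-group estimation
   y_gi ~ StudentT(ν, µ_g, σ_g) with broad canonical priors, reported as
   the posterior mean of µ1 − µ2 with its 95% highest density interval and
   the effect size (µ1−µ2)/√((σ1²+σ2²)/2); plus Mann–Whitney tests,
   Spearman correlations, severity-vs-age regression and 95% data ellipses.
5. **Simulates**: a seeded synthetic cohort (per-case neuron counts,
   per-complex deficits with ground-truth labels) and synthetic images, so
   the full pipeline is testable without any tissue data.

## Worked example

```r
library(oxphosimc)

cfg <- pipeline_config(
  mode   = "synthetic",
  cohort = default_cohort_config(seed = 42),   # control / PD / POLG cohort
  best   = list(chains = 2L, warmup = 500L, draws = 1500L),
  mass_contrasts = FALSE, seed = 42)
report <- run_pipeline(cfg)

report$severity$categories
#>     group n_neurons pct_cat0 pct_cat1 pct_cat2 pct_cat3 pct_cat4 pct_cat5
#> 1 control       455    59.56     31.9     7.69    0.879      0.0    0.000
#> 2      PD       321    13.71     30.8    35.51   14.330      5.3    0.312
#> 3    POLG       173     2.89     11.0    31.79   32.948     15.6    5.780
```

Severity categories count how many of the five complexes are called
decreased in each neuron: in this simulated cohort (deficit fraction 0 /
0.25 / 0.5 per complex for control / PD / POLG), ~60% of control neurons
are fully normal while POLG neurons concentrate in the multi-complex
categories. The ~10% of control neurons in category ≥ 1 per complex is the
expected one-sided false-flag rate of the 80% prediction-interval rule.

```r
gb <- report$group_best
gb[grep("NDUFA13|mass", gb$contrast),
   c("contrast", "mu_diff_mean", "hdi_lower", "hdi_upper", "effect_size_mean")]
#>                   contrast mu_diff_mean hdi_lower hdi_upper effect_size_mean
#> 2    PD_vs_control/NDUFA13     -1.11286    -1.363   -0.8603         -0.68027
#> 9       PD_vs_control/mass     -0.08210    -0.223    0.0586         -0.08451
#> 11 POLG_vs_control/NDUFA13     -1.87028    -2.245   -1.4947         -1.06411
#> 18    POLG_vs_control/mass     -0.00286    -0.170    0.1607         -0.00308
```

Each row is a Bayesian two-group contrast on z-scores: complex I (NDUFA13)
expression is clearly shifted down in both disease groups (HDIs excluding
0, more severely in POLG), while mitochondrial mass is not — matching the
simulation's ground truth, which the report also verifies directly:

```r
report$recovery
#>   complex n_deficient recall false_flag_rate
#> 1      CI         169  1.000          0.0808
#> ...
```

`write_report(report, "outdir")` exports every table as CSV plus the frozen
control model as YAML; `make_figures(report, "outdir")` renders z-score
histograms (bin width 0.1), the z-vs-z scatter with 95% ellipses, the
per-case percent-decreased heatmap and severity stacked bars. A CLI wrapper
with `simulate` / `fit-controls` / `all` subcommands is installed at
`inst/cli/oxphosimc.R`.

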