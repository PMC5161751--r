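# cdkphos

Quantitative analysis of CDK substrate phosphorylation dynamics from SILAC
phosphoproteomics.

## The problem

Cyclin-dependent kinase (CDK) activity rises through the cell cycle, and
individual substrates become net-phosphorylated at different activity
levels. Dissecting this requires several coupled quantitative analyses of
phosphosite-level SILAC ratio data ("relative phosphorylation" — the ratio
of a phosphopeptide in a sample channel over a common reference channel):

* **Substrate calling** from kinase-inactivation time courses. Sites at the
  minimal CDK consensus (S/T-P) whose signal after inhibitor addition
  follows a one-phase exponential decay
  `y(t) = (Y0 − Plateau)·e^(−K·t) + Plateau` (constraints `K > 0`,
  `Plateau > 0`) with `R² > 0.9` and `Plateau < 0.5` are direct substrates;
  the half-life is `ln 2 / K` and `K` itself is the dephosphorylation rate.
  A four-criteria filter (initial-value bounds, data sufficiency, 2-fold
  decrease, fit quality) plus single-timepoint anomaly screening implements
  the calling workflow.
* **Activity thresholds** from inhibitor (1-NmPP1) titrations. Per-site
  dose-responses are fitted with a constrained four-parameter logistic
  `y = Bottom + (Top − Bottom)/(1 + 10^((log10 IC50 − log10 d)·h))`
  (`h < 0`, `Bottom > 0`) with ROUT-style robust outlier removal
  (Q = 10%), giving IC50 and Hill-slope values per phosphosite.
* **In vivo kinase-to-phosphatase activity** from washout rate assays: the
  initial linear slope of re-phosphorylation after restoring kinase
  activity, per cell-cycle stage, relative to mitosis.
* **Temporal classification** (early / mid / late) of cell-cycle
  trajectories by hierarchical clustering (Euclidean, average linkage),
  after kNN imputation and nearest-neighbour smoothing; plus the G2/M AUC
  timing statistic (trapezoidal integral over 50–100 min after release).
* **G1/S cyclin specificity score**: phosphorylation medians are mapped
  through class-median dose-response curves back to equivalent inhibitor
  concentrations, normalized to late substrates, inverted, and compared
  between genotypes; a class specifically served by G1/S cyclins scores
  above 1 in wild type versus a G1/S-cyclin-less background.
* **Sequence context**: minimal/full CDK consensus calls, RxL
  cyclin-docking motifs (`[RK]xL x? [FYLIVMP]`), positional amino-acid
  profiles, and Fisher-exact annotation enrichment at BH FDR < 0.02.

Every stage is exercised end-to-end on synthetic MaxQuant-dialect SILAC
tables with known kinetic ground truth, so parameter recovery is testable
without any external download.

## Worked example

```r
library(cdkphos)
report <- run_pipeline(list(simulate = list(n_sites = 3000, seed = 1),
                            clusters = 8), "demo_out")
str(report$summary)
```

simulates a 3,000-site experiment (decay time courses in mitosis and S
phase, an 11-dose titration, two-cycle releases in four genotypes, washout
assays in four stages), writes the tables, re-reads them through QC, and
runs every stage. The summary it printed when this README was written:

```
$ median_half_life_min : 2.179
$ median_ic50_uM       : early 3.60, mid 1.76, late 0.205   (uM)
$ rate_profile_pct     : G1 1.71, S 7.38, G2 36.4, M 100    (% of mitosis)
$ specificity_score    : early 0.91, mid 5.87               (wt / dCCP)
$ class_counts         : early 251, mid 257, late 981
```

Read: substrate phosphorylations turn over with a ~2.2-min median
half-life; early substrates tolerate ~18x more inhibitor than late ones
(lower activity threshold); kinase activity rises ~60-fold from G1 to
mitosis; and only the mid class shows a G1/S-cyclin specificity score well
above 1 — all matching the generator's configured ground truth.

A command-line interface wrapping each stage is installed at
`system.file("cli", "cdkphos", package = "cdkphos")` (subcommands `run`,
`simulate`, `call-substrates`, `dose-response`, `rates`, `auc`, `motifs`,
`enrich`).

## Layout

* `R/` — simulation (`sim_config`, `make_ground_truth`, `simulate_*`),
  IO (`read_site_table`, `experiment_map`, ...), preprocessing
  (`impute_knn`, `smooth_nn`), kinetics (`fit_one_phase_decay`,
  `call_substrates`, `fit_four_pl`, `phosphorylation_rate`, `auc_window`),
  classification and scoring (`hierarchical_cluster`,
  `assign_temporal_classes`, `specificity_score`), motifs/enrichment, and
  the pipeline driver (`run_pipeline`).
* `vignettes/cdkphos-methods.Rmd` — the model, parameter choices, and what
  the synthetic world does and does not establish.
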