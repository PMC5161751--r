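---
title: "Models and methods behind cdkphos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cdkphos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdkphos)
```

# Scope and quantities

cdkphos analyses phosphoproteomic SILAC ratio data in which every value is
a *relative phosphorylation*: the ratio of a phosphopeptide's signal in a
sample channel over a common reference channel. Raw MaxQuant-style tables
report normalized H:L ratios whose orientation depends on which channel
held the reference; the reader re-orients everything to sample/reference
once, so no downstream function ever sees a mixed orientation. Site
identifiers are `protein_id` + residue + 1-based position; windows are
31-residue strings centred on the site, padded with `_` at protein termini.

QC at read time follows standard post-search practice: reverse and
contaminant rows are dropped, localization probability must exceed 0.9
(a site at 0.89 is excluded), and rows without a single valid ratio are
removed.

# Decay kinetics and substrate calling

Inactivation time courses (0, 1, 3, 6, 9, 12, 24 min) are fitted with a
one-phase exponential decay
$y(t) = (Y_0 - P)\,e^{-Kt} + P$ under box constraints $K > 0$, $P > 0$,
by `nls` (port algorithm) started at $Y_0 = y(0)$, $P = \min y$,
$K = 0.3\,\mathrm{min}^{-1}$, with a constrained quasi-Newton fallback for
degenerate series. The half-life is $\ln 2 / K$; the dephosphorylation
rate is reported as $K$ itself — the only rate the one-phase model yields,
and the quantity used wherever "rate" appears downstream.

Substrate calling applies four criteria per dataset: (i) the 0-min value
must lie within dataset-specific bounds — in mitosis between 0.5 and 2
(that sample is a replicate-vs-replicate comparison whose theoretical
value is 1), in S phase above 0.25; (ii) at least 4 of 7 timepoints
measured; (iii) at least one of the 1–12-min values below half the 0-min
value (the 24-min point deliberately does not count); (iv) a decay fit
with $R^2 > 0.9$ and plateau $< 0.5$. Failures undergo anomaly screening:
each non-zero timepoint is removed in turn and the criteria re-evaluated;
among passing removals the highest-$R^2$ one wins. The 0-min anchor is
never removed, so a corrupted anchor is never rescued — by design.
Screening runs only on failures, so a plainly-passing call can never be
altered by it. Criterion iv is evaluated only when i–iii hold; this is an
optimisation (flat series are never fitted), not a semantic change, since
the conjunction is what matters.

One open point we resolved: whether a rescued site must satisfy both
datasets' criteria after removal. The two datasets are processed
independently (as the original workflow ran them), so each rescue is
per-dataset.

# Dose-response thresholds

Titration curves are fitted with the four-parameter logistic
$y = B + (T - B)\,/\,(1 + 10^{(\log_{10}\mathrm{IC50} - \log_{10} d)\,h})$
constrained to $h < 0$, $B > 0$. Outlier handling follows the published
ROUT outline rather than any proprietary implementation: an iteratively
reweighted fit with Lorentzian weights gives a robust residual scale (the
68.27th percentile of absolute residuals inflated by $n/(n-4)$); residual
t-tail p-values are gated by Benjamini–Hochberg at $Q = 0.10$; flagged
points are excluded and the final fit is ordinary least squares on the
rest, with $R^2$ computed on retained points only. Optimisation is
multi-start (three canonical starts) L-BFGS-B followed by a Gauss–Newton
polish, which recovers noiseless parameters to better than four
significant digits. A fit is *accepted* when $R^2 > 0.9$, $B < 0.5$ and
$T/B > 2$.

The zero-dose (DMSO) control has no log-dose coordinate. Default policy:
it normalizes the curve (control = 1) and is excluded from the fit; a
`pseudo_dose` mode instead assigns it one log10 below the lowest tested
dose. Both are tested; IC50 agreement between the modes is within a few
percent on clean data.

Threshold comparisons (`delta_ic50_analysis`) consider only proteins with
at least two accepted IC50 values, and test intra-protein against
inter-protein absolute differences with a two-sided Mann–Whitney U test —
exact for small tie-free samples, normal approximation with tie
correction otherwise. We compare intra against *inter* pairs (disjoint
sets) rather than intra against all pairs, to avoid testing a sample
against a superset of itself; both vectors are returned.

# Rates and AUC

Washout assays sample at 0, 0.5, 1, 2 and 10 min after restoring kinase
activity. Only sites in the dephosphorylated state at washout (0-min value
below 0.5) are eligible. The rate is the ordinary least-squares slope over
the 0–2-min window; the 10-min point is excluded by default as saturating
(the window is a parameter). Stage profiles can be computed from the
median trajectory of eligible sites (default) or as the median of per-site
slopes — the source wording supports both, so both are implemented and the
flag decides; on synthetic data they agree within a few percent.

The G2/M AUC is the trapezoidal integral of an imputed-and-smoothed
trajectory over 50–100 min after release, with linear interpolation at the
window edges. It is additive over subintervals and exact for piecewise
linear trajectories.

# Preprocessing

Imputation mirrors the documented defaults of the classic `knnImputation`
routine (the original package is not a dependency; the algorithm is
reimplemented): rows need at least 50% valid values; each missing cell is
the $\exp(-d)$-weighted mean of the $k = 10$ nearest complete rows, with
Euclidean distance over the row's observed columns on column-standardised
values. Observed cells are never altered. Whether to standardise before
the distance is not documented for the smoothing step, so it is a flag:
on for imputation (matching the cited routine), off for smoothing.
Smoothing replaces each row by the unweighted mean of its five nearest
neighbours (self excluded — "its neighbours" cannot sensibly include the
site itself), always computed from the pre-smoothing matrix, so the
operation is a single pass and deliberately not idempotent.

# Temporal classes and the specificity score

Trajectories are clustered with Euclidean distance and average linkage
(the distance is stated by the source environment, the linkage is not;
average linkage is that environment's common default and is exposed as a
flag), then cut into a configurable number of flat clusters. Class rules
operationalise the verbal archetypes: a cluster is *early* if its mean
trajectory is at ≥ 50% of its in-window maximum at the G1/S transition,
*late* if it is < 25% there and first crosses half-maximum after the G2/M
annotation, *mid* otherwise, and *unassigned* if essentially flat. The
thresholds are parameters, and a manual override table is honoured
(mirroring the fact that even the original analysis overrode two sites
after visual inspection).

The G1/S cyclin specificity score interpolates class-median
phosphorylation through the class's median titration curve to an
equivalent inhibitor concentration, normalizes to the late-class
concentration, inverts, and takes the genotype ratio. Scores are computed
only at S-phase timepoints. Values outside the open (Bottom, Top) range of
a curve are flagged per timepoint, never clamped. Under genotype-identical
inputs the score is exactly 1 by construction (the same inversion appears
in numerator and denominator), which the tests assert to 1e-9.

# The synthetic world

The generator emulates four experiment designs with one shared
ground-truth table. Stated-world defaults: 3,000 sites; class mixture
early/mid/late/nonsubstrate = 0.10/0.10/0.40/0.40; decay constants
lognormal around $\ln 2 / 2.2\,\mathrm{min}^{-1}$ clamped to
$[0.12, 2]$ (so the 2-fold-decrease criterion is satisfiable on the 7-point
grid); plateaus uniform on $[0, 0.3)$; class-median IC50s 3.7 / 1.7 / 0.2
µM and Hill slopes −3.6 / −1.33 / −1.41 with lognormal spread plus a
protein-level random effect shared by co-resident sites (so intra-protein
threshold differences are smaller than inter-protein ones); stage
activities 1.7 / 7.3 / 36 / 100% of mitosis. No noise magnitude is stated
anywhere for these data, so `noise_sd = 0.05` (log2 scale, multiplicative
on ratios — SILAC ratio error is multiplicative) was chosen once such that
replicate half-life correlation is high (r > 0.9), qualitatively matching
the published repeat comparison. Missingness is completely at random at
10% by default, with a low-value-biased mode available; real MS
missingness is intensity-dependent, which MCAR does not capture.

The cell-cycle trajectories are occupancies of each site's dose-response
curve at the instantaneous activity of a piecewise-exponential profile
(reset at each mitotic exit; release from G2 arrest, first division at
25 min, second cycle 25–110 min, G1/S at 45 min). Activity maps to an
equivalent inhibitor dose via
$d = 0.04 / a^{1.53}$ µM: the exponent reflects that net kinase activity
is an ultrasensitive function of inhibitor in feedback-competent cells
(the titration itself was performed in a feedback-bypassed background),
and the two constants were derived *forward* from the stated class
medians so that at G1/S the early/mid/late classes sit at roughly
0.7/0.3/0.02 of maximal occupancy and late sites exceed 0.9 in mitosis.
Genotype effects: wild type multiplies interphase activity by 1.5
(generic G1/S-cyclin contribution) and additionally by 3 for mid-class
sites (specificity); the rum1-deleted background gets a 1.3 generic
boost. The noise stream is shared across genotypes (a paired design), so
zero-boost genotypes are byte-identical.

Reproducibility protocol: one seeded generator per experiment, with the
sub-seed derived by hashing the experiment label into the master seed, and
a fixed draw order documented in `make_ground_truth()` — so any draw
(e.g. the class multinomial) can be reproduced independently.

What a green test establishes: that the estimators recover the generating
parameters under lognormal noise and MCAR missingness at realistic
magnitudes, and that every statistical primitive agrees with an
independent oracle. What it does not establish: robustness to
intensity-dependent missingness, peptide-level interference,
mis-localization, or any property of the real deposited data.

# Numerical choices and known limitations

* Sensitivity/specificity of substrate calling are evaluated over sites
  whose 0-min anchor was observed: with missingness completely at random,
  10% of sites lack the anchor and are unquantifiable by design; counting
  them as calling errors would cap sensitivity at 0.90 regardless of the
  procedure.
* The decay fit reports $R^2 = 0$ (not `NA`) for a constant series and
  flags it non-decaying; the 4PL fit reports failure when fewer than six
  positive doses survive outlier removal.
* Average-linkage heights are compared to a quadratic-time Lance–Williams
  reference in the tests; ties in distance are broken by `hclust`'s
  internal order, so leaf order (not partition content) may differ across
  platforms.
* The number of flat clusters that reproduces any particular published
  cluster count is not identifiable from the method description; class
  counts are therefore not a target, only the ordering and shape of the
  class medians.
* The ROUT implementation preserves the Q-as-FDR semantics, not
  bit-compatibility with any commercial tool.
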