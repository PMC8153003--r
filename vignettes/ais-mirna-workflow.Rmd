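---
title: "Arousal-based screening and brain-area miRNA/mRNA analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arousal-based screening and brain-area miRNA/mRNA analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aismir)
```

## The problem this package addresses

After a single severe traumatic stressor, only a fraction of exposed animals
develop a persistent PTSD-like phenotype. The arousal-based individual
screening (AIS) approach phenotypes each stressed mouse from its acoustic
startle reactivity (ASR): a pre-trauma session fixes the baseline, two
post-stress sessions (days 14 and 28) are expressed as percent of baseline,
and a *z*-normalized **arousal score** splits stressed mice into
**susceptible** (score ≥ 1) and **resilient** (score < 1) subgroups.
Unstressed controls keep the label `control`.

Downstream, the package analyses brain-area RT-qPCR data for a panel of four
miRNAs (miR-15a-5p, let-7d-5p, miR-497a-5p, miR-511-5p) and two of their
shared target transcripts (FKBP5, the glucocorticoid-receptor co-chaperone;
BDNF, the canonical neurotrophin) in hippocampus (HIP), hypothalamus (HT)
and medial prefrontal cortex (mPFC): relative quantification, group
statistics, correlation structure, combinatorial ("synergic") regression,
regulator set overlaps and pathway over-representation.

## Scoring model

For a measure $x$ and a reference population $R$,
$z(x) = (x - \bar{x}_R) / s_R$ with the $n-1$ sample SD. Choices the
protocol leaves open, and how this package resolves them (all configurable
through `segregation_config()`):

* **Reference population** — controls (default). Controls define the
  unstressed norm; z-scoring stressed mice against them measures deviation
  from that norm rather than from a mixture that already contains the
  pathology.
* **Session aggregation** — the arousal score is the mean of the two
  per-session z-scores (default `mean_of_z`). The alternative `z_of_mean`
  (z-transform of the mean percent change) is provided because the source
  protocol does not state which was used; the two agree on null mice and
  differ only in weighting of between-session variance.
* **Composite scores** — each behavioral readout (open-field, elevated plus
  maze, social memory) is z-normalized, sign-oriented so that *larger =
  more PTSD-like* (`orientation`, defaults: ASR +1, OF −1, EPM −1, SM −1),
  and combined by equal-weight means: avoidance = mean(OF, EPM) z-scores,
  social memory = SM z-score, PTSD-like = mean(arousal, avoidance, social
  memory). Equal weights are the neutral choice in the absence of stated
  weights.
* **Threshold** — susceptibility is inclusive at the cutoff: a score of
  exactly 1 is susceptible.

## Relative quantification

Technical triplicates are averaged on the Ct scale (the scale on which
qPCR noise is approximately Gaussian); replicate SD > 0.5 cycles is flagged
in a QC attribute but not excluded — exclusion policy belongs to the user.
Then, per mouse/area/analyte:

$$\Delta Ct = Ct_\text{target} - Ct_\text{reference}, \qquad
  \Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_\text{calibrator},
  \qquad RQ = 2^{-\Delta\Delta Ct}$$

mRNAs are referenced to GAPDH, miRNAs to U6 snRNA (`default_reference_map()`).
The calibrator is the arithmetic mean ΔCt of the control group per
(area, analyte) — this makes the *geometric* mean control RQ exactly 1, the
convention behind plots normalized around controls. Amplification-efficiency
correction and standard curves are out of scope: the pure $2^{-\Delta\Delta Ct}$
form is used.

Two exact invariants follow and are enforced by tests: RQ is unchanged by
any constant Ct shift within an area, and $\log_2 RQ$ is affine in the
target Ct with slope −1.

## Group statistics

* **Normality**: the D'Agostino–Pearson omnibus test,
  $K^2 = Z^2_{skew} + Z^2_{kurt} \sim \chi^2_2$, implemented from the
  standard skewness (D'Agostino 1970) and kurtosis (Anscombe–Glynn 1983)
  z-transforms; it requires $n \ge 8$. No installed R package provides this
  omnibus form, so it is implemented here and checked against an
  independent reference implementation on a frozen vector.
* **Group differences**: one-way ANOVA (via `lm`) across
  control/susceptible/resilient, followed by the Tukey HSD post hoc with
  the Tukey–Kramer denominator for unbalanced groups
  ($SE_{ij} = \sqrt{MSE/2\,(1/n_i + 1/n_j)}$) and p-values from the
  studentized range distribution with parameters $(k, N-k)$. The study's
  groups are intrinsically unbalanced (e.g. 12/7/11), so Tukey–Kramer is the
  default and only form.
* **Correlation**: Pearson $r$ with the two-sided $t$-based p-value on
  $n-2$ df. Correlation matrices carry star codes (* < 0.05, ** < 0.01,
  *** < 0.001, uncorrected two-sided p, matching the table convention) and
  mark pairs with fewer than 3 complete observations as *not computable*.
  Target:miRNA correlations default to **all** mice in an area — the
  printed per-area p-values back-compute correctly from the full area n
  (e.g. r = −0.40 at n = 30 gives p = 0.03) — while score correlations and
  regressions default to stressed mice only; both are switchable via the
  `mice` argument.

## Synergic regression search

For each target transcript and area, the admissible predictor pool keeps
the miRNAs with a *negative* sample correlation against the target
(`strict` mode) — the sign expected of a repressing miRNA. `permissive`
mode admits all four miRNAs; it exists because published model tables of
this kind sometimes contain predictors whose marginal correlation is
positive, so the filter and the table can conflict and both behaviors
should be reproducible. The search then enumerates **every** subset of
sizes 4, 3 and 2 from the pool, fits each by OLS, and reports the model
with the highest multiple correlation $R$ per size, with $R^2$ and the
overall-F p-value (the standard single-model p; the source tables print one
p per model without defining it). Ties break by lexicographic
predictor-name order. The full enumeration ledger is returned so users can
apply multiplicity corrections post hoc — none is applied by default, as
none was applied in the source analysis.

Score regressions fit, per composite score and area on stressed mice,
three models — miRNAs + mRNAs (6 predictors), miRNAs (4), mRNAs (2) — with
the same summaries. OLS nesting guarantees
$R^2_{miRNA+mRNA} \ge \max(R^2_{miRNA}, R^2_{mRNA})$; this is asserted in
tests as a structural check.

## Regulator overlaps and pathway enrichment

`pairwise_overlap()` and `common_to_all()` compute exact, deterministic set
intersections of per-miRNA regulator sets (TFs with promoter ChIP evidence;
lncRNAs predicted to decoy the miRNAs), after whitespace trimming and
case-sensitive matching. The packaged fixture sets
(`tf_regulator_sets_synthetic.tsv`, `lncrna_decoy_sets_synthetic.tsv`)
reconstruct each miRNA's set as the union of its published pairwise-shared
regulator lists plus clearly namespaced `DECOY_*` padding unique to each
miRNA: the published intersections (27 TFs shared by miR-15a and miR-497a;
Kcnq1ot1 and Gm4117 decoying all four miRNAs) are reproduced exactly, while
the padding keeps the operation non-trivial. The padding makes the files
partly synthetic, hence the file names.

Enrichment is the classical over-representation analysis: one-sided Fisher
exact (upper-tail hypergeometric) p per pathway, Benjamini–Hochberg FDR
across all pathways tested, significance at FDR < 0.05 and −log₁₀ FDR for
plotting. The default background universe is the union of all pathway genes
— the original web-tool background is not reproducible, so the choice is
explicit and overridable. The packaged GMT and target list are synthetic
fixtures with three planted signal pathways.

## The synthetic cohort generator

Raw per-mouse data behind the study design are not published, so the
generator (`cohort_config()` + `generate_cohort()`) emulates the study
conditions and gives every stage a testable input:

* **Cohort**: 46 mice — 18 controls + 28 stressed; 12 + 18 provide HIP and
  mPFC, the remaining 6 + 10 provide HT (the dissection split of the study
  design).
* **Latent susceptibility**: each stressed mouse carries a standard-normal
  latent trait that raises its post-stress ASR (12% of baseline per SD) and
  moves its expression profile from the resilient toward the susceptible
  ΔCt shifts through a logistic weight (`susceptibility_link` = 1.5). The
  trait is only ever thresholded downstream by the arousal-score rule, so
  the segregation operation is honestly exercised.
* **ASR model**: control sessions ~ N(100, 15) percent of baseline;
  stressed sessions add a +8% shift, the susceptibility gain, and N(0, 9)
  session noise, so the stressed marginal SD matches the control SD
  ($\sqrt{12^2 + 9^2} = 15$). Under normal theory this puts
  P(arousal ≥ 1) near 0.30, and the realized mean susceptible fraction over
  200 seeds is 0.32 — inside the 25–35% yield the screening protocol
  reports. The protocol gives no distributional parameters, so these
  defaults are documented free parameters chosen by that design
  calculation.
* **Expression model**: ΔCt values are Gaussian on the ΔCt scale (log2-linear
  in expression — the natural additive scale given $RQ = 2^{-\Delta\Delta Ct}$),
  with per-area, per-analyte mean shifts of ±0.8–0.9 cycles (≈ 1.7–1.9-fold)
  for the susceptible and resilient profiles following the reported
  direction of every area-specific effect, biological SD 0.7 cycles, and a
  planted analyte correlation matrix: miRNA:miRNA +0.45 everywhere,
  miRNA:FKBP5 −0.35 in HIP and HT (the functional repression signature),
  miRNA:BDNF +0.45 in HT. Matrices are validated symmetric, unit-diagonal
  and positive semidefinite at construction.
* **Technical noise**: triplicate Ct replicates add N(0, 0.15) cycles;
  reference-gene Ct varies N(0, 0.4) per mouse (RNA input), which cancels
  in ΔCt by construction. Averaging triplicates leaves $2\sigma_r^2/3$
  of technical variance on each ΔCt, attenuating observable correlations
  by $\sigma^2 / (\sigma^2 + 2\sigma_r^2/3) \approx 0.97$; the
  planted-correlation recovery check therefore measures the planted
  biological covariance at `replicate_sd = 0` and verifies the attenuated
  value under default noise against this closed-form prediction.
* **Determinism**: a single integer seed makes the generated tables
  bit-identical; all values are rounded to 6 significant digits so a
  TSV write/read round trip is the identity.

What the generator does **not** model — and hence what green tests do not
establish about real data: restraint-stress physiology (corticosterone,
immune markers), sex effects (the emulated cohort is male-only),
non-Gaussian Ct error, amplification-efficiency differences between
assays, floor/ceiling effects in behavioral measures, and any causal
coupling beyond the single latent trait and the planted covariance.

## Numerical choices and degenerate inputs

* Zero reference SD in z-scoring, zero pooled variance in Tukey, zero
  variance in Pearson, rank-deficient OLS designs and inconsistent Fisher
  tables are explicit errors, never silent NaN/Inf.
* One-way ANOVA handles the zero-residual-variance corner explicitly:
  identical group means give F = 0, p = 1; distinct means give F = ∞,
  p = 0.
* Best-subset ties break by lexicographic predictor-name order; subset
  sizes exceeding the pool or the sample size are skipped with a message.
* The pipeline fans one seed into all stages and records it, the package
  version, a config hash and per-file MD5 checksums in `manifest.tsv`.

## Problem sizes used by tests and the acceptance script

Simulation-based checks use cohorts of 20–200 mice and 25–500 replicates
per property (e.g. 200 seeds for the segregation yield, 100 seeded
replicates at n = 200 for planted-correlation recovery, 500 cohorts for the
null ANOVA calibration with the 99% binomial band taken at the realized
number of valid replicates, 200 random 6-predictor problems for the
best-subset oracle). These sizes make each check's sampling distribution
tight relative to its asserted band while keeping the default suite fast.

## Known limitations

* The AIS composites weight sub-measures equally; the original weighting is
  unknown.
* The source tables' per-model p definition is assumed to be the overall
  F-test; if the original software reported something else, absolute
  p-values (not R or R²) could differ.
* One printed hypothalamic correlation p-value (r = −0.69 reported with
  p = 0.002) is not reproducible from the stated cohort size n = 16 under
  the two-sided t-based formula, which yields 0.003; the package reproduces
  the formula, not the printed number.
* Enrichment results depend strongly on the background universe; with the
  default (union of pathway genes) p-values are typically conservative
  relative to a genome-wide background.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "ais_run")
res$scores          # per-mouse composite scores + phenotype
res$synergy$best    # best miRNA combination per target/area/size
res$enrichment      # ranked pathways with FDR
```
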