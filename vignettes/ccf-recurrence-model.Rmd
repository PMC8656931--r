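---
title: "Modelling recurrence risk from cancer cell fractions"
author: "ccfRisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling recurrence risk from cancer cell fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfRisk)
```

## The problem

Targeted deep sequencing of a tumor specimen reports, for every somatic
mutation, how many reads carry the variant allele. Two patients with the
same mutated gene can still differ enormously in how much of the tumor
actually carries the mutation: a variant confined to a small subclone is
a different biological object from one present in every tumor cell.
`ccfRisk` quantifies that difference — the **cancer cell fraction**
(CCF) of each mutation — and uses it, rather than binary mutation
status, to model post-surgery recurrence risk in esophageal squamous
cell carcinoma (ESCC) and comparable targeted-panel cohorts.

The package covers the full path from caller output to evaluated risk
model: CCF inference and clonality calls, gene-level CCF matrices,
survival screens and CCF-dependent effect patterns, SCAD-penalized Cox
model building with stepwise BIC and stability selection, recursive-
partitioning risk stratification, and IPCW time-dependent ROC
evaluation. A synthetic-cohort simulator with fully known ground truth
makes every stage testable without patient data.

## CCF inference

For a mutation with multiplicity $m$ (mutant copies per mutated cell) at
a locus of tumor total copy number $CN_t$, in a sample of purity
$\rho$, a clone of size $c$ (the CCF) yields the expected variant allele
fraction

$$ v(c) \;=\; \frac{c\, m\, \rho}{\rho\, CN_t + 2(1-\rho)} , $$

assuming the contaminating normal cells are diploid at the locus. With
alt/total read counts $(a, d)$ the package evaluates a posterior over a
grid of 100 CCF values ($0.01, \dots, 1.00$) with a uniform prior and a
binomial likelihood $a \sim \mathrm{Bin}(d, v(c))$. The grid form keeps
every derived quantity an explicit finite sum: the point estimate is the
posterior mode, and the clonality statistic is
$P(\mathrm{CCF} > 0.9) = \sum_{c > 0.9} \pi(c \mid a, d)$. A mutation is
called **clonal** when that probability exceeds 0.5 — the
$P_{\mathrm{CCF}>0.90} > 0.5$ rule — and subclonal otherwise.

Multiplicity is estimated first, as
$m = \max\!\big(1, \mathrm{round}(\mathrm{VAF} \cdot
[\rho\, CN_t + 2(1-\rho)]/\rho)\big)$, clamped above by the rounded
total copy number; when a supplied $m$ would imply $v(1) > 1$ it is
reduced to the largest consistent value with a warning. Loci not covered
by any copy-number segment fall back to $CN_t = 2$ and are flagged.
Purity is an input; `estimatePurityHeuristic()` (twice the top-decile
VAF) exists only as a labelled fallback.

Two practical notes on calibration. At exactly 1000x depth on a diploid
locus, a clonal mutation in a $\rho \ge 0.7$ sample is called clonal in
about 99.5% of draws, and a CCF-0.2 mutation subclonal in essentially
all of them; the test suite measures exactly this experiment. The
information content degrades away from those conditions: at $\rho = 0.4$
the binomial VAF noise maps to a CCF standard deviation near 0.07, so
several percent of truly clonal mutations must fall below any 0.9
boundary regardless of the estimator, and on whole simulated cohorts —
negative-binomial depths down to ~550x, loci at copy number 3–4, the
full (0.3, 0.95) purity range — the clonal-call rate drops to roughly
96–99% depending on the stratum. The $\rho \ge 0.7$ restriction is the
same one a practitioner applies before interpreting subclonal
architecture.

## Subclone counting

Per-sample subclone counts use a one-dimensional Gaussian mixture on
logit-transformed CCF point estimates (components $K = 1,\dots,6$,
equal- and unequal-variance models, BIC selection via `mclust`). This is
a deliberate, documented stand-in for Dirichlet-process clustering: for
*counting* well-separated subpopulations the mixture is adequate,
deterministic and dependency-light. CCFs are clamped to
$[0.005, 0.995]$ before the logit; because the clamp can shatter the
clonal point mass into near-identical components, components whose
back-transformed centers lie within 0.05 of each other are merged
(weights summed, centers weight-averaged). Clusters with centers below
the 0.9 clonal boundary count as subclones; samples with fewer than five
mutations return a flagged single-cluster model. On planted mixtures
with centers at least 0.25 apart and 30+ mutations per cluster the
planted $K$ is recovered in at least 90% of seeds.

Gene-level clonality preference is a two-sided exact binomial test of a
gene's subclonal count against the cohort-wide subclonal fraction,
BH-adjusted across genes.

## The gene CCF matrix

Per patient and gene, the matrix entry is the **maximum** CCF point
estimate over that patient's mutations in the gene (0 for wildtype,
capped at 1). The maximum represents the largest affected clone; other
aggregation rules (sum, mean) double-count nested clones or dilute
single strong hits. The matrix ships as a `SummarizedExperiment` (genes
in rows, clinical data as `colData`) and serializes to a plain TSV that
round-trips to six decimals.

## CCF-dependent prognostic patterns

Each sufficiently frequent gene (cohort frequency at least 5%) is
classified by how its prognostic effect relates to CCF, using exactly
three tools:

* a mutant-vs-wildtype log-rank test (effect of *having* the mutation),
* a Cox model on continuous CCF among mutant samples (dose response),
* the maximally selected rank statistic among mutants (threshold
  response), with a permutation p value that accounts for the cutoff
  search.

The maxstat statistic uses Nelson-Aalen log-rank scores
$a_i = \delta_i - \hat\Lambda(t_i)$: at a candidate cutoff the
standardized score sum of the low-CCF group is compared over all
admissible cutpoints (midpoints of adjacent distinct CCFs inside the
inner 10–90% quantile range), and the permutation null re-randomizes the
scores, so the p value is automatically selection-adjusted.

The cascade labels a gene `dose_dependent` if the continuous-CCF Cox
model is significant, else `dominant` (with the selected cutoff) if the
maxstat permutation p is significant, else `independent` if the status
log-rank is significant, else `none`. One adjudication was forced by the
geometry of the problem: a genuine threshold effect *always* also
induces a significant linear CCF trend, so when both the dose and
threshold steps fire, the two single-parameter Cox models among mutants
are compared by partial likelihood, and the threshold shape must win by
more than two log-likelihood units — its expected advantage from having
optimized the cutoff — to claim `dominant`. On planted scenarios
(status-only, threshold-at-0.9, linear log-hazard) this assigns the
correct label in essentially every seed. No multiple-testing correction
is applied inside the cascade; BH-FDR applies only to the flat
univariable screens.

## Survival modelling core

**Cox fits.** Unpenalized fits maximize the Efron-tied log partial
likelihood by Newton-Raphson with step halving, to a gradient sup-norm
below 1e-8. Constant covariates are dropped; runaway coefficients are
reported as likely monotone-likelihood separation.

**SCAD penalty.** The smoothly clipped absolute deviation penalty with
shape $a = 3.7$ (the canonical recommendation) is linear near zero,
quadratically clipped on $(\lambda, a\lambda]$, and constant beyond, so
large coefficients are essentially unshrunk. `fitScadCox()` solves the
penalized Cox problem by a local linear approximation (LLA) outer loop —
each iteration re-weights an $L_1$ penalty by the SCAD derivative at the
current coefficients — around an IRLS inner loop whose weighted
least-squares subproblem is solved by coordinate descent in C++
(active-set sweeps, convergence at a 1e-6 maximum coefficient change).
Covariates are standardized internally; coefficients return on the
original scale.

**Penalty choice.** `cvChooseLambda()` builds a 50-value log-spaced grid
from $\lambda_{max}$ (the smallest penalty zeroing everything) down to
$0.01\,\lambda_{max}$ and minimizes the Verweij–van Houwelingen
cross-validated partial-likelihood deviance over 10 folds stratified by
the event indicator. A capacity guard (`dfmax`, default half the event
count) stops the path once a fit grows past the number of parameters the
events can support; the cross-validation minimum has never been observed
in that region. Like every min-deviance rule, the chosen penalty admits
some winner's-curse noise genes; that is what the second step exists
for.

**Stepwise BIC.** The SCAD-selected set is pruned by backward-forward
stepwise search minimizing $-2\log PL + q \log d$ with $d$ the event
count (the standard effective sample size for Cox BIC), ties broken
toward the smaller model, followed by an unpenalized refit.
`stabilitySelection()` repeats the entire two-step on 70% subsamples and
reports per-gene selection frequencies.

**Risk score and stratification.** The risk score is the plain inner
product of model coefficients with the patient's gene CCFs — for the
packaged published eight-gene ESCC model:
score $= 1.18\,\mathrm{CCF}_{GPR98} + 1.31\,\mathrm{CCF}_{LAMA1} +
1.42\,\mathrm{CCF}_{IFT140} + 1.18\,\mathrm{CCF}_{MUC17} +
1.78\,\mathrm{CCF}_{PTPRB} - 1.37\,\mathrm{CCF}_{AHNAK2} -
2.78\,\mathrm{CCF}_{PREX2} - 3.02\,\mathrm{CCF}_{SPATA31D1}$, with
calibrated cutoffs $-0.0565$ and $0.168$ separating low, intermediate
and high risk. `partitionRisk()` re-derives such cutoffs on a cohort by
greedy recursive partitioning of the score axis: each step scans all
admissible cutpoints (at least 15 subjects per side) and takes the split
with the largest two-group log-rank statistic, until three leaves exist.

**Evaluation.** `tdAuc()` computes the cumulative-case / dynamic-control
AUC at a horizon (36 months by default) with inverse-probability-of-
censoring weights from the reverse Kaplan–Meier, and a seeded 200-
resample bootstrap SE. Two markers evaluated with the same seed share
their bootstrap resamples, so `compareAucZ()` can form the paired-
bootstrap Z statistic for the AUC difference — the package's concrete
reading of "AUCs compared by Z-test", chosen because the paired design
respects the strong within-cohort correlation of competing markers. The
proportional-hazards check is the classic Grambsch–Therneau
Schoenfeld-residual score test with KM-transformed time; it is
implemented directly (the revised variance used by newer `survival`
versions differs by a few percent) and is uniform under the null.

## The synthetic cohort generator

`presetDeepPanel()` encodes the study conditions the package is built
for: 201 patients (adjustable), a 548-gene panel with heavy-tailed
mutation frequencies (one hot gene at 60%, tiers at 15%, 8% and 4%,
about 44 mutations per patient), purity uniform on (0.3, 0.95),
negative-binomial depth with mean 1000x, one clonal population plus 1–4
subclones per patient (weights tilted so most patients carry at least
two), subclone CCFs uniform on (0.08, 0.85), and a 28.4% clonal
assignment probability giving roughly 71% subclonal mutations.
Survival is exponential with baseline hazard 0.028 per month on the
linear predictor of the eight published coefficients applied to the true
gene CCFs, under administrative (84 months) plus exponential censoring —
matching a ~65% three-year recurrence fraction and a ~34% three-year
DFS rate. `presetLowDepth()` differs only in its 55x mean depth and
demonstrates the loss of subclonal detection sensitivity at exome-like
coverage. Mutations are emitted as variant calls only when at least
three alt reads support them, a somatic caller's practical floor; the
truth tables keep everything.

What the simulator does **not** emulate: trinucleotide mutation spectra,
phylogenetic constraints between subclones, copy-number segments beyond
the mutated loci, germline contamination, or non-proportional hazards.
Passing recovery tests therefore demonstrates correctness of the
inference machinery under the stated generative model, not robustness to
every failure mode of real panels.

## Numerical choices and problem sizes

* CCF grid: 100 points, expected VAFs clipped to
  $[10^{-6}, 1-10^{-6}]$; posteriors normalized to 1e-9.
* Newton tolerance 1e-8 (gradient sup-norm); coordinate-descent and LLA
  tolerance 1e-6 (max coefficient change); IRLS curvature floored at
  1e-5.
* Maxstat candidates restricted to the inner 10–90% CCF quantiles; at
  least 10 mutants required; permutation p uses the add-one estimator
  $(1 + \#\{\text{exceedances}\})/(1 + B)$.
* Recursive partitioning: minimum leaf 15, at most 3 groups; ties in
  score midpoints cannot occur because cutpoints are midpoints of
  distinct values.
* Default seed 20211202; every stochastic routine takes an explicit
  seed.
* Test-suite problem sizes: recovery runs use 20 cohorts of 300
  patients at full panel size; calibration runs use 200 replicates of
  small (n = 60–200) designs; module simulations use 5–10 seeds at
  n = 150–400. These sizes keep the full suite in the tens of minutes
  on one CPU while leaving every statistical bound comfortably away
  from its Monte-Carlo noise floor.

## Known limitations

* Multiplicity is a single point estimate; mutation copy-number
  ambiguity (and LOH-aware multiplicity from minor copy number) is out
  of scope because the input carries no minor CN.
* The binomial clonality-preference null uses the cohort-wide subclonal
  fraction; other nulls (per-gene expected fractions under local copy
  number) would shift individual p values.
* CV-min penalty choice deliberately over-selects; interpret the SCAD
  stage as a screen and the stepwise-BIC stage as the model.
* The maxstat permutation test permutes CCFs against outcomes among
  mutants, which assumes exchangeability under the null within the
  mutant subset.
* Single-sample inference only: no multi-region or longitudinal
  phylogenetics.

## A minimal session

```{r example, eval = FALSE}
sim <- simulateCohort(presetDeepPanel(201), seed = 1)
report <- runPipeline(sim$cohort, seed = 1)
print(report)

## score new patients with the published model
model <- publishedRiskModel()
scores <- riskScore(model, report$matrix)
table(assignRiskGroup(model, scores))
```
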