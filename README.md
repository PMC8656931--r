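# ccfRisk

Recurrence-risk modelling from the **cancer cell fraction** (CCF) of
somatic mutations in targeted deep-sequencing cohorts.

Most mutation-based prognostic models treat a gene as mutant or
wildtype. In a heterogeneous tumor that throws away the most informative
part of the measurement: a mutation carried by 8% of tumor cells is not
the same observation as one carried by all of them. `ccfRisk` is built
for surgical ESCC (esophageal squamous cell carcinoma) panel cohorts and
similar designs, where ~1000x coverage makes the CCF of each mutation
estimable per patient. It implements the full analysis path:

* **CCF inference** — for alt/total read counts $(a,d)$, purity $\rho$,
  local total copy number $CN_t$ and multiplicity $m$, the expected VAF
  of a clone of size $c$ is $v(c) = c\,m\,\rho /(\rho\,CN_t +
  2(1-\rho))$; a uniform-prior grid posterior over $c$ gives the point
  estimate and $P(\mathrm{CCF} > 0.9)$, with mutations called clonal
  when that probability exceeds 0.5.
* **Subclonal architecture** — Gaussian-mixture counting of subclones on
  logit CCFs; exact binomial tests for genes preferring clonal or
  subclonal states.
* **CCF-dependent prognostic patterns** — each frequent gene is
  classified as CCF-independent, CCF-dominant (threshold found by
  maximally selected rank statistics with a selection-adjusted
  permutation p) or CCF dose-dependent.
* **Model building** — SCAD-penalized Cox regression (local linear
  approximation around a C++ coordinate-descent core) with 10-fold
  cross-validated penalty choice, stepwise BIC filtering, stability
  selection, and recursive-partitioning stratification of the risk score
  into low / intermediate / high groups.
* **Evaluation** — Kaplan–Meier with Greenwood log-log bands, log-rank
  tests, reverse-KM follow-up, IPCW time-dependent ROC at a 36-month
  horizon, and paired-bootstrap Z comparison of AUCs.
* **Synthetic cohorts** — `presetDeepPanel()` generates 201-patient,
  548-gene, 1000x cohorts with known clonal structure, planted survival
  coefficients and independent censoring, so every stage has a recovery
  test; `presetLowDepth()` is the 55x exome-like counterpart.

The package ships the published eight-gene ESCC recurrence model

```
score = 1.18 CCF_GPR98 + 1.31 CCF_LAMA1 + 1.42 CCF_IFT140 + 1.18 CCF_MUC17
      + 1.78 CCF_PTPRB - 1.37 CCF_AHNAK2 - 2.78 CCF_PREX2 - 3.02 CCF_SPATA31D1
```

with risk-group cutoffs −0.0565 and 0.168, available via
`publishedRiskModel()`.

## Worked example

Score a simulated deep-sequencing cohort with the packaged model:

```r
library(ccfRisk)

sim   <- simulateCohort(presetDeepPanel(201), seed = 1)
model <- publishedRiskModel()
est   <- inferCCF(sim$cohort)
se    <- buildGeneCCFMatrix(est, sim$cohort,
                            genes = sort(unique(variantCalls(sim$cohort)$gene)))
scores <- riskScore(model, se)
table(assignRiskGroup(model, scores))
#>          low intermediate         high
#>           71           50           80

cl <- clinicalData(sim$cohort)
logrankTest(assignRiskGroup(model, scores), cl$dfs_time, cl$dfs_event)
#> log-rank chisq 92.02, df 2, p = 1.04e-20
tdAuc(scores, cl$dfs_time, cl$dfs_event, horizon = 36, seed = 1)
#> tdAUC(model) at 36 months: 0.848 (bootstrap SE 0.029)
```

The three groups split the simulated cohort into sharply distinct
recurrence strata (the simulator plants the same eight coefficients the
model carries, so this is a positive control, not a validation), and the
36-month IPCW AUC quantifies discrimination while accounting for
censoring. A single mutation can be examined directly:

```r
ccfPosterior(alt = 300, depth = 1000, purity = 0.8, total_cn = 2)
#> CCFEstimate: ccf = 0.75, m = 1, P(CCF > 0.9) = 0.000 (subclonal)
```

`runPipeline(cohort)` chains every stage (CCF → matrix → screens and
patterns → two-step selection on the training cohort → stratification →
validation-set evaluation) and returns a report object;
`runPipelineConfig("cfg.yaml")` does the same from file paths, and
`inst/scripts/ccfrisk.R` wraps simulation and pipeline runs for the
shell.

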