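## Shared fixtures, all built in code.

## Six-subject survival fixture with one binary covariate and no ties:
## small enough for brute-force oracles. The covariate is interleaved
## across the death order so the partial-likelihood maximum is finite.
sixSubjectFixture <- function() {
  list(time = c(1, 2, 3, 4, 5, 6),
       event = c(1, 1, 1, 1, 0, 0),
       x = c(0, 1, 0, 1, 0, 1))
}

## Efron == Breslow partial likelihood for untied data; independent
## hand implementation used as the grid-search oracle.
plUntied <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    atRisk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[atRisk])))
  }
  ll
}

## Tiny three-sample cohort with explicit numbers.
toyCohort <- function() {
  variants <- data.frame(
    sample_id = c("S1", "S1", "S2", "S3"),
    gene = c("MUC17", "MUC17", "GPR98", "TP53"),
    chrom = c("1", "1", "2", "3"),
    pos = c(100L, 900L, 500L, 500L),
    ref = "C", alt = "T",
    alt_reads = c(150L, 400L, 250L, 100L),
    total_depth = c(1000L, 1000L, 1000L, 1000L),
    stringsAsFactors = FALSE)
  variants$vaf <- variants$alt_reads / variants$total_depth
  segments <- data.frame(
    sample_id = c("S1", "S2"),
    chrom = c("1", "2"),
    start = c(1L, 1L), end = c(1000L, 1000L),
    total_cn = c(2, 4), stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("S1", "S2", "S3"),
                        purity = c(1, 0.8, 0.6), stringsAsFactors = FALSE)
  clinical <- data.frame(
    sample_id = c("S1", "S2", "S3"),
    dfs_time = c(10, 20, 30), dfs_event = c(1L, 1L, 0L),
    os_time = c(12, 25, 30), os_event = c(1L, 0L, 0L),
    pN = c("N1", "N2-3", "N1"), stringsAsFactors = FALSE)
  suppressWarnings(EsccCohort(variants, segments, samples, clinical))
}

## Survival draw under proportional hazards with admin + exponential
## censoring; returns time/event.
phDraw <- function(lp, h0 = 0.03, censRate = 0.008, admin = 70) {
  n <- length(lp)
  tEv <- rexp(n, h0 * exp(lp))
  tC <- pmin(rexp(n, censRate), admin)
  list(time = pmin(tEv, tC), event = as.integer(tEv <= tC))
}

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
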