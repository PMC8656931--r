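test_that("locus copy number lookup is inclusive with diploid fallback", {
  co <- toyCohort()
  v <- variantCalls(co)
  expect_warning(cn <- locusCopyNumber(v, cnSegments(co)), "CN = 2")
  expect_equal(cn$total_cn, c(2, 2, 4, 2))      # S3 has no segment
  expect_equal(cn$cn_fallback, c(FALSE, FALSE, FALSE, TRUE))

  ## boundary position pos == end is covered (1-based inclusive)
  v2 <- v[1, ]; v2$pos <- 1000L
  cn2 <- locusCopyNumber(v2, cnSegments(co))
  expect_false(cn2$cn_fallback)
})

test_that("multiplicity point estimate follows the purity/CN formula", {
  expect_equal(estimateMultiplicity(0.5, 1, 2), 1L)
  expect_equal(estimateMultiplicity(0.8, 1, 2), 2L)   # round(1.6)
  expect_equal(estimateMultiplicity(0.05, 0.5, 2), 1L)  # clamped at 1
  expect_equal(estimateMultiplicity(0.99, 1, 2), 2L)  # clamped at CN
  expect_error(estimateMultiplicity(0.5, 0, 2), "purity")
})

test_that("grid posterior matches a brute-force normalization oracle", {
  ## pure diploid het at VAF 0.5: clonal with point estimate 1
  e1 <- ccfPosterior(500, 1000, purity = 1, total_cn = 2, m = 1)
  expect_equal(e1@ccfPoint, 1.00)
  expect_true(e1@isClonal)

  ## zero alt reads: mass at the smallest grid value, subclonal
  e2 <- ccfPosterior(0, 1000, purity = 1, total_cn = 2, m = 1)
  expect_equal(e2@ccfPoint, 0.01)
  expect_false(e2@isClonal)

  ## independent brute-force oracle over the 100-point grid
  alt <- 150; depth <- 1000; purity <- 0.6; cn <- 2; m <- 1
  grid <- seq(0.01, 1, by = 0.01)
  vaf <- pmin(pmax(grid * m * purity / (purity * cn + (1 - purity) * 2),
                   1e-6), 1 - 1e-6)
  lik <- dbinom(alt, depth, vaf)
  post <- lik / sum(lik)
  e3 <- ccfPosterior(alt, depth, purity, cn, m)
  expect_equal(e3@posterior, post, tolerance = 1e-12)
  expect_equal(e3@pClonal, sum(post[grid > 0.9]), tolerance = 1e-12)
  expect_equal(sum(e3@posterior), 1, tolerance = 1e-9)

  ## inconsistent multiplicity (expected VAF > 1 at CCF 1) is reduced
  expect_warning(e4 <- ccfPosterior(900, 1000, purity = 0.5, total_cn = 2,
                                    m = 6), "reduced")
  expect_equal(e4@multiplicity, 4L)   # largest m with expected VAF <= 1
})

test_that("ccf point estimate is monotone in alt and matches the
           identity limit", {
  pts <- vapply(seq(0, 1000, by = 50), function(alt)
    ccfPosterior(alt, 1000, 1, 2, m = 1)@ccfPoint, numeric(1))
  expect_true(all(diff(pts) >= 0))
  ## purity 1, CN 2, m 1: ccf = min(1, 2 vaf) within one grid step
  for (alt in c(100, 250, 333, 480)) {
    e <- ccfPosterior(alt, 1000, 1, 2, m = 1)
    expect_lte(abs(e@ccfPoint - min(1, 2 * alt / 1000)), 0.0100001)
  }
})

test_that("cohort-level inference assembles estimates with annotations", {
  co <- toyCohort()
  est <- suppressWarnings(inferCCF(co))
  expect_equal(nrow(est), 4L)
  expect_true(all(c("multiplicity", "ccf_point", "p_clonal",
                    "is_clonal") %in% names(est)))
  ## S1 diploid pure sample: VAF 0.15 -> CCF 0.30; VAF 0.4 -> 0.80
  expect_equal(est$ccf_point[1:2], c(0.30, 0.80))
  expect_true(all(abs(rowSums(
    ccfRisk:::.ccfPosteriorMatrix(est$alt_reads, est$total_depth,
                                  c(1, 1, 0.8, 0.6), est$total_cn,
                                  est$multiplicity)) - 1) < 1e-9))
})

test_that("clonality calls are calibrated at deep coverage", {
  set.seed(42)
  n <- 500
  ## true clonal, purity 0.8, diploid: expected VAF 0.4
  alt <- rbinom(n, 1000, 0.4)
  clonalCalls <- vapply(alt, function(a)
    ccfPosterior(a, 1000, 0.8, 2, m = 1)@isClonal, logical(1))
  expect_gte(mean(clonalCalls), 0.99)
  ## true CCF 0.2: expected VAF 0.08
  alt2 <- rbinom(n, 1000, 0.08)
  subCalls <- vapply(alt2, function(a)
    ccfPosterior(a, 1000, 0.8, 2, m = 1)@isClonal, logical(1))
  expect_gte(mean(!subCalls), 0.99)
})

test_that("subclone counting recovers planted mixtures", {
  ## all clonal: one cluster, zero subclones
  sm0 <- countSubclones(rep(1, 30))
  expect_equal(length(sm0@centers), 1L)
  expect_equal(sm0@nSubclones, 0L)

  ## too few mutations: flagged single-cluster model
  sm1 <- countSubclones(c(0.5, 0.6, 0.7))
  expect_true(sm1@flagged)
  expect_equal(length(sm1@centers), 1L)

  ## planted {1.0, 0.4} mixture, tight noise
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    ccf <- c(pmin(rnorm(50, 1.0, 0.03), 1), rnorm(50, 0.4, 0.04))
    sm <- countSubclones(ccf)
    if (length(sm@centers) == 2 &&
        all(abs(sort(sm@centers) - c(0.4, 1.0)) <= 0.05) &&
        sm@nSubclones == 1L) hits <- hits + 1
  }
  expect_gte(hits, 9)

  ## well-separated K = 3 recovered in >= 90% of seeds
  rec <- 0
  for (s in 1:10) {
    set.seed(s + 100)
    ccf <- c(pmin(rnorm(40, 0.95, 0.03), 1), rnorm(40, 0.6, 0.03),
             rnorm(40, 0.25, 0.03))
    if (length(countSubclones(ccf)@centers) == 3) rec <- rec + 1
  }
  expect_gte(rec, 9)
})

test_that("clonality preference test matches exact binomial enumeration", {
  g <- 0.716
  ## 8/8 subclonal: oracle = exhaustive two-sided tail over Binom(8, g)
  probs <- dbinom(0:8, 8, g)
  oracle <- sum(probs[probs <= dbinom(8, 8, g) * (1 + 1e-7)])
  est <- data.frame(gene = rep(c("FRYlike", "NULLG"), c(8, 10)),
                    is_clonal = c(rep(FALSE, 8),
                                  rep(c(TRUE, FALSE), 5)))
  res <- clonalityPreferenceTest(est, globalFraction = g)
  expect_equal(res$p_value[res$gene == "FRYlike"], oracle,
               tolerance = 1e-12)
  ## observed proportion equal to the null: p = 1
  est2 <- data.frame(gene = "G", is_clonal = rep(c(TRUE, FALSE), 4))
  expect_equal(clonalityPreferenceTest(est2, globalFraction = 0.5)$p_value,
               1)
  ## fdr adjusts across genes and preserves [0, 1]
  expect_true(all(res$fdr >= res$p_value - 1e-12 & res$fdr <= 1))
})

test_that("strong subclonal bias like the cohort's most skewed gene is
           flagged at small FDR", {
  ## 35/36 subclonal against a 0.716 cohort fraction
  est <- data.frame(
    gene = rep(c("FRY", paste0("N", 1:20)), c(36, rep(10, 20))),
    is_clonal = c(rep(c(FALSE, TRUE), c(35, 1)),
                  rep(rep(c(TRUE, FALSE), c(3, 7)), 20)))
  res <- clonalityPreferenceTest(est, globalFraction = 0.716)
  fry <- res[res$gene == "FRY", ]
  expect_gt(fry$n_subclonal / fry$n_mutations, 0.716)  # subclonal-biased
  expect_lt(fry$fdr, 0.05)
})

test_that("gene CCF matrix takes the per-gene maximum and keeps panel
           shape", {
  co <- toyCohort()
  est <- suppressWarnings(inferCCF(co))
  se <- buildGeneCCFMatrix(est, co, genes = c("GPR98", "MUC17", "TP53",
                                              "WILDTYPE1"))
  m <- SummarizedExperiment::assay(se, "ccf")
  expect_equal(dim(m), c(4L, 3L))
  expect_equal(m["MUC17", "S1"], 0.80)    # max of 0.30 and 0.80
  expect_equal(m["WILDTYPE1", "S1"], 0)
  expect_true(all(m >= 0 & m <= 1))

  b <- binarizeMatrix(se)
  bm <- SummarizedExperiment::assay(b, "status")
  expect_equal(dim(bm), dim(m))
  expect_equal(bm["MUC17", "S1"], 1)
  expect_equal(bm["WILDTYPE1", "S2"], 0)
})
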