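test_that("BH adjustment reproduces the hand computation", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.04, 0.9)
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("univariable screen filters by frequency and estimates hazard
           ratios", {
  set.seed(90)
  n <- 200
  status <- cbind(
    planted = rbinom(n, 1, 0.3),
    rare = rbinom(n, 1, 0.04),      # below the 5% filter
    null1 = rbinom(n, 1, 0.2),
    null2 = rbinom(n, 1, 0.25))
  sv <- phDraw(log(2.5) * status[, "planted"], h0 = 0.04)
  res <- univariableScreen(status, sv$time, sv$event)
  expect_false("rare" %in% res$alteration)
  ## HR equals the independent implementation's exp(coef)
  ref <- survival::coxph(survival::Surv(sv$time, sv$event) ~
                           status[, "planted"], ties = "efron")
  expect_equal(res$hazard_ratio[res$alteration == "planted"],
               unname(exp(coef(ref))), tolerance = 1e-6)
  expect_true(all(res$hazard_ratio > 0))
  expect_true(all(res$fdr >= res$p_value - 1e-12))
})

test_that("screen recovers a planted hazard ratio across seeds", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s + 90)
    n <- 200
    status <- matrix(rbinom(n, 1, 0.35), ncol = 1,
                     dimnames = list(NULL, "g"))
    sv <- phDraw(log(2.5) * status[, 1], h0 = 0.05, censRate = 0.005)
    res <- univariableScreen(status, sv$time, sv$event)
    if (nrow(res) == 1 && res$hazard_ratio >= 1.8 &&
        res$hazard_ratio <= 3.5) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("maxstat agrees with an exhaustive brute-force scan", {
  set.seed(101)
  n <- 12
  ccf <- round(runif(n, 0.1, 1), 2)
  sv <- phDraw(ccf)
  ms <- maxstatCutoff(ccf, sv$time, sv$event, nPerm = 50, seed = 1)

  ## independent oracle: Nelson-Aalen scores and per-split statistics
  ord <- order(sv$time)
  H <- numeric(n)
  for (i in 1:n) {
    dead <- which(sv$event == 1 & sv$time <= sv$time[i])
    H[i] <- sum(vapply(dead, function(j)
      1 / sum(sv$time >= sv$time[j]), numeric(1)))
  }
  a <- sv$event - H
  qr <- quantile(ccf, c(0.1, 0.9), names = FALSE)
  sccf <- sort(unique(ccf))
  cand <- (sccf[-1] + sccf[-length(sccf)]) / 2
  cand <- cand[cand >= qr[1] & cand <= qr[2]]
  stats <- vapply(cand, function(cut) {
    g <- ccf <= cut
    m1 <- sum(g)
    abs(sum(a[g]) - m1 * mean(a)) /
      sqrt(m1 * (n - m1) / (n * (n - 1)) * sum((a - mean(a))^2))
  }, numeric(1))
  expect_equal(ms$statistic, max(stats), tolerance = 1e-10)
  expect_equal(ms$cutoff, cand[which.max(stats)])

  ## degenerate inputs: constant CCF and too few mutants are flagged
  set.seed(5)
  tt20 <- rexp(20, 0.1); ev20 <- rbinom(20, 1, 0.8)
  expect_warning(msc <- maxstatCutoff(rep(0.5, 20), tt20, ev20),
                 "admissible")
  expect_true(msc$flagged)
  expect_warning(ms2 <- maxstatCutoff(ccf[1:5], sv$time[1:5], sv$event[1:5]),
                 "mutant")
  expect_true(ms2$flagged)
})

test_that("maxstat recovers a planted threshold across seeds", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 150
    ccf <- runif(n)
    sv <- phDraw(log(2) * (ccf > 0.6))
    ms <- maxstatCutoff(ccf, sv$time, sv$event, nPerm = 50, seed = s)
    if (abs(ms$cutoff - 0.6) <= 0.1) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("pattern cascade assigns exactly one label per planted scenario", {
  counts <- c(independent = 0, dominant = 0, dose_dependent = 0)
  cutoffs <- numeric(0)
  for (s in 1:10) {
    set.seed(s)
    n <- 300
    ## CCF-independent status effect
    ccfI <- ifelse(runif(n) < 0.3, round(runif(n, 0.1, 1), 2), 0)
    svI <- phDraw(log(2.2) * (ccfI > 0), h0 = 0.025)
    pI <- classifyPattern(ccfI, svI$time, svI$event, nPerm = 300, seed = s)
    ## threshold effect at CCF 0.9
    ccfD <- ifelse(runif(n) < 0.45, round(runif(n, 0.2, 1), 2), 0)
    svD <- phDraw(log(5) * (ccfD > 0.9), h0 = 0.025)
    pD <- classifyPattern(ccfD, svD$time, svD$event, nPerm = 300, seed = s)
    ## linear log-hazard in CCF
    ccfL <- ifelse(runif(n) < 0.4, round(runif(n, 0.05, 1), 2), 0)
    svL <- phDraw(1.8 * ccfL, h0 = 0.025)
    pL <- classifyPattern(ccfL, svL$time, svL$event, nPerm = 300, seed = s)

    for (p in list(pI, pD, pL)) {
      expect_true(p$pattern %in% c("independent", "dominant",
                                   "dose_dependent", "none"))
      ## cutoff present iff dominant
      expect_identical(!is.na(p$cutoff), p$pattern == "dominant")
    }
    counts["independent"] <- counts["independent"] +
      (pI$pattern == "independent")
    counts["dominant"] <- counts["dominant"] + (pD$pattern == "dominant")
    counts["dose_dependent"] <- counts["dose_dependent"] +
      (pL$pattern == "dose_dependent")
    if (pD$pattern == "dominant") cutoffs <- c(cutoffs, pD$cutoff)
  }
  expect_gte(counts[["independent"]], 8)
  expect_gte(counts[["dominant"]], 8)
  expect_gte(counts[["dose_dependent"]], 8)
  expect_lt(max(abs(cutoffs - 0.9)), 0.1)  # threshold located near 0.9

  ## genes below the frequency floor are refused
  expect_error(classifyPattern(c(rep(0, 98), 0.5, 0.6), rexp(100),
                               rbinom(100, 1, 0.5)), "5%")
})
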