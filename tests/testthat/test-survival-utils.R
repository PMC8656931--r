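test_that("KM estimate equals the hand product-limit computation", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))

  ## all censored: survival identically one
  km2 <- kmEstimate(c(5, 10), c(0, 0))
  expect_true(all(km2$surv == 1))

  ## brute-force product over risk sets on a random fixture with ties
  set.seed(150)
  tt <- sample(1:8, 30, replace = TRUE)
  ev <- rbinom(30, 1, 0.7)
  km3 <- kmEstimate(tt, ev)
  oracle <- vapply(km3$time, function(t) {
    prod(vapply(sort(unique(tt[ev == 1 & tt <= t])), function(u) {
      1 - sum(tt == u & ev == 1) / sum(tt >= u)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(km3$surv, oracle, tolerance = 1e-12)
  expect_true(all(diff(km3$surv) <= 1e-12))   # non-increasing

  expect_equal(kmAt(km3, 0.5)$surv, 1)        # before first time
})

test_that("reverse KM median follow-up flips the censoring indicator", {
  ## everyone censored at 49.1: median follow-up 49.1
  r <- reverseKmMedianFollowup(rep(49.1, 10), rep(0, 10))
  expect_equal(r$median, 49.1)

  ## all events: undefined, flagged
  expect_warning(r2 <- reverseKmMedianFollowup(1:10, rep(1, 10)),
                 "undefined")
  expect_true(is.na(r2$median))

  ## mixed fixture equals the KM median of the flipped indicator
  set.seed(151)
  tt <- rexp(80, 0.03); ev <- rbinom(80, 1, 0.5)
  r3 <- reverseKmMedianFollowup(tt, ev)
  km <- kmEstimate(tt, 1 - ev)
  expect_equal(r3$median, min(km$time[km$surv <= 0.5]))
})

test_that("log-rank test matches the observed-minus-expected oracle", {
  ## identical groups: statistic zero
  tt <- rep(c(2, 5, 9), 2); ev <- rep(1L, 6)
  g <- rep(c("a", "b"), each = 3)
  expect_lt(logrankTest(g, tt, ev)$chisq, 1e-10)

  expect_error(logrankTest(rep("a", 6), tt, ev), "two")

  ## small two-group fixture vs hand computation
  set.seed(152)
  tt2 <- rexp(24, 0.05); ev2 <- rbinom(24, 1, 0.8)
  g2 <- rep(0:1, each = 12)
  O <- E <- V <- 0
  for (u in sort(unique(tt2[ev2 == 1]))) {
    atRisk <- tt2 >= u
    n1 <- sum(atRisk & g2 == 1); N <- sum(atRisk)
    d <- sum(tt2 == u & ev2 == 1); d1 <- sum(tt2 == u & ev2 == 1 & g2 == 1)
    O <- O + d1; E <- E + d * n1 / N
    if (N > 1) V <- V + d * (n1 / N) * (1 - n1 / N) * (N - d) / (N - 1)
  }
  lr <- logrankTest(g2, tt2, ev2)
  expect_equal(lr$chisq, (O - E)^2 / V, tolerance = 1e-9)
  expect_equal(lr$df, 1L)
})

test_that("tdAUC reduces to the Mann-Whitney statistic without censoring
           and is calibrated under the null", {
  set.seed(153)
  n <- 300
  tt <- rexp(n, 0.04); ev <- rep(1L, n)
  ## perfect score: earlier events get higher scores
  expect_equal(tdAuc(-tt, tt, ev, horizon = 20, nBoot = 0)$auc, 1)
  ## random score equals U/(n1 n0)
  sc <- rnorm(n)
  r <- tdAuc(sc, tt, ev, horizon = 20, nBoot = 0)
  case <- tt <= 20
  u <- sum(outer(sc[case], sc[!case], ">")) +
    0.5 * sum(outer(sc[case], sc[!case], "=="))
  expect_equal(r$auc, u / (sum(case) * sum(!case)), tolerance = 1e-12)

  ## independent score, large n: AUC ~ 0.5
  set.seed(154)
  n2 <- 2000
  tt2 <- rexp(n2, 0.04)
  r2 <- tdAuc(rnorm(n2), tt2, rep(1L, n2), horizon = 20, nBoot = 0)
  expect_lt(abs(r2$auc - 0.5), 0.03)

  expect_error(tdAuc(rnorm(10), rep(50, 10), rep(1, 10), horizon = 20),
               "events before")
})

test_that("paired AUC comparison is antisymmetric and detects an
           informative marker", {
  set.seed(155)
  n <- 400
  lp <- rnorm(n)
  sv <- phDraw(1.2 * lp, h0 = 0.03)
  good <- tdAuc(lp, sv$time, sv$event, horizon = 24, nBoot = 100,
                seed = 7, label = "informative")
  noise <- tdAuc(rnorm(n), sv$time, sv$event, horizon = 24, nBoot = 100,
                 seed = 7, label = "noise")
  z1 <- compareAucZ(good, noise)
  z2 <- compareAucZ(noise, good)
  expect_equal(z1$z, -z2$z)
  expect_lt(z1$p, 0.05)
  ## identical scores: z = 0, p = 1
  same <- compareAucZ(good, good)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ## unpaired bootstraps are refused
  other <- tdAuc(lp, sv$time, sv$event, horizon = 24, nBoot = 100,
                 seed = 8)
  expect_error(compareAucZ(good, other), "seed")
})

test_that("the informative marker beats noise consistently across seeds", {
  wins <- 0
  for (s in 1:10) {
    set.seed(s + 160)
    n <- 400
    lp <- rnorm(n)
    sv <- phDraw(1.2 * lp, h0 = 0.03)
    good <- tdAuc(lp, sv$time, sv$event, horizon = 24, nBoot = 80,
                  seed = s)
    noise <- tdAuc(rnorm(n), sv$time, sv$event, horizon = 24, nBoot = 80,
                   seed = s)
    if (compareAucZ(good, noise)$p < 0.05) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("the proportional-hazards check matches a hand single-covariate
           computation and flags time-varying effects", {
  set.seed(170)
  n <- 80
  x <- rnorm(n)
  sv <- phDraw(0.5 * x, h0 = 0.04)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  mine <- phTest(X, sv$time, sv$event)

  ## hand computation: Schoenfeld residuals + KM-transform correlation
  fit <- coxFit(X, sv$time, sv$event)
  b <- fit$coefficients[[1]]
  dTimes <- sort(sv$time[sv$event == 1])
  sres <- vapply(dTimes, function(u) {
    i <- which(sv$time == u & sv$event == 1)[1]
    R <- sv$time >= u
    x[i] - sum(x[R] * exp(b * x[R])) / sum(exp(b * x[R]))
  }, numeric(1))
  kmf <- survival::survfit(survival::Surv(sv$time, sv$event) ~ 1)
  g <- 1 - c(1, kmf$surv)[findInterval(dTimes, kmf$time) + 1]
  gc <- g - mean(g)
  d <- length(dTimes)
  chisq <- (sum(gc * sres))^2 * d * fit$se[[1]]^2 / sum(gc^2)
  expect_equal(mine$chisq, chisq, tolerance = 1e-8)

  ## loose agreement with the survival package's revised test
  zph <- survival::cox.zph(
    survival::coxph(survival::Surv(sv$time, sv$event) ~ x,
                    ties = "efron"), transform = "km")
  expect_lt(abs(mine$chisq - zph$table[1, "chisq"]),
            0.25 * max(1, zph$table[1, "chisq"]))

  ## strongly time-varying planted effect is detected
  flags <- 0
  for (s in 1:10) {
    set.seed(s + 175)
    n2 <- 200
    x2 <- rnorm(n2)
    t1 <- rexp(n2, 0.05 * exp(1.2 * x2))
    tt <- ifelse(t1 <= 15, t1, 15 + rexp(n2, 0.05 * exp(-1.2 * x2)))
    ev <- as.integer(tt < 60)
    p <- phTest(matrix(x2, ncol = 1), pmin(tt, 60), ev)$p
    if (p < 0.05) flags <- flags + 1
  }
  expect_gte(flags, 8)
})

test_that("rate summaries format printed-count percentages", {
  expect_equal(rateSummary(55, 56)$percent, 98.2)
  expect_equal(rateSummary(194, 201)$percent, 96.5)
  expect_equal(rateSummary(0, 10)$percent, 0)
  expect_error(rateSummary(5, 0))
})
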