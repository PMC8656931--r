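test_that("SCAD penalty matches its closed form and is C1 at the joins", {
  expect_equal(scadPenalty(0, 2)$value, 0)
  expect_equal(scadPenalty(0.5, 1, 3.7)$value, 0.5)
  expect_equal(scadPenalty(2, 1, 3.7)$value,
               -(4 - 2 * 3.7 * 2 + 1) / (2 * 2.7), tolerance = 1e-12)
  expect_equal(scadPenalty(5, 1, 3.7)$value, 4.7 / 2, tolerance = 1e-12)
  expect_equal(scadPenalty(-5, 1, 3.7)$value, 2.35)  # symmetric in beta

  ## continuity of value and derivative at |b| = lambda and a*lambda
  lam <- 0.8; a <- 3.7
  for (b in c(lam, a * lam)) {
    lo <- scadPenalty(b - 1e-9, lam, a)
    hi <- scadPenalty(b + 1e-9, lam, a)
    expect_lt(abs(lo$value - hi$value), 1e-8)
    expect_lt(abs(lo$derivative - hi$derivative), 1e-8)
  }
  expect_error(scadPenalty(1, 1, a = 2), "exceed 2")
})

test_that("SCAD-Cox collapses to the unpenalized fit at lambda 0 and to
           zero at large lambda", {
  set.seed(21)
  n <- 120
  X <- cbind(g1 = rnorm(n), g2 = rnorm(n), g3 = rbinom(n, 1, 0.3))
  sv <- phDraw(0.8 * X[, 1] - 0.6 * X[, 3])
  free <- coxFit(X, sv$time, sv$event)
  sc0 <- fitScadCox(X, sv$time, sv$event, lambda = 0)
  expect_equal(unname(sc0$coefficients), unname(free$coefficients),
               tolerance = 1e-4)
  scBig <- fitScadCox(X, sv$time, sv$event, lambda = 10)
  expect_true(all(scBig$coefficients == 0))
})

test_that("SCAD leaves large coefficients unshrunk (unbiasedness region)", {
  set.seed(22)
  n <- 400
  x <- scale(rnorm(n))[, 1]
  sv <- phDraw(1.0 * x)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  free <- coxFit(X, sv$time, sv$event)
  lam <- 0.1           # a * lam = 0.37 << |beta_hat| ~ 1
  expect_gt(abs(free$coefficients[1]), 3.7 * lam)
  sc <- fitScadCox(X, sv$time, sv$event, lambda = lam)
  expect_equal(unname(sc$coefficients), unname(free$coefficients),
               tolerance = 1e-3)
})

test_that("cross-validated path is seed-deterministic with a monotone
           sparsity profile", {
  set.seed(23)
  n <- 150; p <- 25
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  sv <- phDraw(0.9 * X[, 1] - 0.9 * X[, 2])
  path1 <- cvChooseLambda(X, sv$time, sv$event, k = 5, seed = 99,
                          nlambda = 25)
  path2 <- cvChooseLambda(X, sv$time, sv$event, k = 5, seed = 99,
                          nlambda = 25)
  expect_identical(path1$beta, path2$beta)
  expect_identical(path1$cvm, path2$cvm)
  expect_true(all(is.finite(path1$cvm)))
  ## sparsity non-increasing in lambda, up to solver tolerance
  expect_true(all(diff(path1$nonzero) >= -1))
  expect_error(cvChooseLambda(X, sv$time, rep(0:1, c(n - 4, 4)), k = 10),
               "fewer events")
})

test_that("pure-noise designs select (near-)empty models", {
  empties <- 0
  for (s in 1:5) {
    set.seed(s + 30)
    n <- 150; p <- 30
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
    sv <- phDraw(rep(0, n))
    path <- cvChooseLambda(X, sv$time, sv$event, k = 5, seed = s,
                           nlambda = 25)
    fit <- fitScadCox(X, sv$time, sv$event, lambda = path$lambda_min)
    if (length(fit$selected) <= 2) empties <- empties + 1
  }
  expect_gte(empties, 4)
})

test_that("planted signals among nulls are recovered by the CV-tuned
           SCAD stage and pruned by the two-step", {
  superset <- 0
  fpScad <- fpStep <- integer(5)
  for (s in 1:5) {
    set.seed(s + 50)
    n <- 300; p <- 105
    ## CCF-like sparse design: zero when wildtype, CCF when mutated
    X <- matrix(round(runif(n * p, 0.2, 1), 2) * rbinom(n * p, 1, 0.35),
                n, p, dimnames = list(NULL, paste0("g", 1:p)))
    beta <- c(1.5, -1.3, 1.1, -0.9, 0.8, rep(0, p - 5))
    sv <- phDraw(drop(X %*% beta), h0 = 0.04)
    path <- cvChooseLambda(X, sv$time, sv$event, k = 10, seed = s)
    fit <- fitScadCox(X, sv$time, sv$event, lambda = path$lambda_min)
    trueSet <- paste0("g", 1:5)
    if (all(trueSet %in% fit$selected)) superset <- superset + 1
    fpScad[s] <- length(setdiff(fit$selected, trueSet))
    st <- suppressWarnings(stepwiseBIC(fit$selected, X, sv$time, sv$event))
    fpStep[s] <- length(setdiff(st$genes, trueSet))
  }
  ## every planted gene selected at the CV-chosen penalty in most seeds
  expect_gte(superset, 4)
  ## CV-min admits winner's-curse noise (as any CV-tuned selector does at
  ## this n/p); the model stays sparse and stepwise BIC prunes it further
  expect_lte(max(fpScad), 25)
  expect_true(mean(fpStep) <= mean(fpScad))
  expect_lte(max(fpStep), 10)
})

test_that("stepwise BIC drops noise, keeps signal, and matches the BIC
           arithmetic", {
  ## hand BIC on the six-subject fixture: stepwise must return whichever
  ## of {empty, x} has the smaller -2 logPL + q log(d)
  fx <- sixSubjectFixture()
  X <- matrix(fx$x, ncol = 1, dimnames = list(NULL, "x"))
  fit <- coxFit(X, fx$time, fx$event)
  d <- sum(fx$event)
  bicX <- -2 * fit$loglik + 1 * log(d)
  null <- vapply(which(fx$event == 1), function(i)
    -log(sum(fx$time >= fx$time[i])), numeric(1))
  bic0 <- -2 * sum(null)
  step <- stepwiseBIC("x", X, fx$time, fx$event)
  expect_equal(step$bic, min(bic0, bicX), tolerance = 1e-10)
  expect_identical(step$genes, if (bicX < bic0) "x" else character(0))

  ## strong + noise covariate: noise removed in most seeds
  drops <- 0
  for (s in 1:5) {
    set.seed(s + 70)
    n <- 400
    X2 <- cbind(strong = rnorm(n), noise = rnorm(n))
    sv <- phDraw(1.0 * X2[, 1])
    st <- stepwiseBIC(c("strong", "noise"), X2, sv$time, sv$event)
    if (identical(st$genes, "strong")) drops <- drops + 1
  }
  expect_gte(drops, 4)

  ## a covariate whose removal raises BIC is retained
  set.seed(77)
  n <- 300
  X3 <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "z"))
  sv <- phDraw(1.2 * X3[, 1])
  expect_identical(stepwiseBIC("z", X3, sv$time, sv$event)$genes, "z")

  expect_warning(empty <- stepwiseBIC(character(), X3, sv$time, sv$event),
                 "empty")
  expect_length(empty$genes, 0)
})

test_that("stability selection ranks planted genes above nulls and is
           reproducible", {
  set.seed(81)
  n <- 160; p <- 15
  X <- matrix(round(runif(n * p, 0.1, 1), 2) * rbinom(n * p, 1, 0.25),
              n, p, dimnames = list(NULL, paste0("g", 1:p)))
  sv <- phDraw(drop(X[, 1:2] %*% c(1.8, -1.8)))
  f1 <- stabilitySelection(X, sv$time, sv$event, nSubsamples = 10,
                           seed = 5, k = 5, nlambda = 20)
  f2 <- stabilitySelection(X, sv$time, sv$event, nSubsamples = 10,
                           seed = 5, k = 5, nlambda = 20)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0 & f1 <= 1))
  expect_gt(min(f1[c("g1", "g2")]), median(f1[paste0("g", 3:p)]))
})
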