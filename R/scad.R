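## SCAD-penalized Cox regression.
##
## The smoothly clipped absolute deviation (SCAD) penalty is a folded
## concave penalty that behaves like the lasso near zero but levels off,
## leaving large coefficients essentially unshrunk. The Cox solver uses
## the local linear approximation (LLA): each outer iteration replaces
## the SCAD penalty by a weighted L1 penalty with weights equal to the
## SCAD derivative at the current coefficients, and the resulting
## weighted-lasso Cox problem is solved by iteratively reweighted least
## squares around a C++ coordinate-descent kernel.

#' SCAD penalty and its derivative
#'
#' Piecewise form with shape parameter \code{a} (must exceed 2; the
#' canonical default is 3.7): \code{lambda * |b|} for \code{|b| <= lambda};
#' \code{-(b^2 - 2*a*lambda*|b| + lambda^2) / (2*(a - 1))} for
#' \code{lambda < |b| <= a*lambda}; constant \code{(a + 1) * lambda^2 / 2}
#' beyond. Value and derivative are continuous at both joins. Vectorized
#' in \code{beta}.
#'
#' @param beta Coefficient value(s).
#' @param lambda Penalty level, >= 0.
#' @param a Shape parameter, > 2 (default 3.7).
#' @return list with \code{value} and \code{derivative} (derivative with
#'   respect to \code{|beta|}, always >= 0).
#' @export
scadPenalty <- function(beta, lambda, a = 3.7) {
  if (a <= 2) stop("SCAD shape parameter a must exceed 2", call. = FALSE)
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  b <- abs(beta)
  value <- ifelse(b <= lambda, lambda * b,
           ifelse(b <= a * lambda,
                  -(b^2 - 2 * a * lambda * b + lambda^2) / (2 * (a - 1)),
                  (a + 1) * lambda^2 / 2))
  derivative <- ifelse(b <= lambda, lambda,
                pmax(a * lambda - b, 0) / (a - 1))
  list(value = value, derivative = derivative)
}

## Breslow log partial likelihood at beta (used for CV deviance scoring).
.coxBreslowLoglik <- function(beta, X, time, event) {
  eta <- drop(as.matrix(X) %*% beta)
  ord <- order(time)
  eta <- eta[ord]; ev <- event[ord]; tt <- time[ord]
  w <- exp(eta - max(eta))
  S0 <- rev(cumsum(rev(w)))               # sum over {j: t_j >= t_i}
  first <- match(tt, tt)                  # index of first subject with tied time
  sum(ev * (eta - max(eta) - log(S0[first])))
}

## Per-subject Breslow score (g = dl/deta) and curvature (w = -d2l/deta2
## diagonal approximation) for the IRLS working response. Fully
## vectorized over a single time-sorted pass.
.coxIrlsWeights <- function(eta, time, event) {
  ord <- order(time)
  rnk <- order(ord)
  eta <- eta[ord]; ev <- event[ord]; tt <- time[ord]
  w <- exp(eta - mean(eta))
  S0 <- rev(cumsum(rev(w)))
  rl <- rle(tt)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  grp <- rep.int(seq_along(ends), rl$lengths)
  S0first <- S0[starts][grp]              # risk-set sum at the subject's time
  inc <- ev / S0first                     # per-event hazard increments
  inc2 <- ev / S0first^2
  H <- cumsum(inc)[ends][grp]             # cumulative through the tie group
  G <- cumsum(inc2)[ends][grp]
  g <- ev - w * H
  wt <- pmax(w * H - w^2 * G, 1e-5)
  list(g = g[rnk], w = wt[rnk])
}

## Weighted-lasso Cox fit on standardized design, per-coefficient
## penalties lamVec; returns standardized-scale coefficients.
.coxLassoIrls <- function(Xs, time, event, lamVec, betaInit,
                          tol = 1e-6, maxit = 15) {
  beta <- betaInit
  for (it in seq_len(maxit)) {
    eta <- drop(Xs %*% beta)
    irls <- .coxIrlsWeights(eta, time, event)
    z <- eta + irls$g / irls$w
    betaNew <- cdWeightedLasso(Xs, irls$w, z, lamVec, beta, tol, 200L)
    if (max(abs(betaNew - beta)) < tol) { beta <- betaNew; break }
    beta <- betaNew
  }
  beta
}

.standardize <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  keep <- scl > 1e-10
  Xs <- sweep(X[, keep, drop = FALSE], 2, ctr[keep])
  Xs <- sweep(Xs, 2, scl[keep], "/")
  list(Xs = Xs, center = ctr, scale = scl, keep = keep)
}

## One SCAD-Cox fit at a given lambda via LLA; standardized-scale beta
## in/out (betaInit on standardized scale).
.scadCoxStd <- function(Xs, time, event, lambda, a, betaInit,
                        llaIter = 3, tol = 1e-6) {
  beta <- betaInit
  for (outer in seq_len(llaIter)) {
    lamVec <- scadPenalty(beta, lambda, a)$derivative
    betaNew <- .coxLassoIrls(Xs, time, event, lamVec, beta, tol = tol)
    if (max(abs(betaNew - beta)) < tol) { beta <- betaNew; break }
    beta <- betaNew
  }
  beta
}

#' Fit a SCAD-penalized Cox model at one penalty level
#'
#' Local-linear-approximation outer loop (SCAD derivative as
#' per-coefficient L1 weights) around an IRLS / coordinate-descent inner
#' solver. Covariates are standardized internally; coefficients are
#' returned on the original scale.
#'
#' @param X Covariate matrix (samples in rows, named columns).
#' @param time,event Survival outcome.
#' @param lambda Penalty level.
#' @param a SCAD shape parameter (default 3.7).
#' @param betaInit Optional warm start (original scale).
#' @return Object of class \code{"ccfScadFit"}: \code{coefficients}
#'   (named, original scale, exact zeros for excluded covariates),
#'   \code{selected} (names of nonzero coefficients), \code{lambda},
#'   \code{a}.
#' @export
fitScadCox <- function(X, time, event, lambda, a = 3.7, betaInit = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  std <- .standardize(X)
  init <- numeric(ncol(std$Xs))
  if (!is.null(betaInit))
    init <- (betaInit[std$keep] * std$scale[std$keep])
  bStd <- .scadCoxStd(std$Xs, time, event, lambda, a, init)
  beta <- setNames(numeric(ncol(X)), colnames(X))
  beta[std$keep] <- bStd / std$scale[std$keep]
  structure(list(coefficients = beta,
                 selected = names(beta)[beta != 0],
                 lambda = lambda, a = a),
            class = "ccfScadFit")
}

#' @export
print.ccfScadFit <- function(x, ...) {
  cat(sprintf("SCAD-Cox fit (lambda = %.4g, a = %.2f): %d nonzero\n",
              x$lambda, x$a, length(x$selected)))
  if (length(x$selected))
    print(round(x$coefficients[x$selected], 4))
  invisible(x)
}

#' Choose the SCAD penalty by cross-validated partial likelihood
#'
#' Computes the SCAD-Cox path on a 50-value log-spaced grid from
#' \code{lambda_max} (the smallest penalty zeroing every coefficient)
#' down to \code{0.01 * lambda_max}, then k-fold cross-validation with
#' folds stratified by the event indicator; the deviance is the
#' Verweij-van Houwelingen cross-validated partial likelihood. The chosen
#' penalty minimizes the mean deviance. Deterministic given \code{seed}.
#'
#' @param X Covariate matrix.
#' @param time,event Survival outcome.
#' @param k Number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param nlambda Grid size (default 50).
#' @param a SCAD shape parameter.
#' @param dfmax Solver capacity guard: the path stops descending once a
#'   fit retains more than this many covariates (the last fit is carried
#'   forward); defaults to half the number of events.
#' @return Object of class \code{"ccfScadPath"}: \code{lambda} (grid),
#'   \code{beta} (p x nlambda, original scale, full-data path),
#'   \code{nonzero}, \code{cvm}, \code{cvsd}, \code{lambda_min},
#'   \code{a}, \code{seed}.
#' @export
cvChooseLambda <- function(X, time, event, k = 10, seed = 20211202,
                           nlambda = 50, a = 3.7,
                           dfmax = max(10L, floor(sum(event) / 2))) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (sum(event) < k)
    stop("fewer events than folds; cross-validation undefined", call. = FALSE)
  std <- .standardize(X)
  Xs <- std$Xs
  irls0 <- .coxIrlsWeights(rep(0, nrow(Xs)), time, event)
  lambdaMax <- max(abs(crossprod(Xs, irls0$g))) / nrow(Xs)
  lambda <- exp(seq(log(lambdaMax), log(0.01 * lambdaMax),
                    length.out = nlambda))
  pathFit <- function(rows) {
    Xa <- X[rows, , drop = FALSE]
    stdA <- .standardize(Xa)
    betaStd <- numeric(ncol(stdA$Xs))
    out <- matrix(0, ncol(X), nlambda,
                  dimnames = list(colnames(X), NULL))
    for (l in seq_along(lambda)) {
      betaStd <- .scadCoxStd(stdA$Xs, time[rows], event[rows],
                             lambda[l], a, betaStd)
      out[stdA$keep, l] <- betaStd / stdA$scale[stdA$keep]
      if (sum(betaStd != 0) > dfmax) {    # dense tail: carry fit forward
        if (l < nlambda)
          out[, (l + 1L):nlambda] <- out[, l]
        break
      }
    }
    out
  }
  betaFull <- pathFit(seq_len(nrow(X)))
  ## event-stratified folds
  set.seed(seed)
  fold <- integer(nrow(X))
  for (e in unique(event)) {
    idx <- which(event == e)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  dev <- matrix(NA_real_, k, nlambda)
  for (f in seq_len(k)) {
    train <- which(fold != f)
    betaTrain <- pathFit(train)
    for (l in seq_len(nlambda)) {
      b <- betaTrain[, l]
      dev[f, l] <- -2 * (.coxBreslowLoglik(b, X, time, event) -
                         .coxBreslowLoglik(b, X[train, , drop = FALSE],
                                           time[train], event[train]))
    }
  }
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2, sd) / sqrt(k)
  structure(list(lambda = lambda, beta = betaFull,
                 nonzero = colSums(betaFull != 0),
                 cvm = cvm, cvsd = cvsd,
                 lambda_min = lambda[which.min(cvm)],
                 a = a, seed = seed),
            class = "ccfScadPath")
}

#' @export
print.ccfScadPath <- function(x, ...) {
  cat(sprintf(
    "SCAD-Cox path: %d lambdas in [%.4g, %.4g], lambda_min = %.4g (%d nonzero)\n",
    length(x$lambda), min(x$lambda), max(x$lambda), x$lambda_min,
    x$nonzero[which.min(x$cvm)]))
  invisible(x)
}

#' Stepwise Cox filtering by BIC
#'
#' Backward-forward stepwise search over the supplied candidate set,
#' minimizing \code{BIC = -2 logPL + q log(d)} where \code{q} is the
#' number of retained covariates and \code{d} the number of events. Ties
#' in BIC are broken toward the smaller model. An empty candidate set
#' returns an empty model with a warning.
#'
#' @param genes Candidate covariate names (typically the SCAD-selected
#'   set).
#' @param X Covariate matrix containing those columns.
#' @param time,event Survival outcome.
#' @return list with \code{genes} (final set), \code{fit} (the
#'   \code{\link{coxFit}} on the final set, or NULL when empty) and
#'   \code{bic}.
#' @export
stepwiseBIC <- function(genes, X, time, event) {
  X <- as.matrix(X)
  d <- sum(event)
  ## null log partial likelihood (Efron, consistent with coxFit)
  nullLoglik <- .coxEfron(numeric(1), matrix(0, nrow(X), 1), time, event)$loglik
  evalSet <- function(set) {
    if (!length(set)) return(list(bic = -2 * nullLoglik, fit = NULL))
    fit <- coxFit(X[, set, drop = FALSE], time, event)
    list(bic = -2 * fit$loglik + length(set) * log(d), fit = fit)
  }
  if (!length(genes)) {
    warning("empty candidate set; returning empty model")
    return(list(genes = character(), fit = NULL, bic = -2 * nullLoglik))
  }
  current <- genes
  cache <- new.env()
  getEval <- function(set) {
    key <- paste0("s:", paste(sort(set), collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- evalSet(set)
    cache[[key]] <- val
    val
  }
  best <- getEval(current)
  repeat {
    moves <- list()
    for (g in current)
      moves[[length(moves) + 1L]] <- setdiff(current, g)
    for (g in setdiff(genes, current))
      moves[[length(moves) + 1L]] <- c(current, g)
    if (!length(moves)) break
    sizes <- vapply(moves, length, integer(1))
    ord <- order(sizes)                   # smaller models first: tie-break
    improved <- FALSE
    bestMove <- NULL; bestEval <- best
    for (i in ord) {
      ev <- getEval(moves[[i]])
      if (ev$bic < bestEval$bic - 1e-9 ||
          (abs(ev$bic - bestEval$bic) <= 1e-9 &&
           length(moves[[i]]) < length(if (is.null(bestMove)) current
                                       else bestMove))) {
        bestMove <- moves[[i]]; bestEval <- ev; improved <- TRUE
      }
    }
    if (!improved) break
    current <- bestMove; best <- bestEval
  }
  list(genes = current, fit = best$fit, bic = best$bic)
}

#' Two-step variable selection
#'
#' The full selection pipeline used for model building: SCAD-Cox with
#' cross-validated penalty choice, followed by stepwise BIC filtering of
#' the SCAD-selected genes and an unpenalized refit.
#'
#' @param X Gene-level CCF matrix (samples x genes).
#' @param time,event Survival outcome.
#' @param k CV folds.
#' @param seed RNG seed.
#' @param nlambda Penalty grid size.
#' @param a SCAD shape parameter.
#' @return list with \code{path} (the CV path), \code{scad_selected},
#'   \code{genes}, \code{fit} (final unpenalized Cox fit) and
#'   \code{model} (a \code{\linkS4class{RiskModel}} without cutoffs).
#' @export
selectTwoStep <- function(X, time, event, k = 10, seed = 20211202,
                          nlambda = 50, a = 3.7) {
  path <- cvChooseLambda(X, time, event, k = k, seed = seed,
                         nlambda = nlambda, a = a)
  sfit <- fitScadCox(X, time, event, lambda = path$lambda_min, a = a)
  step <- suppressWarnings(stepwiseBIC(sfit$selected, X, time, event))
  coefs <- if (length(step$genes)) step$fit$coefficients else numeric(0)
  list(path = path,
       scad_selected = sfit$selected,
       genes = step$genes,
       fit = step$fit,
       model = new("RiskModel",
                   genes = step$genes,
                   coefficients = unname(coefs),
                   cutoffs = numeric(0)))
}

#' Stability selection for the two-step pipeline
#'
#' Repeats the full two-step selection (\code{\link{selectTwoStep}}) on
#' random subsamples of the cohort and reports, per gene, the fraction of
#' subsamples in which it was retained in the final model.
#'
#' @param X Covariate matrix.
#' @param time,event Survival outcome.
#' @param nSubsamples Number of subsamples (default 100).
#' @param subsampleFrac Fraction of samples drawn without replacement
#'   (default 0.7).
#' @param seed RNG seed.
#' @param k,nlambda,a Passed to \code{\link{selectTwoStep}}.
#' @return Named numeric vector of selection frequencies in [0, 1].
#' @export
stabilitySelection <- function(X, time, event, nSubsamples = 100,
                               subsampleFrac = 0.7, seed = 20211202,
                               k = 10, nlambda = 50, a = 3.7) {
  X <- as.matrix(X)
  count <- setNames(numeric(ncol(X)), colnames(X))
  n <- nrow(X)
  for (b in seq_len(nSubsamples)) {
    set.seed(seed + b)
    rows <- sort(sample.int(n, floor(subsampleFrac * n)))
    if (sum(event[rows]) < k) next
    sel <- tryCatch(
      selectTwoStep(X[rows, , drop = FALSE], time[rows], event[rows],
                    k = k, seed = seed + b, nlambda = nlambda, a = a)$genes,
      error = function(e) character())
    count[sel] <- count[sel] + 1
  }
  count / nSubsamples
}
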