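## Cox proportional-hazards machinery: Efron-tied partial likelihood with
## analytic gradient/Hessian and a Newton-Raphson fitter. This is the
## unpenalized backbone used by the univariable screen, the stepwise BIC
## filter and the final model refits; the high-dimensional SCAD path has
## its own IRLS/coordinate-descent solver (see scad.R).

## Efron log partial likelihood, gradient and Hessian at beta.
## X: n x p matrix; time/event vectors. Returns list(loglik, grad, hess).
## Single descending pass: the risk-set sums S0/S1/S2 are accumulated
## incrementally per tie group, so the total cost is O(n p^2).
.coxEfron <- function(beta, X, time, event) {
  p <- ncol(X)
  ord <- order(time)
  X <- X[ord, , drop = FALSE]; time <- time[ord]; event <- event[ord]
  eta <- drop(X %*% beta)
  eta <- eta - mean(eta)                  # numeric stability only
  w <- exp(eta)
  rl <- rle(time)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  loglik <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  for (b in rev(seq_along(ends))) {
    idx <- starts[b]:ends[b]
    Xb <- X[idx, , drop = FALSE]
    sw <- sqrt(w[idx])
    S0 <- S0 + sum(w[idx])
    S1 <- S1 + colSums(w[idx] * Xb)
    S2 <- S2 + crossprod(sw * Xb)
    D <- idx[event[idx] == 1]
    d <- length(D)
    if (!d) next
    XD <- X[D, , drop = FALSE]
    wD <- w[D]
    sD <- sum(wD); xD <- colSums(wD * XD)
    qD <- crossprod(sqrt(wD) * XD)
    loglik <- loglik + sum(eta[D])
    for (k in seq_len(d) - 1L) {
      f <- k / d
      s <- S0 - f * sD
      xbar <- (S1 - f * xD) / s
      loglik <- loglik - log(s)
      grad <- grad - xbar
      hess <- hess - ((S2 - f * qD) / s - tcrossprod(xbar))
    }
    grad <- grad + colSums(XD)
  }
  list(loglik = loglik, grad = grad, hess = hess)
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the Efron-tied log partial likelihood,
#' iterated until the gradient sup-norm falls below \code{tol}. Constant
#' covariates are dropped with a warning; monotone-likelihood separation
#' (a coefficient running away) is detected and flagged.
#'
#' @param X Covariate matrix (samples in rows) or data.frame.
#' @param time,event Survival times (> 0) and 0/1 event indicators.
#' @param tol Convergence tolerance on the gradient sup-norm
#'   (default 1e-8).
#' @param maxit Maximum Newton iterations (default 100).
#' @return An object of class \code{"ccfCoxFit"}: list with
#'   \code{coefficients}, \code{se}, \code{loglik} (at the optimum),
#'   \code{loglik_null}, \code{ties = "efron"}, \code{iterations},
#'   \code{converged}, \code{separated} (flagged covariates),
#'   \code{dropped} (constant covariates), \code{n}, \code{nevent}.
#' @export
coxFit <- function(X, time, event, tol = 1e-8, maxit = 100) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(time), length(time) == length(event),
            all(event %in% c(0, 1)))
  if (sum(event) == 0) stop("no events; Cox model undefined", call. = FALSE)
  const <- apply(X, 2, function(col) max(col) - min(col) == 0)
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (!ncol(X)) stop("no usable covariates", call. = FALSE)
  p <- ncol(X)
  beta <- numeric(p)
  pl <- .coxEfron(beta, X, time, event)
  loglik0 <- pl$loglik
  converged <- FALSE
  it <- 0
  while (it < maxit) {
    it <- it + 1
    if (max(abs(pl$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(pl$hess + diag(1e-10, p), pl$grad),
                     error = function(e) pl$grad / (abs(diag(pl$hess)) + 1e-8))
    betaNew <- beta - step
    plNew <- .coxEfron(betaNew, X, time, event)
    halv <- 0
    while (plNew$loglik < pl$loglik - 1e-12 && halv < 30) {
      halv <- halv + 1
      betaNew <- beta - step / 2^halv
      plNew <- .coxEfron(betaNew, X, time, event)
    }
    beta <- betaNew; pl <- plNew
  }
  separated <- colnames(X)[abs(beta) > 15]
  if (length(separated))
    warning("possible monotone likelihood (separation) for: ",
            paste(separated, collapse = ", "))
  if (!converged && !length(separated))
    stop(sprintf(
      "Cox fit did not converge in %d iterations (grad sup-norm %.3g)",
      maxit, max(abs(pl$grad))), call. = FALSE)
  covb <- tryCatch(solve(-pl$hess), error = function(e)
    matrix(NA_real_, p, p))
  structure(list(
    coefficients = setNames(beta, colnames(X)),
    se = setNames(sqrt(pmax(diag(covb), 0)), colnames(X)),
    loglik = pl$loglik,
    loglik_null = loglik0,
    ties = "efron",
    iterations = it,
    converged = converged,
    separated = separated,
    dropped = if (any(const)) names(const)[const] else character(),
    n = length(time),
    nevent = sum(event)
  ), class = "ccfCoxFit")
}

#' @export
print.ccfCoxFit <- function(x, ...) {
  cat("Cox model (Efron ties),", x$n, "subjects,", x$nevent, "events\n")
  z <- x$coefficients / x$se
  tab <- data.frame(coef = x$coefficients, HR = exp(x$coefficients),
                    se = x$se, z = z, p = 2 * pnorm(-abs(z)))
  print(signif(tab, 4))
  invisible(x)
}

## Wald summary for one covariate of a fit.
.coxWald <- function(fit, name = names(fit$coefficients)[1]) {
  b <- fit$coefficients[[name]]; s <- fit$se[[name]]
  z <- b / s
  list(hr = exp(b), lo = exp(b - 1.96 * s), hi = exp(b + 1.96 * s),
       p = 2 * pnorm(-abs(z)))
}
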