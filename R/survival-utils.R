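## Kaplan-Meier, log-rank, reverse KM, IPCW time-dependent ROC and the
## proportional-hazards check. KM curves and the k-group log-rank go
## through the survival package; the tdAUC estimator and the paired
## bootstrap AUC comparison are implemented here.

#' Kaplan-Meier estimate with Greenwood log-log confidence bands
#'
#' @param time,event Survival outcome (times > 0, event 0/1).
#' @return data.frame with \code{time}, \code{n_risk}, \code{n_event},
#'   \code{surv}, \code{lower}, \code{upper} (95\% CI, log-log
#'   transform), one row per distinct observed time.
#' @export
kmEstimate <- function(time, event) {
  stopifnot(length(time) >= 1, all(event %in% c(0, 1)))
  fit <- survfit(Surv(time, event) ~ 1, conf.type = "log-log")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv, lower = fit$lower, upper = fit$upper)
}

#' Survival probability at a horizon
#'
#' Reads the KM estimate at the last event-or-censoring time not after
#' \code{horizon} (1 before the first).
#'
#' @param km data.frame from \code{\link{kmEstimate}}.
#' @param horizon Time point (months).
#' @return Survival probability (and CI) at the horizon.
#' @export
kmAt <- function(km, horizon) {
  idx <- which(km$time <= horizon)
  if (!length(idx)) return(data.frame(surv = 1, lower = 1, upper = 1))
  km[max(idx), c("surv", "lower", "upper")]
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' KM with the censoring indicator as the event; the median of that curve
#' estimates the follow-up duration. Undefined (flagged NA) when no
#' subject is censored.
#'
#' @param time,event Survival outcome.
#' @return list with \code{median} and \code{ci} (95\%).
#' @export
reverseKmMedianFollowup <- function(time, event) {
  cens <- 1 - event
  if (sum(cens) == 0) {
    warning("no censored subjects; median follow-up undefined")
    return(list(median = NA_real_, ci = c(NA_real_, NA_real_)))
  }
  fit <- survfit(Surv(time, cens) ~ 1, conf.type = "log-log")
  q <- quantile(fit, probs = 0.5)
  list(median = unname(q$quantile), ci = c(unname(q$lower), unname(q$upper)))
}

#' k-group log-rank test
#'
#' @param groups Group labels (>= 2 non-empty groups).
#' @param time,event Survival outcome.
#' @return list with \code{chisq}, \code{df} (k - 1) and \code{p}.
#' @export
logrankTest <- function(groups, time, event) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2)
    stop("log-rank test needs at least two non-empty groups", call. = FALSE)
  sd <- survdiff(Surv(time, event) ~ groups)
  df <- nlevels(groups) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

## Censoring-survival weights G(t) = P(C > t) from the reverse KM,
## evaluated just before t (left limit).
.censorSurv <- function(time, event) {
  fit <- survfit(Surv(time, 1 - event) ~ 1)
  function(t) {
    s <- c(1, fit$surv)[findInterval(t - 1e-9, fit$time) + 1L]
    pmax(s, 1e-6)
  }
}

.aucIpcw <- function(scores, time, event, horizon, Gfun) {
  case <- which(time <= horizon & event == 1)
  ctrl <- which(time > horizon)
  if (!length(case) || !length(ctrl)) return(NA_real_)
  wc <- 1 / Gfun(time[case])
  wk <- rep(1 / Gfun(horizon)[1], length(ctrl))
  cmp <- outer(scores[case], scores[ctrl], ">") +
         0.5 * outer(scores[case], scores[ctrl], "==")
  ww <- outer(wc, wk)
  sum(ww * cmp) / sum(ww)
}

#' Time-dependent ROC AUC with IPCW
#'
#' Cumulative-case / dynamic-control AUC at a horizon: cases are subjects
#' with an event by the horizon, controls those still event-free beyond
#' it; contributions are weighted by inverse probability of censoring
#' from the reverse Kaplan-Meier. A seeded bootstrap (200 resamples)
#' provides the standard error; the replicate AUCs are retained so that
#' two markers evaluated with the same seed share resamples for a paired
#' comparison.
#'
#' @param scores Numeric risk scores (higher = riskier).
#' @param time,event Survival outcome.
#' @param horizon Evaluation time in months (default 36).
#' @param nBoot Bootstrap resamples for the SE (default 200).
#' @param seed RNG seed for the bootstrap.
#' @param label Model label carried into the result.
#' @return Object of class \code{"ccfTdRoc"}: \code{auc}, \code{se},
#'   \code{horizon}, \code{n_case}, \code{n_control}, \code{boot}
#'   (replicate AUCs), \code{label}, \code{seed}.
#' @export
tdAuc <- function(scores, time, event, horizon = 36, nBoot = 200,
                  seed = 20211202, label = "model") {
  stopifnot(length(scores) == length(time))
  if (!any(time <= horizon & event == 1))
    stop("no events before the horizon; AUC undefined", call. = FALSE)
  if (!any(time > horizon))
    stop("no subjects at risk beyond the horizon", call. = FALSE)
  Gfun <- .censorSurv(time, event)
  auc <- .aucIpcw(scores, time, event, horizon, Gfun)
  boot <- rep(NA_real_, nBoot)
  if (nBoot > 0) {
    set.seed(seed)
    n <- length(scores)
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot[b] <- tryCatch(
        .aucIpcw(scores[idx], time[idx], event[idx], horizon,
                 .censorSurv(time[idx], event[idx])),
        error = function(e) NA_real_)
    }
  }
  structure(list(auc = auc, se = sd(boot, na.rm = TRUE), horizon = horizon,
                 n_case = sum(time <= horizon & event == 1),
                 n_control = sum(time > horizon),
                 boot = boot, label = label, seed = seed),
            class = "ccfTdRoc")
}

#' @export
print.ccfTdRoc <- function(x, ...) {
  cat(sprintf("tdAUC(%s) at %g months: %.3f (bootstrap SE %.3f)\n",
              x$label, x$horizon, x$auc, x$se))
  invisible(x)
}

#' Compare two time-dependent AUCs by paired-bootstrap Z-test
#'
#' Both AUCs must come from \code{\link{tdAuc}} runs on the same cohort,
#' horizon and bootstrap seed, so that replicate b of each used the same
#' resampled subjects; the Z statistic is the AUC difference divided by
#' the standard deviation of the paired replicate differences.
#'
#' @param a,b \code{"ccfTdRoc"} objects.
#' @return list with \code{z}, \code{p} (two-sided normal),
#'   \code{auc_diff}, \code{se_diff}.
#' @export
compareAucZ <- function(a, b) {
  stopifnot(inherits(a, "ccfTdRoc"), inherits(b, "ccfTdRoc"))
  if (a$horizon != b$horizon)
    stop("AUCs evaluated at different horizons", call. = FALSE)
  if (length(a$boot) != length(b$boot) || a$seed != b$seed)
    stop("paired comparison needs shared bootstrap resamples (same seed)",
         call. = FALSE)
  d <- a$boot - b$boot
  seDiff <- sd(d, na.rm = TRUE)
  if (!is.finite(seDiff) || seDiff == 0) {
    if (isTRUE(all.equal(a$auc, b$auc)))
      return(list(z = 0, p = 1, auc_diff = 0, se_diff = 0))
    stop("zero variance of paired AUC differences", call. = FALSE)
  }
  z <- (a$auc - b$auc) / seDiff
  list(z = z, p = 2 * pnorm(-abs(z)), auc_diff = a$auc - b$auc,
       se_diff = seDiff)
}

#' Proportional-hazards check
#'
#' Schoenfeld-residual score test of the proportional-hazards assumption
#' (Grambsch-Therneau): per event time the Schoenfeld residual is
#' correlated with the KM-transformed time \code{g(t) = 1 - S_KM(t)};
#' the global statistic is \code{u' V u d / sum((g - gbar)^2)} with
#' \code{u = sum (g_k - gbar) s_k} and \code{V} the coefficient
#' covariance, referred to a chi-square with p degrees of freedom.
#'
#' @param X Covariate matrix or data.frame.
#' @param time,event Survival outcome.
#' @return list with \code{p} (global), \code{chisq}, \code{df},
#'   \code{table} (per-covariate chi-square and p).
#' @export
phTest <- function(X, time, event) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fit <- coxFit(X, time, event)
  beta <- fit$coefficients
  X <- X[, names(beta), drop = FALSE]
  p <- ncol(X)
  ord <- order(time)
  tt <- time[ord]; ev <- event[ord]; Xs <- X[ord, , drop = FALSE]
  w <- exp(drop(Xs %*% beta))
  dIdx <- which(ev == 1)
  ## Schoenfeld residual at each event: x_k minus risk-set weighted mean
  resid <- matrix(NA_real_, length(dIdx), p)
  for (i in seq_along(dIdx)) {
    k <- dIdx[i]
    R <- which(tt >= tt[k])
    xbar <- colSums(w[R] * Xs[R, , drop = FALSE]) / sum(w[R])
    resid[i, ] <- Xs[k, ] - xbar
  }
  kmf <- survfit(Surv(time, event) ~ 1)
  g <- 1 - c(1, kmf$surv)[findInterval(tt[dIdx], kmf$time) + 1L]
  gc <- g - mean(g)
  d <- length(dIdx)
  V <- tryCatch(solve(-.coxEfron(beta, X, time, event)$hess),
                error = function(e) matrix(NA_real_, p, p))
  u <- drop(crossprod(gc, resid))
  denom <- sum(gc^2)
  chisq <- drop(t(u) %*% V %*% u) * d / denom
  perCov <- (u^2) * d * diag(V) / denom
  tab <- data.frame(chisq = perCov, df = 1,
                    p = pchisq(perCov, 1, lower.tail = FALSE),
                    row.names = names(beta))
  list(p = pchisq(chisq, p, lower.tail = FALSE), chisq = chisq, df = p,
       table = tab)
}

#' Percentage summary of a count
#'
#' Report utility for printed confirmation-rate style numbers: formats a
#' numerator/denominator count as a percentage rounded to one decimal.
#'
#' @param numerator,denominator Non-negative counts.
#' @return list with \code{fraction} and \code{percent}.
#' @export
rateSummary <- function(numerator, denominator) {
  stopifnot(denominator > 0, numerator >= 0, numerator <= denominator)
  frac <- numerator / denominator
  list(fraction = frac, percent = round(100 * frac, 1))
}
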