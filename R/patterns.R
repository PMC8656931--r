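## Survival screening of alterations and classification of CCF-dependent
## prognostic patterns. A mutated gene's effect on outcome can be
## CCF-independent (any mutation shifts the hazard), CCF-dominant (the
## effect switches on above a CCF threshold, found by maximally selected
## rank statistics) or CCF dose-dependent (log-hazard changes with CCF as
## a continuous exposure).

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; adjusted values are monotone after sorting and
#' never smaller than the raw p values.
#'
#' @param p Numeric p values in [0, 1].
#' @return Adjusted values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Univariable survival screen of binary alterations
#'
#' Fits a univariable Cox model per alteration (mutation status or
#' gene-level CNA as a 0/1 covariate). Only alterations with cohort
#' frequency of at least \code{minFreq} (default 5\%) enter the screen;
#' p values are BH-adjusted across the tested set. Alterations for which
#' the fit degenerates (e.g. complete separation) are skipped and listed
#' in the \code{"skipped"} attribute.
#'
#' @param status Binary alteration matrix: a \code{SummarizedExperiment}
#'   with assay \code{"status"} (alterations in rows) or a plain
#'   samples-by-alterations 0/1 matrix.
#' @param time,event Survival outcome, in sample order of \code{status}.
#' @param minFreq Frequency filter applied before testing (default 0.05).
#' @param endpoint Label ("DFS" or "OS") carried into the result.
#' @return data.frame with \code{alteration}, \code{frequency},
#'   \code{hazard_ratio}, \code{ci_low}, \code{ci_high}, \code{p_value},
#'   \code{fdr}, \code{endpoint}.
#' @export
univariableScreen <- function(status, time, event, minFreq = 0.05,
                              endpoint = "DFS") {
  m <- if (is(status, "SummarizedExperiment"))
    t(assay(status, 1)) else as.matrix(status)
  stopifnot(nrow(m) == length(time))
  freq <- colMeans(m > 0)
  keep <- which(freq >= minFreq & freq < 1)
  skipped <- character()
  rows <- list()
  for (j in keep) {
    alt <- colnames(m)[j]
    fit <- tryCatch(
      suppressWarnings(coxFit(m[, j, drop = FALSE], time, event)),
      error = function(e) NULL)
    if (is.null(fit) || length(fit$separated) || !is.finite(fit$se[1])) {
      skipped <- c(skipped, alt)
      next
    }
    w <- .coxWald(fit)
    rows[[length(rows) + 1L]] <- data.frame(
      alteration = alt, frequency = freq[j],
      hazard_ratio = w$hr, ci_low = w$lo, ci_high = w$hi,
      p_value = w$p, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(alteration = character(), frequency = numeric(),
               hazard_ratio = numeric(), ci_low = numeric(),
               ci_high = numeric(), p_value = numeric())
  out$fdr <- bhAdjust(out$p_value)
  out$endpoint <- rep(endpoint, nrow(out))
  rownames(out) <- NULL
  out <- out[order(out$p_value), , drop = FALSE]
  attr(out, "skipped") <- skipped
  out
}

#' Maximally selected rank statistic cutoff
#'
#' Finds, among the mutant samples, the CCF cutoff maximizing the
#' standardized two-group log-rank statistic. Log-rank scores are
#' \code{a_i = event_i - NelsonAalen(t_i)}; the statistic at a cutoff c
#' is the standardized sum of scores of samples with CCF <= c. Candidate
#' cutoffs are midpoints of adjacent distinct CCF values restricted to
#' the inner 10-90\% quantile range. The p value comes from permuting the
#' CCF values against the survival outcome (which accounts for the cutoff
#' search). With fewer than \code{minMutants} samples or no admissible
#' candidate the result is flagged and carries no cutoff.
#'
#' @param ccf CCF values of the mutant samples.
#' @param time,event Their survival outcome.
#' @param nPerm Permutations for the selection-adjusted p (default
#'   10000).
#' @param seed RNG seed for the permutations.
#' @param minMutants Minimum number of mutants (default 10).
#' @return list with \code{cutoff}, \code{statistic}, \code{p},
#'   \code{candidates}, \code{stats} (statistic per candidate),
#'   \code{flagged}.
#' @export
maxstatCutoff <- function(ccf, time, event, nPerm = 10000,
                          seed = 20211202, minMutants = 10) {
  n <- length(ccf)
  noCut <- list(cutoff = NA_real_, statistic = NA_real_, p = NA_real_,
                candidates = numeric(), stats = numeric(), flagged = TRUE)
  if (n < minMutants) {
    warning(sprintf("only %d mutant(s); no cutoff search", n))
    return(noCut)
  }
  a <- .logrankScores(time, event)
  ord <- order(ccf)
  ccfS <- ccf[ord]; aS <- a[ord]
  qr <- quantile(ccf, c(0.1, 0.9), names = FALSE)
  ## split after position k: cutoff = midpoint of ccfS[k], ccfS[k+1]
  kset <- which(diff(ccfS) > 0)
  mids <- (ccfS[kset] + ccfS[kset + 1]) / 2
  adm <- mids >= qr[1] & mids <= qr[2]
  kset <- kset[adm]; mids <- mids[adm]
  if (!length(kset)) {
    warning("no admissible cutoff (CCF values too concentrated)")
    return(noCut)
  }
  sdA <- sqrt(sum((a - mean(a))^2))
  stdStat <- function(scores) {
    cs <- cumsum(scores)[kset]
    abs(cs - kset * mean(scores)) /
      (sqrt(kset * (n - kset) / (n * (n - 1))) * sdA)
  }
  obsStats <- stdStat(aS)
  obs <- max(obsStats)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    if (max(stdStat(sample(a))) >= obs - 1e-12) exceed <- exceed + 1L
  }
  list(cutoff = mids[which.max(obsStats)],
       statistic = obs,
       p = (1 + exceed) / (1 + nPerm),
       candidates = mids,
       stats = obsStats,
       flagged = FALSE)
}

## Log-rank scores: event indicator minus Nelson-Aalen cumulative hazard
## at the subject's time; they sum to zero.
.logrankScores <- function(time, event) {
  ord <- order(time)
  tt <- time[ord]; ev <- event[ord]
  n <- length(tt)
  rl <- rle(tt)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  grp <- rep.int(seq_along(ends), rl$lengths)
  dGrp <- diff(c(0, cumsum(ev)[ends]))    # deaths per distinct time
  inc <- dGrp / (n - starts + 1)          # Nelson-Aalen increments
  H <- cumsum(inc)[grp]                   # includes the subject's own time
  (ev - H)[order(ord)]
}

#' Classify the CCF pattern of a gene's prognostic effect
#'
#' Decision cascade using exactly three tools, most specific first:
#' (a) the continuous-CCF Cox model among mutant samples
#' (\code{dose_dependent}); (b) the maximally selected rank statistic's
#' permutation test (\code{dominant}, with the selected cutoff); (c) the
#' mutant-vs-wildtype log-rank test (\code{independent}); (d) else
#' \code{none}. A threshold effect also induces a significant linear
#' trend, so when (a) and (b) both reach significance the two
#' single-parameter Cox models among mutants (linear CCF vs.
#' above-cutoff indicator) are compared by partial likelihood and the
#' better-fitting shape wins. No multiple-testing correction is applied
#' inside the cascade.
#'
#' @param ccf Gene CCF values for all samples (0 = wildtype).
#' @param time,event Survival outcome.
#' @param gene,endpoint Labels carried into the result.
#' @param alpha Significance level of each cascade step (default 0.05).
#' @param nPerm Permutations for the maxstat p.
#' @param seed RNG seed.
#' @param minFreq Minimum mutant frequency (default 0.05).
#' @return One-row data.frame: \code{gene}, \code{endpoint},
#'   \code{pattern} (one of independent / dominant / dose_dependent /
#'   none), \code{cutoff} (non-NA iff dominant), \code{logrank_p},
#'   \code{ccf_cox_p}, \code{ccf_cox_sign}, \code{maxstat_p},
#'   \code{maxstat_cutoff}.
#' @export
classifyPattern <- function(ccf, time, event, gene = "gene",
                            endpoint = "DFS", alpha = 0.05, nPerm = 1000,
                            seed = 20211202, minFreq = 0.05) {
  stopifnot(length(ccf) == length(time))
  mut <- ccf > 0
  if (mean(mut) < minFreq)
    stop(sprintf("gene mutated in %.1f%% of samples (< %.0f%%); not tested",
                 100 * mean(mut), 100 * minFreq), call. = FALSE)
  lrP <- tryCatch(logrankTest(mut, time, event)$p, error = function(e) NA)
  coxP <- NA_real_; coxSign <- NA_real_
  if (sum(event[mut]) >= 2 && sd(ccf[mut]) > 0) {
    cfit <- tryCatch(
      suppressWarnings(coxFit(matrix(ccf[mut], ncol = 1,
                                     dimnames = list(NULL, "ccf")),
                              time[mut], event[mut])),
      error = function(e) NULL)
    if (!is.null(cfit) && !length(cfit$separated) && is.finite(cfit$se[1])) {
      coxP <- .coxWald(cfit)$p
      coxSign <- sign(cfit$coefficients[1])
    }
  }
  ms <- suppressWarnings(
    maxstatCutoff(ccf[mut], time[mut], event[mut], nPerm = nPerm,
                  seed = seed))
  coxSig <- is.finite(coxP) && coxP < alpha
  msSig <- !ms$flagged && is.finite(ms$p) && ms$p < alpha
  pattern <- "none"; cutoff <- NA_real_
  if (coxSig && msSig) {
    llOf <- function(xcol) {
      fit <- tryCatch(
        suppressWarnings(coxFit(matrix(xcol, ncol = 1), time[mut],
                                event[mut])),
        error = function(e) NULL)
      if (is.null(fit)) -Inf else fit$loglik
    }
    ## the cutoff is itself fitted by maximization, so the threshold
    ## model must beat the linear one by more than its expected
    ## selection advantage (two log-likelihood units)
    if (llOf((ccf[mut] > ms$cutoff) + 0) - 2 > llOf(ccf[mut])) {
      pattern <- "dominant"; cutoff <- ms$cutoff
    } else pattern <- "dose_dependent"
  } else if (coxSig) {
    pattern <- "dose_dependent"
  } else if (msSig) {
    pattern <- "dominant"; cutoff <- ms$cutoff
  } else if (is.finite(lrP) && lrP < alpha) {
    pattern <- "independent"
  }
  data.frame(gene = gene, endpoint = endpoint, pattern = pattern,
             cutoff = cutoff, logrank_p = lrP, ccf_cox_p = coxP,
             ccf_cox_sign = unname(coxSign), maxstat_p = ms$p,
             maxstat_cutoff = ms$cutoff, stringsAsFactors = FALSE)
}
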