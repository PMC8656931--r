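## The gene-level CCF risk score and its stratification into prognosis
## groups by recursive partitioning of the score axis.

#' The packaged published eight-gene recurrence model
#'
#' Loads the published esophageal squamous cell carcinoma eight-gene CCF
#' risk model shipped with the package: the linear score
#' \deqn{1.18\,CCF_{GPR98} + 1.31\,CCF_{LAMA1} + 1.42\,CCF_{IFT140} +
#'       1.18\,CCF_{MUC17} + 1.78\,CCF_{PTPRB} - 1.37\,CCF_{AHNAK2} -
#'       2.78\,CCF_{PREX2} - 3.02\,CCF_{SPATA31D1}}
#' with risk-group cutoffs -0.0565 and 0.168 (score <= first cutoff: low;
#' above second: high; between: intermediate).
#'
#' @return A \code{\linkS4class{RiskModel}}.
#' @export
publishedRiskModel <- function() {
  path <- system.file("extdata", "published_model.tsv", package = "ccfRisk",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  new("RiskModel", genes = tab$gene, coefficients = tab$coefficient,
      cutoffs = c(-0.0565, 0.168))
}

#' Read / write a risk model as TSV
#'
#' Plain-text model exchange format: a gene/coefficient table, with the
#' two cutoffs (if calibrated) in a \code{# cutoffs:} header comment.
#'
#' @param model A \code{\linkS4class{RiskModel}}.
#' @param path File path.
#' @return \code{readRiskModel}: a \code{RiskModel};
#'   \code{writeRiskModel}: \code{path} invisibly.
#' @export
writeRiskModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(riskCutoffs(model)))
    writeLines(sprintf("# cutoffs: %.10g %.10g", riskCutoffs(model)[1],
                       riskCutoffs(model)[2]), con)
  writeLines("gene\tcoefficient", con)
  writeLines(sprintf("%s\t%.10g", modelGenes(model),
                     unname(modelCoefficients(model))), con)
  invisible(path)
}

#' @rdname writeRiskModel
#' @export
readRiskModel <- function(path) {
  lines <- readLines(path)
  cutoffs <- numeric(0)
  hdr <- grep("^# cutoffs:", lines, value = TRUE)
  if (length(hdr))
    cutoffs <- as.numeric(strsplit(sub("^# cutoffs:\\s*", "", hdr[1]),
                                   "\\s+")[[1]])
  tab <- read.delim(text = paste(grep("^#", lines, invert = TRUE,
                                      value = TRUE), collapse = "\n"),
                    stringsAsFactors = FALSE)
  new("RiskModel", genes = tab$gene, coefficients = tab$coefficient,
      cutoffs = cutoffs)
}

#' Risk score of a model on gene-level CCFs
#'
#' The plain inner product of the model coefficients with the per-gene
#' CCFs; genes absent from the input count as wildtype (CCF 0). No
#' intercept.
#'
#' @param model A \code{\linkS4class{RiskModel}}.
#' @param ccf A named numeric vector (one patient), a samples-by-genes
#'   matrix, or a \code{SummarizedExperiment} from
#'   \code{\link{buildGeneCCFMatrix}}.
#' @return Numeric score(s), named by sample for matrix input.
#' @export
riskScore <- function(model, ccf) {
  stopifnot(is(model, "RiskModel"))
  beta <- modelCoefficients(model)
  if (is(ccf, "SummarizedExperiment")) ccf <- t(assay(ccf, "ccf"))
  if (is.null(dim(ccf))) {
    vals <- setNames(numeric(length(beta)), names(beta))
    hit <- intersect(names(ccf), names(beta))
    vals[hit] <- ccf[hit]
    return(sum(beta * vals))
  }
  m <- as.matrix(ccf)
  full <- matrix(0, nrow(m), length(beta),
                 dimnames = list(rownames(m), names(beta)))
  hit <- intersect(colnames(m), names(beta))
  full[, hit] <- m[, hit]
  drop(full %*% beta)
}

## Two-group log-rank chi-square (score split at a cutoff); used by the
## recursive partitioning scan. survdiff is exact but slow in a tight
## loop, so this is a direct observed-minus-expected computation.
.logrank2 <- function(grp, time, event) {
  ord <- order(time)
  g <- grp[ord]; tt <- time[ord]; ev <- event[ord]
  n <- length(tt)
  dt <- unique(tt[ev == 1])
  O <- E <- V <- 0
  for (t in dt) {
    at <- tt >= t
    n1 <- sum(at & g); n0 <- sum(at) - n1
    d <- sum(tt == t & ev == 1)
    d1 <- sum(tt == t & ev == 1 & g)
    N <- n1 + n0
    if (N < 2) next
    O <- O + d1
    E <- E + d * n1 / N
    V <- V + d * (n1 / N) * (n0 / N) * (N - d) / (N - 1)
  }
  if (V <= 0) return(0)
  (O - E)^2 / V
}

#' Stratify patients by recursive partitioning of the risk score
#'
#' Greedy binary splits of the one-dimensional score axis: each step
#' scans all admissible cutpoints (midpoints of adjacent distinct
#' scores leaving at least \code{minLeaf} subjects per side) in every
#' current leaf, and takes the split with the largest two-group log-rank
#' statistic; splitting stops at \code{maxGroups} leaves or when no
#' admissible split remains. Groups are labelled low / intermediate /
#' high in ascending score order.
#'
#' @param scores Numeric risk scores.
#' @param time,event Survival outcome.
#' @param maxGroups Number of leaves to grow (default 3).
#' @param minLeaf Minimum subjects per leaf (default 15).
#' @return Object of class \code{"ccfStratification"}: \code{cutoffs}
#'   (ascending), \code{group} (factor low/intermediate/high per
#'   subject), \code{km} (per-group \code{\link{kmEstimate}} tables),
#'   \code{logrank} (k-group test across final groups), \code{flagged}.
#' @export
partitionRisk <- function(scores, time, event, maxGroups = 3,
                          minLeaf = 15) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 2 * minLeaf || length(unique(scores)) == 1) {
    if (length(unique(scores)) == 1)
      warning("all scores identical; no stratification")
    return(.stratify(scores, numeric(0), time, event, flagged = TRUE))
  }
  bestSplitIn <- function(idx) {
    s <- sort(unique(scores[idx]))
    if (length(s) < 2) return(NULL)
    mids <- (s[-1] + s[-length(s)]) / 2
    best <- NULL
    for (cut in mids) {
      left <- scores[idx] <= cut
      if (sum(left) < minLeaf || sum(!left) < minLeaf) next
      stat <- .logrank2(left, time[idx], event[idx])
      if (is.null(best) || stat > best$stat)
        best <- list(cut = cut, stat = stat)
    }
    best
  }
  cutoffs <- numeric(0)
  repeat {
    nGroups <- length(cutoffs) + 1L
    if (nGroups >= maxGroups) break
    leaves <- split(seq_len(n),
                    findInterval(scores, sort(cutoffs)))
    cand <- lapply(leaves, bestSplitIn)
    stats <- vapply(cand, function(x) if (is.null(x)) -Inf else x$stat,
                    numeric(1))
    if (!length(stats) || all(!is.finite(stats))) break
    pick <- cand[[which.max(stats)]]
    cutoffs <- sort(c(cutoffs, pick$cut))
  }
  .stratify(scores, cutoffs, time, event,
            flagged = length(cutoffs) < maxGroups - 1L)
}

.stratify <- function(scores, cutoffs, time, event, flagged = FALSE) {
  labs <- switch(as.character(length(cutoffs) + 1L),
                 "1" = "all",
                 "2" = c("low", "high"),
                 "3" = c("low", "intermediate", "high"),
                 paste0("g", seq_len(length(cutoffs) + 1L)))
  grp <- factor(labs[findInterval(scores, sort(cutoffs)) + 1L],
                levels = labs)
  km <- lapply(split(seq_along(scores), grp), function(idx)
    if (length(idx)) kmEstimate(time[idx], event[idx]) else NULL)
  lr <- if (nlevels(droplevels(grp)) >= 2)
    logrankTest(grp, time, event) else NULL
  structure(list(cutoffs = cutoffs, group = grp, km = km,
                 logrank = lr, flagged = flagged),
            class = "ccfStratification")
}

#' @export
print.ccfStratification <- function(x, ...) {
  cat("Risk stratification:", nlevels(x$group), "group(s)")
  if (length(x$cutoffs))
    cat(" at cutoffs", paste(signif(x$cutoffs, 4), collapse = ", "))
  cat("\n")
  print(table(x$group))
  if (!is.null(x$logrank))
    cat(sprintf("log-rank chi-square %.2f (df %d), p = %.3g\n",
                x$logrank$chisq, x$logrank$df, x$logrank$p))
  invisible(x)
}

#' Assign risk groups from calibrated model cutoffs
#'
#' @param model A \code{\linkS4class{RiskModel}} with cutoffs.
#' @param scores Numeric risk scores.
#' @return factor with levels low / intermediate / high.
#' @export
assignRiskGroup <- function(model, scores) {
  cuts <- riskCutoffs(model)
  if (length(cuts) != 2)
    stop("model carries no calibrated cutoffs", call. = FALSE)
  labs <- c("low", "intermediate", "high")
  factor(labs[findInterval(scores, cuts) + 1L], levels = labs)
}
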