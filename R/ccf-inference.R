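## Cancer cell fraction inference.
##
## For a mutation with multiplicity m at a locus of tumor total copy
## number CN_t in a sample of purity rho, a clone of size c (the CCF)
## produces the expected variant allele fraction
##     v(c) = c * m * rho / (rho * CN_t + (1 - rho) * 2),
## assuming a diploid normal locus. The posterior over c is evaluated on
## a 100-point grid (0.01 .. 1.00) with a uniform prior and a binomial
## read-count likelihood; a mutation is called clonal when the posterior
## probability of c > 0.9 exceeds 0.5.

.CCF_GRID <- seq(0.01, 1, by = 0.01)
.CLONAL_BOUNDARY <- 0.9

#' Total copy number at each variant locus
#'
#' Looks up, per variant, the copy-number segment of the same sample and
#' chromosome covering its position (segment ends inclusive). Loci not
#' covered by any segment fall back to the diploid value 2 and are
#' flagged; the number of fallbacks is reported in one warning.
#'
#' @param variants Variant table (see \code{\link{readVariants}}).
#' @param segments Segment table (see \code{\link{readSegments}}).
#' @return data.frame with columns \code{total_cn} and \code{cn_fallback},
#'   one row per variant.
#' @export
locusCopyNumber <- function(variants, segments) {
  n <- nrow(variants)
  cn <- rep(2, n)
  fb <- rep(TRUE, n)
  if (nrow(segments)) {
    segKey <- paste(segments$sample_id, segments$chrom)
    varKey <- paste(variants$sample_id, variants$chrom)
    segSplit <- split(seq_len(nrow(segments)), segKey)
    for (key in intersect(unique(varKey), names(segSplit))) {
      vi <- which(varKey == key)
      si <- segSplit[[key]]
      for (i in vi) {
        hit <- si[segments$start[si] <= variants$pos[i] &
                  segments$end[si] >= variants$pos[i]]
        if (length(hit)) { cn[i] <- segments$total_cn[hit[1]]; fb[i] <- FALSE }
      }
    }
  }
  if (any(fb) && n)
    warning(sprintf("%d variant(s) not covered by any segment; using CN = 2",
                    sum(fb)))
  data.frame(total_cn = cn, cn_fallback = fb)
}

#' Mutation multiplicity from VAF, purity and copy number
#'
#' Point estimate of the number of mutant copies per mutated cell:
#' \code{m = max(1, round(vaf * (purity * cn + (1 - purity) * 2) / purity))},
#' clamped above by the rounded total copy number. Vectorized.
#'
#' @param vaf Variant allele fraction(s) in [0, 1].
#' @param purity Tumor purity in (0, 1].
#' @param total_cn Tumor total copy number at the locus.
#' @return Integer multiplicities.
#' @export
estimateMultiplicity <- function(vaf, purity, total_cn) {
  if (any(purity <= 0 | purity > 1))
    stop("purity must lie in (0, 1]", call. = FALSE)
  m <- pmax(1, round(vaf * (purity * total_cn + (1 - purity) * 2) / purity))
  as.integer(pmin(m, pmax(1, round(total_cn))))
}

## Log-likelihood matrix over the CCF grid for vectors of variants;
## returns (n_variants x n_grid) normalized posterior.
.ccfPosteriorMatrix <- function(alt, depth, purity, total_cn, m) {
  denom <- purity * total_cn + (1 - purity) * 2
  vafPerCcf <- m * purity / denom          # expected VAF at CCF = 1
  ll <- outer(vafPerCcf, .CCF_GRID)        # expected VAF at each grid point
  ll <- pmin(pmax(ll, 1e-6), 1 - 1e-6)
  ll <- alt * log(ll) + (depth - alt) * log1p(-ll)
  ll <- ll - apply(ll, 1, max)
  post <- exp(ll)
  post / rowSums(post)
}

#' Posterior CCF for one mutation
#'
#' Evaluates the grid posterior for a single variant. When the supplied
#' multiplicity implies an expected VAF above 1 at CCF = 1 it is reduced
#' to the largest consistent value with a warning.
#'
#' @param alt Alt read count.
#' @param depth Total depth (\code{alt <= depth}).
#' @param purity Tumor purity in (0, 1].
#' @param total_cn Tumor total copy number at the locus.
#' @param m Multiplicity (defaults to \code{\link{estimateMultiplicity}}
#'   on the observed VAF).
#' @return A \code{\linkS4class{CCFEstimate}}.
#' @export
ccfPosterior <- function(alt, depth, purity, total_cn,
                         m = estimateMultiplicity(alt / depth, purity,
                                                  total_cn)) {
  stopifnot(length(alt) == 1L, alt >= 0, depth >= alt, m >= 1)
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  denom <- purity * total_cn + (1 - purity) * 2
  if (m * purity / denom > 1) {
    mNew <- max(1L, as.integer(floor(denom / purity)))
    warning(sprintf("multiplicity %d implies VAF > 1; reduced to %d", m, mNew))
    m <- mNew
  }
  post <- .ccfPosteriorMatrix(alt, depth, purity, total_cn, m)[1, ]
  pClonal <- sum(post[.CCF_GRID > .CLONAL_BOUNDARY])
  new("CCFEstimate",
      multiplicity = as.integer(m),
      grid = .CCF_GRID,
      posterior = post,
      ccfPoint = .CCF_GRID[which.max(post)],
      pClonal = pClonal,
      isClonal = pClonal > 0.5)
}

#' Infer CCFs for every variant of a cohort
#'
#' Runs the full per-mutation inference: locus copy number lookup,
#' multiplicity estimation, grid posterior, clonality call.
#'
#' @param cohort An \code{\linkS4class{EsccCohort}}.
#' @return The variant table extended with \code{total_cn},
#'   \code{cn_fallback}, \code{multiplicity}, \code{ccf_point},
#'   \code{p_clonal}, \code{is_clonal}.
#' @export
inferCCF <- function(cohort) {
  v <- variantCalls(cohort)
  if (!nrow(v)) {
    v[c("total_cn", "cn_fallback", "multiplicity",
        "ccf_point", "p_clonal")] <- numeric(0)
    v$is_clonal <- logical(0)
    return(v)
  }
  cn <- locusCopyNumber(v, cnSegments(cohort))
  purity <- sampleInfo(cohort)$purity[
    match(v$sample_id, sampleInfo(cohort)$sample_id)]
  m <- estimateMultiplicity(v$vaf, purity, cn$total_cn)
  post <- .ccfPosteriorMatrix(v$alt_reads, v$total_depth, purity,
                              cn$total_cn, m)
  v$total_cn <- cn$total_cn
  v$cn_fallback <- cn$cn_fallback
  v$multiplicity <- m
  v$ccf_point <- .CCF_GRID[max.col(post, ties.method = "first")]
  v$p_clonal <- rowSums(post[, .CCF_GRID > .CLONAL_BOUNDARY, drop = FALSE])
  v$is_clonal <- v$p_clonal > 0.5
  v
}

#' Count tumor subclones in one sample
#'
#' Fits one-dimensional Gaussian mixtures to the logit-transformed CCF
#' point estimates of a sample's mutations for K = 1 .. \code{maxClusters}
#' components and selects K by BIC. Clusters whose back-transformed
#' center lies below the clonal boundary (0.9) are counted as subclones.
#' Samples with fewer than five mutations return a flagged single-cluster
#' model.
#'
#' @param ccf Numeric vector of per-mutation CCF point estimates.
#' @param sampleId Sample label carried into the result.
#' @param maxClusters Maximum number of mixture components (default 6).
#' @return A \code{\linkS4class{SubcloneModel}}.
#' @export
countSubclones <- function(ccf, sampleId = "sample", maxClusters = 6) {
  ccf <- ccf[!is.na(ccf)]
  single <- function(flag) new("SubcloneModel",
    sampleId = sampleId,
    centers = if (length(ccf)) mean(ccf) else numeric(0),
    weights = if (length(ccf)) 1 else numeric(0),
    assignments = rep(1L, length(ccf)),
    nSubclones = if (length(ccf) && mean(ccf) < .CLONAL_BOUNDARY) 1L else 0L,
    flagged = flag)
  if (length(ccf) < 5L) return(single(TRUE))
  x <- qlogis(pmin(pmax(ccf, 0.005), 0.995))
  if (sd(x) < 1e-8) {
    fit <- single(FALSE)
    return(fit)
  }
  mc <- Mclust(x, G = seq_len(maxClusters), modelNames = c("E", "V"),
               verbose = FALSE)
  if (is.null(mc)) return(single(TRUE))
  centers <- pmin(plogis(as.numeric(mc$parameters$mean)), 1)
  weights <- as.numeric(mc$parameters$pro)
  cl <- as.integer(mc$classification)
  ## merge components closer than 0.05 on the CCF scale: the boundary
  ## clamp can split one subpopulation into near-identical pieces
  repeat {
    ord <- order(centers)
    centers <- centers[ord]; weights <- weights[ord]
    cl <- match(cl, ord)
    gap <- diff(centers)
    if (!length(gap) || min(gap) >= 0.05) break
    j <- which.min(gap)
    wsum <- weights[j] + weights[j + 1]
    centers[j] <- (centers[j] * weights[j] +
                   centers[j + 1] * weights[j + 1]) / wsum
    weights[j] <- wsum
    centers <- centers[-(j + 1)]; weights <- weights[-(j + 1)]
    cl[cl > j] <- cl[cl > j] - 1L
  }
  new("SubcloneModel",
      sampleId = sampleId,
      centers = centers,
      weights = weights,
      assignments = cl,
      nSubclones = sum(centers < .CLONAL_BOUNDARY),
      flagged = FALSE)
}

#' Per-gene clonality preference test
#'
#' Tests, per gene, whether its mutations are more often subclonal (or
#' clonal) than the cohort-wide subclonal fraction, with a two-sided
#' exact binomial test; p values are BH-adjusted across genes. Genes with
#' no mutations are excluded.
#'
#' @param estimates CCF table from \code{\link{inferCCF}} (needs columns
#'   \code{gene}, \code{is_clonal}).
#' @param globalFraction Cohort-wide subclonal fraction; defaults to the
#'   fraction observed in \code{estimates}.
#' @return data.frame with \code{gene}, \code{n_mutations},
#'   \code{n_subclonal}, \code{expected_fraction}, \code{p_value},
#'   \code{fdr}, sorted by p value.
#' @export
clonalityPreferenceTest <- function(estimates,
                                    globalFraction = mean(!estimates$is_clonal)) {
  stopifnot(globalFraction >= 0, globalFraction <= 1)
  est <- estimates[!is.na(estimates$gene), , drop = FALSE]
  if (!nrow(est))
    return(data.frame(gene = character(), n_mutations = integer(),
                      n_subclonal = integer(), expected_fraction = numeric(),
                      p_value = numeric(), fdr = numeric()))
  nTot <- table(est$gene)
  nSub <- tapply(!est$is_clonal, est$gene, sum)
  genes <- names(nTot)
  p <- vapply(genes, function(g)
    binom.test(nSub[[g]], nTot[[g]], p = globalFraction,
               alternative = "two.sided")$p.value, numeric(1))
  out <- data.frame(gene = genes,
                    n_mutations = as.integer(nTot),
                    n_subclonal = as.integer(nSub),
                    expected_fraction = globalFraction,
                    p_value = unname(p),
                    fdr = p.adjust(unname(p), method = "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$p_value), , drop = FALSE]
}

#' Assemble the gene-level CCF matrix
#'
#' Builds a \code{SummarizedExperiment} with genes in rows and samples in
#' columns; the entry for (gene, sample) is the maximum CCF point
#' estimate over that sample's mutations in the gene (capped at 1), and 0
#' for wildtype. Clinical records are attached as \code{colData}.
#'
#' @param estimates CCF table from \code{\link{inferCCF}}.
#' @param cohort The \code{\linkS4class{EsccCohort}} (supplies the sample
#'   set and clinical data).
#' @param genes Gene universe for the rows; defaults to the genes observed
#'   in \code{estimates}. Pass the full panel to keep wildtype genes.
#' @return A \code{SummarizedExperiment} with assay \code{"ccf"}.
#' @export
buildGeneCCFMatrix <- function(estimates, cohort,
                               genes = sort(unique(estimates$gene))) {
  samples <- sampleInfo(cohort)$sample_id
  m <- matrix(0, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  keep <- estimates$gene %in% genes & estimates$sample_id %in% samples
  est <- estimates[keep, , drop = FALSE]
  if (nrow(est)) {
    val <- pmin(est$ccf_point, 1)
    idx <- cbind(match(est$gene, genes), match(est$sample_id, samples))
    o <- order(val)                       # later (larger) writes win: max
    m[idx[o, , drop = FALSE]] <- val[o]
  }
  cl <- clinicalData(cohort)
  cd <- DataFrame(cl[match(samples, cl$sample_id), , drop = FALSE],
                  row.names = samples)
  SummarizedExperiment(assays = list(ccf = m), colData = cd)
}

#' Binary mutation-status matrix
#'
#' Thresholds a gene-level CCF matrix at zero: any positive CCF becomes 1
#' (mutant), zero stays 0 (wildtype).
#'
#' @param x \code{SummarizedExperiment} from
#'   \code{\link{buildGeneCCFMatrix}} or a plain numeric matrix.
#' @return Same container with assay \code{"status"} (or a 0/1 matrix).
#' @export
binarizeMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    b <- (assay(x, "ccf") > 0) + 0L
    return(SummarizedExperiment(assays = list(status = b),
                                colData = colData(x)))
  }
  (as.matrix(x) > 0) + 0L
}

#' Heuristic tumor purity from VAFs
#'
#' Fallback when purity is not supplied: twice the top-decile VAF of a
#' sample's variants on (assumed) diploid loci, capped to (0, 1].
#' A rough device only; supplied purities should be preferred.
#'
#' @param vaf Numeric VAFs of one sample.
#' @return Purity estimate in (0, 1].
#' @export
estimatePurityHeuristic <- function(vaf) {
  vaf <- vaf[!is.na(vaf)]
  if (!length(vaf)) stop("no VAFs supplied", call. = FALSE)
  min(1, max(2 * quantile(vaf, 0.9, names = FALSE), 1e-3))
}
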