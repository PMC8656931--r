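## Synthetic tumor-cohort simulator with known ground truth.
##
## Each patient gets a purity, a clonal population (CCF 1) plus a drawn
## number of subclones with CCFs below the clonal boundary; panel genes
## mutate independently with per-gene probabilities, each mutation is
## assigned to a clone, and reads are drawn binomially at the expected
## VAF implied by CCF, multiplicity, purity and local copy number.
## Survival follows a proportional-hazards model with exponential
## baseline driven by the true gene-level CCFs with planted
## coefficients, under administrative plus independent exponential
## censoring. Only mutations supported by at least three alt reads are
## emitted as variant calls (a somatic caller's detection floor); the
## truth table keeps every planted mutation.

.publishedCoefficients <- function() {
  c(GPR98 = 1.18, LAMA1 = 1.31, IFT140 = 1.42, MUC17 = 1.18,
    PTPRB = 1.78, AHNAK2 = -1.37, PREX2 = -2.78, SPATA31D1 = -3.02)
}

#' Synthetic cohort configuration
#'
#' Builds a configuration for \code{\link{simulateCohort}}. All
#' distributions are explicit so that ground truth is fully known.
#'
#' @param nPatients Cohort size.
#' @param genes Character vector of panel gene names.
#' @param geneMutProb Named per-gene per-patient mutation probabilities.
#' @param beta Named planted Cox coefficients on the gene-CCF scale
#'   (genes absent from the name set have no survival effect).
#' @param subcloneCountProbs Weights for 1..4 subclones per patient.
#' @param subcloneCcfRange Subclone CCFs are uniform on this interval
#'   (within (0, 0.9)).
#' @param clonalProb Probability that a mutation belongs to the clonal
#'   population (CCF 1).
#' @param purityRange Per-patient purity is uniform on this interval.
#' @param depthMean,depthSize Negative-binomial sequencing depth (mean
#'   and size/overdispersion).
#' @param cnProbs Named probabilities of locus total copy number
#'   (names "1","2","3","4").
#' @param baselineHazard Exponential baseline hazard per month.
#' @param censorRate Independent exponential censoring rate per month.
#' @param adminHorizon Administrative censoring time (months).
#' @param osHazardScale OS linear predictor = DFS linear predictor times
#'   this factor (OS shares the planted genes).
#' @param trainFraction Fraction labelled as training cohort.
#' @param minAltReads Detection floor: planted mutations with fewer alt
#'   reads are not emitted as variant calls.
#' @return list of class \code{"ccfSimConfig"}.
#' @export
syntheticConfig <- function(nPatients = 201,
                            genes,
                            geneMutProb,
                            beta = .publishedCoefficients(),
                            subcloneCountProbs = c(0.12, 0.38, 0.33, 0.17),
                            subcloneCcfRange = c(0.08, 0.85),
                            clonalProb = 0.284,
                            purityRange = c(0.3, 0.95),
                            depthMean = 1000, depthSize = 30,
                            cnProbs = c("1" = 0.05, "2" = 0.85,
                                        "3" = 0.07, "4" = 0.03),
                            baselineHazard = 0.028,
                            censorRate = 0.005,
                            adminHorizon = 84,
                            osHazardScale = 0.8,
                            trainFraction = 0.7,
                            minAltReads = 3L) {
  stopifnot(length(geneMutProb) == length(genes),
            all(geneMutProb >= 0 & geneMutProb <= 1),
            clonalProb >= 0, clonalProb <= 1,
            baselineHazard > 0, censorRate >= 0, adminHorizon > 0,
            subcloneCcfRange[1] > 0, subcloneCcfRange[2] < 0.9,
            abs(sum(cnProbs) - 1) < 1e-9)
  structure(list(
    nPatients = nPatients, genes = genes,
    geneMutProb = setNames(geneMutProb, genes),
    beta = beta,
    subcloneCountProbs = subcloneCountProbs / sum(subcloneCountProbs),
    subcloneCcfRange = subcloneCcfRange,
    clonalProb = clonalProb, purityRange = purityRange,
    depthMean = depthMean, depthSize = depthSize,
    cnProbs = cnProbs,
    baselineHazard = baselineHazard, censorRate = censorRate,
    adminHorizon = adminHorizon, osHazardScale = osHazardScale,
    trainFraction = trainFraction, minAltReads = as.integer(minAltReads)
  ), class = "ccfSimConfig")
}

#' Configuration emulating the deep-sequencing study cohort
#'
#' Defaults chosen so that simulated cohorts match the targeted-panel
#' cohort descriptors in expectation: 201 patients, a 548-gene panel,
#' mean depth near 1000x, roughly 70\% subclonal mutations, most
#' patients carrying at least two subclones, and a 3-year recurrence
#' fraction around 65\%. The eight published model genes carry the
#' published coefficients as planted truth.
#'
#' @param nPatients Cohort size (default 201).
#' @return \code{"ccfSimConfig"}.
#' @export
presetDeepPanel <- function(nPatients = 201) {
  modelGenes <- names(.publishedCoefficients())
  extra <- c("TP53", "PIK3CA", "EP300", "NFE2L2", "FAT1", "ZFHX3",
             "KMT2C", "FRY", "ADAM29", "DOCK1", "DOCK2", "MUC16",
             "LAMA5", "FLG", "DCHS2")
  nFiller <- 548 - length(modelGenes) - length(extra)
  genes <- c(modelGenes, extra, sprintf("PANEL%03d", seq_len(nFiller)))
  ## heavy-tailed mutation frequencies: one hot gene, a frequent tier, a
  ## moderate tier and a rare tail; mean mutations/patient ~ 44
  prob <- setNames(numeric(length(genes)), genes)
  prob[modelGenes] <- 0.18
  prob["TP53"] <- 0.6
  prob[extra[-1]] <- 0.15
  filler <- sprintf("PANEL%03d", seq_len(nFiller))
  prob[filler[seq_len(106)]] <- 0.15
  prob[filler[107:266]] <- 0.08
  prob[filler[267:nFiller]] <- 0.04
  syntheticConfig(nPatients = nPatients, genes = genes, geneMutProb = prob)
}

#' Low-depth variant of the deep-panel configuration
#'
#' Identical cohort generation but with mean sequencing depth 55x
#' (exome-like), used to demonstrate the reduced sensitivity of
#' subclonal-mutation detection at shallow depth.
#'
#' @param nPatients Cohort size (default 201).
#' @return \code{"ccfSimConfig"}.
#' @export
presetLowDepth <- function(nPatients = 201) {
  cfg <- presetDeepPanel(nPatients)
  cfg$depthMean <- 55
  cfg$depthSize <- 10
  cfg
}

#' Simulate a cohort with known truth
#'
#' @param config \code{"ccfSimConfig"} from \code{\link{syntheticConfig}}
#'   or a preset.
#' @param seed RNG seed; the output is a pure function of (config, seed).
#' @return list with \code{cohort} (an \code{\linkS4class{EsccCohort}})
#'   and \code{truth}: \code{mutations} (per planted mutation: true CCF,
#'   multiplicity, clonality, detection), \code{patients} (true subclone
#'   count, linear predictor, event times), \code{beta},
#'   \code{gene_ccf} (true samples-by-genes CCF matrix).
#' @export
simulateCohort <- function(config, seed = 20211202) {
  stopifnot(inherits(config, "ccfSimConfig"))
  set.seed(seed)
  ng <- length(config$genes)
  ids <- sprintf("P%03d", seq_len(config$nPatients))
  purity <- runif(config$nPatients, config$purityRange[1],
                  config$purityRange[2])
  nSub <- sample(seq_along(config$subcloneCountProbs), config$nPatients,
                 replace = TRUE, prob = config$subcloneCountProbs)
  geneChrom <- as.character((seq_len(ng) - 1L) %% 22 + 1L)
  genePos <- as.integer(1e6 * (((seq_len(ng) - 1L) %/% 22) + 1L))
  cnVals <- as.numeric(names(config$cnProbs))

  mutRows <- vector("list", config$nPatients)
  for (i in seq_len(config$nPatients)) {
    mutated <- which(runif(ng) < config$geneMutProb)
    if (!length(mutated)) next
    k <- nSub[i]
    subCcf <- sort(runif(k, config$subcloneCcfRange[1],
                         config$subcloneCcfRange[2]), decreasing = TRUE)
    nm <- length(mutated)
    clone <- ifelse(runif(nm) < config$clonalProb, 0L,
                    sample.int(k, nm, replace = TRUE))
    ccf <- ifelse(clone == 0L, 1, subCcf[pmax(clone, 1L)])
    cn <- sample(cnVals, nm, replace = TRUE, prob = config$cnProbs)
    m <- ifelse(cn >= 2 & runif(nm) < 0.1, 2L, 1L)
    m <- pmin(m, pmax(cn, 1))
    mutRows[[i]] <- data.frame(
      sample_id = ids[i], gene = config$genes[mutated],
      chrom = geneChrom[mutated], pos = genePos[mutated],
      true_ccf = ccf, true_m = as.integer(m), total_cn = cn,
      clone = clone, stringsAsFactors = FALSE)
  }
  mut <- do.call(rbind, mutRows)
  nm <- nrow(mut)
  pur <- purity[match(mut$sample_id, ids)]
  denom <- pur * mut$total_cn + (1 - pur) * 2
  expVaf <- mut$true_ccf * mut$true_m * pur / denom
  if (any(expVaf > 1 + 1e-12))
    stop("configuration implies expected VAF > 1", call. = FALSE)
  expVaf <- pmin(expVaf, 1)
  depth <- pmax(rnbinom(nm, mu = config$depthMean,
                        size = config$depthSize), 30L)
  alt <- rbinom(nm, depth, expVaf)
  mut$total_depth <- as.integer(depth)
  mut$alt_reads <- as.integer(alt)
  mut$true_clonal <- mut$clone == 0L
  mut$detected <- mut$alt_reads >= config$minAltReads

  ## true gene-level CCF matrix (max over a gene's mutations)
  geneCcf <- matrix(0, config$nPatients, ng,
                    dimnames = list(ids, config$genes))
  o <- order(mut$true_ccf)
  geneCcf[cbind(match(mut$sample_id, ids),
                match(mut$gene, config$genes))[o, , drop = FALSE]] <-
    mut$true_ccf[o]

  betaFull <- setNames(numeric(ng), config$genes)
  hit <- intersect(names(config$beta), config$genes)
  betaFull[hit] <- config$beta[hit]
  lp <- drop(geneCcf %*% betaFull)
  tEvent <- rexp(config$nPatients, config$baselineHazard * exp(lp))
  tCens <- pmin(config$adminHorizon,
                if (config$censorRate > 0)
                  rexp(config$nPatients, config$censorRate) else Inf)
  dfsTime <- pmax(pmin(tEvent, tCens), 0.1)
  dfsEvent <- as.integer(tEvent <= tCens)
  lpOs <- lp * config$osHazardScale
  tOs <- rexp(config$nPatients, config$baselineHazard * 0.8 * exp(lpOs))
  osTime <- pmax(pmin(tOs, tCens), 0.1)
  osEvent <- as.integer(tOs <= tCens)

  lpStd <- if (sd(lp) > 0) (lp - mean(lp)) / sd(lp) else rep(0, length(lp))
  pN <- ifelse(runif(config$nPatients) < plogis(0.4 * lpStd),
               "N2-3", "N1")
  clinical <- data.frame(
    sample_id = ids,
    dfs_time = round(dfsTime, 2), dfs_event = dfsEvent,
    os_time = round(osTime, 2), os_event = osEvent,
    sex = sample(c("male", "female"), config$nPatients, TRUE,
                 prob = c(0.83, 0.17)),
    age_group = sample(c("<60", ">=60"), config$nPatients, TRUE),
    pT = sample(c("T1-2", "T3-4a"), config$nPatients, TRUE,
                prob = c(0.15, 0.85)),
    pN = pN,
    lns_examined = sample(c(">=21", "<21"), config$nPatients, TRUE,
                          prob = c(0.76, 0.24)),
    surgical_approach = sample(c("left", "right"), config$nPatients, TRUE,
                               prob = c(0.33, 0.67)),
    adjuvant_therapy = sample(c("yes", "no"), config$nPatients, TRUE,
                              prob = c(0.3, 0.7)),
    cohort = ifelse(seq_len(config$nPatients) <=
                      round(config$trainFraction * config$nPatients),
                    "training", "validation"),
    stringsAsFactors = FALSE)

  det <- mut[mut$detected, , drop = FALSE]
  variants <- data.frame(
    sample_id = det$sample_id, gene = det$gene, chrom = det$chrom,
    pos = det$pos, ref = "C", alt = "T",
    alt_reads = det$alt_reads, total_depth = det$total_depth,
    vaf = det$alt_reads / det$total_depth, stringsAsFactors = FALSE)
  segments <- data.frame(
    sample_id = det$sample_id, chrom = det$chrom,
    start = det$pos - 500L, end = det$pos + 500L,
    total_cn = det$total_cn, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = ids, purity = purity,
                        stringsAsFactors = FALSE)
  cohort <- EsccCohort(variants, segments, samples, clinical)
  truth <- list(
    mutations = mut,
    patients = data.frame(sample_id = ids, purity = purity,
                          n_subclones = nSub, lp = lp,
                          t_event = tEvent, t_censor = tCens,
                          stringsAsFactors = FALSE),
    beta = config$beta,
    gene_ccf = geneCcf)
  list(cohort = cohort, truth = truth)
}

#' Write a simulated cohort in the pipeline's TSV dialects
#'
#' @param sim Result of \code{\link{simulateCohort}}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  co <- sim$cohort
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  v <- variantCalls(co)
  v <- data.frame(sample_id = v$sample_id, gene = v$gene, chrom = v$chrom,
                  pos = v$pos, ref = v$ref, alt = v$alt,
                  t_alt_count = v$alt_reads, t_depth = v$total_depth,
                  stringsAsFactors = FALSE)
  wt(v, "variants.tsv")
  wt(cnSegments(co), "segments.tsv")
  wt(sampleInfo(co), "purity.tsv")
  wt(clinicalData(co), "clinical.tsv")
  invisible(dir)
}
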