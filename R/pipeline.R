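## End-to-end orchestration: CCF inference -> gene CCF matrix -> pattern
## screen -> two-step model selection on the training cohort -> risk
## stratification -> validation-set evaluation, plus the discordant-
## stratum genotype-enrichment analysis.

#' Run the full recurrence-prediction pipeline
#'
#' Executes every stage on a cohort: per-mutation CCF inference, gene
#' CCF matrix assembly, the 5\%-frequency univariable screen, SCAD +
#' stepwise-BIC model selection on the training subset, recursive-
#' partitioning risk stratification, application of the cutoffs to the
#' validation subset, and IPCW time-dependent ROC evaluation of the
#' genetic, pathological (pN + pT) and combined models. The training /
#' validation split honours a \code{cohort} column in the clinical table
#' when present; otherwise a seeded 70/30 random split is drawn. All
#' randomness is governed by \code{seed}.
#'
#' @param cohort An \code{\linkS4class{EsccCohort}}.
#' @param endpoint \code{"dfs"} (default) or \code{"os"}.
#' @param seed RNG seed.
#' @param minFreq Gene frequency filter before model selection (default
#'   0.05).
#' @param horizon Evaluation horizon in months (default 36).
#' @param k CV folds for the SCAD stage.
#' @param nlambda SCAD penalty grid size.
#' @param patterns Also classify CCF patterns for every screened gene
#'   (adds permutation tests; default TRUE).
#' @param nPermPatterns Permutations per gene for the pattern maxstat
#'   step.
#' @param outDir Optional directory for intermediate TSVs.
#' @return list of class \code{"ccfPipelineReport"} with elements
#'   \code{estimates}, \code{matrix} (SummarizedExperiment),
#'   \code{screen}, \code{patterns}, \code{selection}, \code{model}
#'   (calibrated \code{RiskModel}), \code{stratification} (training),
#'   \code{validation} (scores, groups, log-rank), \code{evaluation}
#'   (AUCs and Z-tests), \code{summary} (one-row data.frame of headline
#'   numbers), \code{seed}.
#' @export
runPipeline <- function(cohort, endpoint = c("dfs", "os"),
                        seed = 20211202, minFreq = 0.05, horizon = 36,
                        k = 10, nlambda = 50, patterns = TRUE,
                        nPermPatterns = 500, outDir = NULL) {
  endpoint <- match.arg(endpoint)
  stage <- "ccf"
  res <- tryCatch({
    cl <- clinicalData(cohort)
    timeCol <- paste0(endpoint, "_time"); eventCol <- paste0(endpoint, "_event")
    if (any(is.na(cl[[timeCol]])))
      stop("endpoint '", endpoint, "' missing for some samples")
    est <- inferCCF(cohort)

    stage <- "matrix"
    panel <- sort(unique(variantCalls(cohort)$gene))
    se <- buildGeneCCFMatrix(est, cohort, genes = panel)
    ccfMat <- t(assay(se, "ccf"))          # samples x genes
    cl <- cl[match(rownames(ccfMat), cl$sample_id), , drop = FALSE]
    time <- cl[[timeCol]]; event <- cl[[eventCol]]

    stage <- "screen"
    statusMat <- (ccfMat > 0) + 0L
    screen <- univariableScreen(statusMat, time, event, minFreq = minFreq,
                                endpoint = toupper(endpoint))

    stage <- "patterns"
    patTab <- NULL
    if (patterns) {
      testable <- colnames(ccfMat)[colMeans(statusMat) >= minFreq]
      patList <- lapply(testable, function(g)
        tryCatch(classifyPattern(ccfMat[, g], time, event, gene = g,
                                 endpoint = toupper(endpoint),
                                 nPerm = nPermPatterns, seed = seed),
                 error = function(e) NULL))
      patTab <- do.call(rbind, patList)
    }

    stage <- "fit"
    if ("cohort" %in% names(cl) && !any(is.na(cl$cohort))) {
      train <- cl$cohort == "training"
    } else {
      set.seed(seed)
      train <- seq_len(nrow(cl)) %in%
        sample.int(nrow(cl), round(0.7 * nrow(cl)))
    }
    freqTrain <- colMeans(statusMat[train, , drop = FALSE])
    Xtrain <- ccfMat[train, freqTrain >= minFreq, drop = FALSE]
    sel <- selectTwoStep(Xtrain, time[train], event[train], k = k,
                         seed = seed, nlambda = nlambda)

    stage <- "stratify"
    trainScores <- riskScore(sel$model, ccfMat[train, , drop = FALSE])
    strat <- partitionRisk(trainScores, time[train], event[train])
    cuts <- if (length(strat$cutoffs) == 2) strat$cutoffs else numeric(0)
    model <- new("RiskModel", genes = modelGenes(sel$model),
                 coefficients = unname(modelCoefficients(sel$model)),
                 cutoffs = cuts)

    stage <- "evaluate"
    validScores <- riskScore(model, ccfMat[!train, , drop = FALSE])
    validGroup <- if (length(cuts)) assignRiskGroup(model, validScores)
                  else factor(rep("all", sum(!train)))
    validLr <- if (nlevels(droplevels(validGroup)) >= 2)
      logrankTest(validGroup, time[!train], event[!train]) else NULL
    allScores <- riskScore(model, ccfMat)
    pathScore <- (cl$pN == "N2-3") + 0.5 * (cl$pT == "T3-4a")
    combFit <- suppressWarnings(
      coxFit(cbind(genetic = allScores[train], pN = (cl$pN == "N2-3")[train],
                   pT = (cl$pT == "T3-4a")[train]),
             time[train], event[train]))
    combScores <- drop(cbind(allScores, (cl$pN == "N2-3"),
                             (cl$pT == "T3-4a")) %*% combFit$coefficients)
    aucGenetic <- tdAuc(allScores, time, event, horizon = horizon,
                        seed = seed, label = "genetic")
    aucPath <- tdAuc(pathScore, time, event, horizon = horizon,
                     seed = seed, label = "pathological")
    aucComb <- tdAuc(combScores, time, event, horizon = horizon,
                     seed = seed, label = "combined")
    zGvP <- compareAucZ(aucGenetic, aucPath)
    zCvP <- compareAucZ(aucComb, aucPath)

    kmAtHorizon <- vapply(strat$km, function(kmx)
      if (is.null(kmx)) NA_real_ else kmAt(kmx, horizon)$surv, numeric(1))
    summary <- data.frame(
      endpoint = toupper(endpoint),
      n = nrow(cl), n_train = sum(train), n_genes_model = length(modelGenes(model)),
      km_low = kmAtHorizon[["low"]],
      km_intermediate = if ("intermediate" %in% names(kmAtHorizon))
        kmAtHorizon[["intermediate"]] else NA_real_,
      km_high = if ("high" %in% names(kmAtHorizon))
        kmAtHorizon[["high"]] else NA_real_,
      auc_genetic = aucGenetic$auc, auc_pathological = aucPath$auc,
      auc_combined = aucComb$auc,
      z_genetic_vs_path = zGvP$z, p_genetic_vs_path = zGvP$p,
      z_combined_vs_path = zCvP$z, p_combined_vs_path = zCvP$p)

    list(estimates = est, matrix = se, screen = screen, patterns = patTab,
         selection = sel, model = model, stratification = strat,
         train = train,
         validation = list(scores = validScores, group = validGroup,
                           logrank = validLr),
         evaluation = list(genetic = aucGenetic, pathological = aucPath,
                           combined = aucComb, z_genetic_vs_path = zGvP,
                           z_combined_vs_path = zCvP),
         summary = summary, seed = seed)
  }, error = function(e)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) write.table(df, file.path(outDir, f), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
    wt(res$estimates, "ccf_estimates.tsv")
    writeGeneCCFMatrix(res$matrix, file.path(outDir, "gene_ccf_matrix.tsv"))
    wt(res$screen, "screen.tsv")
    if (!is.null(res$patterns)) wt(res$patterns, "patterns.tsv")
    writeRiskModel(res$model, file.path(outDir, "risk_model.tsv"))
    wt(res$summary, "summary.tsv")
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("ccfRisk version: %s",
                         as.character(utils::packageVersion("ccfRisk")))),
               file.path(outDir, "run_info.txt"))
  }
  class(res) <- "ccfPipelineReport"
  res
}

#' @export
print.ccfPipelineReport <- function(x, ...) {
  cat("ccfRisk pipeline report (seed", x$seed, ")\n")
  print(x$model)
  print(x$stratification)
  cat(sprintf("tdAUC at %g months: genetic %.3f, pathological %.3f, combined %.3f\n",
              x$evaluation$genetic$horizon, x$evaluation$genetic$auc,
              x$evaluation$pathological$auc, x$evaluation$combined$auc))
  invisible(x)
}

#' Genotype enrichment in discordant risk strata
#'
#' Cross-tabulates the genetic risk group against the pathological
#' lymph-node stratum and asks which genes distinguish the discordant
#' subset (advanced pN but genetically low risk) from the concordant
#' remainder of the same pN stratum: per gene, Fisher's exact test on
#' mutation status, BH-adjusted.
#'
#' @param group factor of genetic risk groups (low / intermediate /
#'   high) per sample.
#' @param pN Character/factor pathological N stage per sample
#'   (\code{"N1"} vs \code{"N2-3"}).
#' @param status Samples-by-genes 0/1 mutation matrix (rows aligned with
#'   \code{group}).
#' @param advanced Label of the advanced stratum (default \code{"N2-3"}).
#' @param lowLabel Label of the low-risk group (default \code{"low"}).
#' @return data.frame per gene: mutation counts in the discordant and
#'   concordant subsets, odds ratio, \code{p_value}, \code{fdr};
#'   attribute \code{"crosstab"} carries the group-by-pN table. Empty
#'   (with a warning) when no discordant patients exist.
#' @export
discordantEnrichment <- function(group, pN, status, advanced = "N2-3",
                                 lowLabel = "low") {
  status <- as.matrix(status)
  stopifnot(length(group) == length(pN), nrow(status) == length(group))
  inStr <- pN == advanced
  disc <- inStr & group == lowLabel
  conc <- inStr & group != lowLabel
  crosstab <- table(risk = group, pN = pN)
  empty <- data.frame(gene = character(), n_discordant_mut = integer(),
                      n_discordant = integer(), n_concordant_mut = integer(),
                      n_concordant = integer(), odds_ratio = numeric(),
                      p_value = numeric(), fdr = numeric())
  if (!sum(disc)) {
    warning("no discordant (advanced-stage, low-risk) patients")
    attr(empty, "crosstab") <- crosstab
    return(empty)
  }
  rows <- lapply(colnames(status), function(g) {
    a <- sum(status[disc, g] > 0); b <- sum(disc) - a
    c <- sum(status[conc, g] > 0); d <- sum(conc) - c
    if (a + c == 0) return(NULL)           # gene unmutated in the stratum
    ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    data.frame(gene = g, n_discordant_mut = a, n_discordant = sum(disc),
               n_concordant_mut = c, n_concordant = sum(conc),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) { attr(empty, "crosstab") <- crosstab; return(empty) }
  out$fdr <- bhAdjust(out$p_value)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "crosstab") <- crosstab
  out
}

#' Run the pipeline from a YAML configuration file
#'
#' The file lists input paths (\code{variants}, \code{segments},
#' \code{purity}, \code{clinical}), and optionally \code{endpoint},
#' \code{seed}, \code{horizon}, \code{min_freq}, \code{out_dir}.
#'
#' @param path YAML config path.
#' @return The \code{\link{runPipeline}} report.
#' @export
runPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("variants", "segments", "purity", "clinical"))
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("config must point to an existing '", f, "' file", call. = FALSE)
  cohort <- EsccCohort(
    variants = readVariants(cfg$variants),
    segments = readSegments(cfg$segments),
    samples  = read.delim(cfg$purity, stringsAsFactors = FALSE),
    clinical = readClinical(cfg$clinical))
  runPipeline(cohort,
              endpoint = if (is.null(cfg$endpoint)) "dfs" else cfg$endpoint,
              seed = if (is.null(cfg$seed)) 20211202 else cfg$seed,
              minFreq = if (is.null(cfg$min_freq)) 0.05 else cfg$min_freq,
              horizon = if (is.null(cfg$horizon)) 36 else cfg$horizon,
              outDir = cfg$out_dir)
}
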