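#' Cohort container for targeted-sequencing survival analysis
#'
#' An \code{EsccCohort} bundles the four tables the pipeline consumes:
#' somatic variant calls with read counts, copy-number segments, per-sample
#' tumor purity and the clinical follow-up table. All downstream modules
#' take this object (or pieces of it) as input.
#'
#' @slot variants data.frame of somatic calls: \code{sample_id}, \code{gene},
#'   \code{chrom}, \code{pos} (1-based), \code{ref}, \code{alt},
#'   \code{alt_reads}, \code{total_depth}, \code{vaf} (always recomputed
#'   from the counts).
#' @slot segments data.frame of copy-number segments: \code{sample_id},
#'   \code{chrom}, \code{start}, \code{end} (1-based inclusive),
#'   \code{total_cn}.
#' @slot samples data.frame with \code{sample_id} and \code{purity} in (0,1].
#' @slot clinical data.frame with \code{sample_id}, \code{dfs_time},
#'   \code{dfs_event}, \code{os_time}, \code{os_event} and any further
#'   covariate columns (pN stage, pT stage, adjuvant therapy, cohort label
#'   ...), carried through untouched.
#'
#' @seealso \code{\link{EsccCohort}} for the validating constructor,
#'   \code{\link{simulateCohort}} for synthetic cohorts.
#' @exportClass EsccCohort
setClass("EsccCohort",
  representation(
    variants = "data.frame",
    segments = "data.frame",
    samples  = "data.frame",
    clinical = "data.frame"
  )
)

setValidity("EsccCohort", function(object) {
  msg <- character()
  v <- object@variants; s <- object@samples; cl <- object@clinical
  if (nrow(v) && !all(v$sample_id %in% s$sample_id))
    msg <- c(msg, "variants contain sample_ids absent from the sample table")
  if (nrow(object@segments) &&
      !all(object@segments$sample_id %in% s$sample_id))
    msg <- c(msg, "segments contain sample_ids absent from the sample table")
  if (nrow(s) && !all(s$sample_id %in% cl$sample_id))
    msg <- c(msg, "samples without a clinical record")
  if (nrow(s) && any(s$purity <= 0 | s$purity > 1))
    msg <- c(msg, "purity must lie in (0, 1]")
  if (nrow(v)) {
    if (any(v$alt_reads < 0 | v$alt_reads > v$total_depth))
      msg <- c(msg, "alt_reads must lie in [0, total_depth]")
    key <- paste(v$sample_id, v$chrom, v$pos, v$alt)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (sample_id, chrom, pos, alt) variant keys")
  }
  if (length(msg)) msg else TRUE
})

#' Posterior cancer cell fraction for one mutation
#'
#' Holds the grid posterior over CCF for a single variant given its allele
#' counts, multiplicity, local copy number and the sample purity, together
#' with the derived point estimate and clonality call.
#'
#' @slot multiplicity integer, mutation copies per mutated cell.
#' @slot grid numeric, the CCF grid (0.01 to 1.00 in steps of 0.01).
#' @slot posterior numeric, posterior probability at each grid point
#'   (sums to one).
#' @slot ccfPoint numeric, posterior-maximizing grid value.
#' @slot pClonal numeric, posterior probability that CCF exceeds 0.9.
#' @slot isClonal logical, \code{pClonal > 0.5}.
#'
#' @seealso \code{\link{ccfPosterior}}
#' @exportClass CCFEstimate
setClass("CCFEstimate",
  representation(
    multiplicity = "integer",
    grid = "numeric",
    posterior = "numeric",
    ccfPoint = "numeric",
    pClonal = "numeric",
    isClonal = "logical"
  )
)

setValidity("CCFEstimate", function(object) {
  msg <- character()
  if (abs(sum(object@posterior) - 1) > 1e-9)
    msg <- c(msg, "posterior must sum to 1 (tolerance 1e-9)")
  if (length(object@posterior) != length(object@grid))
    msg <- c(msg, "posterior and grid lengths differ")
  if (!object@ccfPoint %in% object@grid)
    msg <- c(msg, "ccfPoint must be a grid value")
  if (object@isClonal != (object@pClonal > 0.5))
    msg <- c(msg, "isClonal must equal pClonal > 0.5")
  if (length(msg)) msg else TRUE
})

#' Subclonal architecture of one sample
#'
#' Result of fitting a one-dimensional Gaussian mixture to logit-transformed
#' per-mutation CCF point estimates; clusters whose back-transformed centers
#' fall below the clonal boundary (0.9) are counted as subclones.
#'
#' @slot sampleId character.
#' @slot centers numeric, cluster centers on the CCF scale, in (0, 1].
#' @slot weights numeric, mixing weights (sum to one).
#' @slot assignments integer, cluster index per mutation.
#' @slot nSubclones integer, clusters with center below the clonal boundary.
#' @slot flagged logical, TRUE when too few mutations supported a fit.
#'
#' @seealso \code{\link{countSubclones}}
#' @exportClass SubcloneModel
setClass("SubcloneModel",
  representation(
    sampleId = "character",
    centers = "numeric",
    weights = "numeric",
    assignments = "integer",
    nSubclones = "integer",
    flagged = "logical"
  )
)

setValidity("SubcloneModel", function(object) {
  msg <- character()
  if (length(object@weights) &&
      (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-6))
    msg <- c(msg, "weights must be non-negative and sum to 1")
  if (length(object@centers) &&
      any(object@centers <= 0 | object@centers > 1))
    msg <- c(msg, "centers must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Gene-level CCF risk model
#'
#' A linear risk score over gene-level CCFs: the score of a patient is the
#' inner product of the model coefficients with the patient's per-gene CCF
#' values (wildtype genes contribute zero). Two ascending cutoffs split the
#' score axis into low / intermediate / high recurrence-risk groups.
#'
#' @slot genes character, model genes in coefficient order.
#' @slot coefficients numeric, Cox log-hazard coefficients per gene.
#' @slot cutoffs numeric of length 2 (ascending) or length 0 when the model
#'   has not been calibrated to cutoffs yet.
#'
#' @seealso \code{\link{publishedRiskModel}}, \code{\link{riskScore}},
#'   \code{\link{partitionRisk}}
#' @exportClass RiskModel
setClass("RiskModel",
  representation(
    genes = "character",
    coefficients = "numeric",
    cutoffs = "numeric"
  )
)

setValidity("RiskModel", function(object) {
  msg <- character()
  if (length(object@genes) != length(object@coefficients))
    msg <- c(msg, "one coefficient per gene required")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicated model genes")
  if (length(object@cutoffs) &&
      (length(object@cutoffs) != 2 || diff(object@cutoffs) <= 0))
    msg <- c(msg, "cutoffs must be two strictly ascending numbers")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EsccCohort", function(object) {
  cat("EsccCohort with", nrow(object@samples), "samples,",
      nrow(object@variants), "variants,",
      nrow(object@segments), "copy-number segments\n")
  ev <- object@clinical$dfs_event
  if (length(ev))
    cat("  DFS events:", sum(ev == 1, na.rm = TRUE), "/", length(ev), "\n")
})

setMethod("show", "CCFEstimate", function(object) {
  cat(sprintf(
    "CCFEstimate: ccf = %.2f, m = %d, P(CCF > 0.9) = %.3f (%s)\n",
    object@ccfPoint, object@multiplicity, object@pClonal,
    if (object@isClonal) "clonal" else "subclonal"))
})

setMethod("show", "SubcloneModel", function(object) {
  cat("SubcloneModel for", object@sampleId, "-",
      length(object@centers), "cluster(s),",
      object@nSubclones, "subclone(s)\n")
  if (length(object@centers))
    cat("  centers:", paste(sprintf("%.2f", object@centers), collapse = ", "),
        "\n")
})

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel over", length(object@genes), "genes\n")
  print(round(setNames(object@coefficients, object@genes), 4))
  if (length(object@cutoffs))
    cat("  cutoffs (low | intermediate | high):",
        paste(signif(object@cutoffs, 4), collapse = ", "), "\n")
})

#' Construct a validated cohort
#'
#' Assembles the four input tables into an \code{\linkS4class{EsccCohort}}.
#' Variants and segments whose \code{sample_id} has no entry in the sample
#' table are dropped with a counted warning (sample IDs are matched
#' case-sensitively); a missing clinical record for a profiled sample is an
#' error.
#'
#' @param variants data.frame as returned by \code{\link{readVariants}}.
#' @param segments data.frame as returned by \code{\link{readSegments}}.
#' @param samples data.frame with columns \code{sample_id}, \code{purity}.
#' @param clinical data.frame as returned by \code{\link{readClinical}}.
#' @return An \code{EsccCohort}.
#' @export
EsccCohort <- function(variants, segments, samples, clinical) {
  variants <- as.data.frame(variants)
  segments <- as.data.frame(segments)
  samples  <- as.data.frame(samples)
  clinical <- as.data.frame(clinical)
  known <- samples$sample_id
  dropV <- nrow(variants) && any(!variants$sample_id %in% known)
  if (isTRUE(dropV)) {
    n <- sum(!variants$sample_id %in% known)
    warning(sprintf("dropping %d variant(s) with unmatched sample_id", n))
    variants <- variants[variants$sample_id %in% known, , drop = FALSE]
  }
  if (nrow(segments) && any(!segments$sample_id %in% known)) {
    n <- sum(!segments$sample_id %in% known)
    warning(sprintf("dropping %d segment(s) with unmatched sample_id", n))
    segments <- segments[segments$sample_id %in% known, , drop = FALSE]
  }
  new("EsccCohort", variants = variants, segments = segments,
      samples = samples, clinical = clinical)
}

#' @rdname EsccCohort-accessors
#' @name EsccCohort-accessors
#' @title Accessors for EsccCohort slots
#' @param x An \code{EsccCohort}.
#' @return The corresponding data.frame.
#' @export
variantCalls <- function(x) { stopifnot(is(x, "EsccCohort")); x@variants }

#' @rdname EsccCohort-accessors
#' @export
cnSegments <- function(x) { stopifnot(is(x, "EsccCohort")); x@segments }

#' @rdname EsccCohort-accessors
#' @export
sampleInfo <- function(x) { stopifnot(is(x, "EsccCohort")); x@samples }

#' @rdname EsccCohort-accessors
#' @export
clinicalData <- function(x) { stopifnot(is(x, "EsccCohort")); x@clinical }

#' @rdname RiskModel-accessors
#' @name RiskModel-accessors
#' @title Accessors for RiskModel slots
#' @param x A \code{RiskModel}.
#' @return Genes, named coefficients, or cutoffs.
#' @export
modelGenes <- function(x) { stopifnot(is(x, "RiskModel")); x@genes }

#' @rdname RiskModel-accessors
#' @export
modelCoefficients <- function(x) {
  stopifnot(is(x, "RiskModel"))
  setNames(x@coefficients, x@genes)
}

#' @rdname RiskModel-accessors
#' @export
riskCutoffs <- function(x) { stopifnot(is(x, "RiskModel")); x@cutoffs }
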