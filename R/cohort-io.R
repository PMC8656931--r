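## Readers/writers for the tabular dialects the pipeline touches.
## Coordinates are 1-based inclusive throughout (MAF/SEG convention);
## VCF input is converted on read.

.requireCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read somatic variant calls
#'
#' Reads a MAF-like TSV (columns \code{sample_id}, \code{gene},
#' \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{t_alt_count},
#' \code{t_depth}) or a VCF with \code{AD}/\code{DP} FORMAT fields into a
#' variant table. The VAF is always recomputed as
#' \code{alt_reads / total_depth}; a stored VAF column is ignored with a
#' message. Multi-allelic VCF records are split into one row per alt
#' allele; the gene symbol is taken from a \code{GENE} INFO key.
#'
#' @param path Path to the file.
#' @param format \code{"maf_tsv"} (default) or \code{"vcf"}.
#' @return data.frame with columns \code{sample_id}, \code{gene},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{alt_reads},
#'   \code{total_depth}, \code{vaf}.
#' @export
readVariants <- function(path, format = c("maf_tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "vcf") return(.readVariantsVcf(path))
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .requireCols(df, c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                     "t_alt_count", "t_depth"), "variant table")
  if ("vaf" %in% names(df))
    message("ignoring stored 'vaf' column; VAF is recomputed from counts")
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    gene = as.character(df$gene),
    chrom = as.character(df$chrom),
    pos = as.integer(df$pos),
    ref = as.character(df$ref),
    alt = as.character(df$alt),
    alt_reads = as.integer(df$t_alt_count),
    total_depth = as.integer(df$t_depth),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) {
    warning("variant table has a header but no records")
    out$vaf <- numeric(0)
    return(out)
  }
  bad <- which(out$alt_reads < 0 | out$total_depth <= 0 |
               out$alt_reads > out$total_depth)
  if (length(bad))
    stop(sprintf("invalid read counts (alt_reads outside [0, depth]) at row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  out$vaf <- out$alt_reads / out$total_depth
  out
}

.readVariantsVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gene <- vcfR::extract.info(v, element = "GENE")
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  if (is.null(ad) || is.null(dp))
    stop("VCF must carry AD and DP FORMAT fields", call. = FALSE)
  rows <- list()
  for (j in seq_len(ncol(ad))) {
    smp <- colnames(ad)[j]
    for (i in seq_len(nrow(ad))) {
      if (is.na(ad[i, j])) next
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      counts <- as.integer(strsplit(ad[i, j], ",", fixed = TRUE)[[1]])
      for (k in seq_along(alts)) {      # multi-allelic: one row per alt
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = smp,
          gene = if (is.null(gene) || is.na(gene[i])) NA_character_ else gene[i],
          chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = alts[k],
          alt_reads = counts[k + 1L],
          total_depth = as.integer(dp[i, j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), gene = character(),
               chrom = character(), pos = integer(), ref = character(),
               alt = character(), alt_reads = integer(),
               total_depth = integer(), stringsAsFactors = FALSE)
  if (nrow(out) == 0L) warning("VCF contained no usable records")
  out$vaf <- if (nrow(out)) out$alt_reads / out$total_depth else numeric(0)
  out
}

#' Read copy-number segments
#'
#' Reads a SEG-style TSV with columns \code{sample_id}, \code{chrom},
#' \code{start}, \code{end}, \code{total_cn}. Segments of one sample must
#' not overlap on a chromosome (coordinates 1-based inclusive).
#'
#' @param path Path to the TSV.
#' @return Validated data.frame of segments.
#' @export
readSegments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  .requireCols(df, c("sample_id", "chrom", "start", "end", "total_cn"),
               "segment table")
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    chrom = as.character(df$chrom),
    start = as.integer(df$start),
    end = as.integer(df$end),
    total_cn = as.numeric(df$total_cn),
    stringsAsFactors = FALSE
  )
  if (any(out$total_cn < 0))
    stop("negative total_cn in segment table", call. = FALSE)
  if (any(out$start > out$end))
    stop("segment with start > end", call. = FALSE)
  .checkSegmentOverlap(out)
  out
}

.checkSegmentOverlap <- function(seg) {
  if (!nrow(seg)) return(invisible(TRUE))
  for (key in unique(paste(seg$sample_id, seg$chrom))) {
    idx <- which(paste(seg$sample_id, seg$chrom) == key)
    if (length(idx) < 2) next
    o <- idx[order(seg$start[idx])]
    bad <- which(seg$start[o][-1] <= seg$end[o][-length(o)])
    if (length(bad))
      stop(sprintf(
        "overlapping segments for sample %s on %s: [%d,%d] and [%d,%d]",
        seg$sample_id[o[1]], seg$chrom[o[1]],
        seg$start[o[bad[1]]], seg$end[o[bad[1]]],
        seg$start[o[bad[1] + 1]], seg$end[o[bad[1] + 1]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read the clinical follow-up table
#'
#' Expects a TSV with \code{sample_id}, \code{dfs_time}, \code{dfs_event}
#' and, optionally, \code{os_time}, \code{os_event}; any further columns
#' (stage, therapy, cohort label, ...) are carried through as covariates.
#' Times are in months and must be positive; events are 0/1.
#'
#' @param path Path to the TSV.
#' @return data.frame of clinical records.
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  .requireCols(df, c("sample_id", "dfs_time", "dfs_event"), "clinical table")
  df$sample_id <- as.character(df$sample_id)
  df$dfs_time <- as.numeric(df$dfs_time)
  df$dfs_event <- as.integer(df$dfs_event)
  if (!all(c("os_time", "os_event") %in% names(df))) {
    warning("no OS columns found; overall survival marked absent")
    df$os_time <- NA_real_
    df$os_event <- NA_integer_
  } else {
    df$os_time <- as.numeric(df$os_time)
    df$os_event <- as.integer(df$os_event)
  }
  for (col in c("dfs_time", "os_time")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad))
      stop(sprintf("non-positive %s at row(s): %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (col in c("dfs_event", "os_event")) {
    if (any(!df[[col]] %in% c(0L, 1L, NA_integer_)))
      stop(sprintf("%s must be 0/1", col), call. = FALSE)
  }
  df
}

#' Write / read a gene-level CCF matrix as TSV
#'
#' The on-disk layout has one row per sample and one column per gene
#' (first column \code{sample_id}); entries are CCFs in [0, 1] with 0
#' meaning wildtype, written with six decimals so that a read-after-write
#' round trip is lossless to 1e-6.
#'
#' @param x A \code{SummarizedExperiment} from
#'   \code{\link{buildGeneCCFMatrix}} (genes in rows) or a plain
#'   samples-by-genes matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneCCFMatrix <- function(x, path) {
  m <- if (is(x, "SummarizedExperiment")) t(assay(x)) else as.matrix(x)
  df <- data.frame(sample_id = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(m)) {
    vals <- as.data.frame(apply(m, 2, function(col) sprintf("%.6f", col)))
    if (nrow(m) == 1L) vals <- as.data.frame(t(vals))  # apply drops dims
    names(vals) <- colnames(m)
    df <- cbind(df, vals)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneCCFMatrix
#' @export
readGeneCCFMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .requireCols(df, "sample_id", "gene CCF matrix")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$sample_id
  if (length(m) && (min(m) < 0 || max(m) > 1))
    stop("CCF entries must lie in [0, 1]", call. = FALSE)
  m
}
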