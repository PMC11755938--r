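# Catalog input and the quality screen: QUAL >= 30, 10 <= DP <= 50,
# SNV-only, autosome-only, with fixed drop-reason precedence.

#' Default autosome label set
#'
#' @param n number of autosomes (20 for the rhesus macaque).
#' @return character vector \code{chr1..chrN}.
#' @export
autosomeLabels <- function(n = 20) paste0("chr", seq_len(n))

#' Read a variant catalog from VCF
#'
#' Parses a VCF 4.x file (via VariantAnnotation) into one record per ALT
#' allele, splitting multi-allelic sites. The INFO keys \code{DP, AF, GENE,
#' EFFECT, DMG, CADD} are consumed when present; records lacking an
#' annotation key are kept un-annotated (NA), never dropped. Coordinates
#' stay 1-based.
#'
#' @param path VCF file path.
#' @return data.frame with columns \code{chrom, pos, ref, alt, qual, depth,
#'   af, gene, effect, damaging, cadd}.
#' @export
readCatalog <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  bad <- body[vapply(strsplit(lines[body], "\t", fixed = TRUE), length,
                     integer(1)) < 8L]
  if (length(bad))
    stop("malformed VCF line ", bad[1], " in ", path,
         ": fewer than 8 tab-separated fields", call. = FALSE)

  vcf <- VariantAnnotation::readVcf(path, genome = "catalog")
  vcf <- VariantAnnotation::expand(vcf)
  n <- length(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)

  getKey <- function(key, default) {
    if (n == 0L || !key %in% colnames(info)) return(rep(default, n))
    v <- info[[key]]
    if (is(v, "List")) v <- as.vector(unlist(lapply(v, function(e)
      if (length(e)) e[[1]] else default)))
    v[is.na(v)] <- default
    v
  }

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    qual = as.numeric(VariantAnnotation::qual(vcf)),
    depth = as.integer(getKey("DP", NA_integer_)),
    af = as.numeric(getKey("AF", NA_real_)),
    gene = as.character(getKey("GENE", NA_character_)),
    effect = as.character(getKey("EFFECT", NA_character_)),
    damaging = as.logical(getKey("DMG", FALSE)),
    cadd = as.numeric(getKey("CADD", NA_real_)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Apply the variant quality screen
#'
#' A record is retained iff \code{qual >= qualMin}, \code{depthMin <= depth
#' <= depthMax}, both alleles are single bases (SNV) and the chromosome is
#' in the autosome set. Boundary values are kept (the screen excludes
#' strictly below/above the stated thresholds). Drop reasons are assigned
#' with precedence quality > depth > indel > non-autosome so each record is
#' counted once; missing qual or depth counts as a failure of that rule.
#'
#' @param records data.frame from \code{\link{readCatalog}}.
#' @param qualMin minimum quality score kept (default 30).
#' @param depthMin,depthMax inclusive depth bounds kept (default 10, 50).
#' @param autosomes character vector of retained chromosome labels.
#' @return list with elements \code{records} (the retained subset) and
#'   \code{summary} (a \linkS4class{QCSummary}).
#' @export
#' @examples
#' rec <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G",
#'                   qual = 29.9, depth = 30, af = 0.1, gene = "G1",
#'                   effect = "missense", damaging = FALSE, cadd = NA)
#' qcFilter(rec)$summary   # dropped: reason qual
qcFilter <- function(records, qualMin = 30, depthMin = 10, depthMax = 50,
                     autosomes = autosomeLabels()) {
  stopifnot(is.finite(qualMin), is.finite(depthMin), is.finite(depthMax),
            length(autosomes) > 0)
  n <- nrow(records)
  if (n == 0L) {
    summary <- new("QCSummary", nInput = 0L, nDroppedQual = 0L,
                   nDroppedDepth = 0L, nDroppedIndel = 0L,
                   nDroppedNonautosome = 0L, nRetained = 0L,
                   nSnvRetained = 0L, nIndelSeen = 0L,
                   snvFraction = NA_real_)
    return(list(records = records, summary = summary))
  }
  failQual <- is.na(records$qual) | records$qual < qualMin
  failDepth <- is.na(records$depth) | records$depth < depthMin |
    records$depth > depthMax
  isSnv <- nchar(records$ref) == 1L & nchar(records$alt) == 1L
  failChrom <- !(records$chrom %in% autosomes)

  reason <- rep(NA_character_, n)
  reason[!failQual & !failDepth & isSnv & failChrom] <- "nonautosome"
  reason[!failQual & !failDepth & !isSnv] <- "indel"
  reason[!failQual & failDepth] <- "depth"
  reason[failQual] <- "qual"
  keep <- is.na(reason)

  qdPass <- !failQual & !failDepth
  nSnv <- sum(qdPass & isSnv)
  nIndel <- sum(qdPass & !isSnv)
  summary <- new("QCSummary",
                 nInput = n,
                 nDroppedQual = sum(reason == "qual", na.rm = TRUE),
                 nDroppedDepth = sum(reason == "depth", na.rm = TRUE),
                 nDroppedIndel = sum(reason == "indel", na.rm = TRUE),
                 nDroppedNonautosome = sum(reason == "nonautosome",
                                           na.rm = TRUE),
                 nRetained = sum(keep),
                 nSnvRetained = nSnv,
                 nIndelSeen = nIndel,
                 snvFraction = snvFractionPct(nSnv, nIndel))
  list(records = records[keep, , drop = FALSE], summary = summary)
}

#' SNV percentage among quality/depth survivors
#'
#' @param nSnv,nIndel SNV and indel counts after the quality and depth
#'   screens.
#' @return percentage of SNVs on the 0--100 scale, half-up at 1 d.p.;
#'   \code{NA} when both counts are zero.
#' @export
#' @examples
#' snvFractionPct(32507418, 4996245)  # 86.7
snvFractionPct <- function(nSnv, nIndel) {
  tot <- nSnv + nIndel
  if (tot == 0) return(NA_real_)
  pctHalfUp(nSnv, tot, 1)
}

#' Render a QC summary as a tabular report
#'
#' @param summary a \linkS4class{QCSummary}.
#' @param path optional TSV output path.
#' @return data.frame with \code{metric} and \code{value} columns;
#'   percentages at 1 d.p. (half-up), rendered \code{"NA"} for empty input.
#' @export
summarizeQc <- function(summary, path = NULL) {
  stopifnot(is(summary, "QCSummary"))
  pf <- function(num, den) {
    p <- pctHalfUp(num, den)
    if (is.na(p)) "NA" else sprintf("%.1f", p)
  }
  df <- data.frame(
    metric = c("n_input", "n_dropped_qual", "n_dropped_depth",
               "n_dropped_indel", "n_dropped_nonautosome", "n_retained",
               "n_snv_retained", "n_indel_seen", "snv_fraction_pct",
               "retained_pct", "conservation_ok"),
    value = c(summary@nInput, summary@nDroppedQual, summary@nDroppedDepth,
              summary@nDroppedIndel, summary@nDroppedNonautosome,
              summary@nRetained, summary@nSnvRetained, summary@nIndelSeen,
              if (is.na(summary@snvFraction)) "NA"
              else sprintf("%.1f", summary@snvFraction),
              pf(summary@nRetained, summary@nInput),
              as.character(summary@nInput == summary@nRetained +
                             summary@nDroppedQual + summary@nDroppedDepth +
                             summary@nDroppedIndel +
                             summary@nDroppedNonautosome)),
    stringsAsFactors = FALSE)
  if (!is.null(path)) writeTsv(df, path)
  df
}
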