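# Residual Variation Intolerance Score (RVIS).
#
# Per gene: x = total protein-coding variants (missense + LoF + synonymous),
# y = common functional variants (missense + LoF at allele frequency >= the
# MAF threshold). OLS of y on x with intercept; the studentized residual is
# the constraint score. Genes with fewer common functional variants than
# their burden predicts score negative (constrained, intolerant).

CODING_EFFECTS <- c("missense", "lof", "synonymous")
FUNCTIONAL_EFFECTS <- c("missense", "lof")

#' Count per-gene coding and common functional variants
#'
#' Aggregates QC-passed variant records into the two per-gene counts feeding
#' the intolerance regression. Every gene in the gene models appears (zero
#' counts allowed); a variant contributes only to its annotated gene.
#' Noncoding and un-annotated records contribute to neither count. Variants
#' annotated to a gene absent from the models are counted under that gene
#' with a warning.
#'
#' @param records QC-passed variant data.frame (see \code{\link{qcFilter}}).
#' @param geneModels \code{GRanges} with a \code{gene} column (see
#'   \code{\link{readGeneModels}}), or a data.frame with a \code{gene}
#'   column, or a character vector of gene ids.
#' @param mafThreshold allele-frequency cut for the common/rare split
#'   (default 0.001; common means \code{af >= mafThreshold}).
#' @return data.frame \code{gene, x, y} with \code{y <= x}.
#' @export
#' @examples
#' rec <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "G",
#'                   qual = 50, depth = 30, af = c(0.05, 0.3, 2e-4),
#'                   gene = "G1",
#'                   effect = c("missense", "synonymous", "lof"),
#'                   damaging = FALSE, cadd = NA)
#' countGeneVariants(rec, "G1")    # x = 3, y = 1
countGeneVariants <- function(records, geneModels, mafThreshold = 0.001) {
  modelGenes <- if (is.character(geneModels)) geneModels
  else if (is.data.frame(geneModels)) geneModels$gene
  else geneModels$gene
  modelGenes <- unique(as.character(modelGenes))
  if (!length(modelGenes)) stop("no genes in gene models", call. = FALSE)

  rec <- records[!is.na(records$gene), , drop = FALSE]
  stray <- setdiff(unique(rec$gene), modelGenes)
  if (length(stray))
    warning(length(stray), " annotated gene(s) absent from gene models ",
            "(counted anyway): ", paste(utils::head(stray, 5),
                                        collapse = ", "),
            call. = FALSE)
  genes <- c(modelGenes, stray)
  isCoding <- rec$effect %in% CODING_EFFECTS
  isCommonFunc <- rec$effect %in% FUNCTIONAL_EFFECTS &
    !is.na(rec$af) & rec$af >= mafThreshold
  x <- table(factor(rec$gene[isCoding], levels = genes))
  y <- table(factor(rec$gene[isCommonFunc], levels = genes))
  data.frame(gene = genes, x = as.integer(x), y = as.integer(y),
             stringsAsFactors = FALSE)
}

# Externally studentized residuals with the zero-sigma limit made explicit:
# a point whose deletion leaves an exact fit gets +/- Inf (nonzero residual)
# rather than NaN.
.studentize <- function(fit, flavor) {
  r <- stats::residuals(fit)
  t <- if (flavor == "external") rstudent(fit) else rstandard(fit)
  bad <- is.nan(t) | is.infinite(t) | abs(t) > 1e12
  t[bad & abs(r) > 1e-10] <- sign(r[bad & abs(r) > 1e-10]) * Inf
  t[bad & abs(r) <= 1e-10] <- 0
  t
}

#' Fit the intolerance regression and score genes
#'
#' Ordinary least squares of y (common functional count) on x (total coding
#' count) with intercept; scores are studentized residuals, externally
#' (leave-one-out) by default. The reported \code{rvis} column is centred to
#' mean 0 over the fitted genes; the uncentred studentized residual is kept
#' alongside. A perfect linear fit is degenerate: all scores are 0 and the
#' table is flagged.
#'
#' @param counts data.frame \code{gene, x, y} from
#'   \code{\link{countGeneVariants}}.
#' @param flavor \code{"external"} (default) or \code{"internal"}
#'   studentization.
#' @return an \linkS4class{RVISTable}.
#' @export
computeRVIS <- function(counts, flavor = c("external", "internal")) {
  flavor <- match.arg(flavor)
  stopifnot(is.data.frame(counts), all(c("gene", "x", "y") %in% names(counts)))
  if (nrow(counts) < 3L)
    stop("need at least 3 genes to fit the intolerance regression",
         call. = FALSE)
  if (any(counts$y > counts$x))
    stop("invalid counts: y > x for some gene", call. = FALSE)
  if (var(counts$x) == 0)
    stop("degenerate regression: all genes have identical x", call. = FALSE)

  fit <- lm(y ~ x, data = counts)
  raw <- as.numeric(stats::residuals(fit))
  # summary() warns on an essentially perfect fit; that case is handled
  # explicitly below via the degenerate flag
  sigma <- suppressWarnings(summary(fit)$sigma)
  degenerate <- sigma < 1e-10
  t <- if (degenerate) rep(0, nrow(counts)) else .studentize(fit, flavor)
  fin <- is.finite(t)
  rvis <- t - mean(t[fin])
  rvis[!fin] <- t[!fin]

  new("RVISTable",
      scores = data.frame(gene = counts$gene, x = counts$x, y = counts$y,
                          raw = raw, studentized = as.numeric(t),
                          rvis = as.numeric(rvis),
                          excluded = FALSE, stringsAsFactors = FALSE),
      intercept = unname(coef(fit)[1]),
      slope = unname(coef(fit)[2]),
      sigma = sigma,
      nFit = nrow(counts),
      flavor = flavor,
      degenerate = degenerate,
      outlierThreshold = NA_real_)
}

#' Remove extreme high-score outliers and refit
#'
#' Flags genes whose centred score exceeds \code{threshold} (one-sided:
#' strongly mutation-tolerant outliers only; strongly negative scores are
#' kept), then recomputes the regression and studentization once on the
#' remaining genes. No cascade: the refit is not re-screened.
#'
#' @param table an \linkS4class{RVISTable}.
#' @param threshold positive score cutoff (default 11).
#' @return a refitted \linkS4class{RVISTable}; excluded genes keep their
#'   counts but carry \code{NA} scores and \code{excluded = TRUE}.
#' @export
removeOutliers <- function(table, threshold = 11) {
  stopifnot(is(table, "RVISTable"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("outlier threshold must be a positive number", call. = FALSE)
  sc <- table@scores
  out <- !sc$excluded & !is.na(sc$rvis) & sc$rvis > threshold
  if (!any(out)) {
    table@outlierThreshold <- threshold
    return(table)
  }
  keep <- sc[!out, c("gene", "x", "y")]
  refit <- computeRVIS(keep, flavor = table@flavor)
  merged <- refit@scores
  dropped <- sc[out, c("gene", "x", "y")]
  dropped$raw <- NA_real_
  dropped$studentized <- NA_real_
  dropped$rvis <- NA_real_
  dropped$excluded <- TRUE
  merged <- rbind(merged, dropped)
  merged <- merged[match(sc$gene, merged$gene), ]
  rownames(merged) <- NULL
  refit@scores <- merged
  refit@outlierThreshold <- threshold
  refit
}
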