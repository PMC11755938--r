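# Group-difference and association statistics between gene sets and the
# constraint score: Welch t-test, logistic regression odds ratio, and
# cross-species Pearson correlation.

#' Welch two-sample t-test on constraint scores
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value.
#'
#' @param scoresSet,scoresBackground numeric score vectors (each of length
#'   >= 2 with finite variance).
#' @return list: \code{t, df, p, meanSet, sdSet, nSet, meanBackground,
#'   sdBackground, nBackground}.
#' @export
welchTTest <- function(scoresSet, scoresBackground) {
  if (length(scoresSet) < 2L || length(scoresBackground) < 2L)
    stop("both groups need at least 2 values", call. = FALSE)
  if (!all(is.finite(scoresSet)) || !all(is.finite(scoresBackground)))
    stop("scores must be finite", call. = FALSE)
  ht <- t.test(scoresSet, scoresBackground, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       meanSet = mean(scoresSet), sdSet = sd(scoresSet),
       nSet = length(scoresSet),
       meanBackground = mean(scoresBackground),
       sdBackground = sd(scoresBackground),
       nBackground = length(scoresBackground))
}

#' Logistic association between set membership and constraint
#'
#' Maximum-likelihood logistic regression of membership on the score
#' (intercept + slope). The odds ratio is \code{exp(beta)} per one score
#' unit, so sets enriched for constrained (negative-scoring) genes yield
#' OR < 1.
#'
#' @param membership logical (or 0/1) vector, one element per gene.
#' @param rvis numeric score vector of the same length.
#' @return list: \code{beta, se, oddsRatio, p, n, nMembers}.
#' @export
logisticAssociation <- function(membership, rvis) {
  membership <- as.logical(membership)
  stopifnot(length(membership) == length(rvis))
  ok <- !is.na(membership) & is.finite(rvis)
  membership <- membership[ok]; rvis <- rvis[ok]
  if (!any(membership) || all(membership))
    stop("membership must contain both classes", call. = FALSE)
  if (max(rvis[membership]) < min(rvis[!membership]) ||
      min(rvis[membership]) > max(rvis[!membership]))
    stop("perfect separation: membership fully determined by score",
         call. = FALSE)
  fit <- suppressWarnings(glm(membership ~ rvis, family = binomial()))
  cf <- summary(fit)$coefficients
  if (abs(cf["rvis", "Estimate"]) > 50)
    stop("perfect separation: logistic fit diverged", call. = FALSE)
  list(beta = cf["rvis", "Estimate"],
       se = cf["rvis", "Std. Error"],
       oddsRatio = exp(cf["rvis", "Estimate"]),
       p = cf["rvis", "Pr(>|z|)"],
       n = length(rvis), nMembers = sum(membership))
}

#' Cross-species constraint correlation
#'
#' Pearson product-moment correlation of two per-gene score tables over
#' their inner join on gene id, with the Fisher-z 95\% confidence interval.
#'
#' @param tableA,tableB data.frames with columns \code{gene} and \code{rvis}.
#' @return list: \code{r, ciLow, ciHigh, p, nJoined, nOnlyA, nOnlyB}.
#' @export
crossSpeciesCorrelation <- function(tableA, tableB) {
  stopifnot(all(c("gene", "rvis") %in% names(tableA)),
            all(c("gene", "rvis") %in% names(tableB)))
  a <- tableA[!is.na(tableA$rvis), c("gene", "rvis")]
  b <- tableB[!is.na(tableB$rvis), c("gene", "rvis")]
  j <- merge(a, b, by = "gene", suffixes = c(".a", ".b"))
  if (nrow(j) < 3L)
    stop("fewer than 3 shared genes between the two tables", call. = FALSE)
  ct <- cor.test(j$rvis.a, j$rvis.b, method = "pearson")
  list(r = unname(ct$estimate),
       ciLow = ct$conf.int[1], ciHigh = ct$conf.int[2],
       p = ct$p.value, nJoined = nrow(j),
       nOnlyA = nrow(a) - nrow(j), nOnlyB = nrow(b) - nrow(j))
}

#' Constraint tests for a collection of gene sets
#'
#' For each set: Welch t-test of set scores against the background (all
#' scored genes not in the set) and logistic regression of membership on
#' the score, after outlier exclusion. Gene symbols are matched exactly and
#' case-sensitively unless \code{normalizeCase} is set.
#'
#' @param table an \linkS4class{RVISTable}.
#' @param geneSets named list of character vectors (see
#'   \code{\link{readGeneSets}}).
#' @param normalizeCase uppercase both sides before matching (default off).
#' @return data.frame, one row per set: group sizes, means, SDs, t, df, p,
#'   beta, seBeta, oddsRatio, orP.
#' @export
constraintTests <- function(table, geneSets, normalizeCase = FALSE) {
  stopifnot(is(table, "RVISTable"), is.list(geneSets),
            !is.null(names(geneSets)))
  sc <- rvisScores(table)
  sc <- sc[!sc$excluded & !is.na(sc$rvis), ]
  genes <- sc$gene
  if (normalizeCase) genes <- toupper(genes)
  rows <- lapply(names(geneSets), function(nm) {
    members <- geneSets[[nm]]
    if (normalizeCase) members <- toupper(members)
    inSet <- genes %in% members
    if (sum(inSet) < 2L || sum(!inSet) < 2L)
      stop("set '", nm, "': fewer than 2 scored genes in a group",
           call. = FALSE)
    wt <- welchTTest(sc$rvis[inSet], sc$rvis[!inSet])
    lg <- logisticAssociation(inSet, sc$rvis)
    data.frame(set = nm,
               nSet = wt$nSet, meanSet = wt$meanSet, sdSet = wt$sdSet,
               nBackground = wt$nBackground,
               meanBackground = wt$meanBackground,
               sdBackground = wt$sdBackground,
               t = wt$t, df = wt$df, p = wt$p,
               beta = lg$beta, seBeta = lg$se,
               oddsRatio = lg$oddsRatio, orP = lg$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
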