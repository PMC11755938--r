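# Gene set enrichment over the constraint-ranked genome: unweighted
# Kolmogorov-Smirnov running-sum enrichment score with a permutation null,
# and hypergeometric over-representation within the most constrained tail.

#' Rank genes by constraint
#'
#' Orders scored genes ascending by score (most constrained first); ties
#' are broken by gene label in lexicographic order. Excluded or unscored
#' genes are dropped.
#'
#' @param table an \linkS4class{RVISTable}, or a data.frame with columns
#'   \code{gene} and \code{rvis}.
#' @return character vector of gene ids, most constrained first.
#' @export
rankGenes <- function(table) {
  sc <- if (is(table, "RVISTable")) rvisScores(table) else table
  stopifnot(all(c("gene", "rvis") %in% names(sc)))
  if ("excluded" %in% names(sc)) sc <- sc[!sc$excluded, ]
  sc <- sc[!is.na(sc$rvis), ]
  if (nrow(sc) == 0L) stop("no scored genes to rank", call. = FALSE)
  sc$gene[order(sc$rvis, sc$gene, method = "radix")]
}

# Signed extremum of the hit/miss running sum, computed from hit positions:
# the walk's local maxima sit just after a hit, local minima just before
# one (or at the walk ends, where the sum is 0).
.ksFromHits <- function(hitPos, N, Nh) {
  i <- seq_len(Nh)
  after <- i / Nh - (hitPos - i) / (N - Nh)
  before <- (i - 1) / Nh - (hitPos - i) / (N - Nh)
  hi <- max(after, 0)
  lo <- min(before, 0)
  # exact ties between the positive and negative extremum resolve positive;
  # the comparison is rounded so both extrema routes agree to fp error
  if (round(hi + lo, 9) >= 0) hi else lo
}

#' Kolmogorov-Smirnov enrichment score
#'
#' Unweighted running sum over the ranked genome: each set member (hit)
#' adds 1/Nh, each miss subtracts 1/(N - Nh). The enrichment score is the
#' deviation of maximum absolute value, signed: positive when the set
#' clusters toward the constrained top of the ranking (ties between equal
#' positive and negative extrema resolve positive). The sum returns to 0
#' after the last gene.
#'
#' @param ranked character vector from \code{\link{rankGenes}}.
#' @param set character vector of set member gene ids.
#' @return the enrichment score in [-1, 1].
#' @export
#' @examples
#' ksEnrichmentScore(letters[1:10], letters[1:3])   # 1: all hits on top
ksEnrichmentScore <- function(ranked, set) {
  hits <- ranked %in% set
  Nh <- sum(hits)
  N <- length(ranked)
  if (Nh == 0L) stop("gene set is disjoint from the ranked genome",
                     call. = FALSE)
  if (Nh == N) stop("gene set covers the entire ranked genome",
                    call. = FALSE)
  .ksFromHits(which(hits), N, Nh)
}

#' Permutation p-value for the enrichment score
#'
#' Null distribution built by drawing \code{nPerm} random gene sets of the
#' same size from the ranked genome (label sampling, equivalent to
#' permuting the ranking for an unweighted statistic). The p-value is
#' \code{(1 + #\{|ES_null| >= |ES_obs|\}) / (nPerm + 1)}, so it is bounded
#' below by \code{1/(nPerm + 1)}. Deterministic for a fixed seed.
#'
#' @param ranked character vector from \code{\link{rankGenes}}.
#' @param set character vector of set member gene ids.
#' @param nPerm number of permutations (>= 100; default 10000).
#' @param seed integer seed (mandatory).
#' @param setName optional label carried into the result.
#' @return list: \code{set, es, p, nPerm, seed, leadingEdgeSize, nHits}.
#' @export
permutationPvalue <- function(ranked, set, nPerm = 10000, seed,
                              setName = NA_character_) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (nPerm < 100) stop("nPerm must be at least 100", call. = FALSE)
  hits <- which(ranked %in% set)
  N <- length(ranked)
  Nh <- length(hits)
  if (Nh == 0L) stop("gene set is disjoint from the ranked genome",
                     call. = FALSE)
  if (Nh == N) stop("gene set covers the entire ranked genome",
                    call. = FALSE)
  es <- .ksFromHits(hits, N, Nh)

  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i)
    .ksFromHits(sort.int(sample.int(N, Nh)), N, Nh), numeric(1))
  p <- (1 + sum(abs(null) >= abs(es))) / (nPerm + 1)

  # leading edge: hits at or before the positive extremum (resp. from the
  # negative one onwards)
  i <- seq_len(Nh)
  after <- i / Nh - (hits - i) / (N - Nh)
  before <- (i - 1) / Nh - (hits - i) / (N - Nh)
  lead <- if (es >= 0) which.max(after) else Nh - which.min(before) + 1L
  list(set = setName, es = es, p = p, nPerm = as.integer(nPerm),
       seed = as.integer(seed), leadingEdgeSize = as.integer(lead),
       nHits = Nh)
}

#' Size of the most constrained tail
#'
#' @param nGenes number of ranked genes.
#' @param fraction tail fraction in (0, 1) (default 0.02).
#' @return \code{floor(nGenes * fraction)} as an integer.
#' @export
#' @examples
#' topTailSize(18166)   # 363
topTailSize <- function(nGenes, fraction = 0.02) {
  stopifnot(fraction > 0, fraction < 1, isCount(nGenes, 1L))
  as.integer(floor(round(nGenes * fraction, 9)))
}

#' Hypergeometric over-representation in the constrained tail
#'
#' Upper-tail probability of observing at least the seen number of set
#' members among the top-fraction most constrained genes: population
#' N = ranked genome size, successes K = set members present in the
#' ranking, draws n = tail size, observed k = set members in the tail.
#' Set members absent from the ranking are dropped from K with a warning.
#'
#' @param ranked character vector from \code{\link{rankGenes}}.
#' @param set character vector of set member gene ids.
#' @param fraction tail fraction (default 0.02).
#' @param setName optional label carried into the result.
#' @return list: \code{set, universeN, tailN, setK, overlapK, p}.
#' @export
hypergeometricOverrep <- function(ranked, set, fraction = 0.02,
                                  setName = NA_character_) {
  N <- length(ranked)
  n <- topTailSize(N, fraction)
  if (n == 0L) stop("degenerate tail: zero genes at this fraction",
                    call. = FALSE)
  set <- unique(set)
  present <- set[set %in% ranked]
  if (length(present) < length(set))
    warning(length(set) - length(present),
            " set gene(s) absent from the ranked genome dropped",
            call. = FALSE)
  K <- length(present)
  if (K == 0L) stop("gene set is disjoint from the ranked genome",
                    call. = FALSE)
  k <- sum(ranked[seq_len(n)] %in% present)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(set = setName, universeN = N, tailN = n, setK = K,
       overlapK = k, p = p)
}

#' Enrichment analysis for a collection of gene sets
#'
#' Runs the KS enrichment score with permutation p-value and the top-tail
#' hypergeometric over-representation for every set against one ranking.
#'
#' @param ranked character vector from \code{\link{rankGenes}}.
#' @param geneSets named list of character vectors.
#' @param nPerm permutations per set.
#' @param seed integer seed; per-set seeds are derived from it.
#' @param fraction constrained-tail fraction.
#' @return data.frame, one row per set: \code{set, nHits, es, esP, tailN,
#'   overlapK, overrepP}.
#' @export
enrichmentTests <- function(ranked, geneSets, nPerm = 10000, seed,
                            fraction = 0.02) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  rows <- lapply(names(geneSets), function(nm) {
    pr <- permutationPvalue(ranked, geneSets[[nm]], nPerm = nPerm,
                            seed = deriveSeed(seed, paste0("gsea:", nm)),
                            setName = nm)
    ov <- hypergeometricOverrep(ranked, geneSets[[nm]], fraction = fraction,
                                setName = nm)
    data.frame(set = nm, nHits = pr$nHits, es = pr$es, esP = pr$p,
               tailN = ov$tailN, overlapK = ov$overlapK, overrepP = ov$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
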