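# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# Externally studentized residuals by literally refitting OLS n times with
# each point left out: t_i = r_i / (s_(-i) * sqrt(1 - h_i)).
oracleStudentized <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  fitAll <- lm.fit(X, y)
  r <- fitAll$residuals
  vapply(seq_len(n), function(i) {
    fit <- lm.fit(X[-i, , drop = FALSE], y[-i])
    s2 <- sum(fit$residuals^2) / (n - 1 - 2)
    den <- sqrt(s2 * (1 - H[i, i]))
    val <- r[i] / den
    # the leave-one-out limit: deleting the point leaves an exact fit
    if (!is.finite(val) || abs(val) > 1e12) sign(r[i]) * Inf else val
  }, numeric(1))
}

# KS enrichment score by accumulating the full running sum step by step.
oracleKS <- function(ranked, set) {
  hits <- ranked %in% set
  Nh <- sum(hits)
  N <- length(ranked)
  step <- ifelse(hits, 1 / Nh, -1 / (N - Nh))
  s <- cumsum(step)
  hi <- max(c(s, 0))
  lo <- min(c(s, 0))
  if (round(hi + lo, 9) >= 0) hi else lo
}

# Hypergeometric upper tail P(X >= k) by direct combinatorial enumeration.
oracleHyper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Welch statistic from the textbook formulas.
oracleWelch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Shared small variant-record constructor for filter tests.
makeRecords <- function(n = 1, chrom = "chr1", pos = seq_len(n) * 100,
                        ref = "A", alt = "G", qual = 50, depth = 30,
                        af = 0.1, gene = "G1", effect = "missense",
                        damaging = FALSE, cadd = NA_real_) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
             depth = depth, af = af, gene = gene, effect = effect,
             damaging = damaging, cadd = cadd, stringsAsFactors = FALSE)
}

smallConfig <- function(seed = 1, nGenes = 60, ...) {
  SimConfig(nGenes = nGenes, seed = seed, ...)
}
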