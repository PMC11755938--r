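---
title: "Gene-level constraint from population variant catalogs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level constraint from population variant catalogs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GeneConstraint)
```

# Overview

GeneConstraint implements a gene-level mutational constraint analysis for a
population variant catalog: a quality screen over the catalog, a
Residual Variation Intolerance Score (RVIS) per gene, group statistics and
rank-based enrichment for disease gene sets, and a chain-file liftover
intersection of predicted-damaging variants with disease variant catalogs.
A seeded generator produces synthetic input bundles with known ground
truth, so every stage has parameter-recovery and calibration tests.

# The constraint model

## Counts

After filtering, each QC-passing variant carries a gene annotation, an
effect class from the controlled vocabulary `missense`, `lof`,
`synonymous`, `noncoding`, and an allele frequency. Per gene we form

* `x` — all protein-coding SNVs (`missense + lof + synonymous`);
* `y` — *common functional* SNVs: `missense + lof` with allele frequency at
  or above the MAF threshold.

`y <= x` by construction. Genes present in the gene models but absent from
the catalog participate with `x = y = 0`: a genome-wide score requires all
annotated genes in the fit, and a zero-burden gene is information, not
missingness. Variants annotated to genes missing from the models are
counted under their annotated gene with a warning rather than silently
dropped.

## Regression and studentization

`computeRVIS()` fits ordinary least squares of `y` on `x` with an
intercept and scores each gene with its *externally* studentized residual

$$ t_i = \frac{e_i}{s_{(-i)} \sqrt{1 - h_i}} $$

where `h_i` is the leverage and `s_(-i)` the residual standard error with
gene *i* deleted. Externally studentized residuals are the default because
a single strongly deviant gene otherwise inflates the variance estimate
used to judge itself; the internally studentized variant
(`flavor = "internal"`) is available for sensitivity analysis. The suite
verifies the scores against a brute-force oracle that literally refits the
regression *n* times.

Two numerical conventions deserve note:

* **Centring.** Studentized residuals do not sum exactly to zero, but the
  score is conventionally reported centred on 0. The table therefore
  carries both `studentized` (the raw leave-one-out value, which is what
  the oracle checks to 1e-8) and `rvis` (centred so that scored genes have
  mean 0 to below 1e-6). All downstream statistics use `rvis`; the Welch
  *t*, logistic slope, ranks and enrichment results are unaffected by the
  constant shift.
* **Degenerate limits.** If deleting one point leaves an exact fit,
  `s_(-i) = 0` and the mathematical limit of `t_i` is signed infinity; the
  implementation returns `+/-Inf` there (and the oracle does the same)
  rather than `NaN`. If the whole fit is exact, every score is defined as
  0 and the table is flagged degenerate.

## Outlier removal

`removeOutliers()` excludes genes with centred score above +11 — extreme
*tolerant* outliers, typically huge mucin-like genes whose burden swamps
the fit — and refits once. The threshold is one-sided by design: strongly
negative (constrained) genes are the signal, never pruned. The pass runs
once with a single refit, no cascade; re-screening after the refit could
iterate to an arbitrary depth and makes the estimator harder to reason
about.

# Group statistics

`constraintTests()` compares each gene set against the background of all
other scored genes (computed after outlier exclusion):

* Welch's unequal-variance *t*-test, two-sided. The disease sets are one to
  two orders of magnitude smaller than the background, and their score
  variance differs, so the Satterthwaite correction is not optional.
* Logistic regression of membership on the score. The odds ratio is
  `exp(beta)` per score unit, so constraint-enriched sets give OR < 1.
  Perfect separation is detected and refused (it means the asymptotic Wald
  machinery is meaningless), as is a single-class outcome.

`crossSpeciesCorrelation()` reports the Pearson correlation over the inner
join of two score tables with a Fisher-z 95% interval; genes missing from
either table are excluded and counted.

Gene symbols match exactly and case-sensitively by default; an uppercasing
hook exists but is off, because silent case-folding can merge distinct
symbols.

# Enrichment

`rankGenes()` orders scored genes ascending (most constrained first),
breaking score ties lexicographically by gene label so the ranking is a
deterministic function of its input.

`ksEnrichmentScore()` is the unweighted Kolmogorov–Smirnov running sum:
hits add `1/Nh`, misses subtract `1/(N-Nh)`, and the enrichment score ES is
the deviation of maximum absolute value, signed. The sum returns to zero
after the last gene. Implementation detail: the extrema are computed from
hit positions in O(Nh) — the walk's maxima occur just after hits, minima
just before — which the suite checks against a full cumulative-sum oracle;
an exact tie between the positive and negative extremum resolves positive,
with the comparison rounded at 1e-9 so both computations agree. The
weighted (score-modulated) GSEA statistic is deliberately out of scope.

`permutationPvalue()` draws random gene sets of size `Nh` as the null —
for an unweighted statistic this is equivalent to permuting the ranking,
and cheaper — and reports `p = (1 + #{|ES_null| >= |ES_obs|}) / (nPerm +
1)`. The +1 correction keeps p away from zero; the floor is
`1/(nPerm + 1)`.

`topTailSize()` floors `N * fraction` (the product is rounded at 1e-9
first, so exact integer products are not lost to floating point). For an
18,166-gene universe at 2% this gives 363; published descriptions of the
same cutoff cite both 363 and 369, and the floor convention is adopted
here without reconciling the two. `hypergeometricOverrep()` then reports
the upper-tail probability of the observed overlap between a set and the
tail, with set genes absent from the ranked universe dropped from `K`
under a warning.

# Liftover and damaging-variant reports

The chain parser resolves UCSC chain blocks to absolute paired intervals
and validates the block arithmetic against the stated spans, failing with
the chain id on mismatch. `liftPosition()` maps single 1-based positions:
offset within a block, reflection through the sequence length on
reverse-strand chains, `unmapped` (never an error) in gaps or outside
chains, highest-scoring chain winning where several cover a position.
Interval/indel liftover is out of scope since the upstream analysis is
SNV-only. The suite cross-checks the lifter against rtracklayer's
implementation on multi-block fixtures and round-trips through inverse
chains.

`overlapDiseaseVariants()` requires identical lifted position *and*
identical ref/alt alleles — a positional match with different alleles is a
different mutation. Strand-aware allele complementing is available behind
`flipAlleles` but off by default, so reverse-strand matching is an explicit
analyst decision. `setDamageReport()` counts genes (not variants) with at
least one damaging variant, so duplicated records cannot inflate the
proportions, which are reported half-up at one decimal place.
`rankByCadd()` orders by CADD descending with (chrom, pos) tie-breaks.

# The quality screen

A record is retained iff `qual >= 30`, `10 <= depth <= 50`, both alleles
are single bases, and the chromosome is in the autosome set. The published
screen states only the exclusion bounds ("< 30", "< 10 or > 50"), so the
boundary values 30, 10 and 50 are kept — the literal complement. Drop
reasons are assigned with fixed precedence (quality, depth, indel,
non-autosome), making the counts a partition: `n_input = n_retained + sum
of drops`, an invariant the summary object enforces. The SNV fraction is
computed among quality/depth survivors, matching how catalog releases
report it. Depth is the site-level `DP`; per-sample depth aggregation is
upstream's concern. Multi-allelic sites are split per ALT before
filtering, because effect annotations are per-allele. No MAF-based
exclusion is applied at this stage — the MAF threshold only enters the
common/rare split inside the RVIS numerator.

# Key parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `qualMin` | 30 | Phred | literal exclusion bound of the screen |
| `depthMin`, `depthMax` | 10, 50 | reads | inclusive complement of "< 10 or > 50" |
| `mafThreshold` | 0.001 | allele freq. | the conventional RVIS common/rare cut; the macaque value is unstated upstream, so it is exposed (`--maf-threshold` equivalent: argument) |
| `outlierThreshold` | 11 | score units | published removal rule for extreme tolerant genes |
| `tailFraction` | 0.02 | fraction | top-2% constrained tail |
| `nPerm` | 10000 (module), 1000 (pipeline) | draws | p floor 1e-4 / 1e-3; raise for smaller nominal p |
| `flavor` | external | — | leave-one-out studentization; internal available |

# The synthetic generator

`generateCatalog()` draws, per gene: a constrained flag
(`constrainedFraction`), total coding burden `X ~ NegBin(mean =
meanCodingVariants, size = dispersion)` (negative binomial because real
per-gene burdens are overdispersed; Poisson is the large-`size` limit),
and `Y ~ Binomial(X, p0 * c)` with `c = constraintFactor` for constrained
genes, else 1. Variants then realise these counts exactly: `Y` common
functional variants (AF uniform on `[mafThreshold, 0.5]`), the remaining
coding variants split between synonymous and rare functional (AF below the
threshold), plus a small Poisson number of noncoding variants. Functional
variants are flagged predicted-damaging at `damagingRate` with CADD drawn
uniform 10–50. QC-noise extras each violate exactly one screen rule and
are recorded. The chain files use one full-chromosome block at a constant
offset — enough to exercise the liftover arithmetic; richer chains
(gaps, reverse strand, multiple blocks) are covered by hand fixtures in
the tests. A configurable number of damaging variants is mirrored into the
disease catalog after applying the offset, giving planted matches the
overlap stage must recover exactly; decoy disease variants are placed
below the gene space so they can match nothing.

Everything is drawn from a single seed and serialised with fixed formats,
so a configuration reproduces its bundle byte for byte.

## Default study conditions

The defaults are the conditions under which the package's recovery and
calibration properties are stated: 2,000 genes on 20 autosomes (the
macaque autosome count), mean burden 40 with dispersion 5, baseline common
functional rate 0.4, constraint factor 0.3 applied to a constrained tenth
of the genome, four disease sets sized 4–10% of the genome drawing 70% of
members from the constrained class, damaging rate 0.1, QC noise 5% per
rule, chain offset 1000, five planted matches. The constrained fraction
(0.10) and set bias (0.70) were fixed a priori by an analytic power
calculation: with a 2% tail of 40 genes, the hypergeometric
over-representation test must reach p < 0.01 in at least 95% of
replicates for the *smallest* default set, which requires the tail to be
dominated by a compact constrained class and sets substantially enriched
in it (computed power > 99% at these values, versus ~10–25% at a
constrained quarter with 50% bias). These are generator properties chosen
once, not tuning knobs for individual analyses.

With `constraintFactor = 1` constrained and unconstrained genes are
exchangeable, and the suite checks that Welch, logistic and permutation
p-values are then uniform over 200 replicate seeds (Kolmogorov–Smirnov
uniformity at alpha 0.01). Hypergeometric p-values are excluded from the
uniformity check only because their severe discreteness at desk scale
makes a KS test inappropriate, not because they misbehave.

## What the generator does not emulate

No linkage disequilibrium, no pedigree or admixture structure, no
platform-specific error models, no realistic allele-frequency spectrum
(AFs are uniform within their class, since only the threshold crossing
matters downstream), no shared variants between genes, and gene intervals
are regular and non-overlapping. Passing recovery tests therefore
demonstrates correctness of the statistical machinery under the stated
generative model — not robustness to the correlation structure of real
catalogs.

# Pipeline and reproducibility

`runPipeline()` composes simulate → qc → rvis → stats → gsea → overlap.
All randomness flows from one global seed through per-stage derived seeds
(hashed from the stage name), so inserting a stage leaves the other
streams untouched. Inputs are validated before any output is written;
failures raise classed conditions (`pipelineError_<stage>`) naming the
stage. Every output file's SHA-256 goes into `manifest.json`, and reruns
with an identical configuration are hash-identical. The pipeline is
exposed as an R function (with a YAML config option) rather than a shell
executable: the package's users drive analyses from R, and the function
surface composes and tests better than a subprocess.

# Problem sizes used by the test suite

Oracle-equivalence checks run at n ≤ 50 (regression), N ≤ 30 (running
sum) and N ≤ 20 (hypergeometric enumeration). Recovery runs 100
replicates at the full default scale (2,000 genes) on the generator's
count layer, where a replicate costs a simulation plus one OLS fit;
calibration runs 200 replicates at 500 genes with 199 permutations each.
These sizes were chosen so the entire suite completes in well under a
minute per file while keeping every binomial acceptance band at three
standard errors or tighter.

# Known limitations

* Constraint is modelled at the gene level; domain-level constraint is out
  of scope.
* The score regresses on a single covariate; gene length or GC content are
  not adjusted for, matching the univariate published design.
* `invertChain()` handles forward-strand chains only (reverse-strand
  mapping itself is supported in `liftPosition`).
* Alternative constraint metrics (pLI/LOEUF-style mixture models) are not
  implemented; RVIS is the deliberate choice for its interpretability and
  cross-species portability.
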