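#' @import methods
#' @importFrom stats lm rstudent rstandard coef t.test glm binomial cor.test
#'   phyper rbinom rnbinom rpois runif var sd setNames
#' @importFrom utils head read.table write.table
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Simulation configuration for the synthetic variant catalog
#'
#' Holds every knob of the synthetic-catalog generator: per-gene burden
#' distribution, the constraint gradient, gene-set composition, QC-noise
#' rates and the toy cross-assembly offset. Defaults describe the standard
#' study conditions used throughout the package's tests: 2,000 genes on 20
#' autosomes, a mean of 40 coding variants per gene (negative binomial,
#' size 5), a baseline common-functional rate of 0.4 reduced by a factor of
#' 0.3 in the constrained tenth of the genome, and disease sets drawing 70
#' percent of their members from the constrained class.
#'
#' @slot nGenes number of genes (>= 10).
#' @slot nChromosomes number of autosomes, labelled \code{chr1..chrN}.
#' @slot meanCodingVariants mean total protein-coding variants per gene (the
#'   negative binomial mean of X).
#' @slot dispersion negative binomial \code{size}; large values approach the
#'   Poisson limit.
#' @slot baselineRate expected Y/X for unconstrained genes (probability p0
#'   that a coding variant is common functional).
#' @slot constrainedFraction fraction of genes flagged constrained.
#' @slot constraintFactor multiplier in [0, 1] applied to \code{baselineRate}
#'   for constrained genes; 1 makes the two groups exchangeable.
#' @slot setSpecs list of gene-set specifications, each a list with elements
#'   \code{name}, \code{size}, \code{constrainedBias} (fraction of the set
#'   drawn from constrained genes).
#' @slot damagingRate probability that a functional variant is flagged
#'   predicted-damaging.
#' @slot qcNoise named numeric vector (\code{qual}, \code{depth},
#'   \code{indel}, \code{nonautosome}): fraction of extra variants generated
#'   to fail exactly that QC rule.
#' @slot mafThreshold allele-frequency cut separating common from rare.
#' @slot chainOffset signed integer offset of the toy target assembly.
#' @slot nPlantedMatches number of damaging variants mirrored into the
#'   disease catalog (exact matches after liftover).
#' @slot nDiseaseDecoys number of disease-catalog variants matching nothing.
#' @slot seed integer seed; the full bundle is byte-identical for a fixed
#'   seed.
#' @export
setClass("SimConfig", representation(
  nGenes = "integer",
  nChromosomes = "integer",
  meanCodingVariants = "numeric",
  dispersion = "numeric",
  baselineRate = "numeric",
  constrainedFraction = "numeric",
  constraintFactor = "numeric",
  setSpecs = "list",
  damagingRate = "numeric",
  qcNoise = "numeric",
  mafThreshold = "numeric",
  chainOffset = "integer",
  nPlantedMatches = "integer",
  nDiseaseDecoys = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 10L) msg <- c(msg, "nGenes must be >= 10")
  if (object@nChromosomes < 1L) msg <- c(msg, "nChromosomes must be >= 1")
  if (object@meanCodingVariants <= 0) msg <- c(msg, "meanCodingVariants must be positive")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be positive")
  for (p in c("baselineRate", "constrainedFraction", "damagingRate", "mafThreshold"))
    if (!isProb(slot(object, p))) msg <- c(msg, paste(p, "must be a probability in [0, 1]"))
  if (!(object@constraintFactor >= 0 && object@constraintFactor <= 1))
    msg <- c(msg, "constraintFactor must lie in [0, 1]")
  if (!all(c("qual", "depth", "indel", "nonautosome") %in% names(object@qcNoise)) ||
      !all(object@qcNoise >= 0 & object@qcNoise <= 1))
    msg <- c(msg, "qcNoise must be named probabilities: qual, depth, indel, nonautosome")
  for (s in object@setSpecs) {
    if (!all(c("name", "size", "constrainedBias") %in% names(s))) {
      msg <- c(msg, "each setSpec needs name, size, constrainedBias")
    } else {
      if (s$size > object@nGenes)
        msg <- c(msg, sprintf("set '%s': size exceeds nGenes", s$name))
      if (!isProb(s$constrainedBias))
        msg <- c(msg, sprintf("set '%s': constrainedBias must be in [0, 1]", s$name))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param nGenes,nChromosomes,meanCodingVariants,dispersion,baselineRate
#'   see the class documentation.
#' @param constrainedFraction,constraintFactor,setSpecs,damagingRate see the
#'   class documentation.
#' @param qcNoise,mafThreshold,chainOffset,nPlantedMatches,nDiseaseDecoys,seed
#'   see the class documentation.
#' @return a validated \linkS4class{SimConfig}.
#' @export
#' @examples
#' cfg <- SimConfig(nGenes = 200, seed = 1)
SimConfig <- function(nGenes = 2000,
                      nChromosomes = 20,
                      meanCodingVariants = 40,
                      dispersion = 5,
                      baselineRate = 0.4,
                      constrainedFraction = 0.1,
                      constraintFactor = 0.3,
                      setSpecs = NULL,
                      damagingRate = 0.1,
                      qcNoise = c(qual = 0.05, depth = 0.05,
                                  indel = 0.05, nonautosome = 0.05),
                      mafThreshold = 0.001,
                      chainOffset = 1000,
                      nPlantedMatches = 5,
                      nDiseaseDecoys = 50,
                      seed = 1) {
  if (!isCount(seed) && !(is.numeric(seed) && seed == floor(seed)))
    stop("seed must be an integer", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != floor(seed))
    stop("seed must be an integer", call. = FALSE)
  if (is.null(setSpecs)) {
    # default disease-set sizes scale with the genome: roughly the relative
    # sizes of the ASD/ID/epilepsy/schizophrenia lists
    frac <- c(ASD = 0.04, ID = 0.08, epilepsy = 0.045, SCZ = 0.10)
    setSpecs <- lapply(names(frac), function(nm) list(
      name = nm, size = max(2L, as.integer(round(nGenes * frac[[nm]]))),
      constrainedBias = 0.7))
  }
  new("SimConfig",
      nGenes = as.integer(nGenes),
      nChromosomes = as.integer(nChromosomes),
      meanCodingVariants = as.numeric(meanCodingVariants),
      dispersion = as.numeric(dispersion),
      baselineRate = as.numeric(baselineRate),
      constrainedFraction = as.numeric(constrainedFraction),
      constraintFactor = as.numeric(constraintFactor),
      setSpecs = setSpecs,
      damagingRate = as.numeric(damagingRate),
      qcNoise = qcNoise,
      mafThreshold = as.numeric(mafThreshold),
      chainOffset = as.integer(chainOffset),
      nPlantedMatches = as.integer(nPlantedMatches),
      nDiseaseDecoys = as.integer(nDiseaseDecoys),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes on", object@nChromosomes,
      "autosomes\n")
  cat("  X ~ NB(mean =", object@meanCodingVariants, ", size =",
      object@dispersion, "); p0 =", object@baselineRate, "\n")
  cat("  constrained fraction", object@constrainedFraction,
      "x factor", object@constraintFactor, "\n")
  cat("  gene sets:", paste(vapply(object@setSpecs, `[[`, "", "name"),
                            collapse = ", "), "\n")
  cat("  seed:", object@seed, "\n")
})

#' Synthetic catalog bundle
#'
#' In-memory result of \code{\link{generateCatalog}}: the variant table
#' (clean variants plus QC-violating extras), gene models, gene sets,
#' disease-variant catalog, damaging-variant table, forward and inverse
#' chain text, and the per-gene ground truth.
#'
#' @slot variants data.frame of all emitted variants (column \code{qcFail}
#'   names the violated rule, \code{NA} for clean variants).
#' @slot geneModels \code{GRanges} of coding intervals (one per gene,
#'   \code{$gene} metadata column).
#' @slot geneSets named list of character vectors.
#' @slot diseaseVariants data.frame (target-assembly coordinates).
#' @slot damagingVariants data.frame (source-assembly coordinates).
#' @slot chainLines character: UCSC chain text, source -> target.
#' @slot chainInverseLines character: target -> source chain text.
#' @slot truth per-gene ground-truth data.frame.
#' @slot config the generating \linkS4class{SimConfig}.
#' @export
setClass("CatalogBundle", representation(
  variants = "data.frame",
  geneModels = "GRanges",
  geneSets = "list",
  diseaseVariants = "data.frame",
  damagingVariants = "data.frame",
  chainLines = "character",
  chainInverseLines = "character",
  truth = "data.frame",
  config = "SimConfig"
))

setValidity("CatalogBundle", function(object) {
  tr <- object@truth
  if (nrow(tr) && any(tr$y > tr$x)) return("truth violates y <= x")
  if (nrow(tr) != object@config@nGenes) return("one truth row per gene required")
  TRUE
})

setMethod("show", "CatalogBundle", function(object) {
  cat("CatalogBundle:", nrow(object@truth), "genes,",
      nrow(object@variants), "variants (",
      sum(!is.na(object@variants$qcFail)), "QC-violating ),",
      length(object@geneSets), "gene sets\n")
})

#' Quality-control summary
#'
#' Counts from one pass of \code{\link{qcFilter}}. Drop reasons are assigned
#' with fixed precedence (quality, then depth, then indel, then
#' non-autosome) so every record is counted exactly once and
#' \code{nInput = nRetained + sum(dropped)}. The SNV fraction is computed
#' among records surviving the quality and depth screens, on the 0--100
#' scale at one decimal place.
#'
#' @slot nInput,nRetained record counts in and out.
#' @slot nDroppedQual,nDroppedDepth,nDroppedIndel,nDroppedNonautosome drop
#'   counts by reason.
#' @slot nSnvRetained,nIndelSeen SNV/indel counts among qual+depth survivors.
#' @slot snvFraction percentage of SNVs among qual+depth survivors (1 d.p.).
#' @export
setClass("QCSummary", representation(
  nInput = "integer",
  nDroppedQual = "integer",
  nDroppedDepth = "integer",
  nDroppedIndel = "integer",
  nDroppedNonautosome = "integer",
  nRetained = "integer",
  nSnvRetained = "integer",
  nIndelSeen = "integer",
  snvFraction = "numeric"
))

setValidity("QCSummary", function(object) {
  tot <- object@nRetained + object@nDroppedQual + object@nDroppedDepth +
    object@nDroppedIndel + object@nDroppedNonautosome
  if (tot != object@nInput) return("count conservation violated")
  TRUE
})

setMethod("show", "QCSummary", function(object) {
  cat("QCSummary:", object@nInput, "in,", object@nRetained, "retained\n")
  cat("  dropped: qual", object@nDroppedQual, "| depth",
      object@nDroppedDepth, "| indel", object@nDroppedIndel,
      "| non-autosome", object@nDroppedNonautosome, "\n")
  cat("  SNV fraction among qual+depth survivors:",
      ifelse(is.na(object@snvFraction), "NA",
             paste0(object@snvFraction, "%")), "\n")
})

#' Per-gene constraint score table
#'
#' Result of the intolerance regression: ordinary least squares of the
#' common functional variant count (y) on the total protein-coding variant
#' count (x), with studentized residuals as the constraint score. The
#' \code{rvis} column is the mean-centred studentized residual (so scored
#' genes centre exactly on 0); \code{studentized} keeps the uncentred value.
#' Negative scores mean fewer common functional variants than predicted,
#' i.e. a constrained, mutation-intolerant gene.
#'
#' @slot scores data.frame: \code{gene, x, y, raw, studentized, rvis,
#'   excluded}.
#' @slot intercept,slope,sigma OLS fit parameters (residual standard error).
#' @slot nFit number of genes in the fit.
#' @slot flavor \code{"external"} (leave-one-out) or \code{"internal"}
#'   studentization.
#' @slot degenerate TRUE when the fit is exact (all residuals zero) and the
#'   scores were set to 0.
#' @slot outlierThreshold threshold used by \code{\link{removeOutliers}}
#'   (NA before outlier removal).
#' @export
setClass("RVISTable", representation(
  scores = "data.frame",
  intercept = "numeric",
  slope = "numeric",
  sigma = "numeric",
  nFit = "integer",
  flavor = "character",
  degenerate = "logical",
  outlierThreshold = "numeric"
))

setValidity("RVISTable", function(object) {
  need <- c("gene", "x", "y", "raw", "studentized", "rvis", "excluded")
  if (!all(need %in% names(object@scores)))
    return(paste("scores must have columns:", paste(need, collapse = ", ")))
  sc <- object@scores
  if (any(!sc$excluded & is.na(sc$rvis)))
    return("non-excluded genes must carry a score")
  ok <- sc$rvis[!sc$excluded & is.finite(sc$rvis)]
  if (!object@degenerate && length(ok) > 2 && abs(mean(ok)) > 1e-6)
    return("mean of fitted scores must be 0 (within 1e-6)")
  TRUE
})

setMethod("show", "RVISTable", function(object) {
  cat("RVISTable:", nrow(object@scores), "genes (",
      sum(object@scores$excluded), "excluded ),", object@flavor,
      "studentization\n")
  cat(sprintf("  fit: y = %.4f + %.4f x, sigma = %.4f, n = %d\n",
              object@intercept, object@slope, object@sigma, object@nFit))
  if (!is.na(object@outlierThreshold))
    cat("  outliers removed above", object@outlierThreshold, "\n")
})

#' Accessor: per-gene scores of an RVISTable
#' @param object an \linkS4class{RVISTable}.
#' @return data.frame with columns gene, x, y, raw, studentized, rvis,
#'   excluded.
#' @export
setGeneric("rvisScores", function(object) standardGeneric("rvisScores"))

#' @rdname rvisScores
#' @export
setMethod("rvisScores", "RVISTable", function(object) object@scores)

#' Accessor: regression fit of an RVISTable
#' @param object an \linkS4class{RVISTable}.
#' @return list with intercept, slope, sigma, nFit, flavor, degenerate.
#' @export
setGeneric("rvisFit", function(object) standardGeneric("rvisFit"))

#' @rdname rvisFit
#' @export
setMethod("rvisFit", "RVISTable", function(object) {
  list(intercept = object@intercept, slope = object@slope,
       sigma = object@sigma, nFit = object@nFit,
       flavor = object@flavor, degenerate = object@degenerate)
})

#' Accessor: QC counts as a named vector
#' @param object a \linkS4class{QCSummary}.
#' @return named integer/numeric vector of all summary fields.
#' @export
setGeneric("qcCounts", function(object) standardGeneric("qcCounts"))

#' @rdname qcCounts
#' @export
setMethod("qcCounts", "QCSummary", function(object) {
  c(nInput = object@nInput,
    nDroppedQual = object@nDroppedQual,
    nDroppedDepth = object@nDroppedDepth,
    nDroppedIndel = object@nDroppedIndel,
    nDroppedNonautosome = object@nDroppedNonautosome,
    nRetained = object@nRetained,
    nSnvRetained = object@nSnvRetained,
    nIndelSeen = object@nIndelSeen,
    snvFraction = object@snvFraction)
})

#' Parsed chain index for point liftover
#'
#' UCSC chain alignments resolved to paired absolute intervals. Source
#' (\code{t}) intervals are 0-based half-open on the forward strand; target
#' (\code{q}) block starts are kept in strand coordinates and reflected at
#' lookup time when the chain maps to the reverse strand.
#'
#' @slot blocks data.frame: \code{chainId, score, tName, tSize, qName,
#'   qSize, qStrand, sStart, sEnd, qStart}.
#' @slot chains data.frame of chain headers.
#' @export
setClass("ChainIndex", representation(
  blocks = "data.frame",
  chains = "data.frame"
))

setValidity("ChainIndex", function(object) {
  b <- object@blocks
  if (nrow(b) == 0) return(TRUE)
  if (any(b$sEnd <= b$sStart)) return("empty or inverted block")
  if (any(b$sEnd > b$tSize)) return("block exceeds source sequence size")
  sp <- split(b, paste(b$chainId, b$tName))
  for (g in sp) {
    g <- g[order(g$sStart), ]
    if (nrow(g) > 1 && any(g$sStart[-1] < g$sEnd[-nrow(g)]))
      return("overlapping blocks within a chain")
  }
  TRUE
})

setMethod("show", "ChainIndex", function(object) {
  cat("ChainIndex:", nrow(object@chains), "chains,",
      nrow(object@blocks), "alignment blocks\n")
  if (nrow(object@chains))
    cat("  source:", paste(unique(object@chains$tName), collapse = " "),
        "-> target:", paste(unique(object@chains$qName), collapse = " "),
        "\n")
})
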