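# End-to-end orchestration: simulate -> qc -> rvis -> stats -> gsea ->
# overlap, with a deterministic manifest. All randomness flows from one
# global seed through per-stage derived seeds, so adding a stage does not
# shift the streams of the others.

.pipelineStop <- function(stage, message) {
  stop(structure(class = c(paste0("pipelineError_", stage),
                           "pipelineError", "error", "condition"),
                 list(message = paste0("[stage ", stage, "] ", message),
                      call = NULL, stage = stage)))
}

.runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "pipelineError")) stop(e)
    .pipelineStop(stage, conditionMessage(e))
  })
}

#' Default pipeline configuration
#'
#' @param outputDir directory for all stage outputs.
#' @param seed global integer seed.
#' @param sim named list of \code{\link{SimConfig}} arguments for the
#'   simulate stage (ignored when \code{inputs} is given).
#' @param inputs optional named list of pre-existing input paths
#'   (\code{vcf, geneModels, setsDir, disease, damaging, chain}); when
#'   supplied the simulate stage is skipped.
#' @param qualMin,depthMin,depthMax QC thresholds.
#' @param autosomes retained chromosome labels.
#' @param mafThreshold common/rare allele-frequency cut.
#' @param outlierThreshold one-sided score cutoff for outlier removal.
#' @param tailFraction constrained-tail fraction for over-representation.
#' @param nPerm permutations for the enrichment null.
#' @param residualFlavor \code{"external"} or \code{"internal"}
#'   studentization.
#' @return a validated configuration list for \code{\link{runPipeline}}.
#' @export
pipelineConfig <- function(outputDir, seed, sim = list(), inputs = NULL,
                           qualMin = 30, depthMin = 10, depthMax = 50,
                           autosomes = NULL, mafThreshold = 0.001,
                           outlierThreshold = 11, tailFraction = 0.02,
                           nPerm = 1000,
                           residualFlavor = c("external", "internal")) {
  if (missing(outputDir)) stop("outputDir is required", call. = FALSE)
  if (missing(seed) || !isCount(abs(seed)))
    stop("an integer seed is required", call. = FALSE)
  list(outputDir = outputDir, seed = as.integer(seed), sim = sim,
       inputs = inputs, qualMin = qualMin, depthMin = depthMin,
       depthMax = depthMax, autosomes = autosomes,
       mafThreshold = mafThreshold, outlierThreshold = outlierThreshold,
       tailFraction = tailFraction, nPerm = nPerm,
       residualFlavor = match.arg(residualFlavor))
}

#' Run the full constraint pipeline
#'
#' Executes the six stages in order and writes every report plus a
#' \code{manifest.json} recording each file's SHA-256. Reruns with an
#' identical configuration reproduce identical hashes. Input paths are
#' validated before any stage runs, so a missing input never leaves partial
#' output behind; stage failures raise classed conditions
#' (\code{pipelineError_<stage>}) naming the stage.
#'
#' @param config a list from \code{\link{pipelineConfig}}, or the path of a
#'   YAML file holding the same fields.
#' @return the manifest, invisibly (list with \code{seed}, \code{parameters}
#'   and per-file \code{files} entries).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    raw <- yaml::read_yaml(config)
    config <- do.call(pipelineConfig, raw)
  }
  stopifnot(is.list(config), !is.null(config$outputDir),
            !is.null(config$seed))
  dir <- config$outputDir

  # validate external inputs before touching the output directory
  if (!is.null(config$inputs)) {
    need <- c("vcf", "geneModels", "setsDir", "disease", "damaging", "chain")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      .pipelineStop("inputs", paste("missing input entries:",
                                    paste(miss, collapse = ", ")))
    for (nm in need) {
      p <- config$inputs[[nm]]
      ok <- if (nm == "setsDir") dir.exists(p) else file.exists(p)
      if (!ok) .pipelineStop("inputs", paste0("missing input ", nm, ": ", p))
    }
  }

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  addFiles <- function(stage, paths) {
    for (p in paths) files[[length(files) + 1L]] <<- list(
      file = basename(p), stage = stage, sha256 = unname(fileSha256(p)))
  }

  # -- simulate ------------------------------------------------------------
  if (is.null(config$inputs)) {
    inDir <- file.path(dir, "inputs")
    paths <- .runStage("simulate", {
      simArgs <- config$sim
      simArgs$seed <- deriveSeed(config$seed, "simulate")
      bundle <- generateCatalog(do.call(SimConfig, simArgs))
      writeCatalog(bundle, inDir)
    })
    addFiles("simulate", paths)
    inputs <- list(vcf = paths[["vcf"]],
                   geneModels = paths[["gene_models"]],
                   setsDir = file.path(inDir, "sets"),
                   disease = paths[["disease"]],
                   damaging = paths[["damaging"]],
                   chain = paths[["chain"]])
    nChrom <- if (!is.null(config$sim$nChromosomes))
      config$sim$nChromosomes else 20
  } else {
    inputs <- config$inputs
    nChrom <- 20
  }
  autosomes <- if (!is.null(config$autosomes)) config$autosomes
  else autosomeLabels(nChrom)

  # -- qc ------------------------------------------------------------------
  qc <- .runStage("qc", {
    records <- readCatalog(inputs$vcf)
    qcFilter(records, qualMin = config$qualMin, depthMin = config$depthMin,
             depthMax = config$depthMax, autosomes = autosomes)
  })
  qcSummaryPath <- file.path(dir, "qc_summary.tsv")
  summarizeQc(qc$summary, qcSummaryPath)
  retainedPath <- file.path(dir, "retained_variants.tsv")
  writeTsv(qc$records, retainedPath)
  addFiles("qc", c(qcSummaryPath, retainedPath))

  # -- rvis ----------------------------------------------------------------
  rvisTable <- .runStage("rvis", {
    models <- readGeneModels(inputs$geneModels)
    counts <- countGeneVariants(qc$records, models,
                                mafThreshold = config$mafThreshold)
    removeOutliers(computeRVIS(counts, flavor = config$residualFlavor),
                   threshold = config$outlierThreshold)
  })
  rvisPath <- file.path(dir, "rvis_scores.tsv")
  writeTsv(rvisScores(rvisTable), rvisPath)
  addFiles("rvis", rvisPath)

  # -- stats ---------------------------------------------------------------
  geneSets <- .runStage("stats", readGeneSets(inputs$setsDir))
  statsDf <- .runStage("stats", constraintTests(rvisTable, geneSets))
  statsPath <- file.path(dir, "constraint_stats.tsv")
  writeTsv(statsDf, statsPath)
  addFiles("stats", statsPath)

  # -- gsea ----------------------------------------------------------------
  gseaDf <- .runStage("gsea", {
    ranked <- rankGenes(rvisTable)
    enrichmentTests(ranked, geneSets, nPerm = config$nPerm,
                    seed = deriveSeed(config$seed, "gsea"),
                    fraction = config$tailFraction)
  })
  gseaPath <- file.path(dir, "enrichment.tsv")
  writeTsv(gseaDf, gseaPath)
  addFiles("gsea", gseaPath)

  # -- overlap -------------------------------------------------------------
  overlap <- .runStage("overlap", {
    chainIdx <- parseChain(inputs$chain)
    damaging <- readTsv(inputs$damaging)
    disease <- readTsv(inputs$disease)
    list(matches = overlapDiseaseVariants(damaging, chainIdx, disease),
         report = setDamageReport(geneSets, damaging),
         cadd = rankByCadd(damaging))
  })
  matchPath <- file.path(dir, "overlap_matches.tsv")
  reportPath <- file.path(dir, "damage_report.tsv")
  caddPath <- file.path(dir, "cadd_top.tsv")
  writeTsv(overlap$matches, matchPath)
  writeTsv(overlap$report, reportPath)
  writeTsv(overlap$cadd, caddPath)
  addFiles("overlap", c(matchPath, reportPath, caddPath))

  manifest <- list(
    seed = config$seed,
    parameters = list(qualMin = config$qualMin, depthMin = config$depthMin,
                      depthMax = config$depthMax,
                      mafThreshold = config$mafThreshold,
                      outlierThreshold = config$outlierThreshold,
                      tailFraction = config$tailFraction,
                      nPerm = config$nPerm,
                      residualFlavor = config$residualFlavor),
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
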