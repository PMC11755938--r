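# Synthetic variant-catalog generator.
#
# Emulates the statistical structure the constraint analysis assumes: per-gene
# total coding burdens X drawn negative-binomial, common functional counts
# Y ~ Binomial(X, p0 * c_gene) with c_gene < 1 for constrained genes, disease
# gene sets biased toward constrained genes, predicted-damaging flags on
# functional variants, QC-violating extras at configurable rates, and a toy
# chain file linking the source assembly to an offset target assembly.

GENE_LEN <- 3000L      # coding interval length per gene (bp)
GENE_SPACING <- 5000L  # interval pitch along a chromosome
GENE_OFFSET <- 10000L  # 0-based start of the first interval on each chromosome

.effectLevels <- c("missense", "lof", "synonymous", "noncoding")
.damagingSources <- c("clinvar_pathogenic", "polyphen_damaging", "snpeff_high")

# Per-gene ground truth; assumes the RNG has already been seeded.
.simTruth <- function(config) {
  n <- config@nGenes
  genes <- sprintf("G%0*d", nchar(as.character(n)), seq_len(n))
  chrom <- paste0("chr", ((seq_len(n) - 1L) %% config@nChromosomes) + 1L)
  constrained <- runif(n) < config@constrainedFraction
  x <- rnbinom(n, size = config@dispersion, mu = config@meanCodingVariants)
  rate <- config@baselineRate *
    ifelse(constrained, config@constraintFactor, 1)
  y <- rbinom(n, x, rate)
  truth <- data.frame(gene = genes, chrom = chrom, constrained = constrained,
                      rate = rate, x = x, y = y,
                      stringsAsFactors = FALSE)
  for (spec in config@setSpecs) {
    conPool <- genes[constrained]
    unconPool <- genes[!constrained]
    nCon <- min(round(spec$size * spec$constrainedBias), length(conPool))
    nUncon <- min(spec$size - nCon, length(unconPool))
    members <- c(if (nCon) sample(conPool, nCon),
                 if (nUncon) sample(unconPool, nUncon))
    truth[[paste0("in_", spec$name)]] <- genes %in% members
  }
  truth
}

#' Simulate per-gene variant counts only
#'
#' Fast path through the generator: draws the per-gene ground truth (total
#' coding count x, common functional count y, constrained flag, gene-set
#' memberships) without materialising individual variants. Useful for
#' calibration studies that only need counts.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return data.frame with one row per gene: \code{gene, chrom, constrained,
#'   rate, x, y} plus one logical \code{in_<set>} column per configured set.
#' @export
#' @examples
#' tr <- simulateGeneCounts(SimConfig(nGenes = 50, seed = 3))
#' all(tr$y <= tr$x)
simulateGeneCounts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  .simTruth(config)
}

# Gene coding intervals laid out deterministically: genes assigned round-robin
# to chromosomes, fixed pitch within a chromosome. 1-based closed GRanges.
.geneModels <- function(truth, config) {
  slot <- stats::ave(seq_len(nrow(truth)), truth$chrom, FUN = seq_along)
  start0 <- GENE_OFFSET + (slot - 1L) * GENE_SPACING
  GenomicRanges::GRanges(
    seqnames = truth$chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = start0 + GENE_LEN),
    gene = truth$gene)
}

# Clean (QC-passing) variants realising the truth counts exactly.
.cleanVariants <- function(truth, models, config) {
  n <- nrow(truth)
  nnc <- rpois(n, 2)                       # noncoding variants per gene
  m <- pmin(truth$x + nnc, GENE_LEN)       # distinct positions available
  nnc <- m - truth$x
  gi <- rep(seq_len(n), m)
  start0 <- GenomicRanges::start(models) - 1L
  offs <- unlist(lapply(seq_len(n),
                        function(i) sample.int(GENE_LEN, m[i])),
                 use.names = FALSE)
  pos <- start0[gi] + offs
  idx <- sequence(m)
  isCommonFunc <- idx <= truth$y[gi]
  isCoding <- idx <= truth$x[gi]

  nv <- length(gi)
  effect <- character(nv)
  af <- numeric(nv)
  funcClass <- function(k) ifelse(runif(k) < 0.8, "missense", "lof")

  effect[isCommonFunc] <- funcClass(sum(isCommonFunc))
  af[isCommonFunc] <- runif(sum(isCommonFunc), config@mafThreshold, 0.5)

  rest <- isCoding & !isCommonFunc
  restSyn <- rest & (runif(nv) < 0.5)
  restRare <- rest & !restSyn
  effect[restSyn] <- "synonymous"
  af[restSyn] <- runif(sum(restSyn), 1e-6, 0.5)
  effect[restRare] <- funcClass(sum(restRare))
  af[restRare] <- runif(sum(restRare), 1e-6, config@mafThreshold * 0.999)

  nc <- !isCoding
  effect[nc] <- "noncoding"
  af[nc] <- runif(sum(nc), 1e-6, 0.5)

  ref <- sample(c("A", "C", "G", "T"), nv, replace = TRUE)
  altShift <- sample.int(3L, nv, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  alt <- bases[(match(ref, bases) - 1L + altShift) %% 4L + 1L]

  damaging <- effect %in% c("missense", "lof") &
    runif(nv) < config@damagingRate
  cadd <- rep(NA_real_, nv)
  cadd[damaging] <- roundHalfUp(runif(sum(damaging), 10, 50), 1)

  data.frame(chrom = truth$chrom[gi], pos = pos, ref = ref, alt = alt,
             qual = roundHalfUp(runif(nv, 30, 1500), 1),
             depth = sample(10:50, nv, replace = TRUE),
             af = af, gene = truth$gene[gi], effect = effect,
             damaging = damaging, cadd = cadd,
             qcFail = NA_character_, stringsAsFactors = FALSE)
}

# Extra variants violating exactly one QC rule each. Placed below the gene
# space (positions 1..GENE_OFFSET - 1000) so they never collide with clean
# variants; non-autosome extras go to chrX.
.qcExtras <- function(nCore, config) {
  rules <- c("qual", "depth", "indel", "nonautosome")
  counts <- vapply(rules, function(r) rbinom(1L, nCore, config@qcNoise[[r]]),
                   integer(1))
  tot <- sum(counts)
  if (tot == 0L) return(NULL)
  rule <- rep(rules, counts)
  chrom <- paste0("chr", sample.int(config@nChromosomes, tot, replace = TRUE))
  chrom[rule == "nonautosome"] <- "chrX"
  pos <- sample.int(GENE_OFFSET - 1000L, tot, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, tot, replace = TRUE)
  alt <- bases[(match(ref, bases) + sample.int(3L, tot, TRUE) - 1L) %% 4L + 1L]
  ref[rule == "indel"] <- paste0(ref[rule == "indel"],
                                 sample(bases, sum(rule == "indel"),
                                        replace = TRUE))
  qual <- roundHalfUp(runif(tot, 30, 1500), 1)
  qual[rule == "qual"] <- roundHalfUp(runif(sum(rule == "qual"), 1, 29.9), 1)
  depth <- sample(10:50, tot, replace = TRUE)
  nd <- sum(rule == "depth")
  if (nd) {
    lo <- runif(nd) < 0.5
    depth[rule == "depth"] <- ifelse(lo, sample(0:9, nd, replace = TRUE),
                                     sample(51:120, nd, replace = TRUE))
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             qual = qual, depth = depth,
             af = runif(tot, 1e-6, 0.5), gene = NA_character_,
             effect = "noncoding", damaging = FALSE, cadd = NA_real_,
             qcFail = rule, stringsAsFactors = FALSE)
}

.chromSizes <- function(models, config) {
  sizes <- vapply(split(GenomicRanges::end(models),
                        as.character(GenomicRanges::seqnames(models))),
                  max, numeric(1)) + 20000
  # every configured autosome gets a size even if it carries no gene
  all <- paste0("chr", seq_len(config@nChromosomes))
  out <- setNames(rep(GENE_OFFSET + 20000, length(all)), all)
  out[names(sizes)] <- sizes
  out
}

# One chain per autosome: a single block shifted by a constant offset.
.chainText <- function(sizes, offset, inverse = FALSE) {
  lines <- character(0)
  id <- 0L
  for (chrom in names(sizes)) {
    id <- id + 1L
    size <- as.integer(sizes[[chrom]])
    tStart <- max(0L, -offset)
    qStart <- tStart + offset
    bs <- size - tStart
    qEnd <- qStart + bs
    qSize <- max(size + offset, qEnd) + 1000L
    hdr <- if (!inverse) {
      sprintf("chain 1000 %s %d + %d %d %s %d + %d %d %d",
              chrom, size, tStart, size, chrom, qSize, qStart, qEnd, id)
    } else {
      sprintf("chain 1000 %s %d + %d %d %s %d + %d %d %d",
              chrom, qSize, qStart, qEnd, chrom, size, tStart, size, id)
    }
    lines <- c(lines, hdr, as.character(bs), "")
  }
  lines
}

#' Generate a synthetic catalog bundle
#'
#' Draws the full input bundle for the constraint pipeline from a seeded
#' configuration: per-gene ground truth, a variant table realising those
#' counts exactly (plus QC-violating extras), gene models, biased gene sets,
#' a predicted-damaging table, a disease-variant catalog containing planted
#' liftover matches, and forward/inverse chain text. The same seed yields an
#' identical bundle; \code{\link{writeCatalog}} serialises it byte-identically.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{CatalogBundle}.
#' @export
#' @examples
#' b <- generateCatalog(SimConfig(nGenes = 40, seed = 1))
#' b
generateCatalog <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)

  truth <- .simTruth(config)
  models <- .geneModels(truth, config)
  clean <- .cleanVariants(truth, models, config)
  extras <- .qcExtras(nrow(clean), config)
  variants <- rbind(clean, extras)
  chromNum <- suppressWarnings(as.integer(sub("^chr", "", variants$chrom)))
  variants <- variants[order(is.na(chromNum), chromNum, variants$pos,
                             variants$ref, variants$alt), ]
  rownames(variants) <- NULL

  geneSets <- lapply(config@setSpecs, function(s)
    truth$gene[truth[[paste0("in_", s$name)]]])
  names(geneSets) <- vapply(config@setSpecs, `[[`, "", "name")

  dmg <- variants[variants$damaging & is.na(variants$qcFail), ]
  damagingVariants <- data.frame(
    chrom = dmg$chrom, pos = dmg$pos, ref = dmg$ref, alt = dmg$alt,
    gene = dmg$gene,
    flags = sample(.damagingSources, nrow(dmg), replace = TRUE),
    cadd = dmg$cadd, stringsAsFactors = FALSE)

  nPlant <- config@nPlantedMatches
  if (nPlant > nrow(damagingVariants))
    stop("nPlantedMatches exceeds the number of damaging variants drawn (",
         nrow(damagingVariants), ")", call. = FALSE)
  diseases <- if (length(geneSets)) names(geneSets) else "disease"
  planted <- if (nPlant > 0) {
    p <- damagingVariants[sample.int(nrow(damagingVariants), nPlant), ]
    data.frame(chrom = p$chrom, pos = p$pos + config@chainOffset,
               ref = p$ref, alt = p$alt,
               disease = sample(diseases, nPlant, replace = TRUE),
               stringsAsFactors = FALSE)
  } else NULL
  nDecoy <- config@nDiseaseDecoys
  decoys <- if (nDecoy > 0) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nDecoy, replace = TRUE)
    data.frame(
      chrom = paste0("chr", sample.int(config@nChromosomes, nDecoy,
                                       replace = TRUE)),
      # below the gene space, so no damaging variant can lift onto a decoy
      pos = sample.int(GENE_OFFSET - 1000L, nDecoy, replace = TRUE) +
        config@chainOffset,
      ref = ref,
      alt = bases[(match(ref, bases) + sample.int(3L, nDecoy, TRUE) - 1L)
                  %% 4L + 1L],
      disease = sample(diseases, nDecoy, replace = TRUE),
      stringsAsFactors = FALSE)
  } else NULL
  diseaseVariants <- rbind(planted, decoys)
  if (is.null(diseaseVariants))
    diseaseVariants <- data.frame(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  disease = character(),
                                  stringsAsFactors = FALSE)

  sizes <- .chromSizes(models, config)
  new("CatalogBundle",
      variants = variants,
      geneModels = models,
      geneSets = geneSets,
      diseaseVariants = diseaseVariants,
      damagingVariants = damagingVariants,
      chainLines = .chainText(sizes, config@chainOffset),
      chainInverseLines = .chainText(sizes, config@chainOffset,
                                     inverse = TRUE),
      truth = truth,
      config = config)
}

.vcfHeader <- function(bundle) {
  sizes <- .chromSizes(bundle@geneModels, bundle@config)
  if (any(bundle@variants$chrom == "chrX"))
    sizes <- c(sizes, chrX = GENE_OFFSET + 20000)
  c("##fileformat=VCFv4.2",
    "##source=GeneConstraint-synthetic",
    sprintf("##contig=<ID=%s,length=%d>", names(sizes), as.integer(sizes)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Annotated gene\">",
    "##INFO=<ID=EFFECT,Number=A,Type=String,Description=\"Effect class\">",
    "##INFO=<ID=DMG,Number=0,Type=Flag,Description=\"Predicted damaging\">",
    "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"CADD score\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
}

.vcfBody <- function(v) {
  info <- sprintf("DP=%d;AF=%s;EFFECT=%s", v$depth,
                  formatC(v$af, format = "g", digits = 6), v$effect)
  hasGene <- !is.na(v$gene)
  info[hasGene] <- paste0(info[hasGene], ";GENE=", v$gene[hasGene])
  info[v$damaging] <- paste0(info[v$damaging], ";DMG")
  hasCadd <- !is.na(v$cadd)
  info[hasCadd] <- paste0(info[hasCadd], ";CADD=",
                          formatC(v$cadd[hasCadd], format = "f", digits = 1))
  sprintf("%s\t%d\t.\t%s\t%s\t%.1f\tPASS\t%s",
          v$chrom, v$pos, v$ref, v$alt, v$qual, info)
}

#' Write a catalog bundle to disk
#'
#' Serialises every component of the bundle as plain text: a VCF 4.2
#' catalog, BED-like gene models (0-based half-open), one gene-set file per
#' set, disease and damaging variant TSVs, forward and inverse UCSC chain
#' files, the per-gene truth table and a QC-noise audit table. Output is
#' byte-identical for a fixed configuration.
#'
#' @param bundle a \linkS4class{CatalogBundle}.
#' @param dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
writeCatalog <- function(bundle, dir) {
  stopifnot(is(bundle, "CatalogBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "sets"), showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "catalog.vcf"),
    gene_models = file.path(dir, "gene_models.tsv"),
    disease = file.path(dir, "disease_variants.tsv"),
    damaging = file.path(dir, "damaging_variants.tsv"),
    chain = file.path(dir, "map.chain"),
    chain_inverse = file.path(dir, "map_inverse.chain"),
    truth = file.path(dir, "truth.tsv"),
    qc_extras = file.path(dir, "qc_extras.tsv"))

  writeLines(c(.vcfHeader(bundle), .vcfBody(bundle@variants)), paths["vcf"])

  gm <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(bundle@geneModels)),
    start = GenomicRanges::start(bundle@geneModels) - 1L,
    end = GenomicRanges::end(bundle@geneModels),
    gene = bundle@geneModels$gene, stringsAsFactors = FALSE)
  writeTsv(gm, paths["gene_models"])

  for (nm in names(bundle@geneSets)) {
    p <- file.path(dir, "sets", paste0(nm, ".txt"))
    writeLines(sort(bundle@geneSets[[nm]]), p)
    paths[paste0("set_", nm)] <- p
  }
  writeTsv(bundle@diseaseVariants, paths["disease"])
  writeTsv(bundle@damagingVariants, paths["damaging"])
  writeLines(bundle@chainLines, paths["chain"])
  writeLines(bundle@chainInverseLines, paths["chain_inverse"])
  writeTruth(bundle@truth, paths["truth"])

  ex <- bundle@variants$qcFail
  writeTsv(data.frame(rule = c("qual", "depth", "indel", "nonautosome"),
                      n = c(sum(ex == "qual", na.rm = TRUE),
                            sum(ex == "depth", na.rm = TRUE),
                            sum(ex == "indel", na.rm = TRUE),
                            sum(ex == "nonautosome", na.rm = TRUE))),
           paths["qc_extras"])
  invisible(paths)
}

#' Write / read the per-gene truth table
#'
#' Plain TSV round-trip for the generator's ground truth; an empty truth
#' yields a header-only file.
#'
#' @param truth data.frame as produced by \code{\link{generateCatalog}} (or
#'   \code{\link{simulateGeneCounts}}).
#' @param path file path.
#' @return \code{writeTruth}: the path, invisibly. \code{readTruth}: the
#'   truth data.frame.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is.data.frame(truth))
  writeTsv(truth, path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path, call. = FALSE)
  df <- readTsv(path)
  for (cl in grep("^(constrained|in_)", names(df), value = TRUE))
    df[[cl]] <- as.logical(df[[cl]])
  df
}

#' Read gene models from a BED-like TSV
#'
#' Expects columns \code{chrom, start, end, gene} with 0-based half-open
#' coordinates, and returns 1-based closed genomic ranges.
#'
#' @param path TSV path.
#' @return \code{GRanges} with a \code{gene} metadata column.
#' @export
readGeneModels <- function(path) {
  df <- readTsv(path)
  need <- c("chrom", "start", "end", "gene")
  if (!all(need %in% names(df)))
    stop("gene model table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end),
                         gene = df$gene)
}

#' Read gene sets from a directory of plain-text lists
#'
#' Each \code{*.txt} file holds one gene symbol per line; the file name
#' (without extension) becomes the set name. Blank lines are dropped and
#' duplicate symbols collapsed.
#'
#' @param dir directory containing the set files.
#' @return named list of character vectors.
#' @export
readGeneSets <- function(dir) {
  if (!dir.exists(dir)) stop("gene-set directory not found: ", dir,
                             call. = FALSE)
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no .txt gene-set files in ", dir, call. = FALSE)
  sets <- lapply(files, function(f) {
    g <- unique(trimws(readLines(f)))
    g <- g[nzchar(g)]
    if (!length(g)) stop("empty gene set: ", f, call. = FALSE)
    g
  })
  names(sets) <- sub("\\.txt$", "", basename(files))
  sets
}
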