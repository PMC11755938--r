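# UCSC chain parsing, point liftover, disease-variant overlap and the
# damaging-variant reports.
#
# Chain conventions: the target (t) side of a chain header is the source
# assembly of the liftover, the query (q) side the destination; t coordinates
# are always forward-strand, q coordinates are strand-local and reflected
# through qSize when qStrand is '-'. All block bookkeeping is 0-based
# half-open; user-facing positions are 1-based.

#' Parse a UCSC chain file
#'
#' Resolves every alignment block to an absolute paired interval and
#' validates the chain arithmetic: block sizes plus gaps must reproduce the
#' stated t and q spans, otherwise parsing fails naming the chain id.
#'
#' @param path chain file path.
#' @return a \linkS4class{ChainIndex}.
#' @export
parseChain <- function(path) {
  if (!file.exists(path)) stop("chain file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  i <- 1L
  chains <- list()
  blocks <- list()
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) != 13L)
      stop("chain parse error at line ", i, ": expected a 13-field chain ",
           "header", call. = FALSE)
    hdr <- list(score = as.numeric(f[2]),
                tName = f[3], tSize = as.numeric(f[4]), tStrand = f[5],
                tStart = as.numeric(f[6]), tEnd = as.numeric(f[7]),
                qName = f[8], qSize = as.numeric(f[9]), qStrand = f[10],
                qStart = as.numeric(f[11]), qEnd = as.numeric(f[12]),
                id = f[13])
    if (hdr$tStrand != "+")
      stop("chain ", hdr$id, ": target strand must be '+'", call. = FALSE)
    i <- i + 1L
    sizes <- numeric(0); dts <- numeric(0); dqs <- numeric(0)
    repeat {
      if (i > length(lines) || !nzchar(lines[i]))
        stop("chain ", hdr$id, ": truncated block list", call. = FALSE)
      g <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t]+")[[1]]))
      if (any(is.na(g)))
        stop("chain ", hdr$id, ": malformed block line ", i, call. = FALSE)
      if (length(g) == 1L) { sizes <- c(sizes, g); i <- i + 1L; break }
      if (length(g) != 3L)
        stop("chain ", hdr$id, ": block line must have 1 or 3 fields",
             call. = FALSE)
      sizes <- c(sizes, g[1]); dts <- c(dts, g[2]); dqs <- c(dqs, g[3])
      i <- i + 1L
    }
    if (sum(sizes) + sum(dts) != hdr$tEnd - hdr$tStart ||
        sum(sizes) + sum(dqs) != hdr$qEnd - hdr$qStart)
      stop("chain ", hdr$id, ": block arithmetic does not match the ",
           "stated spans", call. = FALSE)
    sStart <- hdr$tStart + cumsum(c(0, sizes[-length(sizes)] +
                                      if (length(dts)) dts else numeric(0)))
    qStart <- hdr$qStart + cumsum(c(0, sizes[-length(sizes)] +
                                      if (length(dqs)) dqs else numeric(0)))
    blocks[[length(blocks) + 1L]] <- data.frame(
      chainId = hdr$id, score = hdr$score,
      tName = hdr$tName, tSize = hdr$tSize,
      qName = hdr$qName, qSize = hdr$qSize, qStrand = hdr$qStrand,
      sStart = sStart, sEnd = sStart + sizes, qStart = qStart,
      stringsAsFactors = FALSE)
    chains[[length(chains) + 1L]] <- as.data.frame(hdr,
                                                   stringsAsFactors = FALSE)
  }
  if (!length(chains)) stop("no chains found in ", path, call. = FALSE)
  new("ChainIndex", blocks = do.call(rbind, blocks),
      chains = do.call(rbind, chains))
}

#' Map single positions across assemblies
#'
#' Looks up each 1-based source position in the chain blocks. Positions
#' inside an aligned block map by offset, reflected through the sequence
#' length on reverse-strand chains; positions falling in alignment gaps or
#' outside every chain are reported unmapped (never an error). When several
#' chains cover a position the highest-scoring chain wins.
#'
#' @param index a \linkS4class{ChainIndex}.
#' @param chrom character vector of source chromosome labels.
#' @param pos integer vector of 1-based source positions.
#' @return data.frame: \code{chrom, pos, strand, mapped} (target coordinates
#'   where mapped, NA otherwise), one row per input position.
#' @export
liftPosition <- function(index, chrom, pos) {
  stopifnot(is(index, "ChainIndex"), length(chrom) == length(pos))
  b <- index@blocks
  out <- data.frame(chrom = rep(NA_character_, length(pos)),
                    pos = rep(NA_real_, length(pos)),
                    strand = rep(NA_character_, length(pos)),
                    mapped = rep(FALSE, length(pos)),
                    stringsAsFactors = FALSE)
  for (j in seq_along(pos)) {
    p0 <- pos[j] - 1
    hit <- b[b$tName == chrom[j] & b$sStart <= p0 & p0 < b$sEnd, ]
    if (!nrow(hit)) next
    hit <- hit[which.max(hit$score), ]
    q0 <- hit$qStart + (p0 - hit$sStart)
    if (hit$qStrand == "-") q0 <- hit$qSize - 1 - q0
    out$chrom[j] <- hit$qName
    out$pos[j] <- q0 + 1
    out$strand[j] <- hit$qStrand
    out$mapped[j] <- TRUE
  }
  out
}

#' Invert a chain index
#'
#' Swaps the source and target sides of every forward-strand chain, giving
#' the index that maps lifted coordinates back. Reverse-strand chains are
#' not invertible here and raise an error.
#'
#' @param index a \linkS4class{ChainIndex}.
#' @return the inverted \linkS4class{ChainIndex}.
#' @export
invertChain <- function(index) {
  stopifnot(is(index, "ChainIndex"))
  b <- index@blocks
  if (any(b$qStrand != "+"))
    stop("only forward-strand chains can be inverted", call. = FALSE)
  sizes <- b$sEnd - b$sStart
  inv <- data.frame(chainId = b$chainId, score = b$score,
                    tName = b$qName, tSize = b$qSize,
                    qName = b$tName, qSize = b$tSize, qStrand = "+",
                    sStart = b$qStart, sEnd = b$qStart + sizes,
                    qStart = b$sStart, stringsAsFactors = FALSE)
  ch <- index@chains
  chInv <- ch
  chInv$tName <- ch$qName; chInv$tSize <- ch$qSize
  chInv$tStart <- ch$qStart; chInv$tEnd <- ch$qEnd
  chInv$qName <- ch$tName; chInv$qSize <- ch$tSize
  chInv$qStart <- ch$tStart; chInv$qEnd <- ch$tEnd
  new("ChainIndex", blocks = inv, chains = chInv)
}

.complementBase <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Intersect lifted damaging variants with a disease catalog
#'
#' Lifts every predicted-damaging variant through the chain index and
#' reports pairs whose lifted (chrom, pos) and ref/alt alleles exactly
#' match a disease-catalog entry. Allele identity is required; with
#' \code{flipAlleles} the ref/alt pair is complemented for variants landing
#' on the reverse strand before matching.
#'
#' @param damaging data.frame: \code{chrom, pos, ref, alt} (source
#'   coordinates), plus any annotation columns.
#' @param index a \linkS4class{ChainIndex}.
#' @param diseaseCatalog data.frame: \code{chrom, pos, ref, alt, disease}
#'   (target coordinates).
#' @param flipAlleles complement alleles on reverse-strand mappings
#'   (default off).
#' @return data.frame of matched pairs: source coordinates, lifted
#'   coordinates, alleles, gene (if present) and disease; zero rows when
#'   nothing overlaps.
#' @export
overlapDiseaseVariants <- function(damaging, index, diseaseCatalog,
                                   flipAlleles = FALSE) {
  empty <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      gene = character(), liftedChrom = character(),
                      liftedPos = numeric(), disease = character(),
                      stringsAsFactors = FALSE)
  if (nrow(damaging) == 0L || nrow(diseaseCatalog) == 0L) return(empty)
  lifted <- liftPosition(index, damaging$chrom, damaging$pos)
  ref <- damaging$ref
  alt <- damaging$alt
  if (flipAlleles) {
    rev <- lifted$mapped & lifted$strand == "-"
    ref[rev] <- .complementBase(ref[rev])
    alt[rev] <- .complementBase(alt[rev])
  }
  keyD <- paste(lifted$chrom, lifted$pos, ref, alt, sep = ":")
  keyC <- paste(diseaseCatalog$chrom, diseaseCatalog$pos,
                diseaseCatalog$ref, diseaseCatalog$alt, sep = ":")
  hits <- which(lifted$mapped & keyD %in% keyC)
  if (!length(hits)) return(empty)
  rows <- lapply(hits, function(j) {
    cat_ <- diseaseCatalog[keyC == keyD[j], , drop = FALSE]
    cat_ <- cat_[!duplicated(cat_$disease), , drop = FALSE]
    data.frame(chrom = damaging$chrom[j], pos = damaging$pos[j],
               ref = damaging$ref[j], alt = damaging$alt[j],
               gene = if ("gene" %in% names(damaging))
                 damaging$gene[j] else NA_character_,
               liftedChrom = lifted$chrom[j], liftedPos = lifted$pos[j],
               disease = cat_$disease, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-set damaging-variant burden report
#'
#' For each gene set: the number of genes carrying at least one
#' predicted-damaging variant and the corresponding proportion (gene-level
#' presence, so duplicated variants do not change the report).
#'
#' @param geneSets named list of character vectors.
#' @param damaging data.frame with a \code{gene} column.
#' @return data.frame: \code{set, nGenes, nWithDamaging, proportionPct}
#'   (0--100 scale, half-up at 1 d.p.).
#' @export
#' @examples
#' setDamageReport(list(s = c("A", "B")),
#'                 data.frame(gene = c("A", "A")))  # 1 of 2 genes: 50.0
setDamageReport <- function(geneSets, damaging) {
  stopifnot(is.list(geneSets), !is.null(names(geneSets)),
            all(lengths(geneSets) > 0))
  hitGenes <- unique(damaging$gene)
  rows <- lapply(names(geneSets), function(nm) {
    g <- unique(geneSets[[nm]])
    nWith <- sum(g %in% hitGenes)
    data.frame(set = nm, nGenes = length(g), nWithDamaging = nWith,
               proportionPct = damageProportion(nWith, length(g)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Proportion of genes with a damaging variant
#'
#' @param nWith genes carrying at least one predicted-damaging variant.
#' @param nGenes genes in the set.
#' @return percentage on the 0--100 scale, half-up at 1 d.p.
#' @export
#' @examples
#' damageProportion(823, 1071)   # 76.8
#' damageProportion(2098, 2872)  # 73.1
damageProportion <- function(nWith, nGenes) pctHalfUp(nWith, nGenes, 1)

#' Rank damaging variants by CADD score
#'
#' Descending CADD; ties broken by (chrom, pos) ascending, chromosome
#' compared as a label. Variants without a CADD value are excluded.
#'
#' @param damaging data.frame with columns \code{chrom, pos, cadd} (plus
#'   annotation columns, carried through).
#' @param topN maximum rows returned (default 20).
#' @return the top rows of the reordered table.
#' @export
rankByCadd <- function(damaging, topN = 20) {
  has <- !is.na(damaging$cadd)
  if (!any(has)) stop("no variant carries a CADD score", call. = FALSE)
  d <- damaging[has, , drop = FALSE]
  d <- d[order(-d$cadd, d$chrom, d$pos, method = "radix"), , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, topN)
}
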