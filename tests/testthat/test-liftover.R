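# Chain parsing, point liftover, disease overlap and the damage reports.

writeChain <- function(lines, envir = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".chain", .local_envir = envir)
  writeLines(lines, f)
  f
}

test_that("single-block chains parse and map by offset", {
  # identity block [100, 200) -> [100, 200)
  f <- writeChain(c("chain 100 chr1 1000 + 100 200 chr1 1000 + 100 200 1",
                    "100", ""))
  idx <- parseChain(f)
  expect_equal(nrow(idx@blocks), 1L)
  got <- liftPosition(idx, "chr1", 150)
  expect_true(got$mapped)
  expect_equal(got$pos, 150)

  # same source block shifted to [1100, 1200)
  f <- writeChain(c("chain 100 chr1 1000 + 100 200 chr1 2000 + 1100 1200 1",
                    "100", ""))
  idx <- parseChain(f)
  expect_equal(liftPosition(idx, "chr1", 150)$pos, 1150)
  # outside the block: unmapped, not an error
  out <- liftPosition(idx, "chr1", 250)
  expect_false(out$mapped)
  expect_true(is.na(out$pos))
  # unknown chromosome: unmapped
  expect_false(liftPosition(idx, "chr9", 150)$mapped)
})

test_that("gap chains produce two offset target intervals", {
  # 50 aligned, 10 bp skipped in the source (dt = 10), then 40 aligned
  f <- writeChain(c("chain 100 chr1 1000 + 100 200 chr1 1000 + 500 590 1",
                    "50 10 0", "40", ""))
  idx <- parseChain(f)
  expect_equal(nrow(idx@blocks), 2L)
  expect_equal(liftPosition(idx, "chr1", 101)$pos, 501)   # first block
  expect_equal(liftPosition(idx, "chr1", 150)$pos, 550)   # last base block 1
  expect_false(liftPosition(idx, "chr1", 155)$mapped)     # in the gap
  expect_equal(liftPosition(idx, "chr1", 161)$pos, 551)   # second block
})

test_that("reverse-strand chains reflect coordinates; parser rejects bad chains", {
  # q on '-': block [100, 200) maps to strand-local [300, 400) of a 1000 bp
  # sequence, i.e. forward-strand 601..700 reversed
  f <- writeChain(c("chain 100 chr1 1000 + 100 200 chr2 1000 - 300 400 7",
                    "100", ""))
  idx <- parseChain(f)
  got <- liftPosition(idx, "chr1", 101)
  expect_equal(got$chrom, "chr2")
  expect_equal(got$strand, "-")
  expect_equal(got$pos, 1000 - 300)   # first source base -> forward 700
  expect_equal(liftPosition(idx, "chr1", 200)$pos, 601)

  # arithmetic mismatch names the chain id
  bad <- writeChain(c("chain 100 chr1 1000 + 100 200 chr1 1000 + 100 250 9",
                      "100", ""))
  expect_error(parseChain(bad), "chain 9")
  # truncated file
  trunc <- writeChain(c("chain 100 chr1 1000 + 100 200 chr1 1000 + 100 200 3",
                        "50 10 10"))
  expect_error(parseChain(trunc), "truncated")
})

test_that("point liftover agrees with rtracklayer on a multi-block chain", {
  f <- writeChain(c("chain 900 chr1 5000 + 100 900 chr1 9000 + 1100 2000 5",
                    "200 100 200", "300 50 50", "150", ""))
  idx <- parseChain(f)
  ch <- rtracklayer::import.chain(f)
  pos <- c(101, 250, 300, 350, 401, 700, 750, 755, 899, 1000)
  mine <- liftPosition(idx, rep("chr1", length(pos)), pos)
  for (j in seq_along(pos)) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos[j], pos[j]))
    lifted <- unlist(rtracklayer::liftOver(gr, ch))
    if (length(lifted) == 0) {
      expect_false(mine$mapped[j], info = paste("pos", pos[j]))
    } else {
      expect_true(mine$mapped[j], info = paste("pos", pos[j]))
      expect_equal(mine$pos[j], GenomicRanges::start(lifted),
                   info = paste("pos", pos[j]))
    }
  }
})

test_that("liftover round-trips through the inverse chain", {
  b <- generateCatalog(smallConfig(seed = 6))
  fwdFile <- withr::local_tempfile(); writeLines(b@chainLines, fwdFile)
  invFile <- withr::local_tempfile()
  writeLines(b@chainInverseLines, invFile)
  fwd <- parseChain(fwdFile)
  inv <- parseChain(invFile)
  set.seed(1)
  chrom <- paste0("chr", sample.int(20, 50, replace = TRUE))
  pos <- sample.int(20000, 50, replace = TRUE)
  there <- liftPosition(fwd, chrom, pos)
  back <- liftPosition(inv, there$chrom[there$mapped],
                       there$pos[there$mapped])
  expect_true(all(back$mapped))
  expect_equal(back$pos, pos[there$mapped])
  expect_equal(back$chrom, chrom[there$mapped])
  # invertChain gives the same mapping as the generator's inverse file
  inv2 <- invertChain(fwd)
  back2 <- liftPosition(inv2, there$chrom[there$mapped],
                        there$pos[there$mapped])
  expect_equal(back2$pos, back$pos)
})

test_that("disease overlap requires allele identity and finds planted matches", {
  idx <- parseChain(writeChain(
    c("chain 100 chr1 1000 + 0 1000 chr1 2000 + 1000 2000 1", "1000", "")))
  dmg <- data.frame(chrom = "chr1", pos = 150, ref = "A", alt = "G",
                    gene = "G1", cadd = 30, stringsAsFactors = FALSE)
  cat0 <- data.frame(chrom = "chr1", pos = 1150, ref = "A", alt = "G",
                     disease = "ASD", stringsAsFactors = FALSE)
  # empty damaging list
  expect_equal(nrow(overlapDiseaseVariants(dmg[0, ], idx, cat0)), 0L)
  # exact lifted + allele match
  m <- overlapDiseaseVariants(dmg, idx, cat0)
  expect_equal(nrow(m), 1L)
  expect_equal(m$liftedPos, 1150)
  expect_equal(m$disease, "ASD")
  # same position, different allele: no match
  catAlt <- cat0; catAlt$alt <- "T"
  expect_equal(nrow(overlapDiseaseVariants(dmg, idx, catAlt)), 0L)

  # planted matches in a synthetic bundle are recovered exactly
  b <- generateCatalog(smallConfig(seed = 15, nPlantedMatches = 7))
  fwdFile <- withr::local_tempfile(); writeLines(b@chainLines, fwdFile)
  got <- overlapDiseaseVariants(b@damagingVariants, parseChain(fwdFile),
                                b@diseaseVariants)
  expect_equal(nrow(got), 7L)
})

test_that("damage report proportions are gene-level and half-up at 1 d.p.", {
  sets <- list(ASD = c("A", "B", "C"), empty = c("X", "Y"))
  dmg <- data.frame(gene = c("A", "A", "C"), stringsAsFactors = FALSE)
  rep <- setDamageReport(sets, dmg)
  expect_equal(rep$nWithDamaging, c(2L, 0L))
  expect_equal(rep$proportionPct, c(66.7, 0.0))
  # duplicating every damaging variant changes nothing
  rep2 <- setDamageReport(sets, rbind(dmg, dmg))
  expect_equal(rep2, rep)
  # published Table-style arithmetic
  expect_equal(damageProportion(823, 1071), 76.8)
  expect_equal(damageProportion(1732, 2165), 80.0)
  expect_equal(damageProportion(2098, 2872), 73.1)
})

test_that("CADD ranking orders descending with positional tie-break", {
  d <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  pos = c(10, 20, 5), cadd = c(45, 40, 37),
                  stringsAsFactors = FALSE)
  top <- rankByCadd(d, topN = 2)
  expect_equal(top$cadd, c(45, 40))
  # tie broken by position within chromosome
  tie <- data.frame(chrom = "chr1", pos = c(100, 50), cadd = 35,
                    stringsAsFactors = FALSE)
  expect_equal(rankByCadd(tie)$pos, c(50, 100))
  # variants without CADD are excluded; all-NA errors
  withNa <- rbind(d, data.frame(chrom = "chr3", pos = 1, cadd = NA))
  expect_equal(nrow(rankByCadd(withNa, topN = 10)), 3L)
  expect_error(rankByCadd(data.frame(chrom = "chr1", pos = 1,
                                     cadd = NA_real_)), "CADD")
  # order agrees with an independent sort on random input
  set.seed(2)
  r <- data.frame(chrom = paste0("chr", sample(1:5, 100, TRUE)),
                  pos = sample.int(1e4, 100), cadd = runif(100, 0, 50),
                  stringsAsFactors = FALSE)
  got <- rankByCadd(r, topN = 100)
  want <- r[order(-r$cadd, r$chrom, r$pos), ]
  rownames(want) <- NULL
  expect_equal(got, want)
})
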