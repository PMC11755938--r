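# VCF input and the quality screen.

writeTestVcf <- function(lines) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=100000>",
           "##contig=<ID=chr2,length=100000>",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"a\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
           "##INFO=<ID=EFFECT,Number=A,Type=String,Description=\"e\">",
           "##INFO=<ID=DMG,Number=0,Type=Flag,Description=\"f\">",
           "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"c\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf",
                             .local_envir = parent.frame())
  writeLines(c(hdr, lines), f)
  f
}

test_that("readCatalog parses records, splits multi-allelic sites, keeps coordinates", {
  # header-only file: empty record set
  f <- writeTestVcf(character(0))
  expect_equal(nrow(readCatalog(f)), 0L)

  # one biallelic SNV
  f <- writeTestVcf("chr1\t150\t.\tA\tG\t45.0\tPASS\tDP=20;AF=0.1;EFFECT=missense;GENE=G1")
  rec <- readCatalog(f)
  expect_equal(rec$chrom, "chr1")
  expect_equal(rec$pos, 150L)
  expect_equal(rec$ref, "A")
  expect_equal(rec$alt, "G")
  expect_equal(rec$qual, 45)
  expect_equal(rec$depth, 20L)
  expect_equal(rec$gene, "G1")

  # multi-allelic site: two records sharing chrom/pos/ref, per-allele INFO
  f <- writeTestVcf("chr1\t200\t.\tC\tA,T\t50\tPASS\tDP=30;AF=0.2,0.01;EFFECT=missense,lof;GENE=G2")
  rec <- readCatalog(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$chrom, c("chr1", "chr1"))
  expect_equal(rec$pos, c(200L, 200L))
  expect_equal(rec$ref, c("C", "C"))
  expect_setequal(rec$alt, c("A", "T"))
  expect_equal(rec$af[rec$alt == "T"], 0.01)
  expect_equal(rec$effect[rec$alt == "T"], "lof")

  # missing annotation key: record kept, un-annotated
  f <- writeTestVcf("chr1\t300\t.\tG\tT\t50\tPASS\tDP=30;AF=0.2;EFFECT=missense")
  rec <- readCatalog(f)
  expect_equal(nrow(rec), 1L)
  expect_true(is.na(rec$gene))

  # malformed line: parse error naming the line number
  f <- writeTestVcf("chr1\t400\tbroken")
  expect_error(readCatalog(f), "line 11")
})

test_that("screen thresholds use the exclusion bounds literally", {
  # qual 29.9: dropped with reason qual even though depth passes
  res <- qcFilter(makeRecords(qual = 29.9, depth = 30))
  expect_equal(res$summary@nDroppedQual, 1L)
  expect_equal(res$summary@nRetained, 0L)
  # boundary values kept: qual = 30, depth = 50 and depth = 10
  res <- qcFilter(makeRecords(n = 2, qual = 30, depth = c(10, 50)))
  expect_equal(res$summary@nRetained, 2L)
  # depth 9 and 51 dropped
  res <- qcFilter(makeRecords(n = 2, qual = 40, depth = c(9, 51)))
  expect_equal(res$summary@nDroppedDepth, 2L)
  # indel dropped, non-autosome dropped
  res <- qcFilter(rbind(makeRecords(ref = "AT"),
                        makeRecords(chrom = "chrX")))
  expect_equal(res$summary@nDroppedIndel, 1L)
  expect_equal(res$summary@nDroppedNonautosome, 1L)
})

test_that("drop reasons follow the qual > depth > indel > chrom precedence", {
  # a record failing everything counts once, under qual
  rec <- makeRecords(chrom = "chrX", ref = "AT", qual = 5, depth = 200)
  res <- qcFilter(rec)
  expect_equal(res$summary@nDroppedQual, 1L)
  expect_equal(res$summary@nDroppedDepth + res$summary@nDroppedIndel +
                 res$summary@nDroppedNonautosome, 0L)
  # failing depth + indel counts under depth
  res <- qcFilter(makeRecords(ref = "AT", depth = 5))
  expect_equal(res$summary@nDroppedDepth, 1L)
  expect_equal(res$summary@nDroppedIndel, 0L)
})

test_that("counts are conserved, filtering is idempotent and order-invariant", {
  b <- generateCatalog(smallConfig(seed = 11))
  rec <- b@variants
  res <- qcFilter(rec)
  s <- res$summary
  expect_equal(s@nInput,
               s@nRetained + s@nDroppedQual + s@nDroppedDepth +
                 s@nDroppedIndel + s@nDroppedNonautosome)
  # idempotence
  res2 <- qcFilter(res$records)
  expect_equal(nrow(res2$records), nrow(res$records))
  expect_equal(res2$summary@nRetained, res2$summary@nInput)
  # order invariance of the summary
  set.seed(1)
  perm <- rec[sample.int(nrow(rec)), ]
  expect_equal(qcCounts(qcFilter(perm)$summary), qcCounts(s))
})

test_that("SNV fraction among qual/depth survivors matches published arithmetic", {
  # 32,507,418 SNVs and 4,996,245 indels surviving the qual/depth screens
  expect_equal(snvFractionPct(32507418, 4996245), 86.7)
  expect_equal(32507418 + 4996245, 37503663)
})

test_that("qc drop counts on a noisy bundle sit near their binomial expectation", {
  cfg <- SimConfig(nGenes = 240, meanCodingVariants = 40, seed = 13,
                   qcNoise = c(qual = 0.05, depth = 0.05, indel = 0.05,
                               nonautosome = 0.05))
  b <- generateCatalog(cfg)
  nCore <- sum(is.na(b@variants$qcFail))
  s <- qcFilter(b@variants, autosomes = autosomeLabels(20))$summary
  expected <- 0.05 * nCore
  se <- sqrt(nCore * 0.05 * 0.95)
  for (got in c(s@nDroppedQual, s@nDroppedDepth, s@nDroppedIndel,
                s@nDroppedNonautosome))
    expect_lt(abs(got - expected), 3 * se)
})

test_that("summary report renders zeroes, NA fractions and the conservation check", {
  z <- qcFilter(makeRecords()[0, ])$summary
  rep <- summarizeQc(z)
  expect_equal(rep$value[rep$metric == "n_input"], "0")
  expect_equal(rep$value[rep$metric == "snv_fraction_pct"], "NA")
  expect_equal(rep$value[rep$metric == "conservation_ok"], "TRUE")

  rec <- rbind(makeRecords(n = 7),
               makeRecords(qual = 1), makeRecords(depth = 99),
               makeRecords(ref = "ATT"))
  rep <- summarizeQc(qcFilter(rec)$summary)
  expect_equal(rep$value[rep$metric == "n_input"], "10")
  expect_equal(rep$value[rep$metric == "n_retained"], "7")
  expect_equal(rep$value[rep$metric == "conservation_ok"], "TRUE")
})
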