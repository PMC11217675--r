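# minimal hand-written ClinVar-style VCF fixture
writeToyVcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.1",
    "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
    "##INFO=<ID=OTHER,Number=1,Type=String,Description=\"Unrelated key\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"), collapse = "\t"),
    "chr1\t11\trs1\tA\tG\t.\t.\tCLNSIG=Pathogenic",
    "chr1\t21\trs2\tC\tT\t.\t.\tOTHER=x", # no CLNSIG
    "chr1\t30\trs3\tG\tA,C\t.\t.\tCLNSIG=Likely_benign", # multi-allelic
    "chr1\t40\trs4\tGT\tG\t.\t.\tCLNSIG=Benign", # indel: skipped
    "chr2\t11\trs5\tT\tC\t.\t.\tCLNSIG=Uncertain_significance"
  ), path)
}

test_that("ClinVar-style VCFs parse with verbatim CLNSIG and SNV filtering", {
  vf <- withr::local_tempfile(fileext = ".vcf")
  writeToyVcf(vf)
  expect_message(cv <- parseClinvarVcf(vf), "1 non-SNV")
  # 4 SNV lines, the multi-allelic one split into two rows
  expect_identical(nrow(cv), 5L)
  expect_identical(cv$clnsig[cv$id == "rs1"], "Pathogenic")
  expect_true(is.na(cv$clnsig[cv$id == "rs2"]))
  expect_identical(cv$alt[cv$id == "rs3"], c("A", "C"))
  expect_identical(cv$clnsig[cv$id == "rs3"], rep("Likely_benign", 2))
  expect_false("rs4" %in% cv$id)
  expect_identical(cv$pos[cv$id == "rs5"], 11L)
})

test_that("SNP/interval overlap honors half-open BED boundaries", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tucne1", bed)
  iv <- readBed(bed)
  snps <- data.frame(chrom = "chr1", pos = c(10L, 11L, 20L, 21L))
  ov <- overlapSnps(snps, iv)
  # BED [10,20) covers 1-based 11..20: pos 11 and 20 in, 10 and 21 out
  expect_identical(ov$pos, c(11L, 20L))
})

test_that("overlap agrees with a naive double loop on random fixtures", {
  withr::with_seed(43, {
    snps <- data.frame(
      chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
      pos = sample.int(5000, 300, replace = TRUE)
    )
    ivStart <- sample.int(4500, 20)
    iv <- GenomicRanges::GRanges(
      sample(c("chr1", "chr2"), 20, replace = TRUE),
      IRanges::IRanges(ivStart, ivStart + sample.int(300, 20))
    )
  })
  got <- overlapSnps(snps, iv)
  naive <- snps[vapply(seq_len(nrow(snps)), function(i) {
    any(snps$chrom[i] == as.character(GenomicRanges::seqnames(iv)) &
      snps$pos[i] >= GenomicRanges::start(iv) &
      snps$pos[i] <= GenomicRanges::end(iv))
  }, logical(1)), , drop = FALSE]
  expect_identical(got$pos, naive$pos)
  expect_identical(got$chrom, naive$chrom)
})

test_that("CLNSIG tabulation buckets unmatched SNPs as absent and sums to n", {
  vf <- withr::local_tempfile(fileext = ".vcf")
  writeToyVcf(vf)
  suppressMessages(cv <- parseClinvarVcf(vf))
  snps <- data.frame(chrom = c("chr1", "chr1", "chr3"), pos = c(11L, 99L, 11L))
  tab <- tabulateClnsig(snps, cv)
  expect_identical(tab[["Pathogenic"]], 1L)
  expect_identical(tab[["absent"]], 2L)
  expect_identical(sum(tab), nrow(snps))
  # empty catalogue: everything absent
  empty <- cv[0, ]
  expect_identical(tabulateClnsig(snps, empty)[["absent"]], 3L)
})

test_that("tabulation recovers planted category proportions exactly", {
  vf <- withr::local_tempfile(fileext = ".vcf")
  res <- syntheticSnpVcf(vf, 1e5, 1000, c(Pathogenic = 0.2, Benign = 0.3), seed = 47)
  cv <- parseClinvarVcf(vf)
  tab <- tabulateClnsig(res$snps[, c("chrom", "pos", "ref", "alt")], cv)
  expect_identical(tab[["Pathogenic"]], sum(res$snps$clnsig == "Pathogenic", na.rm = TRUE))
  expect_identical(tab[["Benign"]], sum(res$snps$clnsig == "Benign", na.rm = TRUE))
  expect_identical(sum(tab), 1000L)
})

test_that("Monte-Carlo p-values respect the add-one floor and directions", {
  vf <- withr::local_tempfile(fileext = ".vcf")
  res <- syntheticSnpVcf(vf, 1e6, 5000, c(Pathogenic = 0.3), seed = 53)
  cv <- parseClinvarVcf(vf)
  pool <- res$snps[, c("chrom", "pos", "ref", "alt")]
  # observed below every null count: the floor 1/(nSets+1)
  mc <- monteCarloEnrichment(0, pool, setSize = 500, nSets = 100,
    category = "Pathogenic", clinvar = cv, seed = 57
  )
  expect_equal(pValue(mc), 1 / 101)
  expect_identical(sprintf("%.2f", pValue(mc)), "0.01")
  expect_gt(nullMeans(mc)[["Pathogenic"]], 100) # ~150 expected per subset
  # same draw, enriched direction: observed 0 is below everything -> p = 1
  mce <- monteCarloEnrichment(0, pool, setSize = 500, nSets = 100,
    category = "Pathogenic", clinvar = cv, seed = 57, direction = "enriched"
  )
  expect_equal(pValue(mce), 1)
  # nSets = 1 with observed above the single null count, depleted -> p = 1
  mc1 <- monteCarloEnrichment(1e6, pool, setSize = 100, nSets = 1,
    category = "Pathogenic", clinvar = cv, seed = 59
  )
  expect_equal(pValue(mc1), 1)
  # observed at the null median -> p near one half
  med <- stats::median(mc@nullCounts)
  mcm <- monteCarloEnrichment(med, pool, setSize = 500, nSets = 100,
    category = "Pathogenic", clinvar = cv, seed = 57
  )
  expect_lt(abs(pValue(mcm) - 0.5), 0.15)
  expect_error(
    monteCarloEnrichment(0, pool, setSize = 1e6, nSets = 10,
      category = "Pathogenic", clinvar = cv, seed = 1
    ),
    "exceeds the null pool"
  )
  # determinism
  mc2 <- monteCarloEnrichment(0, pool, setSize = 500, nSets = 100,
    category = "Pathogenic", clinvar = cv, seed = 57
  )
  expect_identical(mc@nullCounts, mc2@nullCounts)
})
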