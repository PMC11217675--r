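# ClinVar-style Monte-Carlo analysis: SNP/interval overlap, CLNSIG
# tabulation, and empirical enrichment/depletion p-values from
# size-matched random SNP sets.

#' Parse a ClinVar-style VCF
#'
#' Reads a VCF (v4.1-style, as distributed by ClinVar) and returns one row
#' per single-nucleotide variant with the `CLNSIG` INFO value extracted
#' verbatim (`NA` when absent). Multi-allelic lines are split into one row
#' per ALT allele; non-SNV records are skipped and their count reported in
#' a message.
#'
#' @param path VCF path (plain text or gzipped).
#' @return data.frame with columns `chrom`, `pos` (1-based integer), `id`,
#'   `ref`, `alt`, `clnsig`.
#' @export
parseClinvarVcf <- function(path) {
  if (!file.exists(path)) {
    stop("VCF file not found: ", path, call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(
      chrom = character(0), pos = integer(0), id = character(0),
      ref = character(0), alt = character(0), clnsig = character(0)
    ))
  }
  clnsig <- vcfR::extract.info(vcf, "CLNSIG")
  # split multi-allelic ALT into one row per allele (CLNSIG carried along)
  alts <- strsplit(ifelse(is.na(fix$ALT), ".", fix$ALT), ",", fixed = TRUE)
  nAlt <- lengths(alts)
  row <- rep(seq_len(nrow(fix)), nAlt)
  out <- data.frame(
    chrom = fix$CHROM[row],
    pos = as.integer(fix$POS[row]),
    id = fix$ID[row],
    ref = fix$REF[row],
    alt = unlist(alts),
    clnsig = clnsig[row],
    stringsAsFactors = FALSE
  )
  snv <- nchar(out$ref) == 1L & out$ref %in% BASES &
    nchar(out$alt) == 1L & out$alt %in% BASES
  skipped <- sum(!snv)
  if (skipped > 0L) {
    message(skipped, " non-SNV record(s) skipped")
  }
  out <- out[snv, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.snpGRanges <- function(snps) {
  GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L)
  )
}

#' Subset SNPs overlapping intervals
#'
#' Returns the SNPs whose position falls inside any of the intervals
#' (each SNP counted once). SNP positions are 1-based; intervals follow
#' the `GRanges` 1-based closed convention, so a BED interval
#' `[start, end)` read by [readBed()] behaves exactly as half-open.
#'
#' @param snps data.frame with `chrom` and 1-based `pos` (e.g. from
#'   [parseClinvarVcf()] or [syntheticSnpVcf()]).
#' @param intervals `GRanges` (e.g. from [readBed()]).
#' @return the overlapping subset of `snps`.
#' @export
overlapSnps <- function(snps, intervals) {
  stopifnot(methods::is(intervals, "GRanges"))
  if (nrow(snps) == 0L) {
    return(snps)
  }
  hit <- IRanges::overlapsAny(.snpGRanges(snps), intervals)
  out <- snps[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# chrom+pos(+ref/alt when both sides carry alleles) matching key
.snpKey <- function(snps, useAlleles) {
  if (useAlleles) {
    paste(snps$chrom, snps$pos, snps$ref, snps$alt, sep = ":")
  } else {
    paste(snps$chrom, snps$pos, sep = ":")
  }
}

#' Tabulate clinical-significance categories of a SNP set
#'
#' Looks each input SNP up in a ClinVar-style table (matching by
#' chromosome and position, plus ref/alt alleles when both sides provide
#' them) and counts its `CLNSIG` category. SNPs not found in the
#' catalogue -- or found without a CLNSIG value -- are counted under
#' `"absent"`. The counts sum to the number of input SNPs.
#'
#' @param snps data.frame with `chrom`, `pos` (and optionally `ref`,
#'   `alt`).
#' @param clinvar data.frame from [parseClinvarVcf()].
#' @return named integer vector of category counts.
#' @export
tabulateClnsig <- function(snps, clinvar) {
  useAlleles <- all(c("ref", "alt") %in% names(snps)) &&
    all(c("ref", "alt") %in% names(clinvar))
  if (nrow(snps) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- match(.snpKey(snps, useAlleles), .snpKey(clinvar, useAlleles))
  cat <- clinvar$clnsig[m]
  cat[is.na(cat)] <- "absent"
  tab <- table(cat)
  stats::setNames(as.integer(tab), names(tab))
}

#' Monte-Carlo enrichment / depletion test for a CLNSIG category
#'
#' Draws `nSets` random SNP subsets of size `setSize` (without
#' replacement) from a null pool, tabulates the focal category count in
#' each against the clinical catalogue, and compares the observed count
#' with that null distribution using the add-one empirical p-value
#' `p = (1 + #{null <= observed}) / (nSets + 1)` for depletion
#' (`>=` for enrichment). With 100 null sets the p-value floor is
#' 1/101 ~ 0.0099, which prints as 0.01. Deterministic given `seed`.
#'
#' @param observedCount observed count of `category` in the SNP set under
#'   test (e.g. from [tabulateClnsig()] on the UCNE-overlapping SNPs).
#' @param nullPool data.frame of candidate null SNPs (`chrom`, `pos`, and
#'   optionally `ref`, `alt`).
#' @param setSize size of each random subset (the size of the observed
#'   set); must not exceed the pool.
#' @param nSets number of random subsets (default 100).
#' @param category CLNSIG category tested, e.g. `"Pathogenic"`.
#' @param clinvar clinical catalogue, as in [tabulateClnsig()].
#' @param seed integer seed.
#' @param direction `"depleted"` (default: is the observed count lower
#'   than random expectation?) or `"enriched"`.
#' @return an [EnrichmentReport-class].
#' @export
monteCarloEnrichment <- function(observedCount, nullPool, setSize,
                                 nSets = 100L, category, clinvar, seed,
                                 direction = c("depleted", "enriched")) {
  direction <- match.arg(direction)
  nSets <- as.integer(nSets)
  setSize <- as.integer(setSize)
  if (nSets < 1L) {
    stop("nSets must be >= 1", call. = FALSE)
  }
  if (setSize > nrow(nullPool)) {
    stop("setSize (", setSize, ") exceeds the null pool (", nrow(nullPool), ")",
      call. = FALSE
    )
  }
  useAlleles <- all(c("ref", "alt") %in% names(nullPool)) &&
    all(c("ref", "alt") %in% names(clinvar))
  m <- match(.snpKey(nullPool, useAlleles), .snpKey(clinvar, useAlleles))
  poolCat <- clinvar$clnsig[m]
  poolCat[is.na(poolCat)] <- "absent"
  cats <- sort(unique(c(poolCat, category)))
  poolFac <- factor(poolCat, levels = cats)
  .withSeed(seed, {
    catCounts <- matrix(0L, nrow = nSets, ncol = length(cats), dimnames = list(NULL, cats))
    for (i in seq_len(nSets)) {
      idx <- sample.int(nrow(nullPool), setSize)
      catCounts[i, ] <- tabulate(poolFac[idx], nbins = length(cats))
    }
    nullCounts <- catCounts[, category]
    extreme <- if (direction == "depleted") {
      sum(nullCounts <= observedCount)
    } else {
      sum(nullCounts >= observedCount)
    }
    methods::new("EnrichmentReport",
      category = category,
      observed = stats::setNames(as.numeric(observedCount), category),
      nullMean = colMeans(catCounts),
      nullCounts = as.numeric(nullCounts),
      nSets = nSets, setSize = setSize,
      pValue = (1 + extreme) / (nSets + 1),
      direction = direction, seed = as.integer(seed)
    )
  })
}

#' @describeIn pValue empirical Monte-Carlo p-value.
#' @export
setMethod("pValue", "EnrichmentReport", function(object) object@pValue)

#' @describeIn nullMeans per-category mean counts over the null sets.
#' @export
setMethod("nullMeans", "EnrichmentReport", function(object) object@nullMean)

setMethod("show", "EnrichmentReport", function(object) {
  cat(sprintf(
    "EnrichmentReport: '%s' %s, observed %g vs null mean %.2f over %d sets of %d (P = %.2f)\n",
    object@category, object@direction, object@observed[[1]],
    object@nullMean[[object@category]], object@nSets, object@setSize,
    object@pValue
  ))
})
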