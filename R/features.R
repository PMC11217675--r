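# The nine composition features. All counting is case-insensitive and
# N-excluding (see patterns.R). Frequency-type features are reported per 100
# valid windows of the relevant width; the spacing ratio is x100; the
# alternating-dinucleotide ratio is a plain ratio; GC content is a percent.
# These per-column scales cancel under z-normalization (see classify.R), so
# the unit choice is documented, not load-bearing.

# counts of every k-mer (k = 2..6 used) over valid windows, as a flat
# base-4 index table; list(counts, valid)
.kmerCounts <- function(codes, w) {
  n <- length(codes)
  if (n < w) {
    return(list(counts = integer(4L^w), valid = 0L))
  }
  ok <- .validWindows(codes, w)
  i <- seq_len(n - w + 1L)
  idx <- rep(0L, n - w + 1L)
  for (k in seq_len(w)) {
    idx <- idx * 4L + (codes[i + k - 1L] - 1L)
  }
  list(counts = tabulate(idx[ok] + 1L, nbins = 4L^w), valid = sum(ok))
}

.kmerIndex <- function(kmer) {
  codes <- match(strsplit(kmer, "", fixed = TRUE)[[1]], BASES)
  as.integer(sum((codes - 1L) * 4L^(rev(seq_along(codes)) - 1L)) + 1L)
}

#' GpC dinucleotide frequency (feature F1)
#'
#' Frequency of the GpC dinucleotide (G followed by C on one strand) per
#' 100 valid dinucleotide windows. GpC overabundance is the single
#' strongest compositional marker of ultraconserved non-coding elements.
#'
#' @param seq a single sequence.
#' @return numeric frequency (per 100 windows).
#' @examples
#' gpcFrequency("GCGCGC") # 3 GpC in 5 windows = 60
#' @export
gpcFrequency <- function(seq) {
  d <- countDinucleotides(seq)
  tot <- sum(d)
  if (tot == 0L) {
    stop("no valid dinucleotide window in sequence", call. = FALSE)
  }
  100 * d[["GC"]] / tot
}

#' Combined CC + GG dinucleotide frequency (feature F2)
#'
#' Frequency of CpC plus GpG dinucleotides per 100 valid dinucleotide
#' windows; depleted in ultraconserved elements.
#'
#' @inheritParams gpcFrequency
#' @return numeric frequency (per 100 windows).
#' @export
ccggFrequency <- function(seq) {
  d <- countDinucleotides(seq)
  tot <- sum(d)
  if (tot == 0L) {
    stop("no valid dinucleotide window in sequence", call. = FALSE)
  }
  100 * (d[["CC"]] + d[["GG"]]) / tot
}

#' Normalized GpC / (CC+GG) ratio
#'
#' The single-number summary R = (2 * F1 / F2) x 100% combining the two
#' strongest markers (GpC enrichment, CC+GG depletion); on real data this
#' ratio alone separates ultraconserved elements from genomic background
#' with about 74% accuracy.
#'
#' @param f1 GpC frequency ([gpcFrequency()]).
#' @param f2 CC+GG frequency ([ccggFrequency()]); vectors recycled.
#' @return R in percent; `NA` where `f2` is 0 (undefined, reported missing).
#' @examples
#' ratioR(13.33, 11.9) # 224.03
#' @export
ratioR <- function(f1, f2) {
  r <- 200 * f1 / f2
  r[f1 == 0] <- 0
  bad <- f2 == 0 & f1 != 0
  if (any(bad)) {
    warning(sum(bad), " ratio value(s) undefined (F2 = 0); reported as NA")
    r[bad] <- NA_real_
  }
  r
}

# total F3-pair counts at one spacing distance
.f3TotalAtL <- function(codes, L) {
  pc <- .pairCountsAtL(codes, L)
  i1 <- match(.F3_PAIRS[, 1], DINUCLEOTIDES)
  i2 <- match(.F3_PAIRS[, 2], DINUCLEOTIDES)
  sum(pc$counts[(i1 - 1L) * 16L + i2])
}

#' L4/L3 spacing-ratio of the 17 signature pairs (feature F3)
#'
#' Sums occurrences of the 17 signature dinucleotide pairs ([f3Pairs()]) at
#' spacing L = 4 (two spacer bases, e.g. TAnnGC) and at L = 3 (one spacer,
#' e.g. TAnGC), and returns 100 x (total at L4) / (total at L3). Values
#' above 100 are characteristic of ultraconserved elements. A zero L3
#' total makes the ratio undefined; `NA` is returned and replaced by a
#' sentinel at table-build time (see [buildFeatureTable()]).
#'
#' @inheritParams gpcFrequency
#' @return numeric ratio x100, or `NA` if no L3 occurrence exists.
#' @export
l4l3Ratio <- function(seq) {
  s <- .asSequenceString(seq)
  .checkAlphabet(s)
  codes <- .seqCodes(s)
  l3 <- .f3TotalAtL(codes, 3L)
  l4 <- .f3TotalAtL(codes, 4L)
  if (l3 == 0L) {
    return(NA_real_)
  }
  100 * l4 / l3
}

# combined overlapping frequency of a plain k-mer list, per 100 valid windows
.kmerSetFrequency <- function(seq, kmers) {
  s <- .asSequenceString(seq)
  .checkAlphabet(s)
  codes <- .seqCodes(s)
  w <- nchar(kmers[1])
  kc <- .kmerCounts(codes, w)
  if (kc$valid == 0L) {
    stop("no valid window of width ", w, " in sequence", call. = FALSE)
  }
  100 * sum(kc$counts[vapply(kmers, .kmerIndex, integer(1))]) / kc$valid
}

#' GC-rich triplet frequency (feature F4)
#'
#' Combined overlapping frequency of the eight GC-rich triplets
#' ([f4Triplets()]) per 100 valid trinucleotide windows.
#'
#' @inheritParams gpcFrequency
#' @return numeric frequency.
#' @export
gcTripletFrequency <- function(seq) .kmerSetFrequency(seq, .F4_TRIPLETS)

#' AT-rich triplet frequency (feature F5)
#'
#' Combined overlapping frequency of the four AT-rich triplets
#' ([f5Triplets()]) per 100 valid trinucleotide windows.
#'
#' @inheritParams gpcFrequency
#' @return numeric frequency.
#' @export
atTripletFrequency <- function(seq) .kmerSetFrequency(seq, .F5_TRIPLETS)

#' Enriched adjacent dinucleotide-pair frequency (feature F6)
#'
#' Combined overlapping frequency of the 17 UCNE-enriched adjacent
#' dinucleotide pairs (4-mers, [f6Tetramers()]) per 100 valid 4-mer windows.
#'
#' @inheritParams gpcFrequency
#' @return numeric frequency.
#' @export
adjacentPairFrequency <- function(seq) .kmerSetFrequency(seq, .F6_TETRAMERS)

#' Enriched one-spacer dinucleotide-pair frequency (feature F7)
#'
#' Combined overlapping frequency of the 18 UCNE-enriched dinucleotide
#' pairs separated by one base (wildcard 5-mers, [f7Motifs()]) per 100
#' valid 5-mer windows.
#'
#' @inheritParams gpcFrequency
#' @return numeric frequency.
#' @export
oneSpacerPairFrequency <- function(seq) {
  s <- .asSequenceString(seq)
  .checkAlphabet(s)
  codes <- .seqCodes(s)
  pc <- .pairCountsAtL(codes, 3L) # d1 n d2 = spacing L 3, window width 5
  if (pc$valid == 0L) {
    stop("no valid window of width 5 in sequence", call. = FALSE)
  }
  d1 <- substr(.F7_MOTIFS, 1L, 2L)
  d2 <- substr(.F7_MOTIFS, 4L, 5L)
  i1 <- match(d1, DINUCLEOTIDES)
  i2 <- match(d2, DINUCLEOTIDES)
  100 * sum(pc$counts[(i1 - 1L) * 16L + i2]) / pc$valid
}

#' Alternating / homotype dinucleotide ratio (feature F8)
#'
#' Ratio of purine-pyrimidine alternating dinucleotides (TpG, CpA, GpT,
#' ApC) to homopurine/homopyrimidine dinucleotides (ApG, CpT, GpA, TpC).
#' A zero denominator returns `NA`, replaced by a sentinel at table-build
#' time.
#'
#' @inheritParams gpcFrequency
#' @return numeric ratio, or `NA` if the homotype group is absent.
#' @examples
#' altDinucleotideRatio("ACAG") # (AC + CA) / AG = 2
#' @export
altDinucleotideRatio <- function(seq) {
  d <- countDinucleotides(seq)
  num <- d[["TG"]] + d[["CA"]] + d[["GT"]] + d[["AC"]]
  den <- d[["AG"]] + d[["CT"]] + d[["GA"]] + d[["TC"]]
  if (den == 0L) {
    return(NA_real_)
  }
  num / den
}

#' GC content (feature F9)
#'
#' Percent G+C among non-N bases, case-insensitive. Ultraconserved
#' elements average about 37% GC against about 42% for random genomic
#' fragments.
#'
#' @inheritParams gpcFrequency
#' @return percent in \[0, 100\].
#' @examples
#' gcContent("ACGT") # 50
#' @export
gcContent <- function(seq) {
  s <- .asSequenceString(seq)
  .checkAlphabet(s)
  codes <- .seqCodes(s)
  nb <- sum(!is.na(codes))
  if (nb == 0L) {
    stop("sequence contains no A/C/G/T base", call. = FALSE)
  }
  100 * sum(codes %in% c(2L, 3L)) / nb
}

#' Compute the nine-feature vector of one sequence
#'
#' Computes F1 (GpC), F2 (CC+GG), F3 (L4/L3 spacing ratio), F4 (GC-rich
#' triplets), F5 (AT-rich triplets), F6 (adjacent pairs), F7 (one-spacer
#' pairs), F8 (alternating ratio) and F9 (GC content). Deterministic;
#' undefined ratios (F3, F8) come back as `NA` and are resolved to
#' sentinels by [buildFeatureTable()].
#'
#' @param seq a single sequence.
#' @param minLength minimum accepted sequence length in nt (default 200,
#'   the lower bound of the UCNE length distribution).
#' @return named numeric vector F1..F9.
#' @export
computeFeatures <- function(seq, minLength = 200L) {
  s <- .asSequenceString(seq)
  if (nchar(s) < minLength) {
    stop("sequence length ", nchar(s), " is below the minimum of ", minLength, " nt",
      call. = FALSE
    )
  }
  c(
    F1 = unname(gpcFrequency(s)),
    F2 = unname(ccggFrequency(s)),
    F3 = unname(l4l3Ratio(s)),
    F4 = unname(gcTripletFrequency(s)),
    F5 = unname(atTripletFrequency(s)),
    F6 = unname(adjacentPairFrequency(s)),
    F7 = unname(oneSpacerPairFrequency(s)),
    F8 = unname(altDinucleotideRatio(s)),
    F9 = unname(gcContent(s))
  )
}

#' Build the labelled feature table
#'
#' One row per sequence with columns `ID`, `F1`..`F9`, `Class` (1 for the
#' UCNE-like positives, 0 for background), the input layout of the
#' classifiers. Undefined ratio values (F3 with no L3 occurrence, F8 with
#' no homotype dinucleotide) are replaced by the column-wide maximum
#' finite value, with a warning; this keeps rows usable without
#' fabricating infinities.
#'
#' @param positives,negatives [MaskedDNA-class] sets (or named character
#'   vectors) of the two classes.
#' @param minLength per-sequence minimum length, see [computeFeatures()].
#' @return data.frame with attributes `provenance` (free-text metadata).
#' @export
buildFeatureTable <- function(positives, negatives, minLength = 200L) {
  toChar <- function(x) {
    if (methods::is(x, "XStringSet")) as.character(x) else x
  }
  pos <- toChar(positives)
  neg <- toChar(negatives)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both positive and negative sets must be non-empty", call. = FALSE)
  }
  ids <- c(
    if (is.null(names(pos))) paste0("pos_", seq_along(pos)) else names(pos),
    if (is.null(names(neg))) paste0("neg_", seq_along(neg)) else names(neg)
  )
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in feature table: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- c(pos, neg)
  feat <- t(vapply(seqs, computeFeatures, numeric(9L), minLength = minLength))
  tab <- data.frame(ID = ids, feat, Class = rep(c(1L, 0L), c(length(pos), length(neg))))
  rownames(tab) <- NULL
  for (col in c("F3", "F8")) {
    nas <- is.na(tab[[col]])
    if (any(nas)) {
      fin <- tab[[col]][!nas]
      if (length(fin) == 0L) {
        stop("all ", col, " values undefined; cannot derive a sentinel", call. = FALSE)
      }
      warning(sum(nas), " undefined ", col, " value(s) replaced by the column maximum ",
        signif(max(fin), 6),
        call. = FALSE
      )
      tab[[col]][nas] <- max(fin)
    }
  }
  attr(tab, "provenance") <- sprintf(
    "%d positives, %d negatives; minLength=%d; built %s",
    length(pos), length(neg), minLength, format(Sys.time(), "%Y-%m-%d")
  )
  tab
}

#' Write / read a feature table as TSV
#'
#' Tab-separated, columns `ID`, `F1`..`F9`, `Class`.
#'
#' @param table feature table from [buildFeatureTable()].
#' @param path file path.
#' @return `path` invisibly / the table.
#' @export
writeFeatureTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("ID", paste0("F", 1:9), "Class")
  if (!all(need %in% names(tab))) {
    stop("feature table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Best-threshold accuracy of a single feature
#'
#' The maximum 0/1 classification accuracy achievable with a single
#' threshold on one feature, over all cut points and both directions --
#' the per-feature "prediction power" used to screen features (features
#' entered the final model only above 67%).
#'
#' @param values numeric feature values.
#' @param labels 0/1 class labels.
#' @return best accuracy as a fraction in \[0.5, 1\].
#' @examples
#' singleFeaturePower(c(1, 2, 3, 4), c(0, 0, 1, 1)) # separable: 1
#' @export
singleFeaturePower <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("values must not contain NA", call. = FALSE)
  }
  ord <- order(values)
  v <- values[ord]
  y <- labels[ord]
  n <- length(y)
  P <- sum(y == 1L)
  N <- n - P
  cpos <- c(0L, cumsum(y == 1L)) # positives among the first i values
  cneg <- c(0L, cumsum(y == 0L))
  # cuts allowed before position 1, after position n, and between distinct values
  cut <- c(TRUE, v[-1] != v[-n], TRUE)
  i <- which(cut) - 1L # number of values at or below the cut
  accHigh <- (P - cpos[i + 1L] + cneg[i + 1L]) / n # predict 1 above the cut
  accLow <- (cpos[i + 1L] + N - cneg[i + 1L]) / n # predict 1 at/below the cut
  max(accHigh, accLow)
}
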