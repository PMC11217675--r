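# Core counting engine: overlapping motif occurrences, dinucleotide tallies
# and spacing-distance profiles. All counting is case-insensitive (soft
# masking is metadata, not composition); any window containing N is excluded
# from both the match count and the valid-window denominator.

#' Spacing distance between two dinucleotides
#'
#' The spacing distance L between two dinucleotides is the difference of
#' their start positions: L = 1 means the dinucleotides intersect (share one
#' base, e.g. AT and TG inside ATG), L = 2 adjacent, L = 3 one spacer base,
#' L = 4 two spacer bases.
#'
#' @param start1,start2 start positions of the first and second dinucleotide
#'   (both 0-based or both 1-based); `start2` must exceed `start1`.
#' @return integer L.
#' @examples
#' spacingDistance(0, 1) # AT vs TG in "ATG": intersected, L = 1
#' spacingDistance(0, 4) # TA vs GC in "TAnnGC": two spacers, L = 4
#' @export
spacingDistance <- function(start1, start2) {
  if (!(start2 > start1)) {
    stop("start2 must be greater than start1 (the second dinucleotide lies downstream)",
      call. = FALSE
    )
  }
  as.integer(start2 - start1)
}

# parse a motif string into integer codes (NA = wildcard n/N)
.motifCodes <- function(motif) {
  .assertScalarString(motif, "motif")
  ch <- strsplit(motif, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c(BASES, tolower(BASES), "n", "N"))) {
    stop("motif '", motif, "' contains characters outside {A,C,G,T,n}", call. = FALSE)
  }
  codes <- match(toupper(ch), BASES) # n/N -> NA = wildcard
  if (length(codes) < 2L || sum(!is.na(codes)) < 2L) {
    stop("motif '", motif, "' must be >= 2 long with >= 2 non-wildcard bases", call. = FALSE)
  }
  codes
}

# count on pre-computed codes; mcodes from .motifCodes
.countMotifCodes <- function(codes, mcodes) {
  w <- length(mcodes)
  n <- length(codes)
  if (n < w) {
    return(0L)
  }
  i <- seq_len(n - w + 1L)
  ok <- .validWindows(codes, w) # N anywhere in the window kills the match
  for (k in seq_len(w)) {
    ck <- codes[i + k - 1L]
    if (!is.na(mcodes[k])) {
      m <- ck == mcodes[k]
      m[is.na(m)] <- FALSE
      ok <- ok & m
    }
  }
  sum(ok)
}

#' Count overlapping motif occurrences
#'
#' Counts every (possibly overlapping) window of the sequence matching a
#' motif over `{A,C,G,T,n}`, case-insensitively. The wildcard `n` matches
#' any of A/C/G/T only; windows containing the ambiguity base N never match.
#'
#' @param seq a single sequence (string, or one-element [MaskedDNA-class]).
#' @param motif motif string, e.g. `"TAnnGC"`.
#' @return integer count.
#' @examples
#' countMotif("AAA", "AA") # overlapping: 2
#' countMotif("TAGGGC", "TAnnGC") # 1
#' countMotif("TANGGC", "TAnnGC") # N blocks the window: 0
#' @export
countMotif <- function(seq, motif) {
  s <- .asSequenceString(seq)
  .checkAlphabet(s)
  .countMotifCodes(.seqCodes(s), .motifCodes(motif))
}

.checkAlphabet <- function(s) {
  hit <- regexpr("[^ACGTNacgtn]", s)
  if (hit > 0L) {
    stop(sprintf(
      "illegal character '%s' at position %d (alphabet is A,C,G,T,N any case)",
      substr(s, hit, hit), hit
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Tally the 16 ordered dinucleotides
#'
#' Overlapping, case-insensitive counts of all 16 ordered dinucleotides.
#' Windows containing N are skipped, so the counts sum to the number of
#' valid dinucleotide windows.
#'
#' @param seq a single sequence.
#' @return named integer vector of length 16 (AA, AC, ..., TT).
#' @examples
#' countDinucleotides("ACGT")
#' @export
countDinucleotides <- function(seq) {
  s <- .asSequenceString(seq)
  .checkAlphabet(s)
  codes <- .seqCodes(s)
  n <- length(codes)
  out <- stats::setNames(integer(16L), DINUCLEOTIDES)
  if (n < 2L) {
    return(out)
  }
  c1 <- codes[-n]
  c2 <- codes[-1L]
  ok <- !is.na(c1) & !is.na(c2)
  idx <- (c1[ok] - 1L) * 4L + c2[ok]
  out[] <- tabulate(idx, nbins = 16L)
  out
}

# all 256 ordered dinucleotide-pair counts at spacing L, plus the number of
# valid windows of width L+2. Returns list(counts = 16x16-flattened vector
# indexed (d1-1)*16 + d2, valid = integer).
.pairCountsAtL <- function(codes, L) {
  w <- L + 2L
  n <- length(codes)
  if (n < w) {
    return(list(counts = integer(256L), valid = 0L))
  }
  ok <- .validWindows(codes, w)
  i <- seq_len(n - w + 1L)
  d1 <- (codes[i] - 1L) * 4L + codes[i + 1L]
  d2 <- (codes[i + L] - 1L) * 4L + codes[i + L + 1L]
  idx <- (d1 - 1L) * 16L + d2
  list(counts = tabulate(idx[ok], nbins = 256L), valid = sum(ok))
}

.dinucIndex <- function(d) {
  i <- match(toupper(d), DINUCLEOTIDES)
  if (is.na(i)) {
    stop("'", d, "' is not an ordered dinucleotide over A,C,G,T", call. = FALSE)
  }
  i
}

#' Spacing-distance profile of a dinucleotide pair
#'
#' For an ordered pair (d1, d2), counts co-occurrences with d1 starting at
#' position p and d2 at p + L, for L = 1..Lmax, pooled over a set of
#' sequences. Frequencies are normalized per valid (N-free) window of width
#' L + 2; `sigma` is the standard deviation of the per-sequence frequency,
#' and [spacingBand()] gives the +/-3 sigma band of the mean curve
#' (3 * sigma / sqrt(n)).
#'
#' @param seqs [MaskedDNA-class] or character vector of sequences.
#' @param d1,d2 ordered dinucleotides, e.g. `"TA"`, `"GC"`.
#' @param lmax largest spacing distance (default 50, the visible range of a
#'   spacing-distribution plot).
#' @return a [SpacingProfile-class].
#' @examples
#' spacingProfile("TAGC", "TA", "GC", lmax = 3) # one placement at L = 2
#' @export
spacingProfile <- function(seqs, d1, d2, lmax = 50L) {
  if (methods::is(seqs, "XStringSet")) {
    seqs <- as.character(seqs)
  }
  if (length(seqs) == 0L) {
    stop("empty input: need at least one sequence", call. = FALSE)
  }
  lmax <- as.integer(lmax)
  if (lmax < 1L) {
    stop("lmax must be >= 1", call. = FALSE)
  }
  i1 <- .dinucIndex(d1)
  i2 <- .dinucIndex(d2)
  flat <- (i1 - 1L) * 16L + i2
  ncnt <- matrix(0L, nrow = length(seqs), ncol = lmax)
  nval <- matrix(0L, nrow = length(seqs), ncol = lmax)
  for (s in seq_along(seqs)) {
    .checkAlphabet(seqs[[s]])
    codes <- .seqCodes(seqs[[s]])
    for (L in seq_len(lmax)) {
      pc <- .pairCountsAtL(codes, L)
      ncnt[s, L] <- pc$counts[flat]
      nval[s, L] <- pc$valid
    }
  }
  freqSeq <- ncnt / ifelse(nval > 0L, nval, NA_real_)
  ln <- as.character(seq_len(lmax))
  methods::new("SpacingProfile",
    pair = c(toupper(d1), toupper(d2)),
    counts = stats::setNames(as.integer(colSums(ncnt)), ln),
    frequencies = stats::setNames(
      colSums(ncnt) / pmax(colSums(nval), 1L), ln
    ),
    sigma = stats::setNames(apply(freqSeq, 2, stats::sd, na.rm = TRUE), ln),
    nseq = length(seqs),
    lmax = lmax
  )
}

#' @describeIn spacingCounts pooled co-occurrence counts per L.
#' @export
setMethod("spacingCounts", "SpacingProfile", function(object) object@counts)

#' @describeIn spacingFrequencies pooled frequency per valid window, per L.
#' @export
setMethod("spacingFrequencies", "SpacingProfile", function(object) object@frequencies)

#' @describeIn spacingSigma across-sequence sd of the per-sequence frequency.
#' @export
setMethod("spacingSigma", "SpacingProfile", function(object) object@sigma)

#' @describeIn spacingBand half-width of the 99.7% (+/-3 sigma) band of the
#'   mean curve: 3 * sigma / sqrt(nseq).
#' @export
setMethod("spacingBand", "SpacingProfile", function(object) {
  3 * object@sigma / sqrt(object@nseq)
})

setMethod("show", "SpacingProfile", function(object) {
  cat(sprintf(
    "SpacingProfile %s..%s over %d sequence(s), L = 1..%d\n",
    object@pair[1], object@pair[2], object@nseq, object@lmax
  ))
  print(utils::head(data.frame(
    L = seq_len(object@lmax),
    count = object@counts,
    frequency = object@frequencies,
    sigma = object@sigma,
    row.names = NULL
  ), 10L))
  if (object@lmax > 10L) cat("...\n")
})

#' Export a spacing profile as TSV
#'
#' Writes columns `pair`, `L`, `count`, `frequency`, `sigma`.
#'
#' @param profile a [SpacingProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpacingProfile <- function(profile, path) {
  stopifnot(methods::is(profile, "SpacingProfile"))
  df <- data.frame(
    pair = paste0(profile@pair[1], "..", profile@pair[2]),
    L = seq_len(profile@lmax),
    count = profile@counts,
    frequency = profile@frequencies,
    sigma = profile@sigma
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a spacing profile
#'
#' Mean per-sequence frequency against spacing distance L with the
#' +/-3 sigma band of the mean curve.
#'
#' @param x a [SpacingProfile-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted data.frame.
#' @importFrom graphics arrows
#' @export
setMethod("plot", c("SpacingProfile", "missing"), function(x, y, ...) {
  L <- seq_len(x@lmax)
  f <- x@frequencies
  b <- spacingBand(x)
  graphics::plot(L, f,
    type = "b", pch = 16, xlab = "spacing distance L (nt)",
    ylab = "frequency per valid window",
    main = sprintf("%s..%s spacing profile", x@pair[1], x@pair[2]), ...
  )
  graphics::arrows(L, f - b, L, f + b, angle = 90, code = 3, length = 0.03)
  invisible(data.frame(L = L, frequency = f, band = b))
})

#' Construct a motif set
#'
#' @param name set label.
#' @param motifs character vector of motifs over `{A,C,G,T,n}`.
#' @return a [MotifSet-class].
#' @examples
#' MotifSet("toy", c("AATT", "ACnGC"))
#' @export
MotifSet <- function(name, motifs) {
  methods::new("MotifSet", name = name, motifs = as.character(motifs))
}

#' @describeIn motifs the motif strings of a set.
#' @export
setMethod("motifs", "MotifSet", function(object) object@motifs)

setMethod("show", "MotifSet", function(object) {
  cat(sprintf("MotifSet '%s': %d motif(s)\n", object@name, length(object@motifs)))
  cat(" ", paste(object@motifs, collapse = ", "), "\n")
})

setMethod("length", "MotifSet", function(x) length(x@motifs))

#' Read a motif set from a plain-text file
#'
#' One motif per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @param name set label (default: file name).
#' @return a [MotifSet-class].
#' @export
readMotifSet <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  MotifSet(name, lines)
}

# ---- the fixed feature pattern lists --------------------------------------

# 17 ordered dinucleotide pairs whose spacing profile peaks at L = 4 in
# UCNEs; counted at L = 3 (one wildcard) and L = 4 (two wildcards).
.F3_PAIRS <- matrix(
  c(
    "TA", "GA", "TA", "GC", "TA", "GG", "TA", "GT",
    "AC", "TA", "CC", "TA", "GC", "TA", "TC", "TA",
    "AA", "GC", "AT", "GC", "GC", "TT", "AG", "AT",
    "GG", "AT", "AG", "GT", "AC", "CT", "AT", "CT",
    "GC", "TC"
  ),
  ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("d1", "d2"))
)

.F4_TRIPLETS <- c("GGG", "CCC", "GAG", "CCT", "CCA", "CTC", "TGG", "AGG")
.F5_TRIPLETS <- c("TTA", "TAA", "ATT", "AAT")
.F6_TETRAMERS <- c(
  "AATT", "TACA", "TTAC", "GTAA", "TTAT", "ATAA", "AATG", "CATT", "ATTA",
  "TAAT", "TCAT", "ATGA", "TTAA", "TCAA", "TTGA", "CAAT", "ATTG"
)
.F7_MOTIFS <- c(
  "ACnGC", "GCnGT", "ACnGT", "AAnAG", "CTnTT", "TGnCA", "CTnAT", "ATnAG",
  "CAnTA", "TAnTG", "TTnAT", "ATnAA", "TTnTC", "GAnAA", "TAnTA", "GTnAT",
  "ATnAC", "ATnAT"
)

#' Shipped feature pattern lists
#'
#' The fixed pattern collections behind the composition features:
#' `f3Pairs()` returns the 17 ordered dinucleotide pairs of the L4/L3
#' spacing-ratio feature as a two-column matrix; the others return
#' [MotifSet-class] objects: 8 GC-rich triplets, 4 AT-rich triplets, 17
#' UCNE-enriched adjacent dinucleotide pairs (4-mers) and 18 one-spacer
#' pairs (wildcard 5-mers).
#'
#' @return see Description.
#' @examples
#' f3Pairs()
#' motifs(f7Motifs())
#' @export
f3Pairs <- function() .F3_PAIRS

#' @rdname f3Pairs
#' @param L spacing distance at which to expand the pairs into motifs
#'   (3 = one wildcard, 4 = two wildcards).
#' @export
f3Motifs <- function(L = 4L) {
  stopifnot(L >= 2L)
  wild <- strrep("n", L - 2L)
  MotifSet(
    sprintf("spacing-ratio pairs at L=%d", L),
    paste0(.F3_PAIRS[, 1], wild, .F3_PAIRS[, 2])
  )
}

#' @rdname f3Pairs
#' @export
f4Triplets <- function() MotifSet("GC-rich triplets", .F4_TRIPLETS)

#' @rdname f3Pairs
#' @export
f5Triplets <- function() MotifSet("AT-rich triplets", .F5_TRIPLETS)

#' @rdname f3Pairs
#' @export
f6Tetramers <- function() MotifSet("enriched adjacent dinucleotide pairs", .F6_TETRAMERS)

#' @rdname f3Pairs
#' @export
f7Motifs <- function() MotifSet("enriched one-spacer dinucleotide pairs", .F7_MOTIFS)
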