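# internal helpers shared across modules

BASES <- c("A", "C", "G", "T")

# ordered dinucleotide alphabet: AA AC AG AT CA ... TT (first base slow index)
DINUCLEOTIDES <- paste0(rep(BASES, each = 4L), BASES)

#' @importFrom withr with_seed
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# k reproducible child seeds from one master seed; kept < 2^31
.childSeeds <- function(seed, k) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# character string -> integer codes 1..4 (A,C,G,T), NA for N; case-insensitive.
# Input is assumed pre-validated to the {A,C,G,T,N} alphabet (any case).
.seqCodes <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], BASES)
}

# number of NA-free windows of width w, and logical index of valid window starts
.validWindows <- function(codes, w) {
  n <- length(codes)
  if (n < w) {
    return(logical(0))
  }
  cs <- c(0L, cumsum(is.na(codes)))
  i <- seq_len(n - w + 1L)
  (cs[i + w] - cs[i]) == 0L
}

.assertScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
}

# accept a MaskedDNA/BStringSet element or a plain string; return one string
.asSequenceString <- function(seq) {
  if (methods::is(seq, "XStringSet")) {
    if (length(seq) != 1L) {
      stop("expected a single sequence, got ", length(seq), call. = FALSE)
    }
    return(as.character(seq)[[1]])
  }
  if (methods::is(seq, "XString")) {
    return(as.character(seq))
  }
  .assertScalarString(seq, "seq")
  seq
}
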