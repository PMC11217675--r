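#' Case-preserving DNA sequence set
#'
#' A thin subclass of [Biostrings::BStringSet] restricted to the alphabet
#' `{A,C,G,T,N,a,c,g,t,n}`. Lowercase letters carry soft-masking (repeat
#' annotation) exactly as in UCSC genome FASTA files; the class preserves
#' case on round-trip, so masking survives I/O. `N`/`n` mark assembly gaps
#' and are excluded from all pattern counts downstream.
#'
#' @slot .Data inherited `BStringSet` storage.
#' @seealso [readFasta()], [writeFasta()], [maskedFraction()]
#' @importClassesFrom Biostrings BStringSet
#' @exportClass MaskedDNA
setClass("MaskedDNA", contains = "BStringSet")

.validMaskedDNA <- function(object) {
  seqs <- as.character(object)
  hit <- regexpr("[^ACGTNacgtn]", seqs)
  off <- which(hit > 0L)
  if (length(off) > 0L) {
    i <- off[1L]
    id <- if (!is.null(names(seqs))) names(seqs)[i] else as.character(i)
    return(sprintf(
      "illegal character '%s' in record '%s' at position %d (alphabet is A,C,G,T,N any case)",
      substr(seqs[i], hit[i], hit[i]), id, hit[i]
    ))
  }
  TRUE
}
setValidity("MaskedDNA", .validMaskedDNA)

#' Construct a MaskedDNA set
#'
#' @param x named character vector of sequences (names become record ids),
#'   or a `BStringSet`.
#' @return a [MaskedDNA-class] object.
#' @examples
#' MaskedDNA(c(s1 = "ACGTacgtNn"))
#' @export
MaskedDNA <- function(x) {
  if (is.character(x)) {
    x <- Biostrings::BStringSet(x)
  }
  methods::validObject(obj <- methods::new("MaskedDNA", x))
  obj
}

#' Spacing-distance profile between two dinucleotides
#'
#' Co-occurrence counts of an ordered dinucleotide pair (d1, d2) as a
#' function of the spacing distance L = start(d2) - start(d1), accumulated
#' over a set of sequences. L = 1 means the two dinucleotides intersect
#' (share one base), L = 2 adjacent, L = 3 one spacer base, L = 4 two
#' spacer bases. Frequencies are counts per valid (N-free) window of width
#' L + 2; `sigma` is the across-sequence standard deviation of the
#' per-sequence frequency, from which the +/-3 sigma band of the mean
#' curve is derived (sd / sqrt(n), a standard error).
#'
#' @slot pair character(2), the ordered dinucleotides (d1, d2).
#' @slot counts integer vector named by L (1..Lmax), pooled counts.
#' @slot frequencies numeric vector named by L, pooled counts per valid window.
#' @slot sigma numeric vector named by L, per-sequence sd of the frequency.
#' @slot nseq number of sequences profiled.
#' @slot lmax largest spacing distance profiled.
#' @seealso [spacingProfile()], [spacingBand()]
#' @exportClass SpacingProfile
setClass("SpacingProfile", representation(
  pair = "character",
  counts = "integer",
  frequencies = "numeric",
  sigma = "numeric",
  nseq = "integer",
  lmax = "integer"
))

setValidity("SpacingProfile", function(object) {
  if (length(object@pair) != 2L || !all(object@pair %in% DINUCLEOTIDES)) {
    return("pair must be two ordered dinucleotides over A,C,G,T")
  }
  if (any(object@counts < 0L)) {
    return("counts must be non-negative")
  }
  if (length(object@counts) != object@lmax ||
    length(object@frequencies) != object@lmax ||
    length(object@sigma) != object@lmax) {
    return("counts/frequencies/sigma must have one entry per L = 1..Lmax")
  }
  if (any(object@frequencies < 0)) {
    return("frequencies must be non-negative")
  }
  TRUE
})

#' Wildcard dinucleotide-pattern set
#'
#' A named collection of motifs over the alphabet `{A,C,G,T,n}` where `n`
#' is a single-base wildcard matching any of A/C/G/T (but never N). Used to
#' hold the fixed pattern lists behind the composition features (GC-rich
#' triplets, AT-rich triplets, enriched adjacent and one-spacer dinucleotide
#' pairs, and the spacing-ratio pairs).
#'
#' @slot name set label.
#' @slot motifs character vector of unique motifs.
#' @seealso [MotifSet()], [readMotifSet()], [f3Pairs()]
#' @exportClass MotifSet
setClass("MotifSet", representation(name = "character", motifs = "character"))

setValidity("MotifSet", function(object) {
  if (length(object@name) != 1L) {
    return("name must be a single string")
  }
  if (anyDuplicated(object@motifs)) {
    return("motifs must be unique within a set")
  }
  bad <- grepl("[^ACGTn]", object@motifs)
  if (any(bad)) {
    return(sprintf("invalid motif '%s' (alphabet is A,C,G,T and wildcard n)", object@motifs[bad][1]))
  }
  if (any(nchar(object@motifs) < 2L)) {
    return("motifs must be at least 2 bases long")
  }
  if (any(nchar(gsub("n", "", object@motifs, fixed = TRUE)) < 2L)) {
    return("motifs must contain at least two non-wildcard bases")
  }
  TRUE
})

#' First-order Markov composition specification
#'
#' Defines a sequence-generating process: a 4x4 conditional next-base matrix
#' (rows = preceding base A,C,G,T; rows sum to 1), an initial base
#' distribution (by construction the stationary distribution), a length
#' model (discretized log-normal clipped to \[min, max\] with the given
#' mode), and an optional table of motifs planted on top of the Markov
#' background at a Poisson rate per kb.
#'
#' @slot transitionProbs 4x4 stochastic matrix, dimnames A,C,G,T.
#' @slot initialProbs length-4 probability vector (stationary distribution).
#' @slot lengthModel list with `min`, `mode`, `max` (nt) and `sdlog`.
#' @slot plantedMotifs data.frame with columns `motif`, `rate` (events/kb),
#'   possibly empty.
#' @seealso [compositionSpec()], [markovGenerate()]
#' @exportClass CompositionSpec
setClass("CompositionSpec", representation(
  transitionProbs = "matrix",
  initialProbs = "numeric",
  lengthModel = "list",
  plantedMotifs = "data.frame"
))

setValidity("CompositionSpec", function(object) {
  tp <- object@transitionProbs
  if (!all(dim(tp) == c(4L, 4L))) {
    return("transitionProbs must be 4x4")
  }
  if (any(tp < 0) || any(abs(rowSums(tp) - 1) > 1e-9)) {
    return("transitionProbs rows must be probabilities summing to 1")
  }
  ip <- object@initialProbs
  if (length(ip) != 4L || any(ip < 0) || abs(sum(ip) - 1) > 1e-9) {
    return("initialProbs must be a length-4 probability vector")
  }
  lm <- object@lengthModel
  need <- c("min", "mode", "max", "sdlog")
  if (!all(need %in% names(lm))) {
    return("lengthModel needs min, mode, max, sdlog")
  }
  if (!(lm$min <= lm$mode && lm$mode <= lm$max) || lm$min < 1) {
    return("lengthModel must satisfy 1 <= min <= mode <= max")
  }
  pm <- object@plantedMotifs
  if (nrow(pm) > 0L && !all(c("motif", "rate") %in% names(pm))) {
    return("plantedMotifs needs columns motif and rate")
  }
  TRUE
})

#' Labelled synthetic benchmark
#'
#' Positive (UCNE-like) and negative (genomic background) sequence sets
#' generated from two [CompositionSpec-class] objects, with the master seed
#' recorded for reproducibility.
#'
#' @slot positives,negatives [MaskedDNA-class] sets.
#' @slot posSpec,negSpec the generating [CompositionSpec-class] objects.
#' @slot seed master seed used.
#' @seealso [makeBenchmark()]
#' @exportClass BenchmarkSet
setClass("BenchmarkSet", representation(
  positives = "MaskedDNA",
  negatives = "MaskedDNA",
  posSpec = "CompositionSpec",
  negSpec = "CompositionSpec",
  seed = "integer"
))

#' Classifier evaluation report
#'
#' Held-out test-set evaluation of one classifier: confusion matrix,
#' sensitivity, specificity, accuracy with exact binomial (Clopper-Pearson)
#' 95% CI, ROC points and trapezoidal AUC. The positive class is the
#' UCNE-like label 1.
#'
#' @slot model model key ("svm_rbf", "random_forest" or "ann").
#' @slot confusion 2x2 integer matrix, predicted x actual.
#' @slot sensitivity TP / (TP + FN).
#' @slot specificity TN / (TN + FP).
#' @slot accuracy (TP + TN) / total.
#' @slot accuracyCI numeric(2), exact binomial 95% CI on accuracy.
#' @slot auc area under the ROC curve (trapezoid, ties half-credit).
#' @slot rocPoints data.frame with columns FPR, TPR.
#' @slot predictions data.frame with per-test-sequence `ID`, `actual`,
#'   `predicted`, `score`.
#' @slot config list echoing the model configuration and seed.
#' @seealso [trainEval()], [metrics()]
#' @exportClass EvalReport
setClass("EvalReport", representation(
  model = "character",
  confusion = "matrix",
  sensitivity = "numeric",
  specificity = "numeric",
  accuracy = "numeric",
  accuracyCI = "numeric",
  auc = "numeric",
  rocPoints = "data.frame",
  predictions = "data.frame",
  config = "list"
))

setValidity("EvalReport", function(object) {
  cm <- object@confusion
  if (!all(dim(cm) == c(2L, 2L))) {
    return("confusion must be 2x2")
  }
  if (object@auc < 0 || object@auc > 1) {
    return("auc must be in [0, 1]")
  }
  TRUE
})

#' Monte-Carlo variant-set enrichment report
#'
#' Compares the observed count of a clinical-significance category inside a
#' SNP set with its distribution over size-matched random SNP sets drawn
#' from a null pool, using the add-one empirical p-value
#' p = (1 + #\{null at least as extreme\}) / (n_sets + 1).
#'
#' @slot category the CLNSIG category tested.
#' @slot observed named numeric, observed count for `category`.
#' @slot nullMean named numeric, per-category mean count over the null sets.
#' @slot nullCounts numeric, the focal-category count in each null set.
#' @slot nSets,setSize Monte-Carlo design.
#' @slot pValue empirical p-value.
#' @slot direction "depleted" or "enriched".
#' @slot seed RNG seed used.
#' @seealso [monteCarloEnrichment()]
#' @exportClass EnrichmentReport
setClass("EnrichmentReport", representation(
  category = "character",
  observed = "numeric",
  nullMean = "numeric",
  nullCounts = "numeric",
  nSets = "integer",
  setSize = "integer",
  pValue = "numeric",
  direction = "character",
  seed = "integer"
))

setValidity("EnrichmentReport", function(object) {
  if (object@pValue < 1 / (object@nSets + 1) - 1e-12 || object@pValue > 1 + 1e-12) {
    return("pValue must lie in [1/(nSets+1), 1]")
  }
  if (!object@direction %in% c("depleted", "enriched")) {
    return("direction must be 'depleted' or 'enriched'")
  }
  TRUE
})
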