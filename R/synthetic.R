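# Synthetic benchmark generator: first-order Markov sequences with
# controlled GC content and dinucleotide enrichment, planted spacing
# motifs, and toy ClinVar-style VCF fixtures.

# stationary base distribution with a given GC percent, A=T and G=C
.stationaryFromGC <- function(gcPercent) {
  gc <- gcPercent / 100
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  p
}

# joint dinucleotide matrix with marginals p on both axes, where the
# (G,C), (C,C) and (G,G) cells are exact fold-changes of the independence
# baseline. Fixed-cell iterative proportional fitting: the targeted cells
# stay put, free cells absorb the marginal corrections.
.jointWithFolds <- function(p, gpcFold, ccggFold, tol = 1e-12, maxit = 10000L) {
  B <- outer(p, p)
  J <- B
  fixed <- matrix(FALSE, 4L, 4L, dimnames = dimnames(B))
  J["G", "C"] <- gpcFold * B["G", "C"]
  fixed["G", "C"] <- TRUE
  J["C", "C"] <- ccggFold * B["C", "C"]
  J["G", "G"] <- ccggFold * B["G", "G"]
  fixed["C", "C"] <- fixed["G", "G"] <- TRUE
  for (it in seq_len(maxit)) {
    for (i in 1:4) {
      free <- !fixed[i, ]
      target <- p[i] - sum(J[i, !free])
      fs <- sum(J[i, free])
      if (target <= 0 || fs <= 0) {
        stop("infeasible composition targets (row renormalization failed)", call. = FALSE)
      }
      J[i, free] <- J[i, free] * target / fs
    }
    for (j in 1:4) {
      free <- !fixed[, j]
      target <- p[j] - sum(J[!free, j])
      fs <- sum(J[free, j])
      if (target <= 0 || fs <= 0) {
        stop("infeasible composition targets (column renormalization failed)", call. = FALSE)
      }
      J[free, j] <- J[free, j] * target / fs
    }
    err <- max(abs(rowSums(J) - p), abs(colSums(J) - p))
    if (err < tol) {
      return(J)
    }
  }
  stop("composition renormalization failed to converge", call. = FALSE)
}

#' Build a composition specification from compositional targets
#'
#' Constructs a first-order Markov [CompositionSpec-class] whose stationary
#' GC content equals `gc` and whose stationary GpC and CC/GG dinucleotide
#' frequencies are exact fold-changes of the GC-matched independence
#' baseline (`gpcFold` times, `ccggFold` times). The remaining dinucleotide
#' cells are renormalized (fixed-cell iterative proportional fitting) so
#' that both marginals stay at the target base composition. With neutral
#' folds and gc = 50 this reduces to the uniform independence matrix.
#'
#' @param gc stationary GC content in percent (0 < gc < 100).
#' @param gpcFold,ccggFold fold-change of the GpC and of the CC and GG
#'   stationary frequencies relative to independence (defaults 1 =
#'   neutral). UCNE-like composition is GpC-enriched, CC/GG-depleted.
#' @param lengthModel list with `min`, `mode`, `max` (nt) and `sdlog`; the
#'   default (200/300/1000, sdlog 0.45) mimics the UCNE length
#'   distribution: most sequences near 300 nt, rarely up to 1000.
#' @param plantedMotifs `NULL`, or a data.frame with columns `motif` (over
#'   `{A,C,G,T,n}`) and `rate` (expected insertions per kb).
#' @return a [CompositionSpec-class].
#' @examples
#' spec <- compositionSpec(gc = 37, gpcFold = 1.5, ccggFold = 0.7)
#' transitionProbs(spec)
#' @export
compositionSpec <- function(gc = 37, gpcFold = 1, ccggFold = 1,
                            lengthModel = list(min = 200L, mode = 300L, max = 1000L, sdlog = 0.45),
                            plantedMotifs = NULL) {
  if (!(gc > 0 && gc < 100)) {
    stop("gc must be strictly between 0 and 100", call. = FALSE)
  }
  if (gpcFold <= 0 || ccggFold <= 0) {
    stop("fold changes must be positive", call. = FALSE)
  }
  p <- .stationaryFromGC(gc)
  J <- .jointWithFolds(p, gpcFold, ccggFold)
  T <- J / rowSums(J)
  dimnames(T) <- list(BASES, BASES)
  if (is.null(plantedMotifs)) {
    plantedMotifs <- data.frame(motif = character(0), rate = numeric(0))
  }
  for (m in plantedMotifs$motif) .motifCodes(m) # validate
  methods::new("CompositionSpec",
    transitionProbs = T,
    initialProbs = stats::setNames(as.numeric(p), BASES),
    lengthModel = lengthModel,
    plantedMotifs = plantedMotifs
  )
}

#' @describeIn transitionProbs conditional next-base matrix of a spec.
#' @export
setMethod("transitionProbs", "CompositionSpec", function(object) object@transitionProbs)

#' @describeIn stationaryProbs stationary base distribution of a spec
#'   (equals its initial distribution by construction).
#' @export
setMethod("stationaryProbs", "CompositionSpec", function(object) object@initialProbs)

#' Stationary dinucleotide probabilities of a composition spec
#'
#' The joint probability of each ordered dinucleotide under the stationary
#' process, `pi_i * T[i, j]`.
#'
#' @param spec a [CompositionSpec-class].
#' @return named numeric vector of length 16 (AA..TT).
#' @export
stationaryDinucleotideProbs <- function(spec) {
  stopifnot(methods::is(spec, "CompositionSpec"))
  J <- spec@initialProbs * spec@transitionProbs
  stats::setNames(as.vector(t(J)), DINUCLEOTIDES)
}

setMethod("show", "CompositionSpec", function(object) {
  p <- object@initialProbs
  cat(sprintf(
    "CompositionSpec: stationary GC %.1f%%, lengths %d-%d nt (mode %d), %d planted motif(s)\n",
    100 * (p["C"] + p["G"]), object@lengthModel$min, object@lengthModel$max,
    object@lengthModel$mode, nrow(object@plantedMotifs)
  ))
  print(round(object@transitionProbs, 3))
})

# lengths from a discretized log-normal with given mode, rejected into
# [min, max]
.drawLengths <- function(n, lm) {
  meanlog <- log(lm$mode) + lm$sdlog^2
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rlnorm(2L * (n - length(out)) + 10L, meanlog, lm$sdlog))
    out <- c(out, x[x >= lm$min & x <= lm$max])
  }
  as.integer(out[seq_len(n)])
}

#' Generate first-order Markov sequences
#'
#' Simulates `n` sequences from a [CompositionSpec-class]: lengths from
#' the spec's length model (or `lengths` if supplied), bases from the
#' Markov chain started at stationarity, then any planted motifs written
#' over the background at Poisson(rate x length/1000) uniform positions
#' (wildcard positions filled with random bases; overwriting keeps lengths
#' exact). Deterministic given `seed`. True planting positions are
#' attached as attribute `plantLog` for diagnostics.
#'
#' @param spec a [CompositionSpec-class].
#' @param n number of sequences.
#' @param seed integer seed.
#' @param lengths optional explicit integer lengths overriding the model.
#' @param prefix id prefix (default "synth").
#' @return [MaskedDNA-class] of `n` uppercase sequences.
#' @export
markovGenerate <- function(spec, n, seed, lengths = NULL, prefix = "synth") {
  stopifnot(methods::is(spec, "CompositionSpec"), n >= 1L)
  .withSeed(seed, {
    lm <- spec@lengthModel
    len <- if (is.null(lengths)) .drawLengths(n, lm) else rep_len(as.integer(lengths), n)
    maxlen <- max(len)
    cum <- t(apply(spec@transitionProbs, 1L, cumsum))
    cini <- cumsum(spec@initialProbs)
    states <- matrix(0L, nrow = n, ncol = maxlen)
    u <- stats::runif(n)
    states[, 1L] <- 1L + (u > cini[1]) + (u > cini[2]) + (u > cini[3])
    if (maxlen >= 2L) {
      for (j in 2:maxlen) {
        alive <- which(len >= j)
        u <- stats::runif(length(alive))
        cur <- states[alive, j - 1L]
        states[alive, j] <- 1L + (u > cum[cur, 1L]) + (u > cum[cur, 2L]) + (u > cum[cur, 3L])
      }
    }
    plant <- spec@plantedMotifs
    logRows <- list()
    if (nrow(plant) > 0L) {
      for (i in seq_len(n)) {
        for (r in seq_len(nrow(plant))) {
          mc <- .motifCodes(plant$motif[r])
          w <- length(mc)
          if (len[i] < w) next
          k <- stats::rpois(1L, plant$rate[r] * len[i] / 1000)
          if (k == 0L) next
          starts <- sample.int(len[i] - w + 1L, k, replace = TRUE)
          for (st in starts) {
            fill <- mc
            wild <- is.na(fill)
            if (any(wild)) {
              fill[wild] <- sample.int(4L, sum(wild), replace = TRUE)
            }
            states[i, st:(st + w - 1L)] <- fill
          }
          logRows[[length(logRows) + 1L]] <- data.frame(
            seq = i, motif = plant$motif[r], start = starts
          )
        }
      }
    }
    out <- vapply(
      seq_len(n),
      function(i) paste(BASES[states[i, seq_len(len[i])]], collapse = ""),
      character(1)
    )
    names(out) <- sprintf("%s_%d", prefix, seq_len(n))
    res <- MaskedDNA(out)
    attr(res, "plantLog") <- if (length(logRows)) do.call(rbind, logRows) else NULL
    res
  })
}

#' Generate a labelled synthetic benchmark
#'
#' Positive (UCNE-like) and negative (genomic-background-like) sequence
#' sets. The default positive spec has 37% GC, 1.5-fold GpC enrichment,
#' 0.7-fold CC/GG depletion and the 17 signature dinucleotide pairs
#' planted at L = 4 spacing at a combined rate of 2 per kb; the default
#' negative spec is a neutral 42% GC background -- the compositional
#' contrasts the real UCNE/uWGE datasets exhibit.
#'
#' @param nPerClass sequences per class.
#' @param seed master seed.
#' @param posSpec,negSpec [CompositionSpec-class] objects; `NULL` for the
#'   defaults above.
#' @return a [BenchmarkSet-class].
#' @examples
#' bench <- makeBenchmark(5, seed = 1)
#' positives(bench)
#' @export
makeBenchmark <- function(nPerClass, seed, posSpec = NULL, negSpec = NULL) {
  stopifnot(nPerClass >= 1L)
  if (is.null(posSpec)) {
    posSpec <- compositionSpec(
      gc = 37, gpcFold = 1.5, ccggFold = 0.7,
      plantedMotifs = f3PlantingMotifs(rate = 2)
    )
  }
  if (is.null(negSpec)) {
    negSpec <- compositionSpec(gc = 42)
  }
  seeds <- .childSeeds(seed, 2L)
  methods::new("BenchmarkSet",
    positives = markovGenerate(posSpec, nPerClass, seeds[1], prefix = "ucne_like"),
    negatives = markovGenerate(negSpec, nPerClass, seeds[2], prefix = "background"),
    posSpec = posSpec, negSpec = negSpec, seed = as.integer(seed)
  )
}

#' Planting table for the signature spacing pairs
#'
#' The 17 signature dinucleotide pairs expanded at L = 4 (two wildcards),
#' with a combined planting rate of `rate` events per kb split evenly
#' across the pairs. Used as the default positive-class planting of
#' [makeBenchmark()].
#'
#' @param rate combined insertion rate per kb.
#' @return data.frame with columns `motif`, `rate`.
#' @export
f3PlantingMotifs <- function(rate = 2) {
  m <- motifs(f3Motifs(4L))
  data.frame(motif = m, rate = rate / length(m))
}

#' @describeIn positives positive (UCNE-like) sequences of a benchmark.
#' @export
setMethod("positives", "BenchmarkSet", function(object) object@positives)

#' @describeIn negatives negative (background) sequences of a benchmark.
#' @export
setMethod("negatives", "BenchmarkSet", function(object) object@negatives)

setMethod("show", "BenchmarkSet", function(object) {
  cat(sprintf(
    "BenchmarkSet: %d positives, %d negatives (seed %d)\n",
    length(object@positives), length(object@negatives), object@seed
  ))
})

#' Write a toy ClinVar-style VCF and SNP list
#'
#' Generates `nSnps` SNVs at distinct uniform positions on one chromosome
#' and writes a VCF v4.1 with a `CLNSIG` INFO key assigned according to
#' `clnsigProportions` (a named vector of per-SNP probabilities; the
#' remainder carries no CLNSIG annotation, emulating variants absent from
#' the clinical catalogue). Deterministic given `seed`.
#'
#' @param path output VCF path.
#' @param genomeLength chromosome length in nt.
#' @param nSnps number of SNVs.
#' @param clnsigProportions named numeric, e.g.
#'   `c(Pathogenic = 0.001, Benign = 0.002)`; must sum to <= 1.
#' @param seed integer seed.
#' @param chrom chromosome name (default "chr1").
#' @return invisibly, a list with `vcf` (the path) and `snps` (data.frame
#'   `chrom`, 1-based `pos`, `id`, `ref`, `alt`, `clnsig`).
#' @export
syntheticSnpVcf <- function(path, genomeLength, nSnps, clnsigProportions,
                            seed, chrom = "chr1") {
  if (sum(clnsigProportions) > 1 + 1e-9) {
    stop("clnsigProportions must sum to at most 1", call. = FALSE)
  }
  if (nSnps > genomeLength) {
    stop("more SNPs requested than genome positions", call. = FALSE)
  }
  .withSeed(seed, {
    pos <- sort(sample.int(genomeLength, nSnps))
    cats <- c(names(clnsigProportions), NA_character_)
    probs <- c(as.numeric(clnsigProportions), 1 - sum(clnsigProportions))
    clnsig <- sample(cats, nSnps, replace = TRUE, prob = probs)
    ref <- BASES[sample.int(4L, nSnps, replace = TRUE)]
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
    snps <- data.frame(
      chrom = chrom, pos = pos, id = sprintf("snp_%d", seq_len(nSnps)),
      ref = ref, alt = alt, clnsig = clnsig, stringsAsFactors = FALSE
    )
    info <- ifelse(is.na(clnsig), ".", paste0("CLNSIG=", clnsig))
    lines <- c(
      "##fileformat=VCFv4.1",
      sprintf("##contig=<ID=%s,length=%d>", chrom, genomeLength),
      "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
        collapse = "\t"
      ),
      sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s", chrom, pos, snps$id, ref, alt, info)
    )
    writeLines(lines, path)
    invisible(list(vcf = path, snps = snps))
  })
}
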