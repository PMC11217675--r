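# Length-matched genomic control sampling and dinucleotide-preserving
# shuffles. WGE-style fragments may contain soft-masked (lowercase) repeats;
# uWGE-style fragments must be repeat-free. Fragments containing N (assembly
# gaps) are never accepted in either mode.

.fragmentOk <- function(frag, allowMasked) {
  if (grepl("[Nn]", frag)) {
    return(FALSE)
  }
  if (!allowMasked && grepl("[acgt]", frag)) {
    return(FALSE)
  }
  TRUE
}

.sampleUniform <- function(seqs, widths, lengths, allowMasked, maxTries, label) {
  out <- character(length(lengths))
  manifest <- data.frame(
    id = character(length(lengths)), chrom = character(length(lengths)),
    start = integer(length(lengths)), end = integer(length(lengths)),
    length = integer(length(lengths)), stringsAsFactors = FALSE
  )
  for (k in seq_along(lengths)) {
    len <- lengths[k]
    slots <- pmax(widths - len + 1L, 0L)
    if (sum(slots) == 0L) {
      stop("no contig long enough for a fragment of length ", len, call. = FALSE)
    }
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      ci <- sample.int(length(seqs), 1L, prob = slots)
      start <- sample.int(slots[ci], 1L)
      frag <- substr(seqs[[ci]], start, start + len - 1L)
      if (.fragmentOk(frag, allowMasked)) {
        out[k] <- frag
        manifest$id[k] <- sprintf("%s_%d", label, k)
        manifest$chrom[k] <- names(seqs)[ci]
        manifest$start[k] <- start - 1L # 0-based half-open
        manifest$end[k] <- start - 1L + len
        manifest$length[k] <- len
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(
        "could not place a fragment of length ", len, " after ", maxTries,
        " tries (genome too masked or gapped)",
        call. = FALSE
      )
    }
  }
  names(out) <- manifest$id
  res <- MaskedDNA(out)
  S4Vectors::mcols(res) <- S4Vectors::DataFrame(manifest[, -1L])
  res
}

#' Sample length-matched random genomic fragments (WGE-style controls)
#'
#' Draws fragments from a genome whose length multiset equals `lengths`
#' exactly, emulating whole-genome element (WGE) control sets. Uniform
#' mode draws start positions uniformly over all eligible loci genome-wide
#' (fragments may overlap each other and may contain soft-masked repeats);
#' walk mode advances a cursor by `step` nt between picks along a single
#' chromosome, giving non-overlapping, locally clustered controls.
#' Fragments containing N are rejected. Deterministic given `seed`.
#'
#' @param genome [MaskedDNA-class] (or named character vector) of contigs.
#' @param lengths integer vector of fragment lengths to match (e.g.
#'   `width()` of a reference UCNE set).
#' @param seed integer seed.
#' @param mode `"uniform"` or `"walk"`.
#' @param step walk-mode cursor increment in nt (default 5000).
#' @param chrom walk-mode chromosome (default: first contig).
#' @param maxTries per-fragment rejection budget in uniform mode.
#' @return [MaskedDNA-class] with a manifest (`chrom`, 0-based `start`,
#'   half-open `end`, `length`) in `mcols()`.
#' @export
sampleGenomicFragments <- function(genome, lengths, seed,
                                   mode = c("uniform", "walk"),
                                   step = 5000L, chrom = NULL,
                                   maxTries = 1000L) {
  mode <- match.arg(mode)
  seqs <- if (methods::is(genome, "XStringSet")) as.character(genome) else genome
  if (is.null(names(seqs))) {
    names(seqs) <- paste0("contig_", seq_along(seqs))
  }
  lengths <- as.integer(lengths)
  stopifnot(all(lengths >= 1L))
  widths <- nchar(seqs)
  .withSeed(seed, {
    if (mode == "uniform") {
      .sampleUniform(seqs, widths, lengths, allowMasked = TRUE, maxTries, "wge")
    } else {
      if (is.null(chrom)) {
        chrom <- names(seqs)[1]
      }
      s <- seqs[[chrom]]
      W <- nchar(s)
      cursor <- sample.int(step, 1L)
      out <- character(length(lengths))
      manifest <- data.frame(
        id = sprintf("wge_%d", seq_along(lengths)), chrom = chrom,
        start = 0L, end = 0L, length = lengths, stringsAsFactors = FALSE
      )
      for (k in seq_along(lengths)) {
        repeat {
          if (cursor + lengths[k] - 1L > W) {
            stop("walk exhausted chromosome '", chrom, "' at fragment ", k,
              " of ", length(lengths),
              call. = FALSE
            )
          }
          frag <- substr(s, cursor, cursor + lengths[k] - 1L)
          if (.fragmentOk(frag, allowMasked = TRUE)) {
            out[k] <- frag
            manifest$start[k] <- cursor - 1L
            manifest$end[k] <- cursor - 1L + lengths[k]
            cursor <- cursor + step
            break
          }
          cursor <- cursor + step # skip gapped windows, keep >= step increments
        }
      }
      names(out) <- manifest$id
      res <- MaskedDNA(out)
      S4Vectors::mcols(res) <- S4Vectors::DataFrame(manifest[, -1L])
      res
    }
  })
}

#' Sample repeat-free genomic fragments (uWGE-style controls)
#'
#' As uniform [sampleGenomicFragments()], with the added constraint that
#' accepted fragments contain neither lowercase (soft-masked repeat) nor N
#' residues -- the "unique" whole-genome element construction.
#'
#' @inheritParams sampleGenomicFragments
#' @return [MaskedDNA-class] with manifest in `mcols()`.
#' @export
sampleUniqueFragments <- function(genome, lengths, seed, maxTries = 1000L) {
  seqs <- if (methods::is(genome, "XStringSet")) as.character(genome) else genome
  if (is.null(names(seqs))) {
    names(seqs) <- paste0("contig_", seq_along(seqs))
  }
  lengths <- as.integer(lengths)
  stopifnot(all(lengths >= 1L))
  .withSeed(seed, {
    res <- .sampleUniform(seqs, nchar(seqs), lengths,
      allowMasked = FALSE,
      maxTries = maxTries, label = "uwge"
    )
    res
  })
}

#' Exact dinucleotide-preserving shuffle
#'
#' Returns a uniformly drawn sequence with exactly the same dinucleotide
#' count vector as the input (hence identical mononucleotide counts and GC
#' content), via the Euler-path construction of Altschul and Erickson:
#' random last-exit edges are drawn per vertex until they form an
#' arborescence into the final base, remaining edges are permuted, and the
#' Eulerian walk is read off. The quasi-random null for spacing-profile
#' analysis.
#'
#' @param seq a single sequence, length >= 3, no N.
#' @param seed integer seed.
#' @return shuffled sequence as an uppercase character string (soft-masking
#'   is meaningless after shuffling).
#' @examples
#' dinucleotideShuffle("AACAG", seed = 1)
#' @export
dinucleotideShuffle <- function(seq, seed) {
  s <- .asSequenceString(seq)
  .checkAlphabet(s)
  if (grepl("[Nn]", s)) {
    stop("cannot shuffle a sequence containing N", call. = FALSE)
  }
  codes <- .seqCodes(s)
  n <- length(codes)
  if (n < 3L) {
    stop("sequence must be at least 3 nt long", call. = FALSE)
  }
  .withSeed(seed, {
    vend <- codes[n]
    succ <- lapply(1:4, function(v) codes[which(codes[-n] == v) + 1L])
    nout <- lengths(succ)
    active <- which(nout > 0L)
    # draw last-exit edges until they form an arborescence into vend
    lastTo <- integer(4L)
    repeat {
      ok <- TRUE
      for (v in active) {
        if (v == vend) next
        lastTo[v] <- succ[[v]][sample.int(nout[v], 1L)]
      }
      for (v in active) {
        if (v == vend) next
        cur <- v
        hops <- 0L
        while (cur != vend && hops <= 4L) {
          cur <- lastTo[cur]
          hops <- hops + 1L
          if (cur == 0L) break
        }
        if (cur != vend) {
          ok <- FALSE
          break
        }
      }
      if (ok) break
    }
    order <- vector("list", 4L)
    for (v in active) {
      ed <- succ[[v]]
      if (v == vend) {
        order[[v]] <- ed[sample.int(length(ed))]
      } else {
        # remove one copy of the chosen last edge, permute the rest, append it
        drop <- match(lastTo[v], ed)
        rest <- ed[-drop]
        order[[v]] <- c(rest[sample.int(max(length(rest), 0L))], lastTo[v])
      }
    }
    res <- integer(n)
    ptr <- rep(1L, 4L)
    cur <- codes[1]
    res[1] <- cur
    for (i in 2:n) {
      nxt <- order[[cur]][ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      res[i] <- nxt
      cur <- nxt
    }
    paste(BASES[res], collapse = "")
  })
}

#' Replicated control sets
#'
#' Draws `nSubsets` independent control sets by calling `sampler` with
#' distinct child seeds derived from one master seed, reproducing the
#' many-subset design used to measure control-sampling variability.
#'
#' @param sampler function of one argument (`seed`) returning one control
#'   set, e.g. a closure over [sampleGenomicFragments()].
#' @param nSubsets number of sets (>= 2).
#' @param seed master seed.
#' @return list of `nSubsets` control sets.
#' @export
controlReplicates <- function(sampler, nSubsets, seed) {
  stopifnot(nSubsets >= 2L)
  seeds <- .childSeeds(seed, nSubsets)
  lapply(seeds, sampler)
}
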