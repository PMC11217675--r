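#' Read a (soft-masked) FASTA file
#'
#' Reads FASTA into a [MaskedDNA-class] set with residue case preserved
#' verbatim, so lowercase soft-masking (UCSC-style repeat annotation)
#' survives the round trip. Both single-line and wrapped FASTA are
#' accepted. Characters outside `{A,C,G,T,N}` (any case) are rejected,
#' never coerced, so downstream counts are unambiguous.
#'
#' @param path FASTA file path.
#' @return [MaskedDNA-class] with one record per header, order preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTacgt"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  # keep only the first whitespace-delimited token of each header as the id
  names(set) <- sub("\\s.*$", "", names(set))
  MaskedDNA(set)
}

#' Write a MaskedDNA set to FASTA
#'
#' Residue case is written verbatim; lines are wrapped at 60 columns.
#' `readFasta(writeFasta(x))` is the identity on ids, residues and order.
#'
#' @param records [MaskedDNA-class] (or named character vector).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path) {
  if (is.character(records)) {
    records <- MaskedDNA(records)
  }
  stopifnot(methods::is(records, "MaskedDNA"))
  Biostrings::writeXStringSet(records, filepath = path, width = 60L)
  invisible(path)
}

#' Read BED intervals
#'
#' Reads BED3/BED4 into a `GRanges`. BED coordinates are 0-based
#' half-open; the returned `GRanges` follows the Bioconductor 1-based
#' closed convention (conversion handled by rtracklayer), so a BED line
#' `chr1 10 20` becomes `chr1:11-20`. Records with `start >= end` are
#' rejected.
#'
#' @param path BED file path.
#' @return `GRanges`, with BED name column (if present) in `mcols()$name`.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) {
    stop("BED file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) {
    stop("BED needs at least 3 tab-separated columns", call. = FALSE)
  }
  bad <- which(raw[[2]] >= raw[[3]])
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid BED interval on line %d: start (%s) >= end (%s)",
      bad[1], raw[bad[1], 2], raw[bad[1], 3]
    ), call. = FALSE)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED in ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  gr
}

#' Write GRanges intervals as BED
#'
#' Inverse of [readBed()]: 1-based closed `GRanges` are written as 0-based
#' half-open BED lines, names included when present.
#'
#' @param intervals `GRanges`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(intervals, path) {
  stopifnot(methods::is(intervals, "GRanges"))
  rtracklayer::export(intervals, path, format = "BED")
  invisible(path)
}

#' @describeIn maskedFraction fraction of soft-masked (lowercase) residues
#'   per record.
#' @export
setMethod("maskedFraction", "MaskedDNA", function(object) {
  seqs <- as.character(object)
  low <- vapply(
    seqs,
    function(s) sum(strsplit(s, "", fixed = TRUE)[[1]] %in% c("a", "c", "g", "t", "n")),
    integer(1)
  )
  stats::setNames(low / nchar(seqs), names(seqs))
})

setMethod("show", "MaskedDNA", function(object) {
  cat(sprintf(
    "MaskedDNA set of %d sequence(s), %d nt total, %.1f%% soft-masked\n",
    length(object), sum(Biostrings::width(object)),
    100 * sum(maskedFraction(object) * Biostrings::width(object)) /
      max(1L, sum(Biostrings::width(object)))
  ))
  if (length(object) > 0L) {
    methods::callNextMethod()
  }
})
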