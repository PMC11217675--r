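# Independent brute-force oracles. These deliberately avoid the package's
# integer-code engine: windows are extracted as strings and matched by
# regex / string equality.

oracleCountMotif <- function(seq, motif) {
  seq <- toupper(seq)
  w <- nchar(motif)
  n <- nchar(seq)
  if (n < w) {
    return(0L)
  }
  windows <- substring(seq, 1:(n - w + 1), w:n)
  rx <- paste0("^", gsub("n", "[ACGT]", motif), "$")
  sum(grepl(rx, windows, perl = TRUE))
}

oracleDinucleotides <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  win <- if (n >= 2) substring(seq, 1:(n - 1), 2:n) else character(0)
  win <- win[!grepl("N", win, fixed = TRUE)]
  bases <- c("A", "C", "G", "T")
  dinucs <- paste0(rep(bases, each = 4), bases)
  counts <- vapply(dinucs, function(d) sum(win == d), integer(1))
  counts
}

# valid (N-free) windows of width w, as strings
oracleWindows <- function(seq, w) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < w) {
    return(character(0))
  }
  win <- substring(seq, 1:(n - w + 1), w:n)
  win[!grepl("N", win, fixed = TRUE)]
}

# the shipped pattern lists, frozen independently of the package constants
ORACLE_F3_D1 <- c(
  "TA", "TA", "TA", "TA", "AC", "CC", "GC", "TC", "AA", "AT", "GC", "AG",
  "GG", "AG", "AC", "AT", "GC"
)
ORACLE_F3_D2 <- c(
  "GA", "GC", "GG", "GT", "TA", "TA", "TA", "TA", "GC", "GC", "TT", "AT",
  "AT", "GT", "CT", "CT", "TC"
)
ORACLE_F4 <- c("GGG", "CCC", "GAG", "CCT", "CCA", "CTC", "TGG", "AGG")
ORACLE_F5 <- c("TTA", "TAA", "ATT", "AAT")
ORACLE_F6 <- c(
  "AATT", "TACA", "TTAC", "GTAA", "TTAT", "ATAA", "AATG", "CATT", "ATTA",
  "TAAT", "TCAT", "ATGA", "TTAA", "TCAA", "TTGA", "CAAT", "ATTG"
)
ORACLE_F7 <- c(
  "ACnGC", "GCnGT", "ACnGT", "AAnAG", "CTnTT", "TGnCA", "CTnAT", "ATnAG",
  "CAnTA", "TAnTG", "TTnAT", "ATnAA", "TTnTC", "GAnAA", "TAnTA", "GTnAT",
  "ATnAC", "ATnAT"
)

oracleF3 <- function(seq) {
  m3 <- paste0(ORACLE_F3_D1, "n", ORACLE_F3_D2)
  m4 <- paste0(ORACLE_F3_D1, "nn", ORACLE_F3_D2)
  l3 <- sum(vapply(m3, oracleCountMotif, integer(1), seq = seq))
  l4 <- sum(vapply(m4, oracleCountMotif, integer(1), seq = seq))
  if (l3 == 0) NA_real_ else 100 * l4 / l3
}

oracleFeatures <- function(seq) {
  w2 <- oracleWindows(seq, 2)
  w3 <- oracleWindows(seq, 3)
  w4 <- oracleWindows(seq, 4)
  w5 <- oracleWindows(seq, 5)
  num <- sum(w2 %in% c("TG", "CA", "GT", "AC"))
  den <- sum(w2 %in% c("AG", "CT", "GA", "TC"))
  ch <- strsplit(toupper(seq), "")[[1]]
  ch <- ch[ch != "N"]
  c(
    F1 = 100 * sum(w2 == "GC") / length(w2),
    F2 = 100 * sum(w2 %in% c("CC", "GG")) / length(w2),
    F3 = oracleF3(seq),
    F4 = 100 * sum(w3 %in% ORACLE_F4) / length(w3),
    F5 = 100 * sum(w3 %in% ORACLE_F5) / length(w3),
    F6 = 100 * sum(w4 %in% ORACLE_F6) / length(w4),
    F7 = 100 * sum(vapply(ORACLE_F7, oracleCountMotif, integer(1), seq = seq)) / length(w5),
    F8 = if (den == 0) NA_real_ else num / den,
    F9 = 100 * sum(ch %in% c("G", "C")) / length(ch)
  )
}

# AUC as the normalized Mann-Whitney U statistic (rank formula)
oracleAuc <- function(scores, labels) {
  r <- rank(scores)
  pos <- labels == 1
  nP <- sum(pos)
  nN <- sum(!pos)
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

# stationary distribution of a transition matrix, by left eigenvector
oracleStationary <- function(tm) {
  e <- eigen(t(tm))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# uniform random sequence, optionally salted with N
randomSeq <- function(len, seed = NULL, nProb = 0) {
  draw <- function() {
    alph <- c("A", "C", "G", "T")
    ch <- sample(alph, len, replace = TRUE)
    if (nProb > 0) {
      ch[runif(len) < nProb] <- "N"
    }
    paste(ch, collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
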