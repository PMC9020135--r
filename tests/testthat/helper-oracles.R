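# Independent oracles used across test files. These deliberately avoid the
# package's internal code paths: digestion enumerates boundary pairs,
# ORF search enumerates stop-free substrings, and projection maps single
# bases through expanded coordinate vectors.

oracle_digest <- function(protein, mc, min_len, max_len, keil = TRUE) {
  ch <- strsplit(protein, "")[[1]]
  n <- length(ch)
  cuts <- integer(0)
  for (i in seq_len(n - 1)) {
    if (ch[i] %in% c("K", "R") && (!keil || ch[i + 1] != "P")) {
      cuts <- c(cuts, i)
    }
  }
  bounds <- c(0, cuts, n)
  peps <- character(0)
  for (a in seq_along(bounds)) {
    for (b in seq_along(bounds)) {
      if (b <= a) next
      internal <- sum(cuts > bounds[a] & cuts < bounds[b])
      len <- bounds[b] - bounds[a]
      if (internal <= mc && len >= min_len && len <= max_len) {
        peps <- c(peps, substr(protein, bounds[a] + 1, bounds[b]))
      }
    }
  }
  sort(unique(peps))
}

# frame translations via Biostrings (independent codon machinery)
oracle_six_frames <- function(seq) {
  dna <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(dna)
  one <- function(x, off) {
    n <- length(x) - off
    n <- n - n %% 3
    if (n <= 0) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, off + 1, off + n), if.fuzzy.codon = "X",
      no.init.codon = TRUE))
  }
  c(one(dna, 0), one(dna, 1), one(dna, 2), one(rc, 0), one(rc, 1), one(rc, 2))
}

# exhaustive stop-free substring search over all six frames; returns the
# winner under the frame-order-then-leftmost tie-break
oracle_longest_orf <- function(translations) {
  best <- NULL
  for (k in 1:6) {
    aa <- translations[[k]]
    L <- nchar(aa)
    if (L == 0) next
    ch <- strsplit(aa, "")[[1]]
    for (i in seq_len(L)) {
      if (ch[i] %in% c("*", "X")) next
      j <- i
      while (j < L && !(ch[j + 1] %in% c("*", "X"))) j <- j + 1
      len <- j - i + 1
      if (is.null(best) || len > best$len) {
        best <- list(len = len, frame_idx = k, aa_start = i - 1,
                     aa = substr(aa, i, j))
      }
    }
  }
  best
}

# genome positions (0-based, in transcript order) of every transcript base
oracle_tx_positions <- function(blocks, strand) {
  pos <- unlist(lapply(seq_len(nrow(blocks)), function(k)
    seq(blocks[k, 1], blocks[k, 2] - 1)))
  if (strand == "-") rev(pos) else pos
}

# random multi-block transcript alignment on a virtual genome
random_alignment <- function(n_nt) {
  n_blocks <- sample(1:4, 1)
  lens <- as.vector(stats::rmultinom(1, n_nt - n_blocks, rep(1, n_blocks))) + 1
  gaps <- sample(50:500, n_blocks)
  starts <- cumsum(gaps + c(0, lens[-n_blocks]))
  cbind(start = starts, end = starts + lens)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
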