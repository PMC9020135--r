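# Standard genetic code, indexed by codon string. Codons containing N (or any
# non-ACGT base) translate to 'X'.
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # order: TTT, CTT, ATT, GTT, TCT, ... (first base varies fastest)
  aa <- character(64)
  std <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  std[codons]
})

.complement_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a nucleotide sequence
#'
#' @param sequence A single nucleotide string over \code{A,C,G,T,N}.
#' @return The reverse complement as a single string.
#' @export
revcomp <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  paste(rev(unname(.complement_map[chars])), collapse = "")
}

.check_nt <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty nucleotide string", call. = FALSE)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  invisible(sequence)
}

.translate_frame <- function(sequence, offset) {
  n <- nchar(sequence) - offset
  n_codons <- n %/% 3L
  if (n_codons <= 0L) return("")
  starts <- offset + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(sequence, starts, starts + 2L)
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates a transcript in all three forward frames and all three frames of
#' its reverse complement using the standard genetic code. Stops are written as
#' \code{*}; codons containing \code{N} translate to \code{X}. Trailing bases
#' that do not complete a codon are dropped.
#'
#' @param sequence A single nucleotide string over \code{A,C,G,T,N}.
#' @return A character vector of 6 translations named
#'   \code{"+1","+2","+3","-1","-2","-3"}; reverse frames translate the
#'   reverse complement read 5' to 3'.
#' @examples
#' translate_six_frames("ATGAAATAG")
#' @export
translate_six_frames <- function(sequence) {
  .check_nt(sequence)
  rc <- revcomp(sequence)
  out <- c(
    .translate_frame(sequence, 0L), .translate_frame(sequence, 1L),
    .translate_frame(sequence, 2L),
    .translate_frame(rc, 0L), .translate_frame(rc, 1L),
    .translate_frame(rc, 2L)
  )
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

.frame_names <- c("+1", "+2", "+3", "-1", "-2", "-3")

# Maximal stop-free segments of one frame translation. 'X' (ambiguous codon)
# terminates a segment like a stop: no sequence is fabricated across an
# ambiguous base. Returns a data.frame of aa_start (0-based), aa_seq.
.orf_segments <- function(aa) {
  if (nchar(aa) == 0L) {
    return(data.frame(aa_start = integer(0), aa_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(aa, "[*X]")[[1]]
  if (length(parts) == 0L) parts <- ""
  # recover 0-based positions of each segment
  pos <- integer(length(parts))
  cum <- 0L
  for (i in seq_along(parts)) {
    pos[i] <- cum
    cum <- cum + nchar(parts[i]) + 1L  # +1 for the separator consumed
  }
  keep <- nchar(parts) > 0L
  data.frame(aa_start = pos[keep], aa_seq = parts[keep],
             stringsAsFactors = FALSE)
}

#' Extract the longest open reading frame across six frames
#'
#' The ORF is the longest stop-free (and \code{X}-free) segment over all six
#' frame translations of a transcript, stop-to-stop with no start-codon
#' requirement (six-frame search databases conventionally do not require an
#' initiator methionine). Ties are broken by frame order
#' \code{+1,+2,+3,-1,-2,-3}, then by leftmost position within the frame.
#'
#' @param translations The 6-frame translations from
#'   \code{\link{translate_six_frames}} (named \code{"+1"..."-3"}).
#' @param transcript_id Optional id recorded on the result.
#' @return An object of class \code{translated_orf}: a list with
#'   \code{transcript_id}, \code{frame} (integer in \code{+1..+3,-1..-3}),
#'   \code{aa_sequence}, and \code{tx_nt_start}/\code{tx_nt_end} — the 0-based
#'   half-open nucleotide span of the ORF in the coordinates of the frame's
#'   reading strand (reverse frames are addressed on the reverse complement).
#'   Returns \code{NULL} (with a warning) when every frame is empty or
#'   all-stop.
#' @export
extract_longest_orf <- function(translations, transcript_id = NA_character_) {
  stopifnot(length(translations) == 6L)
  best <- NULL
  for (k in seq_len(6L)) {
    segs <- .orf_segments(translations[[k]])
    if (nrow(segs) == 0L) next
    lens <- nchar(segs$aa_seq)
    i <- which.max(lens)  # leftmost among equals
    if (is.null(best) || lens[i] > nchar(best$aa_seq)) {
      offset <- if (k <= 3L) k - 1L else k - 4L
      best <- list(
        transcript_id = transcript_id,
        frame = if (k <= 3L) k else -(k - 3L),
        aa_sequence = segs$aa_seq[i],
        tx_nt_start = offset + 3L * segs$aa_start[i],
        tx_nt_end = offset + 3L * (segs$aa_start[i] + lens[i])
      )
    }
  }
  if (is.null(best)) {
    warning("no open reading frame found",
            if (!is.na(transcript_id)) paste0(" for transcript ", transcript_id),
            call. = FALSE)
    return(NULL)
  }
  structure(best, class = "translated_orf")
}

#' @export
print.translated_orf <- function(x, ...) {
  cat(sprintf("<translated_orf> %s frame %+d, %d aa, nt [%d,%d)\n",
              x$transcript_id, x$frame, nchar(x$aa_sequence),
              x$tx_nt_start, x$tx_nt_end))
  invisible(x)
}

#' Extract all open reading frames above a length threshold
#'
#' Variant of \code{\link{extract_longest_orf}} returning every stop-free
#' segment of length at least \code{min_aa} in all six frames, for users who
#' want a denser (PGA-like) database than the single-longest-ORF default.
#'
#' @inheritParams extract_longest_orf
#' @param min_aa Minimum ORF length in amino acids.
#' @return A list of \code{translated_orf} objects (possibly empty), ordered
#'   by frame then position.
#' @export
extract_all_orfs <- function(translations, transcript_id = NA_character_,
                             min_aa = 1L) {
  stopifnot(length(translations) == 6L)
  out <- list()
  for (k in seq_len(6L)) {
    segs <- .orf_segments(translations[[k]])
    segs <- segs[nchar(segs$aa_seq) >= min_aa, , drop = FALSE]
    if (nrow(segs) == 0L) next
    offset <- if (k <= 3L) k - 1L else k - 4L
    for (i in seq_len(nrow(segs))) {
      out[[length(out) + 1L]] <- structure(list(
        transcript_id = transcript_id,
        frame = if (k <= 3L) k else -(k - 3L),
        aa_sequence = segs$aa_seq[i],
        tx_nt_start = offset + 3L * segs$aa_start[i],
        tx_nt_end = offset + 3L * (segs$aa_start[i] + nchar(segs$aa_seq[i]))
      ), class = "translated_orf")
    }
  }
  out
}
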