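# Merge bookended blocks (end of one == start of next) in a sorted matrix.
.merge_adjacent <- function(blocks) {
  if (nrow(blocks) <= 1L) return(blocks)
  out <- blocks[1L, , drop = FALSE]
  for (i in 2L:nrow(blocks)) {
    if (blocks[i, 1L] == out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- blocks[i, 2L]
    } else {
      out <- rbind(out, blocks[i, , drop = FALSE])
    }
  }
  out
}

# Map a transcript-forward coordinate span [s, e) through alignment blocks
# (genome-forward sorted, 0-based half-open) to genomic blocks. For a minus
# alignment, transcript base 0 is the last genomic base of the last block.
.tx_span_to_genome <- function(blocks, strand, s, e) {
  lens <- blocks[, 2L] - blocks[, 1L]
  total <- sum(lens)
  if (s < 0L || e > total || s >= e) {
    stop("transcript span exceeds the alignment", call. = FALSE)
  }
  pieces <- list()
  if (strand == "+") {
    cum <- 0L
    for (i in seq_len(nrow(blocks))) {
      lo <- max(s, cum); hi <- min(e, cum + lens[i])
      if (lo < hi) {
        pieces[[length(pieces) + 1L]] <-
          c(blocks[i, 1L] + (lo - cum), blocks[i, 1L] + (hi - cum))
      }
      cum <- cum + lens[i]
    }
  } else {
    cum <- 0L
    for (i in rev(seq_len(nrow(blocks)))) {
      lo <- max(s, cum); hi <- min(e, cum + lens[i])
      if (lo < hi) {
        pieces[[length(pieces) + 1L]] <-
          c(blocks[i, 2L] - (hi - cum), blocks[i, 2L] - (lo - cum))
      }
      cum <- cum + lens[i]
    }
  }
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1L]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  .merge_adjacent(m)
}

#' Project a peptide to genomic coordinates
#'
#' Maps a peptide occurring at a known offset within a transcript's ORF to
#' genome-forward blocks through the transcript's alignment. The peptide's
#' nucleotide span on the ORF's reading strand is
#' \code{tx_nt_start + 3*peptide_start_aa} for \code{3*nchar(peptide)}
#' bases; minus-frame ORFs are mirrored into transcript-forward coordinates
#' before mapping, and minus-strand alignments mirror again into
#' genome-forward blocks.
#'
#' @param peptide_start_aa 0-based amino-acid offset of the peptide within
#'   \code{orf$aa_sequence}.
#' @param peptide Peptide sequence; must match the ORF at the stated offset.
#' @param orf A \code{translated_orf} from \code{\link{extract_longest_orf}}.
#' @param transcript The source \code{\link{assembled_transcript}}; must
#'   carry an alignment.
#' @return An object of class \code{peptide_alignment}: list with
#'   \code{peptide}, \code{chrom}, \code{strand} (the coding strand of the
#'   peptide on the genome), \code{blocks} (genome-forward sorted matrix),
#'   \code{source_transcript_id}, \code{orf_frame}.
#' @export
project_peptide <- function(peptide_start_aa, peptide, orf, transcript) {
  if (is.null(transcript$alignment)) {
    stop("transcript ", transcript$id, " has no genome alignment",
         call. = FALSE)
  }
  len <- nchar(peptide)
  found <- substr(orf$aa_sequence, peptide_start_aa + 1L,
                  peptide_start_aa + len)
  if (!identical(found, peptide)) {
    stop("peptide does not occur at the stated ORF offset (found '",
         found, "')", call. = FALSE)
  }
  rs <- orf$tx_nt_start + 3L * peptide_start_aa
  re <- rs + 3L * len
  L <- nchar(transcript$sequence)
  if (orf$frame > 0L) {
    tx_s <- rs; tx_e <- re
  } else {
    tx_s <- L - re; tx_e <- L - rs
  }
  aln <- transcript$alignment
  blocks <- .tx_span_to_genome(aln$blocks, aln$strand, tx_s, tx_e)
  stopifnot(sum(blocks[, 2L] - blocks[, 1L]) == 3L * len)
  pep_strand <- if ((aln$strand == "+") == (orf$frame > 0L)) "+" else "-"
  structure(list(peptide = peptide, chrom = aln$chrom, strand = pep_strand,
                 blocks = blocks, source_transcript_id = transcript$id,
                 orf_frame = orf$frame),
            class = "peptide_alignment")
}

#' @export
print.peptide_alignment <- function(x, ...) {
  cat(sprintf("<peptide_alignment> %s %s:%s %s\n", x$peptide, x$chrom,
              x$strand,
              paste(sprintf("[%d,%d)", x$blocks[, 1L], x$blocks[, 2L]),
                    collapse = ",")))
  invisible(x)
}

.locus_key <- function(a) {
  paste(a$chrom, a$strand,
        paste(a$blocks[, 1L], a$blocks[, 2L], sep = "-", collapse = ","),
        sep = "|")
}

#' Remove peptides mapping to multiple genomic loci
#'
#' Alignments of the same peptide that collapse to one locus (identical
#' chromosome, strand and merged block structure — e.g. via two isoforms of
#' one gene) count once; a peptide with more than one distinct locus is
#' removed entirely.
#'
#' @param alignments List of \code{peptide_alignment} objects (all alignments
#'   of all peptides).
#' @return A list with \code{kept} (one representative alignment per
#'   single-locus peptide, in first-seen order) and \code{removed} (character
#'   vector of multi-locus peptide sequences).
#' @export
remove_multimapped <- function(alignments) {
  peps <- vapply(alignments, `[[`, character(1), "peptide")
  keys <- vapply(alignments, .locus_key, character(1))
  kept <- list()
  removed <- character(0)
  for (p in unique(peps)) {
    idx <- which(peps == p)
    if (length(unique(keys[idx])) > 1L) {
      removed <- c(removed, p)
    } else {
      kept[[length(kept) + 1L]] <- alignments[[idx[1L]]]
    }
  }
  list(kept = kept, removed = removed)
}
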