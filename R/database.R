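#' Assembled transcript with optional genome alignment
#'
#' @param id Transcript identifier (unique within a run).
#' @param sequence Nucleotide string over \code{A,C,G,T,N}.
#' @param chrom,strand,blocks Optional genome alignment: chromosome name,
#'   strand (\code{"+"} or \code{"-"}), and a two-column integer matrix of
#'   0-based half-open genomic blocks sorted genome-forward and
#'   non-overlapping. Block lengths must sum to the sequence length.
#' @return An object of class \code{assembled_transcript}.
#' @export
assembled_transcript <- function(id, sequence, chrom = NULL, strand = NULL,
                                 blocks = NULL) {
  .check_nt(sequence)
  alignment <- NULL
  if (!is.null(blocks)) {
    blocks <- matrix(as.integer(blocks), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
    if (any(blocks[, 2L] <= blocks[, 1L])) {
      stop("alignment blocks must have end > start", call. = FALSE)
    }
    if (is.unsorted(blocks[, 1L], strictly = TRUE) ||
        any(blocks[-1L, 1L] < blocks[-nrow(blocks), 2L])) {
      stop("alignment blocks must be sorted and non-overlapping",
           call. = FALSE)
    }
    if (sum(blocks[, 2L] - blocks[, 1L]) != nchar(sequence)) {
      stop("alignment block lengths must sum to the sequence length",
           call. = FALSE)
    }
    if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'",
                                       call. = FALSE)
    alignment <- list(chrom = chrom, strand = strand, blocks = blocks)
  }
  structure(list(id = id, sequence = sequence, alignment = alignment),
            class = "assembled_transcript")
}

#' Labelled protein database entry
#'
#' @param id Entry identifier.
#' @param source One of \code{"REFERENCE"}, \code{"NOVEL_ORF"},
#'   \code{"DECOY"}.
#' @param aa_sequence Amino-acid sequence (no stop symbols).
#' @param origin Optional \code{translated_orf} recording the six-frame
#'   provenance of a NOVEL_ORF entry.
#' @return An object of class \code{protein_entry}.
#' @export
protein_entry <- function(id, source, aa_sequence, origin = NULL) {
  source <- match.arg(source, c("REFERENCE", "NOVEL_ORF", "DECOY"))
  stopifnot(is.character(aa_sequence), length(aa_sequence) == 1L,
            nchar(aa_sequence) > 0L)
  structure(list(id = id, source = source, aa_sequence = aa_sequence,
                 origin = origin),
            class = "protein_entry")
}

.reverse_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Build the custom search database
#'
#' Merges the reference proteome with one novel-ORF entry per assembled
#' transcript (the longest stop-free segment across its six frame
#' translations) and appends one reversed decoy per target, mirroring how
#' search tools generate decoys by reversing targets. Transcripts with no
#' open reading frame are skipped with a warning.
#'
#' @param transcripts List of \code{\link{assembled_transcript}} objects with
#'   unique ids.
#' @param reference List of \code{\link{protein_entry}} objects with source
#'   \code{REFERENCE}.
#' @param all_orfs If \code{TRUE}, keep every ORF of length at least
#'   \code{min_orf_aa} per transcript instead of only the longest.
#' @param min_orf_aa Minimum ORF length (amino acids) when
#'   \code{all_orfs = TRUE}.
#' @param decoy_prefix Prefix for decoy entry ids.
#' @return A list of \code{protein_entry}: reference targets, then novel-ORF
#'   targets in input transcript order, then decoys in the same target order.
#' @export
build_custom_database <- function(transcripts, reference,
                                  all_orfs = FALSE, min_orf_aa = 1L,
                                  decoy_prefix = "DECOY_") {
  ids <- vapply(transcripts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (e in reference) {
    if (!inherits(e, "protein_entry") || e$source != "REFERENCE") {
      stop("reference entries must be protein_entry with source REFERENCE",
           call. = FALSE)
    }
  }
  if (length(transcripts) == 0L) {
    warning("no transcripts supplied; database holds reference + decoys only",
            call. = FALSE)
  }
  novel <- list()
  for (tx in transcripts) {
    tr <- translate_six_frames(tx$sequence)
    if (all_orfs) {
      orfs <- extract_all_orfs(tr, tx$id, min_aa = min_orf_aa)
      for (i in seq_along(orfs)) {
        o <- orfs[[i]]
        novel[[length(novel) + 1L]] <- protein_entry(
          sprintf("%s.orf%d", tx$id, i), "NOVEL_ORF", o$aa_sequence, o)
      }
    } else {
      o <- suppressWarnings(extract_longest_orf(tr, tx$id))
      if (is.null(o)) {
        warning("transcript ", tx$id, " has no ORF; skipped", call. = FALSE)
        next
      }
      novel[[length(novel) + 1L]] <- protein_entry(
        tx$id, "NOVEL_ORF", o$aa_sequence, o)
    }
  }
  targets <- c(reference, novel)
  target_ids <- vapply(targets, `[[`, character(1), "id")
  if (anyDuplicated(target_ids)) {
    stop("duplicate database entry ids after merging", call. = FALSE)
  }
  target_seqs <- vapply(targets, `[[`, character(1), "aa_sequence")
  decoys <- mapply(function(id, seq) {
    protein_entry(paste0(decoy_prefix, id), "DECOY", .reverse_string(seq))
  }, target_ids, target_seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  pal <- target_seqs == vapply(decoys, `[[`, character(1), "aa_sequence")
  if (any(pal)) {
    message(sum(pal), " palindromic target sequence(s): decoy equals target")
  }
  c(targets, decoys)
}

#' Write a protein database to FASTA
#'
#' Headers follow the convention
#' \code{>id src=REFERENCE|NOVEL_ORF|DECOY [tx=... frame=...]}.
#'
#' @param entries List of \code{protein_entry}.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_database_fasta <- function(entries, path) {
  seqs <- vapply(entries, `[[`, character(1), "aa_sequence")
  hdr <- vapply(entries, function(e) {
    h <- sprintf("%s src=%s", e$id, e$source)
    if (!is.null(e$origin)) {
      h <- sprintf("%s tx=%s frame=%+d", h, e$origin$transcript_id,
                   e$origin$frame)
    }
    h
  }, character(1))
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a protein FASTA as labelled database entries
#'
#' Headers without a \code{src=} tag are labelled \code{REFERENCE}; the id is
#' the first whitespace-delimited token.
#'
#' @param path FASTA path.
#' @param source Default source label for untagged entries.
#' @return A list of \code{protein_entry}.
#' @export
read_protein_fasta <- function(path, source = "REFERENCE") {
  x <- Biostrings::readAAStringSet(path)
  hdr <- names(x)
  ids <- sub("\\s.*$", "", hdr)
  src <- rep(source, length(x))
  has_tag <- grepl("src=", hdr)
  src[has_tag] <- sub("^src=", "", regmatches(hdr, regexpr("src=[A-Z_]+", hdr)))
  mapply(function(id, s, seq) protein_entry(id, s, seq),
         ids, src, as.character(x), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Read transcript FASTA, optionally with BED12 alignments
#'
#' @param fasta Transcript FASTA path.
#' @param bed12 Optional BED12 path giving each transcript's genomic blocks
#'   (name column matching the FASTA ids).
#' @return A list of \code{\link{assembled_transcript}}.
#' @export
read_transcripts <- function(fasta, bed12 = NULL) {
  x <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(x))
  aln <- if (!is.null(bed12)) read_bed12(bed12) else NULL
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    a <- if (!is.null(aln)) aln[[ids[i]]] else NULL
    out[[i]] <- if (is.null(a)) {
      assembled_transcript(ids[i], as.character(x[[i]]))
    } else {
      assembled_transcript(ids[i], as.character(x[[i]]),
                           chrom = a$chrom, strand = a$strand,
                           blocks = a$blocks)
    }
  }
  out
}
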