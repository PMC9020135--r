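# Union of [start,end) intervals in a data.frame -> matrix
.interval_union <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  d <- df[order(df$start, df$end), , drop = FALSE]
  out <- matrix(c(d$start[1L], d$end[1L]), ncol = 2L)
  for (i in seq_len(nrow(d))[-1L]) {
    if (d$start[i] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], d$end[i])
    } else {
      out <- rbind(out, c(d$start[i], d$end[i]))
    }
  }
  colnames(out) <- c("start", "end")
  out
}

.union_overlap_len <- function(un, s, e) {
  if (nrow(un) == 0L) return(0L)
  sum(.ov_len(un[, 1L], un[, 2L], s, e))
}

# Codon offset (0,1,2 along the translation direction) of the annotated CDS
# of transcript `tid` at genomic position p, or NA when p is outside the CDS.
.cds_frame_at <- function(annotation, tid, p) {
  cc <- annotation$cds[annotation$cds$tx_id == tid, , drop = FALSE]
  if (nrow(cc) == 0L) return(NA_integer_)
  strand <- annotation$transcripts$strand[
    match(tid, annotation$transcripts$tx_id)]
  k <- which(cc$start <= p & p < cc$end)
  if (length(k) == 0L) return(NA_integer_)
  k <- k[1L]
  lens <- cc$end - cc$start
  if (strand == "+") {
    cum <- if (k > 1L) sum(lens[seq_len(k - 1L)]) else 0L
    cum <- cum + (p - cc$start[k])
    ph <- cc$phase[1L]
  } else {
    cum <- if (k < nrow(cc)) sum(lens[(k + 1L):nrow(cc)]) else 0L
    cum <- cum + (cc$end[k] - 1L - p)
    ph <- cc$phase[nrow(cc)]
  }
  if (is.na(ph)) ph <- 0L
  ((cum - ph) %% 3L)
}

# Transcript-forward coordinate of genomic position p through an alignment,
# or NA when p is not covered.
.genome_to_tx <- function(blocks, strand, p) {
  lens <- blocks[, 2L] - blocks[, 1L]
  k <- which(blocks[, 1L] <= p & p < blocks[, 2L])
  if (length(k) == 0L) return(NA_integer_)
  k <- k[1L]
  if (strand == "+") {
    (if (k > 1L) sum(lens[seq_len(k - 1L)]) else 0L) + (p - blocks[k, 1L])
  } else {
    (if (k < nrow(blocks)) sum(lens[(k + 1L):nrow(blocks)]) else 0L) +
      (blocks[k, 2L] - 1L - p)
  }
}

# Codon offset of an ORF at genomic position p through its source transcript,
# plus the genomic coding direction of the ORF; NA when p not covered.
.orf_frame_at <- function(transcript, orf, p) {
  aln <- transcript$alignment
  t_fwd <- .genome_to_tx(aln$blocks, aln$strand, p)
  if (is.na(t_fwd)) return(list(offset = NA_integer_, strand = NA_character_))
  L <- nchar(transcript$sequence)
  r <- if (orf$frame > 0L) t_fwd else L - 1L - t_fwd
  strand <- if ((aln$strand == "+") == (orf$frame > 0L)) "+" else "-"
  list(offset = ((r - orf$tx_nt_start) %% 3L), strand = strand)
}

# Does the source transcript alignment overlap >=1 annotated exon of gene?
.source_linked <- function(transcript, annotation, gene) {
  if (is.null(transcript) || is.null(transcript$alignment)) return(FALSE)
  aln <- transcript$alignment
  if (aln$chrom != gene$chrom) return(FALSE)
  ex <- .gene_exons(annotation, gene$gene_id)
  any(vapply(seq_len(nrow(aln$blocks)), function(i) {
    .df_overlap_len(ex, aln$blocks[i, 1L], aln$blocks[i, 2L]) > 0L
  }, logical(1)))
}

# Is the source ORF in frame (same direction, same codon offset) with the
# annotated CDS of any transcript of `gene` at some genomic position shared
# by the source alignment and the annotated CDS?
.orf_in_frame_with_cds <- function(transcript, orf, annotation, gene) {
  if (is.null(transcript) || is.null(transcript$alignment) || is.null(orf)) {
    return(FALSE)
  }
  aln <- transcript$alignment
  if (aln$chrom != gene$chrom) return(FALSE)
  cds <- .gene_region(annotation, gene$gene_id, "cds")
  if (nrow(cds) == 0L) return(FALSE)
  for (tid in unique(cds$tx_id)) {
    cc <- cds[cds$tx_id == tid, , drop = FALSE]
    tstrand <- annotation$transcripts$strand[
      match(tid, annotation$transcripts$tx_id)]
    for (i in seq_len(nrow(aln$blocks))) {
      for (j in seq_len(nrow(cc))) {
        lo <- max(aln$blocks[i, 1L], cc$start[j])
        hi <- min(aln$blocks[i, 2L], cc$end[j])
        if (lo >= hi) next
        of <- .orf_frame_at(transcript, orf, lo)
        cf <- .cds_frame_at(annotation, tid, lo)
        if (!is.na(of$offset) && !is.na(cf) &&
            identical(of$strand, tstrand) && of$offset == cf) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

.category_top_level <- c(
  UTR5 = "PROTEIN_CODING_GENE", UTR3 = "PROTEIN_CODING_GENE",
  EXON_SKIPPING = "PROTEIN_CODING_GENE",
  EXON_EXTENSION_OVERLAP = "PROTEIN_CODING_GENE",
  EXON_EXTENSION_INTRONIC = "PROTEIN_CODING_GENE",
  JUNCTIONAL_VARIATION = "PROTEIN_CODING_GENE",
  FRAMESHIFT_NOVEL_FRAME = "PROTEIN_CODING_GENE",
  PSEUDOGENE = "NONCODING_GENE", LNCRNA = "NONCODING_GENE",
  TEC_OTHER = "NONCODING_GENE",
  NORF_INTRONIC = "NORF", NORF_UTR_REGION = "NORF",
  NORF_ALTFRAME = "NORF", NORF_INTERGENIC = "NORF"
)

#' Peptide event categories
#'
#' @return Character vector of all category labels assigned by
#'   \code{\link{classify_peptide}}.
#' @export
peptide_categories <- function() names(.category_top_level)

# gap matches a skipped exon of some transcript: boundaries coincide with the
# end/start of non-consecutive exons.
.gap_is_skip <- function(annotation, gene, gs, ge) {
  txs <- annotation$transcripts$tx_id[
    annotation$transcripts$gene_id == gene$gene_id]
  for (tid in txs) {
    e <- annotation$exons[annotation$exons$tx_id == tid, , drop = FALSE]
    if (nrow(e) < 3L) next
    i <- match(gs, e$end)
    j <- match(ge, e$start)
    if (!is.na(i) && !is.na(j) && j >= i + 2L) return(TRUE)
  }
  FALSE
}

# gap is an annotated intron (between consecutive exons) of some transcript.
.gap_is_annotated_intron <- function(annotation, gene, gs, ge) {
  txs <- annotation$transcripts$tx_id[
    annotation$transcripts$gene_id == gene$gene_id]
  intr <- annotation$introns[annotation$introns$tx_id %in% txs, , drop = FALSE]
  any(intr$start == gs & intr$end == ge)
}

#' Classify a peptide alignment into an event category
#'
#' Assigns exactly one category by a fixed precedence ladder. Top-level
#' partition first: overlap with any protein-coding gene beats overlap with a
#' noncoding gene, which beats intergenic. Within a protein-coding gene:
#' exon skipping (a peptide junction whose implied intron joins
#' non-consecutive annotated exons) beats junctional variation (junction
#' within the gene matching no annotated intron, both sides exonic) beats
#' exon-extension overlap (a block crossing an exon boundary into the intron)
#' beats 5'/3' UTR placement beats in-frame intronic extension beats
#' out-of-frame CDS overlap. Coding-gene peptides with no frame or
#' source-transcript link to the annotation demote to the corresponding
#' novel-ORF (\code{NORF_*}) category.
#'
#' @param alignment A \code{peptide_alignment} (one locus; run
#'   \code{\link{remove_multimapped}} first).
#' @param annotation A \code{\link{load_annotation}} result.
#' @param transcript The source \code{assembled_transcript} (for
#'   linkage/frame checks); may be \code{NULL}.
#' @param orf The source \code{translated_orf}; may be \code{NULL}.
#' @return A one-row data.frame: \code{peptide}, \code{chrom},
#'   \code{strand}, \code{blocks} (\code{start-end} comma-joined),
#'   \code{top_level}, \code{category}, \code{gene_id} (NA when intergenic),
#'   \code{source_transcript_id}.
#' @export
classify_peptide <- function(alignment, annotation, transcript = NULL,
                             orf = NULL) {
  b <- alignment$blocks
  g <- annotation$genes
  same_chrom <- g$chrom == alignment$chrom
  ov <- integer(nrow(g))
  for (i in which(same_chrom)) {
    ov[i] <- sum(vapply(seq_len(nrow(b)), function(k)
      .ov_len(g$start[i], g$end[i], b[k, 1L], b[k, 2L]), integer(1)))
  }
  cand <- which(ov > 0L)
  # prefer genes on the peptide's coding strand when both strands overlap
  if (length(cand) > 1L && any(g$strand[cand] == alignment$strand)) {
    cand <- cand[g$strand[cand] == alignment$strand]
  }
  category <- NULL
  gene_id <- NA_character_
  if (length(cand) == 0L) {
    category <- "NORF_INTERGENIC"
  } else {
    coding <- cand[g$biotype[cand] == "protein_coding"]
    if (length(coding) > 0L) {
      pick <- coding[order(-ov[coding], g$gene_id[coding])][1L]
      gene <- g[pick, , drop = FALSE]
      gene_id <- gene$gene_id
      category <- .classify_in_coding_gene(alignment, annotation, gene,
                                           transcript, orf)
    } else {
      pick <- cand[order(-ov[cand], g$gene_id[cand])][1L]
      gene_id <- g$gene_id[pick]
      category <- switch(g$biotype[pick],
                         pseudogene = "PSEUDOGENE",
                         lncRNA = "LNCRNA",
                         "TEC_OTHER")
    }
  }
  data.frame(
    peptide = alignment$peptide, chrom = alignment$chrom,
    strand = alignment$strand,
    blocks = paste(b[, 1L], b[, 2L], sep = "-", collapse = ","),
    top_level = unname(.category_top_level[category]), category = category,
    gene_id = gene_id,
    source_transcript_id = alignment$source_transcript_id,
    stringsAsFactors = FALSE
  )
}

.classify_in_coding_gene <- function(alignment, annotation, gene, transcript,
                                     orf) {
  b <- alignment$blocks
  ex <- .gene_exons(annotation, gene$gene_id)
  exu <- .interval_union(ex)
  nb <- nrow(b)

  if (nb >= 2L) {
    gaps <- cbind(b[-nb, 2L], b[-1L, 1L])
    skip <- vapply(seq_len(nrow(gaps)), function(i)
      .gap_is_skip(annotation, gene, gaps[i, 1L], gaps[i, 2L]), logical(1))
    if (any(skip)) return("EXON_SKIPPING")
    annotated <- vapply(seq_len(nrow(gaps)), function(i)
      .gap_is_annotated_intron(annotation, gene, gaps[i, 1L], gaps[i, 2L]),
      logical(1))
    block_ex <- vapply(seq_len(nb), function(k)
      .union_overlap_len(exu, b[k, 1L], b[k, 2L]), integer(1))
    if (!all(annotated) && all(block_ex > 0L)) return("JUNCTIONAL_VARIATION")
  }

  lens <- b[, 2L] - b[, 1L]
  exov <- vapply(seq_len(nb), function(k)
    .union_overlap_len(exu, b[k, 1L], b[k, 2L]), integer(1))
  if (any(exov > 0L & exov < lens)) return("EXON_EXTENSION_OVERLAP")
  if (any(exov == lens) && any(exov == 0L)) return("EXON_EXTENSION_OVERLAP")

  linked <- .source_linked(transcript, annotation, gene)
  if (all(exov == lens)) {
    u5 <- .gene_region(annotation, gene$gene_id, "utr5")
    u3 <- .gene_region(annotation, gene$gene_id, "utr3")
    in5 <- any(vapply(seq_len(nb), function(k)
      .df_overlap_len(u5, b[k, 1L], b[k, 2L]) > 0L, logical(1)))
    in3 <- any(vapply(seq_len(nb), function(k)
      .df_overlap_len(u3, b[k, 1L], b[k, 2L]) > 0L, logical(1)))
    if (in5) return(if (linked) "UTR5" else "NORF_UTR_REGION")
    if (in3) return(if (linked) "UTR3" else "NORF_UTR_REGION")
    # fully inside annotated CDS exons: compare reading frames
    in_frame <- .orf_in_frame_with_cds(transcript, orf, annotation, gene)
    if (!in_frame && linked) return("FRAMESHIFT_NOVEL_FRAME")
    return("NORF_ALTFRAME")
  }
  # all blocks without exon overlap: intronic within the gene
  in_frame <- .orf_in_frame_with_cds(transcript, orf, annotation, gene)
  if (linked && in_frame) return("EXON_EXTENSION_INTRONIC")
  "NORF_INTRONIC"
}

#' Classify many peptide alignments
#'
#' @param alignments List of \code{peptide_alignment} objects.
#' @param annotation A \code{\link{load_annotation}} result.
#' @param transcripts Optional named list of source
#'   \code{assembled_transcript} objects (names = transcript ids).
#' @param orfs Optional named list of \code{translated_orf} objects (names =
#'   transcript ids).
#' @return A data.frame with one row per alignment (see
#'   \code{\link{classify_peptide}}).
#' @export
classify_peptides <- function(alignments, annotation, transcripts = NULL,
                              orfs = NULL) {
  rows <- lapply(alignments, function(a) {
    tid <- a$source_transcript_id
    classify_peptide(a, annotation,
                     transcript = transcripts[[tid]],
                     orf = orfs[[tid]])
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Chromosome-by-category peptide counts
#'
#' @param classified Data.frame from \code{\link{classify_peptides}}.
#' @return A contingency \code{table} (chromosome rows, category columns)
#'   whose cells partition the classified peptides.
#' @export
summarize_by_chromosome <- function(classified) {
  if (nrow(classified) == 0L) {
    return(table(chrom = character(0), category = character(0)))
  }
  table(chrom = classified$chrom, category = classified$category)
}
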