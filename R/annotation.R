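# Interval helpers on 0-based half-open [start, end) blocks.
.ov_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

.blocks_overlap <- function(blocks, s, e) {
  any(.ov_len(blocks[, 1L], blocks[, 2L], s, e) > 0L)
}

# region table (start,end df) overlap with a block
.df_overlap_len <- function(df, s, e) {
  if (is.null(df) || nrow(df) == 0L) return(0L)
  sum(.ov_len(df$start, df$end, s, e))
}

#' Load a genome annotation from GTF/GFF3
#'
#' Parses gene, transcript/mRNA, exon and CDS features, converts the file's
#' 1-based inclusive coordinates to 0-based half-open, derives introns as
#' gaps between consecutive exons and 5'/3' UTRs as the exonic sequence
#' upstream/downstream of the CDS (strand-aware). Genes without a recognised
#' biotype attribute (\code{gene_biotype} or \code{biotype}) are assigned
#' \code{"other"} with a warning.
#'
#' @param path GTF or GFF3 path.
#' @return An object of class \code{genome_annotation}: a list of data.frames
#'   \code{genes} (gene_id, chrom, start, end, strand, biotype),
#'   \code{transcripts} (tx_id, gene_id), \code{exons}, \code{cds},
#'   \code{introns}, \code{utr5}, \code{utr3} (each tx_id, start, end, all
#'   0-based half-open, sorted genome-forward).
#' @export
load_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    stringsAsFactors = FALSE
  )
  md <- S4Vectors::mcols(gr)
  get_attr <- function(name) {
    if (name %in% names(md)) as.character(md[[name]]) else
      rep(NA_character_, nrow(df))
  }
  id <- get_attr("ID")
  parent <- md$Parent
  parent <- if (is.null(parent)) rep(NA_character_, nrow(df)) else
    vapply(as.list(parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
  biotype <- get_attr("gene_biotype")
  alt <- get_attr("biotype")
  biotype[is.na(biotype)] <- alt[is.na(biotype)]

  is_gene <- type == "gene"
  genes <- data.frame(
    gene_id = id[is_gene], chrom = df$chrom[is_gene],
    start = df$start[is_gene], end = df$end[is_gene],
    strand = df$strand[is_gene], biotype = biotype[is_gene],
    stringsAsFactors = FALSE
  )
  if (anyNA(genes$biotype)) {
    warning(sum(is.na(genes$biotype)),
            " gene(s) without a biotype attribute; assigned 'other'",
            call. = FALSE)
    genes$biotype[is.na(genes$biotype)] <- "other"
  }
  is_tx <- type %in% c("transcript", "mRNA")
  transcripts <- data.frame(
    tx_id = id[is_tx], gene_id = parent[is_tx],
    chrom = df$chrom[is_tx], strand = df$strand[is_tx],
    stringsAsFactors = FALSE
  )
  take <- function(sel, with_phase = FALSE) {
    out <- data.frame(tx_id = parent[sel], start = df$start[sel],
                      end = df$end[sel], stringsAsFactors = FALSE)
    if (with_phase) {
      ph <- if ("phase" %in% names(md)) as.integer(md$phase[sel]) else
        rep(NA_integer_, sum(sel))
      out$phase <- ph
    }
    bad <- is.na(out$tx_id) | !(out$tx_id %in% transcripts$tx_id)
    if (any(bad)) {
      warning("dropping ", sum(bad), " feature row(s) with no parent ",
              "transcript", call. = FALSE)
      out <- out[!bad, , drop = FALSE]
    }
    out[order(out$tx_id, out$start), , drop = FALSE]
  }
  exons <- take(type == "exon")
  cds <- take(type == "CDS", with_phase = TRUE)

  introns <- do.call(rbind, lapply(split(exons, exons$tx_id), function(e) {
    if (nrow(e) < 2L) return(NULL)
    data.frame(tx_id = e$tx_id[1], start = e$end[-nrow(e)],
               end = e$start[-1L], stringsAsFactors = FALSE)
  }))
  if (is.null(introns)) {
    introns <- data.frame(tx_id = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE)
  }
  row.names(introns) <- NULL

  # UTRs: exonic minus CDS, split by side of the CDS span, 5' vs 3' by strand
  utr5 <- list(); utr3 <- list()
  for (tid in unique(cds$tx_id)) {
    e <- exons[exons$tx_id == tid, , drop = FALSE]
    cc <- cds[cds$tx_id == tid, , drop = FALSE]
    if (nrow(e) == 0L || nrow(cc) == 0L) next
    strand <- transcripts$strand[match(tid, transcripts$tx_id)]
    cds_lo <- min(cc$start); cds_hi <- max(cc$end)
    up <- data.frame(tx_id = tid,
                     start = pmin(e$start, cds_lo),
                     end = pmin(e$end, cds_lo), stringsAsFactors = FALSE)
    up <- up[up$end > up$start, , drop = FALSE]
    dn <- data.frame(tx_id = tid,
                     start = pmax(e$start, cds_hi),
                     end = pmax(e$end, cds_hi), stringsAsFactors = FALSE)
    dn <- dn[dn$end > dn$start, , drop = FALSE]
    if (strand == "+") {
      utr5[[tid]] <- up; utr3[[tid]] <- dn
    } else {
      utr5[[tid]] <- dn; utr3[[tid]] <- up
    }
  }
  bindr <- function(l) {
    d <- do.call(rbind, l)
    if (is.null(d)) d <- data.frame(tx_id = character(0), start = integer(0),
                                    end = integer(0), stringsAsFactors = FALSE)
    row.names(d) <- NULL
    d
  }
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds, introns = introns,
                 utr5 = bindr(utr5), utr3 = bindr(utr3)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d genes (%s), %d transcripts, %d exons\n",
              nrow(x$genes),
              paste(sprintf("%s:%d", names(table(x$genes$biotype)),
                            as.integer(table(x$genes$biotype))),
                    collapse = ", "),
              nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

# exons of all transcripts of a gene, as a start/end data.frame
.gene_exons <- function(annotation, gene_id) {
  txs <- annotation$transcripts$tx_id[annotation$transcripts$gene_id == gene_id]
  annotation$exons[annotation$exons$tx_id %in% txs, , drop = FALSE]
}

.gene_region <- function(annotation, gene_id, what = c("cds", "utr5", "utr3",
                                                       "introns")) {
  what <- match.arg(what)
  txs <- annotation$transcripts$tx_id[annotation$transcripts$gene_id == gene_id]
  annotation[[what]][annotation[[what]]$tx_id %in% txs, , drop = FALSE]
}
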