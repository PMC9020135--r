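#' @include translate.R classify.R
NULL

# Synthetic fixture generation: a toy two-chromosome genome carrying genes
# engineered so that each novel transcript's longest six-frame ORF contains
# exactly one planted tryptic peptide whose genomic placement realises one
# event category unambiguously. Every random draw happens inside a
# verification loop, so the guarantees hold for any seed.

.event_categories <- c("EXON_SKIPPING", "JUNCTIONAL_VARIATION",
                       "EXON_EXTENSION_OVERLAP", "EXON_EXTENSION_INTRONIC",
                       "UTR5", "UTR3", "FRAMESHIFT_NOVEL_FRAME",
                       "PSEUDOGENE", "LNCRNA", "NORF_INTERGENIC")

#' Fixture generation parameters
#'
#' @param seed Integer seed; identical seed implies byte-identical outputs.
#' @param events_per_category Number of planted events for each of the 10
#'   categories (scalar, or named vector over
#'   \code{\link{peptide_categories}} event names).
#' @param n_samples Clinical cohort size (>= 20).
#' @param hazard_ratio Planted hazard ratio between high- and low-expression
#'   groups of the effect peptide.
#' @param censoring_rate Expected fraction of censored samples in
#'   \code{[0, 1)}.
#' @param n_experiments Number of synthetic search experiments for PSM
#'   tables.
#' @param n_known_peptides Reference (known) peptides planted in PSM tables.
#' @param fraction_pass Fraction of novel peptides given a passing PepQuery
#'   result (p-value at most 0.01, zero modifications).
#' @param parent_effect Tie the survival effect to the effect peptide's
#'   parent gene as well (models the case where a peptide must be excluded
#'   because its parent gene is itself survival-associated).
#' @param n_null_peptides Additional no-effect peptide rows in the clinical
#'   expression matrix.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1L, events_per_category = 5L,
                         n_samples = 120L, hazard_ratio = 3,
                         censoring_rate = 0.2, n_experiments = 4L,
                         n_known_peptides = 30L, fraction_pass = 0.8,
                         parent_effect = FALSE, n_null_peptides = 20L) {
  if (is.null(names(events_per_category))) {
    stopifnot(length(events_per_category) == 1L)
    events <- stats::setNames(rep(as.integer(events_per_category),
                                  length(.event_categories)),
                              .event_categories)
  } else {
    stopifnot(all(names(events_per_category) %in% .event_categories))
    events <- stats::setNames(rep(0L, length(.event_categories)),
                              .event_categories)
    events[names(events_per_category)] <- as.integer(events_per_category)
  }
  if (n_samples < 20L) stop("n_samples must be >= 20", call. = FALSE)
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), events = events,
                 n_samples = as.integer(n_samples),
                 hazard_ratio = hazard_ratio,
                 censoring_rate = censoring_rate,
                 n_experiments = as.integer(n_experiments),
                 n_known_peptides = as.integer(n_known_peptides),
                 fraction_pass = fraction_pass,
                 parent_effect = isTRUE(parent_effect),
                 n_null_peptides = as.integer(n_null_peptides)),
            class = "fixture_spec")
}

# --- low-level sequence draws --------------------------------------------

.stop_codons <- c("TAA", "TAG", "TGA")
.all_codons <- names(.codon_table)
.nonstop_codons <- setdiff(.all_codons, .stop_codons)
# codons by encoded amino acid, for degenerate re-draws
.codons_by_aa <- split(names(.codon_table), unname(.codon_table))
.pep_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "M", "N", "Q", "S",
                   "T", "V", "W", "Y")  # no K/R (tryptic ends), I/L, P

.rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
.rand_codons <- function(n, exclude_aa = character(0)) {
  pool <- .nonstop_codons
  if (length(exclude_aa)) {
    pool <- pool[!.codon_table[pool] %in% exclude_aa]
  }
  paste(sample(pool, n, replace = TRUE), collapse = "")
}
.codons_for <- function(aa) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(a) {
    opts <- .codons_by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}
.rand_peptide <- function(len = 10L) {
  paste0(paste(sample(.pep_alphabet, len - 1L, replace = TRUE),
               collapse = ""), "K")
}
.k_codon <- function() sample(c("AAA", "AAG"), 1L)

# verify that the designed peptide is the unique, tryptic payload of the
# transcript's longest six-frame ORF
.orf_carries_peptide <- function(tx_seq, peptide) {
  orf <- suppressWarnings(
    extract_longest_orf(translate_six_frames(tx_seq), "chk"))
  if (is.null(orf)) return(NULL)
  hits <- gregexpr(peptide, orf$aa_sequence, fixed = TRUE)[[1]]
  if (length(hits) != 1L || hits[1] == -1L) return(NULL)
  pos <- hits[1]
  prev_ok <- pos == 1L ||
    substr(orf$aa_sequence, pos - 1L, pos - 1L) %in% c("K", "R")
  if (!prev_ok) return(NULL)
  if (!peptide %in% digest_tryptic(orf$aa_sequence)) return(NULL)
  orf
}

# --- locus designers ------------------------------------------------------
# Each returns NULL on a failed draw (caller retries) or a list:
#   seq          locus nucleotide sequence
#   features     relative-coordinate feature df (type, start, end, phase)
#   tx_blocks    relative novel-transcript blocks (matrix)
#   peptide      planted peptide
#   pep_blocks   relative genomic blocks of the peptide (matrix)
#   protein      annotated protein (coding genes; NULL otherwise)
#   biotype      gene biotype or NA (intergenic)

.coding_features <- function(u5, cds1, i1, cds2, i2, cds3, u3) {
  e1 <- u5 + cds1
  e2s <- e1 + i1
  e2e <- e2s + cds2
  e3s <- e2e + i2
  e3e <- e3s + cds3 + 3L + u3
  data.frame(
    type = c("gene", "mRNA", "exon", "exon", "exon", "CDS", "CDS", "CDS"),
    start = c(0L, 0L, 0L, e2s, e3s, u5, e2s, e3s),
    end = c(e3e, e3e, e1, e2e, e3e, e1, e2e, e3s + cds3 + 3L),
    phase = c(NA, NA, NA, NA, NA, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

.design_exon_skipping <- function(peptide) {
  u5 <- .rand_codons(14L)                       # 42 nt, stop-free
  pc <- .codons_for(peptide)
  cds1 <- paste0(.rand_codons(12L), .k_codon(), substr(pc, 1L, 15L))
  cds2 <- .rand_codons(10L)
  cds3 <- paste0(substr(pc, 16L, 30L),
                 .rand_codons(1L, exclude_aa = "P"), .rand_codons(9L))
  u3 <- .rand_codons(10L)
  i1 <- .rand_nt(123L); i2 <- .rand_nt(135L)
  f <- .coding_features(42L, nchar(cds1), nchar(i1), nchar(cds2), nchar(i2),
                        nchar(cds3), nchar(u3))
  seqs <- paste0(u5, cds1, i1, cds2, i2, cds3, "TAA", u3)
  e1 <- 42L + nchar(cds1)
  e3s <- f$start[5L]
  tx_blocks <- rbind(c(0L, e1), c(e3s, f$end[5L]))
  tx_seq <- paste0(substr(seqs, 1L, e1), substr(seqs, e3s + 1L, f$end[5L]))
  if (is.null(.orf_carries_peptide(tx_seq, peptide))) return(NULL)
  list(seq = seqs, features = f, tx_blocks = tx_blocks, peptide = peptide,
       pep_blocks = rbind(c(e1 - 15L, e1), c(e3s, e3s + 15L)),
       protein = .translate_frame(paste0(cds1, cds2, cds3), 0L),
       biotype = "protein_coding")
}

.design_junctional <- function(peptide) {
  u5 <- .rand_codons(14L)
  pc <- .codons_for(peptide)
  cds1 <- paste0(.rand_codons(12L), .k_codon(), substr(pc, 1L, 15L),
                 .rand_codons(3L))              # last 9 nt skipped by the tx
  cds2 <- paste0(substr(pc, 16L, 30L),
                 .rand_codons(1L, exclude_aa = "P"), .rand_codons(9L))
  cds3 <- .rand_codons(6L)
  u3 <- .rand_codons(10L)
  i1 <- .rand_nt(123L); i2 <- .rand_nt(135L)
  f <- .coding_features(42L, nchar(cds1), nchar(i1), nchar(cds2), nchar(i2),
                        nchar(cds3), nchar(u3))
  seqs <- paste0(u5, cds1, i1, cds2, i2, cds3, "TAA", u3)
  e1 <- 42L + nchar(cds1)
  j <- e1 - 9L
  e2s <- f$start[4L]; e2e <- f$end[4L]
  tx_blocks <- rbind(c(0L, j), c(e2s, e2e))
  tx_seq <- paste0(substr(seqs, 1L, j), substr(seqs, e2s + 1L, e2e))
  if (is.null(.orf_carries_peptide(tx_seq, peptide))) return(NULL)
  list(seq = seqs, features = f, tx_blocks = tx_blocks, peptide = peptide,
       pep_blocks = rbind(c(j - 15L, j), c(e2s, e2s + 15L)),
       protein = .translate_frame(paste0(cds1, cds2, cds3), 0L),
       biotype = "protein_coding")
}

.design_extension_overlap <- function(peptide) {
  u5 <- .rand_codons(14L)
  pc <- .codons_for(peptide)
  cds1 <- paste0(.rand_codons(12L), .k_codon(), substr(pc, 1L, 15L))
  # intron 1 continues the reading frame: rest of the peptide, a non-proline
  # codon, then an in-frame stop
  i1 <- paste0(substr(pc, 16L, 30L), .rand_codons(1L, exclude_aa = "P"),
               "TAA", .rand_nt(99L))
  cds2 <- .rand_codons(10L)
  cds3 <- .rand_codons(8L)
  u3 <- .rand_codons(10L)
  i2 <- .rand_nt(135L)
  f <- .coding_features(42L, nchar(cds1), nchar(i1), nchar(cds2), nchar(i2),
                        nchar(cds3), nchar(u3))
  seqs <- paste0(u5, cds1, i1, cds2, i2, cds3, "TAA", u3)
  e1 <- 42L + nchar(cds1)
  tx_blocks <- rbind(c(0L, e1 + 33L))
  tx_seq <- substr(seqs, 1L, e1 + 33L)
  if (is.null(.orf_carries_peptide(tx_seq, peptide))) return(NULL)
  list(seq = seqs, features = f, tx_blocks = tx_blocks, peptide = peptide,
       pep_blocks = rbind(c(e1 - 15L, e1 + 15L)),
       protein = .translate_frame(paste0(cds1, cds2, cds3), 0L),
       biotype = "protein_coding")
}

.design_retained_intron <- function(peptide) {
  u5 <- .rand_codons(14L)
  pc <- .codons_for(peptide)
  cds1 <- .rand_codons(15L)
  # intron 1 is frame-aligned and stop-free so the retained-intron transcript
  # translates straight through it
  i1 <- paste0(.rand_codons(3L), .k_codon(), pc,
               .rand_codons(1L, exclude_aa = "P"), .rand_codons(25L))
  cds2 <- .rand_codons(15L)
  cds3 <- .rand_codons(8L)
  u3 <- .rand_codons(10L)
  i2 <- .rand_nt(135L)
  f <- .coding_features(42L, nchar(cds1), nchar(i1), nchar(cds2), nchar(i2),
                        nchar(cds3), nchar(u3))
  seqs <- paste0(u5, cds1, i1, cds2, i2, cds3, "TAA", u3)
  e1 <- 42L + nchar(cds1)
  e2e <- f$end[4L]
  tx_blocks <- rbind(c(0L, e2e))                # E1 + intron1 + E2, contiguous
  tx_seq <- substr(seqs, 1L, e2e)
  if (is.null(.orf_carries_peptide(tx_seq, peptide))) return(NULL)
  list(seq = seqs, features = f, tx_blocks = tx_blocks, peptide = peptide,
       pep_blocks = rbind(c(e1 + 12L, e1 + 42L)),
       protein = .translate_frame(paste0(cds1, cds2, cds3), 0L),
       biotype = "protein_coding")
}

.design_utr5 <- function(peptide) {
  pc <- .codons_for(peptide)
  # upstream in-frame extension: the 5' UTR reads through into the CDS with
  # no intervening stop (and no upstream methionine requirement)
  u5 <- paste0(.rand_codons(1L), .k_codon(), pc,
               .rand_codons(1L, exclude_aa = "P"), .rand_codons(1L))
  cds1 <- .rand_codons(15L)
  cds2 <- .rand_codons(15L)
  cds3 <- .rand_codons(8L)
  u3 <- .rand_codons(10L)
  i1 <- .rand_nt(123L); i2 <- .rand_nt(135L)
  f <- .coding_features(nchar(u5), nchar(cds1), nchar(i1), nchar(cds2),
                        nchar(i2), nchar(cds3), nchar(u3))
  seqs <- paste0(u5, cds1, i1, cds2, i2, cds3, "TAA", u3)
  e1 <- nchar(u5) + nchar(cds1)
  tx_blocks <- rbind(c(0L, e1))
  tx_seq <- substr(seqs, 1L, e1)
  if (is.null(.orf_carries_peptide(tx_seq, peptide))) return(NULL)
  list(seq = seqs, features = f, tx_blocks = tx_blocks, peptide = peptide,
       pep_blocks = rbind(c(6L, 36L)),
       protein = .translate_frame(paste0(cds1, cds2, cds3), 0L),
       biotype = "protein_coding")
}

.design_utr3 <- function(peptide) {
  u5 <- .rand_codons(14L)
  pc <- .codons_for(peptide)
  cds1 <- .rand_codons(15L)
  cds2 <- .rand_codons(15L)
  cds3 <- .rand_codons(3L)                      # short: the 3' UTR ORF wins
  u3 <- paste0(.rand_codons(1L), .k_codon(), pc,
               .rand_codons(1L, exclude_aa = "P"), .rand_codons(7L))
  i1 <- .rand_nt(123L); i2 <- .rand_nt(135L)
  f <- .coding_features(42L, nchar(cds1), nchar(i1), nchar(cds2), nchar(i2),
                        nchar(cds3), nchar(u3))
  seqs <- paste0(u5, cds1, i1, cds2, i2, cds3, "TAA", u3)
  e3s <- f$start[5L]; e3e <- f$end[5L]
  tx_blocks <- rbind(c(e3s, e3e))
  tx_seq <- substr(seqs, e3s + 1L, e3e)
  if (is.null(.orf_carries_peptide(tx_seq, peptide))) return(NULL)
  cds3_end <- nchar(cds3) + 3L                  # relative to E3 start
  list(seq = seqs, features = f, tx_blocks = tx_blocks, peptide = peptide,
       pep_blocks = rbind(c(e3s + cds3_end + 6L, e3s + cds3_end + 36L)),
       protein = .translate_frame(paste0(cds1, cds2, cds3), 0L),
       biotype = "protein_coding")
}

.design_frameshift <- function(peptide) {
  u5 <- .rand_codons(14L)
  cds1 <- .rand_codons(15L)
  pc <- .codons_for(peptide)
  # cds2 carries the peptide one base out of the coding frame; the in-frame
  # codons must still be stop-free (it is genuine CDS), which the caller's
  # retry loop enforces via the degenerate codon re-draws
  shifted <- paste0(.k_codon(), pc, .rand_codons(1L, exclude_aa = "P"),
                    .rand_codons(7L))           # 57 nt at offset 1
  cds2 <- paste0(substr(.rand_codons(1L), 1L, 1L), shifted,
                 .rand_nt(2L))                  # 60 nt
  in_frame_codons <- substring(cds2, seq(1L, 58L, 3L), seq(3L, 60L, 3L))
  if (any(in_frame_codons %in% .stop_codons)) return(NULL)
  cds3 <- .rand_codons(8L)
  u3 <- .rand_codons(10L)
  i1 <- .rand_nt(123L)
  # intron 2: immediate in-frame stop (ends the annotated-frame ORF) while
  # the shifted frame continues stop-free
  i2_shift <- .rand_codons(10L)
  i2 <- paste0("TAA", substr(i2_shift, 3L, 30L), .rand_nt(107L))
  shifted_i2 <- substring(i2, seq(2L, 29L, 3L), seq(4L, 31L, 3L))
  if (any(shifted_i2 %in% .stop_codons)) return(NULL)
  f <- .coding_features(42L, nchar(cds1), nchar(i1), nchar(cds2), nchar(i2),
                        nchar(cds3), nchar(u3))
  seqs <- paste0(u5, cds1, i1, cds2, i2, cds3, "TAA", u3)
  e2s <- f$start[4L]; e2e <- f$end[4L]
  tx_blocks <- rbind(c(e2s + 1L, e2e + 33L))
  tx_seq <- substr(seqs, e2s + 2L, e2e + 33L)
  orf <- .orf_carries_peptide(tx_seq, peptide)
  if (is.null(orf) || orf$frame != 1L) return(NULL)
  list(seq = seqs, features = f, tx_blocks = tx_blocks, peptide = peptide,
       pep_blocks = rbind(c(e2s + 4L, e2s + 34L)),
       protein = .translate_frame(paste0(cds1, cds2, cds3), 0L),
       biotype = "protein_coding")
}

.design_noncoding <- function(peptide, biotype) {
  pc <- .codons_for(peptide)
  seqs <- paste0(.rand_codons(3L), .k_codon(), pc,
                 .rand_codons(1L, exclude_aa = "P"), .rand_codons(25L))
  n <- nchar(seqs)
  if (is.null(.orf_carries_peptide(seqs, peptide))) return(NULL)
  features <- if (is.na(biotype)) {
    data.frame(type = character(0), start = integer(0), end = integer(0),
               phase = integer(0), stringsAsFactors = FALSE)
  } else {
    data.frame(type = c("gene", "transcript", "exon"),
               start = c(0L, 0L, 0L), end = c(n, n, n),
               phase = c(NA, NA, NA), stringsAsFactors = FALSE)
  }
  list(seq = seqs, features = features, tx_blocks = rbind(c(0L, n)),
       peptide = peptide, pep_blocks = rbind(c(12L, 42L)),
       protein = NULL, biotype = biotype)
}

.design_locus <- function(category, peptide) {
  switch(category,
    EXON_SKIPPING = .design_exon_skipping(peptide),
    JUNCTIONAL_VARIATION = .design_junctional(peptide),
    EXON_EXTENSION_OVERLAP = .design_extension_overlap(peptide),
    EXON_EXTENSION_INTRONIC = .design_retained_intron(peptide),
    UTR5 = .design_utr5(peptide),
    UTR3 = .design_utr3(peptide),
    FRAMESHIFT_NOVEL_FRAME = .design_frameshift(peptide),
    PSEUDOGENE = .design_noncoding(peptide, "pseudogene"),
    LNCRNA = .design_noncoding(peptide, "lncRNA"),
    NORF_INTERGENIC = .design_noncoding(peptide, NA_character_)
  )
}

# --- genome assembly ------------------------------------------------------

#' Generate a toy genome with engineered event genes and its annotation
#'
#' Lays out one gene locus per requested event (round-robin over two
#' chromosomes, separated by random spacers), writes valid multi-exon coding
#' genes (CDS length divisible by 3, no internal stop), pseudogene/lncRNA
#' loci and bare intergenic ORF regions, and records the planted novel
#' peptide of every locus with its true category and genomic blocks.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @return A list of class \code{fixture_genome}: \code{genome} (named
#'   character vector of chromosome sequences), \code{gff} (GFF3 feature
#'   data.frame, 1-based inclusive), \code{ground_truth} (data.frame:
#'   peptide, category, top_level, gene_id, tx_id, chrom, strand, blocks),
#'   \code{tx_design} (named list of per-transcript alignment blocks),
#'   \code{reference} (named character vector of annotated protein
#'   sequences), and the \code{spec}.
#' @export
generate_genome_and_annotation <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  for (attempt in 0:19) {
    set.seed((spec$seed + attempt * 7919L) %% .Machine$integer.max)
    fix <- .build_fixture_genome(spec)
    if (.fixture_peptides_ok(fix)) {
      fix$spec <- spec
      class(fix) <- "fixture_genome"
      return(fix)
    }
  }
  stop("could not generate a consistent fixture genome", call. = FALSE)
}

.build_fixture_genome <- function(spec) {
  todo <- rep(names(spec$events), spec$events)
  chroms <- c("chr1", "chr2")
  cursor <- stats::setNames(c(0L, 0L), chroms)
  parts <- stats::setNames(list(character(0), character(0)), chroms)
  gff <- list(); truth <- list(); tx_design <- list(); reference <- c()
  gene_n <- 0L
  for (i in seq_along(todo)) {
    cat_i <- todo[i]
    loc <- NULL
    for (try in 1:500) {
      loc <- .design_locus(cat_i, .rand_peptide())
      if (!is.null(loc)) break
    }
    if (is.null(loc)) stop("locus design failed for ", cat_i, call. = FALSE)
    chrom <- chroms[(i - 1L) %% 2L + 1L]
    spacer <- .rand_nt(60L + 3L * sample.int(20L, 1L))
    offset <- cursor[[chrom]] + nchar(spacer)
    parts[[chrom]] <- c(parts[[chrom]], spacer, loc$seq)
    cursor[[chrom]] <- offset + nchar(loc$seq)
    gene_n <- gene_n + 1L
    gid <- sprintf("gene%02d", gene_n)
    tid <- sprintf("annot_tx%02d", gene_n)
    ntx <- sprintf("novel_tx%02d", gene_n)
    if (nrow(loc$features)) {
      f <- loc$features
      f$seqid <- chrom
      f$start <- f$start + offset
      f$end <- f$end + offset
      f$strand <- "+"
      f$gene_id <- gid
      f$tx_id <- tid
      f$biotype <- loc$biotype
      gff[[length(gff) + 1L]] <- f
    }
    if (!is.null(loc$protein)) reference[gid] <- loc$protein
    tx_design[[ntx]] <- list(chrom = chrom, strand = "+",
                             blocks = loc$tx_blocks + offset)
    truth[[length(truth) + 1L]] <- data.frame(
      peptide = loc$peptide, category = cat_i,
      top_level = unname(.category_top_level[cat_i]),
      gene_id = if (is.na(loc$biotype)) NA_character_ else gid,
      tx_id = ntx, chrom = chrom, strand = "+",
      blocks = paste(loc$pep_blocks[, 1L] + offset,
                     loc$pep_blocks[, 2L] + offset, sep = "-",
                     collapse = ","),
      stringsAsFactors = FALSE)
  }
  genome <- vapply(parts, function(p)
    paste0(paste(p, collapse = ""), .rand_nt(90L)), character(1))
  list(genome = genome, gff = do.call(rbind, gff),
       ground_truth = do.call(rbind, truth), tx_design = tx_design,
       reference = reference)
}

# planted peptides must be unique and absent (I/L-folded) from the
# annotated proteome, or the whole genome is redrawn
.fixture_peptides_ok <- function(fix) {
  peps <- fix$ground_truth$peptide
  if (anyDuplicated(peps)) return(FALSE)
  if (length(fix$reference) == 0L) return(TRUE)
  idx <- build_reference_index(unname(fix$reference), il_equivalent = TRUE)
  !any(is_known(idx, peps))
}

#' Write the fixture annotation as GFF3
#'
#' @param fix A \code{fixture_genome}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fixture_gff3 <- function(fix, path) {
  g <- fix$gff
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g))) {
    attrs <- switch(g$type[i],
      gene = sprintf("ID=%s;gene_biotype=%s", g$gene_id[i], g$biotype[i]),
      mRNA = ,
      transcript = sprintf("ID=%s;Parent=%s", g$tx_id[i], g$gene_id[i]),
      sprintf("Parent=%s", g$tx_id[i]))
    lines <- c(lines, paste(
      g$seqid[i], "novelpep", g$type[i], g$start[i] + 1L, g$end[i], ".",
      g$strand[i], ifelse(is.na(g$phase[i]), ".", g$phase[i]), attrs,
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Splice the event transcripts out of the fixture genome
#'
#' @param fix A \code{fixture_genome} from
#'   \code{\link{generate_genome_and_annotation}}.
#' @return Named list of \code{\link{assembled_transcript}} objects (one per
#'   planted event), sequences spliced from the genome through each design's
#'   alignment blocks.
#' @export
generate_event_transcripts <- function(fix) {
  out <- list()
  for (tid in names(fix$tx_design)) {
    d <- fix$tx_design[[tid]]
    chrom_seq <- fix$genome[[d$chrom]]
    seqs <- paste(vapply(seq_len(nrow(d$blocks)), function(k)
      substr(chrom_seq, d$blocks[k, 1L] + 1L, d$blocks[k, 2L]),
      character(1)), collapse = "")
    if (d$strand == "-") seqs <- revcomp(seqs)
    out[[tid]] <- assembled_transcript(tid, seqs, chrom = d$chrom,
                                       strand = d$strand, blocks = d$blocks)
  }
  out
}

#' Reference proteome entries for a fixture genome
#'
#' @param fix A \code{fixture_genome}.
#' @return List of \code{\link{protein_entry}} (source REFERENCE), one per
#'   annotated coding gene.
#' @export
fixture_reference_proteome <- function(fix) {
  mapply(function(id, seqs) protein_entry(paste0("ref_", id), "REFERENCE",
                                          seqs),
         names(fix$reference), unname(fix$reference),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# --- PSM / PepQuery tables ------------------------------------------------

#' Generate synthetic PSM and PepQuery tables
#'
#' Plants PSMs for a sample of known (reference tryptic) peptides and for
#' every novel fixture peptide, spread over experiments with 1-3 PSMs each
#' plus a few sub-threshold rows that an FDR filter must drop. PepQuery
#' results are drawn so that a fixed fraction of the novel peptides passes
#' the validation filter (p-value at most 0.01, zero modifications).
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param database Custom database entries from
#'   \code{\link{build_custom_database}}.
#' @param novel_peptides Character vector of planted novel peptides
#'   (fixture ground truth).
#' @return List with \code{psms} (PSM data.frame), \code{pepquery}
#'   (PepQuery data.frame), and \code{truth}: \code{known},
#'   \code{novel}, \code{pepquery_pass} peptide vectors.
#' @export
generate_psm_tables <- function(spec, database, novel_peptides) {
  set.seed((spec$seed + 1L) %% .Machine$integer.max)
  ref <- Filter(function(e) e$source == "REFERENCE", database)
  ref_peps <- unique(unlist(lapply(ref, function(e)
    digest_tryptic(e$aa_sequence))))
  n_known <- min(spec$n_known_peptides, length(ref_peps))
  known <- sample(ref_peps, n_known)
  exps <- sprintf("exp%02d", seq_len(spec$n_experiments))
  rows <- list()
  add_psms <- function(pep, conf_lo, conf_hi) {
    in_exps <- sample(exps, sample.int(min(2L, length(exps)), 1L))
    for (e in in_exps) {
      for (k in seq_len(sample.int(3L, 1L))) {
        rows[[length(rows) + 1L]] <<- data.frame(
          peptide = pep, experiment_id = e,
          spectrum_id = sprintf("%s.scan%05d", e, sample.int(99999L, 1L)),
          confidence = round(stats::runif(1, conf_lo, conf_hi), 5),
          protein_ids = "", stringsAsFactors = FALSE)
      }
    }
  }
  for (p in known) add_psms(p, 0.992, 1)
  for (p in novel_peptides) add_psms(p, 0.992, 1)
  # sub-threshold rows that a 1% FDR filter must drop
  for (p in sample(ref_peps, min(5L, length(ref_peps)))) add_psms(p, 0, 0.9)
  psms <- do.call(rbind, rows)
  psms <- psms[sample.int(nrow(psms)), , drop = FALSE]
  row.names(psms) <- NULL

  n_pass <- round(spec$fraction_pass * length(novel_peptides))
  pass <- novel_peptides[seq_len(n_pass)]
  pq <- do.call(rbind, lapply(novel_peptides, function(p) {
    ok <- p %in% pass
    data.frame(
      peptide = p, spectrum = sprintf("pq.%s", p),
      hyperscore = round(stats::runif(1, 10, 60), 2),
      p_value = if (ok) round(stats::runif(1, 0.0002, 0.01), 5) else
        round(stats::runif(1, 0.02, 0.8), 5),
      n_ptm = if (ok) 0L else sample(0:2, 1L),
      stringsAsFactors = FALSE)
  }))
  list(psms = psms, pepquery = pq,
       truth = list(known = known, novel = novel_peptides,
                    pepquery_pass = pass))
}

# --- clinical cohort ------------------------------------------------------

#' Generate a synthetic clinical cohort with a planted survival effect
#'
#' Survival times are exponential; samples in the high-expression half of
#' the effect peptide have their hazard multiplied by the spec's hazard
#' ratio. Censoring times are independent exponentials calibrated so that
#' roughly \code{censoring_rate} of baseline samples are censored. Subtypes
#' are assigned round-robin. The effect peptide's parent gene gets
#' independent (no-effect) expression unless \code{parent_effect} is set.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param effect_peptide Name for the effect peptide row.
#' @param effect_gene Name for its parent gene row.
#' @param null_peptides Optional character vector of extra no-effect peptide
#'   row names (defaults to \code{spec$n_null_peptides} generated names).
#' @return List with \code{coverage} (peptide x sample mean-coverage
#'   matrix), \code{library_sizes}, \code{cpm}, \code{parent_cpm} (gene x
#'   sample), \code{clinical} (sample_id, subtype, time_days, event),
#'   \code{peptide_gene} (named map), and \code{truth} (effect peptide/gene
#'   and the planted high-expression group).
#' @export
generate_clinical_cohort <- function(spec, effect_peptide = "PEP_EFFECT",
                                     effect_gene = "GENE_EFFECT",
                                     null_peptides = NULL) {
  set.seed((spec$seed + 2L) %% .Machine$integer.max)
  n <- spec$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  subtypes <- rep(c("basal", "luminal A", "luminal B", "HER2-enriched"),
                  length.out = n)
  if (is.null(null_peptides)) {
    null_peptides <- sprintf("PEP_NULL%02d", seq_len(spec$n_null_peptides))
  }
  grp <- sample(rep(c(0L, 1L), length.out = n))
  base_rate <- 1 / 1000                          # median ~ 700 days
  rate <- base_rate * spec$hazard_ratio^grp
  t_event <- stats::rexp(n, rate)
  if (spec$censoring_rate > 0) {
    c_rate <- base_rate * spec$censoring_rate / (1 - spec$censoring_rate)
    t_cens <- stats::rexp(n, c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- round(pmin(t_event, t_cens), 1)
  event <- as.integer(t_event <= t_cens)
  clinical <- data.frame(sample_id = ids, subtype = subtypes,
                         time_days = time, event = event,
                         stringsAsFactors = FALSE)
  lib <- round(stats::runif(n, 8e6, 1.2e7))
  names(lib) <- ids
  peps <- c(effect_peptide, null_peptides)
  coverage <- matrix(stats::rlnorm(length(peps) * n, meanlog = 2.5,
                                   sdlog = 0.4),
                     nrow = length(peps), dimnames = list(peps, ids))
  coverage[effect_peptide, ] <- 8 + 40 * grp + stats::runif(n, 0, 2)
  genes <- c(effect_gene, sprintf("GENE_NULL%02d", seq_along(null_peptides)))
  parent_cov <- matrix(stats::rlnorm(length(genes) * n, meanlog = 3,
                                     sdlog = 0.4),
                       nrow = length(genes), dimnames = list(genes, ids))
  if (spec$parent_effect) {
    parent_cov[effect_gene, ] <- 8 + 40 * grp + stats::runif(n, 0, 2)
  }
  peptide_gene <- stats::setNames(genes, peps)
  list(coverage = coverage, library_sizes = lib,
       cpm = coverage_to_cpm(coverage, lib),
       parent_cpm = coverage_to_cpm(parent_cov, lib),
       clinical = clinical, peptide_gene = peptide_gene,
       truth = list(effect_peptide = effect_peptide,
                    effect_gene = effect_gene, high_group = ids[grp == 1L]))
}

# --- on-disk emission -----------------------------------------------------

#' Write a complete fixture set to a directory
#'
#' Emits genome FASTA, GFF3 annotation, transcript FASTA + BED12, reference
#' proteome FASTA, PSM and PepQuery TSVs, coverage/library-size/clinical
#' TSVs and a ground-truth JSON — everything the pipeline stages consume.
#' Identical spec (including seed) produces byte-identical files.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly; the fixture objects as an
#'   attribute-free list (\code{fix}, \code{transcripts}, \code{tables},
#'   \code{cohort}).
#' @export
simulate_fixtures <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fix <- generate_genome_and_annotation(spec)
  txs <- generate_event_transcripts(fix)
  ref <- fixture_reference_proteome(fix)

  gfa <- Biostrings::DNAStringSet(fix$genome)
  Biostrings::writeXStringSet(gfa, file.path(dir, "genome.fa"))
  write_fixture_gff3(fix, file.path(dir, "genes.gff3"))
  tfa <- Biostrings::DNAStringSet(vapply(txs, `[[`, character(1),
                                         "sequence"))
  names(tfa) <- names(txs)
  Biostrings::writeXStringSet(tfa, file.path(dir, "transcripts.fa"))
  bed <- data.frame(
    peptide = names(txs),
    chrom = vapply(txs, function(t) t$alignment$chrom, character(1)),
    strand = vapply(txs, function(t) t$alignment$strand, character(1)),
    blocks = vapply(txs, function(t)
      paste(t$alignment$blocks[, 1L], t$alignment$blocks[, 2L], sep = "-",
            collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  write_bed(bed, file.path(dir, "transcripts.bed12"))
  write_database_fasta(ref, file.path(dir, "reference.fa"))

  db <- build_custom_database(unname(txs), ref)
  tables <- generate_psm_tables(spec, db, fix$ground_truth$peptide)
  utils::write.table(tables$psms, file.path(dir, "psms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tables$pepquery, file.path(dir, "pepquery.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cohort <- generate_clinical_cohort(spec)
  cov_df <- data.frame(peptide = rownames(cohort$coverage),
                       cohort$coverage, check.names = FALSE)
  utils::write.table(cov_df, file.path(dir, "coverage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(cohort$library_sizes),
                                library_size = unname(cohort$library_sizes)),
                     file.path(dir, "library_sizes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(ground_truth = fix$ground_truth,
         psm_truth = tables$truth,
         clinical_truth = cohort$truth),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(list(dir = dir, fix = fix, transcripts = txs, tables = tables,
                 cohort = cohort))
}
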