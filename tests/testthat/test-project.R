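make_orf <- function(frame, tx_nt_start, aa) {
  structure(list(transcript_id = "t", frame = frame,
                 tx_nt_start = tx_nt_start,
                 tx_nt_end = tx_nt_start + 3L * nchar(aa),
                 aa_sequence = aa),
            class = "translated_orf")
}

test_that("projection maps a peptide across a splice junction", {
  # transcript of 120 nt over two plus-strand blocks; ORF starts at nt 10
  set.seed(41)
  seqs <- random_dna(120)
  tx <- assembled_transcript("t", seqs, "chr1", "+",
                             rbind(c(100, 160), c(300, 360)))
  aa <- paste(rep("A", 30), collapse = "")
  orf <- make_orf(1L, 10L, aa)
  pep <- paste(rep("A", 7), collapse = "")
  al <- project_peptide(15L, pep, orf, tx)
  expect_equal(al$chrom, "chr1")
  expect_equal(al$strand, "+")
  expect_equal(unname(al$blocks), rbind(c(155L, 160L), c(300L, 316L)),
               ignore_attr = TRUE)
})

test_that("a peptide inside one block projects to a single genomic block", {
  seqs <- random_dna(60)
  tx <- assembled_transcript("t", seqs, "chr1", "+", rbind(c(500, 560)))
  orf <- make_orf(1L, 0L, paste(rep("A", 20), collapse = ""))
  al <- project_peptide(2L, "AAAAA", orf, tx)
  expect_equal(nrow(al$blocks), 1L)
  expect_equal(unname(al$blocks[1, ]), c(506L, 521L))
})

test_that("projection validates the peptide against the ORF", {
  seqs <- random_dna(60)
  tx <- assembled_transcript("t", seqs, "chr1", "+", rbind(c(0, 60)))
  orf <- make_orf(1L, 0L, "AAAAACCCCC")
  expect_error(project_peptide(0L, "CCC", orf, tx), "stated ORF offset")
  tx_free <- assembled_transcript("t", seqs)
  expect_error(project_peptide(0L, "AAA", orf, tx_free), "no genome alignment")
})

test_that("projection agrees base-by-base with the expansion oracle", {
  set.seed(42)
  for (rep in 1:60) {
    n_nt <- 3 * sample(40:120, 1)
    blocks <- random_alignment(n_nt)
    strand <- sample(c("+", "-"), 1)
    seqs <- random_dna(n_nt)
    tx <- assembled_transcript("t", seqs, "chr1", strand, blocks)
    tr <- translate_six_frames(seqs)
    orf <- suppressWarnings(extract_longest_orf(tr, "t"))
    if (is.null(orf) || nchar(orf$aa_sequence) < 4) next
    len <- sample(2:min(12, nchar(orf$aa_sequence)), 1)
    start <- sample(0:(nchar(orf$aa_sequence) - len), 1)
    pep <- substr(orf$aa_sequence, start + 1, start + len)
    # the peptide string may recur in the ORF; projection only needs offsets
    al <- project_peptide(start, pep, orf, tx)
    expect_equal(sum(al$blocks[, 2] - al$blocks[, 1]), 3 * len)
    # oracle: expand every transcript base to its genome position
    gpos <- oracle_tx_positions(blocks, strand)
    rs <- orf$tx_nt_start + 3 * start
    span <- (rs + 1):(rs + 3 * len)
    tx_fwd <- if (orf$frame > 0) span else (n_nt - span + 1)
    want <- sort(gpos[tx_fwd])
    got <- unlist(lapply(seq_len(nrow(al$blocks)), function(k)
      seq(al$blocks[k, 1], al$blocks[k, 2] - 1)))
    expect_equal(got, want)
    # strand of the coding sequence on the genome
    expect_equal(al$strand,
                 if ((strand == "+") == (orf$frame > 0)) "+" else "-")
  }
})

test_that("multi-locus peptides are removed, isoform duplicates collapse", {
  a1 <- structure(list(peptide = "AAAK", chrom = "chr1", strand = "+",
                       blocks = rbind(c(100L, 112L)),
                       source_transcript_id = "t1", orf_frame = 1L),
                  class = "peptide_alignment")
  a2 <- a1; a2$source_transcript_id <- "t2"   # same locus via an isoform
  b2 <- a1; b2$chrom <- "chr5"; b2$source_transcript_id <- "t3"
  res <- remove_multimapped(list(a1, a2))
  expect_length(res$kept, 1L)
  expect_length(res$removed, 0L)
  res2 <- remove_multimapped(list(a1, a2, b2))
  expect_equal(res2$removed, "AAAK")
  expect_length(res2$kept, 0L)
})

test_that("a peptide planted at two paralogous loci is removed", {
  u <- shared_fixture()
  gt <- u$fix$ground_truth
  pep <- gt$peptide[1]
  aligns <- locate_peptides(pep, u$db, u$txs)
  fake <- aligns[[1]]
  fake$blocks <- fake$blocks + 5000L
  res <- remove_multimapped(c(aligns, list(fake)))
  expect_true(pep %in% res$removed)
  # all genuinely single-locus fixture peptides survive
  all_aligns <- locate_peptides(gt$peptide, u$db, u$txs)
  keep <- remove_multimapped(all_aligns)
  expect_length(keep$kept, nrow(gt))
  expect_length(keep$removed, 0L)
})
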